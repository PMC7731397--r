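cultivar,viable,nonviable,total
Leehyunglim,72,528,600
Sambaechea,116,484,600
Choiganggul,453,147,600
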