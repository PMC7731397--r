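#' Bundled reference tables
#'
#' Two small plain-text reference inputs ship with the package:
#' `reference_germination_counts()` returns a published germination-test
#' count table for three watermelon cultivars (600 seeds each; viable vs.
#' nonviable/abnormal), used to exercise the germination-rate arithmetic.
#' `reference_selection_names()` returns the 48 feature names of a published
#' LDA seed-viability model selected by sequential forward selection, used to
#' exercise the selection-composition parser (42 LBP, 2 Gabor, 3 Fourier and
#' 1 intensity feature across the three enhancement sets).
#'
#' @return A data.frame of counts, or a character vector of 48 names.
#' @export
reference_germination_counts <- function() {
  utils::read.csv(system.file("extdata", "germination_counts.csv",
                              package = "seedxray"), stringsAsFactors = FALSE)
}

#' @rdname reference_germination_counts
#' @export
reference_selection_names <- function() {
  readLines(system.file("extdata", "selected_features_48.txt",
                        package = "seedxray"))
}
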