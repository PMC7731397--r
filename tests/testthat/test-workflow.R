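test_that("germination arithmetic reproduces the reference rates with half-up rounding", {
  counts <- reference_germination_counts()
  out <- germination_summary(counts)
  rates <- setNames(out$germination_rate, out$cultivar)
  expect_identical(unname(rates["Leehyunglim"]), 12)
  expect_identical(unname(rates["Sambaechea"]), 19)
  expect_identical(unname(rates["Choiganggul"]), 76)
  expect_identical(unname(rates["Overall"]), 36)
  expect_identical(out$total[out$cultivar == "Overall"], 1800L)

  zero <- germination_summary(data.frame(cultivar = "z", viable = 0, nonviable = 10))
  expect_identical(zero$germination_rate[1], 0)
  expect_error(germination_summary(data.frame(cultivar = "z", viable = 0,
                                              nonviable = 0)), "positive")
  expect_error(germination_summary(data.frame(cultivar = "z", viable = 2,
                                              nonviable = 2, total = 5)), "total")
})

test_that("round-half-up matches the printed-precision convention", {
  expect_identical(round_half_up(75.5), 76)
  expect_identical(round_half_up(12.0), 12)
  expect_identical(round_half_up(20.833, 1), 20.8)
  expect_identical(round_half_up(39.583, 1), 39.6)
  expect_identical(round_half_up(87.5, 1), 87.5)
})

# a single small pipeline run shared by the workflow tests
pipeline_fixture <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      cfg <- run_config(n_per_class = 12, cultivars = "cv1", image_size = 96,
                        max_k = 3, candidate_pool = 8, folds = 4, rng_seed = 2)
      dir <- file.path(tempdir(), "seedxray-run")
      res <<- list(cfg = cfg, dir = dir,
                   run = run_pipeline(cfg, out_dir = dir))
    }
    res
  }
})

test_that("the pipeline runs end to end and reports all three classifiers", {
  fx <- pipeline_fixture()
  run <- fx$run
  expect_s3_class(run, "pipeline_run")
  expect_identical(run$summary$classifier, c("LDA", "QDA", "KNN"))
  expect_true(all(run$summary$lci <= run$summary$mean &
                    run$summary$mean <= run$summary$uci))
  expect_length(run$reports, 3)
  expect_length(run$trace$cv_accuracy_at_step, 3)
  # artifacts traceable to the config hash
  files <- list.files(fx$dir)
  expect_true(any(grepl(paste0("^", run$config_hash, "_selection_trace"), files)))
  expect_true(any(grepl("accuracy_vs_k\\.csv$", files)))
  expect_true(any(grepl("model_archive\\.json$", files)))
})

test_that("rerunning the pipeline with the same config is bit-identical", {
  fx <- pipeline_fixture()
  run2 <- run_pipeline(fx$cfg)
  expect_identical(fx$run$trace$features, run2$trace$features)
  expect_identical(fx$run$trace$cv_accuracy_at_step, run2$trace$cv_accuracy_at_step)
  expect_identical(fx$run$summary, run2$summary)
})

test_that("archived models predict new images, tolerating missing files", {
  fx <- pipeline_fixture()
  imgs <- generate_dataset(fx$cfg$n_per_class, fx$cfg$cultivars,
                           rng_seed = fx$cfg$rng_seed,
                           size = fx$cfg$image_size)$images
  sub <- imgs[c(1, 2, 13, 14)]
  res <- predict_new(fx$run$archive, sub)
  expect_identical(nrow(res), 4L)
  expect_true(all(is.na(res$error)))
  truth <- vapply(sub, `[[`, character(1), "label")
  expect_gte(mean(res$class == truth), 0.75)

  # archive JSON round trip via the written artifact
  path <- list.files(fx$dir, pattern = "model_archive\\.json$", full.names = TRUE)[1]
  res2 <- predict_new(path, sub[1:2])
  expect_identical(res2$class, res$class[1:2])

  # a missing file yields a per-row error entry and the run continues
  res3 <- predict_new(fx$run$archive, list("no_such_file.png", sub[[1]]))
  expect_false(is.na(res3$error[1]))
  expect_true(is.na(res3$error[2]))
  expect_identical(res3$class[2], res$class[1])
})

test_that("run configurations round-trip through YAML", {
  cfg <- run_config(n_per_class = 7, cultivars = c("a", "b"), image_size = 128,
                    feature_config = feature_bank(lbp_radii = 1:3,
                                                  glcm_levels = 16L),
                    max_k = 5, candidate_pool = 20, folds = 3, rng_seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(unclass(back$feature_config)[names(unclass(cfg$feature_config))],
               unclass(cfg$feature_config))
  expect_identical(back$n_per_class, cfg$n_per_class)
  expect_identical(back$rng_seed, cfg$rng_seed)
  expect_identical(seedxray:::config_hash(back), seedxray:::config_hash(cfg))
})

test_that("the CLI driver script is present and wired to package functions", {
  cli <- system.file("exec", "seedxray", package = "seedxray")
  if (cli == "") cli <- file.path(system.file(package = "seedxray"), "exec", "seedxray")
  expect_true(file.exists(cli) || file.exists(sub("inst/", "", cli)))
  src <- readLines(cli)
  expect_true(any(grepl("library\\(seedxray\\)", src)))
  for (sub in c("simulate", "preprocess", "extract", "augment", "select",
                "predict", "report"))
    expect_true(any(grepl(sub, src, fixed = TRUE)))
})
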