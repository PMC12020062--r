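test_that("IQR filtering removes outliers with interpolated quartiles", {
  out <- iqr_filter_controls(c(10, 100, 102, 104, 106, 200))
  expect_equal(out$kept, c(100, 102, 104, 106))
  expect_equal(out$stats$q1, 100.5)
  expect_equal(out$stats$q3, 105.5)
  expect_equal(out$stats$iqr, 5)
  expect_equal(out$stats$n_before, 6L)
  expect_equal(out$stats$n_after, 4L)

  # degenerate spread: everything is kept
  same <- iqr_filter_controls(c(5, 5, 5, 5))
  expect_equal(same$kept, c(5, 5, 5, 5))
  one <- iqr_filter_controls(42)
  expect_equal(one$kept, 42)
  expect_equal(one$stats$sd, 0)
  expect_error(iqr_filter_controls(c(NA, NaN)), "finite")
})

test_that("injected control outliers are removed exactly when separated", {
  withr::with_seed(7, {
    for (i in 1:20) {
      # bounded control scatter, so no genuine control can cross the fence
      ctrl <- runif(30, 95, 105)
      outliers <- c(160, 40, 200)[seq_len(sample(3, 1))]
      out <- iqr_filter_controls(c(ctrl, outliers))
      expect_equal(sort(out$kept), sort(ctrl))
    }
  })
})

test_that("percent of control supports both conventions and they sum to 100", {
  expect_equal(percent_of_control(100, 100, "effect"), 100)
  expect_equal(percent_of_control(100, 100, "inhibition"), 0)
  expect_equal(percent_of_control(50, 100, "effect"), 50)
  expect_equal(percent_of_control(50, 100, "inhibition"), 50)
  expect_equal(percent_of_control(120, 100, "effect"), 120)
  expect_equal(percent_of_control(120, 100, "inhibition"), -20)
  expect_error(percent_of_control(1, 0), "zero")

  withr::with_seed(3, {
    v <- rnorm(200, 80, 30)
    expect_equal(percent_of_control(v, 75, "effect") +
                   percent_of_control(v, 75, "inhibition"),
                 rep(100, 200))
  })
})

test_that("0-h baseline correction subtracts by default, ratio on request", {
  expect_equal(baseline_correct_0h(105, 20), 85)
  expect_equal(baseline_correct_0h(20, 20), 0)
  expect_equal(baseline_correct_0h(105, 20, mode = "ratio"), 5.25)
  expect_error(baseline_correct_0h(1, NA_real_), "0-h")
  expect_error(baseline_correct_0h(1, 0, mode = "ratio"), "zero")
})

test_that("DAPI rules separate true cell death from focus failures", {
  # cell death: replicates are also near zero -> keep the zeros
  death <- clean_imaging_by_dapi(0, c(0, 1, 2, 0),
                                 c(H2AX = 10, `8OHG` = 12))
  expect_equal(death$dapi, 0)
  expect_equal(unname(death$associated), c(0, 0))

  # focus failure: replicates clearly populated -> everything missing
  fail <- clean_imaging_by_dapi(0, c(0, 120, 130, 110),
                                c(H2AX = 10, `8OHG` = 12))
  expect_true(is.na(fail$dapi))
  expect_true(all(is.na(fail$associated)))

  # a nonzero DAPI value is never converted
  ok <- clean_imaging_by_dapi(500, c(0, 0, 0, 0), c(H2AX = 3))
  expect_equal(ok$dapi, 500)
  expect_equal(ok$associated, c(H2AX = 3))
})

test_that("caspase values rescale for cell loss with a guarded denominator", {
  expect_equal(normalize_caspase(150, 40, 60), 300)
  expect_equal(normalize_caspase(88, 0, 0), 88)
  expect_warning(dead <- normalize_caspase(150, 100, 100), "all cells")
  expect_true(is.na(dead))
})

test_that("replicate aggregation ignores missing values", {
  camp <- make_campaign(n_materials = 3, seed = 51, noise_cv = 0.02)
  ds <- preprocess_campaign(ingest_campaign(camp$dir,
                                            camp$files$template_dir))
  agg <- ds$DAPI$aggregated
  expect_true(all(c("material_id", "dose_value", "value") %in% names(agg)))
  # one row per condition key
  expect_equal(nrow(agg), nrow(unique(agg[, c("material_id", "dose_value",
                                              "time_h", "cell_line",
                                              "serum")])))
  # direct checks of the aggregation statistic
  expect_equal(median(c(10, 20, 90)), 20)
  d <- ds$DAPI$data
  k <- d$material_id == agg$material_id[1] &
    d$dose_value == agg$dose_value[1] & d$time_h == agg$time_h[1]
  expect_equal(agg$value[1],
               median(d$normalized[k & d$role == agg$role[1]], na.rm = TRUE))
})

test_that("preprocessing is recorded in provenance and keeps layers aligned", {
  camp <- make_campaign(n_materials = 3, seed = 61, noise_cv = 0.02,
                        n_focus_failures = 1)
  ds <- preprocess_campaign(ingest_campaign(camp$dir,
                                            camp$files$template_dir))
  ops <- vapply(ds$CTG$provenance, `[[`, character(1), "op")
  expect_true(all(c("annotate_dataset", "baseline_correct_0h",
                    "percent_of_control", "aggregate_replicates") %in% ops))
  expect_true("normalized" %in% names(ds$CTG$data))
  expect_equal(length(ds$CTG$data$normalized), nrow(ds$CTG$data))
  # caspase normalization ran and was logged
  expect_true("normalize_caspase" %in%
                vapply(ds$CASP$provenance, `[[`, character(1), "op"))
})

test_that("cleaning NaNs match injected focus failures one to one", {
  camp <- make_campaign(n_materials = 5, seed = 71, noise_cv = 0.02,
                        n_focus_failures = 3)
  ds <- preprocess_campaign(ingest_campaign(camp$dir,
                                            camp$files$template_dir))
  n_inj <- nrow(camp$truth$artifacts$focus_failures)
  d <- ds$DAPI$data
  expect_equal(sum(is.na(d$normalized) & d$role != "blank"), n_inj)
  # the associated imaging endpoints lose the same wells
  h <- ds$H2AX$data
  expect_equal(sum(is.na(h$normalized) & h$role != "blank"), n_inj)
})
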