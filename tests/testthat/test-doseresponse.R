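test_that("first significant dose needs both threshold and test to pass", {
  withr::with_seed(5, {
    ctrl <- rnorm(24, 0, 1)
    ctrl <- (ctrl - median(ctrl)) / sd(ctrl)  # median 0, sd 1 exactly
    doses <- c(1, 2, 4, 8)
    make_series <- function(means, sd = 0.1) {
      sapply(1:4, function(r) means + rnorm(length(means), 0, sd))
    }
    eff <- make_series(c(0.5, 1.5, 8, 9))
    # mean must clear median + 2 (resp. + 3): first such dose is the 3rd,
    # where the Welch test is overwhelming
    expect_equal(first_significant_dose(doses, eff, ctrl, k = 2), 4)
    expect_equal(first_significant_dose(doses, eff, ctrl, k = 3), 4)

    # a flat series at control level has no significant dose
    flat <- make_series(rep(0, 4))
    expect_true(is.na(first_significant_dose(doses, flat, ctrl, k = 2)))

    # the stricter cutoff can only fire later (subset property)
    for (i in 1:100) {
      means <- sort(abs(rnorm(6, 2, 2)))
      eff_i <- sapply(1:4, function(r) means + rnorm(6, 0, 0.3))
      d6 <- c(1, 2, 4, 8, 16, 32)
      f2 <- first_significant_dose(d6, eff_i, ctrl, k = 2)
      f3 <- first_significant_dose(d6, eff_i, ctrl, k = 3)
      if (!is.na(f3)) {
        expect_false(is.na(f2))
        expect_gte(f3, f2)
      }
    }
  })
})

test_that("first significant dose degrades gracefully", {
  ctrl <- c(-1, -0.5, 0, 0.5, 1)
  expect_warning(
    out <- first_significant_dose(c(1, 2), matrix(c(5, 6), 2, 1), ctrl),
    "fewer than 2 replicate"
  )
  expect_true(is.na(out))
  expect_error(first_significant_dose(1, matrix(1:2, 1), c(0, NA)),
               "control")
})

test_that("AUC follows the thresholded trapezoid over log dose", {
  expect_equal(
    dose_response_auc(c(1, 10, 100, 1000), c(0, 5, 50, 80), threshold = 2),
    95
  )
  # everything under the threshold integrates to zero
  expect_equal(
    dose_response_auc(c(1, 10, 100), c(1, 1.5, 0.5), threshold = 2), 0
  )
  # linear in the effects when all are above threshold
  expect_equal(
    dose_response_auc(c(1, 10, 100, 1000), 2 * c(3, 5, 50, 80),
                      threshold = 2),
    2 * dose_response_auc(c(1, 10, 100, 1000), c(3, 5, 50, 80),
                          threshold = 2)
  )
  # dose 0 (controls) never contributes an x point
  expect_equal(
    dose_response_auc(c(0, 1, 10), c(99, 5, 50), threshold = 2),
    dose_response_auc(c(1, 10), c(5, 50), threshold = 2)
  )
  expect_warning(z <- dose_response_auc(1, 5, threshold = 0), "fewer than 2")
  expect_equal(z, 0)
})

test_that("AUC equals dense numeric integration of the interpolant", {
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      doses <- sort(exp(runif(n, log(0.5), log(500))))
      effects <- runif(n, 0, 120)
      thr <- runif(1, 0, 40)
      got <- dose_response_auc(doses, effects, threshold = thr)
      # oracle: zero sub-threshold values, then integrate the piecewise
      # linear interpolant on a dense grid
      y <- ifelse(effects < thr, 0, effects)
      x <- log10(doses)
      grid <- sort(unique(c(seq(min(x), max(x), length.out = 20001), x)))
      g <- approx(x, y, xout = grid)
      oracle <- sum(diff(g$x) * (head(g$y, -1) + tail(g$y, -1)) / 2)
      expect_equal(got, oracle, tolerance = 1e-6)
    }
  })
})

test_that("maximum effect is the median of per-replicate maxima", {
  eff <- cbind(c(10, 80, 30), c(20, 90, 10), c(5, 100, 50))
  expect_equal(max_effect(eff), 90)
  expect_equal(max_effect(matrix(c(1, 7, 3), ncol = 1)), 7)
  eff_na <- cbind(c(10, 80), c(NA, NA), c(20, 100))
  expect_equal(max_effect(eff_na), 90)
  expect_true(is.na(max_effect(matrix(NA_real_, 2, 2))))
})

test_that("the metrics table covers every condition once", {
  camp <- make_campaign(n_materials = 4, seed = 81, noise_cv = 0.02)
  ds <- preprocess_campaign(ingest_campaign(camp$dir,
                                            camp$files$template_dir))
  met <- metrics_table(ds)
  design <- camp$truth$design
  # endpoints x imaging times x serum conditions per material (CTG's 0-h
  # plates are baseline only)
  expect_equal(
    nrow(met),
    4 * length(design$endpoints) * length(design$times_imaging) *
      length(design$serum)
  )
  expect_false(any(met$time_h == 0))
  expect_equal(anyDuplicated(met[, 1:5]), 0L)

  # a potent material beats the inert one on every axis
  manifest <- truth_manifest(camp$truth)
  potent <- manifest$material_id[which.min(manifest$ec50)]
  inert <- manifest$material_id[manifest$emax == 0][1]
  mp <- met[met$material_id == potent & met$endpoint == "DAPI", ]
  mi <- met[met$material_id == inert & met$endpoint == "DAPI", ]
  expect_true(all(is.na(mi$first_sig_2sd)))
  expect_false(any(is.na(mp$first_sig_2sd)))
  expect_true(all(mp$auc > mi$auc))
  expect_true(all(mp$max_effect > mi$max_effect))

  # empty input gives an empty table with the right shape
  empty <- metrics_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("first_sig_2sd", "auc") %in% names(empty)))
})

test_that("first-significant doses track the generator's potency", {
  camp <- make_campaign(n_materials = 5, seed = 91, noise_cv = 0.01,
                        potency_gradient = TRUE)
  ds <- preprocess_campaign(ingest_campaign(camp$dir,
                                            camp$files$template_dir))
  met <- metrics_table(ds)
  m <- met[met$endpoint == "DAPI", ]
  fs <- tapply(m$first_sig_2sd, m$material_id, median, na.rm = TRUE)
  ord <- camp$truth$materials$ec50[match(names(fs),
                                         camp$truth$materials$material_id)]
  # lower EC50 -> first significant effect at a dose at least as low
  expect_true(all(diff(fs[order(ord)]) >= 0))
})
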