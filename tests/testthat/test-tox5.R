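test_that("metric transforms follow their closed forms", {
  expect_equal(transform_metric(1, "neglog10_plus6"), 6)
  expect_equal(transform_metric(256, "neglog10_plus6"), 6 - log10(256))
  expect_error(transform_metric(c(1, 0), "neglog10_plus6"), "positive")
  expect_equal(transform_metric(81, "sqrt"), 9)
  expect_equal(transform_metric(c(-4, 9), "sqrt"), c(0, 3))
  # Yeo-Johnson with lambda = 1 is the identity on x >= 0
  x <- c(0, 0.5, 2, 10)
  expect_equal(transform_metric(x, "yeo_johnson", lambda = 1), x)
  # estimated lambda agrees with the reference implementation
  withr::with_seed(2, {
    y <- exp(rnorm(50))
    lam <- unname(car::powerTransform(y, family = "yjPower")$lambda)
    expect_equal(transform_metric(y, "yeo_johnson"),
                 car::yjPower(y, lam))
  })
  # missing values pass through untouched
  expect_true(is.na(transform_metric(c(4, NA), "sqrt")[2]))
})

test_that("min-max scaling lands in [0,1] with documented degenerate cases", {
  expect_equal(minmax_scale_column(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scale_column(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(minmax_scale_column(c(1, NA, 3)), c(0, 0, 1))
  withr::with_seed(4, {
    v <- minmax_scale_column(rnorm(100))
    expect_true(all(v >= 0 & v <= 1))
  })
})

test_that("auto slicing groups the four metrics with the 50/16.67 weights", {
  eps <- c("CTG", "DAPI", "CASP", "H2AX", "8OHG")
  cols <- as.vector(outer(
    paste0(rep(eps, each = 3), "_", c(6, 24, 72), "h"),
    c("first_sig_2sd", "first_sig_3sd", "auc", "max_effect"),
    paste, sep = "_"
  ))
  slices <- build_slices(cols, mode = "auto")
  expect_length(slices, 15L)
  w <- slices[[1]]$metric_weights
  expect_equal(unname(w[grepl("first_sig_3sd", names(w))]), 0.5)
  expect_equal(unname(w[grepl("auc", names(w))]), 1 / 6)
  expect_equal(sum(w), 1)

  # manual slices pass through, bad weights are rejected
  man <- list(slice_spec("custom", cols[1], 1))
  expect_identical(build_slices(cols, "manual", slices = man), man)
  expect_error(slice_spec("bad", cols[1:2], c(0.6, 0.6)), "sum to 1")
  expect_error(build_slices(c("X_nonsense")), "parse")
})

test_that("scores combine slices as weighted means with competition ranks", {
  sc <- tibble::tibble(material_id = "M1", a_first_sig_3sd = 0.7)
  s1 <- list(slice_spec("a", "a_first_sig_3sd", 1))
  expect_equal(compute_scores(sc, s1)$total, 0.7)

  sc2 <- tibble::tibble(material_id = "M1",
                        a_first_sig_3sd = 0.5, a_first_sig_2sd = 0.2,
                        a_auc = 0.4, a_max_effect = 0.8)
  s2 <- build_slices(names(sc2)[-1], "auto")
  expect_equal(compute_scores(sc2, s2)$total,
               0.25 + (0.2 + 0.4 + 0.8) / 6)

  sc3 <- tibble::tibble(material_id = c("A", "B", "C"),
                        x_auc = c(0.9, 0.5, 0.9))
  s3 <- list(slice_spec("x", "x_auc", 1))
  expect_equal(compute_scores(sc3, s3)$rank, c(1L, 3L, 1L))
})

test_that("totals stay in [0,1] and rise monotonically with any metric", {
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(3:8, 1)
      sc <- tibble::tibble(
        material_id = paste0("M", 1:n),
        a_first_sig_2sd = runif(n), a_first_sig_3sd = runif(n),
        a_auc = runif(n), a_max_effect = runif(n),
        b_first_sig_2sd = runif(n), b_first_sig_3sd = runif(n),
        b_auc = runif(n), b_max_effect = runif(n)
      )
      slices <- build_slices(names(sc)[-1], "auto")
      base <- compute_scores(sc, slices)
      expect_true(all(base$total >= 0 & base$total <= 1))
      expect_true(all(as.matrix(base[, grep("^slice_", names(base))]) >= 0))

      # raise one random metric of one random material
      j <- sample(2:ncol(sc), 1)
      r <- sample(n, 1)
      sc2 <- sc
      sc2[[j]][r] <- min(1, sc[[j]][r] + 0.3)
      bumped <- compute_scores(sc2, slices)
      expect_gte(bumped$total[r], base$total[r])
      expect_true(all(bumped$total[-r] == base$total[-r]))
    }
  })
})

test_that("equal-weight single-metric slices reduce to the plain mean", {
  withr::with_seed(9, {
    sc <- tibble::tibble(material_id = paste0("M", 1:6),
                         a_auc = runif(6), b_auc = runif(6),
                         c_auc = runif(6))
    slices <- lapply(c("a_auc", "b_auc", "c_auc"),
                     function(cn) slice_spec(cn, cn, 1))
    got <- compute_scores(sc, slices)$total
    expect_equal(got, rowMeans(as.matrix(sc[, -1])))
  })
})

test_that("bootstrap intervals are deterministic and cover the estimate", {
  # identical rows: no resampling variance anywhere
  dup <- tibble::tibble(material_id = paste0("M", 1:4),
                        a_auc = rep(2, 4), a_max_effect = rep(5, 4))
  slices <- build_slices(c("a_auc", "a_max_effect"), "auto",
                         weight_rule = c(auc = 0.5, max_effect = 0.5))
  ci <- bootstrap_intervals(dup, slices, n_boot = 50, seed = 1)
  expect_true(all(ci$ci_high - ci$ci_low == 0))

  withr::with_seed(10, {
    trans <- tibble::tibble(material_id = paste0("M", 1:6),
                            a_auc = runif(6, 0, 10),
                            a_max_effect = runif(6, 0, 100))
  })
  ci1 <- bootstrap_intervals(trans, slices, n_boot = 100, seed = 7)
  ci2 <- bootstrap_intervals(trans, slices, n_boot = 100, seed = 7)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_intervals(trans, slices, n_boot = 100, seed = 8)
  expect_false(identical(ci1$ci_low, ci3$ci_low))

  expect_true(all(ci1$ci_low <= ci1$point + 1e-12))
  expect_true(all(ci1$ci_high >= ci1$point - 1e-12))
  expect_error(bootstrap_intervals(trans, slices, n_boot = 1), "n_boot")
})
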