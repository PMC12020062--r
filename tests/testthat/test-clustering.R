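two_blobs <- function(n_per = 5, gap = 10, sd = 0.05, seed = 2, p = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per),
               matrix(rnorm(n_per * p, gap, sd), n_per))
    rownames(x) <- paste0("M", seq_len(2 * n_per))
    x
  })
}

test_that("agglomeration is deterministic and recovers planted structure", {
  x <- rbind(c(1, 1), c(1, 1), c(5, 5))
  ag <- agglomerate(x, k = 2)
  expect_equal(ag$hclust$height[1], 0)     # identical rows merge at 0

  x2 <- two_blobs()
  lab <- agglomerate(x2, k = 2)$labels
  expect_equal(length(unique(lab[1:5])), 1L)
  expect_equal(length(unique(lab[6:10])), 1L)
  expect_false(lab[1] == lab[6])

  expect_error(agglomerate(x2, metric = "cosine", linkage = "ward"),
               "Euclidean")
  expect_error(agglomerate(x2[1, , drop = FALSE]), "at least 2")
})

test_that("single linkage on a 1-D chain merges by ascending gap (MST)", {
  pts <- matrix(c(0, 1, 3, 6, 10), ncol = 1)
  hc <- agglomerate(pts, linkage = "single")$hclust
  # the minimum-spanning-tree edges of a 1-D chain are the adjacent gaps
  gaps <- sort(diff(pts[, 1])) # brute-force MST of a path graph
  expect_equal(hc$height, gaps)
})

test_that("dendrogram heights are monotone for all four linkages", {
  withr::with_seed(6, {
    for (i in 1:10) {
      x <- matrix(rnorm(8 * 3), 8)
      for (lk in c("ward", "single", "complete", "average")) {
        h <- agglomerate(x, linkage = lk)$hclust$height
        expect_true(all(diff(h) >= -1e-12))
      }
    }
  })
})

test_that("elbow and silhouette both find clear cluster counts", {
  x2 <- two_blobs()
  expect_equal(choose_k(x2, "elbow"), 2L)
  expect_equal(choose_k(x2, "silhouette"), 2L)

  withr::with_seed(3, {
    x3 <- rbind(matrix(rnorm(12, 0, 0.05), 6),
                matrix(rnorm(12, 10, 0.05), 6),
                matrix(c(rnorm(6, 0, 0.05), rnorm(6, 10, 0.05)), 6))
  })
  expect_equal(choose_k(x3, "silhouette"), 3L)

  # degenerate data falls back to k = 2
  flat <- matrix(1, 6, 2)
  expect_equal(choose_k(flat, "elbow"), 2L)
  expect_equal(choose_k(flat, "silhouette"), 2L)
  expect_error(choose_k(x2[1:2, ]), "at least 3")
  expect_error(choose_k(x2, k_max = 10), "k_max")
})

test_that("quality indices match their textbook values on toys", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  q <- cluster_quality(x, c(1, 1, 2, 2))
  # silhouette of point 0: a = 0.1, b = (10 + 10.1)/2 = 10.05
  expect_equal(q$silhouette, 0.990, tolerance = 1e-3)
  expect_lt(q$davies_bouldin, 0.05)
  expect_gt(q$calinski_harabasz, 100)

  # random labels on a single blob have near-zero silhouette
  withr::with_seed(12, {
    blob <- matrix(rnorm(40), 20)
    qr <- cluster_quality(blob, sample(1:2, 20, replace = TRUE))
    expect_lt(abs(qr$silhouette), 0.1)
  })
})

test_that("quality indices agree with a brute-force implementation", {
  withr::with_seed(14, {
    x <- matrix(rnorm(10), 5)
    labels <- c(1, 1, 2, 2, 2)
  })
  q <- cluster_quality(x, labels)
  # brute force, index definitions written out longhand
  dmat <- as.matrix(dist(x))
  sil <- sapply(1:5, function(i) {
    own <- labels == labels[i]
    a <- mean(dmat[i, own & seq_len(5) != i])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dmat[i, labels == g])))
    (b - a) / max(a, b)
  })
  expect_equal(q$silhouette, mean(sil))
  cent <- sapply(sort(unique(labels)), function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  })
  s_i <- sapply(sort(unique(labels)), function(g) {
    mean(sqrt(colSums((t(x[labels == g, , drop = FALSE]) - cent[, g])^2)))
  })
  d12 <- sqrt(sum((cent[, 1] - cent[, 2])^2))
  expect_equal(q$davies_bouldin, mean(c((s_i[1] + s_i[2]) / d12,
                                        (s_i[1] + s_i[2]) / d12)))
  overall <- colMeans(x)
  bss <- sum(sapply(sort(unique(labels)), function(g) {
    sum(labels == g) * sum((cent[, g] - overall)^2)
  }))
  wss <- sum(sapply(1:5, function(i) sum((x[i, ] - cent[, labels[i]])^2)))
  expect_equal(q$calinski_harabasz, (bss / 1) / (wss / 3))
})

test_that("AU/BP fit reproduces its closed-form anchor points", {
  r <- seq(0.5, 1.4, by = 0.1)
  # BP_r = 0.5 everywhere: probit is 0, so v = c = 0 and AU = BP = 0.5
  fit <- au_bp_fit(rep(500, 10), r, 1000)
  expect_equal(fit$v, 0)
  expect_equal(fit$c, 0)
  expect_equal(fit$au, 0.5)
  expect_equal(fit$bp, 0.5)

  # a node recovered in every resample at every scale is fully supported
  fit1 <- au_bp_fit(rep(1000, 10), r, 1000)
  expect_equal(fit1$au, 1)
  one_never <- au_bp_fit(rep(0, 10), r, 1000)
  expect_equal(one_never$au, 0)

  # constant BP_r across scales: AU lands on the same side of 1/2 as BP
  for (cnt in c(200, 700, 900)) {
    f <- au_bp_fit(rep(cnt, 10), r, 1000)
    expect_true(f$au >= 0 && f$au <= 1)
    expect_equal(sign(f$au - 0.5), sign(f$bp - 0.5))
  }
})

test_that("multiscale bootstrap is seeded and supports clear clusters", {
  x <- two_blobs(n_per = 4, p = 6, seed = 9)
  mb1 <- multiscale_bootstrap(x, n_boot = 100, seed = 3)
  mb2 <- multiscale_bootstrap(x, n_boot = 100, seed = 3)
  expect_equal(mb1$node, mb2$node)
  expect_true(all(mb1$node$au >= 0 & mb1$node$au <= 1, na.rm = TRUE))
  expect_true(all(mb1$node$bp >= 0 & mb1$node$bp <= 1, na.rm = TRUE))

  # the two planted blobs are recovered in essentially every resample
  blob_keys <- c(paste(1:4, collapse = ","), paste(5:8, collapse = ","))
  blob_au <- mb1$node$au[mb1$node$members %in% blob_keys]
  expect_length(blob_au, 2L)
  expect_true(all(blob_au > 0.95))
  expect_error(multiscale_bootstrap(x[, 1, drop = FALSE]), "at least 2")
})

test_that("dendrograms serialize to parseable Newick", {
  x <- two_blobs(n_per = 3)
  hc <- agglomerate(x)$hclust
  nwk <- hclust_to_newick(hc)
  expect_match(nwk, ";$")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rownames(x))
})
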