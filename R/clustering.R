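#' Distance matrix between material score profiles
#'
#' Supported metrics: `euclidean`, `cityblock` (Manhattan), `minkowski`
#' (with exponent `p`), `cosine` (1 - cosine similarity) and `hamming`
#' (proportion of unequal coordinates).
#'
#' @param x Numeric matrix (rows = materials).
#' @param metric Distance metric name.
#' @param p Minkowski exponent (default 3).
#' @return A `dist` object.
#' @export
score_dist <- function(x, metric = c("euclidean", "cityblock", "cosine",
                                     "hamming", "minkowski"), p = 3) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  switch(metric,
    euclidean = stats::dist(x, method = "euclidean"),
    cityblock = stats::dist(x, method = "manhattan"),
    minkowski = stats::dist(x, method = "minkowski", p = p),
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      sim <- (x %*% t(x)) / outer(nrm, nrm)
      sim[!is.finite(sim)] <- 0
      stats::as.dist(1 - sim)
    },
    hamming = {
      n <- nrow(x)
      m <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) m[i, j] <- mean(x[i, ] != x[j, ])
      }
      stats::as.dist(m)
    }
  )
}

#' Agglomerative clustering of materials by bioactivity profile
#'
#' Hierarchical clustering of the materials x slice-scores matrix with a
#' choice of distance metric and linkage (Ward's method via `ward.D2`,
#' single, complete or average). Ward linkage requires the Euclidean
#' metric. Cutting the tree at `k` yields cluster labels.
#'
#' @param x Numeric matrix or data frame, rows = materials (rownames used
#'   as labels), columns = slice scores. No missing values.
#' @param metric Distance metric (see [score_dist()]).
#' @param linkage `"ward"`, `"single"`, `"complete"` or `"average"`.
#' @param k Optional number of clusters; when given, labels are returned.
#' @return A list with `hclust` (the dendrogram), `dist`, and `labels`
#'   (integer cluster labels, `NULL` when `k` missing).
#' @export
agglomerate <- function(x, metric = "euclidean",
                        linkage = c("ward", "single", "complete", "average"),
                        k = NULL) {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 materials", call. = FALSE)
  if (anyNA(x)) stop("missing values in the score matrix", call. = FALSE)
  if (linkage == "ward" && metric != "euclidean") {
    stop("Ward linkage requires the Euclidean metric", call. = FALSE)
  }
  d <- score_dist(x, metric)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
  list(hclust = hc, dist = d, labels = labels)
}

total_withinss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xm <- x[idx, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }, numeric(1)))
}

#' Choose the number of clusters
#'
#' `elbow` picks the k maximizing the second difference
#' `W(k-1) - 2 W(k) + W(k+1)` of the total within-cluster sum of squares
#' along the dendrogram cuts; `silhouette` picks the k with the largest mean
#' silhouette width. Ties and degenerate inputs (zero within-cluster
#' variation everywhere) fall back to k = 2.
#'
#' @param x Numeric matrix, rows = materials.
#' @param method `"elbow"` or `"silhouette"`.
#' @param k_max Largest k considered (default `min(10, n - 1)`).
#' @param metric,linkage Passed to [agglomerate()].
#' @return Integer k.
#' @export
choose_k <- function(x, method = c("elbow", "silhouette"), k_max = NULL,
                     metric = "euclidean", linkage = "ward") {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 materials to choose k", call. = FALSE)
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  if (k_max < 2 || k_max >= n) {
    stop("k_max must satisfy 2 <= k_max < n", call. = FALSE)
  }
  ag <- agglomerate(x, metric, linkage)
  cuts <- stats::cutree(ag$hclust, k = 1:min(k_max + 1L, n))

  if (method == "elbow") {
    ks <- 2:k_max
    w <- vapply(1:min(k_max + 1L, n),
                function(k) total_withinss(x, cuts[, k]), numeric(1))
    cand <- ks[ks + 1L <= length(w)]
    if (!length(cand)) return(2L)
    curv <- vapply(cand, function(k) w[k - 1] - 2 * w[k] + w[k + 1],
                   numeric(1))
    if (all(!is.finite(curv)) || max(curv) <= 0 && all(curv == curv[1])) {
      return(2L)
    }
    as.integer(cand[which.max(curv)])
  } else {
    ks <- 2:k_max
    sil <- vapply(ks, function(k) {
      lab <- cuts[, k]
      if (length(unique(lab)) < 2) return(NA_real_)
      mean(cluster::silhouette(lab, ag$dist)[, "sil_width"])
    }, numeric(1))
    if (all(!is.finite(sil))) return(2L)
    as.integer(ks[which.max(sil)])
  }
}

#' Cluster quality indices
#'
#' Mean silhouette width, Davies-Bouldin index (lower is better) and
#' Calinski-Harabasz index (higher is better), by their textbook formulas.
#' An index undefined for the given clustering (e.g. Davies-Bouldin with
#' only singleton clusters) is reported as `NA`.
#'
#' @param x Numeric matrix, rows = materials.
#' @param labels Integer cluster labels (>= 2 non-empty clusters).
#' @return A one-row tibble with `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`.
#' @export
cluster_quality <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- nrow(x)
  if (k < 2) stop("need at least 2 clusters", call. = FALSE)

  sil <- mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])

  centroids <- do.call(rbind, lapply(split(seq_len(n), labels), function(idx) {
    colMeans(x[idx, , drop = FALSE])
  }))
  sizes <- tabulate(labels, k)
  # mean within-cluster distance to centroid (cluster scatter)
  scatter <- vapply(seq_len(k), function(j) {
    idx <- which(labels == j)
    mean(sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, centroids[j, ])^2)))
  }, numeric(1))

  db <- NA_real_
  if (any(sizes > 1)) {
    ratios <- vapply(seq_len(k), function(i) {
      r <- vapply(setdiff(seq_len(k), i), function(j) {
        dc <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
        if (dc == 0) return(Inf)
        (scatter[i] + scatter[j]) / dc
      }, numeric(1))
      max(r)
    }, numeric(1))
    db <- mean(ratios)
  }

  ch <- NA_real_
  if (n > k) {
    overall <- colMeans(x)
    bss <- sum(sizes * rowSums(sweep(centroids, 2, overall)^2))
    wss <- total_withinss(x, labels)
    ch <- if (wss == 0) Inf else (bss / (k - 1)) / (wss / (n - k))
  }
  tibble::tibble(silhouette = sil, davies_bouldin = db,
                 calinski_harabasz = ch)
}

#' Fit AU/BP p-values from per-scale bootstrap counts
#'
#' The probit of each per-scale bootstrap probability,
#' `z_r = qnorm(1 - BP_r)`, is regressed on `v * sqrt(r) + c / sqrt(r)` by
#' weighted least squares (weights = inverse delta-method variance of `z_r`
#' under binomial counts); then `AU = 1 - pnorm(v - c)` and
#' `BP = 1 - pnorm(v + c)`. `BP_r` is clipped to
#' `[1/(n_boot+1), n_boot/(n_boot+1)]` before the probit. A node with
#' `BP_r = 0.5` at every scale yields `v = c = 0` and `AU = BP = 0.5`.
#'
#' Only informative scales (0 < count < n_boot) enter the fit, following
#' the reference multiscale-bootstrap implementation; a node hit in every
#' resample at every scale is fully supported (`AU = BP = 1`), one never
#' hit gets `AU = BP = 0`.
#'
#' @param counts Integer vector of per-scale bootstrap hit counts.
#' @param r Scales at which the counts were taken (>= 2 distinct values).
#' @param n_boot Resamples per scale.
#' @return One-row tibble with `v`, `c`, `au`, `bp` (`NA` when the counts
#'   cannot identify a fit).
#' @export
au_bp_fit <- function(counts, r, n_boot) {
  stopifnot(length(counts) == length(r))
  eps <- 1 / (n_boot + 1)
  bp_r <- pmin(pmax(counts / n_boot, eps), 1 - eps)
  z <- stats::qnorm(1 - bp_r)
  # delta-method variance of z from binomial bp
  var_z <- bp_r * (1 - bp_r) / n_boot / stats::dnorm(z)^2
  ok <- counts > 0 & counts < n_boot &
    is.finite(z) & is.finite(var_z) & var_z > 0
  if (sum(ok) < 2 || length(unique(r[ok])) < 2) {
    # degenerate: (almost) always or (almost) never recovered
    pv <- if (mean(counts / n_boot) >= 0.5) 1 else 0
    return(tibble::tibble(v = NA_real_, c = NA_real_, au = pv, bp = pv))
  }
  X <- cbind(sqrt(r[ok]), 1 / sqrt(r[ok]))
  fit <- stats::lm.wfit(X, z[ok], 1 / var_z[ok])
  v <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  tibble::tibble(v = v, c = cc, au = 1 - stats::pnorm(v - cc),
                 bp = 1 - stats::pnorm(v + cc))
}

# Member sets of the n-1 internal nodes of an hclust tree, as sorted
# integer vectors of leaf indices.
hclust_node_members <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[i, j]
      m <- c(m, if (v < 0) -v else members[[v]])
    }
    members[[i]] <- sort(m)
  }
  members
}

#' Multiscale bootstrap cluster significance (AU/BP)
#'
#' For each scale `r`, `round(r * p)` of the `p` feature columns are
#' resampled with replacement `n_boot` times, the materials are reclustered,
#' and the fraction of resamples in which each original node's member set
#' reappears gives the per-scale bootstrap probability `BP_r`. The
#' approximately unbiased p-value comes from a weighted least squares fit of
#' `z_r = qnorm(1 - BP_r)` to `z = v * sqrt(r) + c / sqrt(r)` (weights =
#' inverse delta-method variance of `z_r` from the binomial counts), with
#' `AU = 1 - pnorm(v - c)` and `BP = 1 - pnorm(v + c)`. Per-scale `BP_r` is
#' clipped to `[1/(n_boot+1), n_boot/(n_boot+1)]` before the probit. Nodes
#' whose `BP_r` is 0.5 at every scale get `AU = BP = 0.5`; AU above 0.95 is
#' conventionally read as strong support for the cluster.
#'
#' @param x Numeric matrix, rows = materials, columns = slice-score
#'   features (>= 2).
#' @param metric,linkage Passed to [agglomerate()].
#' @param scales Numeric vector of scales (default `seq(0.5, 1.4, 0.1)`).
#' @param n_boot Resamples per scale (default 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A list of class `multiscale_bootstrap` with `hclust`, and `node`
#'   — a tibble per internal node with `au`, `bp`, `v`, `c` and the
#'   member-set label — plus `bp_table` of per-scale counts.
#' @export
multiscale_bootstrap <- function(x, metric = "euclidean", linkage = "ward",
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  if (p < 2) stop("need at least 2 feature columns", call. = FALSE)
  if (length(unique(round(scales, 10))) < 2) {
    stop("need at least 2 distinct scales", call. = FALSE)
  }
  base <- agglomerate(x, metric, linkage)
  members <- hclust_node_members(base$hclust)
  keys <- vapply(members, paste, character(1), collapse = ",")
  n_nodes <- length(members)

  counts <- matrix(0L, nrow = n_nodes, ncol = length(scales))
  r_used <- numeric(length(scales))
  withr::with_seed(seed, {
    for (si in seq_along(scales)) {
      p_prime <- max(2L, round(scales[si] * p))
      r_used[si] <- p_prime / p
      for (b in seq_len(n_boot)) {
        cols <- sample.int(p, p_prime, replace = TRUE)
        hb <- tryCatch(
          agglomerate(x[, cols, drop = FALSE], metric, linkage)$hclust,
          error = function(e) NULL
        )
        if (is.null(hb)) next
        kb <- vapply(hclust_node_members(hb), paste, character(1),
                     collapse = ",")
        hit <- keys %in% kb
        counts[hit, si] <- counts[hit, si] + 1L
      }
    }
  })

  node <- lapply(seq_len(n_nodes), function(i) {
    fit <- au_bp_fit(counts[i, ], r_used, n_boot)
    dplyr::bind_cols(tibble::tibble(node = i, members = keys[i]), fit)
  })
  structure(
    list(hclust = base$hclust, node = dplyr::bind_rows(node),
         bp_table = tibble::tibble(
           node = rep(seq_len(n_nodes), length(scales)),
           scale = rep(r_used, each = n_nodes),
           bp_count = as.vector(counts), n_boot = n_boot
         ),
         scales = r_used, n_boot = n_boot),
    class = "multiscale_bootstrap"
  )
}

#' @export
print.multiscale_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<multiscale_bootstrap> %d nodes, %d scales x %d resamples\n",
    nrow(x$node), length(x$scales), x$n_boot))
  print(x$node)
  invisible(x)
}

#' Serialize a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @return Newick string with merge heights as branch annotations.
#' @export
hclust_to_newick <- function(hc) {
  labs <- if (is.null(hc$labels)) as.character(seq_along(hc$order)) else
    hc$labels
  build <- function(i) {
    if (i < 0) return(labs[-i])
    left <- build(hc$merge[i, 1])
    right <- build(hc$merge[i, 2])
    sprintf("(%s,%s):%g", left, right, hc$height[i])
  }
  paste0(sub(":[^:]*$", "", build(length(hc$height))), ";")
}
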