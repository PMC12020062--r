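#' Transform a metric column towards a normal distribution
#'
#' Three transforms are supported, matching the scoring conventions for the
#' different metric families: `neglog10_plus6` (`-log10(x) + 6`, for first
#' significant effect doses, which makes lower doses — higher potency —
#' score higher; doses are expected in ug/ml, where the +6 offset keeps
#' values positive down to picogram-range doses), `sqrt` (for AUC and
#' maximum effect), and `yeo_johnson` (power transform with the lambda
#' estimated by maximum likelihood when not supplied). Missing values (e.g.
#' no significant effect observed) stay missing and later scale to 0.
#'
#' @param values Numeric vector.
#' @param kind One of `"neglog10_plus6"`, `"sqrt"`, `"yeo_johnson"`,
#'   `"identity"`.
#' @param lambda Yeo-Johnson lambda; estimated from the data when `NULL`.
#' @param clip_negative_to_zero Clip negative inputs to 0 before `sqrt` and
#'   negative outputs of `neglog10_plus6` to 0 (default `TRUE`).
#' @return Transformed numeric vector.
#' @examples
#' transform_metric(c(1, 256), "neglog10_plus6")  # 6, ~3.59
#' @export
transform_metric <- function(values, kind = c("neglog10_plus6", "sqrt",
                                              "yeo_johnson", "identity"),
                             lambda = NULL, clip_negative_to_zero = TRUE) {
  kind <- match.arg(kind)
  out <- switch(kind,
    identity = values,
    neglog10_plus6 = {
      if (any(values <= 0, na.rm = TRUE)) {
        stop("-log10(x)+6 transform requires positive doses", call. = FALSE)
      }
      v <- -log10(values) + 6
      if (clip_negative_to_zero) v[v < 0 & !is.na(v)] <- 0
      v
    },
    sqrt = {
      v <- values
      if (clip_negative_to_zero) {
        v[v < 0 & !is.na(v)] <- 0
      } else if (any(v < 0, na.rm = TRUE)) {
        stop("sqrt transform on negative values", call. = FALSE)
      }
      sqrt(v)
    },
    yeo_johnson = {
      ok <- is.finite(values)
      if (is.null(lambda)) {
        if (sum(ok) < 2 || stats::sd(values[ok]) == 0) {
          lambda <- 1
        } else {
          lambda <- tryCatch(
            unname(car::powerTransform(values[ok], family = "yjPower")$lambda),
            error = function(e) 1
          )
        }
      }
      v <- values
      v[ok] <- car::yjPower(values[ok], lambda)
      v
    }
  )
  out
}

#' Scale a metric column to the unit interval
#'
#' Min-max scaling over the material library: `(x - min) / (max - min)`.
#' A constant column scales to all 0, and missing values scale to 0 (a
#' missing metric — e.g. no significant effect — counts as least toxic).
#'
#' @param values Numeric vector.
#' @return Values in `[0, 1]`.
#' @export
minmax_scale_column <- function(values) {
  v <- values
  fin <- is.finite(v)
  if (!any(fin)) return(rep(0, length(v)))
  rng <- range(v[fin])
  out <- rep(0, length(v))
  if (rng[2] > rng[1]) {
    out[fin] <- (v[fin] - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Define one slice of the Tox5 pie
#'
#' A slice combines the metric columns of one endpoint x time (x cell line)
#' condition with per-metric weights summing to 1; the slice itself carries
#' a weight in the final score and a color group (its endpoint).
#'
#' @param name Slice name.
#' @param metrics Character vector of metric column names.
#' @param metric_weights Numeric weights (>= 0, summing to 1).
#' @param slice_weight Weight of the slice in the total score (> 0).
#' @param color_group Grouping label for display (default: first token of
#'   `name`).
#' @return A list of class `slice_spec`.
#' @export
slice_spec <- function(name, metrics, metric_weights = NULL,
                       slice_weight = 1,
                       color_group = strsplit(name, "_")[[1]][1]) {
  if (is.null(metric_weights)) {
    metric_weights <- rep(1 / length(metrics), length(metrics))
  }
  if (length(metric_weights) != length(metrics)) {
    stop("one weight per metric required", call. = FALSE)
  }
  if (any(metric_weights < 0) || abs(sum(metric_weights) - 1) > 1e-8) {
    stop("metric weights must be >= 0 and sum to 1", call. = FALSE)
  }
  if (slice_weight <= 0) stop("slice weight must be > 0", call. = FALSE)
  structure(
    list(name = name, metrics = metrics,
         metric_weights = stats::setNames(metric_weights, metrics),
         slice_weight = slice_weight, color_group = color_group),
    class = "slice_spec"
  )
}

#' Build slice definitions from metric column names
#'
#' In `auto` mode the four metrics of each endpoint x time (x cell line,
#' x serum) condition form one slice. The default intra-slice weighting
#' emphasizes sensitivity: the first significant dose at the 3SD cutoff
#' carries 50% of the slice, the other three metrics 1/6 (about 16.67%)
#' each. In `manual` mode explicit [slice_spec()] objects are passed
#' through (after validation).
#'
#' @param metric_columns Character vector of column names shaped
#'   `<condition>_<metric>` where metric is one of `first_sig_2sd`,
#'   `first_sig_3sd`, `auc`, `max_effect`.
#' @param mode `"auto"` or `"manual"`.
#' @param slices Manual list of [slice_spec()] (mode `"manual"`).
#' @param weight_rule Named numeric vector of per-metric weights used in
#'   auto mode; must sum to 1 over the metrics present in a slice.
#' @return List of [slice_spec()] objects.
#' @export
build_slices <- function(metric_columns, mode = c("auto", "manual"),
                         slices = NULL,
                         weight_rule = c(first_sig_3sd = 0.5,
                                         first_sig_2sd = 1 / 6,
                                         auc = 1 / 6,
                                         max_effect = 1 / 6)) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    stopifnot(all(vapply(slices, inherits, logical(1), "slice_spec")))
    for (s in slices) {
      if (!all(s$metrics %in% metric_columns)) {
        stop("slice '", s$name, "' references unknown metric column(s)",
             call. = FALSE)
      }
    }
    return(slices)
  }
  metric_names <- c("first_sig_2sd", "first_sig_3sd", "auc", "max_effect")
  pat <- paste0("_(", paste(metric_names, collapse = "|"), ")$")
  hit <- grepl(pat, metric_columns)
  if (!all(hit)) {
    stop("cannot parse metric column(s): ",
         paste(metric_columns[!hit], collapse = ", "), call. = FALSE)
  }
  cond <- sub(pat, "", metric_columns)
  metric <- sub(paste0("^.*", pat), "\\1", metric_columns)
  out <- lapply(unique(cond), function(cn) {
    cols <- metric_columns[cond == cn]
    mets <- metric[cond == cn]
    w <- unname(weight_rule[mets])
    if (anyNA(w)) {
      stop("weight_rule lacks weights for: ",
           paste(mets[is.na(w)], collapse = ", "), call. = FALSE)
    }
    w <- w / 1  # weights must already sum to 1 over present metrics
    if (abs(sum(w) - 1) > 1e-8) {
      stop("metric weights for slice '", cn, "' sum to ", sum(w),
           ", not 1", call. = FALSE)
    }
    slice_spec(cn, cols, w)
  })
  out
}

#' Compute Tox5 scores, ranks and slice scores
#'
#' Slice score = weighted sum of the material's scaled metrics in the slice;
#' total score = slice-weight-weighted mean of slice scores. Both live in
#' `[0, 1]`. Rank 1 is the most toxic material; ties share the smaller rank
#' (competition ranking).
#'
#' @param scaled Tibble/data frame of scaled metrics in `[0, 1]`, one row
#'   per material, with a `material_id` column.
#' @param slices List of [slice_spec()] objects.
#' @return A tibble of class `tox5_result` with `material_id`, one
#'   `slice_<name>` column per slice, `total` and `rank`.
#' @export
compute_scores <- function(scaled, slices) {
  scaled <- tibble::as_tibble(scaled)
  stopifnot("material_id" %in% names(scaled))
  slice_mat <- vapply(slices, function(s) {
    m <- as.matrix(scaled[, s$metrics, drop = FALSE])
    m[is.na(m)] <- 0
    as.numeric(m %*% s$metric_weights)
  }, numeric(nrow(scaled)))
  slice_mat <- matrix(slice_mat, nrow = nrow(scaled))
  colnames(slice_mat) <- vapply(slices, `[[`, character(1), "name")
  sw <- vapply(slices, `[[`, numeric(1), "slice_weight")
  total <- as.numeric(slice_mat %*% sw) / sum(sw)
  out <- tibble::tibble(material_id = scaled$material_id)
  for (j in seq_along(slices)) {
    out[[paste0("slice_", colnames(slice_mat)[j])]] <- slice_mat[, j]
  }
  out$total <- total
  out$rank <- rank_competition(total)
  class(out) <- c("tox5_result", class(out))
  out
}

#' Competition ranking with 1 = highest value
#'
#' @param x Numeric vector (e.g. total scores).
#' @return Integer ranks; ties share the smaller rank.
#' @export
rank_competition <- function(x) {
  as.integer(rank(-x, ties.method = "min"))
}

#' End-to-end scoring of a metrics table
#'
#' Applies the per-metric transforms (first significant doses:
#' `-log10(x)+6`; AUC and maximum effect: square root by default), min-max
#' scales each column over the material library, builds slices and computes
#' scores.
#'
#' @param wide Wide metrics table from [metrics_wide()].
#' @param slices Optional manual slice list; auto slicing when `NULL`.
#' @param transforms Named character vector mapping metric family to
#'   transform kind.
#' @param weight_rule Auto-mode intra-slice weights (see [build_slices()]).
#' @return List with `scores` ([compute_scores()] result), `scaled`,
#'   `transformed` and `slices`.
#' @export
tox5_pipeline <- function(wide, slices = NULL,
                          transforms = c(first_sig_2sd = "neglog10_plus6",
                                         first_sig_3sd = "neglog10_plus6",
                                         auc = "sqrt",
                                         max_effect = "sqrt"),
                          weight_rule = c(first_sig_3sd = 0.5,
                                          first_sig_2sd = 1 / 6,
                                          auc = 1 / 6,
                                          max_effect = 1 / 6)) {
  wide <- tibble::as_tibble(wide)
  cols <- setdiff(names(wide), "material_id")
  transformed <- wide
  for (cn in cols) {
    fam <- .metric_family(cn)
    transformed[[cn]] <- transform_metric(wide[[cn]], transforms[[fam]])
  }
  scaled <- transformed
  for (cn in cols) scaled[[cn]] <- minmax_scale_column(transformed[[cn]])
  if (is.null(slices)) {
    slices <- build_slices(cols, mode = "auto", weight_rule = weight_rule)
  }
  list(scores = compute_scores(scaled, slices), scaled = scaled,
       transformed = transformed, slices = slices)
}

.metric_family <- function(column) {
  metric_names <- c("first_sig_2sd", "first_sig_3sd", "auc", "max_effect")
  for (m in metric_names) {
    if (grepl(paste0("(^|_)", m, "$"), column)) return(m)
  }
  stop("cannot infer metric family of column: ", column, call. = FALSE)
}

#' Bootstrap confidence intervals for Tox5 scores and ranks
#'
#' Materials are resampled with replacement; each resample redefines the
#' min-max scaling bounds, under which all original materials are rescored
#' (values clipped to `[0, 1]`). Percentile intervals at the requested level
#' are reported for every slice score, the total score and the rank of each
#' material. Deterministic under a fixed seed.
#'
#' @param transformed Transformed (pre-scaling) wide metrics table with
#'   `material_id`.
#' @param slices List of [slice_spec()] objects.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Tibble with columns `material_id`, `quantity` (slice name,
#'   `"total"` or `"rank"`), `point`, `ci_low`, `ci_high`.
#' @export
bootstrap_intervals <- function(transformed, slices, n_boot = 1000,
                                level = 0.95, seed = 1L) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  transformed <- tibble::as_tibble(transformed)
  n <- nrow(transformed)
  if (n < 2) stop("need at least 2 materials to bootstrap", call. = FALSE)
  cols <- setdiff(names(transformed), "material_id")

  score_with_bounds <- function(bounds_rows) {
    scaled <- transformed
    for (cn in cols) {
      b <- transformed[[cn]][bounds_rows]
      b <- b[is.finite(b)]
      v <- rep(0, n)
      if (length(b) && max(b) > min(b)) {
        fin <- is.finite(transformed[[cn]])
        v[fin] <- (transformed[[cn]][fin] - min(b)) / (max(b) - min(b))
        v <- pmin(pmax(v, 0), 1)
      }
      scaled[[cn]] <- v
    }
    compute_scores(scaled, slices)
  }

  point <- score_with_bounds(seq_len(n))
  qty_cols <- setdiff(names(point), "material_id")

  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      score_with_bounds(sample.int(n, n, replace = TRUE))
    })
  })
  alpha <- (1 - level) / 2
  out <- list()
  for (q in qty_cols) {
    mat <- vapply(draws, function(d) as.numeric(d[[q]]), numeric(n))
    mat <- matrix(mat, nrow = n)
    out[[q]] <- tibble::tibble(
      material_id = point$material_id,
      quantity = sub("^slice_", "", q),
      point = as.numeric(point[[q]]),
      ci_low = apply(mat, 1, stats::quantile, probs = alpha, names = FALSE),
      ci_high = apply(mat, 1, stats::quantile, probs = 1 - alpha,
                      names = FALSE)
    )
  }
  dplyr::bind_rows(out)
}
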