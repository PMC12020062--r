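#' First statistically significant effect dose
#'
#' Scans the tested doses in ascending order and returns the first dose at
#' which (a) the mean of the replicate effect values exceeds the control
#' median plus `k` control standard deviations and (b) a two-tailed Welch
#' t-test of the replicate effects against the (IQR-filtered) control values
#' gives p < `alpha`. Returns `NA` when no dose qualifies — absence of a
#' significant effect, not a failure. Because the k = 3 threshold is
#' stricter, the 3SD dose is never below the 2SD dose for the same series.
#'
#' @param doses Numeric vector of tested doses (> 0).
#' @param effects Matrix or data frame of effect values with one row per
#'   dose (aligned with `doses`) and one column per biological replicate,
#'   or a list of per-dose replicate vectors.
#' @param control_values Effect-scale control values (already IQR-filtered),
#'   or a `ControlStats`-style one-row tibble with `median`/`sd` columns
#'   plus a `values` attribute.
#' @param k Threshold multiplier, 2 or 3.
#' @param alpha Significance level (default 0.05).
#' @return The first qualifying dose, or `NA_real_`.
#' @export
first_significant_dose <- function(doses, effects, control_values, k = 2,
                                   alpha = 0.05) {
  stopifnot(k %in% c(2, 3))
  eff <- .as_effect_list(doses, effects)
  o <- order(doses)
  ctrl <- control_values[is.finite(control_values)]
  if (length(ctrl) < 2) {
    stop("need at least 2 finite control values", call. = FALSE)
  }
  thr <- stats::median(ctrl) + k * stats::sd(ctrl)

  any_testable <- FALSE
  for (i in o) {
    v <- eff[[i]]
    v <- v[is.finite(v)]
    if (length(v) < 2) next
    any_testable <- TRUE
    if (mean(v) <= thr) next
    p <- tryCatch(stats::t.test(v, ctrl)$p.value, error = function(e) NA_real_)
    if (is.finite(p) && p < alpha) return(doses[i])
  }
  if (!any_testable) {
    warning("fewer than 2 replicate values at every dose; ",
            "first significant dose undetermined", call. = FALSE)
  }
  NA_real_
}

.as_effect_list <- function(doses, effects) {
  if (is.list(effects) && !is.data.frame(effects)) {
    stopifnot(length(effects) == length(doses))
    return(effects)
  }
  effects <- as.matrix(effects)
  stopifnot(nrow(effects) == length(doses))
  lapply(seq_len(nrow(effects)), function(i) effects[i, ])
}

#' Area under the effect vs log10(dose) curve
#'
#' Effects below the baseline-noise threshold (control median + 2 control
#' SD) are set to 0 (keeping the dose grid intact), then the trapezoid rule
#' is applied over log10(dose). Dose 0 rows (controls) are excluded from the
#' x-axis, and nothing is extrapolated beyond the highest tested dose.
#'
#' @param doses Numeric vector of doses.
#' @param effects Median-of-replicates effect per dose.
#' @param control_values Effect-scale control values used for the threshold,
#'   or `NULL` with an explicit `threshold`.
#' @param threshold Noise threshold overriding `control_values`.
#' @return Non-negative AUC (0, with a warning, when fewer than 2 finite
#'   points remain).
#' @export
dose_response_auc <- function(doses, effects, control_values = NULL,
                              threshold = NULL) {
  stopifnot(length(doses) == length(effects))
  keep <- doses > 0 & is.finite(doses) & is.finite(effects)
  doses <- doses[keep]
  effects <- effects[keep]
  if (length(doses) < 2) {
    warning("fewer than 2 finite dose-effect points; AUC set to 0",
            call. = FALSE)
    return(0)
  }
  if (is.null(threshold)) {
    ctrl <- control_values[is.finite(control_values)]
    if (length(ctrl) < 2) {
      stop("need control values (or an explicit threshold) for the ",
           "baseline-noise cutoff", call. = FALSE)
    }
    threshold <- stats::median(ctrl) + 2 * stats::sd(ctrl)
  }
  effects[effects < threshold] <- 0
  o <- order(doses)
  x <- log10(doses[o])
  y <- effects[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Maximum effect
#'
#' The maximum effect across doses is taken separately within each
#' biological replicate, and the median of these replicate maxima is
#' reported; replicates with no finite value are ignored.
#'
#' @param effects Matrix/data frame (rows = doses, columns = replicates) or
#'   list of per-dose replicate vectors.
#' @return Median of per-replicate maxima (`NA` if nothing finite).
#' @export
max_effect <- function(effects) {
  m <- if (is.list(effects) && !is.data.frame(effects)) {
    do.call(rbind, effects)
  } else {
    as.matrix(effects)
  }
  maxima <- apply(m, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) max(v) else NA_real_
  })
  maxima <- maxima[is.finite(maxima)]
  if (!length(maxima)) return(NA_real_)
  stats::median(maxima)
}

#' Dose-response metrics for every condition of a campaign
#'
#' For each (material, endpoint, time, cell line, serum) combination,
#' computes the four metrics — first significant dose at the 2SD and 3SD
#' cutoffs, AUC over log dose, and maximum effect — from the `normalized`
#' layer, using the plate-wise controls of the matching plates (pooled
#' across replicates, IQR-filtered) as the reference distribution.
#'
#' @param datasets Named list of preprocessed [hts_dataset()] objects.
#' @param alpha Significance level for the first-significant-dose test.
#' @param iqr_mult IQR multiplier for control filtering.
#' @return A tibble with key columns `material_id`, `endpoint`, `time_h`,
#'   `cell_line`, `serum` and metric columns `first_sig_2sd`,
#'   `first_sig_3sd`, `auc`, `max_effect`.
#' @export
metrics_table <- function(datasets, alpha = 0.05, iqr_mult = 1.5) {
  if (inherits(datasets, "hts_dataset")) datasets <- list(datasets)
  rows <- list()
  for (ds in datasets) {
    stopifnot(inherits(ds, "hts_dataset"))
    if (!"normalized" %in% names(ds$data)) {
      stop("dataset ", ds$endpoint, " has no normalized layer; ",
           "run preprocess_endpoint() first", call. = FALSE)
    }
    d <- ds$data[!(ds$data$time_h %in% 0), ]
    conds <- unique(d[d$role == "treated",
                      c("time_h", "cell_line", "serum")])
    for (ci in seq_len(nrow(conds))) {
      sel <- d$time_h %in% conds$time_h[ci] &
        d$cell_line %in% conds$cell_line[ci] & d$serum %in% conds$serum[ci]
      dc <- d[sel, ]
      ctrl <- iqr_filter_controls(
        dc$normalized[dc$role == "control"], mult = iqr_mult
      )$kept
      for (mat in unique(dc$material_id[dc$role == "treated"])) {
        dm <- dc[dc$role == "treated" & dc$material_id == mat, ]
        wide <- dm |>
          dplyr::group_by(.data$dose_value, .data$replicate) |>
          dplyr::summarise(value = mean(.data$normalized, na.rm = TRUE),
                           .groups = "drop") |>
          tidyr::pivot_wider(names_from = "replicate",
                             values_from = "value")
        doses <- wide$dose_value
        effmat <- as.matrix(wide[, -1, drop = FALSE])
        med_eff <- apply(effmat, 1, function(v) {
          v <- v[is.finite(v)]
          if (length(v)) stats::median(v) else NA_real_
        })
        rows[[length(rows) + 1L]] <- tibble::tibble(
          material_id = mat, endpoint = ds$endpoint,
          time_h = conds$time_h[ci], cell_line = conds$cell_line[ci],
          serum = conds$serum[ci],
          first_sig_2sd = first_significant_dose(doses, effmat, ctrl, k = 2,
                                                 alpha = alpha),
          first_sig_3sd = first_significant_dose(doses, effmat, ctrl, k = 3,
                                                 alpha = alpha),
          auc = suppressWarnings(
            dose_response_auc(doses, med_eff, control_values = ctrl)
          ),
          max_effect = max_effect(effmat)
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      material_id = character(), endpoint = character(), time_h = numeric(),
      cell_line = character(), serum = character(),
      first_sig_2sd = numeric(), first_sig_3sd = numeric(),
      auc = numeric(), max_effect = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Pivot a metrics table to one row per material
#'
#' Metric columns are named `<endpoint>_<time>h_<metric>` with the cell line
#' and serum condition appended when the campaign has more than one.
#'
#' @param metrics Long metrics table from [metrics_table()].
#' @return Wide tibble, one row per `material_id`.
#' @export
metrics_wide <- function(metrics) {
  tag <- paste0(metrics$endpoint, "_", metrics$time_h, "h")
  if (length(unique(metrics$cell_line)) > 1) {
    tag <- paste0(tag, "_", metrics$cell_line)
  }
  if (length(unique(metrics$serum)) > 1) {
    tag <- paste0(tag, "_", metrics$serum)
  }
  metrics |>
    dplyr::mutate(.tag = tag) |>
    dplyr::select("material_id", ".tag", "first_sig_2sd", "first_sig_3sd",
                  "auc", "max_effect") |>
    tidyr::pivot_longer(c("first_sig_2sd", "first_sig_3sd", "auc",
                          "max_effect"),
                        names_to = ".metric", values_to = ".value") |>
    dplyr::mutate(column = paste0(.data$.tag, "_", .data$.metric)) |>
    dplyr::select("material_id", "column", ".value") |>
    tidyr::pivot_wider(names_from = "column", values_from = ".value")
}
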