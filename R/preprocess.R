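#' Filter control values by the 1.5 IQR rule and summarize them
#'
#' Percent-of-control normalization is sensitive to outliers among the
#' vehicle controls, so control values outside
#' `[Q1 - mult*IQR, Q3 + mult*IQR]` are removed before any control statistic
#' is used. Quartiles use linear interpolation (quantile type 7).
#'
#' @param values Numeric vector of control values (at least one finite).
#' @param mult IQR multiplier (default 1.5).
#' @return A list with `kept` (filtered values) and `stats`, a one-row
#'   tibble of class-describing control statistics (`median`, `mean`, `sd`,
#'   `q1`, `q3`, `iqr`, `n_before`, `n_after`).
#' @examples
#' iqr_filter_controls(c(10, 100, 102, 104, 106, 200))$kept
#' @export
iqr_filter_controls <- function(values, mult = 1.5) {
  values <- values[is.finite(values)]
  if (!length(values)) {
    stop("no finite control values to filter", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - mult * iqr
  hi <- q[2] + mult * iqr
  kept <- values[values >= lo & values <= hi]
  stats <- tibble::tibble(
    median = stats::median(kept), mean = mean(kept),
    sd = if (length(kept) > 1) stats::sd(kept) else 0,
    q1 = q[1], q3 = q[2], iqr = iqr,
    n_before = length(values), n_after = length(kept)
  )
  list(kept = kept, stats = stats)
}

#' Express a value as percent of the control median
#'
#' Two conventions are supported: `effect` reports `value/median * 100`
#' (100 = control level) and `inhibition` reports
#' `(1 - value/median) * 100` (0 = control level, positive = signal loss).
#' The two modes sum to 100 for any value. Viability-type endpoints are
#' conventionally put on the inhibition scale so that larger always means
#' more toxic.
#'
#' @param value Numeric vector.
#' @param control_median Control median on the same scale (non-zero).
#' @param mode `"effect"` or `"inhibition"`.
#' @return Numeric vector of percentages.
#' @export
percent_of_control <- function(value, control_median,
                               mode = c("effect", "inhibition")) {
  mode <- match.arg(mode)
  if (!is.finite(control_median) || control_median == 0) {
    stop("control median is zero or non-finite; cannot normalize",
         call. = FALSE)
  }
  pct <- value / control_median * 100
  if (mode == "inhibition") 100 - pct else pct
}

#' Correct a value against the 0-h baseline
#'
#' A 0-h exposure plate represents the pre-exposure state and flags assay
#' interference. The default subtracts the median of the 0-h replicate
#' values; the ratio mode divides by it instead.
#'
#' @param value Numeric vector.
#' @param baseline_0h_median Median of the matching 0-h values.
#' @param mode `"subtract"` (default) or `"ratio"`.
#' @return Corrected values.
#' @export
baseline_correct_0h <- function(value, baseline_0h_median,
                                mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  if (!is.finite(baseline_0h_median)) {
    stop("no 0-h baseline available for this endpoint", call. = FALSE)
  }
  if (mode == "subtract") {
    value - baseline_0h_median
  } else {
    if (baseline_0h_median == 0) {
      stop("0-h baseline median is zero; ratio mode undefined", call. = FALSE)
    }
    value / baseline_0h_median
  }
}

#' Clean an imaging well by the DAPI signal rules
#'
#' A DAPI (cell count) value of 0 means either true cell death or a failed
#' image focus. The two cases are told apart by the biological replicates at
#' the same (material, dose, time): if their summary statistic stays at or
#' below `threshold`, cells really died — DAPI stays 0 and the associated
#' imaging endpoints from the same well are set to 0; if it exceeds
#' `threshold`, the well is a focus failure — DAPI and associated endpoints
#' become missing (`NA`). Non-zero DAPI values are never touched. DAPI
#' technical duplicates must be averaged before applying the rule.
#'
#' @param dapi_value Single DAPI value (technical duplicates already
#'   averaged).
#' @param replicate_dapi_values DAPI values of the biological replicates at
#'   the same condition.
#' @param associated_values Named numeric vector of other imaging endpoint
#'   values from the same well.
#' @param threshold Replicate-summary cutoff (default 50).
#' @param stat Replicate summary statistic, `"median"` (default) or
#'   `"mean"`.
#' @return List with cleaned `dapi` and `associated`.
#' @export
clean_imaging_by_dapi <- function(dapi_value, replicate_dapi_values,
                                  associated_values = numeric(),
                                  threshold = 50,
                                  stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (is.na(dapi_value) || dapi_value != 0) {
    return(list(dapi = dapi_value, associated = associated_values))
  }
  f <- if (stat == "median") stats::median else mean
  rep_stat <- f(replicate_dapi_values, na.rm = TRUE)
  if (is.finite(rep_stat) && rep_stat > threshold) {
    # focus failure: no usable signal from this well
    list(dapi = NA_real_,
         associated = stats::setNames(rep(NA_real_, length(associated_values)),
                                      names(associated_values)))
  } else {
    # true cell death: keep the zeros as information
    list(dapi = 0,
         associated = stats::setNames(rep(0, length(associated_values)),
                                      names(associated_values)))
  }
}

#' Normalize a caspase readout for cell loss
#'
#' Apoptosis signal per well underestimates the effect when many cells have
#' already been lost. The caspase percent value is rescaled by the average
#' percent cell loss seen in two viability endpoints (CTG and DAPI):
#' `casp / (1 - average(mean1, mean2)/100)`.
#'
#' @param casp_percent Caspase value as percent of control.
#' @param mean_endpoint1_percent,mean_endpoint2_percent Mean percent
#'   inhibition (cell loss) of the two viability endpoints at the same
#'   condition.
#' @return Normalized caspase values; `NA` with a warning where all cells
#'   were lost (average loss = 100%).
#' @export
normalize_caspase <- function(casp_percent, mean_endpoint1_percent,
                              mean_endpoint2_percent) {
  loss <- (mean_endpoint1_percent + mean_endpoint2_percent) / 2
  denom <- 1 - loss / 100
  out <- casp_percent / denom
  dead <- is.finite(denom) & denom == 0
  if (any(dead, na.rm = TRUE)) {
    warning("all cells lost at ", sum(dead),
            " condition(s); caspase value set to NA", call. = FALSE)
    out[dead] <- NA_real_
  }
  out
}

#' Per-plate control statistics for a dataset layer
#'
#' Controls are the `role == "control"` wells of each plate; each plate's
#' control values are IQR-filtered before computing the summary.
#'
#' @param ds An [hts_dataset()].
#' @param layer Value layer to summarize (default `"raw"`).
#' @param iqr_mult IQR multiplier passed to [iqr_filter_controls()].
#' @return Tibble with one row per `plate_id` plus the control statistics
#'   columns.
#' @export
control_stats <- function(ds, layer = "raw", iqr_mult = 1.5) {
  stopifnot(inherits(ds, "hts_dataset"), layer %in% names(ds$data))
  d <- ds$data[ds$data$role == "control", ]
  parts <- split(d[[layer]], d$plate_id)
  dplyr::bind_rows(lapply(names(parts), function(p) {
    fs <- iqr_filter_controls(parts[[p]], mult = iqr_mult)
    dplyr::bind_cols(tibble::tibble(plate_id = p), fs$stats)
  }))
}

#' Run the endpoint-specific preprocessing recipe on a dataset
#'
#' Applies, in order: averaging of technical duplicates (imaging), 0-h
#' baseline subtraction (endpoints with a 0-h plate), percent of plate-wise
#' IQR-filtered controls (inhibition scale for viability-type endpoints,
#' effect scale otherwise), and the DAPI cleaning rules for imaging
#' endpoints. Caspase cell-loss normalization needs the CTG and DAPI
#' datasets and is applied afterwards with [apply_caspase_normalization()].
#' The result is stored as the `normalized` layer; all steps are logged to
#' provenance.
#'
#' @param ds An [hts_dataset()].
#' @param mode Percent-of-control convention; default `"inhibition"` for
#'   CTG/DAPI, `"effect"` otherwise.
#' @param baseline One of `"auto"` (subtract 0-h median when 0-h records are
#'   present), `"subtract"`, `"ratio"` or `"none"`.
#' @param dapi DAPI-cleaned dataset used to clean associated imaging
#'   endpoints (H2AX, 8OHG, CASP); `NULL` to skip.
#' @param dapi_threshold,dapi_stat Parameters of the DAPI rule.
#' @param iqr_mult IQR multiplier for control filtering.
#' @return The dataset with a `normalized` column appended.
#' @export
preprocess_endpoint <- function(ds,
                                mode = NULL,
                                baseline = "auto",
                                dapi = NULL,
                                dapi_threshold = 50,
                                dapi_stat = "median",
                                iqr_mult = 1.5) {
  stopifnot(inherits(ds, "hts_dataset"))
  if (is.null(mode)) {
    mode <- if (ds$endpoint %in% c("CTG", "DAPI")) "inhibition" else "effect"
  }
  d <- ds$data
  val <- d$raw

  # technical duplicates (DAPI): average before everything else
  if (any(d$tech_rep > 1L)) {
    key <- interaction(d$plate_id, d$well, drop = TRUE)
    val <- stats::ave(val, key, FUN = function(v) mean(v, na.rm = TRUE))
    val[is.nan(val)] <- NA_real_
    keep <- d$tech_rep == 1L
    d <- d[keep, ]
    val <- val[keep]
    ds <- log_provenance(ds, "average_technical_duplicates")
  }

  # DAPI rules, applied on the raw scale before normalization; associated
  # endpoints consult the duplicate-averaged raw DAPI signal of their well
  if (ds$endpoint == "DAPI") {
    d$raw_avg <- val
    val <- .apply_dapi_rule(d, val, d, val, dapi_threshold, dapi_stat)
    d$cleaned_raw <- val
    ds <- log_provenance(ds, "clean_imaging_by_dapi",
                         list(threshold = dapi_threshold, stat = dapi_stat))
  } else if (!is.null(dapi)) {
    stopifnot(inherits(dapi, "hts_dataset"))
    dd <- dapi$data
    dval <- if ("raw_avg" %in% names(dd)) dd$raw_avg else dd$raw
    val <- .apply_dapi_rule(d, val, dd, dval, dapi_threshold, dapi_stat,
                            associated = TRUE)
    ds <- log_provenance(ds, "clean_imaging_by_dapi",
                         list(threshold = dapi_threshold, stat = dapi_stat,
                              source = "DAPI"))
  }

  # 0-h baseline: per well (across replicates), median of the 0-h values,
  # subtracted from (or divided into) the matching later time points
  has_0h <- any(d$time_h == 0, na.rm = TRUE)
  if (baseline == "auto") baseline <- if (has_0h) "subtract" else "none"
  if (baseline %in% c("subtract", "ratio")) {
    if (!has_0h) {
      stop("no 0-h plate present for endpoint ", ds$endpoint, call. = FALSE)
    }
    key <- paste(d$well, d$cell_line, d$serum, sep = "\r")
    b0 <- d$time_h == 0
    base_map <- tapply(val[b0], key[b0], stats::median, na.rm = TRUE)
    base <- unname(base_map[key])
    val <- if (baseline == "subtract") val - base else val / base
    ds <- log_provenance(ds, "baseline_correct_0h", list(mode = baseline))
  }

  # percent of plate-wise IQR-filtered controls; 0-h plates serve only as
  # baseline and are not normalized
  d$.val <- val
  normalized <- rep(NA_real_, nrow(d))
  later <- is.na(d$time_h) | d$time_h > 0
  for (idx in split(which(later), d$plate_id[later])) {
    ctrl <- d$.val[idx][d$role[idx] == "control"]
    fs <- iqr_filter_controls(ctrl, mult = iqr_mult)
    normalized[idx] <- percent_of_control(d$.val[idx], fs$stats$median,
                                          mode = mode)
  }
  d$.val <- NULL
  d$normalized <- normalized
  ds$data <- d
  ds$layers <- union(ds$layers, "normalized")
  ds <- log_provenance(ds, "percent_of_control",
                       list(mode = mode, iqr_mult = iqr_mult))
  ds
}

# Shared DAPI-rule sweep: for each record of `d` whose matched DAPI value is
# 0, consult the biological-replicate DAPI values at the same
# (material, dose, time, cell line, serum) and zero out or NA out `val`.
.apply_dapi_rule <- function(d, val, dapi_d, dapi_val, threshold, stat,
                             associated = FALSE) {
  cond_key <- function(x) {
    paste(x$material_id, x$dose_value, x$time_h, x$cell_line, x$serum,
          sep = "\r")
  }
  well_key <- function(x) {
    paste(cond_key(x), x$replicate, x$well, sep = "\r")
  }
  # DAPI value for each target record's well
  dk <- well_key(dapi_d)
  my_dapi <- dapi_val[match(well_key(d), dk)]
  # replicate DAPI values per condition
  rep_split <- split(dapi_val, cond_key(dapi_d))
  f <- if (stat == "median") stats::median else mean
  rep_stat <- vapply(rep_split, f, numeric(1), na.rm = TRUE)
  my_stat <- rep_stat[cond_key(d)]

  fire <- !is.na(my_dapi) & my_dapi == 0 & d$role != "blank"
  focus_fail <- fire & is.finite(my_stat) & my_stat > threshold
  true_death <- fire & !focus_fail
  val[focus_fail] <- NA_real_
  val[true_death] <- 0
  val
}

#' Apply caspase cell-loss normalization across endpoints
#'
#' Rescales the caspase `normalized` layer (percent effect) by the mean
#' percent cell loss of the CTG and DAPI endpoints at the same
#' (material, dose, time, cell line, serum) condition.
#'
#' @param casp,ctg,dapi Preprocessed [hts_dataset()] objects (`normalized`
#'   layer present; CTG/DAPI on the inhibition scale).
#' @return The caspase dataset with its `normalized` layer rescaled.
#' @export
apply_caspase_normalization <- function(casp, ctg, dapi) {
  stopifnot(inherits(casp, "hts_dataset"),
            "normalized" %in% names(casp$data),
            "normalized" %in% names(ctg$data),
            "normalized" %in% names(dapi$data))
  key <- function(x) {
    paste(x$material_id, x$dose_value, x$time_h, x$cell_line, x$serum,
          sep = "\r")
  }
  mean_by <- function(ds) {
    tapply(ds$data$normalized, key(ds$data), mean, na.rm = TRUE)
  }
  m_ctg <- mean_by(ctg)
  m_dapi <- mean_by(dapi)
  k <- key(casp$data)
  casp$data$normalized <- as.numeric(normalize_caspase(
    casp$data$normalized,
    as.numeric(m_ctg[k]), as.numeric(m_dapi[k])
  ))
  log_provenance(casp, "normalize_caspase", list(sources = c("CTG", "DAPI")))
}

#' Aggregate the normalized layer over biological replicates
#'
#' Computes a per-condition statistic (median by default) of the normalized
#' values over biological replicates, ignoring missing values; a condition
#' whose values are all missing stays missing.
#'
#' @param ds An [hts_dataset()] with a `normalized` layer.
#' @param stat `"median"` (default) or `"mean"`.
#' @return The dataset with an `aggregated` tibble keyed by
#'   (material, dose, time, cell line, serum).
#' @export
aggregate_replicates <- function(ds, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(ds, "hts_dataset"), "normalized" %in% names(ds$data))
  f <- if (stat == "median") stats::median else mean
  agg <- ds$data |>
    dplyr::filter(.data$role != "blank") |>
    dplyr::group_by(.data$material_id, .data$dose_value, .data$time_h,
                    .data$cell_line, .data$serum, .data$role) |>
    dplyr::summarise(
      value = {
        v <- .data$normalized[!is.na(.data$normalized)]
        if (length(v)) f(v) else NA_real_
      },
      n = sum(!is.na(.data$normalized)),
      .groups = "drop"
    )
  ds$aggregated <- agg
  ds$layers <- union(ds$layers, paste0(stat, "_of_replicates"))
  log_provenance(ds, "aggregate_replicates", list(stat = stat))
}
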