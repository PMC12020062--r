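#' Ingest a campaign directory into annotated datasets
#'
#' Finds plate-reader CSVs and imaging TXTs in the given directories,
#' auto-fills any missing files-sheet rows from the filenames, and builds
#' one annotated dataset per endpoint.
#'
#' @param raw_dirs Directories containing raw files (searched
#'   non-recursively).
#' @param template An [annotation_template()] or a path accepted by
#'   [read_annotation_template()].
#' @param geometry A [plate_geometry()].
#' @param pattern A [filename_pattern()] for auto-fill.
#' @return Named list of [hts_dataset()] objects.
#' @export
ingest_campaign <- function(raw_dirs, template,
                            geometry = plate_geometry(),
                            pattern = filename_pattern()) {
  if (is.character(template)) {
    template <- read_annotation_template(template)
  }
  plate_files <- unlist(lapply(raw_dirs, list.files, pattern = "\\.csv$",
                               full.names = TRUE))
  imaging_files <- unlist(lapply(raw_dirs, list.files, pattern = "\\.txt$",
                                 full.names = TRUE))
  template <- autofill_files_sheet(
    c(plate_files, imaging_files), template, pattern
  )
  annotate_dataset(plate_files, imaging_files, template, geometry)
}

#' Preprocess every endpoint of a campaign
#'
#' Runs [preprocess_endpoint()] on each dataset with the endpoint-specific
#' defaults (DAPI first, so its cleaned values can drive the imaging rules
#' of the other endpoints), applies the caspase cell-loss normalization
#' when CTG, DAPI and CASP are all present, and aggregates replicates.
#'
#' @param datasets Named list of [hts_dataset()] from [ingest_campaign()].
#' @param dapi_threshold,dapi_stat DAPI-rule parameters.
#' @param iqr_mult IQR multiplier for control filtering.
#' @param aggregate_stat Replicate aggregation statistic.
#' @return Named list of preprocessed datasets.
#' @export
preprocess_campaign <- function(datasets, dapi_threshold = 50,
                                dapi_stat = "median", iqr_mult = 1.5,
                                aggregate_stat = "median") {
  out <- datasets
  if ("DAPI" %in% names(out)) {
    out$DAPI <- preprocess_endpoint(out$DAPI,
                                    dapi_threshold = dapi_threshold,
                                    dapi_stat = dapi_stat,
                                    iqr_mult = iqr_mult)
  }
  dapi_ds <- out$DAPI
  for (ep in setdiff(names(out), "DAPI")) {
    use_dapi <- if (ep %in% c("CASP", "H2AX", "8OHG")) dapi_ds
    out[[ep]] <- preprocess_endpoint(out[[ep]], dapi = use_dapi,
                                     dapi_threshold = dapi_threshold,
                                     dapi_stat = dapi_stat,
                                     iqr_mult = iqr_mult)
  }
  if (all(c("CASP", "CTG", "DAPI") %in% names(out))) {
    out$CASP <- apply_caspase_normalization(out$CASP, out$CTG, out$DAPI)
  }
  lapply(out, aggregate_replicates, stat = aggregate_stat)
}

#' Run a full campaign from raw files to scores
#'
#' Convenience wrapper: ingest, preprocess, compute the dose-response
#' metrics, and score. Returns every intermediate product.
#'
#' @inheritParams ingest_campaign
#' @param slices Optional manual slice list for [tox5_pipeline()].
#' @param n_boot Bootstrap resamples for confidence intervals (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return List with `datasets`, `metrics`, `wide`, `tox5` (scores etc.)
#'   and `intervals`.
#' @export
run_tox5_campaign <- function(raw_dirs, template,
                              geometry = plate_geometry(),
                              slices = NULL, n_boot = 0, seed = 1L) {
  datasets <- ingest_campaign(raw_dirs, template, geometry)
  datasets <- preprocess_campaign(datasets)
  metrics <- metrics_table(datasets)
  wide <- metrics_wide(metrics)
  tox5 <- tox5_pipeline(wide, slices = slices)
  intervals <- NULL
  if (n_boot >= 2) {
    intervals <- bootstrap_intervals(tox5$transformed, tox5$slices,
                                     n_boot = n_boot, seed = seed)
  }
  list(datasets = datasets, metrics = metrics, wide = wide, tox5 = tox5,
       intervals = intervals)
}
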