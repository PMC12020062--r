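#' Serialize a campaign into one hierarchical NeXus-style HDF5 file
#'
#' One `entry_<endpoint>` group (class `NXentry`) per endpoint holds the
#' well-level records (`wells` subgroup, one dataset per column — the
#' lossless layer) and a dense `data` group (class `NXdata`) with the raw
#' values as a material x dose x time x replicate x cell line x serum
#' matrix plus its axis vectors; sparse designs are padded with NaN.
#' Derived results live under `NXprocess` groups: `process_normalized`
#' (dense normalized matrix per endpoint), `process_median` (replicate
#' aggregates), and at root level `process_doseresponse` (metrics table)
#' and `process_tox5` (scores, ranks, confidence intervals). Provenance
#' logs are stored as JSON attributes. The file is plain HDF5, readable by
#' any generic HDF5 tool.
#'
#' @param datasets Named list of [hts_dataset()] objects (or a single one).
#' @param metrics Optional long metrics table ([metrics_table()]).
#' @param scores Optional `tox5_result` ([compute_scores()]).
#' @param intervals Optional CI table ([bootstrap_intervals()]).
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_nexus <- function(datasets, metrics = NULL, scores = NULL,
                        intervals = NULL, path) {
  if (inherits(datasets, "hts_dataset")) {
    datasets <- stats::setNames(list(datasets), datasets$endpoint)
  }
  stopifnot(all(vapply(datasets, inherits, logical(1), "hts_dataset")))

  lib_materials <- sort(unique(unlist(lapply(datasets, function(ds) {
    ds$data$material_id[ds$data$role == "treated"]
  }))))
  if (!is.null(metrics)) {
    extra <- setdiff(unique(metrics$material_id), lib_materials)
    if (length(extra)) {
      stop("metrics reference material(s) absent from the datasets: ",
           paste(extra, collapse = ", "), " (layer: dose-response)",
           call. = FALSE)
    }
  }
  if (!is.null(scores)) {
    extra <- setdiff(unique(scores$material_id), lib_materials)
    if (length(extra)) {
      stop("scores reference material(s) absent from the datasets: ",
           paste(extra, collapse = ", "), " (layer: tox5)", call. = FALSE)
    }
  }

  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  .h5attr(path, "/", "NX_class", "NXroot")
  .h5attr(path, "/", "creator", "tox5r")

  for (ep in names(datasets)) {
    ds <- datasets[[ep]]
    g <- paste0("entry_", ep)
    rhdf5::h5createGroup(path, g)
    .h5attr(path, g, "NX_class", "NXentry")
    .h5attr(path, g, "endpoint", ep)
    .h5attr(path, g, "layers", paste(ds$layers, collapse = ","))
    .h5attr(path, g, "provenance", .prov_to_json(ds$provenance))
    .h5attr(path, g, "growth_area_cm2", ds$geometry$growth_area_cm2)
    .h5attr(path, g, "well_volume_ul", ds$geometry$well_volume_ul)

    .write_table(path, paste0(g, "/wells"), ds$data)
    if (!is.null(ds$aggregated)) {
      pg <- paste0(g, "/process_median")
      .write_table(path, pg, ds$aggregated)
      .h5attr(path, pg, "NX_class", "NXprocess")
    }

    dn <- .dense_from_records(ds$data, "raw")
    dg <- paste0(g, "/data")
    rhdf5::h5createGroup(path, dg)
    .h5attr(path, dg, "NX_class", "NXdata")
    .h5attr(path, dg, "signal", "raw")
    .h5attr(path, dg, "axes", paste(names(dn$axes), collapse = ","))
    rhdf5::h5write(dn$array, path, paste0(dg, "/raw"))
    for (ax in names(dn$axes)) {
      rhdf5::h5write(dn$axes[[ax]], path, paste0(dg, "/", ax))
    }
    if ("normalized" %in% names(ds$data)) {
      pn <- .dense_from_records(ds$data, "normalized")
      pg <- paste0(g, "/process_normalized")
      rhdf5::h5createGroup(path, pg)
      .h5attr(path, pg, "NX_class", "NXprocess")
      rhdf5::h5write(pn$array, path, paste0(pg, "/normalized"))
    }
  }

  if (!is.null(metrics)) {
    .write_table(path, "process_doseresponse", metrics)
    .h5attr(path, "process_doseresponse", "NX_class", "NXprocess")
  }
  if (!is.null(scores) || !is.null(intervals)) {
    rhdf5::h5createGroup(path, "process_tox5")
    .h5attr(path, "process_tox5", "NX_class", "NXprocess")
    if (!is.null(scores)) {
      .write_table(path, "process_tox5/scores",
                   tibble::as_tibble(as.data.frame(scores)))
    }
    if (!is.null(intervals)) {
      .write_table(path, "process_tox5/intervals", intervals)
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

.h5attr <- function(path, obj, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (obj %in% c("/", "")) {
    oid <- rhdf5::H5Gopen(fid, "/")
  } else {
    oid <- rhdf5::H5Gopen(fid, obj)
  }
  on.exit(rhdf5::H5Gclose(oid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, oid, name)
}

.read_h5attr <- function(path, obj, name) {
  a <- tryCatch(rhdf5::h5readAttributes(path, obj), error = function(e) NULL)
  if (is.null(a) || is.null(a[[name]])) return(NULL)
  as.vector(a[[name]])
}

# write a data frame as one dataset per column (strings: NA -> "")
.write_table <- function(path, group, df) {
  rhdf5::h5createGroup(path, group)
  .h5attr(path, group, "columns", paste(names(df), collapse = ","))
  for (cn in names(df)) {
    v <- df[[cn]]
    if (is.factor(v)) v <- as.character(v)
    if (is.character(v)) v[is.na(v)] <- ""
    rhdf5::h5write(v, path, paste0(group, "/", cn))
  }
}

.read_table <- function(path, group) {
  cols <- strsplit(.read_h5attr(path, group, "columns"), ",")[[1]]
  out <- lapply(cols, function(cn) {
    v <- rhdf5::h5read(path, paste0(group, "/", cn))
    v <- as.vector(v)
    if (is.character(v)) v[v == ""] <- NA_character_
    v
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

.prov_to_json <- function(prov) {
  as.character(jsonlite::toJSON(prov, auto_unbox = TRUE, null = "null"))
}

.dense_from_records <- function(d, layer) {
  t1 <- d[d$role == "treated", ]
  axes <- list(
    material = sort(unique(t1$material_id)),
    dose = sort(unique(t1$dose_value)),
    time_h = sort(unique(t1$time_h)),
    replicate = sort(unique(t1$replicate)),
    cell_line = sort(unique(t1$cell_line)),
    serum = sort(unique(as.character(t1$serum)))
  )
  arr <- array(NA_real_, dim = vapply(axes, length, integer(1)))
  idx <- cbind(
    match(t1$material_id, axes$material),
    match(t1$dose_value, axes$dose),
    match(t1$time_h, axes$time_h),
    match(t1$replicate, axes$replicate),
    match(t1$cell_line, axes$cell_line),
    match(as.character(t1$serum), axes$serum)
  )
  # technical duplicates: keep the first occurrence in the dense view
  first <- !duplicated(idx)
  arr[idx[first, , drop = FALSE]] <- t1[[layer]][first]
  list(array = arr, axes = axes)
}

#' Read a NeXus-style file written by [write_nexus()]
#'
#' @param path HDF5 file path.
#' @return A list with `datasets` (named list of [hts_dataset()]),
#'   `metrics` (tibble or `NULL`) and `scores`/`intervals`.
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- tryCatch(rhdf5::h5ls(path, recursive = FALSE),
                 error = function(e) {
                   stop("not a readable HDF5 file: ", path, " (",
                        conditionMessage(e), ")", call. = FALSE)
                 })
  root_class <- .read_h5attr(path, "/", "NX_class")
  if (is.null(root_class) || root_class != "NXroot") {
    stop("format error: missing NXroot class attribute on '/'",
         call. = FALSE)
  }
  entries <- ls$name[grepl("^entry_", ls$name)]
  datasets <- list()
  for (g in entries) {
    cls <- .read_h5attr(path, g, "NX_class")
    if (is.null(cls) || cls != "NXentry") {
      stop("format error: group ", g, " lacks the NXentry class attribute",
           call. = FALSE)
    }
    ep <- .read_h5attr(path, g, "endpoint")
    geom <- plate_geometry(
      growth_area_cm2 = .read_h5attr(path, g, "growth_area_cm2"),
      well_volume_ul = .read_h5attr(path, g, "well_volume_ul")
    )
    d <- .read_table(path, paste0(g, "/wells"))
    d$replicate <- as.integer(d$replicate)
    d$row <- as.integer(d$row)
    d$col <- as.integer(d$col)
    d$tech_rep <- as.integer(d$tech_rep)
    ds <- hts_dataset(ep, d, geom)
    ds$layers <- strsplit(.read_h5attr(path, g, "layers"), ",")[[1]]
    ds$provenance <- jsonlite::fromJSON(
      .read_h5attr(path, g, "provenance"), simplifyVector = FALSE
    )
    sub <- rhdf5::h5ls(path, recursive = TRUE)
    med <- paste0(g, "/process_median")
    if (any(sub$group == paste0("/", g) & sub$name == "process_median")) {
      ds$aggregated <- .read_table(path, med)
    }
    datasets[[ep]] <- ds
  }
  all_ls <- rhdf5::h5ls(path, recursive = FALSE)
  metrics <- if ("process_doseresponse" %in% all_ls$name) {
    .read_table(path, "process_doseresponse")
  }
  scores <- intervals <- NULL
  if ("process_tox5" %in% all_ls$name) {
    sub <- rhdf5::h5ls(path, recursive = TRUE)
    if (any(sub$group == "/process_tox5" & sub$name == "scores")) {
      scores <- .read_table(path, "process_tox5/scores")
      scores$rank <- as.integer(scores$rank)
    }
    if (any(sub$group == "/process_tox5" & sub$name == "intervals")) {
      intervals <- .read_table(path, "process_tox5/intervals")
    }
  }
  list(datasets = datasets, metrics = metrics, scores = scores,
       intervals = intervals)
}

#' Export one layer of a dataset as a long table
#'
#' @param ds An [hts_dataset()].
#' @param layer `"raw"`, `"normalized"` (well-level, all metadata columns)
#'   or a replicate-aggregate layer such as `"median_of_replicates"`.
#' @return A tibble ready for CSV export.
#' @export
to_long_table <- function(ds, layer = "raw") {
  stopifnot(inherits(ds, "hts_dataset"))
  if (layer %in% names(ds$data)) {
    keep <- c("plate_id", "well", "endpoint", "time_h", "cell_line",
              "replicate", "serum", "tech_rep", "material_id", "dose_value",
              "dose_unit", "role", layer)
    return(ds$data[, intersect(keep, names(ds$data))])
  }
  if (grepl("_of_replicates$", layer) && !is.null(ds$aggregated)) {
    return(ds$aggregated)
  }
  stop("unknown layer '", layer, "' for endpoint ", ds$endpoint,
       call. = FALSE)
}
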