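#' The filename dialect used to auto-fill file metadata
#'
#' Raw-file names in a screening campaign typically concatenate the endpoint,
#' exposure time, replicate number, cell line and serum condition with
#' underscores (e.g. `CTG_24h_R2_BEAS2B_FBS.csv`). The pattern declares the
#' token separator and the vocabularies used to recognize each token;
#' recognition is by token content, so order does not matter and unknown
#' tokens are simply ignored.
#'
#' @param sep Regular expression splitting the (extension-stripped) filename
#'   into tokens.
#' @param dictionary Harmonization dictionary used to recognize endpoint and
#'   cell-line tokens (see [default_harmonization()]).
#' @param endpoints Canonical endpoint labels recognized as endpoint tokens.
#' @param cell_lines Canonical cell-line labels recognized as cell-line
#'   tokens.
#' @param serum_with,serum_without Tokens (case-insensitive) marking the
#'   serum condition.
#' @return A list of class `filename_pattern`.
#' @export
filename_pattern <- function(sep = "[_\\s]+",
                             dictionary = default_harmonization(),
                             endpoints = c("CTG", "DAPI", "CASP", "H2AX", "8OHG"),
                             cell_lines = c("BEAS-2B", "HepG2", "A549", "THP-1"),
                             serum_with = c("FBS", "serum"),
                             serum_without = c("noFBS", "noserum", "serumfree")) {
  if (!is.character(sep) || length(sep) != 1L || !nzchar(sep)) {
    stop("malformed filename pattern: `sep` must be a non-empty regex",
         call. = FALSE)
  }
  structure(
    list(sep = sep, dictionary = dictionary, endpoints = endpoints,
         cell_lines = cell_lines, serum_with = serum_with,
         serum_without = serum_without),
    class = "filename_pattern"
  )
}

#' Parse a raw data filename into file metadata
#'
#' Recognizes endpoint, exposure time (`<n>h`), replicate (`R<n>`), cell
#' line and serum tokens. Unrecognized fields are left missing for manual
#' correction in the annotation template; imaging well-summary files, which
#' carry several endpoints per file, legitimately have no endpoint token.
#'
#' @param filename File name (path components and extension are ignored).
#' @param pattern A [filename_pattern()].
#' @return A one-row tibble (fields `filename`, `endpoint`, `time_h`,
#'   `replicate`, `cell_line`, `serum`); unrecognized fields are `NA`.
#' @examples
#' parse_raw_filename("CTG_24h_R2_BEAS2B.csv")
#' parse_raw_filename("imaging_72h_R4.txt")
#' @export
parse_raw_filename <- function(filename, pattern = filename_pattern()) {
  if (!inherits(pattern, "filename_pattern")) {
    stop("malformed filename pattern: build it with filename_pattern()",
         call. = FALSE)
  }
  if (!is.character(filename) || length(filename) != 1L || !nzchar(filename)) {
    stop("`filename` must be a single non-empty string", call. = FALSE)
  }
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(filename))
  tokens <- strsplit(base, pattern$sep)[[1]]
  tokens <- tokens[nzchar(tokens)]

  meta <- tibble::tibble(
    filename = basename(filename), endpoint = NA_character_,
    time_h = NA_real_, replicate = NA_integer_,
    cell_line = NA_character_, serum = NA_character_
  )
  for (tok in tokens) {
    canon <- canonical_label(tok, pattern$dictionary)
    if (is.na(meta$endpoint) && canon %in% pattern$endpoints) {
      meta$endpoint <- canon
    } else if (is.na(meta$cell_line) && canon %in% pattern$cell_lines) {
      meta$cell_line <- canon
    } else if (is.na(meta$time_h) && grepl("^[0-9]+(\\.[0-9]+)?h$", tok,
                                           ignore.case = TRUE)) {
      meta$time_h <- as.numeric(sub("h$", "", tok, ignore.case = TRUE))
    } else if (is.na(meta$replicate) && grepl("^[Rr][0-9]+$", tok)) {
      meta$replicate <- as.integer(sub("^[Rr]", "", tok))
    } else if (is.na(meta$serum) &&
               tolower(tok) %in% tolower(pattern$serum_without)) {
      meta$serum <- "without"
    } else if (is.na(meta$serum) &&
               tolower(tok) %in% tolower(pattern$serum_with)) {
      meta$serum <- "with"
    }
  }
  meta
}

#' Construct an annotation template
#'
#' The template mirrors a metadata workbook with three sheets: a front sheet
#' mapping plate positions to materials and doses, a files sheet with
#' per-file metadata, and a materials sheet with display names and optional
#' specific surface area (SBET, m2/g).
#'
#' @param front_sheet Tibble with columns `well`, `material_id`,
#'   `dose_value`, `dose_unit`, `role` (`treated`/`control`/`blank`).
#' @param files_sheet Tibble with columns `filename`, `endpoint`, `time_h`,
#'   `replicate`, `cell_line`, `serum`; may be empty before auto-fill.
#' @param materials_sheet Tibble with columns `material_id`, `name`,
#'   optional `erm` and `sbet_m2g`.
#' @return A list of class `annotation_template`.
#' @export
annotation_template <- function(front_sheet,
                                files_sheet = empty_files_sheet(),
                                materials_sheet = NULL) {
  front_sheet <- tibble::as_tibble(front_sheet)
  need <- c("well", "material_id", "dose_value", "dose_unit", "role")
  miss <- setdiff(need, names(front_sheet))
  if (length(miss)) {
    stop("front sheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_ctrl <- front_sheet$role == "control" & front_sheet$dose_value != 0
  if (any(bad_ctrl, na.rm = TRUE)) {
    stop("control wells must have dose 0: ",
         paste(front_sheet$well[which(bad_ctrl)], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(materials_sheet)) {
    ids <- unique(front_sheet$material_id[front_sheet$role == "treated"])
    materials_sheet <- tibble::tibble(material_id = ids, name = ids,
                                      erm = NA_character_, sbet_m2g = NA_real_)
  }
  materials_sheet <- tibble::as_tibble(materials_sheet)
  if (!"sbet_m2g" %in% names(materials_sheet)) {
    materials_sheet$sbet_m2g <- NA_real_
  }
  if (any(materials_sheet$sbet_m2g < 0, na.rm = TRUE)) {
    stop("SBET values must be >= 0", call. = FALSE)
  }
  structure(
    list(front_sheet = front_sheet,
         files_sheet = tibble::as_tibble(files_sheet),
         materials_sheet = materials_sheet),
    class = "annotation_template"
  )
}

#' @rdname annotation_template
#' @export
empty_files_sheet <- function() {
  tibble::tibble(filename = character(), endpoint = character(),
                 time_h = numeric(), replicate = integer(),
                 cell_line = character(), serum = character())
}

#' Auto-fill the files sheet of an annotation template from filenames
#'
#' Appends one parsed metadata row per filename not already present.
#' Existing rows — typically manually corrected — are never overwritten, so
#' the operation is idempotent. Labels are canonicalized through the
#' pattern's harmonization dictionary.
#'
#' @param filenames Character vector of raw data file names.
#' @param template An [annotation_template()].
#' @param pattern A [filename_pattern()].
#' @return The template with an updated files sheet.
#' @export
autofill_files_sheet <- function(filenames, template,
                                 pattern = filename_pattern()) {
  stopifnot(inherits(template, "annotation_template"))
  sheet <- template$files_sheet
  if (anyDuplicated(sheet$filename)) {
    stop("files sheet has duplicate filename rows", call. = FALSE)
  }
  filenames <- basename(filenames)
  if (anyDuplicated(filenames)) {
    stop("duplicate filenames supplied: ",
         paste(unique(filenames[duplicated(filenames)]), collapse = ", "),
         call. = FALSE)
  }
  new <- setdiff(filenames, sheet$filename)
  if (length(new)) {
    rows <- dplyr::bind_rows(lapply(new, parse_raw_filename, pattern = pattern))
    sheet <- dplyr::bind_rows(sheet, rows)
  }
  sheet$endpoint <- canonical_label(sheet$endpoint, pattern$dictionary)
  sheet$cell_line <- canonical_label(sheet$cell_line, pattern$dictionary)
  template$files_sheet <- sheet
  template
}

#' Read a plate-reader CSV as a 16 x 24 value grid
#'
#' The dialect is a CSV holding, after any number of header lines, exactly
#' 16 rows of 24 comma-separated numeric fields (empty field = missing
#' value). The plate identifier is taken from a `plate_id,<id>` header line
#' when present, otherwise from the file name.
#'
#' @param path Path to the CSV file.
#' @return A list with `plate_id` (character) and `grid` (16 x 24 numeric
#'   matrix, dimnames rows A--P / columns 1--24; `NA` = missing).
#' @export
read_plate_reader_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  plate_id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  id_line <- grep("^\\s*plate_?id\\s*[:,]", lines, ignore.case = TRUE)
  if (length(id_line)) {
    plate_id <- trimws(sub("^\\s*plate_?id\\s*[:,]\\s*", "", lines[id_line[1]],
                           ignore.case = TRUE))
  }

  fields <- strsplit(lines, ",", fixed = TRUE)
  is_data <- vapply(fields, function(f) {
    f <- trimws(f)
    length(f) == 24L &&
      all(f == "" | !is.na(suppressWarnings(as.numeric(f))))
  }, logical(1))
  data_rows <- which(is_data)
  if (length(data_rows) != 16L || any(diff(data_rows) != 1L)) {
    stop(sprintf(
      "plate format error in '%s': expected a contiguous block of 16 rows x 24 columns, found %d data row(s)",
      basename(path), length(data_rows)), call. = FALSE)
  }
  grid <- t(vapply(fields[data_rows], function(f) {
    suppressWarnings(as.numeric(ifelse(trimws(f) == "", NA, f)))
  }, numeric(24)))
  dimnames(grid) <- list(PLATE_ROWS, as.character(1:24))
  list(plate_id = plate_id, grid = grid)
}

#' Read an imaging well-summary table
#'
#' Tab-separated file with columns well, endpoint label and well-median
#' intensity; an optional header line is skipped. Endpoint labels are
#' canonicalized; unknown labels trigger a warning and pass through
#' unchanged. DAPI technical duplicates (two rows per well) are preserved as
#' separate rows.
#'
#' @param path Path to the TXT file.
#' @param dictionary Harmonization dictionary for endpoint labels.
#' @param known_endpoints Labels not warned about.
#' @return A tibble with columns `well`, `endpoint`, `value`.
#' @export
read_imaging_table <- function(path, dictionary = default_harmonization(),
                               known_endpoints = c("CTG", "DAPI", "CASP",
                                                   "H2AX", "8OHG")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(well = character(), endpoint = character(),
                          value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fld <- vapply(fields, length, integer(1))
  if (any(n_fld != 3L)) {
    stop(sprintf("imaging format error in '%s': line(s) without 3 tab-separated fields",
                 basename(path)), call. = FALSE)
  }
  first_is_header <- !grepl("^[A-Pa-p][0-9]{1,2}$", trimws(fields[[1]][1]))
  if (first_is_header) fields <- fields[-1]
  well <- vapply(fields, `[`, character(1), 1L)
  endpoint <- canonical_label(vapply(fields, `[`, character(1), 2L), dictionary)
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  unknown <- setdiff(unique(endpoint), known_endpoints)
  if (length(unknown)) {
    warning("unknown endpoint label(s) passed through: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(well = well_to_rc(well)$well, endpoint = endpoint,
                 value = value)
}

#' Per-endpoint container of layered HTS data
#'
#' One `hts_dataset` holds every well record of one endpoint in long format,
#' with value layers (`raw`, then e.g. `normalized`) as aligned columns, an
#' optional replicate-aggregated table, the plate geometry, and an
#' append-only provenance log of applied operations.
#'
#' @param endpoint Canonical endpoint label.
#' @param data Tibble of well records (one row per measured well, incl. the
#'   `raw` value column).
#' @param geometry A [plate_geometry()].
#' @return Object of class `hts_dataset`.
#' @export
hts_dataset <- function(endpoint, data, geometry = plate_geometry()) {
  data <- tibble::as_tibble(data)
  structure(
    list(endpoint = endpoint, data = data, layers = "raw",
         aggregated = NULL, geometry = geometry, provenance = list()),
    class = "hts_dataset"
  )
}

#' @export
print.hts_dataset <- function(x, ...) {
  cat(sprintf("<hts_dataset> endpoint %s: %d well records, layers: %s\n",
              x$endpoint, nrow(x$data), paste(x$layers, collapse = ", ")))
  if (length(x$provenance)) {
    cat("provenance:", paste(vapply(x$provenance, `[[`, character(1), "op"),
                             collapse = " -> "), "\n")
  }
  invisible(x)
}

log_provenance <- function(ds, op, params = list()) {
  ds$provenance <- c(ds$provenance, list(list(op = op, params = params)))
  ds
}

#' Annotate raw plate files into per-endpoint datasets
#'
#' Combines plate-reader grids and imaging tuples with the annotation
#' template: each file's metadata comes from the files sheet, each well's
#' material/dose/role from the front sheet. The result is one long-format
#' dataset per endpoint with the raw value layer populated and provenance
#' initialized.
#'
#' @param plate_files Character vector of plate-reader CSV paths (may be
#'   empty).
#' @param imaging_files Character vector of imaging TXT paths (may be
#'   empty).
#' @param template An [annotation_template()] whose files sheet covers every
#'   file.
#' @param geometry A [plate_geometry()].
#' @return Named list of [hts_dataset()] objects, one per endpoint.
#' @export
annotate_dataset <- function(plate_files = character(),
                             imaging_files = character(),
                             template, geometry = plate_geometry()) {
  stopifnot(inherits(template, "annotation_template"))
  files <- template$files_sheet
  front <- template$front_sheet
  front$well <- well_to_rc(front$well)$well

  lookup_meta <- function(path) {
    i <- match(basename(path), files$filename)
    if (is.na(i)) {
      stop("no files-sheet metadata for file: ", basename(path),
           call. = FALSE)
    }
    files[i, ]
  }
  join_front <- function(rec, plate_id) {
    i <- match(rec$well, front$well)
    if (anyNA(i)) {
      stop("well(s) without front-sheet annotation on plate ", plate_id, ": ",
           paste(unique(rec$well[is.na(i)]), collapse = ", "), call. = FALSE)
    }
    rec$material_id <- front$material_id[i]
    rec$dose_value <- front$dose_value[i]
    rec$dose_unit <- front$dose_unit[i]
    rec$role <- front$role[i]
    rec
  }

  chunks <- list()
  for (path in plate_files) {
    meta <- lookup_meta(path)
    pl <- read_plate_reader_table(path)
    rc <- expand.grid(row = 1:16, col = 1:24, KEEP.OUT.ATTRS = FALSE)
    rec <- tibble::tibble(
      plate_id = pl$plate_id,
      well = rc_to_well(rc$row, rc$col), row = rc$row, col = rc$col,
      endpoint = meta$endpoint, time_h = meta$time_h,
      cell_line = meta$cell_line, replicate = meta$replicate,
      serum = meta$serum, tech_rep = 1L,
      raw = pl$grid[cbind(rc$row, rc$col)]
    )
    chunks[[length(chunks) + 1L]] <- join_front(rec, pl$plate_id)
  }
  for (path in imaging_files) {
    meta <- lookup_meta(path)
    tab <- read_imaging_table(path)
    if (!nrow(tab)) next
    rc <- well_to_rc(tab$well)
    rec <- tibble::tibble(
      plate_id = sub("\\.[A-Za-z0-9]+$", "", basename(path)),
      well = rc$well, row = rc$row, col = rc$col,
      endpoint = tab$endpoint, time_h = meta$time_h,
      cell_line = meta$cell_line, replicate = meta$replicate,
      serum = meta$serum, tech_rep = 1L,
      raw = tab$value
    )
    # number technical duplicates (DAPI appears twice per well) in file order
    rec <- rec |>
      dplyr::group_by(.data$well, .data$endpoint) |>
      dplyr::mutate(tech_rep = seq_len(dplyr::n())) |>
      dplyr::ungroup()
    chunks[[length(chunks) + 1L]] <- join_front(rec, rec$plate_id[1])
  }
  if (!length(chunks)) stop("no input files supplied", call. = FALSE)
  all_rec <- dplyr::bind_rows(chunks)

  out <- lapply(split(all_rec, all_rec$endpoint), function(d) {
    ds <- hts_dataset(d$endpoint[1], d, geometry)
    log_provenance(ds, "annotate_dataset",
                   list(n_files = length(plate_files) + length(imaging_files)))
  })
  out[order(names(out))]
}
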