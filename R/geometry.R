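#' Plate geometry for a 384-well microplate
#'
#' Describes the screening unit: a 16-row (A--P) by 24-column plate with a
#' per-well cell growth area and working volume. The growth area converts
#' nominal doses (ug/ml) into per-area doses (ug/cm2), and the volume gives
#' the mass of material delivered per well.
#'
#' @param growth_area_cm2 Cell growth area per well in cm2. Default 0.1
#'   (10 mm2, Greiner u-clear); quantum-dot screens use 0.0795 (Corning).
#' @param well_volume_ul Final assay volume per well in ul (default 50).
#' @return An object of class `plate_geometry` with fields `n_rows`,
#'   `n_cols`, `n_wells`, `growth_area_cm2`, `well_volume_ul`.
#' @examples
#' plate_geometry()
#' plate_geometry(growth_area_cm2 = 0.0795)
#' @export
plate_geometry <- function(growth_area_cm2 = 0.1, well_volume_ul = 50) {
  if (!is.numeric(growth_area_cm2) || growth_area_cm2 <= 0) {
    stop("`growth_area_cm2` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(well_volume_ul) || well_volume_ul <= 0) {
    stop("`well_volume_ul` must be a positive number", call. = FALSE)
  }
  structure(
    list(
      n_rows = 16L, n_cols = 24L, n_wells = 384L,
      growth_area_cm2 = as.numeric(growth_area_cm2),
      well_volume_ul = as.numeric(well_volume_ul)
    ),
    class = "plate_geometry"
  )
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf(
    "384-well plate geometry (16 x 24), growth area %g cm2/well, volume %g ul/well\n",
    x$growth_area_cm2, x$well_volume_ul
  ))
  invisible(x)
}

PLATE_ROWS <- LETTERS[1:16]

#' Parse well labels into 1-based (row, column) coordinates
#'
#' Accepts both zero-padded and plain labels ("A01" and "A1" are the same
#' well). Rows run A--P, columns 1--24.
#'
#' @param well Character vector of well labels.
#' @return A data frame with columns `well` (canonical, unpadded), `row`
#'   (1--16) and `col` (1--24).
#' @examples
#' well_to_rc(c("A01", "P24"))
#' @export
well_to_rc <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well label(s): ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- match(vapply(m, `[`, character(1), 2L), PLATE_ROWS)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(col < 1L | col > 24L)) {
    stop("well column outside 1-24: ", paste(unique(well[col < 1L | col > 24L]),
         collapse = ", "), call. = FALSE)
  }
  data.frame(well = rc_to_well(row, col), row = row, col = col,
             stringsAsFactors = FALSE)
}

#' Build canonical well labels from (row, column) coordinates
#'
#' @param row Integer row index 1--16 (A--P).
#' @param col Integer column index 1--24.
#' @return Character vector of labels like "A1", "P24" (no zero padding).
#' @export
rc_to_well <- function(row, col) {
  stopifnot(all(row >= 1L & row <= 16L), all(col >= 1L & col <= 24L))
  paste0(PLATE_ROWS[row], as.integer(col))
}
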