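#' Read an annotation template from disk
#'
#' Two on-disk dialects are supported: a directory of three CSV sheets
#' (`front_sheet.csv`, `files.csv`, `materials.csv`) — the format the
#' synthetic campaign generator emits — or an XLSX workbook with sheets
#' "Front sheet", "Files" and "Materials" (requires the readxl package).
#'
#' @param path Directory of CSV sheets or path to an `.xlsx` workbook.
#' @return An [annotation_template()].
#' @export
read_annotation_template <- function(path) {
  if (dir.exists(path)) {
    read_sheet <- function(name, required = TRUE) {
      f <- file.path(path, name)
      if (!file.exists(f)) {
        if (required) stop("missing template sheet: ", f, call. = FALSE)
        return(NULL)
      }
      readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    }
    front <- read_sheet("front_sheet.csv")
    files <- read_sheet("files.csv", required = FALSE)
    mats <- read_sheet("materials.csv", required = FALSE)
  } else if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX templates requires the 'readxl' package",
           call. = FALSE)
    }
    front <- readxl::read_excel(path, sheet = "Front sheet")
    sheets <- readxl::excel_sheets(path)
    files <- if ("Files" %in% sheets) readxl::read_excel(path, "Files")
    mats <- if ("Materials" %in% sheets) readxl::read_excel(path, "Materials")
  } else {
    stop("template path must be a sheet directory or an .xlsx file: ", path,
         call. = FALSE)
  }
  if (is.null(files)) files <- empty_files_sheet()
  files$replicate <- as.integer(files$replicate)
  annotation_template(front, files, mats)
}

#' Write an annotation template as CSV sheets
#'
#' @param template An [annotation_template()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation_template <- function(template, dir) {
  stopifnot(inherits(template, "annotation_template"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(template$front_sheet, file.path(dir, "front_sheet.csv"))
  readr::write_csv(template$files_sheet, file.path(dir, "files.csv"))
  readr::write_csv(template$materials_sheet, file.path(dir, "materials.csv"))
  invisible(dir)
}
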