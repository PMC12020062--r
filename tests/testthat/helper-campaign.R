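# Shared fixture builders. Everything is generated in code at test time.

# small preprocessed campaign; memoised per test file to keep runs fast
local({
  cache <- new.env(parent = emptyenv())
  make_campaign <<- function(n_materials = 4, seed = 11, noise_cv = 0.02,
                             design = design_minimal(), ...) {
    key <- paste(n_materials, seed, noise_cv,
                 paste(deparse(list(...)), collapse = ""), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    dir <- file.path(tempfile("camp"), "raw")
    truth <- simulate_material_library(n_materials, design, seed = seed,
                                       noise_cv = noise_cv, ...)
    files <- emit_plates(truth, dir)
    out <- list(truth = truth, files = files, dir = dir)
    cache[[key]] <- out
    out
  }
})

# a plate CSV with a constant value everywhere (or a given grid)
write_plate_csv <- function(path, value = 1, grid = NULL, plate_id = NULL,
                            n_rows = 16) {
  if (is.null(grid)) grid <- matrix(value, n_rows, 24)
  lines <- apply(grid, 1, function(r) {
    paste(ifelse(is.na(r), "", format(r)), collapse = ",")
  })
  if (!is.null(plate_id)) lines <- c(paste0("plate_id,", plate_id), lines)
  writeLines(lines, path)
  path
}

# a front sheet where every well is a control at dose 0 except a single
# material row, handy for unit tests of annotation
simple_front_sheet <- function() {
  rc <- expand.grid(row = 1:16, col = 1:24)
  tibble::tibble(
    well = rc_to_well(rc$row, rc$col),
    material_id = ifelse(rc$col <= 12, "MAT-1",
                         ifelse(rc$col <= 14, "vehicle", "blank")),
    dose_value = ifelse(rc$col <= 12, 2^(12 - rc$col), 0),
    dose_unit = "ug/ml",
    role = ifelse(rc$col <= 12, "treated",
                  ifelse(rc$col <= 14, "control", "blank"))
  )
}
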