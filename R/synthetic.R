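#' Campaign designs for the synthetic generator
#'
#' `design_calibrate()` mirrors the plate design of a full five-endpoint
#' screen: a 12-dose two-fold dilution series from 256 ug/ml, four
#' biological replicates, imaging endpoints at 6/24/72 h, cell viability
#' (CTG) with an additional 0-h baseline plate, one cell line, with and
#' without serum, and DAPI measured as two technical duplicates per well.
#' `design_minimal()` is a scaled-down variant for fast tests.
#'
#' @param n_doses Number of doses in the two-fold series.
#' @param max_dose_ugml Highest tested dose (ug/ml).
#' @param n_replicates Biological replicates.
#' @param serum Serum conditions (`"with"`, `"without"`).
#' @param endpoints Endpoints screened.
#' @param times_imaging Imaging time points (h).
#' @param include_0h Whether CTG gets a 0-h baseline plate.
#' @return A list of class `hts_design`.
#' @export
design_calibrate <- function(n_doses = 12, max_dose_ugml = 256,
                             n_replicates = 4,
                             serum = c("with", "without"),
                             endpoints = c("CTG", "DAPI", "CASP", "H2AX",
                                           "8OHG"),
                             times_imaging = c(6, 24, 72),
                             include_0h = TRUE) {
  structure(
    list(
      endpoints = endpoints,
      doses = max_dose_ugml / 2^(seq_len(n_doses) - 1),
      n_replicates = n_replicates,
      serum = serum,
      cell_line = "BEAS-2B",
      times_imaging = times_imaging,
      times_ctg = if (include_0h) c(0, times_imaging) else times_imaging,
      dapi_tech_reps = 2L
    ),
    class = "hts_design"
  )
}

#' @rdname design_calibrate
#' @export
design_minimal <- function() {
  design_calibrate(n_doses = 6, n_replicates = 3, serum = "with",
                   times_imaging = c(24))
}

# endpoint raw-signal parameters of the generator
.endpoint_params <- function() {
  list(
    CTG = list(type = "viability", base = 10000, base0 = 500, gain = NA),
    DAPI = list(type = "viability", base = 500, base0 = NA, gain = NA),
    CASP = list(type = "effect", base = 200, base0 = NA, gain = 2),
    H2AX = list(type = "effect", base = 300, base0 = NA, gain = 2),
    `8OHG` = list(type = "effect", base = 300, base0 = NA, gain = 2)
  )
}

#' Simulate the ground truth of a synthetic material library
#'
#' Each material's dose-response follows a Hill curve on the effect-fraction
#' scale, `f(d) = emax * d^h / (ec50^h + d^h)`; viability endpoints lose
#' signal proportionally to `f`, effect endpoints gain signal. The library
#' always contains at least one inert material (`emax = 0`) and one potent
#' material, emulating the span from dispersant controls to positive
#' controls. Measurement noise is Gaussian on the plate-reader scale
#' (`noise_cv` times the endpoint's control level); a per-plate lognormal
#' multiplier models plate-to-plate variation. Artifacts — control-well
#' outliers and DAPI focus failures (a 0 reading in a well whose biological
#' replicates are clearly populated) — are injected at generation time and
#' recorded in the truth object.
#'
#' @param n_materials Number of materials (2--16; one plate row each).
#' @param design An `hts_design` (default [design_calibrate()]).
#' @param seed Integer seed; the truth is reproducible given the seed.
#' @param potency_gradient If `TRUE`, EC50s form a strictly ordered
#'   geometric series (most potent first) instead of random draws.
#' @param noise_cv Noise standard deviation as a fraction of the endpoint
#'   control level (default 0.05; 0 = noise-free).
#' @param plate_effect_sd SD of the log-normal per-plate multiplier
#'   (default 0 = off).
#' @param n_control_outliers Control-well outliers to inject.
#' @param n_focus_failures DAPI focus failures to inject.
#' @return A list of class `synthetic_truth`.
#' @export
simulate_material_library <- function(n_materials = 8,
                                      design = design_calibrate(),
                                      seed = 1L,
                                      potency_gradient = FALSE,
                                      noise_cv = 0.05,
                                      plate_effect_sd = 0,
                                      n_control_outliers = 0,
                                      n_focus_failures = 0) {
  stopifnot(inherits(design, "hts_design"))
  if (n_materials < 2 || n_materials > 16) {
    stop("n_materials must be between 2 and 16 (one plate row per material)",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    ids <- sprintf("NM-%02d", seq_len(n_materials))
    if (potency_gradient) {
      ec50 <- 2 * 2^(seq_len(n_materials) - 1)
      emax <- rep(0.9, n_materials)
    } else {
      ec50 <- exp(stats::runif(n_materials, log(2), log(128)))
      emax <- stats::runif(n_materials, 0.6, 0.95)
      # guarantee one potent and one inert profile
      ec50[1] <- 2
      emax[1] <- 0.95
      ec50[n_materials] <- Inf
      emax[n_materials] <- 0
    }
    hill <- rep(2, n_materials)
    materials <- tibble::tibble(
      material_id = ids, row = seq_len(n_materials),
      ec50 = ec50, emax = emax, hill = hill,
      sbet_m2g = round(stats::runif(n_materials, 5, 250), 2)
    )

    plates <- .plate_index(design)
    plates$plate_effect <- if (plate_effect_sd > 0) {
      exp(stats::rnorm(nrow(plates), 0, plate_effect_sd))
    } else {
      rep(1, nrow(plates))
    }

    artifacts <- list(
      control_outliers = tibble::tibble(
        plate_key = character(), well = character(), factor = numeric()
      ),
      focus_failures = tibble::tibble(
        material_id = character(), dose_value = numeric(), time_h = numeric(),
        serum = character(), replicate = integer(), well = character()
      )
    )
    if (n_control_outliers > 0) {
      ctg_plates <- plates$key[plates$kind == "plate" & plates$time_h > 0]
      if (n_control_outliers > length(ctg_plates)) {
        stop("at most one control outlier per plate is supported",
             call. = FALSE)
      }
      pk <- sample(ctg_plates, n_control_outliers)
      artifacts$control_outliers <- tibble::tibble(
        plate_key = pk,
        well = rc_to_well(sample.int(16, n_control_outliers, replace = TRUE),
                          sample(13:14, n_control_outliers, replace = TRUE)),
        factor = 10
      )
    }
    if (n_focus_failures > 0) {
      # hit low-toxicity conditions so the replicate DAPI signal stays high
      img <- plates[plates$kind == "imaging", ]
      if (n_focus_failures > nrow(img)) {
        stop("at most one focus failure per imaging plate is supported",
             call. = FALSE)
      }
      pick <- img[sample.int(nrow(img), n_focus_failures), ]
      inert_row <- which.max(materials$ec50)
      # cycle over dose columns so no two failures share a condition:
      # the replicate median of the other screens must stay high
      cols <- length(design$doses) -
        (seq_len(n_focus_failures) - 1L) %% length(design$doses)
      artifacts$focus_failures <- tibble::tibble(
        material_id = materials$material_id[inert_row],
        dose_value = design$doses[cols],
        time_h = pick$time_h, serum = pick$serum,
        replicate = pick$replicate,
        well = rc_to_well(rep(inert_row, n_focus_failures), cols)
      )
    }

    structure(
      list(design = design, materials = materials, plates = plates,
           noise_cv = noise_cv, plate_effect_sd = plate_effect_sd,
           artifacts = artifacts, geometry = plate_geometry(), seed = seed),
      class = "synthetic_truth"
    )
  })
}

# one row per physical plate/file of the campaign
.plate_index <- function(design) {
  grids <- list()
  for (serum in design$serum) {
    for (rep in seq_len(design$n_replicates)) {
      if ("CTG" %in% design$endpoints) {
        for (t in design$times_ctg) {
          grids[[length(grids) + 1L]] <- tibble::tibble(
            kind = "plate", endpoint = "CTG", time_h = t,
            replicate = rep, serum = serum
          )
        }
      }
      imaging_eps <- setdiff(design$endpoints, "CTG")
      if (length(imaging_eps)) {
        for (t in design$times_imaging) {
          grids[[length(grids) + 1L]] <- tibble::tibble(
            kind = "imaging", endpoint = NA_character_, time_h = t,
            replicate = rep, serum = serum
          )
        }
      }
    }
  }
  plates <- dplyr::bind_rows(grids)
  serum_tag <- ifelse(plates$serum == "with", "FBS", "noFBS")
  plates$filename <- ifelse(
    plates$kind == "plate",
    sprintf("%s_%gh_R%d_BEAS2B_%s.csv", plates$endpoint, plates$time_h,
            plates$replicate, serum_tag),
    sprintf("imaging_%gh_R%d_BEAS2B_%s.txt", plates$time_h,
            plates$replicate, serum_tag)
  )
  plates$key <- sub("\\.[a-z]+$", "", plates$filename)
  plates
}

# deterministic mean raw signal for one well
.true_signal <- function(truth, endpoint, time_h, material_row, dose,
                         role = "treated") {
  pars <- .endpoint_params()[[endpoint]]
  if (role == "blank") return(0.02 * pars$base)  # no cells seeded
  if (endpoint == "CTG" && time_h == 0) return(pars$base0)
  f <- 0
  if (role == "treated" && !is.na(material_row)) {
    m <- truth$materials[material_row, ]
    if (m$emax > 0 && dose > 0) {
      f <- m$emax * dose^m$hill / (m$ec50^m$hill + dose^m$hill)
    }
  }
  if (pars$type == "viability") pars$base * (1 - f)
  else pars$base * (1 + pars$gain * f)
}

# front-sheet layout shared by every plate: material rows x dose columns
.front_layout <- function(truth) {
  design <- truth$design
  n_mat <- nrow(truth$materials)
  rows <- list()
  for (r in seq_len(16)) {
    for (cc in seq_len(24)) {
      if (r <= n_mat && cc <= length(design$doses)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          well = rc_to_well(r, cc),
          material_id = truth$materials$material_id[r],
          dose_value = design$doses[cc], dose_unit = "ug/ml",
          role = "treated"
        )
      } else if (cc %in% 13:14) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          well = rc_to_well(r, cc), material_id = "vehicle",
          dose_value = 0, dose_unit = "ug/ml", role = "control"
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          well = rc_to_well(r, cc), material_id = "blank",
          dose_value = 0, dose_unit = "ug/ml", role = "blank"
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic campaign to disk
#'
#' Emits one plate-reader CSV per CTG plate, one tab-separated well-summary
#' TXT per imaging plate (DAPI as two technical duplicates), the filled
#' annotation template (CSV sheet directory `template/`), and the truth
#' manifest (`truth_manifest.csv`). Raw values are the Hill-model mean times
#' the plate effect plus Gaussian noise; injected artifacts overwrite the
#' affected wells.
#'
#' @param truth A `synthetic_truth` from [simulate_material_library()].
#' @param out_dir Output directory (created).
#' @return Invisible list with `plate_files`, `imaging_files`,
#'   `template_dir`, `manifest_file`.
#' @export
emit_plates <- function(truth, out_dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  design <- truth$design
  front <- .front_layout(truth)
  front_rc <- well_to_rc(front$well)
  mat_row <- match(front$material_id, truth$materials$material_id)
  pars_all <- .endpoint_params()

  noise <- function(n, base) {
    if (truth$noise_cv > 0) stats::rnorm(n, 0, truth$noise_cv * base) else 0
  }

  plate_files <- character()
  imaging_files <- character()
  withr::with_seed(truth$seed + 1L, {
    for (pi in seq_len(nrow(truth$plates))) {
      pl <- truth$plates[pi, ]
      path <- file.path(out_dir, pl$filename)
      if (pl$kind == "plate") {
        ep <- pl$endpoint
        mu <- vapply(seq_len(nrow(front)), function(i) {
          .true_signal(truth, ep, pl$time_h, mat_row[i],
                       front$dose_value[i], front$role[i])
        }, numeric(1))
        val <- mu * pl$plate_effect + noise(length(mu), pars_all[[ep]]$base)
        co <- truth$artifacts$control_outliers
        co <- co[co$plate_key == pl$key, ]
        if (nrow(co)) {
          i <- match(co$well, front$well)
          val[i] <- val[i] * co$factor
        }
        grid <- matrix(NA_real_, 16, 24)
        grid[cbind(front_rc$row, front_rc$col)] <- val
        lines <- c(paste0("plate_id,", pl$key),
                   apply(grid, 1, function(r) {
                     paste(sprintf("%.10g", r), collapse = ",")
                   }))
        writeLines(lines, path)
        plate_files <- c(plate_files, path)
      } else {
        out <- list()
        for (ep in setdiff(design$endpoints, "CTG")) {
          reps <- if (ep == "DAPI") design$dapi_tech_reps else 1L
          mu <- vapply(seq_len(nrow(front)), function(i) {
            .true_signal(truth, ep, pl$time_h, mat_row[i],
                         front$dose_value[i], front$role[i])
          }, numeric(1))
          for (tr in seq_len(reps)) {
            val <- mu * pl$plate_effect +
              noise(length(mu), pars_all[[ep]]$base)
            if (ep == "DAPI") {
              ff <- truth$artifacts$focus_failures
              ff <- ff[ff$time_h == pl$time_h & ff$serum == pl$serum &
                         ff$replicate == pl$replicate, ]
              if (nrow(ff)) val[match(ff$well, front$well)] <- 0
            }
            out[[length(out) + 1L]] <- tibble::tibble(
              well = front$well, endpoint = ep, value = val
            )
          }
        }
        tab <- dplyr::bind_rows(out)
        # interleave rows by well so duplicates sit with their well
        tab <- tab[order(match(tab$well, front$well)), ]
        writeLines(
          c("well\tendpoint\tvalue",
            sprintf("%s\t%s\t%.10g", tab$well, tab$endpoint, tab$value)),
          path
        )
        imaging_files <- c(imaging_files, path)
      }
    }
  })

  files_sheet <- truth$plates |>
    dplyr::transmute(filename = .data$filename, endpoint = .data$endpoint,
                     time_h = .data$time_h,
                     replicate = as.integer(.data$replicate),
                     cell_line = design$cell_line, serum = .data$serum)
  materials_sheet <- tibble::tibble(
    material_id = c(truth$materials$material_id, "vehicle", "blank"),
    name = c(truth$materials$material_id, "vehicle control", "blank well"),
    erm = NA_character_,
    sbet_m2g = c(truth$materials$sbet_m2g, NA, NA)
  )
  template <- annotation_template(front, files_sheet, materials_sheet)
  template_dir <- file.path(out_dir, "template")
  write_annotation_template(template, template_dir)

  manifest <- truth_manifest(truth)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  manifest_file <- file.path(out_dir, "truth", "truth_manifest.csv")
  readr::write_csv(manifest, manifest_file)

  invisible(list(plate_files = plate_files, imaging_files = imaging_files,
                 template_dir = template_dir, manifest_file = manifest_file))
}

#' Expected qualitative outcomes of a synthetic campaign
#'
#' @param truth A `synthetic_truth`.
#' @return Tibble with, per material, the generator parameters, the
#'   expected potency order (1 = most potent; inert materials share the
#'   last place), whether a first significant effect should be detectable
#'   within the tested dose range, and the injected artifact counts.
#' @export
truth_manifest <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- truth$materials
  potency <- ifelse(m$emax > 0, m$ec50, Inf)
  detectable <- m$emax > 0 & m$ec50 < max(truth$design$doses)
  tibble::tibble(
    material_id = m$material_id, ec50 = m$ec50, emax = m$emax,
    hill = m$hill,
    expected_potency_order = rank_competition(-potency),
    first_sig_detectable = detectable,
    n_control_outliers = nrow(truth$artifacts$control_outliers),
    n_focus_failures = vapply(m$material_id, function(id) {
      sum(truth$artifacts$focus_failures$material_id == id)
    }, integer(1), USE.NAMES = FALSE)
  )
}
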