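#' Dose recalculation between concentration units
#'
#' Non-soluble (nano)material doses can be expressed as nominal mass
#' concentration in medium (ug/ml), mass per cell growth area (ug/cm2), or
#' particle surface area per growth area (cm2/cm2) using the material's BET
#' specific surface area (SBET). `cell_delivered_dose()` converts a nominal
#' concentration to mass per growth area: the mass delivered per well
#' (concentration times well volume) divided by the well's growth area.
#' `sbet_effective_dose()` multiplies the delivered mass (in g) by SBET
#' (converted m2/g to cm2/g) and divides by the growth area.
#'
#' With the default 50 ul / 0.1 cm2 geometry, 256 ug/ml maps to 128 ug/cm2;
#' with SBET 14 m2/g this is 17.92 cm2/cm2.
#'
#' @param dose_ugml Nominal dose in ug/ml (vectorized, >= 0).
#' @param geometry A [plate_geometry()] supplying well volume and growth
#'   area.
#' @param sbet_m2g Specific surface area in m2/g (>= 0).
#' @return Numeric vector of converted doses.
#' @examples
#' cell_delivered_dose(256)                      # 128 ug/cm2
#' sbet_effective_dose(256, sbet_m2g = 14)       # 17.92 cm2/cm2
#' @export
cell_delivered_dose <- function(dose_ugml, geometry = plate_geometry()) {
  stopifnot(inherits(geometry, "plate_geometry"))
  if (geometry$growth_area_cm2 <= 0) {
    stop("growth area must be positive", call. = FALSE)
  }
  if (any(dose_ugml < 0, na.rm = TRUE)) {
    stop("doses must be >= 0", call. = FALSE)
  }
  dose_ugml * (geometry$well_volume_ul / 1000) / geometry$growth_area_cm2
}

#' @rdname cell_delivered_dose
#' @export
sbet_effective_dose <- function(dose_ugml, sbet_m2g,
                                geometry = plate_geometry()) {
  if (is.null(sbet_m2g) || length(sbet_m2g) == 0 || all(is.na(sbet_m2g))) {
    stop("SBET is missing: add an `sbet_m2g` value to the Materials sheet",
         call. = FALSE)
  }
  if (any(sbet_m2g < 0, na.rm = TRUE)) {
    stop("SBET must be >= 0", call. = FALSE)
  }
  mass_ug_per_well <- dose_ugml * geometry$well_volume_ul / 1000
  sbet_cm2_per_ug <- sbet_m2g * 1e4 / 1e6  # m2/g -> cm2/g -> cm2/ug
  mass_ug_per_well * sbet_cm2_per_ug / geometry$growth_area_cm2
}

DOSE_UNITS <- c(ugml = "ug/ml", ugcm2 = "ug/cm2", cm2cm2 = "cm2/cm2",
                delivered = "cm2/cm2 delivered")

#' Convert every dose in a dataset to a target concentration unit
#'
#' Rewrites `dose_value`/`dose_unit` on every record. Conversions are linear
#' in dose, so dilution-series spacing is preserved and control wells stay at
#' dose 0. Surface-area units require SBET on the materials sheet; the
#' cell-delivered unit additionally requires a user-supplied per-material
#' delivered fraction (no sedimentation modelling is attempted).
#'
#' @param ds An [hts_dataset()] whose doses are in ug/ml.
#' @param target_unit One of `"ugml"`, `"ugcm2"`, `"cm2cm2"`, `"delivered"`.
#' @param materials_sheet Materials sheet tibble (for `sbet_m2g`).
#' @param delivered_fraction Named numeric vector (material_id ->
#'   delivered fraction in (0, 1]) for the `"delivered"` unit.
#' @return The dataset with converted doses and a provenance entry.
#' @export
convert_dataset_doses <- function(ds, target_unit = c("ugml", "ugcm2",
                                                      "cm2cm2", "delivered"),
                                  materials_sheet = NULL,
                                  delivered_fraction = NULL) {
  stopifnot(inherits(ds, "hts_dataset"))
  target_unit <- match.arg(target_unit)
  d <- ds$data
  cur <- unique(d$dose_unit[d$role == "treated"])
  cur <- cur[!is.na(cur)]
  if (length(cur) > 1L) {
    stop("dataset mixes dose units: ", paste(cur, collapse = ", "),
         call. = FALSE)
  }
  if (length(cur) == 1L && cur != "ug/ml" && target_unit != "ugml") {
    stop("doses must be in ug/ml before conversion; found ", cur,
         call. = FALSE)
  }

  if (target_unit == "ugml") {
    # inverse conversions back to the nominal unit
    if (length(cur) && cur == DOSE_UNITS[["ugcm2"]]) {
      d$dose_value <- d$dose_value * ds$geometry$growth_area_cm2 /
        (ds$geometry$well_volume_ul / 1000)
    } else if (length(cur) && cur %in% DOSE_UNITS[c("cm2cm2", "delivered")]) {
      stop("conversion back from surface-area units needs per-material SBET; ",
           "re-ingest nominal doses instead", call. = FALSE)
    }
    d$dose_unit <- "ug/ml"
  } else if (target_unit == "ugcm2") {
    d$dose_value <- cell_delivered_dose(d$dose_value, ds$geometry)
    d$dose_unit <- DOSE_UNITS[["ugcm2"]]
  } else {
    mats <- unique(d$material_id[d$role == "treated"])
    sbet <- stats::setNames(rep(NA_real_, length(mats)), mats)
    if (!is.null(materials_sheet) && "sbet_m2g" %in% names(materials_sheet)) {
      i <- match(mats, materials_sheet$material_id)
      sbet[] <- materials_sheet$sbet_m2g[i]
    }
    missing_sbet <- mats[is.na(sbet)]
    if (length(missing_sbet)) {
      stop("SBET missing on the Materials sheet for material(s): ",
           paste(missing_sbet, collapse = ", "), call. = FALSE)
    }
    frac <- rep(1, length(mats))
    if (target_unit == "delivered") {
      frac <- unname(delivered_fraction[mats])
      if (is.null(delivered_fraction) || anyNA(frac)) {
        stop("delivered-dose unit requires `delivered_fraction` for ",
             "material(s): ",
             paste(mats[is.null(delivered_fraction) | is.na(frac)],
                   collapse = ", "), call. = FALSE)
      }
    }
    i <- match(d$material_id, mats)
    treated <- d$role == "treated"
    d$dose_value[treated] <- sbet_effective_dose(
      d$dose_value[treated], sbet[i[treated]], ds$geometry
    ) * frac[i[treated]]
    d$dose_unit <- DOSE_UNITS[[target_unit]]
  }
  d$dose_value[d$role == "control"] <- 0
  ds$data <- d
  log_provenance(ds, "convert_dataset_doses", list(target_unit = target_unit))
}
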