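# Doppler-ultrasound derived vessel metrics. Units are pinned across the
# package: axes mm, velocities cm/s, areas cm^2, flow volumes mL/min.

.VESSELS <- c("BA", "PA", "DA")

#' Construct a Doppler vessel measurement
#'
#' One ultrasound measurement of a vessel: short- and long-axis lumen
#' diameters from the B-mode image and the time-averaged velocity from the
#' Doppler velocity/time trace (the mean of repeated three-cycle tracings).
#'
#' @param vessel `"BA"` (brachial artery), `"PA"` or `"DA"` (radial artery
#'   proximal / distal to the anastomosis).
#' @param short_axis_mm,long_axis_mm Lumen axes (mm), both > 0 with
#'   long >= short.
#' @param tav_velocity_cm_s Time-averaged velocity (cm/s), >= 0.
#' @return A `vessel_measurement` object.
#' @export
vessel_measurement <- function(vessel, short_axis_mm, long_axis_mm,
                               tav_velocity_cm_s) {
  vessel <- match.arg(vessel, .VESSELS)
  if (short_axis_mm <= 0 || long_axis_mm <= 0)
    stop("vessel axes must be positive")
  if (long_axis_mm < short_axis_mm)
    stop("long axis must be >= short axis")
  if (tav_velocity_cm_s < 0) stop("velocity must be non-negative")
  structure(list(vessel = vessel,
                 short_axis_mm = short_axis_mm,
                 long_axis_mm = long_axis_mm,
                 tav_velocity_cm_s = tav_velocity_cm_s),
            class = "vessel_measurement")
}

#' Area-equivalent diameter of an elliptical lumen
#'
#' Diameter of the circle with the same area as the ellipse with the given
#' axes: `sqrt(short * long)`. Always lies between the two axes.
#'
#' @param short_mm,long_mm Axes in mm (> 0).
#' @return Equivalent diameter (mm).
#' @export
equivalent_diameter <- function(short_mm, long_mm) {
  if (any(short_mm <= 0) || any(long_mm <= 0))
    stop("axes must be positive")
  sqrt(short_mm * long_mm)
}

#' Elliptical lumen cross-sectional area
#'
#' `pi * short * long / 4` in mm^2, returned in cm^2. Identical to the
#' area of the circle with the equivalent diameter.
#'
#' @param short_mm,long_mm Axes in mm (> 0).
#' @return Cross-sectional area (cm^2).
#' @export
cross_sectional_area <- function(short_mm, long_mm) {
  if (any(short_mm <= 0) || any(long_mm <= 0))
    stop("axes must be positive")
  pi * short_mm * long_mm / 4 / 100
}

#' Blood flow volume of a vessel
#'
#' BFV = time-averaged velocity x cross-sectional area, converted to
#' mL/min (`cm/s x cm^2 x 60`).
#'
#' @param meas A `vessel_measurement`.
#' @return A `bfv_record`: list with `vessel`, `csa_cm2`,
#'   `equivalent_diameter_mm`, `bfv_ml_min`.
#' @export
blood_flow_volume <- function(meas) {
  stopifnot(inherits(meas, "vessel_measurement"))
  csa <- cross_sectional_area(meas$short_axis_mm, meas$long_axis_mm)
  structure(list(vessel = meas$vessel,
                 csa_cm2 = csa,
                 equivalent_diameter_mm =
                   equivalent_diameter(meas$short_axis_mm, meas$long_axis_mm),
                 bfv_ml_min = meas$tav_velocity_cm_s * csa * 60),
            class = "bfv_record")
}

#' Venous blood flow volume from the two afferent radial limbs
#'
#' In these retrograde-flow radio-cephalic AVFs both the proximal (PA)
#' and distal (DA) radial artery feed the anastomosis, so the venous BFV
#' is their sum.
#'
#' @param pa,da `bfv_record`s for the PA and DA (order irrelevant).
#' @return Venous BFV (mL/min).
#' @export
venous_bfv <- function(pa, da) {
  stopifnot(inherits(pa, "bfv_record"), inherits(da, "bfv_record"))
  if (!setequal(c(pa$vessel, da$vessel), c("PA", "DA")))
    stop("venous BFV needs one PA and one DA record, got ",
         pa$vessel, " + ", da$vessel)
  pa$bfv_ml_min + da$bfv_ml_min
}

#' Compute flow metrics for a table of ultrasound measurements
#'
#' Vectorised driver over a measurement table; appends the derived
#' columns and one `VEN` (venous) row per patient-visit holding the
#' PA + DA sum.
#'
#' @param us `data.frame` with columns `patient_id`, `visit`, `vessel`,
#'   `short_axis_mm`, `long_axis_mm`, `tav_velocity_cm_s`.
#' @return `data.frame` with added `csa_cm2`, `equivalent_diameter_mm`,
#'   `bfv_ml_min` and the venous rows.
#' @export
flow_metrics_table <- function(us) {
  need <- c("patient_id", "visit", "vessel", "short_axis_mm",
            "long_axis_mm", "tav_velocity_cm_s")
  if (!all(need %in% names(us)))
    stop("missing columns: ", paste(setdiff(need, names(us)), collapse = ", "))
  recs <- lapply(seq_len(nrow(us)), function(i) {
    blood_flow_volume(vessel_measurement(
      us$vessel[i], us$short_axis_mm[i], us$long_axis_mm[i],
      us$tav_velocity_cm_s[i]))
  })
  out <- us
  out$csa_cm2 <- vapply(recs, `[[`, numeric(1), "csa_cm2")
  out$equivalent_diameter_mm <-
    vapply(recs, `[[`, numeric(1), "equivalent_diameter_mm")
  out$bfv_ml_min <- vapply(recs, `[[`, numeric(1), "bfv_ml_min")
  ven <- do.call(rbind, lapply(
    split(out, paste(out$patient_id, out$visit, sep = "\r")),
    function(g) {
      pa <- g[g$vessel == "PA", ]; da <- g[g$vessel == "DA", ]
      if (nrow(pa) != 1 || nrow(da) != 1) return(NULL)
      data.frame(patient_id = g$patient_id[1], visit = g$visit[1],
                 vessel = "VEN", short_axis_mm = NA, long_axis_mm = NA,
                 tav_velocity_cm_s = NA, csa_cm2 = NA,
                 equivalent_diameter_mm = NA,
                 bfv_ml_min = pa$bfv_ml_min + da$bfv_ml_min)
    }))
  out <- rbind(out, ven)
  rownames(out) <- NULL
  out
}
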