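#' Coronary flow velocity reserve (CFVR)
#'
#' CFVR is the ratio of the hyperemic to the resting diastolic peak flow
#' velocity measured by Doppler in the left anterior descending artery.
#' A value of 2.5 or below is the conventional marker of coronary
#' microvascular dysfunction (CMD).
#'
#' @param dpv_r Resting diastolic peak velocity, cm/s. Must be positive.
#' @param dpv_h Hyperemic diastolic peak velocity, cm/s. Must be positive.
#' @return Numeric vector of dimensionless CFVR values.
#' @examples
#' compute_cfvr(25, 50) # 2.0
#' @export
compute_cfvr <- function(dpv_r, dpv_h) {
  check_velocity_pair(dpv_r, dpv_h)
  dpv_h / dpv_r
}

#' Companion coronary flow velocity reserve (CCFVR)
#'
#' The companion metric is the distance of the point (DPVr, DPVh) from the
#' origin of the velocity domain: sqrt(DPVr^2 + DPVh^2). Apart from a factor
#' 1/sqrt(2) it equals the quadratic mean of the two velocities, and it is
#' the radius of the pair in polar coordinates (CFVR fixes the angle). Unlike
#' the dimensionless CFVR it retains physical units (cm/s), so it separates
#' subjects whose velocities differ in level but not in ratio.
#'
#' @inheritParams compute_cfvr
#' @return Numeric vector, cm/s.
#' @examples
#' compute_ccfvr(25, 50) # 55.9
#' compute_ccfvr(40, 80) # 89.4
#' @export
compute_ccfvr <- function(dpv_r, dpv_h) {
  check_velocity_pair(dpv_r, dpv_h)
  sqrt(dpv_r^2 + dpv_h^2)
}

#' Mean arterial pressure from cuff measurements
#'
#' Uses the standard sphygmomanometer formula (2 x diastolic + systolic) / 3.
#'
#' @param sap Systolic arterial pressure, mmHg.
#' @param dap Diastolic arterial pressure, mmHg. Must satisfy sap > dap > 0.
#' @return Mean arterial pressure, mmHg.
#' @export
mean_arterial_pressure <- function(sap, dap) {
  stopifnot(is.numeric(sap), is.numeric(dap))
  bad <- !is.na(sap) & !is.na(dap) & (dap <= 0 | sap <= dap)
  if (any(bad)) {
    stop("invalid arterial pressures: need sap > dap > 0 (violated at position ",
         paste(which(bad), collapse = ", "), ")")
  }
  (2 * dap + sap) / 3
}

#' Coronary microvascular resistance
#'
#' Mean arterial pressure divided by the diastolic peak velocity of the
#' matching condition. With resting inputs this is the basal microvascular
#' resistance (BMR); with hyperemic inputs the hyperemic microvascular
#' resistance (HMR).
#'
#' @param map Mean arterial pressure, mmHg.
#' @param dpv Diastolic peak velocity of the same condition, cm/s; positive.
#' @return Resistance, mmHg s/cm.
#' @export
microvascular_resistance <- function(map, dpv) {
  stopifnot(is.numeric(map), is.numeric(dpv))
  bad <- !is.na(dpv) & dpv <= 0
  if (any(bad)) {
    stop("non-positive diastolic peak velocity at position ",
         paste(which(bad), collapse = ", "))
  }
  map / dpv
}

#' Arteriolar resistance index (ARI)
#'
#' The drop in microvascular resistance from rest to maximal hyperemia,
#' BMR - HMR; a marker of the arterioles' capacity to dilate. A negative
#' value (hyperemic resistance above basal) is physiologically anomalous
#' but not impossible; it is returned as-is and flagged downstream rather
#' than rejected.
#'
#' @param bmr Basal microvascular resistance, mmHg s/cm.
#' @param hmr Hyperemic microvascular resistance, mmHg s/cm.
#' @return ARI, mmHg s/cm.
#' @export
arteriolar_resistance_index <- function(bmr, hmr) {
  stopifnot(is.numeric(bmr), is.numeric(hmr))
  bmr - hmr
}

#' Rate-pressure product
#'
#' Heart rate times systolic arterial pressure, the usual bedside index of
#' cardiac work.
#'
#' @param hr Heart rate, bpm; positive.
#' @param sap Systolic arterial pressure, mmHg; positive.
#' @return RPP, mmHg bpm.
#' @export
rate_pressure_product <- function(hr, sap) {
  stopifnot(is.numeric(hr), is.numeric(sap))
  bad <- (!is.na(hr) & hr <= 0) | (!is.na(sap) & sap <= 0)
  if (any(bad)) {
    stop("heart rate and systolic pressure must be positive (position ",
         paste(which(bad), collapse = ", "), ")")
  }
  hr * sap
}

#' CFVR normalised to cardiac work (rpCFVR)
#'
#' CFVR divided by the rate-pressure product and rescaled by 10,000 so that
#' typical values land near the CFVR scale (order 2-4).
#'
#' @param cfvr CFVR values.
#' @param rpp Rate-pressure product, mmHg bpm; positive.
#' @param scale Linear rescaling factor, default 10000.
#' @return rpCFVR, dimensionless (scaled).
#' @export
compute_rpcfvr <- function(cfvr, rpp, scale = 10000) {
  stopifnot(is.numeric(cfvr), is.numeric(rpp))
  bad <- !is.na(rpp) & rpp <= 0
  if (any(bad)) {
    stop("rate-pressure product must be positive (position ",
         paste(which(bad), collapse = ", "), ")")
  }
  cfvr / rpp * scale
}

#' Hyperemia-induced velocity increase
#'
#' The increase of the diastolic peak velocity from rest to hyperemia, in
#' absolute terms (cm/s) and relative to the resting velocity (percent).
#'
#' @inheritParams compute_cfvr
#' @return Data frame with columns `delta_dpv_abs` (cm/s) and
#'   `delta_dpv_pct` (percent).
#' @export
delta_dpv <- function(dpv_r, dpv_h) {
  check_velocity_pair(dpv_r, dpv_h)
  d <- dpv_h - dpv_r
  data.frame(delta_dpv_abs = d, delta_dpv_pct = 100 * d / dpv_r)
}

#' Polar coordinates of a velocity pair
#'
#' Maps the Cartesian pair (DPVr, DPVh) to polar coordinates of the velocity
#' domain: the angle from the DPVr axis encodes CFVR (angle = atan(CFVR)) and
#' the radius is CCFVR. The two views are equivalent; the polar one makes
#' explicit that CFVR discards the level information CCFVR retains.
#'
#' @inheritParams compute_cfvr
#' @return Data frame with columns `angle_deg` (degrees, in (0, 90)) and
#'   `radius` (cm/s, equal to CCFVR).
#' @seealso [from_polar()] for the inverse map.
#' @export
to_polar <- function(dpv_r, dpv_h) {
  check_velocity_pair(dpv_r, dpv_h)
  data.frame(angle_deg = atan2(dpv_h, dpv_r) * 180 / pi,
             radius = sqrt(dpv_r^2 + dpv_h^2))
}

#' Cartesian velocity pair from polar coordinates
#'
#' @param angle_deg Angle from the DPVr axis, degrees.
#' @param radius Distance from the origin (CCFVR), cm/s.
#' @return Data frame with columns `dpv_r` and `dpv_h`.
#' @export
from_polar <- function(angle_deg, radius) {
  stopifnot(is.numeric(angle_deg), is.numeric(radius))
  a <- angle_deg * pi / 180
  data.frame(dpv_r = radius * cos(a), dpv_h = radius * sin(a))
}

#' Per-subject hemodynamic profile table
#'
#' Derives every hemodynamic index from the raw vitals of a cohort table:
#' CFVR, CCFVR, mean arterial pressures, BMR, HMR, ARI, resting rate-pressure
#' product, rpCFVR and the hyperemia-induced velocity increase. Each
#' resistance pairs the mean pressure of a condition with the velocity of
#' the same condition.
#'
#' @param cohort Data frame with columns `dpv_r`, `dpv_h`, `sap_r`, `dap_r`,
#'   `sap_h`, `dap_h`, `hr_r`, `hr_h` (and any others, carried through by
#'   `subject_id` if present).
#' @param rpp_condition Condition whose rate-pressure product normalises
#'   rpCFVR: `"rest"` (default; CFVR is reported once per subject and resting
#'   work is the conventional normaliser) or `"hyperemia"`.
#' @return Data frame, one row per subject, with `subject_id` (if supplied)
#'   and columns `cfvr`, `ccfvr`, `map_r`, `map_h`, `bmr`, `hmr`, `ari`,
#'   `rpp_r`, `rpcfvr`, `delta_dpv_abs`, `delta_dpv_pct`, `dpv_r`, `dpv_h`,
#'   plus `ari_negative` flagging anomalous negative ARI.
#' @export
cohort_metrics <- function(cohort, rpp_condition = c("rest", "hyperemia")) {
  rpp_condition <- match.arg(rpp_condition)
  required <- c("dpv_r", "dpv_h", "sap_r", "dap_r", "sap_h", "dap_h",
                "hr_r", "hr_h")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing required vital columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    if (anyNA(cohort[[col]])) {
      stop("missing values in vital column '", col, "'")
    }
  }
  out <- data.frame(
    dpv_r = cohort$dpv_r,
    dpv_h = cohort$dpv_h,
    cfvr  = compute_cfvr(cohort$dpv_r, cohort$dpv_h),
    ccfvr = compute_ccfvr(cohort$dpv_r, cohort$dpv_h),
    map_r = mean_arterial_pressure(cohort$sap_r, cohort$dap_r),
    map_h = mean_arterial_pressure(cohort$sap_h, cohort$dap_h)
  )
  out$bmr <- microvascular_resistance(out$map_r, cohort$dpv_r)
  out$hmr <- microvascular_resistance(out$map_h, cohort$dpv_h)
  out$ari <- arteriolar_resistance_index(out$bmr, out$hmr)
  out$ari_negative <- out$ari < 0
  out$rpp_r <- rate_pressure_product(cohort$hr_r, cohort$sap_r)
  rpp_used <- if (rpp_condition == "rest") {
    out$rpp_r
  } else {
    rate_pressure_product(cohort$hr_h, cohort$sap_h)
  }
  out$rpcfvr <- compute_rpcfvr(out$cfvr, rpp_used)
  out <- cbind(out, delta_dpv(cohort$dpv_r, cohort$dpv_h))
  if ("subject_id" %in% names(cohort)) {
    out <- cbind(subject_id = cohort$subject_id, out)
  }
  out
}

# velocity invariants shared by every flow metric
check_velocity_pair <- function(dpv_r, dpv_h) {
  stopifnot(is.numeric(dpv_r), is.numeric(dpv_h))
  bad_r <- !is.na(dpv_r) & dpv_r <= 0
  bad_h <- !is.na(dpv_h) & dpv_h <= 0
  if (any(bad_r)) {
    stop("non-positive resting velocity dpv_r at position ",
         paste(which(bad_r), collapse = ", "))
  }
  if (any(bad_h)) {
    stop("non-positive hyperemic velocity dpv_h at position ",
         paste(which(bad_h), collapse = ", "))
  }
  invisible(TRUE)
}
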