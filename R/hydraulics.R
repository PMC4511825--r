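#' Hydrostatic pressure of a water column
#'
#' The lab gravity-feed setup drives flow with a solution reservoir raised
#' above the stem segment; a 1 m column provides 9.8 kPa.
#'
#' @param height_m Column height (m), `>= 0`.
#' @param density Fluid density (kg/m^3).
#' @param g Gravitational acceleration (m/s^2); 9.8 by convention here.
#' @return Pressure in kPa.
#' @export
hydrostatic_pressure <- function(height_m, density = 1000, g = 9.8) {
  if (any(height_m < 0)) abort("`height_m` must be >= 0.")
  density * g * height_m / 1000
}

#' Estimate steady flow from a balance log
#'
#' The balance records cumulative mass at fixed intervals; flow is taken as
#' the least-squares slope of mass against time over a stable window.
#' Window selection: slide a window of `window_s` seconds across the log
#' and pick the latest window whose first-difference coefficient of
#' variation is minimal among windows with linear-fit R^2 >= `min_r2`
#' (mirroring the practice of reading the balance once flow has been
#' approximately constant for at least three minutes).  If no window
#' reaches `min_r2` the minimum-CV window is used and flagged.
#'
#' @param flow_log A data frame with numeric columns `time_s` (strictly
#'   increasing) and `mass_kg`.
#' @param window_s Stable-window length in seconds.
#' @param min_r2 Minimum R^2 for a window to qualify as stable.
#' @return A `flow_estimate` object: `flow_kg_s`, the window bounds,
#'   `r_squared`, `diff_cv`, and flags `r2_ok` and `negative_flow`.
#' @export
estimate_flow <- function(flow_log, window_s = 180, min_r2 = 0.99) {
  if (!all(c("time_s", "mass_kg") %in% names(flow_log))) {
    abort("`flow_log` needs columns time_s and mass_kg.",
          class = "traitgrad_schema_error")
  }
  t <- as.numeric(flow_log$time_s)
  m <- as.numeric(flow_log$mass_kg)
  if (length(t) < 2) abort("Flow log needs at least 2 points.")
  if (any(diff(t) <= 0)) abort("`time_s` must be strictly increasing.")
  span <- t[length(t)] - t[1]
  if (span < window_s) {
    abort(sprintf("Flow log spans %.0f s, shorter than window_s = %.0f s.",
                  span, window_s),
          class = "traitgrad_window_error")
  }
  starts <- which(t <= t[length(t)] - window_s)
  cand <- purrr::map(starts, function(i) {
    j <- which(t >= t[i] + window_s)[1]
    tw <- t[i:j]
    mw <- m[i:j]
    dm <- diff(mw)
    mu_dm <- mean(dm)
    diff_cv <- if (abs(mu_dm) < .Machine$double.eps) {
      if (sd(dm) < .Machine$double.eps) 0 else Inf
    } else {
      sd(dm) / abs(mu_dm)
    }
    tc <- tw - mean(tw)
    slope <- sum(tc * mw) / sum(tc^2)
    sst <- sum((mw - mean(mw))^2)
    sse <- sum((mw - mean(mw) - slope * tc)^2)
    r2 <- if (sst < 1e-300) 1 else max(0, 1 - sse / sst)
    list(start = t[i], end = t[j], slope = slope, r2 = r2, diff_cv = diff_cv,
         n = j - i + 1L)
  })
  r2s <- vapply(cand, `[[`, numeric(1), "r2")
  ok <- r2s >= min_r2
  r2_ok <- any(ok)
  if (!r2_ok) {
    warn("No window reached the R^2 threshold; using the minimum-CV window.")
    ok <- rep(TRUE, length(cand))
  }
  cvs <- vapply(cand, `[[`, numeric(1), "diff_cv")
  cvs[!ok] <- Inf
  # latest window among those attaining the minimal diff CV
  best <- max(which(cvs <= min(cvs) + 1e-15))
  w <- cand[[best]]
  negative <- w$slope < 0
  if (negative) warn("Fitted flow slope is negative; result flagged.")
  structure(
    list(
      flow_kg_s = w$slope, window_start_s = w$start, window_end_s = w$end,
      r_squared = w$r2, diff_cv = w$diff_cv, n_points = w$n,
      r2_ok = r2_ok, negative_flow = negative
    ),
    class = "flow_estimate"
  )
}

#' @export
print.flow_estimate <- function(x, ...) {
  cat(sprintf(
    "<flow_estimate> %.4g kg/s over [%g, %g] s (R^2 = %.4f%s)\n",
    x$flow_kg_s, x$window_start_s, x$window_end_s, x$r_squared,
    if (x$negative_flow) ", NEGATIVE" else ""
  ))
  invisible(x)
}

#' Hydraulic conductivity of a stem segment
#'
#' `compute_kh()` gives the hydraulic conductivity K_h = F * L / dP: mass
#' flow through a unit length of stem divided by the pressure gradient
#' along it.  `compute_ks()` divides K_h by the cross-sectional area of
#' conductive xylem to give sapwood-specific conductivity K_s
#' (kg m^-1 s^-1 MPa^-1), comparable across segment diameters.
#'
#' @param flow_kg_s Steady flow (kg/s), `>= 0`.
#' @param length_m Segment length (m), positive.
#' @param delta_p_mpa Pressure difference across the segment (MPa), positive.
#' @return `compute_kh()`: K_h in kg m s^-1 MPa^-1.
#' @export
compute_kh <- function(flow_kg_s, length_m, delta_p_mpa) {
  if (any(flow_kg_s < 0)) abort("`flow_kg_s` must be >= 0.")
  if (any(length_m <= 0)) abort("`length_m` must be positive.")
  if (any(delta_p_mpa <= 0)) abort("`delta_p_mpa` must be positive.")
  flow_kg_s * length_m / delta_p_mpa
}

#' @param kh Hydraulic conductivity K_h (kg m s^-1 MPa^-1).
#' @param sapwood_area_m2 Conductive xylem cross-sectional area (m^2).
#' @return `compute_ks()`: K_s in kg m^-1 s^-1 MPa^-1.
#' @rdname compute_kh
#' @export
compute_ks <- function(kh, sapwood_area_m2) {
  if (any(sapwood_area_m2 <= 0)) abort("`sapwood_area_m2` must be positive.")
  kh / sapwood_area_m2
}

#' Percent loss of conductivity
#'
#' PLC = (K_max - K_s_native) / K_max, the fraction of maximum conducting
#' capacity lost to embolism.  Negative values (native conductivity above
#' the flushed maximum, i.e. measurement noise) are returned with a warning
#' rather than clamped.
#'
#' @param ks_native Native sapwood-specific conductivity.
#' @param k_max Maximum (flushed) sapwood-specific conductivity, positive.
#' @return PLC as a dimensionless fraction `<= 1`.
#' @export
compute_plc <- function(ks_native, k_max) {
  if (any(k_max <= 0)) abort("`k_max` must be positive.")
  plc <- (k_max - ks_native) / k_max
  if (any(plc < 0)) {
    warn("Negative PLC (native K_s exceeds K_max); values not clamped.")
  }
  plc
}

#' Conductivity records for a set of stem segments
#'
#' End-to-end hydraulics stage: estimates the steady flow of each segment's
#' balance log, then computes K_h, K_s and (when a flushed `k_max` is
#' supplied) PLC.
#'
#' @param flow_logs Tibble with columns `segment_id`, `time_s`, `mass_kg`.
#' @param segments Tibble with columns `segment_id`, `length_m`,
#'   `sapwood_area_m2`, `pressure_head_kpa`, and optionally `k_max`
#'   (kg m^-1 s^-1 MPa^-1).
#' @param window_s Stable-window length for [estimate_flow()].
#' @return A tibble with one row per segment: flow, fit diagnostics, `K_h`,
#'   `K_s`, `K_max` and `PLC` (NA when no `k_max`).
#' @export
conductivity_records <- function(flow_logs, segments, window_s = 180) {
  need <- c("segment_id", "length_m", "sapwood_area_m2", "pressure_head_kpa")
  if (!all(need %in% names(segments))) {
    abort(sprintf("`segments` needs columns %s.", paste(need, collapse = ", ")),
          class = "traitgrad_schema_error")
  }
  if (!"k_max" %in% names(segments)) segments$k_max <- NA_real_
  purrr::pmap_dfr(
    segments[c("segment_id", "length_m", "sapwood_area_m2",
               "pressure_head_kpa", "k_max")],
    function(segment_id, length_m, sapwood_area_m2, pressure_head_kpa, k_max) {
      log_i <- flow_logs[flow_logs$segment_id == segment_id, ]
      if (nrow(log_i) == 0) {
        abort(sprintf("No flow log for segment %s.", segment_id))
      }
      est <- estimate_flow(log_i, window_s = window_s)
      kh <- compute_kh(max(est$flow_kg_s, 0), length_m,
                       pressure_head_kpa / 1000)
      ks <- compute_ks(kh, sapwood_area_m2)
      plc <- if (is.na(k_max)) NA_real_ else compute_plc(ks, k_max)
      tibble(
        segment_id = segment_id, flow_kg_s = est$flow_kg_s,
        r_squared = est$r_squared, negative_flow = est$negative_flow,
        K_h = kh, K_s = ks, K_max = k_max, PLC = plc
      )
    }
  )
}
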