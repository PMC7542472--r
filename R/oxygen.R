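# Oxygen gradient and per-compartment kinetic rates.

#' Radial oxygen profile
#'
#' Oxygen concentration decays exponentially with radial distance from the
#' vessel wall: `C(r) = c0 * 0.5^(r / r_half)`, so concentration halves
#' every `r_half` millimetres.
#'
#' @param c0_pct Oxygen concentration at the vessel wall, percent. Default 16.
#' @param r_half_mm Radial distance half-life of oxygen, millimetres.
#'   Default 0.018 (18 um), which drives near-anoxia at the 100 um cuff edge.
#' @return An object of class `oxygen_profile`.
#' @export
oxygen_profile <- function(c0_pct = 16, r_half_mm = 0.018) {
  stopifnot(is.numeric(c0_pct), length(c0_pct) == 1L, c0_pct > 0,
            is.numeric(r_half_mm), length(r_half_mm) == 1L, r_half_mm > 0)
  structure(list(c0_pct = c0_pct, r_half_mm = r_half_mm),
            class = "oxygen_profile")
}

#' In vitro rate anchors
#'
#' Birth and death rates measured in cell cultures at two oxygen conditions
#' (defaults: 1% and 20% O2, non-small-cell lung cancer lines). The model
#' linearly interpolates between them: birth increases with oxygen from
#' `kb_low` to `kb_high`; death decreases with oxygen from `kd_low` (the
#' hypoxic maximum) to `kd_high`.
#'
#' @param c_low_pct,c_high_pct The two culture oxygen conditions, percent.
#' @param kb_low,kb_high Birth rates (per day) at `c_low_pct` and
#'   `c_high_pct`. Defaults 7.8e-4 and 8.2e-3.
#' @param kd_low,kd_high Death rates (per day) at `c_low_pct` and
#'   `c_high_pct`. Defaults 1.6e-3 and 0.
#' @return An object of class `rate_anchors`.
#' @export
rate_anchors <- function(c_low_pct = 1, c_high_pct = 20,
                         kb_low = 7.8e-4, kb_high = 8.2e-3,
                         kd_low = 1.6e-3, kd_high = 0) {
  stopifnot(c_low_pct < c_high_pct,
            kb_low >= 0, kb_high >= 0, kd_low >= 0, kd_high >= 0)
  structure(list(c_low_pct = c_low_pct, c_high_pct = c_high_pct,
                 kb_low = kb_low, kb_high = kb_high,
                 kd_low = kd_low, kd_high = kd_high),
            class = "rate_anchors")
}

#' Oxygen concentration at a radial distance
#'
#' @param r_mm Radial distance from the vessel wall, millimetres (>= 0;
#'   vectorized).
#' @param ox An [oxygen_profile()].
#' @return Oxygen concentration(s), percent.
#' @export
oxygen_at <- function(r_mm, ox) {
  stopifnot(inherits(ox, "oxygen_profile"), is.numeric(r_mm))
  if (any(r_mm < 0)) stop("radial distance must be nonnegative")
  ox$c0_pct * 0.5^(r_mm / ox$r_half_mm)
}

#' Interpolate birth/death/net growth rates at an oxygen concentration
#'
#' Each rate is the line through its two measured (oxygen, rate) anchor
#' points, evaluated at `c_pct`. Extrapolation outside the measured oxygen
#' span is linear, then clamped below at zero (negative birth or death
#' rates have no meaning in the difference equations). The net rate is
#' birth minus death after clamping.
#'
#' @param c_pct Oxygen concentration, percent (vectorized).
#' @param anchors A [rate_anchors()].
#' @return A list with numeric fields `kb`, `kd`, `kg` (per day).
#' @export
interpolate_rates <- function(c_pct, anchors) {
  stopifnot(inherits(anchors, "rate_anchors"), is.numeric(c_pct))
  dc <- anchors$c_high_pct - anchors$c_low_pct
  mb <- (anchors$kb_high - anchors$kb_low) / dc
  md <- (anchors$kd_high - anchors$kd_low) / dc
  kb <- pmax(0, anchors$kb_low + mb * (c_pct - anchors$c_low_pct))
  kd <- pmax(0, anchors$kd_low + md * (c_pct - anchors$c_low_pct))
  list(kb = kb, kd = kd, kg = kb - kd)
}

#' Distance-based shedding weights
#'
#' One-dimensional diffusive attenuation from compartment midpoint to the
#' vasculature, `w_i = 1 / sqrt(s_i)` with `s_i` in micrometres. The
#' absolute scale of `w` is absorbed by the protein shedding parameters;
#' the micrometre convention is fixed for reproducibility.
#'
#' @param midpoints_um Compartment midpoints, micrometres (all > 0).
#' @return Numeric vector of dimensionless weights, strictly decreasing.
#' @export
shedding_weights <- function(midpoints_um) {
  stopifnot(is.numeric(midpoints_um))
  if (any(midpoints_um <= 0)) stop("midpoints must be strictly positive")
  1 / sqrt(midpoints_um)
}

#' Per-compartment rate table
#'
#' Evaluates the oxygen profile at each compartment midpoint and the anchor
#' interpolation at the resulting concentrations, yielding per-compartment
#' birth, death and net growth rates plus shedding weights.
#'
#' @param cfg A [spatial_config()].
#' @param ox An [oxygen_profile()].
#' @param anchors A [rate_anchors()].
#' @return An object of class `compartment_rates`: a list with fields
#'   `s_um` (midpoints), `c_pct` (oxygen), `kb`, `kd`, `kg` (per day) and
#'   `w` (weights), each of length `n`.
#' @examples
#' rt <- compartment_rate_table(spatial_config(), oxygen_profile(),
#'                              rate_anchors())
#' as.data.frame(rt)
#' @export
compartment_rate_table <- function(cfg, ox, anchors) {
  s_um <- compartment_midpoints(cfg)
  c_pct <- oxygen_at(s_um / UM_PER_MM, ox)
  r <- interpolate_rates(c_pct, anchors)
  structure(
    list(s_um = s_um, c_pct = c_pct, kb = r$kb, kd = r$kd, kg = r$kg,
         w = shedding_weights(s_um)),
    class = "compartment_rates"
  )
}

#' @export
as.data.frame.compartment_rates <- function(x, ...) {
  data.frame(compartment = seq_along(x$s_um), s_um = x$s_um,
             C_pct = x$c_pct, kB = x$kb, kD = x$kd, kG = x$kg, w = x$w)
}

#' @export
print.compartment_rates <- function(x, ...) {
  print(as.data.frame(x), ...)
  invisible(x)
}
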