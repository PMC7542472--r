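# Cylindrical discretization of the perivascular microenvironment.
# All user-facing lengths are in micrometres (suffix _um); internal volume
# arithmetic is done in millimetres so that volumes (mm^3) combine directly
# with cell densities given in cells/mm^3.

UM_PER_MM <- 1000

#' Spatial configuration of the perivascular cylinder
#'
#' Defines the concentric-shell discretization of tumor tissue around a
#' central vessel. The vessel core has radius `delta = mvd/2`; the viable
#' tissue annulus (the necrotic cuff) of width `epsilon` is partitioned into
#' `n = epsilon/sigma` shells of single-cell thickness `sigma`, so the model
#' cylinder has outer radius `R = n*sigma + delta`.
#'
#' `epsilon` must be an exact integer multiple of `sigma`: partial outer
#' shells are not supported.
#'
#' @param sigma_um Partition width (shell thickness), micrometres. Default 10
#'   (approximate single-cell diameter).
#' @param mvd_um Mean vessel diameter `d`, micrometres. Default 60.
#' @param epsilon_um Necrotic cuff width (oxygen diffusion limit),
#'   micrometres. Default 100.
#' @return An object of class `spatial_config` with fields `sigma_um`,
#'   `mvd_um`, `delta_um`, `epsilon_um`, `n`, `R_um`.
#' @examples
#' cfg <- spatial_config()
#' cfg$n        # 10 compartments
#' cfg$delta_um # 30 um core radius
#' @export
spatial_config <- function(sigma_um = 10, mvd_um = 60, epsilon_um = 100) {
  stopifnot(is.numeric(sigma_um), length(sigma_um) == 1L, sigma_um > 0,
            is.numeric(mvd_um), length(mvd_um) == 1L, mvd_um > 0,
            is.numeric(epsilon_um), length(epsilon_um) == 1L, epsilon_um > 0)
  ratio <- epsilon_um / sigma_um
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("epsilon_um (", epsilon_um, ") must be an integer multiple of ",
         "sigma_um (", sigma_um, ")")
  }
  n <- as.integer(round(ratio))
  delta_um <- mvd_um / 2
  structure(
    list(sigma_um = sigma_um, mvd_um = mvd_um, delta_um = delta_um,
         epsilon_um = epsilon_um, n = n, R_um = n * sigma_um + delta_um),
    class = "spatial_config"
  )
}

#' Vascularization parameters
#'
#' The vascular height of the cylindrical system grows linearly in time,
#' `h_t = k_v * t`, modeling steady vessel recruitment. `h` is measured in
#' units of `unit_length_mm` millimetres (default 1 mm).
#'
#' @param k_v Vascularization rate, per day. Default 0.101.
#' @param unit_length_mm Length (mm) represented by one unit of `h`.
#' @return An object of class `vascular_params`.
#' @export
vascular_params <- function(k_v = 0.101, unit_length_mm = 1) {
  stopifnot(is.numeric(k_v), length(k_v) == 1L, k_v >= 0,
            is.numeric(unit_length_mm), length(unit_length_mm) == 1L,
            unit_length_mm > 0)
  structure(list(k_v = k_v, unit_length_mm = unit_length_mm),
            class = "vascular_params")
}

#' Tissue density parameters
#'
#' @param rho_cells_per_mm3 Tumor cell density, cells per mm^3. Default 1e6.
#' @param p_fraction Fraction of tumor volume occupied by tumor cells, in
#'   \[0, 1\]. Default 0.2.
#' @return An object of class `density_params`.
#' @export
density_params <- function(rho_cells_per_mm3 = 1e6, p_fraction = 0.2) {
  stopifnot(is.numeric(rho_cells_per_mm3), length(rho_cells_per_mm3) == 1L,
            rho_cells_per_mm3 > 0,
            is.numeric(p_fraction), length(p_fraction) == 1L,
            p_fraction >= 0, p_fraction <= 1)
  structure(list(rho_cells_per_mm3 = rho_cells_per_mm3,
                 p_fraction = p_fraction),
            class = "density_params")
}

#' Map a radial distance to its compartment index
#'
#' Radial distance `r` is measured outward from the vessel wall; the tissue
#' annulus spans `0 < r <= epsilon`. The discretizing map is
#' `ceiling(r / sigma)`, yielding an index in `1..n`.
#'
#' @param r_um Radial distance from the vessel wall, micrometres.
#' @param cfg A [spatial_config()].
#' @return Integer compartment index (vectorized over `r_um`).
#' @export
map_radius_to_compartment <- function(r_um, cfg) {
  stopifnot(inherits(cfg, "spatial_config"), is.numeric(r_um))
  if (any(r_um <= 0) || any(r_um > cfg$epsilon_um)) {
    stop("radial distance must lie in (0, ", cfg$epsilon_um,
         "] um (inside the modeled tissue annulus)")
  }
  as.integer(ceiling(r_um / cfg$sigma_um))
}

#' Radial midpoints of the compartments
#'
#' Midpoint of compartment `i` is `s_i = ((2i - 1)/2) * sigma`, measured
#' from the vessel wall. Rate constants and shedding weights are evaluated
#' at these midpoints.
#'
#' @param cfg A [spatial_config()].
#' @return Numeric vector of length `n`, micrometres, strictly increasing.
#' @export
compartment_midpoints <- function(cfg) {
  stopifnot(inherits(cfg, "spatial_config"))
  (2 * seq_len(cfg$n) - 1) / 2 * cfg$sigma_um
}

#' Concentric-shell subvolumes
#'
#' Subvolume of shell `i` at vascular height `h`. The innermost subvolume
#' includes the vessel core (`v_1 = pi*(sigma + delta)^2*h`, the basis case
#' of the shell recurrence); outer shells follow the closed form
#' `v_i = pi*((2i - 1)*sigma^2 + 2*sigma*delta)*h` for `i >= 2`. The
#' subvolumes sum exactly to the full cylinder volume `pi*(n*sigma+delta)^2*h`.
#'
#' @param cfg A [spatial_config()].
#' @param h_mm Vascular height, millimetres (>= 0).
#' @return Numeric vector of `n` shell volumes in mm^3.
#' @export
shell_subvolumes <- function(cfg, h_mm) {
  stopifnot(inherits(cfg, "spatial_config"),
            is.numeric(h_mm), length(h_mm) == 1L, h_mm >= 0)
  s <- cfg$sigma_um / UM_PER_MM
  d <- cfg$delta_um / UM_PER_MM
  i <- seq_len(cfg$n)
  v <- pi * ((2 * i - 1) * s^2 + 2 * s * d) * h_mm
  v[1] <- pi * (s + d)^2 * h_mm
  v
}

#' Vascular height at a given time
#'
#' Linear vascularization: `h_t = k_v * t`, converted to millimetres by the
#' configured unit length.
#'
#' @param t_days Time in days (>= 0; vectorized).
#' @param vp A [vascular_params()].
#' @return Height(s) in millimetres.
#' @export
vascular_height <- function(t_days, vp) {
  stopifnot(inherits(vp, "vascular_params"), is.numeric(t_days))
  if (any(t_days < 0)) stop("time must be nonnegative")
  vp$k_v * t_days * vp$unit_length_mm
}

#' Compartmental carrying capacities
#'
#' `K_i = v_i * rho * p`: the number of cells a shell supports given the
#' tumor cell density and packing fraction. Real-valued (not rounded).
#'
#' @param v_mm3 Shell subvolumes in mm^3 (all >= 0).
#' @param dp A [density_params()].
#' @return Numeric vector of cell counts.
#' @export
carrying_capacities <- function(v_mm3, dp) {
  stopifnot(inherits(dp, "density_params"), is.numeric(v_mm3))
  if (any(v_mm3 < 0)) stop("shell volumes must be nonnegative")
  v_mm3 * dp$rho_cells_per_mm3 * dp$p_fraction
}

#' @export
print.spatial_config <- function(x, ...) {
  cat("Perivascular cylinder: n =", x$n, "shells of", x$sigma_um,
      "um around a", x$delta_um, "um core (R =", x$R_um, "um)\n")
  invisible(x)
}
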