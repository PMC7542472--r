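# Daily forward-Euler dynamics of the coupled per-compartment populations.

#' Inter-compartment motility parameters
#'
#' Deterministic daily fractions of each compartment's population that move
#' one compartment inward (toward better oxygenation, slightly favored) or
#' outward. Outward movement is boosted when the donor holds at least
#' `fold_threshold` times the receiver's population, or when the receiver
#' is empty (letting the growth front advance).
#'
#' @param p_in Fraction moved one compartment inward per day. Default 0.10.
#' @param p_out Baseline fraction moved one compartment outward per day.
#'   Default 0.05.
#' @param p_out_boost Outward fraction when the fold condition holds.
#'   Default 0.10.
#' @param fold_threshold Donor/receiver population ratio triggering the
#'   boost. Default 10.
#' @return An object of class `motility_params`, or `NULL`-safe disabled
#'   motility via `motility = FALSE` in [simulate_growth()].
#' @export
motility_params <- function(p_in = 0.10, p_out = 0.05, p_out_boost = 0.10,
                            fold_threshold = 10) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            p_out_boost >= 0, p_out_boost <= 1, fold_threshold > 0,
            p_in + max(p_out, p_out_boost) <= 1)
  structure(list(p_in = p_in, p_out = p_out, p_out_boost = p_out_boost,
                 fold_threshold = fold_threshold),
            class = "motility_params")
}

#' Capacity overflow of a compartment
#'
#' Excess population above carrying capacity, displaced one compartment
#' outward: `P - K` when `P > K` (strict), else 0. Vectorized.
#'
#' @param P Population(s), cells.
#' @param K Carrying capacity(ies), cells.
#' @return Overflow cell count(s), nonnegative.
#' @export
compute_overflow <- function(P, K) {
  stopifnot(is.numeric(P), is.numeric(K), all(P >= 0), all(K >= 0))
  ifelse(P > K, P - K, 0)
}

#' Apply one day of inter-compartment motility
#'
#' All fluxes are computed from the pre-move state and applied
#' simultaneously; total population is conserved exactly. Compartment
#' `i > 1` sends `p_in * P_i` inward; compartment `i < n` sends
#' `p_out * P_i` (or `p_out_boost * P_i` under the fold/empty-receiver
#' condition) outward.
#'
#' @param P Population vector (cells).
#' @param mp A [motility_params()].
#' @return Updated population vector, same total.
#' @export
apply_motility <- function(P, mp) {
  stopifnot(inherits(mp, "motility_params"), is.numeric(P), all(P >= 0))
  n <- length(P)
  if (n == 1L) return(P)
  donor <- P[-n]
  receiver <- P[-1]
  boost <- (receiver > 0 & donor >= mp$fold_threshold * receiver) |
    (receiver == 0 & donor > 0)
  out_flux <- ifelse(boost, mp$p_out_boost, mp$p_out) * donor  # i -> i+1
  in_flux <- mp$p_in * P[-1]                                   # i -> i-1
  Pn <- P
  Pn[-n] <- Pn[-n] - out_flux
  Pn[-1] <- Pn[-1] + out_flux
  Pn[-1] <- Pn[-1] - in_flux
  Pn[-n] <- Pn[-n] + in_flux
  Pn
}

#' Advance the growth state by one day
#'
#' One forward-Euler step of the coupled compartment system, in fixed
#' order: (1) update vascular height and carrying capacities at `t + dt`;
#' (2) per-compartment births `kb*dt*P` and deaths `kd*dt*P`; (3) sweep
#' compartments inner to outer, displacing capacity overflow one
#' compartment outward (the outermost compartment is uncapped and retains
#' any excess); (4) motility. Dead cells are cleared instantly and occupy
#' no capacity.
#'
#' @param state A growth state: list with `t`, `P`, `Dcum`.
#' @param rates A [compartment_rate_table()] result (or compatible list
#'   with `kb`, `kd` vectors).
#' @param cfg A [spatial_config()].
#' @param vp A [vascular_params()].
#' @param dp A [density_params()].
#' @param mp A [motility_params()], or `NULL` to disable motility.
#' @param dt Time step, days. Default 1.
#' @param capacity If `FALSE`, capacities are infinite (no overflow);
#'   used for closed-form Malthusian checks.
#' @return The state at `t + dt`, with per-step `B_inst`, `D_inst` and the
#'   updated `K`, `h`.
#' @export
step_growth <- function(state, rates, cfg, vp, dp, mp = NULL, dt = 1,
                        capacity = TRUE) {
  n <- length(state$P)
  t1 <- state$t + dt
  h <- vascular_height(t1, vp)
  K <- if (capacity) {
    carrying_capacities(shell_subvolumes(cfg, h), dp)
  } else {
    rep(Inf, n)
  }
  B <- rates$kb * dt * state$P
  D <- rates$kd * dt * state$P
  P <- state$P + B - D
  if (capacity && n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (P[i] > K[i]) {
        O <- P[i] - K[i]
        P[i] <- K[i]
        P[i + 1L] <- P[i + 1L] + O
      }
    }
  }
  if (!is.null(mp)) P <- apply_motility(P, mp)
  if (any(!is.finite(P))) {
    stop("non-finite population encountered at day ", t1)
  }
  list(t = t1, P = P, B_inst = B, D_inst = D, Dcum = state$Dcum + D,
       K = K, h = h)
}

#' Simulate vascularized tumor growth
#'
#' Iterates [step_growth()] daily from a seed of `p0` cells in the
#' innermost compartment at `t = 0` (when vascular height, and hence all
#' capacities, are zero; capacities take effect from the first step).
#'
#' @param config A [model_config()]; its spatial, vascular, density,
#'   oxygen, anchor, motility and simulation groups define the run.
#' @param t_end End time in days (overrides the config's).
#' @param p0 Seed population (overrides the config's).
#' @param capacity If `FALSE`, disable carrying capacities.
#' @param motility If `FALSE`, disable inter-compartment motility.
#' @param rates Optional precomputed [compartment_rate_table()].
#' @return An object of class `growth_trajectory`: list with `t` (0..t_end),
#'   matrices `P`, `B_inst`, `D_inst`, `D_cum`, `K` of dimension
#'   `(t_end+1) x n`, vector `h`, the `rates`, and the resolved `config`.
#' @examples
#' traj <- simulate_growth(model_config(), t_end = 365)
#' utils::tail(growth_summary(traj), 3)
#' @export
simulate_growth <- function(config = model_config(), t_end = NULL, p0 = NULL,
                            capacity = TRUE, motility = TRUE, rates = NULL) {
  stopifnot(inherits(config, "model_config"))
  cfg <- config$spatial
  vp <- config$vascular
  dp <- config$density
  mp <- if (motility) config$motility else NULL
  dt <- config$simulation$dt_days
  if (is.null(t_end)) t_end <- config$simulation$t_end_days
  if (is.null(p0)) p0 <- config$simulation$p0_cells
  stopifnot(t_end >= 0, p0 > 0)
  if (is.null(rates)) {
    rates <- compartment_rate_table(cfg, config$oxygen, config$anchors)
  }
  n <- cfg$n
  steps <- as.integer(round(t_end / dt))
  nt <- steps + 1L
  P <- B <- D <- Dc <- K <- matrix(0, nrow = nt, ncol = n)
  h <- numeric(nt)
  state <- list(t = 0, P = c(p0, numeric(n - 1L)), Dcum = numeric(n))
  P[1L, ] <- state$P
  for (k in seq_len(steps)) {
    state <- step_growth(state, rates, cfg, vp, dp, mp, dt = dt,
                         capacity = capacity)
    P[k + 1L, ] <- state$P
    B[k + 1L, ] <- state$B_inst
    D[k + 1L, ] <- state$D_inst
    Dc[k + 1L, ] <- state$Dcum
    K[k + 1L, ] <- state$K
    h[k + 1L] <- state$h
  }
  structure(
    list(t = seq(0, by = dt, length.out = nt), P = P, B_inst = B,
         D_inst = D, D_cum = Dc, K = K, h = h, n = n, dt = dt,
         rates = rates, config = config),
    class = "growth_trajectory"
  )
}

#' Necrotic fraction over a growth trajectory
#'
#' Ratio of cumulative cell death to all cells accounted for (cumulative
#' deaths plus current proliferative population) at each time point. Zero
#' while no deaths have occurred; 1 in the all-dead limit.
#'
#' @param traj A [simulate_growth()] trajectory.
#' @return Numeric vector in \[0, 1\], one value per time point.
#' @export
necrotic_fraction <- function(traj) {
  stopifnot(inherits(traj, "growth_trajectory"))
  if (length(traj$t) == 0L) stop("empty trajectory")
  dead <- rowSums(traj$D_cum)
  alive <- rowSums(traj$P)
  tot <- dead + alive
  ifelse(tot > 0, dead / tot, 0)
}

#' Per-day growth summary
#'
#' @param traj A [simulate_growth()] trajectory.
#' @return A data.frame with columns `t_day`, `P_total`, `B_total_inst`,
#'   `D_total_inst`, `D_cum_total`, `necrotic_fraction`, `h`.
#' @export
growth_summary <- function(traj) {
  stopifnot(inherits(traj, "growth_trajectory"))
  data.frame(
    t_day = traj$t,
    P_total = rowSums(traj$P),
    B_total_inst = rowSums(traj$B_inst),
    D_total_inst = rowSums(traj$D_inst),
    D_cum_total = rowSums(traj$D_cum),
    necrotic_fraction = necrotic_fraction(traj),
    h = traj$h
  )
}

#' @export
as.data.frame.growth_trajectory <- function(x, ...) {
  nt <- length(x$t)
  data.frame(
    t_day = rep(x$t, times = x$n),
    comp = rep(seq_len(x$n), each = nt),
    P = as.vector(x$P),
    D_inst = as.vector(x$D_inst),
    D_cum = as.vector(x$D_cum),
    K = as.vector(x$K),
    h = rep(x$h, times = x$n)
  )
}

#' @export
print.growth_trajectory <- function(x, ...) {
  nt <- length(x$t)
  cat("Growth trajectory:", x$n, "compartments,", nt - 1L, "days\n")
  cat("  final total population:",
      format(sum(x$P[nt, ]), digits = 4), "cells\n")
  cat("  final necrotic fraction:",
      format(necrotic_fraction(x)[nt], digits = 4), "\n")
  invisible(x)
}

#' Detect the exponential-to-capacity-limited growth inflection
#'
#' Finds the day the tumor's early exponential growth gives way to the
#' capacity-limited phase: the trailing `window`-day log-growth rate of the
#' total proliferative population is computed at each day, the initial
#' exponential rate is taken as its maximum over the first simulated year,
#' and the inflection is the first later day the trailing rate falls below
#' half that initial rate.
#'
#' @param traj A [simulate_growth()] trajectory.
#' @param window Trailing window in days. Default 30.
#' @return List with `t_day`, `t_years`, `initial_rate` (per day).
#' @export
detect_growth_inflection <- function(traj, window = 30L) {
  stopifnot(inherits(traj, "growth_trajectory"))
  tot <- rowSums(traj$P)
  nt <- length(tot)
  if (nt <= window + 1L) stop("trajectory shorter than the trailing window")
  lp <- log(pmax(tot, .Machine$double.xmin))
  idx <- (window + 1L):nt
  rate <- (lp[idx] - lp[idx - window]) / (window * traj$dt)
  t_rate <- traj$t[idx]
  early <- t_rate <= 365
  if (!any(early)) early <- seq_len(min(30L, length(rate)))
  r0 <- max(rate[early])
  after <- which(rate < r0 / 2 & t_rate > t_rate[which.max(rate[early])])
  if (length(after) == 0L) {
    return(list(t_day = NA_real_, t_years = NA_real_, initial_rate = r0))
  }
  t_inf <- t_rate[after[1L]]
  list(t_day = t_inf, t_years = t_inf / 365, initial_rate = r0)
}
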