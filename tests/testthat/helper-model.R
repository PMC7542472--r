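# Shared fixtures: small, fast configurations built in code.

# Baseline config with a short horizon for quick runs.
short_config <- function(t_end = 400) {
  update_config(model_config(), t_end_days = t_end)
}

# A single-compartment config with constant birth rate k and no death,
# for closed-form Malthusian checks (run with capacity = FALSE).
malthus_config <- function(k = 5e-3, p0 = 1000, t_end = 100, dt = 1) {
  model_config(
    spatial = spatial_config(sigma_um = 10, mvd_um = 60, epsilon_um = 10),
    anchors = rate_anchors(kb_low = k, kb_high = k, kd_low = 0, kd_high = 0),
    simulation = list(dt_days = dt, t_end_days = t_end, p0_cells = p0)
  )
}

# Fabricate a minimal growth trajectory with prescribed population and
# death matrices, for shedding tests that need controlled inputs.
fake_trajectory <- function(P, D_inst, rates, dt = 1) {
  nt <- nrow(P)
  structure(
    list(t = seq(0, by = dt, length.out = nt), P = P,
         B_inst = matrix(0, nt, ncol(P)), D_inst = D_inst,
         D_cum = apply(D_inst, 2, cumsum), K = matrix(Inf, nt, ncol(P)),
         h = numeric(nt), n = ncol(P), dt = dt, rates = rates,
         config = NULL),
    class = "growth_trajectory"
  )
}

# Rate table for an n-compartment default geometry.
default_rates <- function() {
  compartment_rate_table(spatial_config(), oxygen_profile(), rate_anchors())
}
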