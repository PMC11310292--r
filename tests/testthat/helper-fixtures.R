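# shared fixtures for the test suite; everything is generated in code

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

trapz_num <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# untreated extended-model run for a scenario/diet, reused across tests
untreated_run <- function(preset = "Ia", diet = "CD", t_f = 25) {
  ps <- scenario_preset(preset)
  init <- diet_init(diet, model = "extended", R0_fraction = ps$R0_fraction)
  integrate_model("extended", ps$params, init, c(0, t_f))
}

# state of the untreated run at a given day (nearest grid point)
state_at <- function(traj, day) {
  unlist(traj[which.min(abs(traj$time - day)), c("S", "R", "E", "F")])
}

# random but tame parameter draw for property tests (log-uniform around the
# defaults so the integrator faces realistic, not pathological, stiffness)
random_base_params <- function() {
  jitter <- function(x, dec = 0.5) x * 10^runif(1, -dec, dec)
  base_params(
    k1 = jitter(0.55), a1 = jitter(43), m1 = jitter(1 / 2000),
    r = jitter(20), mu = jitter(5.94), alpha = jitter(1.7e-6)
  )
}

random_ext_params <- function() {
  jitter <- function(x, dec = 0.5) x * 10^runif(1, -dec, dec)
  ext_params(
    k1 = jitter(0.55), a1 = jitter(43), m1 = jitter(1 / 2000),
    r = jitter(20), mu = jitter(5.94), alpha = jitter(1.7e-6),
    eta = jitter(1, 0.3), c = jitter(1, 0.3), l = sample(2:10, 1),
    a2 = jitter(20), a3 = jitter(1), k3 = jitter(0.275),
    k2 = jitter(0.05), m2 = jitter(0.002711), p = runif(1, 0.01, 1)
  )
}
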