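# Shared fixtures and independent oracles for the test suite.
# Everything here is built in code at test time; no stored data.

# A small network configuration for fast, deterministic oracle tests.
tiny_config <- function(n = 8L, m = 6L, l = 3L, ...) {
  sim_config(n_sensory = n, n_excit = m, n_output = l, seed = 42L, ...)
}

# Random small synaptic state (weights safely away from the zero clip).
tiny_state <- function(config, seed = 1) {
  set.seed(seed)
  n <- config$n_sensory; m <- config$n_excit; l <- config$n_output
  synaptic_state(
    W_xE = matrix(runif(m * n, 0.2, 0.6), m, n),
    W_xI = runif(n, 0.3, 0.7),
    W_IE = runif(m, 0.2, 0.6),
    W_Ey = matrix(runif(l * m, 0.2, 0.8), l, m)
  )
}

# Deterministic-rate forward pass: expected spike counts everywhere.
det_counts <- function(state, rates, config, d = 0) {
  x <- rates * config$dt
  I <- inhibitory_drive(x, state$W_xI, state$b_I)
  phi <- excitatory_rates(x, I, state$W_xE, state$W_IE, state$b_E,
                          config$I_floor, d)
  list(x = x, I = I, phi = phi, E = phi * config$dt)
}

# Deterministic salience as a function of the x->I weights (for the
# finite-difference gradient oracle of the relevance rule).
salience_of_wxi <- function(w, state, rates, config) {
  state$W_xI <- w
  salience(det_counts(state, rates, config)$E, config$H)
}

# Central finite differences of f at x (vector-valued x, scalar f).
central_diff <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Deterministic cross-entropy of the category head as a function of the
# full weight state (finite-difference oracle for the backprop update).
category_loss_of <- function(state, rates, config, target) {
  fw <- det_counts(state, rates, config)
  p <- category_rates(fw$E, state$W_Ey, config$kappa) / config$kappa
  cross_entropy(p, target)
}

# Reduced-scale configuration for simulation-level tests: 500 sensory and
# 400 excitatory units with the homeostatic constants rescaled to the same
# target rates (H = sqrt(m * 2.6 Hz * dt), H + A = sqrt(m * 3.9 Hz * dt)).
scaled_config <- function(...) {
  m <- 400L
  H <- sqrt(m * 2.6 * 0.02)
  A <- sqrt(m * 3.9 * 0.02) - H
  sim_config(n_sensory = 500L, n_excit = m, H = H, A = A, theta = H / 4,
             ...)
}

# Schedule with no stimuli: a bare baseline period.
baseline_schedule <- function(config, dur = 10) {
  sc <- inhibrel:::new_sched(ceiling(dur / config$dt), config$dt)
  inhibrel:::finish_sched(sc, "learning_to_ignore", 1L)
}
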