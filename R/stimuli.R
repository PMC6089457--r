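#' Gamma parameters from mode and variance
#'
#' Baseline sensory rates follow a gamma distribution specified by its mode
#' (peak) and variance.  For shape `k` and scale `s` the mode is `(k-1)*s`
#' (requires `k >= 1`) and the variance `k*s^2`; this solves the pair for
#' `(k, s)`, taking the larger root of the resulting quadratic in `k`.  A
#' mode of zero gives the exponential boundary case `k = 1`.
#'
#' @param mode distribution mode in Hz (>= 0).
#' @param variance distribution variance in Hz^2 (> 0).
#' @return named vector with `shape` and `scale`.
#' @examples
#' gamma_params_from_mode_var(0.6, 3)  # shape ~1.4116, scale ~1.4577
#' @export
gamma_params_from_mode_var <- function(mode, variance) {
  if (mode < 0) stop("mode must be >= 0")
  if (variance <= 0) stop("variance must be > 0")
  if (mode == 0) return(c(shape = 1, scale = sqrt(variance)))
  # (k-1)s = mode, k s^2 = variance  =>  v k^2 - (2v + mode^2) k + v = 0
  r <- mode^2 / variance
  disc <- (2 + r)^2 - 4
  k <- ((2 + r) + sqrt(disc)) / 2
  if (k <= 1) stop("no shape > 1 solves this mode/variance pair")
  c(shape = k, scale = mode / (k - 1))
}

#' Build a stimulus library
#'
#' Assigns each stimulus a coding mask of `floor(0.1 * n_sensory)` sensory
#' units, with masks pairwise disjoint, and draws every unit's baseline
#' firing rate once from the gamma law parameterized by
#' `config$baseline_mode` / `config$baseline_var`.  While a stimulus is on,
#' its coding units fire at `config$phi_on`; every other unit keeps firing
#' at its baseline rate (units are never silent, just slower).
#'
#' @param config a [sim_config()].
#' @param n_stimuli number of stimuli (each claims 10% of the sensory
#'   layer, so at most 10 fit when `n_sensory = 1000`).
#' @param uniform_baseline if not `NULL`, replace the gamma draw by this
#'   constant rate (the categorization simulations use a flat 2 Hz
#'   baseline).
#' @param contiguous allocate each mask as a contiguous block of sensory
#'   indices (at a random offset) instead of a random scattered subset.
#'   Used with the smoothed-diagonal `W_xE` initialization, where stimulus
#'   identity lives in the topographic alignment between input blocks and
#'   excitatory receptive fields.
#' @return object of class `stimulus_library`: list with `masks` (list of
#'   integer index vectors), `baseline_rates`, `phi_on`, `n_sensory`.
#' @export
make_stimulus_library <- function(config, n_stimuli,
                                  uniform_baseline = NULL,
                                  contiguous = FALSE) {
  n <- config$n_sensory
  sz <- floor(0.1 * n)
  if (n_stimuli * sz > n)
    stop(n_stimuli, " stimuli of ", sz, " units each do not fit disjointly",
         " in ", n, " sensory units")
  if (contiguous) {
    n_blocks <- n %/% sz
    starts <- (sample.int(n_blocks, n_stimuli) - 1L) * sz
    masks <- lapply(starts, function(s0) s0 + seq_len(sz))
  } else {
    perm <- sample.int(n)
    masks <- lapply(seq_len(n_stimuli), function(k) {
      sort(perm[((k - 1) * sz + 1):(k * sz)])
    })
  }
  names(masks) <- paste0("S", seq_len(n_stimuli))
  baseline <- if (!is.null(uniform_baseline)) {
    rep(uniform_baseline, n)
  } else {
    par <- gamma_params_from_mode_var(config$baseline_mode,
                                      config$baseline_var)
    stats::rgamma(n, shape = par["shape"], scale = par["scale"])
  }
  structure(list(masks = masks, baseline_rates = baseline,
                 phi_on = config$phi_on, n_sensory = n),
            class = "stimulus_library")
}

#' Sensory rate vector for a set of active stimuli
#'
#' @param library a [make_stimulus_library()] result.
#' @param active integer vector of active stimulus indices (possibly empty).
#' @return per-unit firing rates in Hz.
#' @export
stimulus_rates <- function(library, active = integer(0)) {
  r <- library$baseline_rates
  for (k in active) r[library$masks[[k]]] <- library$phi_on
  r
}

#' Initialize the synaptic state
#'
#' Default mode uses the grid-searched starting values: uniform sensory-to-
#' inhibitory weights of 0.5, uniform inhibitory-to-excitatory weights of
#' 0.4, sensory-to-excitatory weights drawn from N(0.3, 0.4^2) with
#' negative draws clipped to zero, and output weights drawn from U(0, 1)
#' with rows rescaled to sum to 1.
#'
#' `mode = "latent_inhibition"` instead builds `W_xE` as a smoothed diagonal
#' band: each excitatory unit listens mainly to a contiguous neighbourhood
#' of sensory units (nearest-index mapping of the `m` rows onto the `n`
#' columns, convolved with a 1-D Gaussian kernel), scaled so the mean weight
#' matches the default mode.  This preserves stimulus identity in the
#' initial condition, which the latent-inhibition simulations require.
#'
#' @param config a [sim_config()].
#' @param mode `"default"` or `"latent_inhibition"`.
#' @param band_sigma Gaussian kernel width (sensory units) for the smoothed
#'   diagonal.
#' @param normalize_output rescale each `W_Ey` row to unit L2 norm.  The
#'   competitive (amygdala) head maintains unit-norm rows, so it starts from
#'   normalized rows; the categorization head trains raw `U(0, 1)` weights.
#' @return a [synaptic_state()].
#' @export
init_weights <- function(config, mode = c("default", "latent_inhibition"),
                         band_sigma = 5, normalize_output = TRUE) {
  mode <- match.arg(mode)
  n <- config$n_sensory; m <- config$n_excit
  k <- config$n_inhib; l <- config$n_output
  mean_default <- 0.3 * stats::pnorm(0.75) + 0.4 * stats::dnorm(0.75)
  W_xE <- if (mode == "default") {
    matrix(pmax(stats::rnorm(m * n, 0.3, 0.4), 0), m, n)
  } else {
    centers <- round((seq_len(m) - 0.5) * n / m + 0.5)
    offs <- outer(centers, seq_len(n), function(ci, j) j - ci)
    W <- exp(-offs^2 / (2 * band_sigma^2))
    W * (mean_default / mean(W))
  }
  # population variant: every inhibitory unit sees the full input at the
  # standard weight, and W_IE is scaled by 1/k so the summed divisive
  # influence matches the single-unit model.
  W_xI <- if (k == 1L) rep(0.5, n) else matrix(0.5, k, n)
  W_IE <- if (k == 1L) rep(0.4, m) else matrix(0.4 / k, m, k)
  W_Ey <- matrix(stats::runif(l * m), l, m)
  if (normalize_output) W_Ey <- W_Ey / sqrt(rowSums(W_Ey^2))
  synaptic_state(W_xE, W_xI, W_IE, W_Ey, b_E = config$b_E, b_I = config$b_I)
}
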