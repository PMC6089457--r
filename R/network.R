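#' Sample Poisson spike counts for one time step
#'
#' Each unit's count is drawn independently from a Poisson distribution with
#' mean `rate * dt`.  Counts of 2 or more are kept: at the rates and time
#' steps used here bins are effectively binary, but the model does not clip.
#'
#' @param rates vector of firing rates in Hz (all >= 0).
#' @param dt time step in seconds.
#' @return integer vector of spike counts, same length as `rates`.
#' @examples
#' set.seed(1)
#' mean(sample_poisson_spikes(rep(20, 1e4), 0.02))  # ~ 0.4
#' @export
sample_poisson_spikes <- function(rates, dt) {
  if (!(dt > 0)) stop("dt must be > 0")
  bad <- which(rates < 0)
  if (length(bad))
    stop("negative firing rate at unit(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  stats::rpois(length(rates), rates * dt)
}

#' Feedforward inhibitory drive
#'
#' Computes `W_xI %*% x + b_I`.  With a single inhibitory unit `W_xI` is a
#' vector and the result a scalar; with the population variant (`n_inhib`
#' rows) the result is a vector.
#'
#' @param x_counts sensory spike counts for the step.
#' @param W_xI inhibitory input weights: a vector of length `n_sensory`, or
#'   an `n_inhib x n_sensory` matrix.
#' @param b_I inhibitory bias (scalar, or vector of length `n_inhib`).
#' @return non-negative scalar or vector of inhibitory activity.
#' @export
inhibitory_drive <- function(x_counts, W_xI, b_I = 0) {
  if (is.matrix(W_xI)) {
    if (ncol(W_xI) != length(x_counts))
      stop("W_xI has ", ncol(W_xI), " columns but x has ",
           length(x_counts), " entries")
    drop(W_xI %*% x_counts) + b_I
  } else {
    if (length(W_xI) != length(x_counts))
      stop("W_xI has ", length(W_xI), " entries but x has ",
           length(x_counts))
    sum(W_xI * x_counts) + b_I
  }
}

#' Divisively normalized excitatory rates
#'
#' The excitatory drive `W_xE %*% x + b_E` is divided element-wise by the
#' inhibition `W_IE %*% I + I_floor`.  A disruption fraction `d` lets that
#' fraction of the drive bypass inhibition entirely (a convex mixture), which
#' models pharmacological or optogenetic weakening of inhibitory
#' transmission:
#' `phi_E = (1-d) * drive/denominator + d * drive`.
#'
#' @param x_counts sensory spike counts.
#' @param I_drive inhibitory activity from [inhibitory_drive()].
#' @param W_xE `n_excit x n_sensory` weight matrix.
#' @param W_IE excitatory-side inhibitory weights: vector of length
#'   `n_excit` (single inhibitory unit) or `n_excit x n_inhib` matrix.
#' @param b_E excitatory bias (scalar or length-`n_excit` vector).
#' @param I_floor additive denominator floor (> 0).
#' @param d disruption fraction in [0, 1].
#' @return vector of excitatory firing rates (Hz), all >= 0.
#' @export
excitatory_rates <- function(x_counts, I_drive, W_xE, W_IE, b_E = 0,
                             I_floor = 0.1, d = 0) {
  if (d < 0 || d > 1) stop("disruption fraction d must lie in [0, 1]")
  drive <- drop(W_xE %*% x_counts) + b_E
  denom <- inhib_denominator(I_drive, W_IE, I_floor)
  if (d == 0) drive / denom else (1 - d) * drive / denom + d * drive
}

# Denominator of the divisive nonlinearity; never below I_floor for
# non-negative weights and drives.
inhib_denominator <- function(I_drive, W_IE, I_floor) {
  if (is.matrix(W_IE)) {
    drop(W_IE %*% I_drive) + I_floor
  } else {
    W_IE * I_drive + I_floor
  }
}

#' Synaptic state of the network
#'
#' Bundles the four weight matrices, bias terms and the eligibility trace.
#' All weights are non-negative at all times (Dale's law: any update that
#' would drive a weight negative clips it at zero).
#'
#' @param W_xE `n_excit x n_sensory` sensory-to-excitatory weights.
#' @param W_xI sensory-to-inhibitory weights (vector or `n_inhib x
#'   n_sensory` matrix).
#' @param W_IE inhibitory-to-excitatory weights (vector or `n_excit x
#'   n_inhib` matrix).
#' @param W_Ey `n_output x n_excit` output weights.
#' @param b_E,b_I bias terms.
#' @param trace eligibility trace over sensory units (zeros at rest).
#' @return an object of class `synaptic_state`.
#' @export
synaptic_state <- function(W_xE, W_xI, W_IE, W_Ey, b_E = 0, b_I = 0,
                           trace = NULL) {
  if (is.null(trace)) {
    trace <- if (is.matrix(W_xI)) {
      matrix(0, nrow(W_xI), ncol(W_xI))
    } else {
      numeric(length(W_xI))
    }
  }
  st <- list(W_xE = W_xE, W_xI = W_xI, W_IE = W_IE, W_Ey = W_Ey,
             b_E = b_E, b_I = b_I, trace = trace)
  class(st) <- "synaptic_state"
  if (min(W_xE) < 0 || min(W_xI) < 0 || min(W_IE) < 0 || min(W_Ey) < 0)
    stop("all synaptic weights must be non-negative")
  st
}

#' Advance the circuit by one time step
#'
#' Samples sensory spikes from the frame's rates, computes the inhibitory
#' drive and divisive excitatory rates, and samples excitatory spikes.  The
#' circuit is memoryless across steps: state persists only through the
#' synaptic weights and eligibility traces.
#'
#' In deterministic mode spike counts are replaced by their expected values
#' `rate * dt`, which is the regime used for the analytical gradient
#' calculations.
#'
#' @param state a [synaptic_state()].
#' @param sensory_rates per-unit sensory firing rates (Hz) for this frame.
#' @param config a [sim_config()].
#' @param d disruption fraction for this step.
#' @param wie_scale multiplicative scale on `W_IE` for this step (models
#'   direct excitation of inhibitory transmission; 1 = unmodified).
#' @param deterministic replace Poisson sampling by expected counts.
#' @return a list (class `step_state`) with `x_counts`, `I_drive`, `phi_E`
#'   (Hz), `E_counts`, and `d`.
#' @export
forward_step <- function(state, sensory_rates, config, d = 0,
                         wie_scale = 1, deterministic = FALSE) {
  x <- if (deterministic) sensory_rates * config$dt
       else sample_poisson_spikes(sensory_rates, config$dt)
  I <- inhibitory_drive(x, state$W_xI, state$b_I)
  W_IE <- if (wie_scale == 1) state$W_IE else state$W_IE * wie_scale
  phi <- excitatory_rates(x, I, state$W_xE, W_IE, state$b_E,
                          config$I_floor, d)
  E <- if (deterministic) phi * config$dt
       else sample_poisson_spikes(phi, config$dt)
  structure(list(x_counts = x, I_drive = I, phi_E = phi, E_counts = E,
                 d = d),
            class = "step_state")
}
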