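#' Salience of the current excitatory population state
#'
#' Salience is the deviation of the L2 norm of the per-step excitatory spike
#' counts from the homeostatic set-point `H`:
#' `S(t) = ||E(t)||_2 - H`.
#'
#' @param E_counts excitatory spike counts for the step.
#' @param H homeostatic set-point (norm units).
#' @return scalar salience; bounded below by `-H`.
#' @export
salience <- function(E_counts, H) {
  sqrt(sum(E_counts^2)) - H
}

#' Unsigned temporal-difference prediction error
#'
#' `beta(t) = A*u(t) + gamma*S(t) - S(t-1)`.  This is an unsigned analogue of
#' the usual TD error: `u` carries only the magnitude of reinforcement, never
#' its sign, so reward and punishment are treated identically.
#'
#' @param u unsigned reinforcement at this step (0/1; graded values allowed).
#' @param S_now,S_prev salience at this and the previous step.
#' @param A salience scale.
#' @param gamma temporal discount factor.
#' @return scalar prediction error.
#' @export
prediction_error <- function(u, S_now, S_prev, A, gamma) {
  A * u + gamma * S_now - S_prev
}

#' Update the eligibility trace
#'
#' `trace <- gamma * lambda * trace + x`.  With `lambda = 0` the trace
#' reduces to the most recent input vector, giving TD(0).
#'
#' @param trace current trace (same shape as `x_counts`).
#' @param x_counts sensory spike counts for the step.
#' @param gamma discount factor.
#' @param lambda_trace trace decay in [0, 1).
#' @return updated trace.
#' @export
update_trace <- function(trace, x_counts, gamma, lambda_trace) {
  if (lambda_trace == 0) return(as.numeric(x_counts))
  gamma * lambda_trace * trace + x_counts
}

#' Apply one relevance-learning weight update
#'
#' Implements the simplified, direction-only stochastic gradient step on the
#' squared difference between salience and scaled unsigned value, for the
#' three plasticity variants:
#' \describe{
#'   \item{`xI`}{`W_xI_j <- W_xI_j - alpha * beta * trace_j` -- positive
#'     surprise releases feedforward inhibition.}
#'   \item{`xE`}{`W_xE_ij <- W_xE_ij + alpha * beta * trace_j`, the same
#'     increment for every postsynaptic row (the simplified gradient has no
#'     row dependence).}
#'   \item{`IE`}{`W_IE_i <- W_IE_i - alpha * beta * I`.}
#' }
#' All results are clipped at zero (Dale's law).  The full-magnitude
#' gradients are used only as an independent oracle in the test-suite.
#'
#' @param state a [synaptic_state()].
#' @param beta prediction error for the step.
#' @param trace eligibility trace to pair with `beta` (for TD(0) this is the
#'   previous step's input, or the current one under literal pairing).
#' @param I_drive inhibitory activity (used by the `IE` variant).
#' @param variant `"xI"`, `"xE"` or `"IE"`.
#' @param alpha learning rate.
#' @return the updated `synaptic_state`.
#' @export
apply_relevance_update <- function(state, beta, trace, I_drive,
                                   variant = c("xI", "xE", "IE"), alpha) {
  variant <- match.arg(variant)
  if (beta == 0) return(state)
  if (variant == "xI") {
    if (is.matrix(state$W_xI)) {
      # population variant: the same presynaptic trace applies to every row
      idx <- which(trace != 0)
      if (length(idx)) {
        delta <- alpha * beta * trace[idx]
        state$W_xI[, idx] <- pmax(sweep(state$W_xI[, idx, drop = FALSE], 2L,
                                        delta, "-"), 0)
      }
    } else {
      idx <- which(trace != 0)
      if (length(idx))
        state$W_xI[idx] <- pmax(state$W_xI[idx] - alpha * beta * trace[idx], 0)
    }
  } else if (variant == "xE") {
    idx <- which(trace != 0)
    if (length(idx)) {
      delta <- alpha * beta * trace[idx]
      state$W_xE[, idx] <- pmax(sweep(state$W_xE[, idx, drop = FALSE], 2L,
                                      delta, "+"), 0)
    }
  } else {
    state$W_IE <- pmax(state$W_IE - alpha * beta * I_drive, 0)
  }
  state
}
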