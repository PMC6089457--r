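#' Category-head firing rates
#'
#' The categorization output layer is a linear-normalized layer (the model
#' calls it "softmax", but the normalization is linear, not exponential):
#' `phi_i = kappa * drive_i / sum(drive)` with `drive = W_Ey %*% e`.  The
#' rates always sum to `kappa` exactly, so `phi_i / kappa` is a probability
#' over the categories.  When the total drive is zero the layer falls back
#' to the uniform distribution `kappa / l`.
#'
#' @param E_counts excitatory activity (spike counts or expected counts).
#' @param W_Ey `n_output x n_excit` weight matrix.
#' @param kappa total output rate in Hz.
#' @return vector of rates summing to `kappa`.
#' @export
category_rates <- function(E_counts, W_Ey, kappa = 20) {
  drive <- drop(W_Ey %*% E_counts)
  tot <- sum(drive)
  if (tot <= 0) return(rep(kappa / length(drive), length(drive)))
  kappa * drive / tot
}

#' Cross-entropy loss of the category head
#'
#' `-sum(o_i * log(p_i))` for a one-hot target `o` and probabilities `p`
#' (rates divided by `kappa`), with probabilities clipped to
#' `[1e-12, 1]` before the logarithm.  Loss is always evaluated on
#' normalized expected rates, never on sampled output spikes.
#'
#' @param probabilities category probabilities (rates / kappa).
#' @param target one-hot target vector, or the index of the true category.
#' @return scalar loss in natural log units.
#' @export
cross_entropy <- function(probabilities, target) {
  p <- pmin(pmax(probabilities, 1e-12), 1)
  if (length(target) == 1L && target == floor(target) &&
      length(probabilities) > 1L) {
    -log(p[target])
  } else {
    -sum(target * log(p))
  }
}

#' Gradient-descent update of the excitatory pathway
#'
#' One backpropagation step on the cross-entropy of the linear-normalized
#' category head, training both `W_Ey` and `W_xE`.  Gradients are computed
#' on expected rates: the forward pass uses expected excitatory counts
#' `lambda = phi_E * dt`, and Poisson sampling is bypassed in the backward
#' pass (straight-through).  The divisive inhibition does not depend on
#' `W_xE`, so the per-unit gain `g_i = (1-d)/denom_i + d` is the exact
#' slope when chaining into `W_xE`.  Updated weights are clipped at zero.
#'
#' @param state a [synaptic_state()].
#' @param x_counts sensory spike counts for the step.
#' @param lambdaE expected excitatory counts `phi_E * dt` for the step.
#' @param gains per-unit excitatory gains `d(phi_E_i)/d(drive_i)`.
#' @param target index of the true category (or one-hot vector).
#' @param alpha_y learning rate.
#' @param dt time step (s).
#' @return list with the updated `state` and the step's `loss`.
#' @export
backprop_update <- function(state, x_counts, lambdaE, gains, target,
                            alpha_y, dt) {
  l <- nrow(state$W_Ey)
  o <- if (length(target) == 1L) {
    v <- numeric(l); v[target] <- 1; v
  } else target
  drive <- drop(state$W_Ey %*% lambdaE)
  Z <- sum(drive)
  if (Z <= 0) return(list(state = state, loss = -sum(o * log(1 / l))))
  p <- pmin(pmax(drive / Z, 1e-12), 1)
  loss <- -sum(o * log(p))
  # dL/ddrive_i = (1 - o_i/p_i) / Z  for linear normalization
  dL_ddrive <- (1 - o / p) / Z
  # output weights: dL/dW_Ey[i,j] = dL/ddrive_i * lambda_j
  gW_Ey <- tcrossprod(dL_ddrive, lambdaE)
  # into the excitatory layer: dL/dlambda_j = sum_i dL/ddrive_i W_Ey[i,j]
  dL_dlambda <- drop(crossprod(state$W_Ey, dL_ddrive))
  # lambda_i = dt * (gain_i * (W_xE[i,] . x) + ...): slope dt * gain_i * x_j
  coef <- dL_dlambda * dt * gains
  idx <- which(x_counts != 0)
  state$W_Ey <- pmax(state$W_Ey - alpha_y * gW_Ey, 0)
  if (length(idx)) {
    gxE <- tcrossprod(coef, x_counts[idx])
    state$W_xE[, idx] <- pmax(state$W_xE[, idx, drop = FALSE] -
                                alpha_y * gxE, 0)
  }
  list(state = state, loss = loss)
}
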