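#' One step of the winner-take-all output layer
#'
#' Each output unit receives `z_i = sum_j W_Ey[i,j] * e_j - theta`.  At most
#' one unit -- the strict argmax of `z` -- may be active; it becomes active
#' only if its input clears threshold (`z >= 0`) or an unconditioned stimulus
#' is present (`u > 0`), in which case its activity is `z + 0.5*u`.  The
#' winning activity is then rescaled by dividing by the summed positive
#' inputs, which keeps activity in a stable range without affecting which
#' unit wins or when learning occurs.  Exact ties for the maximum yield no
#' winner (relevant only for degenerate, e.g. all-zero, inputs).
#'
#' Winner activity is a continuous "activation level"; it is never
#' Poisson-sampled, since each unit stands in for an ensemble.
#'
#' @param E_counts excitatory spike counts for the step.
#' @param W_Ey `n_output x n_excit` weight matrix with unit row sums.
#' @param theta activation threshold (> 0).
#' @param u unsigned reinforcement at this step.
#' @param us_gain gain on the additive US drive (default 0.5).
#' @return list with `z` (inputs), `y` (activities, at most one nonzero) and
#'   `winner` (index, or `NA_integer_` if silent).
#' @export
amygdala_step <- function(E_counts, W_Ey, theta, u = 0, us_gain = 0.5) {
  z <- drop(W_Ey %*% E_counts) - theta
  y <- numeric(length(z))
  top <- which(z == max(z))
  if (length(top) != 1L)  # tie: no strict winner
    return(list(z = z, y = y, winner = NA_integer_))
  if (z[top] >= 0 || u > 0) {
    act <- z[top] + us_gain * u
    pos <- sum(pmax(z, 0))
    if (pos > 0) act <- act / pos
    y[top] <- act
    list(z = z, y = y, winner = top)
  } else {
    list(z = z, y = y, winner = NA_integer_)
  }
}

#' Competitive update of the output weights
#'
#' Standard competitive learning: only the winning row moves, toward the
#' normalized input pattern, gated by the US and the winner's activity:
#' `W[i,] <- W[i,] + alpha_y * u * y_i / ||E|| * (E/||E|| - W[i,])`,
#' clipped at zero and rescaled to unit L2 norm.  With neither an active
#' winner nor a US the weights are unchanged, so the layer learns only about
#' stimuli paired (now or previously) with reinforcement.
#'
#' The rescale keeps each row on the unit sphere, so a row converges (up to
#' scale) to the normalized mean of the excitatory patterns it wins, and the
#' winner's input approaches `||E|| * cos(W, E)`: bounded by `||E|| - theta`
#' after subtracting the threshold, which is what makes a threshold between
#' `H` and `H + A` able to separate relevant from irrelevant stimuli.
#'
#' @param W_Ey output weight matrix.
#' @param E_counts excitatory spike counts.
#' @param y output activities from [amygdala_step()].
#' @param winner winning index (or `NA`).
#' @param u unsigned reinforcement.
#' @param alpha_y learning rate.
#' @return updated `W_Ey` (updated row clipped at 0 and L2-normalized).
#' @export
competitive_update <- function(W_Ey, E_counts, y, winner, u, alpha_y) {
  if (is.na(winner) || y[winner] == 0) return(W_Ey)
  normE <- sqrt(sum(E_counts^2))
  if (normE == 0) return(W_Ey)
  gate <- alpha_y * u * y[winner] / normE
  if (gate == 0) return(W_Ey)
  row <- pmax(W_Ey[winner, ] + gate * (E_counts / normE - W_Ey[winner, ]), 0)
  s <- sqrt(sum(row^2))
  if (s > 0) row <- row / s
  W_Ey[winner, ] <- row
  W_Ey
}

#' Fear response of a run
#'
#' The behavioral readout used for the latent-inhibition and fear-expression
#' protocols: the per-step maximum over output units, averaged across all
#' steps of a stimulus-presentation window.
#'
#' @param y_max per-step maxima of the output activities (vector over the
#'   whole run, as recorded in a run trace).
#' @param cs_window integer indices of the steps belonging to the stimulus
#'   presentation.
#' @return scalar mean response.
#' @export
fear_response <- function(y_max, cs_window) {
  if (length(cs_window) == 0L) stop("cs_window must be non-empty")
  mean(y_max[cs_window])
}
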