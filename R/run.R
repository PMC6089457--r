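#' Run a protocol schedule through the network
#'
#' Steps the circuit through every time step of a schedule, applying the
#' relevance update at every step and the configured output-head update
#' (competitive or gradient-descent) where one is attached.  All randomness
#' flows from a single generator seeded once at the start; draws occur in a
#' fixed order (stimulus library, initial weights, then per-step sensory and
#' excitatory sampling), so identical seeds and configurations give
#' bit-identical traces.
#'
#' @param schedule a [build_protocol()] result.
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param head output head: defaults to the schedule's hint
#'   (`"none"`, `"amygdala"`, or `"category"`).
#' @param library optional pre-built [make_stimulus_library()]; drawn fresh
#'   by default.
#' @param state optional initial [synaptic_state()]; initialized per the
#'   schedule's `init_mode` by default.
#' @param deterministic replace all Poisson sampling by expected counts
#'   (used by the analytical test oracles).
#' @param record_steps keep the full per-step record (otherwise only
#'   per-trial aggregates are returned).
#' @return an object of class `run_trace`: list with `steps` (per-step data
#'   frame: `S`, `beta`, `norm_E`, `mean_phi_E`, `I_drive`, `y_max`,
#'   `winner`, `u`, `d`, `active`, `phase`), `trials` (per-trial aggregates:
#'   `mean_S`, `mean_phi_E`, `mean_norm`, `fear`, `correct`, `xent`),
#'   `final_state`, `library`, `config`, `seed`, `protocol`.
#' @export
run_protocol <- function(schedule, config, seed = config$seed,
                         head = schedule$head, library = NULL,
                         state = NULL, deterministic = FALSE,
                         record_steps = TRUE) {
  stopifnot(inherits(schedule, "protocol_schedule"),
            inherits(config, "sim_config"))
  set.seed(seed)
  if (is.null(library))
    library <- make_stimulus_library(config, schedule$n_stimuli,
                                     uniform_baseline =
                                       schedule$uniform_baseline,
                                     contiguous =
                                       isTRUE(schedule$contiguous))
  if (is.null(state))
    state <- init_weights(config, schedule$init_mode,
                          normalize_output = !identical(head, "category"))

  T_ <- schedule$n_steps
  if (T_ == 0L) return(empty_trace(schedule, config, seed, state, library))
  dt <- config$dt
  st <- schedule$steps
  active <- st$active; u_vec <- st$u; d_vec <- st$d
  wie_vec <- st$wie_scale; wxi_vec <- st$wxi_scale

  # per-step records
  rec_S <- rec_beta <- rec_norm <- rec_phi <- rec_I <- numeric(T_)
  rec_ymax <- numeric(T_); rec_win <- rep(NA_integer_, T_)
  cat_head <- identical(head, "category")
  amy_head <- identical(head, "amygdala")
  p_mat <- if (cat_head) matrix(NA_real_, T_, config$n_output) else NULL
  rec_loss <- if (cat_head) rep(NA_real_, T_) else NULL

  W_xI_is_mat <- is.matrix(state$W_xI)
  rates <- stimulus_rates(library, integer(0))
  cur_active <- 0L
  S_prev <- 0
  trace_prev <- numeric(config$n_sensory)   # eligibility as of t-1
  I_prev <- 0
  lam <- config$lambda_trace; gam <- config$gamma
  A <- config$A; H <- config$H; alpha <- config$alpha
  variant <- config$variant; literal <- config$literal_pairing

  for (t in seq_len(T_)) {
    if (active[t] != cur_active) {
      cur_active <- active[t]
      ids <- which(bitwAnd(cur_active, bitwShiftL(1L, 0:30)) != 0L)
      rates <- stimulus_rates(library, ids)
    }
    x <- if (deterministic) rates * dt
         else stats::rpois(config$n_sensory, rates * dt)
    idx <- which(x != 0)
    xs <- x[idx]
    I <- if (W_xI_is_mat) {
      drop(state$W_xI[, idx, drop = FALSE] %*% xs) * wxi_vec[t] + state$b_I
    } else {
      sum(state$W_xI[idx] * xs) * wxi_vec[t] + state$b_I
    }
    drive <- if (length(idx)) {
      drop(state$W_xE[, idx, drop = FALSE] %*% xs) + state$b_E
    } else rep(state$b_E, config$n_excit)
    W_IE <- state$W_IE
    denom <- if (is.matrix(W_IE)) {
      drop(W_IE %*% I) * wie_vec[t] + config$I_floor
    } else {
      W_IE * I * wie_vec[t] + config$I_floor
    }
    d <- d_vec[t]
    phi <- if (d == 0) drive / denom
           else (1 - d) * drive / denom + d * drive
    E <- if (deterministic) phi * dt
         else stats::rpois(config$n_excit, phi * dt)
    normE <- sqrt(sum(E * E))
    S_now <- normE - H
    beta <- A * u_vec[t] + gam * S_now - S_prev
    if (!is.finite(beta))
      stop("non-finite prediction error at step ", t,
           " (norm=", normE, ")")

    # relevance update: conventional pairing uses the t-1 trace/activity
    if (literal) {
      trace_now <- update_trace(trace_prev, x, gam, lam)
      state <- apply_relevance_update(state, beta, trace_now, I,
                                      variant, alpha)
      trace_prev <- trace_now
    } else {
      state <- apply_relevance_update(state, beta, trace_prev, I_prev,
                                      variant, alpha)
      trace_prev <- update_trace(trace_prev, x, gam, lam)
    }

    if (amy_head) {
      stp <- amygdala_step_sparse(E, state$W_Ey, config$theta, u_vec[t],
                                  config$us_gain)
      if (!is.na(stp$winner)) {
        rec_ymax[t] <- stp$y_winner
        rec_win[t] <- stp$winner
        state$W_Ey <- competitive_update_row(state$W_Ey, E, stp$y_winner,
                                             stp$winner, u_vec[t],
                                             config$alpha_y, normE)
      }
    } else if (cat_head) {
      lambdaE <- phi * dt
      gains <- if (d == 0) 1 / denom else (1 - d) / denom + d
      target <- which(bitwAnd(cur_active, bitwShiftL(1L, 0:30)) != 0L)[1]
      if (!is.na(target) && length(target) == 1L && cur_active != 0L) {
        bp <- backprop_update(state, x, lambdaE, gains, target,
                              config$alpha_cat, dt)
        state <- bp$state
        rec_loss[t] <- bp$loss
      }
      p_mat[t, ] <- category_rates(lambdaE, state$W_Ey,
                                   config$kappa) / config$kappa
    }

    rec_S[t] <- S_now; rec_beta[t] <- beta; rec_norm[t] <- normE
    rec_phi[t] <- mean(phi); rec_I[t] <- mean(I)
    S_prev <- S_now; I_prev <- I
  }

  trials <- aggregate_trials(schedule, rec_S, rec_phi, rec_norm, rec_ymax,
                             p_mat, rec_loss, head)
  steps <- NULL
  if (record_steps) {
    steps <- data.frame(S = rec_S, beta = rec_beta, norm_E = rec_norm,
                        mean_phi_E = rec_phi, I_drive = rec_I,
                        y_max = rec_ymax, winner = rec_win,
                        u = u_vec, d = d_vec, active = active,
                        phase = st$phase)
    if (cat_head) steps$loss <- rec_loss
  }
  structure(list(steps = steps, trials = trials, final_state = state,
                 library = library, config = config, seed = seed,
                 protocol = schedule$name, head = head,
                 schedule = schedule),
            class = "run_trace")
}

# sparse-input amygdala step used in the hot loop (same math as
# amygdala_step, avoiding the dense allocation of y)
amygdala_step_sparse <- function(E, W_Ey, theta, u, us_gain) {
  idx <- which(E != 0)
  z <- if (length(idx)) drop(W_Ey[, idx, drop = FALSE] %*% E[idx]) - theta
       else rep(-theta, nrow(W_Ey))
  top <- which(z == max(z))
  if (length(top) != 1L) return(list(winner = NA_integer_, y_winner = 0))
  if (z[top] >= 0 || u > 0) {
    act <- z[top] + us_gain * u
    pos <- sum(pmax(z, 0))
    if (pos > 0) act <- act / pos
    list(winner = top, y_winner = act)
  } else {
    list(winner = NA_integer_, y_winner = 0)
  }
}

competitive_update_row <- function(W_Ey, E, y_winner, winner, u, alpha_y,
                                   normE) {
  if (normE == 0) return(W_Ey)
  gate <- alpha_y * u * y_winner / normE
  if (gate == 0) return(W_Ey)
  row <- W_Ey[winner, ]
  row <- pmax(row + gate * (E / normE - row), 0)
  s <- sqrt(sum(row^2))
  if (s > 0) row <- row / s
  W_Ey[winner, ] <- row
  W_Ey
}

aggregate_trials <- function(schedule, rec_S, rec_phi, rec_norm, rec_ymax,
                             p_mat, rec_loss, head) {
  tr <- schedule$trials
  if (nrow(tr) == 0L) return(cbind(tr, mean_S = numeric(0),
                                   mean_phi_E = numeric(0),
                                   mean_norm = numeric(0),
                                   fear = numeric(0),
                                   correct = logical(0),
                                   xent = numeric(0)))
  n <- nrow(tr)
  mean_S <- mean_phi <- mean_norm <- fear <- xent <- rep(NA_real_, n)
  correct <- rep(NA, n)
  for (i in seq_len(n)) {
    w <- tr$start[i]:tr$end[i]
    mean_S[i] <- mean(rec_S[w])
    mean_phi[i] <- mean(rec_phi[w])
    mean_norm[i] <- mean(rec_norm[w])
    if (identical(head, "amygdala")) fear[i] <- mean(rec_ymax[w])
    if (identical(head, "category") && !is.null(p_mat)) {
      pbar <- colMeans(p_mat[w, , drop = FALSE])
      correct[i] <- which.max(pbar) == tr$stimulus[i]
      xent[i] <- mean(rec_loss[w], na.rm = TRUE)
    }
  }
  cbind(tr, mean_S = mean_S, mean_phi_E = mean_phi, mean_norm = mean_norm,
        fear = fear, correct = correct, xent = xent)
}

empty_trace <- function(schedule, config, seed, state, library) {
  structure(list(steps = schedule$steps[0, ],
                 trials = aggregate_trials(schedule, numeric(0), numeric(0),
                                           numeric(0), numeric(0), NULL,
                                           NULL, schedule$head),
                 final_state = state, library = library, config = config,
                 seed = seed, protocol = schedule$name,
                 head = schedule$head, schedule = schedule),
            class = "run_trace")
}

#' @export
print.run_trace <- function(x, ...) {
  cat(sprintf("<run_trace> %s (%s head), %d steps, %d trials, seed %d\n",
              x$protocol, x$head,
              if (is.null(x$steps)) x$schedule$n_steps else nrow(x$steps),
              nrow(x$trials), x$seed))
  invisible(x)
}
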