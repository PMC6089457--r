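#' Simulation configuration
#'
#' Builds the complete set of scalar hyperparameters for the network and its
#' learning rules.  Defaults reproduce the standard model: a 1000-unit sensory
#' layer driving 800 excitatory cortical units and a single divisive
#' feedforward inhibitory unit, with an unsigned temporal-difference rule on
#' the sensory-to-inhibitory weights.
#'
#' Norm-based quantities (`H`, `A`, `theta`) are expressed in units of the L2
#' norm of per-step excitatory spike counts.  With `m` excitatory units firing
#' at rate `r` Hz and step `dt`, that norm is approximately `sqrt(m*r*dt)`;
#' the default `H = 6.5` corresponds to a 2.6 Hz population baseline and
#' `H + A = 7.9` to the 3.9 Hz rate evoked by a fully learned
#' reinforcement-predictive stimulus.
#'
#' @param dt time step in seconds.
#' @param n_sensory,n_excit,n_inhib,n_output layer sizes.  `n_inhib = 1` is
#'   the standard model; `n_inhib = 500` gives the population-inhibition
#'   variant.
#' @param H homeostatic set-point for the excitatory spike-count norm.
#' @param A salience scale: the trained norm deviation evoked by a stimulus
#'   whose unsigned value is 1.
#' @param gamma temporal discount factor in (0, 1).
#' @param lambda_trace eligibility-trace decay in [0, 1); 0 gives TD(0).
#' @param theta output-layer threshold; defaults to `H/4`.
#' @param I_floor additive floor on the divisive denominator.
#' @param phi_on firing rate (Hz) of stimulus-coding sensory units while
#'   their stimulus is on.
#' @param kappa total firing rate (Hz) shared by the categorization head.
#' @param alpha learning rate of the relevance (TD) rule.
#' @param alpha_y learning rate of the competitive (amygdala) output head.
#' @param alpha_cat learning rate of the gradient-descent categorization head.
#' @param baseline_mode,baseline_var mode (Hz) and variance (Hz^2) of the
#'   gamma distribution from which non-coding baseline rates are drawn.
#' @param us_gain additive drive an unconditioned stimulus contributes to the
#'   winning output unit.
#' @param b_E,b_I excitatory / inhibitory bias terms (not reported for the
#'   original model; default 0).
#' @param variant which synapses the relevance rule trains: `"xI"`
#'   (sensory to inhibitory, the standard model), `"xE"`, or `"IE"`.
#' @param literal_pairing logical; if `TRUE` the TD update pairs the
#'   prediction error at step t with the input at step t (the formula as
#'   printed), rather than the conventional pairing with the step t-1 trace.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$H / 4 == cfg$theta
#' @export
sim_config <- function(dt = 0.02,
                       n_sensory = 1000L,
                       n_excit = 800L,
                       n_inhib = 1L,
                       n_output = 10L,
                       H = 6.5,
                       A = 1.4,
                       gamma = 0.9,
                       lambda_trace = 0,
                       theta = H / 4,
                       I_floor = 0.1,
                       phi_on = 20,
                       kappa = 20,
                       alpha = 0.02,
                       alpha_y = 0.5,
                       alpha_cat = 30,
                       baseline_mode = 0.6,
                       baseline_var = 3,
                       us_gain = 0.5,
                       b_E = 0,
                       b_I = 0,
                       variant = c("xI", "xE", "IE"),
                       literal_pairing = FALSE,
                       seed = 1L) {
  variant <- match.arg(variant)
  cfg <- list(
    dt = dt,
    n_sensory = as.integer(n_sensory),
    n_excit = as.integer(n_excit),
    n_inhib = as.integer(n_inhib),
    n_output = as.integer(n_output),
    H = H, A = A, gamma = gamma, lambda_trace = lambda_trace,
    theta = theta, I_floor = I_floor,
    phi_on = phi_on, kappa = kappa,
    alpha = alpha, alpha_y = alpha_y, alpha_cat = alpha_cat,
    baseline_mode = baseline_mode, baseline_var = baseline_var,
    us_gain = us_gain, b_E = b_E, b_I = b_I,
    variant = variant,
    literal_pairing = isTRUE(literal_pairing),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x object to validate.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  with(x, {
    if (!(dt > 0)) stop("dt must be > 0")
    counts <- c(n_sensory, n_excit, n_inhib, n_output)
    if (any(counts < 1L)) stop("all layer sizes must be >= 1")
    if (!(gamma > 0 && gamma < 1)) stop("gamma must lie in (0, 1)")
    if (!(lambda_trace >= 0 && lambda_trace < 1))
      stop("lambda_trace must lie in [0, 1)")
    if (!(I_floor > 0)) stop("I_floor must be > 0")
    if (!all(c(H, A, phi_on, kappa) > 0))
      stop("H, A, phi_on and kappa must be > 0")
    if (!all(c(alpha, alpha_y, alpha_cat) > 0)) stop("learning rates must be > 0")
    if (baseline_mode < 0 || baseline_var <= 0)
      stop("baseline_mode must be >= 0 and baseline_var > 0")
  })
  x
}

#' Read a simulation configuration from a JSON document
#'
#' The document must be a single JSON object whose keys mirror the
#' [sim_config()] argument names.  Unknown keys are an error, so typos
#' cannot silently fall back to defaults.
#'
#' @param path path to a JSON file.
#' @return a `sim_config` object.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(doc)) stop("config document must be a JSON object")
  known <- setdiff(names(formals(sim_config)), "")
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, doc)
}

#' Write a simulation configuration as JSON
#'
#' @param config a `sim_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  layers: %d sensory -> %d excit / %d inhib -> %d output\n",
              x$n_sensory, x$n_excit, x$n_inhib, x$n_output))
  cat(sprintf("  dt=%g s  H=%g  A=%g  gamma=%g  lambda=%g  theta=%g\n",
              x$dt, x$H, x$A, x$gamma, x$lambda_trace, x$theta))
  cat(sprintf("  plasticity: %s (alpha=%g)  output alpha_y=%g  seed=%d\n",
              x$variant, x$alpha, x$alpha_y, x$seed))
  invisible(x)
}
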