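#' Build the event schedule for a simulation protocol
#'
#' Constructs the per-time-step event table for one of the six conditioning
#' protocols.  Every protocol starts with a 60 s adaptation period with no
#' stimuli and `u = 0`, during which the weights settle onto the baseline
#' input statistics.
#'
#' \describe{
#'   \item{learning_to_ignore}{50 pairings of a 200 ms CS+ whose onset
#'     precedes the US by 100 ms (`u = 1` from US onset to CS+ offset), with
#'     US inter-trial intervals uniform in 20--30 s; a CS0 is presented the
#'     same number of times at independent random times, never overlapping a
#'     CS+ window.}
#'   \item{blocking}{four phases: 50 interleaved unreinforced pre-exposures
#'     of CS-A and CS-B each, 50 CS-A + US conditioning trials, 50
#'     simultaneous CS-A + CS-B + US trials, and 10 unreinforced test
#'     presentations of each CS; intervals uniform in 10--15 s.}
#'   \item{latent_inhibition}{optionally 30 unreinforced 6 s CS
#'     pre-exposures (6 s ISI), then CS--shock pairings (`u = 1` throughout
#'     the CS), then 4 unreinforced test presentations.  A 20% bypass of
#'     inhibition can be scheduled during the conditioning or the testing
#'     phase (the pharmacological arms).  Durations are the rat protocol
#'     compressed by a factor of 5.}
#'   \item{fear_expression}{a 30 s baseline (with 250 ms disruption pulses
#'     separated by 860 ms in the disruption arm), 12 CS--US pairings (6 s
#'     CS, `u = 1` throughout, ITI uniform 4--30 s), 12 extinction
#'     presentations, then test presentations under the arm's manipulation
#'     (20% inhibition bypass, or `W_IE` scaled by 1.1).}
#'   \item{categorization}{ten 200 ms stimuli in fixed order; the 2 s
#'     sequence repeats for 50 epochs (100 simulated s); `u = 1` throughout
#'     each rewarded stimulus.}
#'   \item{learned_irrelevance}{100 presentations of a 200 ms CS and a
#'     200 ms US at independent uniform times over 800 s, followed by 100
#'     pairings at 5 s intervals with the CS preceding the US by 100 ms; the
#'     `paired_only` arm skips the uncorrelated phase.}
#' }
#'
#' @param name one of `"learning_to_ignore"`, `"blocking"`,
#'   `"latent_inhibition"`, `"fear_expression"`, `"categorization"`,
#'   `"learned_irrelevance"`.
#' @param config a [sim_config()].
#' @param ... protocol options overriding the defaults described above,
#'   e.g. `n_presentations`, `iti`, `disruption`, `preexposed`,
#'   `drug_phase`, `manipulation`, `n_rewarded`, `arm`, `adapt_dur`.
#' @return an object of class `protocol_schedule`: a list with `name`,
#'   `dt`, `n_steps`, `n_stimuli`, `steps` (data frame: `active` bitmask of
#'   stimuli, `u`, `d`, `wie_scale`, `wxi_scale`, `phase`), `trials` (data
#'   frame: `trial`, `stimulus` (0 = no-stimulus measurement window),
#'   `phase`, `start`, `end`), plus head / initialization hints used by
#'   [run_protocol()].
#' @export
build_protocol <- function(name, config, ...) {
  valid <- c("learning_to_ignore", "blocking", "latent_inhibition",
             "fear_expression", "categorization", "learned_irrelevance")
  if (!name %in% valid)
    stop("unknown protocol '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  builder <- switch(name,
    learning_to_ignore = proto_learning_to_ignore,
    blocking = proto_blocking,
    latent_inhibition = proto_latent_inhibition,
    fear_expression = proto_fear_expression,
    categorization = proto_categorization,
    learned_irrelevance = proto_learned_irrelevance)
  builder(config, ...)
}

# ---- schedule assembly helpers ----------------------------------------

# A schedule under construction: plain vectors indexed by step.
new_sched <- function(n_steps, dt) {
  list(dt = dt, n_steps = n_steps,
       active = integer(n_steps), u = numeric(n_steps),
       d = numeric(n_steps), wie_scale = rep(1, n_steps),
       wxi_scale = rep(1, n_steps), phase = rep(NA_character_, n_steps),
       trials = list())
}

steps_of <- function(t_on, dur, dt, n_steps) {
  # small epsilon so grid-aligned onsets are not lost to float rounding
  from <- floor(t_on / dt + 1e-9) + 1L
  to <- min(floor((t_on + dur) / dt + 1e-9), n_steps)
  if (from > to) integer(0) else from:to
}

mark_stimulus <- function(sc, stim, t_on, dur, phase, record_trial = TRUE) {
  w <- steps_of(t_on, dur, sc$dt, sc$n_steps)
  sc$active[w] <- bitwOr(sc$active[w], bitwShiftL(1L, stim - 1L))
  sc$phase[w] <- phase
  if (record_trial)
    sc$trials[[length(sc$trials) + 1L]] <-
      list(stimulus = stim, phase = phase, start = w[1L], end = w[length(w)])
  sc
}

mark_us <- function(sc, t_on, dur) {
  w <- steps_of(t_on, dur, sc$dt, sc$n_steps)
  sc$u[w] <- 1
  sc
}

mark_phase <- function(sc, t_from, t_to, phase) {
  w <- steps_of(t_from, t_to - t_from, sc$dt, sc$n_steps)
  sc$phase[w[is.na(sc$phase[w])]] <- phase
  sc
}

finish_sched <- function(sc, name, n_stimuli, head = "none",
                         init_mode = "default", uniform_baseline = NULL,
                         contiguous = identical(init_mode,
                                                "latent_inhibition")) {
  trials <- if (length(sc$trials)) {
    tr <- data.frame(stimulus = vapply(sc$trials, `[[`, 0L, "stimulus"),
                     phase = vapply(sc$trials, `[[`, "", "phase"),
                     start = vapply(sc$trials, `[[`, 0L, "start"),
                     end = vapply(sc$trials, `[[`, 0L, "end"))
    tr <- tr[order(tr$start, tr$stimulus), , drop = FALSE]
    rownames(tr) <- NULL
    cbind(trial = seq_len(nrow(tr)), tr)   # chronological numbering
  } else {
    data.frame(trial = integer(0), stimulus = integer(0),
               phase = character(0), start = integer(0), end = integer(0))
  }
  sc$phase[is.na(sc$phase)] <- "iti"
  structure(list(name = name, dt = sc$dt, n_steps = sc$n_steps,
                 n_stimuli = n_stimuli,
                 steps = data.frame(active = sc$active, u = sc$u, d = sc$d,
                                    wie_scale = sc$wie_scale,
                                    wxi_scale = sc$wxi_scale,
                                    phase = sc$phase),
                 trials = trials, head = head, init_mode = init_mode,
                 uniform_baseline = uniform_baseline,
                 contiguous = contiguous),
            class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> %s: %d steps (%.1f s), %d stimuli, %d trials\n",
              x$name, x$n_steps, x$n_steps * x$dt, x$n_stimuli,
              nrow(x$trials)))
  print(table(x$trials$phase, x$trials$stimulus))
  invisible(x)
}

# CS0-style placement: onsets that never overlap forbidden windows
place_random_onsets <- function(n, t_min, t_max, dur, forbidden,
                                max_iter = 10000L) {
  onsets <- numeric(0)
  occupied <- forbidden   # matrix with columns from,to
  it <- 0L
  while (length(onsets) < n) {
    it <- it + 1L
    if (it > max_iter) stop("could not place random stimulus onsets")
    o <- stats::runif(1, t_min, t_max - dur)
    if (nrow(occupied) == 0L ||
        all(o + dur <= occupied[, 1L] | o >= occupied[, 2L])) {
      onsets <- c(onsets, o)
      occupied <- rbind(occupied, c(o, o + dur))
    }
  }
  sort(onsets)
}

# ---- the six protocols ------------------------------------------------

proto_learning_to_ignore <- function(config, n_presentations = 50L,
                                     iti = c(20, 30), cs_dur = 0.2,
                                     cs_us_offset = 0.1, us_dur = NULL,
                                     disruption = 0, adapt_dur = 60) {
  dt <- config$dt
  if (is.null(us_dur)) us_dur <- cs_dur - cs_us_offset
  us_onsets <- adapt_dur + cumsum(stats::runif(n_presentations, iti[1], iti[2]))
  total <- us_onsets[n_presentations] + 2
  sc <- new_sched(ceiling(total / dt), dt)
  csp_onsets <- us_onsets - cs_us_offset
  forb <- cbind(csp_onsets - cs_dur, csp_onsets + cs_dur)
  cs0_onsets <- place_random_onsets(n_presentations, adapt_dur,
                                    total - 1, cs_dur, forb)
  for (o in csp_onsets) sc <- mark_stimulus(sc, 1L, o, cs_dur, "train")
  for (o in us_onsets) sc <- mark_us(sc, o, us_dur)
  for (o in cs0_onsets) sc <- mark_stimulus(sc, 2L, o, cs_dur, "train")
  if (disruption > 0) {
    post <- steps_of(adapt_dur, total, dt, sc$n_steps)
    sc$d[post] <- disruption
  }
  sc <- mark_phase(sc, 0, adapt_dur, "adaptation")
  finish_sched(sc, "learning_to_ignore", 2L)
}

proto_blocking <- function(config, n_pre = 50L, n_cond = 50L,
                           n_block = 50L, n_test = 10L, iti = c(10, 15),
                           cs_dur = 0.2, cs_us_offset = 0.1, us_dur = NULL,
                           disruption = 0, adapt_dur = 60) {
  dt <- config$dt
  if (is.null(us_dur)) us_dur <- cs_dur - cs_us_offset
  t <- adapt_dur
  events <- list()   # list(stim vector, us logical, onset, phase)
  add <- function(stims, us, phase) {
    t <<- t + stats::runif(1, iti[1], iti[2])
    events[[length(events) + 1L]] <<- list(stims = stims, us = us,
                                           onset = t, phase = phase)
  }
  for (i in seq_len(n_pre)) {     # interleaved alternation A,B,A,B,...
    add(1L, FALSE, "pre_exposure"); add(2L, FALSE, "pre_exposure")
  }
  for (i in seq_len(n_cond)) add(1L, TRUE, "conditioning")
  for (i in seq_len(n_block)) add(c(1L, 2L), TRUE, "blocking")
  for (i in seq_len(n_test)) {
    add(1L, FALSE, "test"); add(2L, FALSE, "test")
  }
  total <- t + 2
  sc <- new_sched(ceiling(total / dt), dt)
  for (ev in events) {
    for (s in ev$stims)
      sc <- mark_stimulus(sc, s, ev$onset, cs_dur, ev$phase)
    if (ev$us) sc <- mark_us(sc, ev$onset + cs_us_offset, us_dur)
  }
  if (disruption > 0) {
    post <- steps_of(adapt_dur, total, dt, sc$n_steps)
    sc$d[post] <- disruption
  }
  sc <- mark_phase(sc, 0, adapt_dur, "adaptation")
  finish_sched(sc, "blocking", 2L)
}

proto_latent_inhibition <- function(config, preexposed = TRUE,
                                    drug_phase = c("none", "conditioning",
                                                   "testing"),
                                    disruption = 0.2, n_pre = 30L,
                                    n_cond = 10L, n_test = 4L, cs_dur = 6,
                                    isi = 6, adapt_dur = 60) {
  drug_phase <- match.arg(drug_phase)
  dt <- config$dt
  t <- adapt_dur
  events <- list()
  add <- function(us, phase) {
    events[[length(events) + 1L]] <<- list(onset = t, us = us, phase = phase)
    t <<- t + cs_dur + isi
  }
  if (preexposed) for (i in seq_len(n_pre)) add(FALSE, "pre_exposure")
  cond_from <- t
  for (i in seq_len(n_cond)) add(TRUE, "conditioning")
  test_from <- t
  for (i in seq_len(n_test)) add(FALSE, "test")
  total <- t + 1
  sc <- new_sched(ceiling(total / dt), dt)
  for (ev in events) {
    sc <- mark_stimulus(sc, 1L, ev$onset, cs_dur, ev$phase)
    if (ev$us) sc <- mark_us(sc, ev$onset, cs_dur)  # shock spans the CS
  }
  if (drug_phase == "conditioning")
    sc$d[steps_of(cond_from, test_from - cond_from, dt, sc$n_steps)] <-
      disruption
  if (drug_phase == "testing")
    sc$d[steps_of(test_from, total - test_from, dt, sc$n_steps)] <- disruption
  sc <- mark_phase(sc, 0, adapt_dur, "adaptation")
  finish_sched(sc, "latent_inhibition", 1L, head = "amygdala",
               init_mode = "latent_inhibition")
}

proto_fear_expression <- function(config,
                                  manipulation = c("none", "disruption",
                                                   "cond_only", "excitation"),
                                  disruption = 0.2, wie_scale = 1.1,
                                  n_cond = 12L, n_ext = 12L, n_test = 4L,
                                  cs_dur = 6, iti = c(4, 30), isi = 6,
                                  baseline_dur = 30, pulse_on = 0.25,
                                  pulse_off = 0.86, adapt_dur = 60) {
  manipulation <- match.arg(manipulation)
  dt <- config$dt
  with_ext <- manipulation %in% c("none", "disruption")
  t <- adapt_dur + baseline_dur
  events <- list()
  add <- function(us, phase, gap) {
    events[[length(events) + 1L]] <<- list(onset = t, us = us, phase = phase)
    t <<- t + cs_dur + gap
  }
  for (i in seq_len(n_cond))
    add(TRUE, "conditioning", stats::runif(1, iti[1], iti[2]))
  if (with_ext)
    for (i in seq_len(n_ext))
      add(FALSE, "extinction", stats::runif(1, iti[1], iti[2]))
  test_from <- t
  for (i in seq_len(n_test)) add(FALSE, "test", isi)
  total <- t + 1
  sc <- new_sched(ceiling(total / dt), dt)
  # baseline measurement windows follow the 0.9 Hz pulse grid in every arm;
  # only the disruption arm actually bypasses inhibition during them.
  pulse_onsets <- seq(adapt_dur, adapt_dur + baseline_dur - pulse_on,
                      by = pulse_on + pulse_off)
  for (o in pulse_onsets) {
    w <- steps_of(o, pulse_on, dt, sc$n_steps)
    if (manipulation == "disruption") sc$d[w] <- disruption
    sc$trials[[length(sc$trials) + 1L]] <-
      list(stimulus = 0L, phase = "baseline", start = w[1L], end = w[length(w)])
  }
  for (ev in events) {
    sc <- mark_stimulus(sc, 1L, ev$onset, cs_dur, ev$phase)
    if (ev$us) sc <- mark_us(sc, ev$onset, cs_dur)
    if (ev$phase == "test") {
      w <- steps_of(ev$onset, cs_dur, dt, sc$n_steps)
      if (manipulation == "disruption") sc$d[w] <- disruption
      if (manipulation == "excitation") sc$wie_scale[w] <- wie_scale
    }
  }
  sc <- mark_phase(sc, 0, adapt_dur, "adaptation")
  sc <- mark_phase(sc, adapt_dur, adapt_dur + baseline_dur, "baseline")
  finish_sched(sc, "fear_expression", 1L, head = "amygdala",
               init_mode = "latent_inhibition")
}

proto_categorization <- function(config, n_epochs = 50L, n_stimuli = 10L,
                                 n_rewarded = 1L, stim_dur = 0.2,
                                 adapt_dur = 60) {
  dt <- config$dt
  total <- adapt_dur + n_epochs * n_stimuli * stim_dur
  sc <- new_sched(round(total / dt), dt)
  rewarded <- seq_len(n_rewarded)
  for (ep in seq_len(n_epochs)) {
    for (s in seq_len(n_stimuli)) {
      t <- adapt_dur + ((ep - 1L) * n_stimuli + (s - 1L)) * stim_dur
      sc <- mark_stimulus(sc, s, t, stim_dur, paste0("epoch", ep))
      if (s %in% rewarded) sc <- mark_us(sc, t, stim_dur)
    }
  }
  sc <- mark_phase(sc, 0, adapt_dur, "adaptation")
  out <- finish_sched(sc, "categorization", n_stimuli, head = "category",
                      uniform_baseline = 2)
  out$rewarded <- rewarded
  out$n_epochs <- n_epochs
  out
}

proto_learned_irrelevance <- function(config,
                                      arm = c("uncorrelated", "paired_only"),
                                      n_uncorr = 100L, uncorr_span = 800,
                                      n_paired = 100L, paired_interval = 5,
                                      cs_dur = 0.2, us_dur = 0.2,
                                      cs_us_offset = 0.1, adapt_dur = 60) {
  arm <- match.arg(arm)
  dt <- config$dt
  t0 <- adapt_dur
  cs_onsets <- us_onsets <- numeric(0)
  if (arm == "uncorrelated") {
    cs_onsets <- sort(stats::runif(n_uncorr, t0, t0 + uncorr_span - cs_dur))
    us_onsets <- sort(stats::runif(n_uncorr, t0, t0 + uncorr_span - us_dur))
    t0 <- t0 + uncorr_span
  }
  paired_cs <- t0 + paired_interval * (seq_len(n_paired) - 1L)
  total <- paired_cs[n_paired] + paired_interval
  sc <- new_sched(ceiling(total / dt), dt)
  for (o in cs_onsets) sc <- mark_stimulus(sc, 1L, o, cs_dur, "uncorrelated")
  for (o in us_onsets) sc <- mark_us(sc, o, us_dur)
  for (o in paired_cs) {
    sc <- mark_stimulus(sc, 1L, o, cs_dur, "paired")
    sc <- mark_us(sc, o + cs_us_offset, us_dur)
  }
  sc <- mark_phase(sc, 0, adapt_dur, "adaptation")
  finish_sched(sc, "learned_irrelevance", 1L, head = "amygdala")
}

#' Export a schedule's per-step event table as CSV
#'
#' Writes one row per time step (`step`, `time_s`, `active` stimulus
#' bitmask, `u`, `d`, `wie_scale`, `wxi_scale`, `phase`) so a protocol can
#' be audited outside the package.
#'
#' @param schedule a [build_protocol()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  df <- cbind(step = seq_len(schedule$n_steps),
              time_s = seq_len(schedule$n_steps) * schedule$dt,
              schedule$steps)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
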