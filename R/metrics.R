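#' Exact discounted unsigned value of a realized schedule
#'
#' Test oracle for the quantity the salience signal is trained to track:
#' the discounted sum of future unconditioned-stimulus magnitudes,
#' `U(t) = sum_{i>=1} gamma^(i-1) u(t+i)`, computed by backward recursion
#' `U(t) = u(t+1) + gamma * U(t+1)` over the realized event sequence (not
#' the generative expectation; the protocols are deterministic given their
#' sampled intervals).
#'
#' @param u per-step unsigned US values (vector), or a `protocol_schedule`.
#' @param gamma temporal discount factor in (0, 1).
#' @return per-step values `U(t)`, same length as `u`.
#' @export
true_unsigned_value <- function(u, gamma) {
  if (inherits(u, "protocol_schedule")) u <- u$steps$u
  n <- length(u)
  U <- numeric(n)
  if (n < 2L) return(U)
  for (t in (n - 1L):1L) U[t] <- u[t + 1L] + gamma * U[t + 1L]
  U
}

#' Per-trial salience summary across runs
#'
#' Trial-indexed mean salience during presentations of one stimulus,
#' aggregated across runs (mean and SD per trial index).
#'
#' @param runs a list of `run_trace` objects (or a single one).
#' @param stimulus stimulus index to summarize.
#' @param phase optional phase filter.
#' @return data frame with `presentation`, `mean_S`, `sd_S`, `n_runs`.
#' @export
salience_summary <- function(runs, stimulus, phase = NULL) {
  if (inherits(runs, "run_trace")) runs <- list(runs)
  if (length(runs) == 0L) stop("need at least one run")
  per_run <- lapply(runs, function(r) {
    tr <- r$trials[r$trials$stimulus == stimulus, ]
    if (!is.null(phase)) tr <- tr[tr$phase %in% phase, ]
    if (nrow(tr) == 0L)
      stop("no presentations of stimulus ", stimulus, " in run")
    tr$mean_S
  })
  k <- min(lengths(per_run))
  m <- vapply(per_run, function(v) v[seq_len(k)], numeric(k))
  m <- matrix(m, nrow = k)
  data.frame(presentation = seq_len(k),
             mean_S = rowMeans(m),
             sd_S = apply(m, 1L, stats::sd),
             n_runs = length(runs))
}

#' Classification accuracy and cross-entropy per epoch
#'
#' For a categorization run: the fraction of presentations per epoch whose
#' time-averaged output distribution puts its maximum on the true category,
#' and the mean per-step cross-entropy (natural log units).
#'
#' @param run a categorization `run_trace`.
#' @return data frame with `epoch`, `accuracy`, `xent`.
#' @export
classification_metrics <- function(run) {
  if (!identical(run$protocol, "categorization"))
    stop("classification metrics require a categorization run")
  tr <- run$trials
  ep <- as.integer(sub("^epoch", "", tr$phase))
  agg <- lapply(split(seq_len(nrow(tr)), ep), function(i) {
    c(accuracy = mean(tr$correct[i]), xent = mean(tr$xent[i]))
  })
  out <- do.call(rbind, agg)
  data.frame(epoch = as.integer(rownames(out)),
             accuracy = out[, "accuracy"], xent = out[, "xent"],
             row.names = NULL)
}

#' Export a set of runs as delimited text plus a manifest
#'
#' Writes `trials.csv` (columns `run`, `trial`, `phase`, `stimulus`,
#' `mean_S`, `mean_phi_E`, `mean_norm`, `fear`, `correct`, `xent`) and
#' `manifest.json` (configuration, seeds, package version).  Optionally the
#' full per-step records as gzipped CSV, one file per run.
#'
#' @param runs list of `run_trace` objects.
#' @param out_dir output directory (created if needed).
#' @param steps also export per-step records (`steps_<run>.csv.gz`).
#' @return `out_dir`, invisibly.
#' @export
export_run <- function(runs, out_dir, steps = FALSE) {
  if (inherits(runs, "run_trace")) runs <- list(runs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  tabs <- lapply(seq_along(runs), function(i) {
    cbind(run = i, runs[[i]]$trials)
  })
  trials <- do.call(rbind, tabs)
  utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "inhibrel",
    version = as.character(utils::packageVersion("inhibrel")),
    protocol = runs[[1L]]$protocol,
    seeds = vapply(runs, `[[`, 0L, "seed"),
    config = unclass(runs[[1L]]$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (steps) {
    for (i in seq_along(runs)) {
      if (is.null(runs[[i]]$steps)) next
      con <- gzfile(file.path(out_dir, sprintf("steps_%03d.csv.gz", i)))
      utils::write.csv(runs[[i]]$steps, con, row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Re-import an exported trial table
#'
#' @param out_dir directory written by [export_run()].
#' @return list with `trials` (data frame) and `manifest` (list).
#' @export
import_run <- function(out_dir) {
  trials <- utils::read.csv(file.path(out_dir, "trials.csv"))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(trials = trials, manifest = manifest)
}
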