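test_that("unknown protocol names are rejected with the valid list", {
  cfg <- sim_config()
  expect_error(build_protocol("pavlov", cfg), "learning_to_ignore")
})

test_that("every protocol starts with a silent 60 s adaptation", {
  cfg <- sim_config(seed = 1)
  for (nm in c("learning_to_ignore", "blocking", "latent_inhibition",
               "fear_expression", "categorization", "learned_irrelevance")) {
    set.seed(1)
    sch <- build_protocol(nm, cfg)
    first <- sch$steps[seq_len(60 / cfg$dt), ]
    expect_true(all(first$active == 0L), info = nm)
    expect_true(all(first$u == 0), info = nm)
    expect_true(all(first$phase == "adaptation"), info = nm)
  }
})

test_that("learning-to-ignore audit: counts, offsets and intervals", {
  cfg <- sim_config(seed = 5)
  set.seed(5)
  sch <- build_protocol("learning_to_ignore", cfg)
  tr <- sch$trials
  expect_equal(sum(tr$stimulus == 1), 50L)   # CS+
  expect_equal(sum(tr$stimulus == 2), 50L)   # CS0
  # each CS+ lasts 200 ms and overlaps the US, whose onset is 100 ms after
  csp <- tr[tr$stimulus == 1, ]
  expect_true(all(csp$end - csp$start + 1L == 10L))
  u <- sch$steps$u
  for (i in seq_len(nrow(csp))) {
    w <- csp$start[i]:csp$end[i]
    expect_true(all(u[w[1:5]] == 0))         # first 100 ms without US
    expect_true(all(u[w[6:10]] == 1))        # US on from +100 ms
  }
  # total US time equals 50 presentations x 100 ms
  expect_equal(sum(u) * cfg$dt, 50 * 0.1)
  # US inter-onset intervals lie in [20, 30] s
  on <- which(diff(c(0, u)) == 1)
  gaps <- diff(on) * cfg$dt
  expect_true(all(gaps >= 20 - 0.2 & gaps <= 30 + 0.2))
  # CS0 never overlaps a CS+ window
  expect_true(all(sch$steps$active %in% c(0L, 1L, 2L)))
})

test_that("blocking audit: four phases with the printed trial counts", {
  cfg <- sim_config(seed = 6)
  set.seed(6)
  sch <- build_protocol("blocking", cfg)
  tr <- sch$trials
  counts <- table(tr$phase, tr$stimulus)
  expect_equal(unname(counts["pre_exposure", ]), c(50, 50))
  expect_equal(unname(counts["conditioning", ]), c(50, 0))
  expect_equal(unname(counts["blocking", ]), c(50, 50))
  expect_equal(unname(counts["test", ]), c(10, 10))
  # blocking phase presents both stimuli simultaneously
  expect_true(any(sch$steps$active == 3L))
  # test phase is unreinforced
  test_steps <- unlist(mapply(seq, tr$start[tr$phase == "test"],
                              tr$end[tr$phase == "test"]))
  expect_true(all(sch$steps$u[test_steps] == 0))
})

test_that("latent-inhibition audit: pre-exposures, pairing and drug arms", {
  cfg <- sim_config(seed = 7)
  set.seed(7)
  sch <- build_protocol("latent_inhibition", cfg)
  tr <- sch$trials
  expect_equal(sum(tr$phase == "pre_exposure"), 30L)
  expect_equal(sum(tr$phase == "test"), 4L)
  # 6 s CS / 6 s ISI: the rat durations divided by 5 fit a 12 s cycle
  pe <- tr[tr$phase == "pre_exposure", ]
  expect_true(all(diff(pe$start) * cfg$dt == 12))
  expect_true(all(pe$end - pe$start + 1L == 300L))
  # shock spans the whole CS during conditioning
  cd <- tr[tr$phase == "conditioning", ]
  expect_true(all(sch$steps$u[cd$start[1]:cd$end[1]] == 1))
  # no pre-exposure arm drops the phase
  set.seed(7)
  sch2 <- build_protocol("latent_inhibition", cfg, preexposed = FALSE)
  expect_equal(sum(sch2$trials$phase == "pre_exposure"), 0L)
  # drug arms schedule the 20% bypass in the right phase only
  set.seed(7)
  schc <- build_protocol("latent_inhibition", cfg,
                         drug_phase = "conditioning")
  dphase <- tapply(schc$steps$d, schc$steps$phase, max)
  expect_equal(unname(dphase["conditioning"]), 0.2)
  expect_equal(unname(dphase["test"]), 0)
  set.seed(7)
  scht <- build_protocol("latent_inhibition", cfg, drug_phase = "testing")
  dphase <- tapply(scht$steps$d, scht$steps$phase, max)
  expect_equal(unname(dphase["test"]), 0.2)
  expect_equal(unname(dphase["conditioning"]), 0)
})

test_that("fear-expression audit: pulses, pairings and manipulations", {
  cfg <- sim_config(seed = 8)
  set.seed(8)
  sch <- build_protocol("fear_expression", cfg, manipulation = "disruption")
  tr <- sch$trials
  expect_equal(sum(tr$phase == "conditioning"), 12L)
  expect_equal(sum(tr$phase == "extinction"), 12L)
  # baseline pulses: 250 ms of disruption separated by 860 ms
  base <- tr[tr$phase == "baseline", ]
  expect_true(all(diff(base$start) * cfg$dt - 1.11 < 0.05))
  d <- sch$steps$d
  expect_true(all(d[base$start[1]:base$end[1]] == 0.2))
  expect_true(all(d[(base$end[1] + 2):(base$start[2] - 2)] == 0))
  # disruption also covers the test CS
  te <- tr[tr$phase == "test", ]
  expect_true(all(d[te$start[1]:te$end[1]] == 0.2))
  # excitation arm scales W_IE by 1.1 at test and skips extinction
  set.seed(8)
  sch2 <- build_protocol("fear_expression", cfg, manipulation = "excitation")
  expect_equal(sum(sch2$trials$phase == "extinction"), 0L)
  te2 <- sch2$trials[sch2$trials$phase == "test", ]
  expect_true(all(sch2$steps$wie_scale[te2$start[1]:te2$end[1]] == 1.1))
  expect_true(all(sch2$steps$d == 0))
})

test_that("categorization audit: fixed order, epochs, reward flags", {
  cfg <- sim_config(seed = 9)
  set.seed(9)
  sch <- build_protocol("categorization", cfg)
  tr <- sch$trials
  expect_equal(nrow(tr), 500L)               # 50 epochs x 10 stimuli
  expect_equal(unique(tr$end - tr$start + 1L), 10L)   # 200 ms each
  expect_equal(tr$stimulus, rep(1:10, 50))   # fixed order
  expect_equal(sch$n_steps * cfg$dt, 160)    # 60 s adaptation + 100 s
  # u = 1 exactly during the rewarded stimulus
  r1 <- tr[tr$stimulus == 1, ]
  expect_true(all(sch$steps$u[r1$start[1]:r1$end[1]] == 1))
  expect_equal(sum(sch$steps$u), 50 * 10)
  # S4 variant: three rewarded stimuli
  set.seed(9)
  sch3 <- build_protocol("categorization", cfg, n_rewarded = 3L)
  expect_equal(sum(sch3$steps$u), 3 * 50 * 10)
})

test_that("learned-irrelevance audit: uncorrelated then paired phases", {
  cfg <- sim_config(seed = 10)
  set.seed(10)
  sch <- build_protocol("learned_irrelevance", cfg)
  tr <- sch$trials
  expect_equal(sum(tr$phase == "uncorrelated"), 100L)
  expect_equal(sum(tr$phase == "paired"), 100L)
  # paired phase: regular 5 s intervals, CS precedes US by 100 ms
  pa <- tr[tr$phase == "paired", ]
  expect_true(all(abs(diff(pa$start) * cfg$dt - 5) < 1e-9))
  u <- sch$steps$u
  expect_true(all(u[pa$start + 5L] == 1))
  expect_true(all(u[pa$start] == 0))
  set.seed(10)
  sch2 <- build_protocol("learned_irrelevance", cfg, arm = "paired_only")
  expect_equal(sum(sch2$trials$phase == "uncorrelated"), 0L)
})

test_that("runs are deterministic given seed and abort cleanly on NaN", {
  cfg <- scaled_config(seed = 2L)
  set.seed(2)
  sch <- build_protocol("learning_to_ignore", cfg, n_presentations = 2L,
                        iti = c(2, 3), adapt_dur = 4)
  t1 <- run_protocol(sch, cfg, seed = 11)
  t2 <- run_protocol(sch, cfg, seed = 11)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$trials, t2$trials)
  expect_identical(t1$final_state, t2$final_state)
  t3 <- run_protocol(sch, cfg, seed = 12)
  expect_false(identical(t1$steps$S, t3$steps$S))
})

test_that("an empty schedule yields an empty trace", {
  cfg <- sim_config()
  sc <- inhibrel:::new_sched(0L, cfg$dt)
  sch <- inhibrel:::finish_sched(sc, "learning_to_ignore", 1L)
  tr <- run_protocol(sch, cfg, seed = 1)
  expect_equal(nrow(tr$trials), 0L)
  expect_equal(nrow(tr$steps), 0L)
})

test_that("schedules export as auditable CSV", {
  cfg <- sim_config(seed = 30L)
  set.seed(30)
  sch <- build_protocol("categorization", cfg, n_epochs = 2L,
                        adapt_dur = 1)
  f <- tempfile(fileext = ".csv")
  export_schedule(sch, f)
  df <- read.csv(f)
  expect_equal(nrow(df), sch$n_steps)
  expect_equal(df$u, sch$steps$u)
  expect_true(all(c("step", "time_s", "active", "d", "phase") %in%
                    names(df)))
  unlink(f)
})
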