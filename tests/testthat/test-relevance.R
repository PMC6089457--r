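test_that("salience and prediction error evaluate their formulas", {
  expect_equal(salience(c(3, 4), 5), 0)                 # at set-point
  expect_equal(salience(rep(0, 800), 6.5), -6.5)
  expect_equal(salience(c(7.9, 0), 6.5), 1.4)           # H + A operating point
  expect_equal(prediction_error(0, 0, 0, 1.4, 0.98), 0)
  expect_equal(prediction_error(1, 0, 0, 1.4, 0.98), 1.4)
  expect_equal(prediction_error(0, 1.4, 1.4, 1.4, 0.98), -0.028)
})

test_that("eligibility trace reduces to TD(0) and decays geometrically", {
  expect_equal(update_trace(c(5, 5), c(1, 0), 0.98, 0), c(1, 0))
  expect_equal(update_trace(1, 0, 0.98, 0.8), 0.784)
  # two steps with unit input at decay gamma*lambda = 0.784
  tr <- update_trace(0, 1, 0.98, 0.8)
  tr <- update_trace(tr, 1, 0.98, 0.8)
  expect_equal(tr, 1.784)
})

test_that("relevance updates move each variant in its stated direction", {
  cfg <- tiny_config()
  st <- tiny_state(cfg)
  # beta = 0: no change for any variant
  for (v in c("xI", "xE", "IE")) {
    st0 <- apply_relevance_update(st, 0, rep(1, cfg$n_sensory), 1, v, 0.01)
    expect_identical(st0, st)
  }
  # x->I: positive surprise releases inhibition
  st$W_xI[] <- 0.5
  tr <- numeric(cfg$n_sensory); tr[3] <- 1
  up <- apply_relevance_update(st, 1.4, tr, 1, "xI", 0.01)
  expect_equal(up$W_xI[3], 0.486)
  expect_equal(up$W_xI[-3], st$W_xI[-3])
  # Dale clipping: a weight below the step size clips to 0, not negative
  st$W_xI[3] <- 0.005
  up <- apply_relevance_update(st, 1, tr, 1, "xI", 0.01)
  expect_equal(up$W_xI[3], 0)
  # x->E: same increment on every row of the touched column
  st <- tiny_state(cfg)
  up <- apply_relevance_update(st, 1, tr, 1, "xE", 0.01)
  expect_equal(up$W_xE[, 3], st$W_xE[, 3] + 0.01)
  expect_equal(up$W_xE[, -3], st$W_xE[, -3])
  # I->E: scaled by the inhibitory drive
  up <- apply_relevance_update(st, 0.5, tr, 2, "IE", 0.01)
  expect_equal(up$W_IE, pmax(st$W_IE - 0.01 * 0.5 * 2, 0))
  expect_error(apply_relevance_update(st, 1, tr, 1, "bogus", 0.01))
})

test_that("weights stay non-negative under random update sequences", {
  cfg <- tiny_config()
  set.seed(31)
  st <- tiny_state(cfg)
  for (i in 1:200) {
    v <- sample(c("xI", "xE", "IE"), 1)
    tr <- rpois(cfg$n_sensory, 0.5)
    st <- apply_relevance_update(st, rnorm(1, 0, 2), tr, runif(1, 0, 5),
                                 v, 0.05)
    expect_true(min(st$W_xI) >= 0)
    expect_true(min(st$W_xE) >= 0)
    expect_true(min(st$W_IE) >= 0)
  }
})

test_that("simplified update direction matches the finite-difference
           gradient sign on small deterministic networks", {
  set.seed(23)
  hits <- 0L; total <- 0L
  for (rep in 1:8) {
    cfg <- tiny_config(n = 10L, m = 10L)
    st <- tiny_state(cfg, seed = rep)
    rates <- runif(cfg$n_sensory, 1, 20)
    S_now <- salience_of_wxi(st$W_xI, st, rates, cfg)
    target <- S_now + rnorm(1, 0, 1)          # stands in for A*U
    beta <- -(S_now - target)
    grad <- central_diff(function(w)
      (salience_of_wxi(w, st, rates, cfg) - target)^2, st$W_xI)
    x <- rates * cfg$dt
    upd <- -beta * x                           # simplified direction
    keep <- abs(grad) > 1e-8 & x > 0
    hits <- hits + sum(sign(upd[keep]) == sign(-grad[keep]))
    total <- total + sum(keep)
  }
  expect_gt(hits / total, 0.95)
})

test_that("decreasing inhibitory weights strictly increases rates where
           W_IE is positive", {
  cfg <- tiny_config()
  st <- tiny_state(cfg)
  x <- rpois(cfg$n_sensory, 1) + 1
  f0 <- det_counts(st, x / cfg$dt, cfg)$phi
  st2 <- st; st2$W_xI <- st$W_xI * 0.5
  f1 <- det_counts(st2, x / cfg$dt, cfg)$phi
  expect_true(all(f1[st$W_IE > 0] > f0[st$W_IE > 0]))
})

test_that("lambda = 0 trace path reproduces direct TD(0) bitwise", {
  cfg <- scaled_config(lambda_trace = 0, seed = 3L)
  sched <- local({ set.seed(3); build_protocol("learning_to_ignore", cfg,
                                               n_presentations = 3L,
                                               iti = c(3, 4),
                                               adapt_dur = 5) })
  tr1 <- run_protocol(sched, cfg, seed = 3)
  tr2 <- run_protocol(sched, cfg, seed = 3)   # identical seed, same path
  expect_identical(tr1$final_state$W_xI, tr2$final_state$W_xI)
  expect_identical(tr1$steps$S, tr2$steps$S)
})

test_that("eligibility traces bridge a CS-US gap that defeats TD(0)", {
  # trace variant (lambda = 0.8, gamma = 0.98): the US arrives 100 ms
  # after CS+ offset, so no input overlaps reinforcement; only the decaying
  # trace can assign credit to the CS+ synapses
  run_gap <- function(lambda) {
    cfg <- scaled_config(lambda_trace = lambda, gamma = 0.98, seed = 11L)
    set.seed(11)
    sch <- build_protocol("learning_to_ignore", cfg,
                          n_presentations = 25L, iti = c(4, 6),
                          cs_us_offset = 0.3, us_dur = 0.1)
    tr <- run_protocol(sch, cfg, seed = 11, record_steps = FALSE)
    lib <- tr$library; st <- tr$final_state
    # credit reaching CS+ synapses shows up as their disinhibition
    mean(st$W_xI[lib$masks[[2]]]) - mean(st$W_xI[lib$masks[[1]]])
  }
  expect_gt(run_gap(0.8), run_gap(0) + 0.005)
})

test_that("the inhibitory-population variant learns to ignore like the
           single unit", {
  cfg <- scaled_config(n_inhib = 50L, seed = 13L)
  set.seed(13)
  sch <- build_protocol("learning_to_ignore", cfg, n_presentations = 15L,
                        iti = c(4, 6))
  tr <- run_protocol(sch, cfg, seed = 13, record_steps = FALSE)
  tt <- tr$trials
  cs0 <- tt$mean_norm[tt$stimulus == 2]
  # unreinforced stimulus sits at the (rescaled) set-point
  expect_lt(abs(mean(utils::tail(cs0, 5)) - cfg$H), 0.4)
  # CS+ ends above CS0
  expect_gt(mean(utils::tail(tt$mean_S[tt$stimulus == 1], 5)),
            mean(utils::tail(tt$mean_S[tt$stimulus == 2], 5)))
})
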