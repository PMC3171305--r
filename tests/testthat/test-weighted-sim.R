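test_that("step bias reproduces the hand-computed probabilities", {
  fx <- fixture_system("prod_deg")
  # identity multipliers give the natural PMF with unit weight factors
  sb <- step_bias(gamma_scheme(c(1, 1)), fx$system)
  expect_equal(sb$q, sb$p)
  expect_equal(sb$weight_factor, c(1, 1))
  # gamma = (1.2, 1/1.2) at x0 where a1 = a2 = 1
  sb <- step_bias(gamma_scheme(c(1.2, 1 / 1.2)), fx$system)
  expect_equal(sb$q[1], 1.44 / 2.44, tolerance = 1e-12)
  expect_equal(sum(sb$q), 1)
})

test_that("group targets are honored at every sampled state", {
  fx <- fixture_event("convert_decay", theta = 65)
  part <- partition_reactions(fx$system, fx$event)
  targets <- c(0.3, 0.15, 0.55)
  sch <- group_scheme(part, targets)
  tr <- simulate_trajectory(fx$system, fx$event, "wssa", scheme = sch,
                            log = TRUE, seed = 41)
  expect_gt(nrow(tr$q), 20)
  for (k in 1:3) {
    sums <- rowSums(tr$q[, part$group_id == k, drop = FALSE])
    expect_true(all(abs(sums - targets[k]) < 1e-10))
  }
  expect_true(all(abs(rowSums(tr$q) - 1) < 1e-10))
  # per_reaction_q agrees with the logged engine probabilities
  q0 <- per_reaction_q(fx$system, fx$system$x0, part$group_id, targets)
  expect_equal(q0, tr$q[1, ], tolerance = 1e-12)
})

test_that("dead groups redistribute their mass in proportion to the targets", {
  fx <- fixture_event("futile_cycle", theta = 40)
  part <- partition_reactions(fx$system, fx$event)
  targets <- c(0.05, 0.02, 0.93)
  # state 01 (X3 = 0, X6 = 1): the G2 reaction R3 is silent
  x <- c(1, 50, 0, 0, 49, 1)
  q <- per_reaction_q(fx$system, x, part$group_id, targets)
  expect_equal(sum(q), 1)
  expect_equal(q[3], 0)  # R3 has zero propensity
  g1 <- sum(q[part$group_id == 1])
  g3 <- sum(q[part$group_id == 3])
  expect_equal(g1, 0.05 + 0.02 * 0.05 / 0.98, tolerance = 1e-12)
  expect_equal(g3, 0.93 + 0.02 * 0.93 / 0.98, tolerance = 1e-12)
  # sanity on random systems: q sums to one wherever a0 > 0
  for (seed in 1:10) {
    sys <- random_system(seed, N = 3, M = 4)
    a <- propensities(sys, sys$x0)
    if (sum(a) == 0) next
    grp <- rep_len(1:2, length(a))
    q <- per_reaction_q(sys, sys$x0, grp, c(0.7, 0.3))
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_true(all(q[a > 0] > 0))
  }
})

test_that("absolute continuity violations are refused", {
  fx <- fixture_event("convert_decay", theta = 65)
  part <- partition_reactions(fx$system, fx$event)
  sch <- group_scheme(part, c(1, 0, 0))  # G2/G3 have positive propensity
  expect_error(step_bias(sch, fx$system), "absolute continuity")
  expect_error(estimate(fx$system, fx$event, "wssa", sch, n = 10, seed = 1),
               "absolute continuity")
})

test_that("weighted methods with the natural scheme degenerate to the exact ones", {
  fx <- fixture_event("prod_deg", theta = 55)
  a <- simulate_trajectory(fx$system, fx$event, "ssa", log = TRUE, seed = 7)
  b <- simulate_trajectory(fx$system, fx$event, "wssa",
                           scheme = gamma_scheme(c(1, 1)), log = TRUE, seed = 7)
  expect_identical(a$time, b$time)
  expect_identical(a$mu, b$mu)
  expect_equal(b$w, 1)
  cn <- simulate_trajectory(fx$system, fx$event, "nrm", log = TRUE, seed = 7)
  d <- simulate_trajectory(fx$system, fx$event, "wnrm",
                           scheme = natural_scheme(), log = TRUE, seed = 7)
  expect_identical(cn$time, d$time)
  expect_identical(cn$mu, d$mu)
  expect_equal(d$w, 1)
})

test_that("estimator accumulators satisfy their contracts", {
  fx <- fixture_event("prod_deg", theta = 65)
  # single missing run: everything zero
  e <- estimate(fx$system, fx$event, "ssa", n = 1, seed = 1)
  expect_equal(e$p_hat, 0)
  expect_equal(e$var, 0)
  # unweighted estimator: p_hat = hits/n, var = p(1 - p)
  e <- estimate(fx$system, fx$event, "ssa", n = 5000, seed = 2)
  expect_equal(e$p_hat, e$hits / e$n)
  expect_equal(e$var, e$p_hat * (1 - e$p_hat), tolerance = 1e-12)
  # determinism: same (method, scheme, seed, n) - same result
  sel <- select_scheme(fx$system, fx$event, seed = 3)
  e1 <- estimate(fx$system, fx$event, "wssa", sel$scheme, n = 3000, seed = 4)
  e2 <- estimate(fx$system, fx$event, "wssa", sel$scheme, n = 3000, seed = 4)
  expect_identical(e1$k1, e2$k1)
  expect_identical(e1$k2, e2$k2)
  expect_gte(e1$var, 0)
})

test_that("weighted estimates match the analytic first-passage law on a toy", {
  sys <- birth_toy(c = 0.02)
  ev <- rare_event(sys, "B", theta = 1, horizon = 50)
  p_true <- 1 - exp(-0.02 * 50)
  for (method in c("wssa", "wnrm")) {
    e <- estimate(sys, ev, method, gamma_scheme(2), n = 2e4, seed = 51)
    expect_lt(abs(e$p_hat - p_true), 3.5 * e$u68)
  }
})

test_that("weighted estimators stay unbiased against the CTMC oracle", {
  cases <- list(
    list(fx = fixture_event("prod_deg", theta = 65), n = 2e4, bounds = NULL),
    list(fx = fixture_event("convert_decay", theta = 65), n = 2e4,
         bounds = c(S1 = 150, S2 = 150)),
    list(fx = fixture_event("futile_cycle", theta = 40), n = 2e4,
         bounds = NULL))
  for (cs in cases) {
    fx <- cs$fx
    p <- first_passage_prob(build_ctmc(fx$system, fx$event, bounds = cs$bounds),
                            fx$event$horizon)$p
    sel <- select_scheme(fx$system, fx$event, seed = 61)
    for (method in c("wssa", "wnrm")) {
      e <- estimate(fx$system, fx$event, method, sel$scheme, n = cs$n,
                    seed = 62)
      expect_lt(abs(e$p_hat - p), 3.5 * e$u68,
                label = paste(fx$system$name, method, "p_hat"))
    }
    # unbiasedness survives a deliberately perturbed (suboptimal) scheme
    if (sel$scheme$variant == "group") {
      tg <- sel$scheme$targets
      tg <- (tg + 0.2) / sum(tg + 0.2)
      pert <- group_scheme(sel$scheme$groups, tg)
    } else {
      pert <- scaled_scheme(pmax(sel$scheme$lambda * 1.3, 0.1),
                            sel$scheme$slack)
    }
    e <- estimate(fx$system, fx$event, "wssa", pert, n = cs$n, seed = 63)
    expect_lt(abs(e$p_hat - p), 3.5 * e$u68,
              label = paste(fx$system$name, "perturbed"))
  }
})

test_that("biasing leaves the inter-event time law unchanged", {
  fx <- fixture_event("convert_decay", theta = 1e6)
  sel_part <- partition_reactions(fx$system,
                                  rare_event(fx$system, "S2", theta = 65,
                                             horizon = 10))
  sch <- group_scheme(sel_part, c(0.3, 0.1, 0.6))
  set.seed(71)
  gaps_std <- numeric(0)
  for (i in 1:20) {
    tr <- simulate_trajectory(fx$system, fx$event, "wssa", scheme = sch,
                              absorb = FALSE, log = TRUE)
    gaps_std <- c(gaps_std, diff(c(0, tr$time)) * tr$a0)
  }
  ks <- ks.test(gaps_std, "pexp", rate = 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("wSSA and wNRM agree in estimate and variance under one scheme", {
  fx <- fixture_event("convert_decay", theta = 65)
  sel <- select_scheme(fx$system, fx$event, seed = 81)
  e1 <- estimate(fx$system, fx$event, "wssa", sel$scheme, n = 5e4, seed = 82)
  e2 <- estimate(fx$system, fx$event, "wnrm", sel$scheme, n = 5e4, seed = 83)
  expect_lt(abs(e1$p_hat - e2$p_hat),
            3.5 * sqrt(e1$u68^2 + e2$u68^2))
  expect_lt(abs(log(e1$var / e2$var)), log(4))
})

test_that("long heavily-biased trajectories keep finite weights (log-space)", {
  fx <- fixture_event("futile_cycle", theta = 25)
  sch <- scaled_scheme(c(1, 1, 0.05, 1, 1, 8), slack = c(TRUE, TRUE, FALSE,
                                                         TRUE, TRUE, FALSE))
  e <- estimate(fx$system, fx$event, "wssa", sch, n = 2000, seed = 91)
  expect_true(is.finite(e$k1) && is.finite(e$k2))
  expect_gte(e$var, 0)
})
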