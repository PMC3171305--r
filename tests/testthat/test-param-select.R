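test_that("reaction partitions match the known benchmark groupings", {
  pd <- fixture_event("prod_deg", theta = 65)
  expect_equal(partition_reactions(pd$system, pd$event)$group_id, c(1L, 2L))

  cd <- fixture_event("convert_decay", theta = 65)
  expect_equal(partition_reactions(cd$system, cd$event)$group_id,
               c(1L, 2L, 3L, 3L))

  # downward event on S5: the committed catalytic steps R6 (toward) and R3
  # (away) survive; binding/release shuttles land in G3 via pool lumping
  fc <- fixture_event("futile_cycle", theta = 40)
  part <- partition_reactions(fc$system, fc$event)
  expect_equal(part$group_id, c(3L, 3L, 2L, 3L, 3L, 1L))
  expect_equal(which(part$lump == 1), c(5, 6))  # S5 plus its complex S6

  # the mirrored event formulation on S2 gives the same grouping
  ev2 <- rare_event(fc$system, "S2", theta = 60, horizon = 100)
  expect_equal(partition_reactions(fc$system, ev2)$group_id,
               c(3L, 3L, 2L, 3L, 3L, 1L))

  # overrides win
  part_ov <- partition_reactions(cd$system, cd$event, overrides = c(R3 = 1))
  expect_equal(part_ov$group_id[3], 1L)
  expect_equal(part_ov$provenance[3], "override")

  # no reaction toward the threshold: infeasible
  sys <- reaction_system("A", 5, list(reaction(c(A = 1), NULL, rate = 1)))
  ev <- rare_event(sys, "A", theta = 10, horizon = 1)
  expect_error(partition_reactions(sys, ev), "infeasible")
})

test_that("self-silencing directional reactions are demoted in flat systems", {
  # B <-> C on a single molecule: each firing silences the reaction itself
  sys <- reaction_system(c("B", "C", "A"), c(1, 0, 5),
                         list(reaction(c(B = 1), c(C = 1), rate = 1),
                              reaction(c(C = 1), c(B = 1), rate = 1),
                              reaction(NULL, c(A = 1), rate = 1),
                              reaction(c(A = 1), NULL, rate = 0.2)))
  ev <- rare_event(sys, "A", theta = 15, horizon = 10)
  part <- partition_reactions(sys, ev)
  expect_equal(part$group_id, c(3L, 3L, 1L, 2L))
})

test_that("neutral-group subpartition matches the perturbation oracle", {
  cd <- fixture_event("convert_decay", theta = 65)
  part <- partition_reactions(cd$system, cd$event)
  sub <- subpartition_g3(cd$system, part)
  expect_equal(sub, c(NA, NA, 1L, 2L))  # R3 helps (feeds S1), R4 hinders

  # a G3 reaction touching no G1/G2 reactant goes to G33
  sys <- reaction_system(c("A", "B", "C"), c(10, 0, 5),
                         list(reaction(c(A = 1), c(B = 1), rate = 1),
                              reaction(c(B = 1), NULL, rate = 1),
                              reaction(c(C = 1), c(C = 1), rate = 1)))
  ev <- rare_event(sys, "B", theta = 5, horizon = 10)
  part2 <- partition_reactions(sys, ev)
  expect_equal(subpartition_g3(sys, part2)[3], 3L)

  # brute force on random systems: fire each G3 reaction and compare the
  # direction of the G1/G2 propensity-sum change
  for (seed in 1:12) {
    sys <- random_system(seed, N = 4, M = 5, max_x0 = 20)
    ev <- tryCatch(rare_event(sys, 1, offset = 3, horizon = 1),
                   error = function(e) NULL)
    part <- tryCatch(partition_reactions(sys, ev), error = function(e) NULL)
    if (is.null(part)) next
    sub <- subpartition_g3(sys, part)
    g <- part$group_id
    for (m in which(g == 3L)) {
      x <- sys$x0 + sys$reactant_stoich[m, ] * 2L
      y <- x + sys$nu[m, ]
      if (any(y < 0)) next
      d1 <- sum(propensities(sys, y)[g == 1L]) -
        sum(propensities(sys, x)[g == 1L])
      d2 <- sum(propensities(sys, y)[g == 2L]) -
        sum(propensities(sys, x)[g == 2L])
      if (sub[m] == 1L) expect_true(d1 >= 0 && d2 <= 0)
      if (sub[m] == 2L) expect_true(d1 <= 0 && d2 >= 0)
    }
  }
})

test_that("dimer subpartition keys on the effective target step", {
  sys <- dimer_toy()
  ev <- rare_event(sys, "B", theta = 30, horizon = 10)
  part <- partition_reactions(sys, ev)
  expect_equal(part$group_id, c(1L, 2L))
  sub <- subpartition_dimer(sys, part)
  expect_equal(sub, c(12L, 21L))  # 0 -> 2B is a double step toward

  # unit-step system: no 12/22 subgroups, selection uses the plain path
  pd <- fixture_event("prod_deg", theta = 65)
  subu <- subpartition_dimer(pd$system, partition_reactions(pd$system, pd$event))
  expect_equal(subu, c(11L, 21L))
})

test_that("the event count sits at the top of its admissible band", {
  expect_equal(choose_event_count(200.7, 25), 200L)
  expect_equal(choose_event_count(25, 25), 25L)      # bounds collapse
  expect_equal(choose_event_count(300, -25, K_E = 150), 150L)
  expect_error(choose_event_count(20, 25), "infeasible")
  expect_error(choose_event_count(300, 25, K_E = 10), "eta")
  # prod_deg: 25 <= K_E <= 200 at equilibrium flow 200
  pd <- fixture_event("prod_deg", theta = 65)
  ps <- suppressWarnings(
    pilot_statistics(pd$system, pd$event, n_pilot = 500, seed = 3))
  KE <- choose_event_count(ps, 25)
  expect_gte(KE, 25)
  expect_lte(KE, ps$mean_KT)
})

test_that("two-group closed form equals the brute-force maximizer", {
  expect_equal(unname(two_group_Q(200, 25)), c(0.5625, 0.4375))
  expect_equal(unname(two_group_Q(100, 100)), c(1, 0))   # all steps toward
  expect_equal(unname(two_group_Q(1e7, 1)[1]), 0.5, tolerance = 1e-6)
  for (case in list(c(200, 25), c(432, 10), c(50, 13))) {
    q1 <- two_group_Q(case[1], case[2])[[1]]
    expect_equal(q1, brute_two_group_Q1(case[1], case[2]), tolerance = 1e-4)
  }
  # sign of eta is irrelevant
  expect_equal(two_group_Q(200, -25), two_group_Q(200, 25))
})

test_that("dimer-aware two-group probabilities reduce and maximize correctly", {
  # no double steps: identical to the plain closed form
  expect_equal(dimer_two_group_Q(200, 25, N11 = 50, N12 = 0, N21 = 40, N22 = 0),
               two_group_Q(200, 25), ignore_attr = TRUE)
  # dimer toy 0 -> 2B, B -> 0: effective steps e1 = 2, e2 = 1
  KE <- 60; eta <- 4
  qd <- dimer_two_group_Q(KE, eta, N11 = 0, N12 = 30, N21 = 55, N22 = 0)
  # brute-force: maximize the binomial term with K1 = (eta + e2*K2)/e1
  grid <- seq(1e-4, 1 - 1e-4, 1e-4)
  K1 <- (eta + 1 * KE) / (2 + 1)
  K2 <- KE - K1
  obj <- K1 * log(grid) + K2 * log(1 - grid)
  expect_equal(qd[[1]], grid[which.max(obj)], tolerance = 1e-3)
})

test_that("ratio-walk kappa search equals the exhaustive argmax", {
  expect_equal(find_kappa(200, 25, c(0.2, 0.2, 0.6))$kappa, 28L)
  expect_equal(find_kappa(40, 40, c(0.3, 0.3, 0.4))$kappa, 0L)  # single term
  set.seed(5)
  for (i in 1:30) {
    KE <- sample(10:500, 1)
    eta <- sample(1:min(KE, 60), 1)
    Q <- runif(3, 0.05, 1)
    Q <- Q / sum(Q)
    expect_equal(find_kappa(KE, eta, Q)$kappa, brute_kappa(KE, eta, Q),
                 label = sprintf("KE=%d eta=%d", KE, eta))
  }
})

test_that("three-group probabilities maximize the dominant multinomial term", {
  expect_equal(unname(three_group_Q(0, 40, 40)), c(1, 0, 0))  # boundary
  for (case in list(list(29, 25, 200), list(6, 10, 432), list(3, 25, 432))) {
    q <- three_group_Q(case[[1]], case[[2]], case[[3]])
    expect_equal(sum(q), 1)
    # simplex grid oracle on the term with fixed exponents
    k1 <- case[[1]] + case[[2]]; k2 <- case[[1]]
    k3 <- case[[3]] - 2 * case[[1]] - case[[2]]
    gr <- seq(0.002, 0.998, 0.002)
    obj <- function(q1, q2) k1 * log(q1) + k2 * log(q2) +
      k3 * log(1 - q1 - q2)
    bestv <- -Inf
    for (q1 in gr) for (q2 in gr[gr < 1 - q1])
      bestv <- max(bestv, obj(q1, q2))
    # the closed form attains at least the best value seen on the grid
    expect_gte(obj(q[[1]], q[[2]]), bestv - 1e-9)
  }
})

test_that("fine-tuning shifts mass toward helping reactions and conserves it", {
  Q3 <- 0.6
  ft <- fine_tune_g3(Q3, 8, 4, 0, alpha = 0.85, beta = 0.80)
  expect_equal(sum(ft), Q3)
  expect_true(attr(ft, "applied"))
  expect_gt(ft[["Q31"]], Q3 * 8 / 12)   # above the natural share
  expect_lt(ft[["Q32"]], Q3 * 4 / 12)   # below the natural share
  # with a G33 share present
  ft2 <- fine_tune_g3(Q3, 5, 3, 2, alpha = 0.85, beta = 0.80)
  expect_equal(sum(ft2), Q3)
  expect_gt(ft2[["Q31"]], Q3 * 0.5)
  expect_lt(ft2[["Q32"]], Q3 * 0.3)
  expect_lt(ft2[["Q33"]], Q3 * 0.2)
  # inadmissible constants
  expect_error(fine_tune_g3(Q3, 8, 4, 0, alpha = 1.2, beta = 0.8), "inadmissible")
  expect_error(fine_tune_g3(Q3, 8, 4, 0, alpha = 0.8, beta = 1), "inadmissible")
  # nothing to shift: pass-through with a notice
  expect_message(ft3 <- fine_tune_g3(Q3, 8, 0, 0), "not applicable")
  expect_equal(as.numeric(ft3), c(Q3, 0, 0), ignore_attr = TRUE)
})

test_that("fine-tuned estimates are insensitive to the exact constants", {
  cd <- fixture_event("convert_decay", theta = 65)
  s1 <- select_scheme(cd$system, cd$event, seed = 7, fine_tune = TRUE,
                      alpha = 0.85, beta = 0.80)
  s2 <- select_scheme(cd$system, cd$event, seed = 7, fine_tune = TRUE,
                      alpha = 0.80, beta = 0.75)
  e1 <- estimate(cd$system, cd$event, "wssa", s1$scheme, n = 1e5, seed = 8)
  e2 <- estimate(cd$system, cd$event, "wssa", s2$scheme, n = 1e5, seed = 8)
  expect_lt(abs(log(e1$var / e2$var)), log(2))
  expect_lt(abs(e1$p_hat - e2$p_hat), 3.5 * sqrt(e1$u68^2 + e2$u68^2))
})

test_that("selection is deterministic and its report is complete", {
  pd <- fixture_event("prod_deg", theta = 65)
  s1 <- select_scheme(pd$system, pd$event, seed = 9)
  s2 <- select_scheme(pd$system, pd$event, seed = 9)
  expect_equal(s1$report$K_E, s2$report$K_E)
  expect_identical(s1$scheme, s2$scheme)
  expect_equal(unname(s1$report$Q_star[1]),
               (s1$report$K_E + 25) / (2 * s1$report$K_E))
  # the three-group path reports kappa
  cd <- fixture_event("convert_decay", theta = 65)
  s3 <- select_scheme(cd$system, cd$event, seed = 10)
  expect_false(is.na(s3$report$kappa))
  expect_equal(s3$report$variant, "group")
  # the futile cycle selects the state-conditional scaled scheme
  fc <- fixture_event("futile_cycle", theta = 40)
  s4 <- select_scheme(fc$system, fc$event, seed = 11)
  expect_equal(s4$report$variant, "scaled")
  expect_equal(s4$scheme$variant, "scaled")
  expect_gt(s4$scheme$lambda[6], 1)  # R6 biased up for a downward event
  expect_lt(s4$scheme$lambda[3], 1)  # R3 biased down
})

test_that("dimer systems remain unbiased end to end", {
  sys <- dimer_toy(c1 = 2, c2 = 0.1)
  ev <- rare_event(sys, "B", theta = 44, horizon = 10)
  p <- first_passage_prob(build_ctmc(sys, ev, bounds = c(B = 80)), 10)$p
  sel <- select_scheme(sys, ev, seed = 12)
  e <- estimate(sys, ev, "wssa", sel$scheme, n = 2e4, seed = 13)
  expect_lt(abs(e$p_hat - p), 3.5 * e$u68)
})
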