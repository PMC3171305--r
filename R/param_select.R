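#' Partition reactions by their effect on the rare event
#'
#' Reactions are divided into three groups: `G1` moves the target species
#' toward the threshold, `G2` moves it away, `G3` leaves it unchanged.
#' The base rule keys on the sign of `nu_im * eta` for the target species
#' `i`.  Two refinements deal with systems containing binary (0/1-valued)
#' species such as enzyme/complex pairs:
#'
#' 1. *Conserved-pool lumping.*  When a unit of the target species can be
#'    temporarily sequestered into a binary complex (some reaction
#'    consumes the target and produces the complex one-for-one, with the
#'    complex detected as binary from pairwise conservation laws), the
#'    partition is computed on the lumped coordinate
#'    `Y = X_i + sum(complexes)`.  Shuttling reactions that merely bind or
#'    release the target then land in `G3`, and only the reactions that
#'    irreversibly move mass toward or away from the threshold remain in
#'    `G1`/`G2`.  For the enzymatic futile cycle this yields
#'    `G1 = {R6}`, `G2 = {R3}` for downward events on `S5`.
#' 2. *Self-silencing demotion.*  When no pool structure is detected, a
#'    `G1`/`G2` reaction whose own firing always zeroes one of its
#'    (binary) reactant counts cannot fire twice in a row; biasing it is
#'    ineffective and it is demoted to `G3`.  With an active pool the
#'    surviving directional reactions are the committed catalytic steps
#'    and are kept even if transiently self-silencing.
#'
#' Explicit `overrides` win over both rules.
#'
#' @param system a [reaction_system()].
#' @param event a [rare_event()].
#' @param overrides optional integer vector: either full length `M` with
#'   `NA` for "no override", or named like `c(R3 = 2)` mapping reaction
#'   indices to group labels 1, 2, 3.
#' @return A `group_partition`: `group_id` (1/2/3 per reaction),
#'   `provenance` (how each label was assigned), `nu_eff` (effective
#'   state change of the lumped target coordinate), `lump` (0/1 vector of
#'   lumped species), `binary` (detected binary species).
#' @examples
#' fx <- fixture_system("convert_decay")
#' ev <- rare_event(fx$system, "S2", theta = 65, horizon = 10)
#' partition_reactions(fx$system, ev)$group_id  # 1, 2, 3, 3
#' @export
partition_reactions <- function(system, event, overrides = NULL) {
  stopifnot(inherits(system, "reaction_system"), inherits(event, "rare_event"))
  nu <- system$nu
  M <- nrow(nu)
  ub <- species_upper_bounds(system)
  binary <- ub <= 1

  # conserved-pool lumping: target plus binary complexes it sequesters into
  u <- numeric(ncol(nu))
  u[event$target] <- 1
  for (b in which(binary)) {
    if (b == event$target) next
    if (any(nu[, event$target] < 0 & nu[, b] > 0)) u[b] <- 1
  }
  nu_eff <- as.numeric(nu %*% u)

  g <- ifelse(nu_eff * event$eta > 0, 1L, ifelse(nu_eff * event$eta < 0, 2L, 3L))
  prov <- ifelse(g == 3L, "general", "general")
  prov[g != 3L & nu_eff != nu[, event$target]] <- "lumped"

  # Demotion: a directional reaction whose own firing always zeroes one of
  # its reactant counts (binary reactant) cannot fire twice in a row, so
  # biasing it is ineffective.  When the pool lumping is active the
  # remaining G1/G2 reactions are committed catalytic steps whose transient
  # self-silencing is part of the enzyme cycle (demoting them would empty
  # the directional groups), so the rule applies only with a trivial pool.
  if (sum(u) == 1) {
    for (m in which(g != 3L)) {
      consumed <- system$reactant_stoich[m, ] > 0L & nu[m, ] < 0L
      if (any(consumed & binary)) {
        g[m] <- 3L
        prov[m] <- "refinement"
      }
    }
  }

  if (!is.null(overrides)) {
    ov <- rep(NA_integer_, M)
    if (!is.null(names(overrides))) {
      idx <- as.integer(sub("^R", "", names(overrides)))
      ov[idx] <- as.integer(overrides)
    } else {
      if (length(overrides) != M)
        stop("unnamed 'overrides' must have length M", call. = FALSE)
      ov <- as.integer(overrides)
    }
    repl <- !is.na(ov)
    if (any(!ov[repl] %in% 1:3)) stop("override labels must be 1, 2 or 3", call. = FALSE)
    g[repl] <- ov[repl]
    prov[repl] <- "override"
  }

  if (!any(g == 1L))
    stop("selection infeasible: no reaction moves the target species toward the threshold (G1 empty)",
         call. = FALSE)
  structure(list(group_id = g, provenance = prov, nu_eff = nu_eff, lump = u,
                 binary = binary, target = event$target,
                 eta = event$eta),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  for (k in 1:3)
    cat(sprintf("  G%d: %s\n", k,
                if (any(x$group_id == k))
                  paste0("R", which(x$group_id == k), collapse = ", ")
                else "(empty)"))
  invisible(x)
}

# interval bounds implied by pairwise conservation laws and frozen species
species_upper_bounds <- function(system) {
  nu <- system$nu
  N <- ncol(nu)
  ub <- rep(Inf, N)
  for (s in seq_len(N))
    if (all(nu[, s] == 0L)) ub[s] <- system$x0[[s]]
  if (N > 1) {
    for (s in seq_len(N - 1)) for (s2 in (s + 1):N) {
      if (all(nu[, s] + nu[, s2] == 0L)) {
        tot <- system$x0[[s]] + system$x0[[s2]]
        ub[s] <- min(ub[s], tot)
        ub[s2] <- min(ub[s2], tot)
      }
    }
  }
  ub
}

#' Subdivide the neutral group by indirect effect
#'
#' `G3` reactions do not change the (lumped) target coordinate, but they
#' can shift the propensities of the `G1`/`G2` reactions.  `G31` contains
#' `G3` reactions whose firing increases some `G1` propensity or
#' decreases some `G2` propensity (helping the event); `G32` the reverse
#' (hindering); `G33` the rest (including reactions with effects in both
#' directions).  Classification is by the stoichiometric effect on the
#' reactant species of the `G1`/`G2` reactions.
#'
#' @param system a [reaction_system()].
#' @param partition a `group_partition`.
#' @return Integer vector over reactions: 1, 2 or 3 for `G31`, `G32`,
#'   `G33` on `G3` members, `NA` elsewhere.
#' @export
subpartition_g3 <- function(system, partition) {
  g <- partition$group_id
  nu <- system$nu
  reac <- system$reactant_stoich
  sub <- rep(NA_integer_, length(g))
  g1_species <- which(colSums(reac[g == 1L, , drop = FALSE]) > 0)
  g2_species <- which(colSums(reac[g == 2L, , drop = FALSE]) > 0)
  for (m in which(g == 3L)) {
    inc1 <- any(nu[m, g1_species] > 0)
    dec1 <- any(nu[m, g1_species] < 0)
    inc2 <- any(nu[m, g2_species] > 0)
    dec2 <- any(nu[m, g2_species] < 0)
    helps <- inc1 || dec2
    hinders <- dec1 || inc2
    sub[m] <- if (helps && !hinders) 1L else if (hinders && !helps) 2L else 3L
  }
  sub
}

#' Subdivide `G1`/`G2` by step size (dimerization support)
#'
#' Reactions that change the target coordinate by two molecules at a time
#' (e.g. `0 -> 2B`) are separated from unit-step reactions:
#' `G11`/`G21` hold steps of effective size 1 toward/away from the
#' threshold, `G12`/`G22` steps of size 2.
#'
#' @inheritParams subpartition_g3
#' @return Integer vector: 11, 12, 21 or 22 on `G1`/`G2` members, `NA`
#'   elsewhere.
#' @export
subpartition_dimer <- function(system, partition) {
  g <- partition$group_id
  step <- partition$nu_eff * sign(partition$eta)
  sub <- rep(NA_integer_, length(g))
  sub[g == 1L & step == 1] <- 11L
  sub[g == 1L & step == 2] <- 12L
  sub[g == 2L & step == -1] <- 21L
  sub[g == 2L & step == -2] <- 22L
  sub
}

#' Choose the representative event reaction count K_E
#'
#' The event is most likely to occur at a total reaction count near the
#' natural mean of `K_T` (the count distribution is unimodal and the
#' conditional hit probability grows with the number of available steps,
#' but the probability of observing more than the typical number of
#' reactions falls off quickly).  `K_E` is therefore placed at the top of
#' the admissible band `|eta| <= K_E <= mean(K_T)`:
#' `K_E = floor(mean_KT)`, clamped from below at `|eta|`.
#'
#' @param stats a `pilot_stats` (see [pilot_statistics()]), or a number
#'   taken as the mean of `K_T`.
#' @param eta signed threshold offset.
#' @param K_E optional override (must be `>= |eta|`).
#' @return Integer `K_E`.
#' @export
choose_event_count <- function(stats, eta, K_E = NULL) {
  eta_abs <- abs(eta)
  stopifnot(eta_abs >= 1)
  if (!is.null(K_E)) {
    if (K_E < eta_abs) stop("'K_E' override below |eta|", call. = FALSE)
    return(as.integer(round(K_E)))
  }
  mean_KT <- if (inherits(stats, "pilot_stats")) stats$mean_KT else as.numeric(stats)
  if (mean_KT < eta_abs)
    stop("infeasible horizon: the event needs at least ", eta_abs,
         " reactions but on average only ", signif(mean_KT, 4),
         " occur in [0, T]", call. = FALSE)
  max(as.integer(eta_abs), as.integer(floor(mean_KT)))
}

#' Optimal two-group probabilities
#'
#' For a system with only `G1` and `G2` reactions, reaching the threshold
#' at exactly the `K_E`-th reaction requires `K1 - K2 = |eta|` and
#' `K1 + K2 = K_E` firings of each group.  The probability of that count
#' split under constant group probabilities `(Q1, 1 - Q1)` is a binomial
#' term; its maximizer is `Q1* = K1/K_E`:
#' `Q1* = (K_E + |eta|) / (2 K_E)`, `Q2* = 1 - Q1*`.
#'
#' @param K_E representative event reaction count.
#' @param eta signed threshold offset, `|eta| <= K_E`.
#' @return Numeric `c(Q1, Q2)`, summing to 1, `Q1 >= 1/2`.
#' @examples
#' two_group_Q(200, 25)  # 0.5625, 0.4375
#' @export
two_group_Q <- function(K_E, eta) {
  eta_abs <- abs(eta)
  stopifnot(K_E >= eta_abs, K_E >= 1)
  q1 <- (K_E + eta_abs) / (2 * K_E)
  c(Q1 = q1, Q2 = 1 - q1)
}

#' Optimal two-group probabilities with size-2 steps
#'
#' With dimerization reactions the two coarse groups mix unit and double
#' steps.  Within-group proportional allocation preserves the natural mix,
#' so group `g` has mean effective step size
#' `e_g = (N_g1 + 2 N_g2) / (N_g1 + N_g2)` (from the pilot mean counts of
#' its unit- and double-step subgroups).  The event count balance becomes
#' `e1 K1 - e2 K2 = |eta|`, `K1 + K2 = K_E`, and maximizing the same
#' binomial term gives `Q1* = (|eta|/K_E + e2) / (e1 + e2)`.
#' Reduces exactly to [two_group_Q()] when no double steps are present.
#'
#' @inheritParams two_group_Q
#' @param N11,N12,N21,N22 pilot mean firing counts of the `G11`, `G12`,
#'   `G21`, `G22` subgroups.
#' @return Numeric `c(Q1, Q2)`.
#' @export
dimer_two_group_Q <- function(K_E, eta, N11, N12, N21 = 0, N22 = 0) {
  eta_abs <- abs(eta)
  stopifnot(K_E >= eta_abs)
  e1 <- effective_step(N11, N12)
  e2 <- effective_step(N21, N22)
  q1 <- (eta_abs / K_E + e2) / (e1 + e2)
  q1 <- min(max(q1, 0), 1)
  c(Q1 = q1, Q2 = 1 - q1)
}

effective_step <- function(n1, n2) {
  if (n1 + n2 <= 0) return(1)
  (n1 + 2 * n2) / (n1 + n2)
}

#' Dominant term of the event-count expansion
#'
#' Conditional on `K_t = K_E` total reactions, the probability of first
#' reaching the threshold decomposes over the number `K2` of
#' away-steps:
#' the `(K2 + 1)`-th term is the multinomial probability of the split
#' `(K1, K2, K3) = (K2 + |eta|, K2, K_E - 2 K2 - |eta|)` under the
#' natural group frequencies `Q_hat`.  `find_kappa()` locates the index
#' `kappa` of the largest term; the search walks consecutive term ratios
#' in the log domain, so no factorial ever overflows.  With effective
#' step sizes `e1`, `e2 != 1` (dimerization) the balance generalizes to
#' `K1 = (|eta| + e2 K2) / e1` and the terms are evaluated directly via
#' `lgamma`.
#'
#' @inheritParams two_group_Q
#' @param Q_hat natural group frequencies `(Q1, Q2, Q3)`, non-negative,
#'   summing to 1 (estimated from pilot runs as mean group counts over
#'   mean `K_T`).
#' @param e1,e2 effective step sizes of `G1`, `G2` (default 1).
#' @return A `kappa_search` list: `kappa`, `K_E`, `eta`, `log_terms`
#'   (profile over all admissible `K2`), `Q_hat`.
#' @examples
#' find_kappa(200, 25, c(0.2, 0.2, 0.6))$kappa
#' @export
find_kappa <- function(K_E, eta, Q_hat, e1 = 1, e2 = 1) {
  eta_abs <- abs(eta)
  stopifnot(K_E >= eta_abs, length(Q_hat) == 3, all(Q_hat >= -1e-12))
  Q_hat <- pmax(Q_hat, 0)
  if (abs(sum(Q_hat) - 1) > 1e-6)
    stop("'Q_hat' must sum to 1", call. = FALSE)
  unit <- e1 == 1 && e2 == 1
  if (unit && all(Q_hat > 0)) {
    K2max <- floor((K_E - eta_abs) / 2)
    lt <- numeric(K2max + 1)
    if (K2max > 0) {
      K2 <- 0:(K2max - 1)
      K3 <- K_E - 2 * K2 - eta_abs
      logr <- log(K3) + log(K3 - 1) + log(Q_hat[1]) + log(Q_hat[2]) -
        log(K2 + 1 + eta_abs) - log(K2 + 1) - 2 * log(Q_hat[3])
      lt <- c(0, cumsum(logr))
    }
    kappa <- which.max(lt) - 1L
  } else {
    K2max <- floor((e1 * K_E - eta_abs) / (e1 + e2))
    if (K2max < 0) stop("no admissible term: K_E below |eta|/e1", call. = FALSE)
    K2 <- 0:K2max
    K1 <- (eta_abs + e2 * K2) / e1
    K3 <- K_E - K1 - K2
    lt <- lgamma(K_E + 1) - lgamma(K1 + 1) - lgamma(K2 + 1) - lgamma(K3 + 1) +
      xlogq(K1, Q_hat[1]) + xlogq(K2, Q_hat[2]) + xlogq(K3, Q_hat[3])
    if (all(!is.finite(lt)))
      stop("no admissible term has positive probability under 'Q_hat'",
           call. = FALSE)
    kappa <- K2[which.max(lt)]
  }
  structure(list(kappa = as.integer(round(kappa)), K_E = as.integer(K_E),
                 eta = eta, log_terms = lt, Q_hat = Q_hat, e1 = e1, e2 = e2),
            class = "kappa_search")
}

xlogq <- function(k, q) ifelse(k > 0, k * log(q), 0)

#' @export
print.kappa_search <- function(x, ...) {
  cat(sprintf("<kappa_search> kappa = %d (K_E = %d, |eta| = %d)\n",
              x$kappa, x$K_E, abs(x$eta)))
  invisible(x)
}

#' Optimal three-group probabilities
#'
#' Having located the dominant term (see [find_kappa()]), the simulation
#' group probabilities maximize that single multinomial term over the
#' probability simplex, which gives the exponent proportions:
#' `Q* = (kappa + |eta|, kappa, K_E - 2*kappa - |eta|) / K_E`
#' (with `K1 = (|eta| + e2*kappa)/e1` under effective step sizes).
#'
#' @param kappa dominant term index (number of away-steps).
#' @inheritParams find_kappa
#' @return Numeric `c(Q1, Q2, Q3)` summing to 1.
#' @export
three_group_Q <- function(kappa, eta, K_E, e1 = 1, e2 = 1) {
  eta_abs <- abs(eta)
  K1 <- (eta_abs + e2 * kappa) / e1
  K3 <- K_E - K1 - kappa
  stopifnot(kappa >= 0, K3 >= -1e-9)
  q <- c(K1, kappa, max(K3, 0)) / K_E
  setNames(q / sum(q), c("Q1", "Q2", "Q3"))
}

#' Fine-tune the neutral-group probabilities
#'
#' Within its total mass `Q3*`, the neutral group's probability can be
#' shifted from the hindering subgroup `G32` toward the helping subgroup
#' `G31` (see [subpartition_g3()]).  With natural subgroup shares
#' `s3i = Q_hat3i / Q_hat3`, the tuned split is
#'
#' `Q31 = Q3* (s31 + alpha*s33 + (1 - beta)*s32)`,
#' `Q32 = Q3* * beta * s32`,
#' `Q33 = Q3* (1 - alpha) * s33`,
#'
#' i.e. `G32` keeps a fraction `beta < 1` of its natural share and `G31`
#' absorbs the freed mass (plus a fraction `alpha` of `G33`'s share).
#' The three parts sum to `Q3*` identically, `Q31` always exceeds and
#' `Q32` always falls below their natural shares.  Fine-tuning is only
#' applicable when `s31 < 1` (there is mass to take); inadmissible
#' `(alpha, beta)` outside `(0, 1) x [0, 1)` raise an error.
#'
#' @param Q3_star total neutral-group probability.
#' @param Q_hat31,Q_hat32,Q_hat33 natural subgroup frequencies (pilot
#'   mean counts over mean `K_T`; only their ratios matter).
#' @param alpha,beta tuning constants, `alpha` in (0, 1),
#'   `0 <= beta < 1`.
#' @return Numeric `c(Q31, Q32, Q33)` summing to `Q3_star`, with an
#'   attribute `applied` (FALSE when the applicability condition fails,
#'   in which case the natural split is returned unchanged).
#' @export
fine_tune_g3 <- function(Q3_star, Q_hat31, Q_hat32, Q_hat33,
                         alpha = 0.85, beta = 0.80) {
  if (!(alpha > 0 && alpha < 1) || !(beta >= 0 && beta < 1))
    stop("inadmissible fine-tune constants: need 0 < alpha < 1 and 0 <= beta < 1",
         call. = FALSE)
  tot <- Q_hat31 + Q_hat32 + Q_hat33
  if (tot <= 0) stop("neutral group has no natural flow to fine-tune", call. = FALSE)
  s <- c(Q_hat31, Q_hat32, Q_hat33) / tot
  if (s[1] >= 1 || s[2] <= 0) {
    message("fine-tuning not applicable (no hindering flow to shift); using the natural split")
    out <- Q3_star * s
    attr(out, "applied") <- FALSE
    return(setNames(out, c("Q31", "Q32", "Q33")))
  }
  out <- Q3_star * c(s[1] + alpha * s[3] + (1 - beta) * s[2],
                     beta * s[2],
                     (1 - alpha) * s[3])
  attr(out, "applied") <- TRUE
  setNames(out, c("Q31", "Q32", "Q33"))
}

#' Per-reaction biased probabilities from group targets
#'
#' Within each group the target mass is allocated in proportion to the
#' current propensities; a group with zero total propensity has its mass
#' redistributed over the live groups in proportion to their targets.
#' Thin wrapper over [step_bias()] with a [group_scheme()].
#'
#' @param system a [reaction_system()].
#' @param state state vector.
#' @param groups 1-based group label per reaction (or `group_partition`).
#' @param targets per-group total probabilities, summing to 1.
#' @return Numeric probability vector `q` summing to 1.
#' @export
per_reaction_q <- function(system, state, groups, targets)
  step_bias(group_scheme(groups, targets), system, state)$q

#' Automatic importance-sampling parameter selection
#'
#' End-to-end selection of a group [bias_scheme] for a rare event:
#' pilot SSA runs measure the natural flow of reaction counts;
#' reactions are partitioned ([partition_reactions()]); the
#' representative event count `K_E` is chosen ([choose_event_count()]);
#' the optimal group probabilities come from the two-group closed form
#' ([two_group_Q()], or [dimer_two_group_Q()] with size-2 steps) or from
#' the dominant-term analysis ([find_kappa()] + [three_group_Q()]) when a
#' neutral group is present, optionally fine-tuned ([fine_tune_g3()]).
#'
#' @inheritParams estimate
#' @param pilot_n number of pilot runs (default 1000).
#' @param pilot optional precomputed [pilot_statistics()] (skips the
#'   pilot stage; its RNG cost is then not re-paid).
#' @param fine_tune logical: shift neutral-group mass toward helping
#'   reactions.
#' @param alpha,beta fine-tune constants (defaults 0.85, 0.80).
#' @param K_E optional override of the event count.
#' @param overrides optional partition overrides (see
#'   [partition_reactions()]).
#' @return List with `scheme` (a group [bias_scheme]) and `report` (a
#'   `selection_report`: `K_E`, `kappa`, `Q_star`, `Q_hat`, partition,
#'   pilot summaries, fine-tune record).
#' @examples
#' \donttest{
#' fx <- fixture_system("prod_deg")
#' ev <- rare_event(fx$system, "S2", theta = 65, horizon = 100)
#' sel <- select_scheme(fx$system, ev, seed = 1)
#' estimate(fx$system, ev, "wssa", sel$scheme, n = 1e4, seed = 2)
#' }
#' @export
select_scheme <- function(system, event, pilot_n = 1000, pilot = NULL,
                          fine_tune = FALSE, alpha = 0.85, beta = 0.80,
                          K_E = NULL, overrides = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pilot))
    pilot <- pilot_statistics(system, event, n_pilot = pilot_n)
  part <- partition_reactions(system, event, overrides = overrides)
  g <- part$group_id
  KE <- choose_event_count(pilot, event$eta, K_E = K_E)
  eta_abs <- abs(event$eta)

  dimer_sub <- subpartition_dimer(system, part)
  has_dimer_steps <- any(dimer_sub %in% c(12L, 22L))
  Nsub <- function(lbl) sum(pilot$Nm_bar[which(dimer_sub == lbl)])
  e1 <- if (has_dimer_steps) effective_step(Nsub(11L), Nsub(12L)) else 1
  e2 <- if (has_dimer_steps) effective_step(Nsub(21L), Nsub(22L)) else 1

  Ng <- vapply(1:3, function(k) sum(pilot$Nm_bar[g == k]), numeric(1))
  Q_hat <- Ng / sum(Ng)
  report <- list(K_E = KE, eta = event$eta, Q_hat = Q_hat,
                 partition = part, pilot_n = pilot$n_pilot,
                 mean_KT = pilot$mean_KT, sd_KT = pilot$sd_KT,
                 e1 = e1, e2 = e2, kappa = NA_integer_,
                 fine_tune = list(requested = fine_tune, applied = FALSE,
                                  alpha = alpha, beta = beta))

  if (!any(g == 3L) || Q_hat[3] == 0) {
    Qs <- if (has_dimer_steps)
      dimer_two_group_Q(KE, eta_abs, Nsub(11L), Nsub(12L), Nsub(21L), Nsub(22L))
    else two_group_Q(KE, eta_abs)
    groups <- ifelse(g == 1L, 1L, 2L)
    targets <- c(Qs[[1]], Qs[[2]])
    report$Q_star <- setNames(targets, c("Q1", "Q2"))
  } else {
    ks <- find_kappa(KE, eta_abs, Q_hat, e1 = e1, e2 = e2)
    report$kappa <- ks$kappa
    Qs <- three_group_Q(ks$kappa, eta_abs, KE, e1 = e1, e2 = e2)
    if (vanishing_directional(system, part)) {
      # Directional reactions can be silenced by binary species (e.g. an
      # enzyme/complex cycle): constant per-step group totals would distort
      # the state-conditional dynamics, so instead scale each directional
      # reaction's natural probability by a constant factor chosen to make
      # its average group probability hit the target, with the neutral
      # group absorbing the slack.  Per-step weight factors are constant.
      if (fine_tune)
        message("fine-tuning is not combined with the state-conditional (scaled) scheme; ignoring")
      lambda <- rep(1, length(g))
      for (k in 1:2)
        if (Q_hat[k] > 0) lambda[g == k] <- Qs[[k]] / Q_hat[k]
      scheme <- scaled_scheme(lambda, slack = g == 3L)
      report$Q_star <- Qs
      report$lambda <- lambda
      report$variant <- "scaled"
      class(report) <- "selection_report"
      return(list(scheme = scheme, report = report))
    }
    if (fine_tune) {
      sub3 <- subpartition_g3(system, part)
      N3 <- vapply(1:3, function(k) sum(pilot$Nm_bar[which(sub3 == k)]),
                   numeric(1))
      ft <- fine_tune_g3(Qs[[3]], N3[1], N3[2], N3[3],
                         alpha = alpha, beta = beta)
      report$fine_tune$applied <- isTRUE(attr(ft, "applied"))
      report$fine_tune$Q3_split <- as.numeric(ft)
      groups <- integer(length(g))
      groups[g == 1L] <- 1L
      groups[g == 2L] <- 2L
      groups[g == 3L] <- 2L + sub3[g == 3L]
      targets <- c(Qs[[1]], Qs[[2]], as.numeric(ft))
      report$Q_star <- setNames(c(Qs[[1]], Qs[[2]], as.numeric(ft)),
                                c("Q1", "Q2", "Q31", "Q32", "Q33"))
      report$g3_subgroups <- sub3
    } else {
      groups <- g
      targets <- as.numeric(Qs)
      report$Q_star <- Qs
    }
  }
  targets <- targets / sum(targets)
  scheme <- group_scheme(groups, targets)
  report$variant <- "group"
  class(report) <- "selection_report"
  list(scheme = scheme, report = report)
}

# TRUE when some directional (G1/G2) reaction consumes a binary species
# that is not frozen, i.e. its propensity vanishes in recurrent states
vanishing_directional <- function(system, part) {
  ub <- species_upper_bounds(system)
  frozen <- apply(system$nu == 0L, 2, all)
  vol <- ub <= 1 & !frozen
  any(vapply(which(part$group_id != 3L), function(m)
    any(system$reactant_stoich[m, ] > 0L & vol), logical(1)))
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat(sprintf("  pilot: n = %d, mean K_T = %.4g (sd %.3g); K_E = %d\n",
              x$pilot_n, x$mean_KT, x$sd_KT, x$K_E))
  print(x$partition)
  if (!is.na(x$kappa)) cat("  kappa =", x$kappa, "\n")
  cat("  Q_hat: ", paste(signif(x$Q_hat, 4), collapse = ", "), "\n")
  cat("  Q_star:", paste(paste0(names(x$Q_star), "=", signif(x$Q_star, 4)),
                         collapse = ", "), "\n")
  if (x$fine_tune$requested)
    cat(sprintf("  fine-tune: applied = %s (alpha = %g, beta = %g)\n",
                x$fine_tune$applied, x$fine_tune$alpha, x$fine_tune$beta))
  invisible(x)
}
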