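#' Importance-sampling bias schemes
#'
#' A bias scheme determines the per-step reaction-selection probabilities
#' `q_m(x)` used by the weighted simulators.  The inter-event time law is
#' never altered; only the choice of which reaction fires is biased, and
#' each step multiplies the trajectory weight by the likelihood ratio
#' `(a_m(x)/a0(x)) / q_m(x)`.
#'
#' * `natural_scheme()`: `q_m = a_m / a0`; all weights are exactly 1 and
#'   the weighted simulators reduce to the plain SSA / NRM.
#' * `gamma_scheme(gamma)`: fixed positive multipliers,
#'   `q_m = gamma_m a_m / sum(gamma a)`.
#' * `group_scheme(groups, targets)`: reactions are partitioned into
#'   groups; at every state each group receives a constant total
#'   probability (its target), split within the group in proportion to
#'   the current propensities.  If a group has zero total propensity in
#'   some state, its mass is redistributed over the live groups in
#'   proportion to their targets (this preserves `sum(q) = 1` and
#'   absolute continuity).
#'
#' * `scaled_scheme(lambda, slack)`: each directional reaction keeps its
#'   natural state-conditional probability `a_m/a0` scaled by a constant
#'   multiplier `lambda_m`; the reactions flagged `slack` (typically the
#'   neutral group) absorb the remaining mass in proportion to their
#'   propensities.  Used for systems whose directional reactions can
#'   have zero propensity in recurrent states (e.g. enzyme/complex
#'   cycles), where it keeps per-step weight factors constant.
#'
#' @param gamma positive numeric vector, one multiplier per reaction.
#' @param lambda positive multipliers (entries for slack reactions are
#'   ignored).
#' @param slack logical vector flagging the slack (mass-absorbing)
#'   reactions; at least one required.
#' @param groups integer vector, 1-based group label per reaction, or a
#'   `group_partition` object (see [partition_reactions()]).
#' @param targets numeric vector of per-group total probabilities,
#'   summing to 1.
#' @return An object of class `bias_scheme`.
#' @examples
#' natural_scheme()
#' gamma_scheme(c(1.2, 1 / 1.2))
#' group_scheme(c(1, 2), targets = c(0.6, 0.4))
#' @name bias_scheme
NULL

#' @rdname bias_scheme
#' @export
natural_scheme <- function() {
  structure(list(variant = "natural"), class = "bias_scheme")
}

#' @rdname bias_scheme
#' @export
gamma_scheme <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be a vector of positive finite multipliers", call. = FALSE)
  structure(list(variant = "gamma", gamma = as.numeric(gamma)),
            class = "bias_scheme")
}

#' @rdname bias_scheme
#' @export
group_scheme <- function(groups, targets) {
  if (inherits(groups, "group_partition")) groups <- groups$group_id
  groups <- as.integer(groups)
  if (any(is.na(groups)) || any(groups < 1L))
    stop("'groups' must be positive integer labels", call. = FALSE)
  if (length(targets) < max(groups))
    stop("'targets' must have one entry per group", call. = FALSE)
  if (any(targets < 0) || abs(sum(targets) - 1) > 1e-8)
    stop("group targets must be non-negative and sum to 1", call. = FALSE)
  structure(list(variant = "group", groups = groups,
                 targets = as.numeric(targets)),
            class = "bias_scheme")
}

#' @rdname bias_scheme
#' @export
scaled_scheme <- function(lambda, slack) {
  slack <- as.logical(slack)
  if (length(lambda) != length(slack))
    stop("'lambda' and 'slack' must have one entry per reaction", call. = FALSE)
  if (!any(slack))
    stop("'slack' must flag at least one reaction", call. = FALSE)
  if (any(!is.finite(lambda[!slack])) || any(lambda[!slack] <= 0))
    stop("'lambda' must be positive and finite for non-slack reactions",
         call. = FALSE)
  lambda[slack] <- 1
  structure(list(variant = "scaled", lambda = as.numeric(lambda),
                 slack = slack),
            class = "bias_scheme")
}

#' @export
print.bias_scheme <- function(x, ...) {
  cat("<bias_scheme>", x$variant)
  if (x$variant == "gamma")
    cat(":", paste(signif(x$gamma, 4), collapse = ", "))
  if (x$variant == "group")
    cat(": targets", paste(signif(x$targets, 4), collapse = ", "))
  if (x$variant == "scaled")
    cat(": lambda", paste(ifelse(x$slack, "slack", signif(x$lambda, 4)),
                          collapse = ", "))
  cat("\n")
  invisible(x)
}

sch_cpp <- function(scheme, M) {
  stopifnot(inherits(scheme, "bias_scheme"))
  switch(scheme$variant,
    natural = list(type = 0L),
    gamma = {
      if (length(scheme$gamma) != M)
        stop("gamma scheme has ", length(scheme$gamma),
             " multipliers but the system has ", M, " reactions", call. = FALSE)
      list(type = 1L, gamma = scheme$gamma)
    },
    group = {
      if (length(scheme$groups) != M)
        stop("group scheme labels ", length(scheme$groups),
             " reactions but the system has ", M, call. = FALSE)
      list(type = 2L, group = scheme$groups - 1L, targets = scheme$targets)
    },
    scaled = {
      if (length(scheme$lambda) != M)
        stop("scaled scheme has ", length(scheme$lambda),
             " multipliers but the system has ", M, " reactions", call. = FALSE)
      list(type = 3L, lambda = scheme$lambda,
           slack = as.integer(scheme$slack))
    })
}

#' Per-step bias probabilities and weight factors
#'
#' Evaluates a scheme in one state: the biased selection probabilities
#' `q` and the per-reaction likelihood-ratio factors
#' `(a_m/a0) / q_m` that a weighted step with that reaction would
#' contribute to the trajectory weight.
#'
#' @param scheme a [bias_scheme].
#' @param system a [reaction_system()].
#' @param state state vector (defaults to `x0`).
#' @return List with `q` (sums to 1), `weight_factor` (NA where
#'   `a_m = 0`), and the natural probabilities `p`.
#' @export
step_bias <- function(scheme, system, state = system$x0) {
  a <- propensities(system, state)
  a0 <- sum(a)
  if (a0 <= 0) stop("no reaction possible in this state (a0 = 0)", call. = FALSE)
  p <- a / a0
  q <- switch(scheme$variant,
    natural = p,
    gamma = {
      b <- scheme$gamma * a
      b / sum(b)
    },
    group = {
      g <- scheme$groups
      gs <- vapply(seq_along(scheme$targets), function(k) sum(a[g == k]),
                   numeric(1))
      live <- gs > 0
      if (any(scheme$targets[live] == 0 & gs[live] > 0))
        stop("bias scheme assigns zero probability to a group with positive propensity (absolute continuity violated)",
             call. = FALSE)
      qeff <- ifelse(live, scheme$targets, 0)
      qeff <- qeff / sum(qeff)
      q <- numeric(length(a))
      for (k in seq_along(qeff))
        if (live[k]) q[g == k] <- qeff[k] * a[g == k] / gs[k]
      q
    },
    scaled = {
      sl <- scheme$slack
      S <- sum(scheme$lambda[!sl] * a[!sl]) / a0
      slack_sum <- sum(a[sl])
      if (slack_sum > 0 && S < 1) {
        q <- ifelse(sl, (1 - S) * a / slack_sum, scheme$lambda * a / a0)
      } else {
        b <- ifelse(sl, a, scheme$lambda * a)
        q <- b / sum(b)
      }
      q
    })
  if (any(a > 0 & q <= 0))
    stop("bias scheme assigns zero probability to a reaction with positive propensity (absolute continuity violated)",
         call. = FALSE)
  list(q = q, weight_factor = ifelse(a > 0, p / q, NA_real_), p = p)
}
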