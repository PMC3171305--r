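#' Build a truncated CTMC with the event region absorbing
#'
#' Enumerates all states reachable from `x0` (breadth-first over
#' reaction firings) within per-species upper `bounds`, makes every
#' state in the rare-event region absorbing, and collects transitions
#' that would leave the bounds into a single bookkeeping "leak" state.
#' The first-passage probability computed on the truncation is exact up
#' to the reported leak mass.
#'
#' Default bounds combine conservation-law-implied bounds (pairwise
#' conserved sums and frozen species) with, for species left unbounded
#' by those, an empirical envelope derived from a small set of pilot SSA
#' runs (mean + 10 sd of the gross production; consumes RNG draws).
#'
#' @inheritParams estimate
#' @param bounds named (or length-`N`) numeric vector of inclusive upper
#'   bounds per species; `NA` entries fall back to the default rule.
#' @param max_states enumeration budget (error when exceeded).
#' @return A `truncated_ctmc`: `states` (matrix, one row per state),
#'   `transitions` (from/to/rate triplets), `absorbing` (row indices of
#'   event states), `start`, `leak` (boundary transitions), `bounds`.
#' @examples
#' fx <- fixture_system("prod_deg")
#' ev <- rare_event(fx$system, "S2", theta = 65, horizon = 100)
#' ctmc <- build_ctmc(fx$system, ev)
#' nrow(ctmc$states)  # 66: birth-death chain on X2 = 0..65
#' @export
build_ctmc <- function(system, event, bounds = NULL, max_states = 2e5) {
  stopifnot(inherits(system, "reaction_system"), inherits(event, "rare_event"))
  N <- length(system$species)
  ub <- species_upper_bounds(system)
  if (!is.null(bounds)) {
    if (!is.null(names(bounds))) {
      bb <- rep(NA_real_, N)
      bb[match(names(bounds), system$species)] <- bounds
      bounds <- bb
    }
    stopifnot(length(bounds) == N)
    ub <- ifelse(is.na(bounds), ub, pmin(ub, bounds))
  }
  if (any(!is.finite(ub))) {
    env <- empirical_bounds(system, event)
    ub <- ifelse(is.finite(ub), ub, env)
  }
  ub <- pmax(ceiling(ub), system$x0)

  key <- function(x) paste(x, collapse = ",")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  states <- matrix(NA_integer_, 1024L, N)
  nstate <- 0L
  push <- function(x) {
    k <- key(x)
    i <- idx[[k]]
    if (!is.null(i)) return(i)
    nstate <<- nstate + 1L
    if (nstate > max_states)
      stop("state budget exceeded (", max_states,
           "); tighten 'bounds' or raise 'max_states'", call. = FALSE)
    if (nstate > nrow(states))
      states <<- rbind(states, matrix(NA_integer_, nrow(states), N))
    states[nstate, ] <<- x
    idx[[k]] <- nstate
    nstate
  }
  x0 <- unname(as.integer(system$x0))
  start <- push(x0)

  cap <- 4096L
  from <- to <- integer(cap)
  rate <- numeric(cap)
  ntr <- 0L
  add_tr <- function(i, j, r) {
    ntr <<- ntr + 1L
    if (ntr > length(from)) {
      from <<- c(from, integer(length(from)))
      to <<- c(to, integer(length(to)))
      rate <<- c(rate, numeric(length(rate)))
    }
    from[ntr] <<- i; to[ntr] <<- j; rate[ntr] <<- r
  }
  lfrom <- integer(256L); lrate <- numeric(256L); nlk <- 0L
  add_leak <- function(i, r) {
    nlk <<- nlk + 1L
    if (nlk > length(lfrom)) {
      lfrom <<- c(lfrom, integer(length(lfrom)))
      lrate <<- c(lrate, numeric(length(lrate)))
    }
    lfrom[nlk] <<- i; lrate[nlk] <<- r
  }

  absorbing <- integer(0)
  nu <- system$nu
  qhead <- 1L
  while (qhead <= nstate) {
    i <- qhead
    qhead <- qhead + 1L
    x <- states[i, ]
    if (in_omega(event, x)) {
      absorbing <- c(absorbing, i)
      next
    }
    a <- propensities(system, x)
    for (m in which(a > 0)) {
      y <- x + nu[m, ]
      if (any(y > ub)) {
        add_leak(i, a[m])
        next
      }
      add_tr(i, push(y), a[m])
    }
  }
  structure(list(
    states = states[seq_len(nstate), , drop = FALSE],
    transitions = data.frame(from = from[seq_len(ntr)], to = to[seq_len(ntr)],
                             rate = rate[seq_len(ntr)]),
    leak = data.frame(from = lfrom[seq_len(nlk)], rate = lrate[seq_len(nlk)]),
    absorbing = sort(unique(absorbing)), start = start,
    bounds = ub, system_name = system$name),
    class = "truncated_ctmc")
}

empirical_bounds <- function(system, event, n_runs = 200, sd_mult = 10) {
  b <- cpp_sim_batch(sys_cpp(system), ev_cpp(event),
                     sch_cpp(natural_scheme(), nrow(system$nu)), "ssa",
                     as.integer(n_runs), FALSE, TRUE, integer(0))
  K <- b$Km_runs
  step_up <- pmax(apply(system$nu, 2, max), 0)
  mx <- sapply(seq_along(system$species), function(s) {
    gain <- as.numeric(K %*% pmax(system$nu[, s], 0L))
    system$x0[[s]] + mean(gain) + sd_mult * sd(gain)
  })
  pmax(mx, system$x0 + step_up)
}

#' @export
print.truncated_ctmc <- function(x, ...) {
  cat(sprintf("<truncated_ctmc> %d states, %d transitions, %d absorbing\n",
              nrow(x$states), nrow(x$transitions), length(x$absorbing)))
  invisible(x)
}

#' First-passage probability by uniformization
#'
#' Computes the probability that the absorbing (event) region of a
#' [build_ctmc()] chain is reached by time `T`, by uniformizing the
#' chain at the maximal exit rate and summing the Poisson-weighted
#' powers of the uniformized transition matrix.  Absorbing states are
#' retained as self-loops, so the mass in the region at `T` equals the
#' first-passage probability.  The Poisson tail truncation error and the
#' truncation-boundary leak are reported; `p` is exact for the bounded
#' chain up to those two terms.
#'
#' @param ctmc a `truncated_ctmc`.
#' @param T time horizon.
#' @param tol Poisson tail mass to drop (error bound contribution).
#' @return List with `p` (first-passage probability), `leak` (mass lost
#'   at the truncation boundary by `T`; an upper bound on the truncation
#'   error), `tail_error`, `survive` (mass still in transient states),
#'   and `conservation` (total accounted mass; equals 1 up to solver
#'   tolerance).
#' @examples
#' fx <- fixture_system("prod_deg")
#' ev <- rare_event(fx$system, "S2", theta = 65, horizon = 100)
#' first_passage_prob(build_ctmc(fx$system, ev), 100)$p  # about 2.3e-3
#' @export
first_passage_prob <- function(ctmc, T, tol = 1e-12) {
  stopifnot(inherits(ctmc, "truncated_ctmc"), T >= 0)
  S <- nrow(ctmc$states)
  leak_state <- S + 1L
  tr <- ctmc$transitions
  tr <- tr[!(tr$from %in% ctmc$absorbing), , drop = FALSE]
  lk <- ctmc$leak[!(ctmc$leak$from %in% ctmc$absorbing), , drop = FALSE]
  exit <- numeric(leak_state)
  if (nrow(tr) + nrow(lk) > 0) {
    agg <- rowsum(c(tr$rate, lk$rate), c(tr$from, lk$from))
    exit[as.integer(rownames(agg))] <- agg[, 1]
  }
  Lambda <- max(exit, 1e-300)
  i <- c(tr$from, lk$from, seq_len(leak_state))
  j <- c(tr$to, rep(leak_state, nrow(lk)), seq_len(leak_state))
  v <- c(tr$rate / Lambda, lk$rate / Lambda, 1 - exit / Lambda)
  P <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(leak_state, leak_state))
  kmax <- if (Lambda * T > 0) qpois(1 - tol, Lambda * T) + 1 else 0
  wts <- dpois(0:kmax, Lambda * T)
  tail_err <- max(1 - sum(wts), 0)
  abs_mask <- logical(leak_state)
  abs_mask[ctmc$absorbing] <- TRUE
  dense <- numeric(leak_state)
  dense[ctmc$start] <- 1
  p_abs <- p_leak <- p_surv <- 0
  for (k in 0:kmax) {
    w <- wts[k + 1]
    if (w > 0) {
      p_abs <- p_abs + w * sum(dense[abs_mask])
      p_leak <- p_leak + w * dense[leak_state]
      p_surv <- p_surv + w * (sum(dense[!abs_mask]) - dense[leak_state])
    }
    if (k < kmax) dense <- as.numeric(dense %*% P)
  }
  list(p = p_abs, leak = p_leak, tail_error = tail_err, survive = p_surv,
       conservation = p_abs + p_leak + p_surv + tail_err)
}
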