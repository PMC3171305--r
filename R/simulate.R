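#' One step of the direct method
#'
#' Pure inversion step used by the direct-method simulators: the waiting
#' time is `tau = ln(1/r1)/a0` and the reaction index is the smallest `mu`
#' whose cumulative propensity reaches `r2 * a0`.  Exposed mainly for
#' testing and illustration; the simulators draw `r1`, `r2` internally.
#'
#' @param a numeric vector of propensities with `sum(a) > 0`.
#' @param r1,r2 unit-interval uniforms.
#' @return List with `tau` and `mu` (1-based).
#' @examples
#' dm_step(c(1.2, 0.8), r1 = exp(-2), r2 = 0.7)  # tau = 1, mu = 2
#' @export
dm_step <- function(a, r1 = runif(1), r2 = runif(1)) {
  a0 <- sum(a)
  if (a0 <= 0) stop("a0 = 0: no reaction possible", call. = FALSE)
  if (any(a < 0)) stop("negative propensity", call. = FALSE)
  list(tau = log(1 / r1) / a0, mu = which(cumsum(a) >= r2 * a0)[1L])
}

sim_method <- function(method)
  match.arg(method, c("ssa", "nrm", "wssa", "wnrm"))

check_scheme_method <- function(method, scheme) {
  if (method %in% c("ssa", "nrm") && scheme$variant != "natural")
    stop("method '", method, "' is unweighted; use wssa/wnrm for a biased scheme",
         call. = FALSE)
  scheme
}

#' Simulate one trajectory
#'
#' Runs a single trajectory from `x0`, stopping at the first entry into
#' the rare-event region or at the horizon `T` (if `absorb = FALSE` the
#' run ignores the event region and always runs to `T`, as in pilot
#' runs).  With `log = TRUE` the full step log is returned.
#'
#' @param system a [reaction_system()].
#' @param event a [rare_event()].
#' @param method `"ssa"`, `"nrm"`, `"wssa"` or `"wnrm"`.
#' @param scheme a [bias_scheme] (weighted methods only).
#' @param absorb stop when the event region is reached (default `TRUE`).
#' @param log keep the per-step log (time, reaction, state, `a0`,
#'   cumulative log-weight, and the biased probabilities `q` for
#'   weighted methods).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return A `trajectory_outcome`: `hit`, `hit_time`, `w` (exactly 1 for
#'   unweighted methods), `Km` (per-reaction firing counts), `K`
#'   (total), `t_end`, and the log if requested.
#' @export
simulate_trajectory <- function(system, event, method = "ssa",
                                scheme = natural_scheme(), absorb = TRUE,
                                log = FALSE, seed = NULL) {
  method <- sim_method(method)
  check_scheme_method(method, scheme)
  if (!is.null(seed)) set.seed(seed)
  sys <- c(sys_cpp(system), list())
  out <- if (log) {
    cpp_sim_logged(sys, ev_cpp(event), sch_cpp(scheme, nrow(system$nu)),
                   method, absorb, TRUE)
  } else {
    b <- cpp_sim_batch(sys, ev_cpp(event), sch_cpp(scheme, nrow(system$nu)),
                       method, 1L, absorb, TRUE, integer(0))
    list(hit = b$hit_runs[[1L]], hit_time = b$hit_time_runs[[1L]],
         w = if (b$hit_runs[[1L]]) b$w_runs[[1L]] else 1,
         Km = b$Km_runs[1L, ], t_end = NA_real_)
  }
  structure(c(out, list(K = sum(out$Km), method = method)),
            class = "trajectory_outcome")
}

#' Write a logged trajectory as tab-separated text
#'
#' Columns: time, reaction index, then one column per species (state
#' after the firing).  Requires a trajectory simulated with
#' `log = TRUE`.
#'
#' @param outcome a logged `trajectory_outcome`.
#' @param path output file path.
#' @param species optional species names for the header.
#' @return `path`, invisibly.
#' @export
write_trajectory_log <- function(outcome, path, species = NULL) {
  if (is.null(outcome$time) || is.null(outcome$state))
    stop("trajectory was not simulated with log = TRUE", call. = FALSE)
  if (is.null(species))
    species <- paste0("S", seq_len(ncol(outcome$state)))
  df <- data.frame(time = outcome$time, reaction = outcome$mu, outcome$state)
  names(df) <- c("time", "reaction", species)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate a rare-event probability by (weighted) stochastic simulation
#'
#' Runs `n` independent trajectories and accumulates `k1 = sum(w)` and
#' `k2 = sum(w^2)` over the runs that reach the event region.  The
#' estimator is `p_hat = k1/n` (unbiased for any absolutely continuous
#' scheme), with sample variance `sigma2 = k2/n - p_hat^2` and 68%
#' uncertainty `u68 = sqrt(sigma2/n)`.
#'
#' @inheritParams simulate_trajectory
#' @param n number of simulation runs.
#' @param seed integer seed; `(method, scheme, seed, n)` fully determine
#'   the result.
#' @return An `estimate_result` with `p_hat`, `var`, `u68`, `k1`, `k2`,
#'   `n`, `hits`, `method`, `seed`.
#' @examples
#' fx <- fixture_system("prod_deg")
#' ev <- rare_event(fx$system, "S2", theta = 55, horizon = 100)
#' estimate(fx$system, ev, method = "ssa", n = 2000, seed = 1)
#' @export
estimate <- function(system, event, method = "wssa",
                     scheme = natural_scheme(), n = 1e5, seed = NULL) {
  method <- sim_method(method)
  check_scheme_method(method, scheme)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- cpp_sim_batch(sys_cpp(system), ev_cpp(event),
                     sch_cpp(scheme, nrow(system$nu)), method,
                     as.integer(n), TRUE, FALSE, integer(0))
  p <- b$k1 / n
  v <- max(b$k2 / n - p^2, 0)
  structure(list(p_hat = p, var = v, u68 = sqrt(v / n),
                 k1 = b$k1, k2 = b$k2, n = as.integer(n), hits = b$hits,
                 mean_KT = mean(b$KT), method = method, scheme = scheme,
                 seed = seed),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("<estimate_result> %s (%s scheme), n = %d\n", x$method,
              x$scheme$variant, x$n))
  cat(sprintf("  p_hat = %.4g +/- %.3g (68%%), sigma^2 = %.4g, hits = %d\n",
              x$p_hat, x$u68, x$var, x$hits))
  invisible(x)
}

#' Pilot statistics from unweighted runs
#'
#' Makes `n_pilot` plain SSA runs over the full interval `[0, T]`
#' (ignoring the event region, so the natural flow of reaction counts is
#' measured) and summarizes the total reaction count `K_T` and the
#' per-reaction mean firing counts.  These feed the automatic
#' importance-sampling parameter selection.
#'
#' @inheritParams estimate
#' @param n_pilot number of pilot runs (a warning is issued below 1000).
#' @param occupancy optional character/integer vector of species: also
#'   tally the number of reaction events occurring in each joint count
#'   pattern of those species (useful for systems with small sub-state
#'   spaces).
#' @param method `"ssa"` (default) or `"nrm"`.
#' @return A `pilot_stats` object: `n_pilot`, `mean_KT`, `sd_KT`,
#'   `Nm_bar` (per-reaction mean counts, summing to `mean_KT`), and
#'   `occupancy` (data frame of pattern frequencies) when requested.
#' @export
pilot_statistics <- function(system, event, n_pilot = 1000, seed = NULL,
                             occupancy = NULL, method = "ssa") {
  method <- match.arg(method, c("ssa", "nrm"))
  if (n_pilot < 100) stop("'n_pilot' must be at least 100", call. = FALSE)
  if (n_pilot < 1000)
    warning("fewer than 1000 pilot runs; count estimates may be noisy")
  if (!is.null(seed)) set.seed(seed)
  occ_idx <- integer(0)
  if (!is.null(occupancy)) {
    occ_idx <- if (is.character(occupancy)) match(occupancy, system$species)
               else as.integer(occupancy)
    if (any(is.na(occ_idx))) stop("unknown occupancy species", call. = FALSE)
  }
  b <- cpp_sim_batch(sys_cpp(system), ev_cpp(event),
                     sch_cpp(natural_scheme(), nrow(system$nu)), method,
                     as.integer(n_pilot), FALSE, FALSE, occ_idx - 1L)
  out <- list(n_pilot = as.integer(n_pilot),
              mean_KT = mean(b$KT), sd_KT = sd(b$KT),
              Nm_bar = as.numeric(b$Km_sum) / n_pilot,
              horizon = event$horizon)
  if (length(occ_idx)) {
    pat <- as.data.frame(b$occ_patterns)
    names(pat) <- system$species[occ_idx]
    pat$events <- b$occ_counts
    pat$frequency <- b$occ_counts / sum(b$occ_counts)
    out$occupancy <- pat[order(-pat$events), , drop = FALSE]
  }
  structure(out, class = "pilot_stats")
}

#' @export
print.pilot_stats <- function(x, ...) {
  cat(sprintf("<pilot_stats> %d runs over [0, %g]\n", x$n_pilot, x$horizon))
  cat(sprintf("  K_T: mean = %.4g, sd = %.4g\n", x$mean_KT, x$sd_KT))
  cat("  per-reaction means:", paste(signif(x$Nm_bar, 4), collapse = ", "), "\n")
  invisible(x)
}
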