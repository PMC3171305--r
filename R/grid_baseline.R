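#' Try-and-test grid search for fixed bias multipliers
#'
#' The refined try-and-test baseline: for each candidate multiplier
#' vector `gamma`, a moderate number of probe runs of the weighted
#' simulator estimates the variance of the rare-event estimator; the
#' candidate with the smallest probe variance wins.  Unlike
#' [select_scheme()], the candidate set must be guessed in advance.
#'
#' @inheritParams estimate
#' @param gammas candidate set: a list of per-reaction multiplier
#'   vectors, or a plain numeric vector of `delta` values which is
#'   expanded via `expand_delta` (default: `gamma = (delta, 1/delta, 1,
#'   ..., 1)`, the standard choice for a system whose first reaction
#'   makes and second breaks the target species).
#' @param n_probe probe runs per candidate (>= 1000 recommended).
#' @param expand_delta function mapping a scalar `delta` to a multiplier
#'   vector.
#' @return A `grid_search` list: `best` (winning multiplier vector),
#'   `best_index`, and `table` (data frame of candidate, `p_hat`, `var`,
#'   `u68`).
#' @examples
#' \donttest{
#' fx <- fixture_system("prod_deg")
#' ev <- rare_event(fx$system, "S2", theta = 65, horizon = 100)
#' gs <- grid_try_and_test(fx$system, ev, gammas = seq(1.1, 1.8, 0.1),
#'                         n_probe = 2000, seed = 1)
#' gs$table
#' }
#' @export
grid_try_and_test <- function(system, event, gammas, n_probe = 1000,
                              method = "wssa", seed = NULL,
                              expand_delta = NULL) {
  M <- nrow(system$nu)
  if (is.null(expand_delta))
    expand_delta <- function(delta) c(delta, 1 / delta, rep(1, M - 2L))
  if (is.numeric(gammas)) {
    labels <- as.character(gammas)
    gammas <- lapply(gammas, expand_delta)
    names(gammas) <- labels
  }
  if (!length(gammas)) stop("empty candidate grid", call. = FALSE)
  if (is.null(names(gammas)))
    names(gammas) <- paste0("g", seq_along(gammas))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(gammas), function(nm) {
    est <- estimate(system, event, method = method,
                    scheme = gamma_scheme(gammas[[nm]]), n = n_probe)
    data.frame(candidate = nm, p_hat = est$p_hat, var = est$var,
               u68 = est$u68, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$var)
  structure(list(best = gammas[[best]], best_index = best,
                 best_candidate = tab$candidate[[best]], table = tab,
                 n_probe = n_probe),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> best candidate: %s (probe n = %d)\n",
              x$best_candidate, x$n_probe))
  print(x$table, row.names = FALSE)
  invisible(x)
}
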