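#' Specify a rare threshold-crossing event
#'
#' The event is the first passage of a single target species to the
#' threshold `theta = X_i(0) + eta` at some time `t <= T`.  With
#' unit-step reactions the target region is the single state
#' `X_i = theta`; when a step of size 2 can jump over the threshold, the
#' default `"cross"` convention counts the first time
#' `sign(eta) * (X_i - theta) >= 0`, which coincides with the exact hit
#' for unit-step systems.  Use `convention = "hit"` to require
#' `X_i == theta` exactly.
#'
#' @param system a [reaction_system()].
#' @param species target species name or 1-based index `i`.
#' @param theta absolute threshold; exactly one of `theta`/`offset`.
#' @param offset signed offset `eta` (nonzero); `theta = X_i(0) + eta`.
#' @param horizon time horizon `T > 0`.
#' @param convention `"cross"` (default) or `"hit"`.
#'
#' @return An object of class `rare_event` with elements `target`
#'   (1-based index), `theta`, `eta`, `horizon`, `convention`.
#' @examples
#' pd <- fixture_system("prod_deg")
#' rare_event(pd$system, "S2", theta = 65, horizon = 100)
#' @export
rare_event <- function(system, species, theta = NULL, offset = NULL,
                       horizon, convention = c("cross", "hit")) {
  stopifnot(inherits(system, "reaction_system"))
  convention <- match.arg(convention)
  if (is.character(species)) {
    target <- match(species, system$species)
    if (is.na(target)) stop("unknown species '", species, "'", call. = FALSE)
  } else {
    target <- as.integer(species)
    if (is.na(target) || target < 1L || target > length(system$species))
      stop("species index out of range", call. = FALSE)
  }
  if (is.null(theta) == is.null(offset))
    stop("give exactly one of 'theta' or 'offset'", call. = FALSE)
  x0i <- as.numeric(system$x0[[target]])
  if (is.null(theta)) theta <- x0i + offset
  eta <- theta - x0i
  if (eta == 0) stop("'theta' equal to the initial count (eta = 0) does not define a rare event",
                     call. = FALSE)
  if (!is.numeric(horizon) || horizon <= 0) stop("'horizon' must be > 0", call. = FALSE)
  structure(list(target = target, species = system$species[[target]],
                 theta = theta, eta = eta, horizon = as.numeric(horizon),
                 convention = convention),
            class = "rare_event")
}

#' @export
print.rare_event <- function(x, ...) {
  cat(sprintf("<rare_event> %s %s %g (eta = %+g) by T = %g  [%s]\n",
              x$species, if (x$eta > 0) "reaches" else "falls to",
              x$theta, x$eta, x$horizon, x$convention))
  invisible(x)
}

ev_cpp <- function(event) {
  list(target = as.integer(event$target - 1L), theta = as.numeric(event$theta),
       sgn = as.integer(sign(event$eta)),
       exact_hit = as.integer(event$convention == "hit"),
       T = as.numeric(event$horizon))
}

in_omega <- function(event, state) {
  xi <- state[[event$target]]
  if (event$convention == "hit") return(xi == event$theta)
  sign(event$eta) * (xi - event$theta) >= 0
}
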