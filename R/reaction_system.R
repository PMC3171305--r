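#' Define a single mass-action reaction
#'
#' A reaction is given by its reactant and product stoichiometries and a
#' stochastic probability rate constant `c`.  Only elementary reactions are
#' supported: the total reactant order must be 0, 1 or 2.  For a
#' dimerization (two identical reactant molecules) the propensity uses the
#' combinatorial count `c * x * (x - 1) / 2`, so rate constants in
#' configurations are unambiguous.
#'
#' @param reactants named integer vector of reactant stoichiometries
#'   (may be empty or `NULL` for a source reaction).
#' @param products named integer vector of product stoichiometries.
#' @param rate positive probability rate constant (units 1/time for order
#'   0 and 1, 1/(time x molecule) for order 2).
#'
#' @return An object of class `reaction`.
#' @examples
#' reaction(c(S1 = 1), c(S2 = 1), rate = 0.1)         # S1 -> S2
#' reaction(NULL, c(B = 2), rate = 4)                 # 0 -> 2B
#' @export
reaction <- function(reactants = NULL, products = NULL, rate) {
  reactants <- normalize_stoich(reactants, "reactants")
  products <- normalize_stoich(products, "products")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("'rate' must be a single non-negative number", call. = FALSE)
  total_order <- sum(reactants)
  if (total_order > 2L)
    stop("total reactant order must be 0, 1 or 2 (got ", total_order, ")",
         call. = FALSE)
  structure(
    list(reactants = reactants, products = products, rate = as.numeric(rate),
         order = as.integer(total_order), dimer = any(reactants == 2L)),
    class = "reaction")
}

normalize_stoich <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("'", what, "' must be a named vector (names are species)", call. = FALSE)
  if (any(x != round(x)) || any(x < 1))
    stop("'", what, "' stoichiometries must be positive integers", call. = FALSE)
  v <- tapply(as.integer(x), names(x), sum)
  setNames(as.integer(v), names(v))
}

#' Assemble a mass-action reaction network
#'
#' Builds the validated network object used by all simulators: species
#' names, the initial state, the `M x N` state-change matrix `nu`
#' (products minus reactants), per-reaction propensity metadata, and the
#' Gibson-Bruck dependency graph (reaction `m2` depends on `m1` when a
#' species changed by `m1` appears among the reactants of `m2`; every
#' reaction depends on itself).
#'
#' @param species character vector of species names (length `N >= 1`).
#' @param x0 non-negative integer initial state, one count per species
#'   (recycled names are matched against `species` when named).
#' @param reactions list of [reaction()] objects (length `M >= 1`).
#' @param name optional label used in printing and reports.
#'
#' @return An object of class `reaction_system` with elements `species`,
#'   `x0`, `reactions`, `nu`, `rate`, `order`, `dimer` and `depends`.
#' @examples
#' sys <- reaction_system(
#'   species = c("S1", "S2"),
#'   x0 = c(1, 40),
#'   reactions = list(
#'     reaction(c(S1 = 1), c(S1 = 1, S2 = 1), rate = 1),
#'     reaction(c(S2 = 1), NULL, rate = 0.025)
#'   ))
#' propensities(sys, sys$x0)
#' @export
reaction_system <- function(species, x0, reactions, name = NULL) {
  species <- as.character(species)
  N <- length(species)
  if (N < 1L) stop("need at least one species", call. = FALSE)
  if (anyDuplicated(species)) stop("duplicated species names", call. = FALSE)
  if (!is.list(reactions) || length(reactions) < 1L)
    stop("need at least one reaction", call. = FALSE)
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  M <- length(reactions)
  if (!is.null(names(x0))) {
    if (!setequal(names(x0), species))
      stop("names of 'x0' do not match 'species'", call. = FALSE)
    x0 <- x0[species]
  }
  if (length(x0) != N)
    stop("'x0' must have one entry per species", call. = FALSE)
  if (any(x0 != round(x0)) || any(x0 < 0))
    stop("'x0' must be non-negative integers", call. = FALSE)
  x0 <- setNames(as.integer(x0), species)

  nu <- matrix(0L, M, N, dimnames = list(NULL, species))
  reac <- matrix(0L, M, N, dimnames = list(NULL, species))
  for (m in seq_len(M)) {
    r <- reactions[[m]]
    if (!inherits(r, "reaction"))
      stop("reactions[[", m, "]] is not a 'reaction' object", call. = FALSE)
    for (part in c("reactants", "products")) {
      unknown <- setdiff(names(r[[part]]), species)
      if (length(unknown))
        stop("reaction ", m, " references unknown species: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    reac[m, names(r$reactants)] <- r$reactants
    nu[m, names(r$reactants)] <- nu[m, names(r$reactants)] - r$reactants
    nu[m, names(r$products)] <- nu[m, names(r$products)] + r$products
  }

  sys <- structure(
    list(species = species, x0 = x0, reactions = reactions,
         nu = nu, reactant_stoich = reac,
         rate = vapply(reactions, `[[`, numeric(1), "rate"),
         order = vapply(reactions, `[[`, integer(1), "order"),
         dimer = vapply(reactions, `[[`, logical(1), "dimer"),
         name = name),
    class = "reaction_system")
  sys$depends <- dependency_graph(sys)
  sys
}

#' Mass-action propensities of every reaction in a state
#'
#' Order 0: `c`; order 1 on species `j`: `c * x_j`; order 2 on distinct
#' species `j`, `k`: `c * x_j * x_k`; dimerization on `j`:
#' `c * x_j * (x_j - 1) / 2`.
#'
#' @param system a [reaction_system()].
#' @param state non-negative integer state vector (defaults to `x0`).
#' @return Numeric vector of length `M`, all entries `>= 0`.
#' @export
propensities <- function(system, state = system$x0) {
  stopifnot(inherits(system, "reaction_system"))
  if (length(state) != length(system$species))
    stop("'state' must have one entry per species", call. = FALSE)
  if (any(state < 0))
    stop("invalid state: negative species count", call. = FALSE)
  vapply(seq_along(system$reactions), function(m) {
    r <- system$reactions[[m]]
    if (r$order == 0L) return(r$rate)
    xs <- state[match(names(r$reactants), system$species)]
    if (r$order == 1L) return(r$rate * xs[[1L]])
    if (r$dimer) return(r$rate * xs[[1L]] * (xs[[1L]] - 1) / 2)
    r$rate * xs[[1L]] * xs[[2L]]
  }, numeric(1))
}

#' @rdname propensities
#' @export
total_propensity <- function(system, state = system$x0)
  sum(propensities(system, state))

# reaction m2 depends on m1 iff some species changed (or consumed) by m1 is a
# reactant of m2; every reaction depends on itself
dependency_graph <- function(system) {
  M <- nrow(system$nu)
  affected <- (system$nu != 0L) | (system$reactant_stoich > 0L)
  lapply(seq_len(M), function(m1) {
    touched <- affected[m1, ]
    dep <- which(vapply(seq_len(M), function(m2)
      any(system$reactant_stoich[m2, ] > 0L & touched), logical(1)))
    sort(unique(c(m1, dep)))
  })
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system",
      if (!is.null(x$name)) paste0("'", x$name, "'") else "", ">\n", sep = " ")
  cat("  species (", length(x$species), "): ",
      paste0(x$species, "=", x$x0, collapse = ", "), "\n", sep = "")
  for (m in seq_along(x$reactions)) {
    r <- x$reactions[[m]]
    fmt <- function(st) if (length(st) == 0L) "0" else
      paste(ifelse(st > 1L, paste0(st, " "), ""), names(st),
            sep = "", collapse = " + ")
    cat(sprintf("  R%d: %s -> %s   (c = %g)\n", m, fmt(r$reactants),
                fmt(r$products), r$rate))
  }
  invisible(x)
}

# flat representation handed to the C++ engines
sys_cpp <- function(system) {
  M <- nrow(system$nu)
  s1 <- s2 <- rep(-1L, M)
  for (m in seq_len(M)) {
    r <- system$reactions[[m]]
    idx <- match(names(r$reactants), system$species) - 1L
    if (r$order >= 1L) s1[m] <- idx[[1L]]
    if (r$order == 2L) s2[m] <- if (r$dimer) idx[[1L]] else idx[[2L]]
  }
  list(nu = unname(system$nu), s1 = s1, s2 = s2,
       order = as.integer(system$order), dimer = as.integer(system$dimer),
       rate = as.numeric(system$rate),
       dep = lapply(system$depends, function(d) as.integer(d - 1L)),
       x0 = unname(as.integer(system$x0)))
}

#' Generate a random valid reaction network
#'
#' Draws a syntactically valid mass-action network: `M` reactions with
#' uniformly chosen reactant/product orders up to `max_order`, strictly
#' positive rate constants, and a non-negative initial state.  The output
#' is deterministic for a given `seed` and leaves the caller's RNG state
#' untouched.  Intended for property tests.
#'
#' @param seed integer seed.
#' @param N,M number of species and reactions (`>= 1`).
#' @param max_order maximum total reactant order (`<= 2`).
#' @param max_x0 upper bound for initial counts.
#' @return A [reaction_system()].
#' @export
random_system <- function(seed, N = 3, M = 4, max_order = 2, max_x0 = 30) {
  stopifnot(N >= 1, M >= 1, max_order <= 2, max_order >= 0)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  species <- paste0("S", seq_len(N))
  pick <- function(k) {
    s <- sample(species, k, replace = TRUE)
    v <- table(s)
    setNames(as.integer(v), names(v))
  }
  reactions <- lapply(seq_len(M), function(m) {
    ro <- sample.int(max_order + 1L, 1L) - 1L
    po <- sample.int(3L, 1L) - 1L
    # avoid the degenerate no-op reaction
    repeat {
      re <- if (ro > 0) pick(ro) else NULL
      pr <- if (po > 0) pick(po) else NULL
      if (!(is.null(re) && is.null(pr))) break
      po <- 1L
    }
    reaction(re, pr, rate = round(runif(1, 0.05, 2), 3))
  })
  reaction_system(species, sample.int(max_x0 + 1L, N, replace = TRUE) - 1L,
                  reactions, name = paste0("random-", seed))
}
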