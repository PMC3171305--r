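#' Benchmark reaction systems
#'
#' Three small mass-action networks widely used to benchmark rare-event
#' estimators, with their standard rate constants, initial states and
#' study horizons:
#'
#' * `prod_deg` -- single-species production--degradation:
#'   `S1 -> S1 + S2` (`c1 = 1`), `S2 -> 0` (`c2 = 0.025`), `x0 = (1, 40)`,
#'   `T = 100`.  At equilibrium `X2` is Poisson with mean 40; thresholds
#'   `theta = 65..80` are four to six standard deviations above the mean.
#' * `convert_decay` -- four reactions with direct and indirect channels:
#'   `S1 -> S2` (`c1 = 0.1`), `S2 -> 0` (`c2 = 0.1`),
#'   `S3 -> S3 + S1` (`c3 = 8`), `S1 -> 0` (`c4 = 0.1`),
#'   `x0 = (40, 40, 1)`, `T = 10`; events on `S2`.
#' * `futile_cycle` -- enzymatic futile cycle, two opposed
#'   single-substrate enzymatic conversions:
#'   `S1 + S2 -> S3`, `S3 -> S1 + S2`, `S3 -> S1 + S5`,
#'   `S4 + S5 -> S6`, `S6 -> S4 + S5`, `S6 -> S4 + S2`,
#'   `c1 = c2 = c4 = c5 = 1`, `c3 = c6 = 0.1`,
#'   `x0 = (1, 50, 0, 1, 50, 0)`, `T = 100`; events on `S5`.
#'   Conservation: `X1 + X3 = 1`, `X4 + X6 = 1` and
#'   `X2 + X3 + X5 + X6 = 100` hold on every trajectory.
#'
#' @param name one of `"prod_deg"`, `"convert_decay"`, `"futile_cycle"`.
#' @return A list with `system` (a [reaction_system()]), `target` (event
#'   species name), `horizon` (study horizon `T`) and `thetas` (the
#'   benchmark threshold values).
#' @examples
#' fx <- fixture_system("prod_deg")
#' ev <- rare_event(fx$system, fx$target, theta = 65, horizon = fx$horizon)
#' @export
fixture_system <- function(name = c("prod_deg", "convert_decay", "futile_cycle")) {
  name <- match.arg(name)
  switch(name,
    prod_deg = list(
      system = reaction_system(
        c("S1", "S2"), c(1, 40),
        list(reaction(c(S1 = 1), c(S1 = 1, S2 = 1), rate = 1),
             reaction(c(S2 = 1), NULL, rate = 0.025)),
        name = "prod_deg"),
      target = "S2", horizon = 100, thetas = c(65, 70, 75, 80)),
    convert_decay = list(
      system = reaction_system(
        c("S1", "S2", "S3"), c(40, 40, 1),
        list(reaction(c(S1 = 1), c(S2 = 1), rate = 0.1),
             reaction(c(S2 = 1), NULL, rate = 0.1),
             reaction(c(S3 = 1), c(S3 = 1, S1 = 1), rate = 8),
             reaction(c(S1 = 1), NULL, rate = 0.1)),
        name = "convert_decay"),
      target = "S2", horizon = 10, thetas = c(65, 68)),
    futile_cycle = list(
      system = reaction_system(
        paste0("S", 1:6), c(1, 50, 0, 1, 50, 0),
        list(reaction(c(S1 = 1, S2 = 1), c(S3 = 1), rate = 1),
             reaction(c(S3 = 1), c(S1 = 1, S2 = 1), rate = 1),
             reaction(c(S3 = 1), c(S1 = 1, S5 = 1), rate = 0.1),
             reaction(c(S4 = 1, S5 = 1), c(S6 = 1), rate = 1),
             reaction(c(S6 = 1), c(S4 = 1, S5 = 1), rate = 1),
             reaction(c(S6 = 1), c(S4 = 1, S2 = 1), rate = 0.1)),
        name = "futile_cycle"),
      target = "S5", horizon = 100, thetas = c(25, 40)))
}
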