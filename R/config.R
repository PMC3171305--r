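#' Read and write reaction-network configurations
#'
#' Model configurations are YAML (or JSON, which YAML subsumes) with the
#' schema:
#'
#' ```yaml
#' name: prod_deg            # optional
#' species:
#'   - {name: S1, initial: 1}
#'   - {name: S2, initial: 40}
#' reactions:
#'   - {reactants: {S1: 1}, products: {S1: 1, S2: 1}, rate: 1.0}
#'   - {reactants: {S2: 1}, products: {}, rate: 0.025}
#' event:                    # optional
#'   species: S2
#'   theta: 65               # or offset: 25
#'   T: 100
#' ```
#'
#' `write_system_config(read_system_config(path))` round-trips the
#' system semantically.  Configurations for the three bundled benchmark
#' systems ship under `inst/extdata/`.
#'
#' @param path file path (for `read_system_config`, a path or a literal
#'   YAML string).
#' @return `read_system_config`: a list with `system` (a
#'   [reaction_system()]) and `event` (a [rare_event()] or `NULL`).
#' @examples
#' cfg <- system.file("extdata", "prod_deg.yaml", package = "raressa")
#' read_system_config(cfg)$system
#' @export
read_system_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  for (field in c("species", "reactions"))
    if (is.null(cfg[[field]]) || !length(cfg[[field]]))
      stop("config error: missing or empty '", field, "'", call. = FALSE)
  sp <- vapply(cfg$species, function(s) {
    if (is.null(s$name)) stop("config error: species entry without 'name'", call. = FALSE)
    as.character(s$name)
  }, character(1))
  x0 <- vapply(cfg$species, function(s) {
    if (is.null(s$initial)) stop("config error: species '", s$name,
                                 "' without 'initial'", call. = FALSE)
    as.numeric(s$initial)
  }, numeric(1))
  reactions <- lapply(seq_along(cfg$reactions), function(m) {
    r <- cfg$reactions[[m]]
    if (is.null(r$rate)) stop("config error: reaction ", m, " without 'rate'", call. = FALSE)
    if (r$rate < 0) stop("config error: reaction ", m, " has negative 'rate'", call. = FALSE)
    tovec <- function(x) if (is.null(x) || !length(x)) NULL else unlist(x)
    reaction(tovec(r$reactants), tovec(r$products), rate = r$rate)
  })
  system <- reaction_system(sp, x0, reactions, name = cfg$name)
  event <- NULL
  if (!is.null(cfg$event)) {
    e <- cfg$event
    if (is.null(e$species) || is.null(e$T))
      stop("config error: 'event' needs 'species' and 'T'", call. = FALSE)
    event <- rare_event(system, e$species, theta = e$theta, offset = e$offset,
                        horizon = e$T)
  }
  list(system = system, event = event)
}

#' @rdname read_system_config
#' @param system a [reaction_system()].
#' @param event optional [rare_event()] to embed.
#' @export
write_system_config <- function(system, path, event = NULL) {
  stopifnot(inherits(system, "reaction_system"))
  cfg <- list(
    name = system$name,
    species = lapply(seq_along(system$species), function(s)
      list(name = system$species[[s]], initial = unname(system$x0[[s]]))),
    reactions = lapply(system$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           rate = r$rate)))
  if (is.null(cfg$name)) cfg$name <- NULL
  if (!is.null(event))
    cfg$event <- list(species = event$species, theta = event$theta,
                      T = event$horizon)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
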