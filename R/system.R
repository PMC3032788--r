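#' Construct a reaction system by hand
#'
#' Assembles a `reaction_system` from explicit molecule compositions and a
#' reaction table. Useful for worked examples and tests; random systems come
#' from [generate_reaction_system()].
#'
#' @param composition Integer matrix of atom counts, one row per molecule,
#'   with molecule ids as row names.
#' @param reactions A data frame with list columns `substrates`, `sub_mult`,
#'   `products`, `prod_mult` (molecule ids and positive integer
#'   multiplicities), and optionally `rate` (non-negative after direction
#'   normalization) and `locality` (group id or `NA` for bridge).
#' @param universe An [generate_atoms()] universe; by default a single group
#'   containing every atom species of `composition`.
#' @param outflow_coefficient Outflow rate coefficient for sink metabolites.
#' @param check If `TRUE`, verify atom-wise mass conservation of every
#'   reaction.
#'
#' @return A `reaction_system` with sources and sinks assigned.
#' @examples
#' comp <- rbind(H2 = c(2, 0), O2 = c(0, 2), H2O = c(2, 1))
#' water <- reaction_system(comp, tibble::tibble(
#'   substrates = list(c("H2", "O2")), sub_mult = list(c(2L, 1L)),
#'   products = list("H2O"), prod_mult = list(2L), rate = 1
#' ))
#' @export
reaction_system <- function(composition, reactions,
                            universe = NULL,
                            outflow_coefficient = 0.1,
                            check = TRUE) {
  storage.mode(composition) <- "integer"
  if (is.null(rownames(composition))) {
    rownames(composition) <- paste0("M", seq_len(nrow(composition)))
  }
  if (is.null(universe)) universe <- generate_atoms(1L, ncol(composition))
  stopifnot(nrow(universe) == ncol(composition))
  if (any(rowSums(composition) < 1L)) {
    stop("every molecule needs a non-empty composition", call. = FALSE)
  }
  reactions <- tibble::as_tibble(reactions)
  n_rxn <- nrow(reactions)
  if (!"rid" %in% names(reactions)) reactions$rid <- paste0("R", seq_len(n_rxn))
  if (!"rate" %in% names(reactions)) reactions$rate <- rep(NA_real_, n_rxn)
  if (!"locality" %in% names(reactions)) reactions$locality <- rep(NA_integer_, n_rxn)
  reactions <- reactions[, c("rid", "substrates", "sub_mult", "products",
                             "prod_mult", "rate", "locality")]
  for (col in c("sub_mult", "prod_mult")) {
    reactions[[col]] <- lapply(reactions[[col]], as.integer)
  }
  molecules <- tibble::tibble(
    id = rownames(composition),
    scope = apply(composition, 1L, composition_scope,
                  species_group = universe$group),
    mass = as.integer(rowSums(composition))
  )
  system <- structure(list(
    universe = universe,
    molecules = molecules,
    composition = composition,
    reactions = reactions,
    sources = character(0),
    sinks = character(0),
    inflow_weights = numeric(0),
    outflow_coefficient = outflow_coefficient,
    config = generator_config(
      n_groups = attr(universe, "n_groups"),
      species_per_group = attr(universe, "species_per_group"),
      n_reactions = max(n_rxn, 1L)
    ),
    seed = NA_integer_
  ), class = "reaction_system")
  if (check) {
    ok <- vapply(seq_len(n_rxn), function(i) {
      check_mass_conservation(reactions[i, ], composition)
    }, logical(1))
    if (!all(ok)) {
      stop("reaction(s) violating mass conservation: ",
           paste(reactions$rid[!ok], collapse = ", "), call. = FALSE)
    }
  }
  assign_sources_sinks(system)
}

#' Serialize a reaction system to JSON
#'
#' The file is a structured JSON document with keys `atoms`, `molecules`,
#' `reactions`, `sources`, `sinks`, `inflow_weights`, `outflow_coefficient`,
#' `config` and `seed`. Numbers are written at full precision so a
#' write/read round trip is lossless.
#'
#' @param system A `reaction_system`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_system_json <- function(system, path) {
  stopifnot(inherits(system, "reaction_system"))
  rx <- system$reactions
  doc <- list(
    atoms = list(
      n_groups = attr(system$universe, "n_groups"),
      species_per_group = attr(system$universe, "species_per_group"),
      species = system$universe$species,
      group = system$universe$group
    ),
    molecules = list(
      id = system$molecules$id,
      scope = system$molecules$scope,
      mass = system$molecules$mass,
      composition = lapply(seq_len(nrow(system$composition)),
                           function(i) unname(system$composition[i, ]))
    ),
    reactions = list(
      rid = rx$rid,
      substrates = rx$substrates,
      sub_mult = rx$sub_mult,
      products = rx$products,
      prod_mult = rx$prod_mult,
      rate = rx$rate,
      locality = rx$locality
    ),
    sources = system$sources,
    sinks = system$sinks,
    inflow_weights = as.list(system$inflow_weights),
    outflow_coefficient = system$outflow_coefficient,
    config = unclass(system$config),
    seed = system$seed
  )
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = FALSE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a reaction system from JSON
#'
#' @param path Path to a file written by [write_system_json()].
#' @return A `reaction_system`.
#' @export
read_system_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  dbl1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  ints <- function(x) vapply(x, int1, integer(1))
  chrs <- function(x) vapply(x, as.character, character(1))

  universe <- generate_atoms(doc$atoms$n_groups[[1]],
                             doc$atoms$species_per_group[[1]])
  ids <- chrs(doc$molecules$id)
  comp <- do.call(rbind, lapply(doc$molecules$composition, ints))
  rownames(comp) <- ids
  colnames(comp) <- paste0("A", seq_len(ncol(comp)))

  rx <- doc$reactions
  reactions <- tibble::tibble(
    rid = chrs(rx$rid),
    substrates = lapply(rx$substrates, chrs),
    sub_mult = lapply(rx$sub_mult, ints),
    products = lapply(rx$products, chrs),
    prod_mult = lapply(rx$prod_mult, ints),
    rate = vapply(rx$rate, dbl1, numeric(1)),
    locality = ints(rx$locality)
  )
  cfg <- lapply(doc$config, function(x) x[[1]])
  config <- generator_config(
    n_groups = cfg$n_groups, species_per_group = cfg$species_per_group,
    n_reactions = cfg$n_reactions, local_fraction = cfg$local_fraction,
    max_tries = cfg$max_tries, max_molecule_size = cfg$max_molecule_size,
    seed_molecules_per_group = cfg$seed_molecules_per_group
  )
  system <- structure(list(
    universe = universe,
    molecules = tibble::tibble(
      id = ids,
      scope = ints(doc$molecules$scope),
      mass = ints(doc$molecules$mass)
    ),
    composition = comp,
    reactions = reactions,
    sources = chrs(doc$sources),
    sinks = chrs(doc$sinks),
    inflow_weights = stats::setNames(
      vapply(doc$inflow_weights, dbl1, numeric(1)),
      names(doc$inflow_weights)
    ),
    outflow_coefficient = dbl1(doc$outflow_coefficient[[1]]),
    config = config,
    seed = int1(doc$seed[[1]])
  ), class = "reaction_system")
  system
}
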