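#' Generator configuration
#'
#' Parameters controlling the construction of a random mass-conserving
#' reaction system. The fraction `local_fraction` of within-group reactions is
#' the modularity control: at 1 every reaction stays inside one proto-module
#' and the projected substance graph is maximally modular; lowering it adds
#' bridge reactions that connect the modules and lowers modularity.
#'
#' @param n_groups Number of atom proto-modules.
#' @param species_per_group Atom species per group.
#' @param n_reactions Total number of reactions `N_R` to generate. The number
#'   of metabolites `N_M` is an *output* of the construction, not an input.
#' @param local_fraction Fraction `f` of within-group reactions, in `[0, 1]`.
#' @param max_tries Attempts per reaction before falling back to registering
#'   new molecules, and again before giving up entirely.
#' @param max_molecule_size Maximum number of atoms per molecule.
#' @param seed_molecules_per_group Number of molecules seeded per group before
#'   any reaction is generated.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_groups = 3L,
                             species_per_group = 8L,
                             n_reactions = 200L,
                             local_fraction = 0.75,
                             max_tries = 1000L,
                             max_molecule_size = 4L,
                             seed_molecules_per_group = 15L) {
  stopifnot(
    is_count(n_groups), is_count(species_per_group), is_count(n_reactions),
    is_count(max_tries), is_count(max_molecule_size),
    is_count(seed_molecules_per_group),
    is.numeric(local_fraction), length(local_fraction) == 1L,
    local_fraction >= 0, local_fraction <= 1
  )
  structure(list(
    n_groups = as.integer(n_groups),
    species_per_group = as.integer(species_per_group),
    n_reactions = as.integer(n_reactions),
    local_fraction = as.numeric(local_fraction),
    max_tries = as.integer(max_tries),
    max_molecule_size = as.integer(max_molecule_size),
    seed_molecules_per_group = as.integer(seed_molecules_per_group)
  ), class = "generator_config")
}

generation_error <- function(msg) {
  stop(structure(class = c("modmet_generation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## Call the compiled splitting-and-recombining core: generates reactions of
## the requested locality classes (NA = bridge) on top of the given molecules
## and duplicate-blocking reactions. Returns raw compositions and 1-based
## index lists.
run_generator_core <- function(comp0, reactions0_idx, localities, config,
                               seed_molecules = FALSE) {
  species_group <- rep(seq_len(config$n_groups),
                       each = config$species_per_group)
  loc <- ifelse(is.na(localities), 0L, as.integer(localities))
  res <- generate_core_cpp(
    comp0, species_group, config$n_groups, reactions0_idx,
    as.integer(loc),
    if (seed_molecules) config$seed_molecules_per_group else 0L,
    config$max_tries, config$max_molecule_size
  )
  if (!isTRUE(res$ok)) {
    what <- res$failed_locality
    generation_error(sprintf(
      "could not generate a %s reaction within max_tries, even with new molecules",
      if (what == 0L) "bridge" else paste("group", what)))
  }
  res
}

reactions_as_index_lists <- function(system) {
  ids <- system$molecules$id
  rx <- system$reactions
  lapply(seq_len(nrow(rx)), function(i) {
    list(match(rx$substrates[[i]], ids), rx$sub_mult[[i]],
         match(rx$products[[i]], ids), rx$prod_mult[[i]])
  })
}

#' Generate a random mass-conserving reaction system
#'
#' Builds a reaction system with `config$n_reactions` reactions, of which
#' `round(f * n_reactions)` are within-group (split as evenly as possible over
#' the groups, remainder to random groups) and the rest are bridges between
#' modules. Reactions are created by drawing one or two existing molecules as
#' substrates, pooling their atoms, and re-partitioning the pool into product
#' compositions, so every reaction conserves every atom species exactly; a
#' proposal is rejected when a product matches no known molecule (until the
#' retry budget is exhausted, after which new molecules may be registered),
#' when it reuses a substrate, or when the reaction already exists. Molecules
#' that end up in no reaction are pruned, so the metabolite count is an
#' output of the construction. Rate constants are left unset; see
#' [sample_rate_constants()].
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed for reproducible generation.
#'
#' @return A `reaction_system` with sources/sinks assigned structurally.
#' @examples
#' sys <- generate_reaction_system(generator_config(n_reactions = 30L), seed = 1)
#' sys
#' @export
generate_reaction_system <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)

  n_within <- as.integer(round(config$local_fraction * config$n_reactions))
  base <- n_within %/% config$n_groups
  counts <- rep.int(base, config$n_groups)
  extra <- n_within - base * config$n_groups
  if (extra > 0L) {
    picks <- sample.int(config$n_groups, extra)
    counts[picks] <- counts[picks] + 1L
  }
  localities <- c(rep(seq_len(config$n_groups), times = counts),
                  rep(NA_integer_, config$n_reactions - n_within))
  localities <- localities[sample.int(length(localities))]

  n_species <- config$n_groups * config$species_per_group
  res <- run_generator_core(matrix(0L, 0L, n_species), list(), localities,
                            config, seed_molecules = TRUE)
  system <- build_system(res, config, prune = TRUE)
  system$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  assign_sources_sinks(system)
}

## Assemble a reaction_system from generator-core output. `ids` supplies the
## names of pre-existing molecules (core output keeps their order); new
## molecules are numbered on from `next_id`.
build_system <- function(res, config, prune = TRUE, ids = character(0),
                         rate = NULL) {
  n_mol <- nrow(res$comp)
  if (length(ids) < n_mol) {
    next_id <- if (length(ids) == 0L) 1L else {
      max(as.integer(sub("^M", "", ids))) + 1L
    }
    ids <- c(ids, paste0("M", seq.int(next_id, length.out = n_mol - length(ids))))
  }
  n_rxn <- length(res$sub_idx)
  reactions <- tibble::tibble(
    rid = paste0("R", seq_len(n_rxn)),
    substrates = lapply(res$sub_idx, function(i) ids[i]),
    sub_mult = lapply(res$sub_mult, as.integer),
    products = lapply(res$prod_idx, function(i) ids[i]),
    prod_mult = lapply(res$prod_mult, as.integer),
    rate = rate %||% rep(NA_real_, n_rxn),
    locality = as.integer(res$locality)
  )
  comp <- res$comp
  rownames(comp) <- ids
  colnames(comp) <- paste0("A", seq_len(ncol(comp)))
  molecules <- tibble::tibble(
    id = ids,
    scope = as.integer(res$scope),
    mass = as.integer(rowSums(comp))
  )
  system <- structure(list(
    universe = generate_atoms(config$n_groups, config$species_per_group),
    molecules = molecules,
    composition = comp,
    reactions = reactions,
    sources = character(0),
    sinks = character(0),
    inflow_weights = numeric(0),
    outflow_coefficient = 0.1,
    config = config,
    seed = NA_integer_
  ), class = "reaction_system")
  if (prune) prune_unused_molecules(system) else system
}

prune_unused_molecules <- function(system) {
  used <- unique(unlist(c(system$reactions$substrates,
                          system$reactions$products), use.names = FALSE))
  keep <- system$molecules$id %in% used
  if (all(keep)) return(system)
  system$molecules <- system$molecules[keep, ]
  system$composition <- system$composition[keep, , drop = FALSE]
  system$inflow_weights <-
    system$inflow_weights[names(system$inflow_weights) %in% used]
  system
}

#' Generate one additional reaction in an existing reaction system
#'
#' Grows `system` by one mass-conserving reaction of the requested locality
#' class, following the same construction rules as
#' [generate_reaction_system()] (and possibly registering new molecules).
#'
#' @param system A `reaction_system`.
#' @param locality Integer group id for a within-group reaction, or `NA` for a
#'   bridge reaction between modules.
#' @param config A [generator_config()]; defaults to the system's own.
#'
#' @return The system with one more reaction (sources and sinks refreshed).
#' @export
generate_reaction <- function(system, locality = NA, config = NULL) {
  stopifnot(inherits(system, "reaction_system"))
  config <- config %||% system$config
  locality <- normalize_locality(locality, config)
  res <- run_generator_core(system$composition,
                            reactions_as_index_lists(system),
                            locality, config)
  new_system <- build_system(res, config, prune = FALSE,
                             ids = system$molecules$id,
                             rate = NA_real_)
  new_system$reactions <- dplyr::bind_rows(
    system$reactions,
    dplyr::mutate(new_system$reactions,
                  rid = paste0("R", nrow(system$reactions) + 1L))
  )
  new_system$outflow_coefficient <- system$outflow_coefficient
  new_system$inflow_weights <- system$inflow_weights
  new_system$seed <- system$seed
  assign_sources_sinks(new_system)
}

normalize_locality <- function(locality, config) {
  if (length(locality) != 1L) stop("`locality` must be scalar.", call. = FALSE)
  if (is.na(locality)) return(NA_integer_)
  locality <- as.integer(locality)
  if (locality < 1L || locality > config$n_groups) {
    stop("`locality` must be a group id or NA (bridge).", call. = FALSE)
  }
  locality
}

#' Assign sources, sinks and inflow weights
#'
#' A metabolite that is a product of no reaction is a source (mass flows in
#' there); a metabolite that is a substrate of no reaction is a sink (mass
#' flows out at a rate proportional to the outflow coefficient times its
#' concentration). Each source gets a positive inflow weight drawn uniformly
#' on (0, 1) when it first becomes a source; weights of persisting sources
#' are kept.
#'
#' @param system A `reaction_system`.
#' @return The system with `sources`, `sinks` and `inflow_weights` updated.
#' @export
assign_sources_sinks <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  sub_ids <- unique(unlist(system$reactions$substrates, use.names = FALSE))
  prod_ids <- unique(unlist(system$reactions$products, use.names = FALSE))
  ids <- system$molecules$id
  system$sources <- setdiff(ids, prod_ids)
  system$sinks <- setdiff(ids, sub_ids)
  old <- system$inflow_weights
  w <- stats::setNames(rep(NA_real_, length(system$sources)), system$sources)
  keep <- intersect(names(old), system$sources)
  w[keep] <- old[keep]
  miss <- is.na(w)
  if (any(miss)) w[miss] <- stats::runif(sum(miss))
  system$inflow_weights <- w
  system
}

#' Check atom-wise mass conservation of one reaction
#'
#' A reaction conserves mass when, for every atom species, the
#' multiplicity-weighted atom count over the substrates equals the count over
#' the products.
#'
#' @param reaction A list with character vectors `substrates`, `products` and
#'   integer vectors `sub_mult`, `prod_mult`, or one row of a system's
#'   `reactions` tibble.
#' @param composition Integer matrix of atom compositions with molecule ids as
#'   row names (a system's `composition` field).
#'
#' @return `TRUE` iff the reaction conserves every atom species exactly.
#' @examples
#' comp <- rbind(H2 = c(2, 0), O2 = c(0, 2), H2O = c(2, 1))
#' water <- list(substrates = c("H2", "O2"), sub_mult = c(2L, 1L),
#'               products = "H2O", prod_mult = 2L)
#' check_mass_conservation(water, comp)
#' @export
check_mass_conservation <- function(reaction, composition) {
  reaction <- as_reaction_parts(reaction)
  all_ids <- c(reaction$substrates, reaction$products)
  missing <- setdiff(all_ids, rownames(composition))
  if (length(missing) > 0L) {
    stop("unknown molecule id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  side_count <- function(ids, mult) {
    colSums(composition[ids, , drop = FALSE] * mult)
  }
  lhs <- side_count(reaction$substrates, reaction$sub_mult)
  rhs <- side_count(reaction$products, reaction$prod_mult)
  all(lhs == rhs)
}

as_reaction_parts <- function(reaction) {
  if (is.data.frame(reaction)) {
    stopifnot(nrow(reaction) == 1L)
    reaction <- list(
      substrates = reaction$substrates[[1L]], sub_mult = reaction$sub_mult[[1L]],
      products = reaction$products[[1L]], prod_mult = reaction$prod_mult[[1L]]
    )
  }
  stopifnot(length(reaction$substrates) == length(reaction$sub_mult),
            length(reaction$products) == length(reaction$prod_mult),
            length(reaction$substrates) > 0L, length(reaction$products) > 0L)
  reaction
}

#' @export
print.reaction_system <- function(x, ...) {
  n_bridge <- sum(is.na(x$reactions$locality))
  cat(sprintf(
    "<reaction_system> %d metabolites, %d reactions (%d within-group, %d bridge)\n",
    nrow(x$molecules), nrow(x$reactions),
    nrow(x$reactions) - n_bridge, n_bridge))
  cat(sprintf("  groups: %d x %d atom species; sources: %d, sinks: %d\n",
              x$config$n_groups, x$config$species_per_group,
              length(x$sources), length(x$sinks)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
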