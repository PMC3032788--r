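#' Create an atom universe
#'
#' The atom species of the model are partitioned into `n_groups` proto-modules
#' of `species_per_group` species each. Molecules built from a single group's
#' atoms seed the within-group (modular) part of a reaction system; molecules
#' mixing groups arise only through bridge reactions.
#'
#' @param n_groups Number of proto-modules (positive integer).
#' @param species_per_group Number of atom species per group (positive integer).
#'
#' @return A tibble with one row per atom species and columns `species`
#'   (integer id, `1:(n_groups * species_per_group)`) and `group` (integer
#'   group id, `1:n_groups`), of class `atom_universe`.
#' @examples
#' generate_atoms(3, 2)
#' @export
generate_atoms <- function(n_groups, species_per_group) {
  if (!is_count(n_groups) || !is_count(species_per_group)) {
    stop("`n_groups` and `species_per_group` must be positive integers.",
         call. = FALSE)
  }
  n_groups <- as.integer(n_groups)
  species_per_group <- as.integer(species_per_group)
  uni <- tibble::tibble(
    species = seq_len(n_groups * species_per_group),
    group = rep(seq_len(n_groups), each = species_per_group)
  )
  attr(uni, "n_groups") <- n_groups
  attr(uni, "species_per_group") <- species_per_group
  class(uni) <- c("atom_universe", class(uni))
  uni
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == trunc(x)
}

#' Randomly combine atoms into a molecule
#'
#' Draws a molecule composition of 1 to `max_size` atoms. With a group scope
#' only that group's atom species are used; with the global scope (`NA`) any
#' species can enter the composition.
#'
#' @param universe An [generate_atoms()] universe.
#' @param scope Integer group id, or `NA` for the global scope.
#' @param max_size Maximum number of atoms in the molecule (positive integer).
#'
#' @return A named list with `composition` (integer vector over all species of
#'   the universe, counts summing to the molecule size), `scope` (the group all
#'   atoms belong to, or `NA` if mixed), and `mass` (total atom count).
#' @export
sample_molecule <- function(universe, scope = NA, max_size = 4L) {
  stopifnot(inherits(universe, "atom_universe"))
  if (!is_count(max_size)) stop("`max_size` must be a positive integer.", call. = FALSE)
  pool <- molecule_pool(universe, scope)
  size <- sample.int(max_size, 1L)
  atoms <- pool[sample.int(length(pool), size, replace = TRUE)]
  composition <- tabulate(atoms, nbins = nrow(universe))
  list(
    composition = composition,
    scope = composition_scope(composition, universe$group),
    mass = size
  )
}

molecule_pool <- function(universe, scope) {
  if (length(scope) != 1L) stop("`scope` must be a single group id or NA.", call. = FALSE)
  if (is.na(scope)) return(universe$species)
  if (!scope %in% universe$group) {
    stop("`scope` must be an existing group id or NA (global).", call. = FALSE)
  }
  universe$species[universe$group == scope]
}

# Scope derived from a composition vector: the single group all atoms belong
# to, or NA when the composition mixes groups.
composition_scope <- function(composition, species_group) {
  g <- unique(species_group[composition > 0L])
  if (length(g) == 1L) g else NA_integer_
}
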