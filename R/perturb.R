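#' Perturbation configuration
#'
#' @param theta Magnitude of metabolic perturbations: pair swaps continue
#'   until the cumulative redistributed mass first reaches `theta` times the
#'   total system mass. In `(0, 1]`; `theta = 0` is accepted by the
#'   experiment layer as an unperturbed control.
#' @param n_replace Number of reactions replaced by a genetic perturbation.
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(theta = 0.2, n_replace = 2L) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1,
            is_count(n_replace) || n_replace == 0)
  structure(list(theta = theta, n_replace = as.integer(n_replace)),
            class = "perturbation_config")
}

new_perturbation_record <- function(kind, scope, focal_set, magnitude,
                                    achieved, target_module = NA_integer_,
                                    exhausted = FALSE, pairs = NULL) {
  structure(list(
    kind = kind, scope = scope, focal_set = focal_set,
    magnitude = magnitude, achieved = achieved,
    target_module = target_module, exhausted = exhausted, pairs = pairs
  ), class = "perturbation_record")
}

#' @export
print.perturbation_record <- function(x, ...) {
  cat(sprintf("<perturbation_record> %s/%s: |P| = %d, achieved magnitude %.4f\n",
              x$kind, x$scope, length(x$focal_set), x$achieved))
  invisible(x)
}

#' Metabolic perturbation: mass-conserving concentration shock
#'
#' Redistributes metabolite masses by swapping the total masses of randomly
#' formed metabolite pairs (each swap conserves total mass exactly) until the
#' cumulative perturbed mass `sum_i |M_i - M'_i|` first reaches
#' `theta * total mass`. With local scope the pairs are drawn inside one
#' uniformly chosen module of `partition` until the threshold is met or the
#' module runs out of metabolites. With global scope the metabolites are
#' split into a light set S (the fewest lightest metabolites whose total mass
#' exceeds the threshold) and a heavy set L (everything heavier), and each
#' pair takes one member from each, so large masses land on rare metabolites
#' and vice versa.
#'
#' @param state Pre-perturbation [concentration_state()] (at equilibrium).
#' @param system A `reaction_system`.
#' @param scope `"global"` or `"local"`.
#' @param theta Perturbation magnitude in `(0, 1]`.
#' @param partition A `module_partition` (required for local scope).
#' @return A list with `state` (perturbed) and `record`
#'   (a `perturbation_record` whose `focal_set` is all paired metabolites).
#' @export
metabolic_perturbation <- function(state, system, scope = c("global", "local"),
                                   theta = 0.2, partition = NULL) {
  scope <- match.arg(scope)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1) {
    stop("`theta` must be in (0, 1]", call. = FALSE)
  }
  ids <- system$molecules$id
  mass <- stats::setNames(as.numeric(system$molecules$mass), ids)
  conc <- stats::setNames(state_for_system(state, system), ids)
  M <- conc * mass
  M_total <- sum(M)
  threshold <- theta * M_total

  if (scope == "local") {
    if (is.null(partition)) stop("local scope needs a partition", call. = FALSE)
    modules <- unique(unname(partition$membership))
    modules <- modules[sample.int(length(modules))]
    pool <- character(0)
    target <- NA_integer_
    for (md in modules) {
      cand <- names(partition$membership)[partition$membership == md]
      cand <- intersect(cand, ids)
      if (length(cand) >= 2L) { pool <- cand; target <- md; break }
    }
    if (length(pool) < 2L) stop("no module with at least two metabolites",
                                call. = FALSE)
    pool <- pool[sample.int(length(pool))]
    n_pairs <- length(pool) %/% 2L
    first <- pool[2 * seq_len(n_pairs) - 1L]
    second <- pool[2 * seq_len(n_pairs)]
  } else {
    ord <- names(sort(M))
    cum <- cumsum(M[ord])
    n_S <- which(cum > threshold)[1L]
    if (is.na(n_S)) n_S <- length(ord)
    S <- ord[seq_len(n_S)]
    L <- setdiff(ord, S)
    if (length(L) == 0L) stop("degenerate mass distribution: empty heavy set",
                              call. = FALSE)
    n_pairs <- min(length(S), length(L))
    first <- L[sample.int(length(L), n_pairs)]
    second <- S[sample.int(length(S), n_pairs)]
    target <- NA_integer_
  }

  new_M <- M
  used <- 0L
  cum_change <- 0
  for (p in seq_len(n_pairs)) {
    i <- first[p]; j <- second[p]
    delta <- 2 * abs(M[i] - M[j])
    tmp <- new_M[i]; new_M[i] <- new_M[j]; new_M[j] <- tmp
    cum_change <- cum_change + delta
    used <- p
    if (cum_change >= threshold) break
  }
  exhausted <- cum_change < threshold
  focal <- c(first[seq_len(used)], second[seq_len(used)])
  new_conc <- conc
  new_conc[focal] <- new_M[focal] / mass[focal]

  record <- new_perturbation_record(
    kind = "metabolic", scope = scope, focal_set = focal,
    magnitude = theta,
    achieved = unname(cum_change / M_total),
    target_module = target, exhausted = exhausted,
    pairs = data.frame(a = first[seq_len(used)], b = second[seq_len(used)])
  )
  list(state = concentration_state(new_conc, time = attr(state, "time")),
       record = record)
}

#' Genetic perturbation: replace reactions under the construction rules
#'
#' Removes `n_replace` randomly chosen reactions and generates replacements of
#' the same locality class (within-group reactions are rebuilt in their
#' group, bridges as bridges), following the same rules as the original
#' construction — so the reaction count and the within-group/bridge
#' composition are preserved. With local scope the removed reactions are
#' drawn from one uniformly chosen module (a reaction belongs to the module
#' of the majority of its metabolites). Metabolites left without any reaction
#' are deleted and newly created metabolites enter the state; the deleted
#' mass is split equally among the new metabolites (or among all survivors
#' when nothing new was created), so total mass is conserved exactly.
#' Replacement reactions get fresh signed rate constants and sources/sinks
#' are re-derived.
#'
#' @param system A `reaction_system` with direction-normalized rates.
#' @param state Pre-perturbation [concentration_state()].
#' @param scope `"global"` or `"local"`.
#' @param n_replace Number of reactions to replace.
#' @param partition A `module_partition` (required for local scope).
#' @param kin_config A [kinetics_config()] for the new rate constants.
#' @return A list with `system`, `state` and `record`; the record's
#'   `focal_set` is the union of the surviving participants of removed and
#'   added reactions.
#' @export
genetic_perturbation <- function(system, state, scope = c("global", "local"),
                                 n_replace = 2L, partition = NULL,
                                 kin_config = kinetics_config()) {
  scope <- match.arg(scope)
  stopifnot(inherits(system, "reaction_system"))
  n_rxn <- nrow(system$reactions)
  if (n_replace > n_rxn) stop("n_replace exceeds the reaction count", call. = FALSE)
  if (n_replace == 0L) {
    return(list(system = system, state = state,
                record = new_perturbation_record(
                  "genetic", scope, character(0), 0L, 0)))
  }

  if (scope == "local") {
    if (is.null(partition)) stop("local scope needs a partition", call. = FALSE)
    rxn_module <- vapply(seq_len(n_rxn), function(i) {
      assign_reaction_module(system$reactions[i, ], partition)
    }, integer(1))
    md <- sample_one(unique(rxn_module))
    cand <- which(rxn_module == md)
    removed_idx <- cand[sample.int(length(cand), min(n_replace, length(cand)))]
    target <- md
  } else {
    removed_idx <- sample.int(n_rxn, n_replace)
    target <- NA_integer_
  }

  removed <- system$reactions[removed_idx, ]
  removed_parts <- unique(unlist(c(removed$substrates, removed$products),
                                 use.names = FALSE))

  # Generate replacements of the removed localities under the original
  # construction rules. All current reactions (including the removed ones)
  # stay in the duplicate hash, so a replacement cannot trivially recreate
  # what it replaces.
  kept <- system$reactions[-removed_idx, ]
  res <- tryCatch(
    run_generator_core(system$composition,
                       reactions_as_index_lists(system),
                       removed$locality, system$config),
    modmet_generation_error = function(e) e
  )
  if (inherits(res, "modmet_generation_error")) stop(res)
  with_new <- build_system(res, system$config, prune = FALSE,
                           ids = system$molecules$id)
  added_parts <- unique(unlist(c(with_new$reactions$substrates,
                                 with_new$reactions$products),
                               use.names = FALSE))

  new_system <- with_new
  new_system$reactions <- dplyr::bind_rows(kept, with_new$reactions)
  new_system$reactions$rid <- paste0("R", seq_len(nrow(new_system$reactions)))
  new_system <- prune_unused_molecules(new_system)
  new_system$outflow_coefficient <- system$outflow_coefficient
  new_system$inflow_weights <- system$inflow_weights
  new_system$seed <- system$seed

  # rates: kept reactions keep theirs; replacements draw fresh signed
  # constants whose sign sets their direction
  n_new <- length(removed_idx)
  k_new <- stats::rnorm(n_new, 0, kin_config$rate_sd)
  new_system$reactions$rate <- c(kept$rate, abs(k_new))
  flip_new <- nrow(kept) + which(k_new < 0)
  surv <- new_system$molecules$id

  ## Mass bookkeeping
  old_ids <- system$molecules$id
  conc <- stats::setNames(state_for_system(state, system), old_ids)
  old_mass <- stats::setNames(as.numeric(system$molecules$mass), old_ids)
  deleted <- setdiff(old_ids, surv)
  created <- setdiff(surv, old_ids)
  new_mass <- stats::setNames(as.numeric(new_system$molecules$mass), surv)
  new_conc <- stats::setNames(numeric(length(surv)), surv)
  common <- intersect(old_ids, surv)
  new_conc[common] <- conc[common]
  deleted_mass <- sum(conc[deleted] * old_mass[deleted])
  if (length(created) > 0L) {
    share <- deleted_mass / length(created)
    new_conc[created] <- share / new_mass[created]
  } else if (deleted_mass > 0) {
    share <- deleted_mass / length(surv)
    new_conc <- new_conc + share / new_mass
  }

  new_system <- flip_reactions(new_system, flip_new)
  new_system <- assign_sources_sinks(new_system)

  focal <- intersect(unique(c(removed_parts, added_parts)), surv)
  record <- new_perturbation_record(
    kind = "genetic", scope = scope, focal_set = focal,
    magnitude = n_new,
    achieved = if (sum(conc * old_mass) > 0) {
      deleted_mass / sum(conc * old_mass)
    } else 0,
    target_module = target,
    pairs = NULL
  )
  record$deleted <- deleted
  record$created <- created
  list(system = new_system,
       state = concentration_state(new_conc, time = attr(state, "time")),
       record = record)
}

sample_one <- function(x) x[sample.int(length(x), 1L)]
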