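#' Unrobustness: mean rescaled concentration change
#'
#' Averages, over a set of metabolites, the absolute concentration change
#' between two equilibria rescaled by the per-metabolite quadratic mean
#' `rms_i = sqrt((c_i^2 + c_i'^2) / 2)`. The quadratic mean damps the
#' numerical noise of near-zero concentrations in the denominator. A
#' metabolite that is zero in both states contributes 0 (an unchanged absent
#' metabolite is maximally robust). Each term lies in `[0, sqrt(2)]`, and the
#' measure is invariant under a global rescaling of all concentrations.
#'
#' @param before,after [concentration_state()]s (or named numeric vectors).
#' @param subset Molecule ids to average over; defaults to the ids present in
#'   both states. Ids absent from either state are dropped (a genetic
#'   perturbation changes the metabolite set; the measure is defined over the
#'   metabolites present both before and after).
#' @return A number in `[0, sqrt(2)]`.
#' @examples
#' unrobustness(c(a = 1), c(a = 3))  # 2 / sqrt(5)
#' @export
unrobustness <- function(before, after, subset = NULL) {
  b <- as.numeric(before); names(b) <- names(before)
  a <- as.numeric(after); names(a) <- names(after)
  if (is.null(subset)) subset <- intersect(names(b), names(a))
  subset <- intersect(intersect(subset, names(b)), names(a))
  if (length(subset) == 0L) stop("empty metabolite subset", call. = FALSE)
  b <- b[subset]; a <- a[subset]
  rms <- sqrt((b^2 + a^2) / 2)
  term <- ifelse(rms == 0, 0, abs(b - a) / rms)
  mean(term)
}

#' Robustness: reciprocal unrobustness
#'
#' @inheritParams unrobustness
#' @return A positive number, or `Inf` when the two states agree exactly on
#'   the subset.
#' @export
robustness <- function(before, after, subset = NULL) {
  u <- unrobustness(before, after, subset)
  if (u == 0) Inf else 1 / u
}

#' The focal set of a perturbation
#'
#' The metabolites directly affected: for a metabolic perturbation the paired
#' metabolites whose masses were swapped; for a genetic perturbation the
#' surviving metabolites participating in a removed or added reaction.
#'
#' @param record A `perturbation_record`.
#' @return Character vector of molecule ids.
#' @export
focal_set_of <- function(record) {
  stopifnot(inherits(record, "perturbation_record"))
  record$focal_set
}
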