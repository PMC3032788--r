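# Fixture builders used across the test files. All systems are constructed
# in code; nothing is read from disk.

# The combustion worked example: 2 H2 + O2 -> 2 H2O over species (H, O).
water_system <- function(rate = 1) {
  comp <- rbind(H2 = c(2L, 0L), O2 = c(0L, 2L), H2O = c(2L, 1L))
  reaction_system(comp, tibble::tibble(
    substrates = list(c("H2", "O2")), sub_mult = list(c(2L, 1L)),
    products = list("H2O"), prod_mult = list(2L),
    rate = rate
  ))
}

# A linear chain A -> B -> C of single-atom isomers (all mass 1).
chain_system <- function(rates = c(1, 1)) {
  comp <- rbind(A = 1L, B = 1L, C = 1L)
  reaction_system(comp, tibble::tibble(
    substrates = list("A", "B"), sub_mult = list(1L, 1L),
    products = list("B", "C"), prod_mult = list(1L, 1L),
    rate = rates
  ))
}

# Unimolecular isomerization A -> B (used for the closed-form exponential).
ab_system <- function(rate = 1) {
  comp <- rbind(A = 1L, B = 1L)
  reaction_system(comp, tibble::tibble(
    substrates = list("A"), sub_mult = list(1L),
    products = list("B"), prod_mult = list(1L),
    rate = rate
  ))
}

# 2A -> B with B twice the mass of A.
dimer_system <- function(rate = 1) {
  comp <- rbind(A = 1L, B = 2L)
  reaction_system(comp, tibble::tibble(
    substrates = list("A"), sub_mult = list(2L),
    products = list("B"), prod_mult = list(1L),
    rate = rate
  ))
}

state_of <- function(system, values, time = 0) {
  concentration_state(stats::setNames(values, system$molecules$id), time)
}

# closed-system kinetics: no source/sink flows
closed_kinetics <- function(...) kinetics_config(lambda = 0, ...)

# A connected random graph on n named vertices (resampled until >= 1 edge).
random_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= 1L) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# k disjoint cliques of the given sizes, as one graph.
clique_graph <- function(sizes) {
  gs <- lapply(sizes, igraph::make_full_graph)
  g <- Reduce(igraph::disjoint_union, gs)
  igraph::V(g)$name <- paste0("v", seq_len(sum(sizes)))
  g
}

# A small generated-and-parameterized system ready for kinetics.
prepared_system <- function(seed, gen_config = generator_config(),
                            kin_config = kinetics_config()) {
  set.seed(seed)
  sys <- generate_reaction_system(gen_config, seed = seed)
  sample_rate_constants(sys, kin_config)
}
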