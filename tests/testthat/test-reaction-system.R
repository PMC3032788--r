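test_that("atom universes partition species into equal groups", {
  uni <- generate_atoms(3, 2)
  expect_equal(nrow(uni), 6L)
  expect_equal(unname(table(uni$group)), rep(2L, 3L), ignore_attr = TRUE)

  single <- generate_atoms(1, 5)
  expect_equal(unique(single$group), 1L)

  expect_error(generate_atoms(0, 2), "positive")
  expect_error(generate_atoms(3, -1), "positive")
})

test_that("molecule sampling respects scope and size", {
  uni <- generate_atoms(3, 4)
  set.seed(1)
  group1_species <- uni$species[uni$group == 1L]
  for (i in 1:1000) {
    mol <- sample_molecule(uni, scope = 1L, max_size = 4L)
    used <- which(mol$composition > 0L)
    expect_true(all(used %in% group1_species))
    expect_true(sum(mol$composition) >= 1L && sum(mol$composition) <= 4L)
    expect_identical(mol$scope, 1L)
  }
  one_atom <- sample_molecule(uni, scope = 1L, max_size = 1L)
  expect_equal(sum(one_atom$composition), 1L)

  set.seed(2)
  global_groups <- unique(unlist(lapply(1:200, function(i) {
    uni$group[sample_molecule(uni, scope = NA, max_size = 4L)$composition > 0L]
  })))
  expect_setequal(global_groups, 1:3)

  expect_error(sample_molecule(uni, scope = 99L), "group id")
})

test_that("mass conservation check matches the combustion example", {
  comp <- rbind(H2 = c(2L, 0L), O2 = c(0L, 2L), H2O = c(2L, 1L))
  water <- list(substrates = c("H2", "O2"), sub_mult = c(2L, 1L),
                products = "H2O", prod_mult = 2L)
  expect_true(check_mass_conservation(water, comp))

  broken <- water
  broken$prod_mult <- 1L
  expect_false(check_mass_conservation(broken, comp))

  iso <- rbind(A = c(1L, 1L), B = c(1L, 1L))
  expect_true(check_mass_conservation(
    list(substrates = "A", sub_mult = 1L, products = "B", prod_mult = 1L), iso))

  expect_error(check_mass_conservation(
    list(substrates = "X", sub_mult = 1L, products = "H2O", prod_mult = 1L),
    comp), "unknown molecule")
})

test_that("the locality mix follows the within-group fraction f", {
  cfg <- function(f) generator_config(n_reactions = 60L, local_fraction = f)
  all_local <- generate_reaction_system(cfg(1), seed = 1)
  expect_false(anyNA(all_local$reactions$locality))

  all_bridge <- generate_reaction_system(cfg(0), seed = 1)
  expect_true(all(is.na(all_bridge$reactions$locality)))

  mixed <- generate_reaction_system(cfg(0.75), seed = 1)
  expect_equal(sum(!is.na(mixed$reactions$locality)), 45L)
  expect_equal(nrow(mixed$reactions), 60L)
})

test_that("every generated reaction conserves mass and honors locality", {
  for (seed in 1:3) {
    sys <- generate_reaction_system(
      generator_config(n_reactions = 100L, local_fraction = 0.7), seed = seed)
    scope <- stats::setNames(sys$molecules$scope, sys$molecules$id)
    for (i in seq_len(nrow(sys$reactions))) {
      rx <- sys$reactions[i, ]
      expect_true(check_mass_conservation(rx, sys$composition))
      parts <- c(rx$substrates[[1]], rx$products[[1]])
      loc <- rx$locality
      if (!is.na(loc)) {
        # within-group: every participant is built from that group's atoms
        expect_true(all(scope[parts] == loc))
      } else {
        # bridge: a substrate in one group, a product in another
        ss <- scope[rx$substrates[[1]]]
        ps <- scope[rx$products[[1]]]
        pairs <- expand.grid(s = ss[!is.na(ss)], p = ps[!is.na(ps)])
        expect_true(any(pairs$s != pairs$p))
      }
    }
  }
})

test_that("generation is reproducible from config and seed", {
  cfg <- generator_config(n_reactions = 80L)
  a <- generate_reaction_system(cfg, seed = 11)
  b <- generate_reaction_system(cfg, seed = 11)
  expect_identical(a, b)

  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  write_system_json(a, fa); write_system_json(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("sources and sinks are the flow-boundary metabolites", {
  chain <- chain_system()
  expect_identical(chain$sources, "A")
  expect_identical(chain$sinks, "C")

  sys <- prepared_system(5, generator_config(n_reactions = 80L))
  sub_ids <- unique(unlist(sys$reactions$substrates))
  prod_ids <- unique(unlist(sys$reactions$products))
  expect_setequal(sys$sources, setdiff(sys$molecules$id, prod_ids))
  expect_setequal(sys$sinks, setdiff(sys$molecules$id, sub_ids))
  expect_true(all(sys$inflow_weights > 0))
  expect_setequal(names(sys$inflow_weights), sys$sources)
  # every molecule participates in at least one reaction
  expect_setequal(union(sub_ids, prod_ids), sys$molecules$id)
})

test_that("JSON round trip is lossless", {
  sys <- prepared_system(7, generator_config(n_reactions = 60L))
  path <- tempfile(fileext = ".json")
  write_system_json(sys, path)
  back <- read_system_json(path)
  expect_identical(back$molecules, sys$molecules)
  expect_identical(back$composition, sys$composition)
  expect_identical(back$reactions$rate, sys$reactions$rate)
  expect_identical(back$reactions$substrates, sys$reactions$substrates)
  expect_identical(back$reactions$locality, sys$reactions$locality)
  expect_identical(back$sources, sys$sources)
  expect_identical(back$sinks, sys$sinks)
  expect_equal(back$inflow_weights, sys$inflow_weights)
  expect_identical(unclass(back$config), unclass(sys$config))
})

test_that("single reactions can be appended under the same rules", {
  sys <- generate_reaction_system(generator_config(n_reactions = 40L), seed = 3)
  grown <- generate_reaction(sys, locality = 1L)
  expect_equal(nrow(grown$reactions), 41L)
  new_rx <- grown$reactions[41L, ]
  expect_true(check_mass_conservation(new_rx, grown$composition))
  expect_identical(new_rx$locality, 1L)

  bridged <- generate_reaction(sys, locality = NA)
  expect_true(is.na(bridged$reactions$locality[41L]))
  expect_error(generate_reaction(sys, locality = 9L), "group id")
})

test_that("higher within-group fraction gives higher maximized modularity", {
  q_at <- function(f, seeds) {
    vapply(seeds, function(s) {
      sys <- generate_reaction_system(
        generator_config(n_reactions = 120L, local_fraction = f), seed = s)
      detect_modules(substance_graph(sys))$Q
    }, numeric(1))
  }
  q_low <- q_at(0.5, 1:15)
  q_high <- q_at(1.0, 1:15)
  expect_gt(mean(q_high), mean(q_low))
})
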