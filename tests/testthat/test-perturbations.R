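# A two-metabolite fixture with masses 3 and 1 (concentrations chosen so the
# metabolite masses are M = (3, 1)).
two_mass_system <- function() {
  comp <- rbind(H = c(3L, 0L), L = c(1L, 0L))
  reaction_system(comp[, 1, drop = FALSE], tibble::tibble(
    substrates = list("H"), sub_mult = list(1L),
    products = list("L"), prod_mult = list(3L),
    rate = 1
  ))
}

test_that("a single swap exchanges metabolite masses exactly", {
  sys <- two_mass_system()
  st <- state_of(sys, c(1, 1))  # M = (3, 1), total 4
  out <- metabolic_perturbation(st, sys, "global", theta = 0.2)
  m_after <- as.numeric(out$state) * sys$molecules$mass
  expect_equal(sort(m_after), c(1, 3))
  expect_equal(total_mass(out$state, sys), 4)
  # Sum |M - M'| = 4, relative to total mass 4
  expect_equal(out$record$achieved, 1)
  expect_setequal(out$record$focal_set, c("H", "L"))
  expect_equal(nrow(out$record$pairs), 1L)
})

test_that("a vanishing threshold still swaps exactly one pair", {
  sys <- prepared_system(41, generator_config(n_reactions = 80L))
  set.seed(41)
  st <- sample_initial_state(sys, kinetics_config())
  out <- metabolic_perturbation(st, sys, "global", theta = 1e-9)
  expect_equal(length(out$record$focal_set), 2L)
  expect_equal(nrow(out$record$pairs), 1L)

  expect_error(metabolic_perturbation(st, sys, "global", theta = 0),
               "theta")
  expect_error(metabolic_perturbation(st, sys, "global", theta = 1.5),
               "theta")
})

test_that("global pairs bridge the heavy and light mass sets", {
  sys <- prepared_system(43, generator_config(n_reactions = 80L))
  set.seed(43)
  st <- sample_initial_state(sys, kinetics_config())
  M <- as.numeric(st)[match(sys$molecules$id, names(st))] *
    sys$molecules$mass
  names(M) <- sys$molecules$id
  for (rep in 1:20) {
    out <- metabolic_perturbation(st, sys, "global", theta = 0.2)
    pairs <- out$record$pairs
    # every heavy-side member outweighs every light-side member
    expect_gte(min(M[pairs$a]), max(M[pairs$b]))
    expect_gte(out$record$achieved, 0.2)
  }
})

test_that("local metabolic perturbations stay inside one module", {
  sys <- prepared_system(47, generator_config(n_reactions = 120L))
  part <- detect_modules(substance_graph(sys))
  set.seed(47)
  st <- sample_initial_state(sys, kinetics_config())
  for (rep in 1:20) {
    out <- metabolic_perturbation(st, sys, "local", theta = 0.2,
                                  partition = part)
    mods <- unique(part$membership[out$record$focal_set])
    expect_length(mods, 1L)
    expect_equal(mods, out$record$target_module, ignore_attr = TRUE)
    # untouched metabolites keep their concentrations
    untouched <- setdiff(names(st), out$record$focal_set)
    expect_identical(as.numeric(out$state[untouched]),
                     as.numeric(st[untouched]))
  }
  expect_error(metabolic_perturbation(st, sys, "local", theta = 0.2),
               "partition")
})

test_that("both perturbation kinds conserve total mass exactly", {
  sys <- prepared_system(53, generator_config(n_reactions = 120L))
  part <- detect_modules(substance_graph(sys))
  set.seed(53)
  st <- sample_initial_state(sys, kinetics_config())
  m0 <- total_mass(st, sys)
  for (rep in 1:50) {
    met <- metabolic_perturbation(st, sys,
                                  if (rep %% 2) "global" else "local",
                                  theta = 0.2, partition = part)
    expect_equal(total_mass(met$state, sys) / m0, 1, tolerance = 1e-12)

    gen <- genetic_perturbation(sys, st,
                                if (rep %% 2) "global" else "local",
                                n_replace = 2L, partition = part)
    expect_equal(total_mass(gen$state, gen$system) / m0, 1,
                 tolerance = 1e-12)
  }
})

test_that("genetic replacement preserves the reaction-set structure", {
  sys <- prepared_system(59, generator_config(n_reactions = 100L))
  part <- detect_modules(substance_graph(sys))
  set.seed(59)
  st <- sample_initial_state(sys, kinetics_config())
  for (rep in 1:10) {
    out <- genetic_perturbation(sys, st, "global", n_replace = 3L,
                                partition = part)
    expect_equal(nrow(out$system$reactions), nrow(sys$reactions))
    expect_equal(sum(is.na(out$system$reactions$locality)),
                 sum(is.na(sys$reactions$locality)))
    expect_equal(table(out$system$reactions$locality),
                 table(sys$reactions$locality))
    expect_true(all(out$record$focal_set %in% out$system$molecules$id))
    # exactly n_replace reactions differ
    key <- function(s) {
      side <- function(ids, mult) {
        o <- order(ids)
        paste(ids[o], mult[o], sep = "x", collapse = "+")
      }
      vapply(seq_len(nrow(s$reactions)), function(i) {
        rx <- s$reactions[i, ]
        paste(sort(c(side(rx$substrates[[1]], rx$sub_mult[[1]]),
                     side(rx$products[[1]], rx$prod_mult[[1]]))),
              collapse = "=")
      }, character(1))
    }
    expect_equal(sum(!key(sys) %in% key(out$system)), 3L)
  }
})

test_that("deleted mass is split equally among created metabolites", {
  sys <- prepared_system(61, generator_config(n_reactions = 100L))
  part <- detect_modules(substance_graph(sys))
  set.seed(61)
  st <- sample_initial_state(sys, kinetics_config())
  seen_split <- FALSE
  for (rep in 1:60) {
    out <- genetic_perturbation(sys, st, "global", n_replace = 3L,
                                partition = part)
    del <- out$record$deleted
    cre <- out$record$created
    if (length(del) > 0L && length(cre) > 0L) {
      m_del <- sum(as.numeric(st[del]) *
                     sys$molecules$mass[match(del, sys$molecules$id)])
      mass_new <- out$system$molecules$mass[
        match(cre, out$system$molecules$id)]
      got <- as.numeric(out$state[cre]) * mass_new
      expect_equal(got, rep(m_del / length(cre), length(cre)),
                   ignore_attr = TRUE)
      seen_split <- TRUE
    }
  }
  expect_true(seen_split)
})

test_that("an empty genetic perturbation is the identity", {
  sys <- prepared_system(67, generator_config(n_reactions = 60L))
  set.seed(67)
  st <- sample_initial_state(sys, kinetics_config())
  out <- genetic_perturbation(sys, st, "global", n_replace = 0L)
  expect_identical(out$system, sys)
  expect_identical(out$state, st)
  expect_length(out$record$focal_set, 0L)

  expect_error(genetic_perturbation(sys, st, "global",
                                    n_replace = 10000L), "exceeds")
})

test_that("local genetic perturbations draw reactions from one module", {
  sys <- prepared_system(71, generator_config(n_reactions = 100L))
  part <- detect_modules(substance_graph(sys))
  set.seed(71)
  st <- sample_initial_state(sys, kinetics_config())
  out <- genetic_perturbation(sys, st, "local", n_replace = 2L,
                              partition = part)
  expect_false(is.na(out$record$target_module))
  expect_true(out$record$target_module %in% part$membership)
})
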