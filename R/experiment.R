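discard_error <- function(reason) {
  stop(structure(class = c("modmet_discard", "error", "condition"),
                 list(message = reason, call = NULL)))
}

#' Run one full realization of the protocol
#'
#' Generates a reaction system, draws rate constants and an initial state,
#' relaxes to the pre-perturbation equilibrium, and then — independently for
#' each of the four perturbation classes (metabolic/genetic x local/global),
#' all starting from the same equilibrium of the same system — applies the
#' perturbation, relaxes to the new equilibrium and records the system-wide
#' robustness, the focal robustness and the relaxation time. The maximized
#' substance-graph modularity Q of the unperturbed system is recorded
#' alongside.
#'
#' @param gen_config A [generator_config()].
#' @param kin_config A [kinetics_config()].
#' @param pert_config A [perturbation_config()]. With `theta = 0` the
#'   metabolic classes run as unperturbed controls (infinite robustness).
#' @param seed Integer seed; the realization is fully reproducible from it.
#' @return A `realization_record`: list with `seed`, `f`, `Q`,
#'   `n_metabolites`, `n_reactions` and `results`, a tibble with one row per
#'   perturbation class (`kind`, `scope`, `R_sys`, `R_foc`, `unrobustness_sys`,
#'   `unrobustness_foc`, `tau`, `converged`, `n_focal`, `achieved`).
#' @export
run_realization <- function(gen_config = generator_config(),
                            kin_config = kinetics_config(),
                            pert_config = perturbation_config(),
                            seed = 1L) {
  set.seed(seed)
  system <- tryCatch(
    generate_reaction_system(gen_config),
    modmet_generation_error = function(e) discard_error(conditionMessage(e))
  )
  system <- sample_rate_constants(system, kin_config)
  if (length(system$sources) == 0L || length(system$sinks) == 0L) {
    discard_error("generated system has no sources or no sinks")
  }
  graph <- substance_graph(system)
  if (igraph::ecount(graph) == 0L) discard_error("edgeless substance graph")
  partition <- detect_modules(graph)

  state0 <- sample_initial_state(system, kin_config)
  eq0 <- relax_or_discard(state0, system, kin_config, "initial relaxation")
  e0 <- eq0$final_state

  classes <- tidyr::expand_grid(kind = c("metabolic", "genetic"),
                                scope = c("local", "global"))
  rows <- vector("list", nrow(classes))
  for (i in seq_len(nrow(classes))) {
    rows[[i]] <- measure_class(classes$kind[i], classes$scope[i],
                               system, e0, partition, kin_config, pert_config)
  }
  structure(list(
    seed = as.integer(seed),
    f = gen_config$local_fraction,
    Q = partition$Q,
    n_metabolites = nrow(system$molecules),
    n_reactions = nrow(system$reactions),
    results = dplyr::bind_rows(rows)
  ), class = "realization_record")
}

relax_or_discard <- function(state, system, kin_config, what) {
  res <- tryCatch(
    relax(state, system, kin_config),
    modmet_blowup_error = function(e) {
      discard_error(paste0(what, ": numerical blow-up"))
    }
  )
  if (!res$converged) discard_error(paste0(what, ": no convergence"))
  res
}

measure_class <- function(kind, scope, system, e0, partition,
                          kin_config, pert_config) {
  if (kind == "metabolic") {
    if (pert_config$theta == 0) {
      # unperturbed control
      return(class_row(kind, scope, e0, e0, character(0), 0, 0, TRUE))
    }
    p <- metabolic_perturbation(e0, system, scope, pert_config$theta, partition)
    res <- relax_or_discard(p$state, system, kin_config,
                            paste(kind, scope, "re-relaxation"))
    e1 <- res$final_state
    after_system <- system
  } else {
    p <- tryCatch(
      genetic_perturbation(system, e0, scope, pert_config$n_replace,
                           partition, kin_config),
      modmet_generation_error = function(e) {
        discard_error(paste("genetic replacement failed:", conditionMessage(e)))
      }
    )
    after_system <- p$system
    if (length(after_system$sources) == 0L || length(after_system$sinks) == 0L) {
      discard_error("perturbed system has no sources or no sinks")
    }
    res <- relax_or_discard(p$state, after_system, kin_config,
                            paste(kind, scope, "re-relaxation"))
    e1 <- res$final_state
  }
  class_row(kind, scope, e0, e1, focal_set_of(p$record),
            res$tau, p$record$achieved, res$converged)
}

class_row <- function(kind, scope, e0, e1, focal, tau, achieved, converged) {
  u_sys <- unrobustness(e0, e1)
  u_foc <- if (length(focal) > 0L) {
    focal <- intersect(focal, intersect(names(e0), names(e1)))
    if (length(focal) > 0L) unrobustness(e0, e1, focal) else NA_real_
  } else 0
  tibble::tibble(
    kind = kind, scope = scope,
    R_sys = if (u_sys == 0) Inf else 1 / u_sys,
    R_foc = if (is.na(u_foc)) NA_real_ else if (u_foc == 0) Inf else 1 / u_foc,
    unrobustness_sys = u_sys, unrobustness_foc = u_foc,
    tau = tau, converged = converged,
    n_focal = length(focal), achieved = achieved
  )
}

#' @export
print.realization_record <- function(x, ...) {
  cat(sprintf("<realization_record> seed %d: f = %.3f, Q = %.4f, N_M = %d, N_R = %d\n",
              x$seed, x$f, x$Q, x$n_metabolites, x$n_reactions))
  print(x$results)
  invisible(x)
}

#' @export
tidy.realization_record <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(seed = x$seed, f = x$f, Q = x$Q,
                   n_metabolites = x$n_metabolites,
                   n_reactions = x$n_reactions),
    x$results
  )
}

#' Ensemble sweep over the modularity control parameter
#'
#' Runs `n_realizations` retained realizations for every value of the
#' within-group reaction fraction `f`, discarding and replacing realizations
#' that fail generation or convergence (an excessive discard rate aborts).
#' Per `(f, kind, scope)` cell the mean and standard error of Q, the
#' robustness measures and the relaxation time are aggregated.
#'
#' @param f_values Numeric vector of within-group fractions to sweep.
#' @param n_realizations Retained realizations per `f` value (at least 2).
#' @param gen_config,kin_config,pert_config Configurations; the generator's
#'   `local_fraction` is overridden by each `f`.
#' @param seed Master seed; it spawns one sub-seed per realization (and
#'   replacement seeds for discarded ones) so the whole sweep is reproducible.
#' @param verbose Print one status line per realization.
#' @return A `modmet_sweep`: list with `results` (one row per realization per
#'   class), `aggregates` (per `(f, kind, scope)` means and standard errors),
#'   and `discards` (seed, f, reason).
#' @export
run_sweep <- function(f_values = c(0.5, 0.625, 0.75, 0.875, 1.0),
                      n_realizations = 50L,
                      gen_config = generator_config(),
                      kin_config = kinetics_config(),
                      pert_config = perturbation_config(),
                      seed = 1L,
                      verbose = FALSE) {
  stopifnot(length(f_values) >= 1L, n_realizations >= 2L)
  set.seed(seed)
  seed_pool <- sample.int(.Machine$integer.max - 1L,
                          length(f_values) * n_realizations * 20L)
  pool_pos <- 0L
  next_seed <- function() {
    pool_pos <<- pool_pos + 1L
    if (pool_pos > length(seed_pool)) stop("seed pool exhausted", call. = FALSE)
    seed_pool[pool_pos]
  }

  rows <- list()
  discards <- list()
  for (f in f_values) {
    gc_f <- gen_config
    gc_f$local_fraction <- f
    retained <- 0L
    attempts <- 0L
    while (retained < n_realizations) {
      s <- next_seed()
      attempts <- attempts + 1L
      rec <- tryCatch(
        run_realization(gc_f, kin_config, pert_config, seed = s),
        modmet_discard = function(e) e
      )
      if (inherits(rec, "modmet_discard")) {
        discards[[length(discards) + 1L]] <-
          tibble::tibble(seed = s, f = f, reason = conditionMessage(rec))
        if (verbose) message(sprintf("f=%.3f seed=%d DISCARDED: %s",
                                     f, s, conditionMessage(rec)))
        # a persistently excessive discard rate (> 50% once the attempt count
        # dwarfs the requested ensemble) aborts with a diagnostic
        if (attempts >= max(20L, 4L * n_realizations) &&
            (attempts - retained) / attempts > 0.5) {
          stop(sprintf(
            "excessive discard rate at f = %.3f (%d of %d attempts failed)",
            f, attempts - retained, attempts), call. = FALSE)
        }
        next
      }
      retained <- retained + 1L
      rows[[length(rows) + 1L]] <- tidy(rec)
      if (verbose) message(sprintf("f=%.3f seed=%d N_M=%d Q=%.4f",
                                   f, s, rec$n_metabolites, rec$Q))
    }
  }
  results <- dplyr::bind_rows(rows)
  new_sweep(results, dplyr::bind_rows(discards),
            list(f_values = f_values, n_realizations = n_realizations,
                 seed = seed))
}

new_sweep <- function(results, discards, meta) {
  se <- function(x) stats::sd(x) / sqrt(sum(is.finite(x)))
  fin_mean <- function(x) mean(x[is.finite(x)])
  aggregates <- results |>
    dplyr::group_by(.data$f, .data$kind, .data$scope) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_Q = mean(.data$Q), se_Q = se(.data$Q),
      mean_R_sys = fin_mean(.data$R_sys), se_R_sys = se(.data$R_sys),
      mean_R_foc = fin_mean(.data$R_foc), se_R_foc = se(.data$R_foc),
      mean_tau = mean(.data$tau), se_tau = se(.data$tau),
      .groups = "drop"
    )
  structure(list(results = results, aggregates = aggregates,
                 discards = discards, meta = meta),
            class = "modmet_sweep")
}

#' @export
print.modmet_sweep <- function(x, ...) {
  cat(sprintf("<modmet_sweep> %d retained realizations (%d discarded) over f in {%s}\n",
              nrow(x$results) / 4L, nrow(x$discards),
              paste(format(x$meta$f_values), collapse = ", ")))
  print(x$aggregates)
  invisible(x)
}

#' @export
tidy.modmet_sweep <- function(x, ...) x$aggregates

#' @export
glance.modmet_sweep <- function(x, ...) {
  tibble::tibble(
    n_f = length(x$meta$f_values),
    n_realizations = x$meta$n_realizations,
    n_retained = nrow(x$results) / 4L,
    n_discarded = nrow(x$discards),
    seed = x$meta$seed
  )
}

#' Rank-correlation trends of robustness and relaxation time with modularity
#'
#' For each perturbation class and each of the three measures (system-wide
#' robustness, focal robustness, relaxation time), computes the Spearman rank
#' correlation between the per-`f` mean modularity and the per-`f` mean of
#' the measure, with a permutation p-value (exact over all orderings when
#' there are at most 7 aggregate points).
#'
#' @param sweep A `modmet_sweep` from [run_sweep()] with at least 3 `f`
#'   values.
#' @param n_perm Number of random permutations when the exact set is too
#'   large.
#' @return A tibble with columns `kind`, `scope`, `measure`, `rho`,
#'   `direction` and `p_value`.
#' @export
summarize_trends <- function(sweep, n_perm = 999L) {
  agg <- if (inherits(sweep, "modmet_sweep")) sweep$aggregates else sweep
  if (length(unique(agg$f)) < 3L) {
    stop("need at least 3 f values to assess a trend", call. = FALSE)
  }
  measures <- c(R_sys = "mean_R_sys", R_foc = "mean_R_foc", tau = "mean_tau")
  agg |>
    dplyr::group_by(.data$kind, .data$scope) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(names(measures), function(msr) {
        rho <- spearman_rho(d$mean_Q, d[[measures[[msr]]]])
        tibble::tibble(
          measure = msr, rho = rho,
          direction = sign(rho),
          p_value = permutation_p(d$mean_Q, d[[measures[[msr]]]], n_perm)
        )
      })
    }) |>
    dplyr::ungroup()
}

# rho of a constant series is undefined; report 0 (no trend)
spearman_rho <- function(x, y) {
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(r)) 0 else r
}

permutation_p <- function(x, y, n_perm = 999L) {
  obs <- abs(spearman_rho(x, y))
  n <- length(y)
  if (n <= 7L) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, function(p) abs(spearman_rho(x, y[p])))
    mean(stats >= obs - 1e-12)
  } else {
    stats <- replicate(n_perm, abs(spearman_rho(x, sample(y))))
    (sum(stats >= obs - 1e-12) + 1) / (n_perm + 1)
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Plot sweep aggregates against modularity
#'
#' Mean system-wide robustness, focal robustness and relaxation time versus
#' mean maximized modularity, one panel per measure, coloured by perturbation
#' kind and shaped by scope — the trend structure of the model's headline
#' result.
#'
#' @param object A `modmet_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modmet_sweep <- function(object, ...) {
  long <- object$aggregates |>
    tidyr::pivot_longer(c("mean_R_sys", "mean_R_foc", "mean_tau"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = sub("^mean_", "", .data$measure))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_Q, y = .data$value,
                                     colour = .data$kind,
                                     shape = .data$scope)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(
      group = interaction(.data$kind, .data$scope))) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "mean maximized modularity Q", y = NULL,
                  colour = "perturbation", shape = "scope")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
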