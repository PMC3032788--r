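#' Kinetics configuration
#'
#' Parameters of the mass-action simulation. All are in arbitrary
#' concentration/time units.
#'
#' @param dt Euler time step.
#' @param eps Convergence tolerance: integration stops at the first step where
#'   the L1 rate of change `sum(|c(t+dt) - c(t)|) / dt` drops below `eps`;
#'   the relaxation time is the simulated time to that step.
#' @param max_steps Step cap; hitting it marks the trajectory non-converged.
#' @param rate_sd Standard deviation of the zero-mean normal distribution the
#'   signed rate constants are drawn from; the sign sets the reaction
#'   direction.
#' @param init_mean,init_sd Mean and sd of the normal distribution of initial
#'   concentrations (negative draws are clipped to zero).
#' @param lambda Outflow rate coefficient of sink metabolites; `NULL` means
#'   use the system's own `outflow_coefficient`.
#'
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(dt = 0.01, eps = 1e-3, max_steps = 1e6,
                            rate_sd = 1, init_mean = 1, init_sd = 0.5,
                            lambda = NULL) {
  stopifnot(dt > 0, eps > 0, max_steps >= 1,
            rate_sd >= 0, init_sd >= 0,
            is.null(lambda) || lambda >= 0)
  structure(list(
    dt = dt, eps = eps, max_steps = as.integer(max_steps),
    rate_sd = rate_sd, init_mean = init_mean, init_sd = init_sd,
    lambda = lambda
  ), class = "kinetics_config")
}

#' Concentration state
#'
#' A per-metabolite concentration vector at a time point.
#'
#' @param concentrations Named non-negative numeric vector, one entry per
#'   molecule id.
#' @param time Non-negative time stamp.
#' @return A named numeric vector of class `concentration_state` with a
#'   `time` attribute.
#' @export
concentration_state <- function(concentrations, time = 0) {
  stopifnot(!is.null(names(concentrations)), all(concentrations >= 0),
            time >= 0)
  structure(as.numeric(stats::setNames(concentrations, names(concentrations))),
            names = names(concentrations), time = time,
            class = "concentration_state")
}

#' @export
print.concentration_state <- function(x, ...) {
  cat(sprintf("<concentration_state> %d metabolites at t = %g\n",
              length(x), attr(x, "time")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @export
tidy.concentration_state <- function(x, ...) {
  tibble::tibble(id = names(x), concentration = as.numeric(x),
                 time = attr(x, "time"))
}

state_for_system <- function(state, system) {
  ids <- system$molecules$id
  if (is.null(names(state)) || !setequal(names(state), ids)) {
    stop("state keys must match the system's molecule set", call. = FALSE)
  }
  as.numeric(state)[match(ids, names(state))]
}

#' Draw rate constants and normalize reaction directions
#'
#' Each reaction receives a rate constant drawn from a zero-mean normal with
#' sd `rate_sd`. A negative draw means the reaction runs in the opposite
#' direction: substrates and products are swapped and the magnitude is kept
#' as the rate. Because directions change, sources and sinks (and inflow
#' weights for new sources) are re-derived afterwards.
#'
#' @param system A `reaction_system`.
#' @param config A [kinetics_config()].
#' @return The system with non-negative `rate` values and refreshed
#'   sources/sinks.
#' @export
sample_rate_constants <- function(system, config = kinetics_config()) {
  stopifnot(inherits(system, "reaction_system"))
  n <- nrow(system$reactions)
  k <- stats::rnorm(n, 0, config$rate_sd)
  system <- flip_reactions(system, which(k < 0))
  system$reactions$rate <- abs(k)
  assign_sources_sinks(system)
}

flip_reactions <- function(system, idx) {
  if (length(idx) == 0L) return(system)
  rx <- system$reactions
  tmp_s <- rx$substrates[idx]; tmp_m <- rx$sub_mult[idx]
  rx$substrates[idx] <- rx$products[idx]
  rx$sub_mult[idx] <- rx$prod_mult[idx]
  rx$products[idx] <- tmp_s
  rx$prod_mult[idx] <- tmp_m
  system$reactions <- rx
  system
}

#' Draw a random initial concentration state
#'
#' Concentrations are drawn independently from a normal with mean `init_mean`
#' and sd `init_sd`; negative draws are set to zero.
#'
#' @inheritParams sample_rate_constants
#' @return A [concentration_state()] at time 0.
#' @export
sample_initial_state <- function(system, config = kinetics_config()) {
  stopifnot(inherits(system, "reaction_system"))
  c0 <- stats::rnorm(nrow(system$molecules), config$init_mean, config$init_sd)
  c0[c0 < 0] <- 0
  concentration_state(stats::setNames(c0, system$molecules$id), time = 0)
}

## Compressed arrays the integrator consumes.
system_arrays <- function(system, lambda) {
  ids <- system$molecules$id
  rx <- system$reactions
  if (anyNA(rx$rate)) {
    stop("reaction rates are unset; call sample_rate_constants() first",
         call. = FALSE)
  }
  if (any(rx$rate < 0)) {
    stop("rates must be direction-normalized (non-negative)", call. = FALSE)
  }
  sub_idx <- lapply(rx$substrates, function(x) match(x, ids) - 1L)
  prod_idx <- lapply(rx$products, function(x) match(x, ids) - 1L)
  lens <- function(l) vapply(l, length, integer(1))
  shares <- numeric(length(ids))
  if (length(system$sources) > 0L) {
    w <- system$inflow_weights[system$sources]
    shares[match(system$sources, ids)] <- w / sum(w)
  }
  list(
    sub_ptr = c(0L, cumsum(lens(sub_idx))),
    sub_idx = unlist(sub_idx, use.names = FALSE) %||% integer(0),
    sub_mult = as.numeric(unlist(rx$sub_mult, use.names = FALSE) %||% numeric(0)),
    prod_ptr = c(0L, cumsum(lens(prod_idx))),
    prod_idx = unlist(prod_idx, use.names = FALSE) %||% integer(0),
    prod_mult = as.numeric(unlist(rx$prod_mult, use.names = FALSE) %||% numeric(0)),
    rate = rx$rate,
    mass = as.numeric(system$molecules$mass),
    sink_idx = match(system$sinks, ids) - 1L,
    inflow_share = shares,
    lambda = lambda
  )
}

effective_lambda <- function(system, config) {
  config$lambda %||% system$outflow_coefficient
}

#' Time derivative of the concentration state
#'
#' Mass-action kinetics with implicit enzymes: each reaction proceeds at rate
#' `k * prod(c_substrate ^ multiplicity)` and moves multiplicity-weighted
#' concentration from substrates to products. Sink metabolites lose mass at
#' rate `lambda * c`; the same total mass per unit time flows in at the
#' sources, split in proportion to the inflow weights and converted to
#' concentration through molecular mass, so total mass is conserved.
#'
#' @param state A [concentration_state()] matching the system.
#' @param system A `reaction_system` with direction-normalized rates.
#' @param config A [kinetics_config()] (only `lambda` is used).
#' @return Named numeric vector `dc/dt` over the molecule ids.
#' @export
time_derivative <- function(state, system, config = kinetics_config()) {
  arr <- system_arrays(system, effective_lambda(system, config))
  conc <- state_for_system(state, system)
  ids <- system$molecules$id
  dc <- numeric(length(conc))
  rx <- system$reactions
  for (r in seq_len(nrow(rx))) {
    si <- arr$sub_idx[(arr$sub_ptr[r] + 1L):arr$sub_ptr[r + 1L]] + 1L
    sm <- arr$sub_mult[(arr$sub_ptr[r] + 1L):arr$sub_ptr[r + 1L]]
    pi_ <- arr$prod_idx[(arr$prod_ptr[r] + 1L):arr$prod_ptr[r + 1L]] + 1L
    pm <- arr$prod_mult[(arr$prod_ptr[r] + 1L):arr$prod_ptr[r + 1L]]
    v <- arr$rate[r] * prod(conc[si]^sm)
    dc[si] <- dc[si] - sm * v
    dc[pi_] <- dc[pi_] + pm * v
  }
  sinks <- arr$sink_idx + 1L
  out_mass <- arr$lambda * sum(conc[sinks] * arr$mass[sinks])
  dc[sinks] <- dc[sinks] - arr$lambda * conc[sinks]
  src <- arr$inflow_share > 0
  if (out_mass > 0) {
    dc[src] <- dc[src] + arr$inflow_share[src] * out_mass / arr$mass[src]
  }
  stats::setNames(dc, ids)
}

#' One explicit Euler step
#'
#' Advances the state by `c(t + dt) = max(0, c(t) + dt * dc/dt)`; clipping at
#' zero prevents unphysical negative concentrations under Euler overshoot.
#'
#' @inheritParams time_derivative
#' @param dt Time step.
#' @return The advanced [concentration_state()].
#' @export
euler_step <- function(state, system, dt = 0.01, config = kinetics_config()) {
  stopifnot(dt > 0)
  dc <- time_derivative(state, system, config)
  if (any(!is.finite(dc))) {
    stop(structure(class = c("modmet_blowup_error", "error", "condition"),
                   list(message = "non-finite derivative (numerical blow-up)",
                        call = NULL)))
  }
  cn <- pmax(0, as.numeric(state)[match(names(dc), names(state))] + dt * dc)
  concentration_state(stats::setNames(cn, names(dc)),
                      time = attr(state, "time") + dt)
}

#' Relax a system to equilibrium
#'
#' Runs explicit Euler integration until the L1 rate-of-change criterion
#' `sum(|c(t+dt) - c(t)|) / dt < eps` first holds, or `max_steps` is reached.
#' The relaxation time tau is the simulated time from the start to the first
#' step satisfying the criterion.
#'
#' @inheritParams time_derivative
#' @return A `trajectory_result`: list with `final_state`, `tau` (`NA` when
#'   not converged), `converged` and `steps`.
#' @export
relax <- function(state, system, config = kinetics_config()) {
  arr <- system_arrays(system, effective_lambda(system, config))
  conc <- state_for_system(state, system)
  res <- relax_cpp(conc,
                   arr$sub_ptr, arr$sub_idx, arr$sub_mult,
                   arr$prod_ptr, arr$prod_idx, arr$prod_mult,
                   arr$rate, arr$mass, arr$sink_idx, arr$inflow_share,
                   arr$lambda, config$dt, config$eps, config$max_steps)
  if (res$blowup) {
    stop(structure(class = c("modmet_blowup_error", "error", "condition"),
                   list(message = "numerical blow-up during integration",
                        call = NULL)))
  }
  final <- concentration_state(
    stats::setNames(res$conc, system$molecules$id),
    time = attr(state, "time") + res$steps * config$dt)
  structure(list(
    final_state = final,
    tau = if (res$converged) res$steps * config$dt else NA_real_,
    converged = res$converged,
    steps = res$steps
  ), class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %s after %d steps (tau = %s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$steps, format(x$tau)))
  invisible(x)
}

#' @export
glance.trajectory_result <- function(x, ...) {
  tibble::tibble(converged = x$converged, steps = x$steps, tau = x$tau,
                 time = attr(x$final_state, "time"))
}

#' Total mass of a state
#'
#' Sum over metabolites of molecular mass (total atom count) times
#' concentration.
#'
#' @inheritParams time_derivative
#' @return A non-negative number.
#' @export
total_mass <- function(state, system) {
  conc <- state_for_system(state, system)
  sum(conc * system$molecules$mass)
}
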