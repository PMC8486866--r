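#' Simulation configuration
#'
#' @param params A \code{\link{model_params}} object.
#' @param n_steps Number of evolutionary steps (the study design runs
#'   5000).
#' @param metric_interval Steps between community-metric snapshots
#'   (default 100).
#' @param n_replicates Replicates per scenario (the study design runs 20).
#' @param base_seed Base RNG seed; replicate \code{i} runs under seed
#'   \code{base_seed + i}.
#' @param time_model \code{"step"} counts each evolutionary step as one
#'   time unit; \code{"explicit"} accumulates exponentially distributed
#'   waiting times with rate equal to the total mutation rate
#'   \eqn{w = \mu \sum_i N_i}.
#' @param sigma_con_grid Niche widths for multi-scenario experiments.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(params = model_params(), n_steps = 5000L,
                              metric_interval = 100L, n_replicates = 20L,
                              base_seed = 1L,
                              time_model = c("step", "explicit"),
                              sigma_con_grid = seq(0.1, 0.7, by = 0.1)) {
  time_model <- match.arg(time_model)
  stopifnot(n_steps >= 1L, metric_interval >= 1L, n_replicates >= 1L)
  cfg <- list(params = params, n_steps = as.integer(n_steps),
              metric_interval = as.integer(metric_interval),
              n_replicates = as.integer(n_replicates),
              base_seed = as.integer(base_seed), time_model = time_model,
              sigma_con_grid = sigma_con_grid)
  class(cfg) <- "simulation_config"
  cfg
}

#' Seed community of a radiation
#'
#' One monomorphic population at the trait value 0 with abundance 1,
#' labeled species 1 at time 0.  The first equilibrium computation brings
#' it to its carrying capacity.
#'
#' @param params A \code{\link{model_params}} object (unused fields are
#'   accepted for interface symmetry).
#' @return A \code{\link{community_state}} with one population.
#' @export
seed_community <- function(params) {
  community_state(z = 0, N = 1, species_id = 1L, time = 0)
}

#' Waiting time of the explicit-time model
#'
#' Draws \eqn{\Delta t = -(1/w)\ln\rho} with \eqn{\rho} uniform on (0, 1],
#' i.e. an exponential waiting time with mean \eqn{1/w}, where \eqn{w} is
#' the total mutation rate of the system.
#'
#' @param w Total mutation rate (per unit time), must be positive.
#' @param rho Optional uniform deviate (drawn from the session RNG when
#'   omitted); supplying it makes the increment deterministic.
#' @return A strictly positive time increment.
#' @export
explicit_time_increment <- function(w, rho = NULL) {
  if (!is.finite(w) || w <= 0) stop("total mutation rate w must be positive")
  if (is.null(rho)) rho <- 1 - stats::runif(1)   # uniform on (0, 1]
  stopifnot(rho > 0, rho <= 1)
  -log(rho) / w
}

#' One evolutionary step
#'
#' Executes the full step sequence on a community at ecological
#' equilibrium: draw one mutant, evaluate its invasion fitness, run the
#' mutual-invasibility test, apply the verdict (append the mutant, replace
#' its parent, or leave the community unchanged), re-equilibrate, prune
#' extinct populations, advance time, and re-assign species labels
#' (registering any speciation events).
#'
#' @param state A \code{\link{community_state}} at equilibrium.
#' @param params A \code{\link{model_params}} object.
#' @param time_model \code{"step"} or \code{"explicit"} (see
#'   \code{\link{simulation_config}}).
#' @return A list with elements \code{state} (the new equilibrium
#'   community), \code{events} (speciation events emitted this step) and
#'   \code{verdict}.
#' @export
evolutionary_step <- function(state, params, time_model = "step") {
  w <- params$mu * sum(state$N)
  mut <- draw_mutant(state, params)
  dt <- if (time_model == "explicit") explicit_time_increment(w) else 1
  mut$fitness <- invasion_fitness(mut$z_prime, state, params, check = FALSE)
  verdict <- mutual_invasibility(mut, state, params, fitness = mut$fitness)
  if (verdict != "reject") {
    i <- match(mut$parent_pop, state$pop_id)
    new_id <- state$next_pop_id
    state$next_pop_id <- new_id + 1L
    if (verdict == "coexist") {
      state$z <- c(state$z, mut$z_prime)
      state$N <- c(state$N, 1)
      state$pop_id <- c(state$pop_id, new_id)
      state$parent_pop <- c(state$parent_pop, mut$parent_pop)
      state$species_id <- c(state$species_id, state$species_id[i])
    } else {                     # replace parent with the mutant morph
      state$z[i] <- mut$z_prime
      state$parent_pop[i] <- state$pop_id[i]
      state$pop_id[i] <- new_id
    }
    state <- solve_equilibrium(state, params)
  }
  state$time <- state$time + dt
  res <- assign_species(state, params)
  list(state = res$state, events = res$events, verdict = verdict)
}

#' Run one replicate of an adaptive radiation
#'
#' Seeds a monomorphic population at the resource optimum, brings it to
#' carrying capacity, and iterates \code{n_steps} evolutionary steps,
#' recording the speciation-event log, a per-step richness trace,
#' community-metric snapshots every \code{metric_interval} steps, and the
#' final community and phylogeny.  Fully reproducible from
#' \code{(base_seed, replicate)}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param replicate Replicate index (seeds the RNG as
#'   \code{base_seed + replicate}).
#' @return An object of class \code{"radiation_result"}: a list with
#'   \code{config}, \code{replicate}, \code{events}, \code{metrics},
#'   \code{richness} (per-step trace), \code{snapshots} (per-snapshot
#'   species summaries), \code{final_state}, \code{phylogeny}.
#' @export
run_radiation <- function(config, replicate = 1L) {
  params <- config$params
  set.seed(config$base_seed + as.integer(replicate))
  state <- solve_equilibrium(seed_community(params), params)
  events <- empty_event_log()
  richness <- integer(config$n_steps + 1L)
  richness[1L] <- 1L
  metrics <- vector("list", config$n_steps %/% config$metric_interval)
  snapshots <- vector("list", length(metrics))
  for (step in seq_len(config$n_steps)) {
    out <- evolutionary_step(state, params, config$time_model)
    state <- out$state
    if (nrow(out$events)) events <- rbind(events, out$events)
    richness[step + 1L] <- length(unique(state$species_id))
    if (step %% config$metric_interval == 0L) {
      k <- step %/% config$metric_interval
      phy <- phylogeny(events, unique(state$species_id), state$time)
      metrics[[k]] <- metrics_record(state, phy, params, replicate)
      snapshots[[k]] <- cbind(time = state$time, species_summary(state))
    }
  }
  final_phy <- phylogeny(events, unique(state$species_id), state$time)
  res <- list(config = config, replicate = as.integer(replicate),
              events = events,
              metrics = do.call(rbind, metrics),
              richness = richness,
              snapshots = snapshots,
              final_state = state,
              phylogeny = final_phy)
  class(res) <- "radiation_result"
  res
}

#' @export
print.radiation_result <- function(x, ...) {
  cat(sprintf("Adaptive radiation: sigma_con = %g, %d steps, replicate %d\n",
              x$config$params$sigma_con, x$config$n_steps, x$replicate))
  cat(sprintf("  final richness %d species (%d populations), %d speciation events\n",
              length(unique(x$final_state$species_id)),
              length(x$final_state$z), nrow(x$events)))
  invisible(x)
}
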