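#' Experiment presets
#'
#' Named bundles of a simulation configuration and sweep axes.  The
#' \code{"study"} preset is the main study design: constants
#' \code{K0 = 10000}, \code{sigma_K = 1}, \code{r = 1}, \code{mu = 0.01},
#' \code{sigma_mu = 0.02}, niche widths 0.1--0.7 in steps of 0.1, 5000
#' evolutionary steps, metrics every 100 steps, 20 replicates.  The
#' robustness presets vary the growth rate, the mutational step size, the
#' resource-kernel shape, or the time model around that design.
#'
#' @param name One of \code{"study"}, \code{"growth_rate"},
#'   \code{"mutation_sd"}, \code{"kernel_shape"}, \code{"explicit_time"}.
#' @param base_seed Base RNG seed stored in the preset's configuration.
#' @return An object of class \code{"experiment_preset"}: a list with
#'   \code{name}, \code{config}, and sweep axes (\code{sigma_con_grid},
#'   \code{r_grid}, \code{sigma_mu_grid}, \code{kernel_exponents},
#'   \code{time_models}).
#' @export
experiment_preset <- function(name = c("study", "growth_rate", "mutation_sd",
                                       "kernel_shape", "explicit_time"),
                              base_seed = 1L) {
  name <- match.arg(name)
  cfg <- simulation_config(params = model_params(sigma_con = 0.1),
                           n_steps = 5000L, metric_interval = 100L,
                           n_replicates = 20L, base_seed = base_seed)
  axes <- list(sigma_con_grid = seq(0.1, 0.7, by = 0.1), r_grid = 1,
               sigma_mu_grid = 0.02, kernel_exponents = 2,
               time_models = "step")
  axes <- switch(name,
    study = axes,
    growth_rate = { axes$r_grid <- c(0.75, 1, 1.25); axes },
    mutation_sd = { axes$sigma_mu_grid <- c(0.01, 0.02, 0.04); axes },
    kernel_shape = { axes$kernel_exponents <- c(2, 4); axes },
    explicit_time = { axes$time_models <- c("step", "explicit"); axes })
  structure(c(list(name = name, config = cfg), axes),
            class = "experiment_preset")
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("Experiment preset '%s': %d steps x %d replicates\n",
              x$name, x$config$n_steps, x$config$n_replicates))
  cat("  sigma_con grid:", paste(x$sigma_con_grid, collapse = ", "), "\n")
  invisible(x)
}

#' Run an experiment preset
#'
#' Runs every cell of the preset's sweep grid for the requested number of
#' replicates, optionally writing per-replicate metrics (TSV), event logs
#' (JSON) and final trees (Newick) under
#' \code{out_dir/<preset>/<sigma_con>/<replicate>/}, plus an
#' \code{aggregate.tsv} (per-cell, per-snapshot mean and SD over
#' replicates) and a JSON echo of the resolved configuration at the preset
#' root.
#'
#' @param preset An \code{\link{experiment_preset}}.
#' @param scale Fraction in (0, 1] multiplying both the step count and the
#'   replicate count (floored, minimum 1); 1 reproduces the full design.
#' @param out_dir Output directory (created if needed); \code{NULL} skips
#'   all file output.
#' @param quiet Suppress per-run progress messages.
#' @return A list with \code{metrics} (all per-replicate snapshot rows),
#'   \code{aggregate} (mean and SD over replicates per cell and snapshot
#'   time), and \code{runs} (the individual \code{radiation_result}
#'   objects).
#' @export
run_experiment <- function(preset, scale = 1, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(preset, "experiment_preset"), scale > 0, scale <= 1)
  cfg0 <- preset$config
  n_steps <- max(1L, as.integer(floor(cfg0$n_steps * scale)))
  n_reps <- max(1L, as.integer(floor(cfg0$n_replicates * scale)))
  cells <- expand.grid(sigma_con = preset$sigma_con_grid, r = preset$r_grid,
                       sigma_mu = preset$sigma_mu_grid,
                       kernel_exponent = preset$kernel_exponents,
                       time_model = preset$time_models,
                       stringsAsFactors = FALSE)
  runs <- list(); all_metrics <- list()
  root <- if (!is.null(out_dir)) file.path(out_dir, preset$name)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    params <- model_params(sigma_con = cell$sigma_con, r = cell$r,
                           sigma_mu = cell$sigma_mu,
                           kernel_exponent = cell$kernel_exponent)
    cfg <- simulation_config(params = params, n_steps = n_steps,
                             metric_interval = min(cfg0$metric_interval, n_steps),
                             n_replicates = n_reps, base_seed = cfg0$base_seed,
                             time_model = cell$time_model)
    for (rep_i in seq_len(n_reps)) {
      res <- run_radiation(cfg, rep_i)
      if (!quiet)
        message(sprintf("sigma_con %.2g replicate %d: %d species after %d steps",
                        cell$sigma_con, rep_i,
                        length(unique(res$final_state$species_id)), n_steps))
      key <- sprintf("cell%02d_rep%02d", ci, rep_i)
      runs[[key]] <- res
      m <- res$metrics
      if (nrow(cells) > length(preset$sigma_con_grid)) {
        m$r <- cell$r; m$sigma_mu <- cell$sigma_mu
        m$kernel_exponent <- cell$kernel_exponent
        m$time_model <- cell$time_model
      }
      all_metrics[[key]] <- m
      if (!is.null(root)) {
        dir <- file.path(root, format(cell$sigma_con), rep_i)
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        write_metrics_tsv(res$metrics, file.path(dir, "metrics.tsv"))
        write_event_log(res$events, file.path(dir, "events.json"))
        writeLines(to_newick(res$phylogeny), file.path(dir, "tree.nwk"))
      }
    }
  }
  metrics <- do.call(rbind, all_metrics)
  rownames(metrics) <- NULL
  agg <- aggregate_metrics(metrics)
  if (!is.null(root)) {
    utils::write.table(agg, file.path(root, "aggregate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    jsonlite::write_json(
      list(preset = preset$name, n_steps = n_steps, n_replicates = n_reps,
           base_seed = cfg0$base_seed, metric_interval = cfg0$metric_interval,
           cells = cells),
      file.path(root, "config.json"), auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, aggregate = agg, runs = runs)
}

# mean and sd over replicates for each metric, per (sigma_con, time)
aggregate_metrics <- function(metrics) {
  vars <- c("richness", "MPD", "NNPD", "MTD", "MNTD", "gamma")
  key <- metrics[, c("sigma_con", "time")]
  agg_m <- stats::aggregate(metrics[vars], key, mean, na.rm = TRUE)
  agg_s <- stats::aggregate(metrics[vars], key, stats::sd, na.rm = TRUE)
  names(agg_m)[-(1:2)] <- paste0(vars, "_mean")
  names(agg_s)[-(1:2)] <- paste0(vars, "_sd")
  out <- merge(agg_m, agg_s, by = c("sigma_con", "time"), sort = TRUE)
  out[do.call(order, out[c("sigma_con", "time")]), , drop = FALSE]
}

#' Write a speciation-event log as JSON
#'
#' @param events Event data.frame (\code{time}, \code{parent},
#'   \code{child}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_event_log <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small hand-specified communities and trees with hand-computable
#' metrics, shared across the test suites.
#'
#' \describe{
#'   \item{\code{two_species_tree}}{Two extant species split at time 60,
#'     present 100: the single patristic distance is 80.}
#'   \item{\code{three_species_tree}}{Species 2 splits from the root
#'     lineage at time 20 and species 3 at time 80 (present 100), giving
#'     pairwise patristic distances 40, 160, 160.}
#'   \item{\code{random_community}}{\code{n} species with traits and event
#'     times drawn reproducibly from \code{seed}; returns both the
#'     community and its phylogeny.}
#' }
#'
#' @param kind Fixture name.
#' @param n,seed Size and seed of \code{random_community}.
#' @return For the tree fixtures, a \code{\link{phylogeny}}; for
#'   \code{random_community}, a list with \code{state} and \code{phylo}.
#' @export
make_fixture <- function(kind = c("two_species_tree", "three_species_tree",
                                  "random_community"),
                         n = 5L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    two_species_tree = phylogeny(
      data.frame(time = 60, parent = 1L, child = 2L),
      extant = c(1L, 2L), time = 100),
    three_species_tree = phylogeny(
      data.frame(time = c(20, 80), parent = c(1L, 1L), child = c(2L, 3L)),
      extant = 1:3, time = 100),
    random_community = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      stopifnot(n >= 1L)
      ev <- if (n > 1L)
        data.frame(time = sort(stats::runif(n - 1L, 0, 90)),
                   parent = sapply(2:n, function(k) sample.int(k - 1L, 1L)),
                   child = 2:n)
      else empty_event_log()
      st <- community_state(z = stats::rnorm(n, 0, 1),
                            N = stats::runif(n, 100, 10000),
                            species_id = seq_len(n), time = 100)
      list(state = st, phylo = phylogeny(ev, seq_len(n), time = 100))
    })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
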