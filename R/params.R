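#' Model parameters for the trait-based competition model
#'
#' Bundles every constant of the eco-evolutionary model: the resource
#' (carrying-capacity) kernel, the competition kernel, demographic rates and
#' the mutation process.  Defaults are the constants used throughout the
#' simulation study: \code{K0 = 10000}, \code{sigma_K = 1}, \code{r = 1},
#' \code{mu = 0.01}, \code{sigma_mu = 0.02}, with the resource optimum at
#' \code{z_opt = 0}.
#'
#' @param K0 Maximal carrying capacity (individuals), attained at
#'   \code{z = z_opt}.
#' @param sigma_K Width of the resource distribution in trait units.
#' @param sigma_con Consumer niche width (width of the Gaussian competition
#'   kernel) in trait units.  Narrow values mean competition decays quickly
#'   with trait distance; \code{sigma_con < sigma_K} puts the trait optimum
#'   at an evolutionary branching point.
#' @param r Intrinsic per-capita growth rate (per unit ecological time).
#' @param mu Per-individual mutation probability per evolutionary step.
#' @param sigma_mu Standard deviation of mutational steps in trait units.
#' @param z_opt Trait value of peak resource availability.
#' @param kernel_exponent Shape exponent \eqn{p} of the resource kernel
#'   \eqn{K(z) = K_0 \exp(-|z_{opt}-z|^p / (2\sigma_K^p))}; \code{p = 2}
#'   is the Gaussian kernel used in the main analyses.
#' @param eq_horizon Ecological integration horizon used when equilibria are
#'   found by ODE integration (time units).
#' @param extinction_threshold Abundance below which a population is removed
#'   after re-equilibration.
#'
#' @return An object of class \code{"model_params"} (a named list).
#' @examples
#' p <- model_params(sigma_con = 0.3)
#' carrying_capacity(0, p)   # 10000 at the optimum
#' @export
model_params <- function(K0 = 10000, sigma_K = 1, sigma_con = 0.5, r = 1,
                         mu = 0.01, sigma_mu = 0.02, z_opt = 0,
                         kernel_exponent = 2, eq_horizon = 1000,
                         extinction_threshold = 1) {
  p <- list(K0 = K0, sigma_K = sigma_K, sigma_con = sigma_con, r = r,
            mu = mu, sigma_mu = sigma_mu, z_opt = z_opt,
            kernel_exponent = kernel_exponent, eq_horizon = eq_horizon,
            extinction_threshold = extinction_threshold)
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    is.finite(p$K0), p$K0 > 0,
    is.finite(p$sigma_K), p$sigma_K > 0,
    is.finite(p$sigma_con), p$sigma_con > 0,
    is.finite(p$r), p$r > 0,
    is.finite(p$mu), p$mu >= 0, p$mu <= 1,
    is.finite(p$sigma_mu), p$sigma_mu > 0,
    is.finite(p$z_opt),
    is.finite(p$kernel_exponent), p$kernel_exponent > 0,
    is.finite(p$eq_horizon), p$eq_horizon > 0,
    is.finite(p$extinction_threshold), p$extinction_threshold >= 0
  )
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Trait-based competition model parameters\n")
  cat(sprintf("  K0 = %g, sigma_K = %g, z_opt = %g, kernel exponent = %g\n",
              x$K0, x$sigma_K, x$z_opt, x$kernel_exponent))
  cat(sprintf("  sigma_con = %g (%s selection at the optimum)\n", x$sigma_con,
              if (x$sigma_con < x$sigma_K) "disruptive" else
                if (x$sigma_con > x$sigma_K) "stabilizing" else "neutral"))
  cat(sprintf("  r = %g, mu = %g, sigma_mu = %g\n", x$r, x$mu, x$sigma_mu))
  invisible(x)
}

#' Construct a community state
#'
#' A community is the set of coexisting populations (trait morphs) at one
#' point in evolutionary time.  Each population carries a trait value, an
#' abundance, a unique population id, a link to the population it mutated
#' from, and its current species label.
#'
#' @param z Numeric vector of trait values.
#' @param N Numeric vector of abundances (same length as \code{z}).
#' @param species_id Integer vector of species labels (default: all 1).
#' @param time Evolutionary time of the state.
#' @param pop_id,parent_pop Integer vectors of population ids and of the
#'   parental population ids (\code{NA} for founding populations).
#'
#' @return An object of class \code{"community_state"}.
#' @export
community_state <- function(z, N, species_id = rep(1L, length(z)), time = 0,
                            pop_id = seq_along(z),
                            parent_pop = rep(NA_integer_, length(z))) {
  stopifnot(length(N) == length(z), length(species_id) == length(z),
            all(is.finite(z)), all(is.finite(N)), all(N >= 0),
            !anyDuplicated(pop_id))
  s <- list(time = time, z = as.numeric(z), N = as.numeric(N),
            pop_id = as.integer(pop_id),
            parent_pop = as.integer(parent_pop),
            species_id = as.integer(species_id),
            next_pop_id = as.integer(max(pop_id) + 1L),
            next_species_id = as.integer(max(species_id) + 1L))
  class(s) <- "community_state"
  s
}

n_populations <- function(state) length(state$z)

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("Community at time %g: %d population(s), %d species\n",
              x$time, length(x$z), length(unique(x$species_id))))
  if (length(x$z) <= 12) {
    print(data.frame(pop = x$pop_id, species = x$species_id,
                     z = signif(x$z, 5), N = signif(x$N, 6)))
  } else {
    cat(sprintf("  trait range [%.3g, %.3g], total abundance %.6g\n",
                min(x$z), max(x$z), sum(x$N)))
  }
  invisible(x)
}

# subset a community to populations `keep` (logical or integer index),
# preserving ids and counters
subset_community <- function(state, keep) {
  state$z <- state$z[keep]
  state$N <- state$N[keep]
  state$pop_id <- state$pop_id[keep]
  state$parent_pop <- state$parent_pop[keep]
  state$species_id <- state$species_id[keep]
  state
}

#' Per-species summary of a community
#'
#' @param state A \code{community_state}.
#' @return A data.frame with one row per extant species: species id,
#'   number of member populations, abundance-weighted mean trait, and total
#'   abundance.
#' @export
species_summary <- function(state) {
  sp <- sort(unique(state$species_id))
  out <- data.frame(
    species = sp,
    n_populations = vapply(sp, function(s) sum(state$species_id == s), 1L),
    mean_trait = vapply(sp, function(s) {
      i <- state$species_id == s
      sum(state$z[i] * state$N[i]) / sum(state$N[i])
    }, 1.0),
    abundance = vapply(sp, function(s) sum(state$N[state$species_id == s]), 1.0)
  )
  out
}
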