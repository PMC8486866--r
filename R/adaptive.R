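#' Invasion fitness of a mutant trait
#'
#' Initial per-capita growth rate of a rare mutant with trait
#' \code{z_prime} introduced into a resident community at ecological
#' equilibrium:
#' \eqn{G(z') = r - r \sum_j \alpha(z', z_j) N^*_j / K(z')}.
#' Every resident trait has invasion fitness zero in its own equilibrium
#' community (resident neutrality).
#'
#' @param z_prime Mutant trait value(s).
#' @param state Resident \code{\link{community_state}} at equilibrium.
#' @param params A \code{\link{model_params}} object.
#' @param check If \code{TRUE} (default), error when the resident community
#'   is not at equilibrium (residual per-capita growth above
#'   \code{1e-5 * r}).
#' @return Invasion fitness (per unit time), same length as \code{z_prime}.
#' @export
invasion_fitness <- function(z_prime, state, params, check = TRUE) {
  if (!all(is.finite(z_prime))) stop("mutant trait must be finite")
  if (check) check_equilibrium(state, params, tol = 1e-5)
  glv_growth(z_prime, state$N, params, z = state$z)
}

#' Selection gradient on a lone resident population
#'
#' Closed-form fitness gradient of a single population at its own
#' equilibrium (Gaussian kernels only):
#' \eqn{\partial G / \partial z' |_{z'=z} = -(r/\sigma_K^2)\, z}.
#' Positive below the resource optimum and negative above it, so a lone
#' lineage always converges on \code{z_opt}.
#'
#' @param z Resident trait value.
#' @param params A \code{\link{model_params}} object with
#'   \code{kernel_exponent == 2}.
#' @return Selection gradient (per unit time per trait unit).
#' @export
fitness_gradient_seed <- function(z, params) {
  if (params$kernel_exponent != 2)
    stop("closed-form gradient requires the Gaussian kernel (kernel_exponent = 2); ",
         "use numeric differentiation of invasion_fitness() instead")
  -(params$r / params$sigma_K^2) * (z - params$z_opt)
}

#' Fitness curvature at the resource optimum
#'
#' Second derivative of invasion fitness in the mutant trait, evaluated for
#' a lone resident sitting at the optimum at its equilibrium abundance:
#' \eqn{r (1/\sigma_{con}^2 - 1/\sigma_K^2)}.  Positive when the niche is
#' narrower than the resource distribution (disruptive selection, an
#' evolutionary branching point); negative when wider (stabilizing
#' selection, an ESS).
#'
#' @param params A \code{\link{model_params}} object with
#'   \code{kernel_exponent == 2}.
#' @return Fitness curvature (per unit time per squared trait unit).
#' @export
curvature_at_optimum <- function(params) {
  if (params$kernel_exponent != 2)
    stop("closed-form curvature requires the Gaussian kernel (kernel_exponent = 2)")
  params$r * (1 / params$sigma_con^2 - 1 / params$sigma_K^2)
}

#' Draw a single mutant proposal
#'
#' Picks the mutating population with probability proportional to
#' \eqn{N_i \mu_i} (with uniform mutation probability this is proportional
#' to abundance) and draws the mutant trait from a normal distribution
#' centered on the parental trait with standard deviation \code{sigma_mu}.
#' Exactly one proposal is drawn per evolutionary step.
#'
#' @param state A \code{\link{community_state}}.
#' @param params A \code{\link{model_params}} object.
#' @return A list of class \code{"mutant_proposal"} with elements
#'   \code{parent_pop}, \code{parent_index}, \code{z_parent}, \code{z_prime}
#'   and \code{fitness} (\code{NA} until evaluated).
#' @export
draw_mutant <- function(state, params) {
  n <- n_populations(state)
  if (n == 0L) stop("community is empty")
  i <- if (n == 1L) 1L else sample.int(n, 1L, prob = state$N)
  zp <- state$z[i] + stats::rnorm(1L, 0, params$sigma_mu)
  structure(list(parent_pop = state$pop_id[i], parent_index = i,
                 z_parent = state$z[i], z_prime = zp, fitness = NA_real_),
            class = "mutant_proposal")
}

#' @export
print.mutant_proposal <- function(x, ...) {
  cat(sprintf("Mutant proposal: z' = %.5g from population %d (z = %.5g), G = %s\n",
              x$z_prime, x$parent_pop, x$z_parent,
              if (is.na(x$fitness)) "not evaluated" else
                sprintf("%.5g", x$fitness)))
  invisible(x)
}

#' Mutual-invasibility test for a mutant
#'
#' Decides the fate of a mutant proposal against the resident community.
#' A mutant with non-positive invasion fitness is rejected.  Otherwise the
#' mutant is swapped in for its parent (all other residents retained), the
#' swapped community is brought to equilibrium, and the parental trait's
#' invasion fitness is evaluated there: if the parent can invade back the
#' two morphs are mutually invasible and coexist, otherwise the mutant
#' simply replaces its parent.
#'
#' @param mutant A \code{"mutant_proposal"} from \code{\link{draw_mutant}}.
#' @param state Resident \code{\link{community_state}} at equilibrium.
#' @param params A \code{\link{model_params}} object.
#' @param fitness Invasion fitness of the mutant; computed if \code{NULL}.
#' @return One of \code{"coexist"}, \code{"replace"}, \code{"reject"}.
#' @export
mutual_invasibility <- function(mutant, state, params, fitness = NULL) {
  if (is.null(fitness)) fitness <- mutant$fitness
  if (is.null(fitness) || is.na(fitness))
    fitness <- invasion_fitness(mutant$z_prime, state, params)
  # fitness within floating-point noise of zero is treated as non-positive
  # (a mutant this close to neutrality cannot invade on any relevant scale)
  if (fitness <= 1e-10 * params$r) return("reject")
  i <- match(mutant$parent_pop, state$pop_id)
  if (is.na(i)) stop("parent population not present in the community")
  swapped <- state
  swapped$z[i] <- mutant$z_prime
  swapped <- solve_equilibrium(swapped, params)
  if (n_populations(swapped) == 0L) stop("swapped community collapsed")
  g_parent <- invasion_fitness(mutant$z_parent, swapped, params, check = FALSE)
  if (g_parent > 0) "coexist" else "replace"
}
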