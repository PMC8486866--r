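#' Trait-dependent carrying capacity
#'
#' Resource availability along the trait axis, modeled as
#' \eqn{K(z) = K_0 \exp(-|z_{opt} - z|^p / (2 \sigma_K^p))} with
#' \eqn{p} the kernel exponent (2 = Gaussian).  Maximal at the resource
#' optimum and strictly positive everywhere.
#'
#' @param z Trait value(s).
#' @param params A \code{\link{model_params}} object.
#' @return Carrying capacity in individuals, same length as \code{z}.
#' @examples
#' p <- model_params()
#' carrying_capacity(c(0, 1), p)  # 10000, 10000 * exp(-1/2)
#' @export
carrying_capacity <- function(z, params) {
  if (!all(is.finite(z))) stop("trait values must be finite")
  pexp <- params$kernel_exponent
  params$K0 * exp(-abs(params$z_opt - z)^pexp / (2 * params$sigma_K^pexp))
}

#' Competition coefficient between two trait values
#'
#' Gaussian competition kernel
#' \eqn{\alpha(z_i, z_j) = \exp(-(z_i - z_j)^2 / (2 \sigma_{con}^2))}:
#' symmetric, in (0, 1], and equal to 1 exactly when the traits coincide,
#' so intraspecific competition is always the strongest interaction.
#'
#' @param z_i,z_j Trait values (vectorized).
#' @param sigma_con Niche width (competition kernel width) in trait units.
#' @return Dimensionless competition coefficient(s) in (0, 1].
#' @examples
#' competition_coefficient(0, 0.3, 0.3)  # exp(-1/2)
#' @export
competition_coefficient <- function(z_i, z_j, sigma_con) {
  if (!all(is.finite(z_i)) || !all(is.finite(z_j)))
    stop("trait values must be finite")
  stopifnot(sigma_con > 0)
  exp(-(z_i - z_j)^2 / (2 * sigma_con^2))
}

# full pairwise interaction matrix (symmetric, unit diagonal)
interaction_matrix <- function(z, sigma_con) {
  d <- outer(z, z, "-")
  exp(-d^2 / (2 * sigma_con^2))
}

#' Per-capita growth rates of all populations
#'
#' The right-hand side of the trait-based generalized Lotka--Volterra model
#' in per-capita form:
#' \eqn{r - r \sum_j \alpha(z_i, z_j) N_j / K(z_i)}.
#'
#' @param state A \code{\link{community_state}}.
#' @param params A \code{\link{model_params}} object.
#' @return Numeric vector of per-capita growth rates (per unit time).
#' @export
per_capita_growth <- function(state, params) {
  if (n_populations(state) == 0L) stop("community is empty")
  glv_growth(state$z, state$N, params)
}

# growth rate of phenotype(s) zq facing residents (z, N).  Computed with the
# alpha/K ratio in log space so extreme query traits cannot produce 0/0.
glv_growth <- function(zq, N, params, z = zq) {
  pexp <- params$kernel_exponent
  logK <- -abs(params$z_opt - zq)^pexp / (2 * params$sigma_K^pexp)
  load <- vapply(seq_along(zq), function(i) {
    h <- -(zq[i] - z)^2 / (2 * params$sigma_con^2) - logK[i]
    sum(N * exp(h))
  }, 1.0)
  params$r - params$r * load / params$K0
}

#' Ecological equilibrium of a community
#'
#' Replaces the abundances of a community with a non-negative steady state
#' of the Lotka--Volterra dynamics and removes populations that fall below
#' the extinction threshold.  Two routes are available: direct ODE
#' integration of the dynamics over \code{[0, eq_horizon]} (the reference
#' method), and a fast active-set linear solver that finds the saturated
#' equilibrium directly.  Because the Gaussian interaction matrix is
#' symmetric positive definite, the dynamics admit a quadratic Lyapunov
#' function and the stable saturated equilibrium is unique, so both routes
#' agree; the fast path falls back to integration if it fails to converge.
#'
#' @param state A \code{\link{community_state}} with at least one
#'   population.
#' @param params A \code{\link{model_params}} object.
#' @param method \code{"auto"} (active-set solve with ODE fallback, the
#'   default), \code{"ode"} (integration only) or \code{"linear"} (plain
#'   linear solve, falling back to ODE if any component is not above the
#'   extinction threshold).
#' @return The community with equilibrium abundances; populations below the
#'   extinction threshold are removed.  Ids and ordering of survivors are
#'   preserved.
#' @examples
#' p <- model_params()
#' eq <- solve_equilibrium(community_state(0, 1), p)
#' eq$N  # 10000 = K0 for a single population at the optimum
#' @export
solve_equilibrium <- function(state, params, method = c("auto", "ode", "linear")) {
  method <- match.arg(method)
  if (n_populations(state) == 0L) stop("community is empty")
  Neq <- switch(method,
    auto = {
      N <- equilibrium_active_set(state$z, state$N, params)
      if (is.null(N)) equilibrium_ode(state$z, state$N, params) else N
    },
    linear = {
      N <- tryCatch(solve(interaction_matrix(state$z, params$sigma_con),
                          carrying_capacity(state$z, params)),
                    error = function(e) NULL)
      if (is.null(N) || any(N <= params$extinction_threshold))
        equilibrium_ode(state$z, state$N, params)
      else N
    },
    ode = equilibrium_ode(state$z, state$N, params)
  )
  state$N <- Neq
  alive <- Neq >= params$extinction_threshold
  if (!any(alive)) alive[which.max(Neq)] <- TRUE  # K > 0 guarantees a survivor
  if (!all(alive)) {
    state <- subset_community(state, alive)
    # survivors re-equilibrate exactly on their own support
    N2 <- equilibrium_active_set(state$z, state$N, params)
    state$N <- if (is.null(N2)) equilibrium_ode(state$z, state$N, params) else N2
  }
  check_equilibrium(state, params, tol = 1e-6)
  state
}

# Saturated equilibrium: solves  A N = K  restricted to N >= 0 (the unique
# stable state, A being positive definite) with a Lawson-Hanson-style
# active-set iteration: one most-violated addition per outer step plus
# feasibility backtracking, which cannot cycle.  Returns NULL on numerical
# failure (caller falls back to the ODE).
equilibrium_active_set <- function(z, N0, params) {
  n <- length(z)
  A <- interaction_matrix(z, params$sigma_con)
  K <- carrying_capacity(z, params)
  tol_w <- 1e-9 * params$K0          # invasion tolerance on K - A N
  N <- pmax(N0, 1e-6)                # warm start from current abundances
  passive <- rep(TRUE, n)
  outer_max <- 10L * n + 50L
  refit <- function(N, passive) {    # inner loop: restore feasibility
    for (inner in seq_len(n + 5L)) {
      s <- support_solve(A[passive, passive, drop = FALSE], K[passive],
                         params$K0)
      if (is.null(s)) return(NULL)
      if (all(s > 0)) {
        N[] <- 0; N[passive] <- s
        return(list(N = N, passive = passive))
      }
      Np <- N[passive]
      bad <- s <= 0
      den <- Np[bad] - s[bad]
      ratio <- ifelse(den > 0, Np[bad] / den, 0)
      alpha <- min(ratio)
      Np <- Np + alpha * (s - Np)
      Np[which(bad)[ratio <= alpha]] <- 0  # blocking morphs leave exactly
      N[] <- 0; N[passive] <- pmax(Np, 0)
      passive[passive] <- N[passive] > 0
      if (!any(passive)) return(NULL)
    }
    NULL
  }
  st <- refit(N, passive)
  if (is.null(st)) return(NULL)
  for (it in seq_len(outer_max)) {
    w <- K - drop(A %*% st$N)        # shadow resource surplus of each morph
    w[st$passive] <- 0
    if (max(w) <= tol_w) return(st$N)
    add <- which.max(w)
    st$passive[add] <- TRUE
    st <- refit(st$N, st$passive)
    if (is.null(st)) return(NULL)
  }
  NULL
}

# Solve A s = K on the current support.  Morphs with nearly identical
# traits make A numerically singular; the minimum-norm (pseudo-inverse)
# solution then shares the common equilibrium abundance evenly among the
# quasi-neutral twins, which is the correct degenerate limit of the model.
support_solve <- function(A, K, K0) {
  s <- tryCatch(solve(A, K), error = function(e) NULL)
  if (!is.null(s) && all(is.finite(s)) && max(abs(s)) < 100 * K0) return(s)
  sv <- tryCatch(svd(A), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  keep <- sv$d > length(K) * .Machine$double.eps * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% K) / sv$d[keep]))
}

# reference route: integrate the GLV dynamics to eq_horizon (extending once
# by 10x if the steady-state tolerance is not met)
equilibrium_ode <- function(z, N0, params) {
  n <- length(z)
  A <- interaction_matrix(z, params$sigma_con)
  K <- carrying_capacity(z, params)
  rhs <- function(t, N, parms) {
    N <- pmax(N, 0)
    list(params$r * N * (1 - drop(A %*% N) / K))
  }
  N0 <- pmax(N0, 1e-12)
  run <- function(N_init, horizon) {
    out <- deSolve::ode(y = N_init, times = c(0, horizon), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-8)
    if (attr(out, "istate")[1] < 0)
      stop("equilibrium integration failed: ",
           paste(attr(out, "istate"), collapse = " "))
    pmax(as.numeric(out[nrow(out), -1]), 0)
  }
  N <- run(N0, params$eq_horizon)
  resid <- function(N) {
    live <- N > params$extinction_threshold
    if (!any(live)) return(0)
    max(abs(params$r * (1 - drop(A %*% N) / K)[live]))
  }
  if (resid(N) > 1e-6 * params$r) {
    N <- run(N, 10 * params$eq_horizon)
    if (resid(N) > 1e-6 * params$r)
      stop("no steady state within 10x the integration horizon ",
           sprintf("(residual %.3g)", resid(N)))
  }
  N
}

# error unless max |per-capita growth| <= tol * r over all populations
check_equilibrium <- function(state, params, tol = 1e-5) {
  res <- max(abs(per_capita_growth(state, params)))
  if (res > tol * params$r)
    stop(sprintf("community is not at ecological equilibrium (residual %.3g, tolerance %.3g)",
                 res, tol * params$r))
  invisible(res)
}
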