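test_that("residents are neutral and mutants follow the fitness landscape", {
  p <- study_params()
  eq <- solve_equilibrium(community_state(0, 1), p)
  # hand-evaluated landscape value for a nearby mutant
  expect_equal(invasion_fitness(0.1, eq, p), 1 - exp(-0.015), tolerance = 1e-9)
  expect_equal(invasion_fitness(0, eq, p), 0, tolerance = 1e-9)
  # far outside the resourced range competition decays faster than K, so
  # fitness tends to r (such mutants invade but equilibrate below the
  # extinction threshold); the log-space evaluation must not underflow
  expect_equal(invasion_fitness(5, eq, p), p$r, tolerance = 1e-12)
  expect_equal(invasion_fitness(40, eq, p), p$r, tolerance = 1e-12)
  # under stabilizing selection (sigma_con > sigma_K) deviants cannot
  # invade; hand value at z' = 1: r (1 - exp(1/2 - 1/(2 * 1.2^2)))
  ps <- study_params(sigma_con = 1.2)
  eqs <- solve_equilibrium(community_state(0, 1), ps)
  expect_equal(invasion_fitness(1, eqs, ps), 1 - exp(0.5 - 1 / 2.88),
               tolerance = 1e-9)
  expect_lt(invasion_fitness(5, eqs, ps), 0)
  expect_lt(invasion_fitness(40, eqs, ps), 0)  # huge load, still finite
  expect_true(is.finite(invasion_fitness(40, eqs, ps)))
  # resident neutrality holds in multi-species communities too
  p2 <- study_params(sigma_con = 0.4)
  eq2 <- random_equilibrium_community(4, p2, seed = 5)
  expect_equal(invasion_fitness(eq2$z, eq2, p2), rep(0, length(eq2$z)),
               tolerance = 1e-6)
  # evaluating fitness in a transient state is an error
  st <- community_state(0, 5)
  expect_error(invasion_fitness(0.1, st, p), "equilibrium")
})

test_that("closed-form gradient matches its definition and the numeric derivative", {
  p <- study_params()
  expect_equal(fitness_gradient_seed(0, p), 0)
  expect_equal(fitness_gradient_seed(0.5, p), -0.5)
  h <- 1e-4
  for (z in c(-0.5, -0.2, 0.1, 0.4)) {
    eq <- solve_equilibrium(community_state(z, 1), p)
    num <- (invasion_fitness(z + h, eq, p) - invasion_fitness(z - h, eq, p)) / (2 * h)
    expect_equal(num, fitness_gradient_seed(z, p), tolerance = 1e-5)
  }
  expect_error(fitness_gradient_seed(0.5, model_params(kernel_exponent = 4)),
               "Gaussian")
})

test_that("fitness curvature separates branching points from ESSs", {
  expect_equal(curvature_at_optimum(model_params(sigma_con = 0.5)), 3)
  expect_equal(curvature_at_optimum(model_params(sigma_con = 2)), -0.75)
  expect_equal(curvature_at_optimum(model_params(sigma_con = 1)), 0)
  # sign dichotomy across a grid
  for (sc in c(0.1, 0.3, 0.7, 0.99, 1.01, 1.5)) {
    curv <- curvature_at_optimum(model_params(sigma_con = sc))
    expect_identical(curv > 0, sc < 1)
  }
  expect_error(curvature_at_optimum(model_params(kernel_exponent = 4)),
               "Gaussian")
})

test_that("numeric landscape derivatives match closed forms across the parameter grid", {
  h <- 2e-4
  for (r in c(0.75, 1, 1.25)) {
    for (sc in seq(0.1, 0.7, by = 0.2)) {
      p <- model_params(r = r, sigma_con = sc)
      eq <- solve_equilibrium(community_state(0.3, 1), p)
      num_grad <- (invasion_fitness(0.3 + h, eq, p) -
                     invasion_fitness(0.3 - h, eq, p)) / (2 * h)
      expect_equal(num_grad, fitness_gradient_seed(0.3, p),
                   tolerance = 1e-4 * abs(fitness_gradient_seed(0.3, p)))
      eq0 <- solve_equilibrium(community_state(0, 1), p)
      num_curv <- (invasion_fitness(h, eq0, p) - 2 * invasion_fitness(0, eq0, p) +
                     invasion_fitness(-h, eq0, p)) / h^2
      expect_equal(num_curv, curvature_at_optimum(p),
                   tolerance = 1e-4 * abs(curvature_at_optimum(p)))
    }
  }
})

test_that("mutant proposals are abundance-weighted and reproducible", {
  p <- study_params()
  one <- solve_equilibrium(community_state(0, 1), p)
  m <- draw_mutant(one, p)
  expect_equal(m$parent_pop, one$pop_id[1])
  set.seed(99); m1 <- draw_mutant(one, p)
  set.seed(99); m2 <- draw_mutant(one, p)
  expect_identical(m1, m2)
  # parent choice proportional to abundance
  st <- community_state(z = c(0, 0.5), N = c(9000, 1000), pop_id = 1:2)
  set.seed(7)
  draws <- replicate(1e4, draw_mutant(st, p)$parent_pop)
  freq <- mean(draws == 1L)
  se <- sqrt(0.9 * 0.1 / 1e4)
  expect_lt(abs(freq - 0.9), 3 * se)
  # mutational step size: spread of z' - z over many draws
  steps <- replicate(2e3, { m <- draw_mutant(st, p); m$z_prime - m$z_parent })
  expect_equal(sd(steps), p$sigma_mu, tolerance = 0.1)
})

test_that("mutual invasibility classifies coexist, replace and reject", {
  # neutral mutant: identical trait, zero fitness
  p <- study_params(sigma_con = 0.5)
  eq <- solve_equilibrium(community_state(0, 1), p)
  neutral <- structure(list(parent_pop = eq$pop_id[1], z_parent = 0,
                            z_prime = 0, fitness = NA_real_),
                       class = "mutant_proposal")
  expect_equal(mutual_invasibility(neutral, eq, p), "reject")
  # disruptive regime: small symmetric deviation coexists with its parent
  near <- structure(list(parent_pop = eq$pop_id[1], z_parent = 0,
                         z_prime = 0.05, fitness = NA_real_),
                    class = "mutant_proposal")
  expect_equal(mutual_invasibility(near, eq, p), "coexist")
  # stabilizing regime: directional steps toward the optimum replace
  p2 <- study_params(sigma_con = 1.5)
  eq2 <- solve_equilibrium(community_state(0.2, 1), p2)
  toward <- structure(list(parent_pop = eq2$pop_id[1], z_parent = 0.2,
                           z_prime = 0.1, fitness = NA_real_),
                      class = "mutant_proposal")
  expect_equal(mutual_invasibility(toward, eq2, p2), "replace")
})

test_that("mutual invasibility is invariant to resident ordering", {
  p <- study_params(sigma_con = 0.4)
  eq <- random_equilibrium_community(4, p, seed = 21)
  i <- 2L
  mut <- structure(list(parent_pop = eq$pop_id[i], z_parent = eq$z[i],
                        z_prime = eq$z[i] + 0.04, fitness = NA_real_),
                   class = "mutant_proposal")
  v1 <- mutual_invasibility(mut, eq, p)
  perm <- rev(seq_along(eq$z))
  shuffled <- ecoevorad:::subset_community(eq, perm)
  v2 <- mutual_invasibility(mut, shuffled, p)
  expect_identical(v1, v2)
})
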