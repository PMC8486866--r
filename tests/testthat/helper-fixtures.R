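# shared helpers: small communities with known equilibria and brute-force
# metric oracles kept deliberately naive (explicit loops over pairs)

study_params <- function(sigma_con = 0.5, ...) {
  model_params(sigma_con = sigma_con, ...)
}

random_equilibrium_community <- function(n, params, seed) {
  set.seed(seed)
  # spread traits so coexistence is plausible but not forced; re-draw until
  # morphs are not quasi-neutral (tiny gaps relax too slowly for the ODE)
  repeat {
    z <- sort(stats::runif(n, -1.5, 1.5))
    if (min(diff(z)) > 0.15) break
  }
  st <- community_state(z = z, N = rep(params$K0 / n, n))
  solve_equilibrium(st, params, method = "ode")
}

brute_mean_pairwise <- function(D) {
  n <- nrow(D); tot <- 0; k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + D[i, j]; k <- k + 1
  }
  tot / k
}

brute_mean_nearest <- function(D) {
  n <- nrow(D)
  mins <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) if (j != i && D[i, j] < best) best <- D[i, j]
    mins[i] <- best
  }
  mean(mins)
}

# independent Pybus-Harvey evaluation, written directly from the published
# formula with explicit loops (oracle for gamma_statistic)
oracle_gamma <- function(btimes, Tnow) {
  btimes <- sort(btimes)
  n <- length(btimes) + 1
  stopifnot(n >= 3)
  g <- numeric(n)  # g[k] = interval with k lineages, k = 2..n
  for (k in 2:n) {
    lo <- btimes[k - 1]
    hi <- if (k == n) Tnow else btimes[k]
    g[k] <- hi - lo
  }
  Tt <- 0
  for (k in 2:n) Tt <- Tt + k * g[k]
  acc <- 0
  for (i in 2:(n - 1)) {
    s <- 0
    for (k in 2:i) s <- s + k * g[k]
    acc <- acc + s
  }
  (acc / (n - 2) - Tt / 2) / (Tt * sqrt(1 / (12 * (n - 2))))
}

# random ultrametric phylogeny via a random event registry
random_phylogeny <- function(n, seed, Tnow = 100) {
  set.seed(seed)
  ev <- if (n > 1)
    data.frame(time = sort(stats::runif(n - 1, 0, 0.9 * Tnow)),
               parent = vapply(2:n, function(k) sample.int(k - 1, 1), 1L),
               child = 2:n)
  else data.frame(time = numeric(0), parent = integer(0), child = integer(0))
  phylogeny(ev, extant = seq_len(n), time = Tnow)
}
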