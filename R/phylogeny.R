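#' Phylogeny from a speciation-event log
#'
#' Builds the phylogeny implied by a registry of speciation events
#' (\code{time}, \code{parent} species, \code{child} species).  Only the
#' listed extant species are retained as tips; extinct side branches are
#' pruned by construction because pairwise divergence times are traced
#' through the ancestry chains of the extant tips.  The resulting tree is
#' ultrametric: every tip sits at depth \code{time} (the present).
#'
#' @param events Data.frame with columns \code{time}, \code{parent},
#'   \code{child}; child ids must be unique and times non-decreasing.
#' @param extant Integer vector of extant species ids.
#' @param time Current time (depth of the tips).
#' @param root_species Id of the founding species (origin time 0).
#' @return An object of class \code{"phylogeny"}.
#' @export
phylogeny <- function(events, extant, time, root_species = 1L) {
  stopifnot(nrow(events) == 0L || !is.unsorted(events$time),
            !anyDuplicated(events$child),
            length(extant) >= 1L)
  p <- list(events = events, extant = sort(unique(as.integer(extant))),
            time = time, root_species = as.integer(root_species))
  class(p) <- "phylogeny"
  # ancestry chain per extant species: ids from root to tip + entry times
  p$chains <- lapply(p$extant, ancestry_chain, events = events,
                     root = p$root_species)
  names(p$chains) <- as.character(p$extant)
  p
}

ancestry_chain <- function(species, events, root) {
  ids <- integer(0); entry <- numeric(0)
  s <- species
  while (s != root) {
    i <- match(s, events$child)
    if (is.na(i)) stop("species ", s, " has no recorded origin")
    ids <- c(s, ids); entry <- c(events$time[i], entry)
    s <- events$parent[i]
  }
  list(ids = c(root, ids), entry = c(0, entry))
}

#' @export
print.phylogeny <- function(x, ...) {
  cat(sprintf("Ultrametric phylogeny: %d extant species at time %g (%d recorded speciation events)\n",
              length(x$extant), x$time, nrow(x$events)))
  invisible(x)
}

# divergence (MRCA) time of two extant species via their ancestry chains
divergence_time <- function(phylo, a, b) {
  if (a == b) return(phylo$time)
  ca <- phylo$chains[[as.character(a)]]
  cb <- phylo$chains[[as.character(b)]]
  if (is.null(ca) || is.null(cb)) stop("unknown species id")
  m <- min(length(ca$ids), length(cb$ids))
  shared <- ca$ids[seq_len(m)] == cb$ids[seq_len(m)]
  L <- if (all(shared)) m else which(!shared)[1L] - 1L
  if (L == 0L) stop("species do not share the root lineage")
  cand <- c(if (length(ca$entry) > L) ca$entry[L + 1L],
            if (length(cb$entry) > L) cb$entry[L + 1L])
  min(cand)
}

# matrix of pairwise divergence times over extant species
divergence_matrix <- function(phylo) {
  sp <- phylo$extant
  n <- length(sp)
  D <- matrix(phylo$time, n, n, dimnames = list(sp, sp))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- divergence_time(phylo, sp[i], sp[j])
  D
}

#' Patristic distance between two extant species
#'
#' Distance along the tree between two tips.  On an ultrametric tree this
#' is twice the time elapsed since their most recent common ancestor:
#' \eqn{2 (T - t_{MRCA})}.
#'
#' @param phylo A \code{\link{phylogeny}}.
#' @param a,b Extant species ids.
#' @return Patristic distance in time units (0 iff \code{a == b}).
#' @export
patristic_distance <- function(phylo, a, b) {
  2 * (phylo$time - divergence_time(phylo, a, b))
}

# full patristic matrix
patristic_matrix <- function(phylo) 2 * (phylo$time - divergence_matrix(phylo))

#' Newick export of a phylogeny
#'
#' Writes the ultrametric tree over the extant species as a Newick string
#' with branch lengths in evolutionary time units; tips are labeled
#' \code{S<id>}.  Simultaneous splits yield multifurcations.  Parsing the
#' string back (e.g. with \code{ape::read.tree}) recovers every pairwise
#' patristic distance.
#'
#' @param phylo A \code{\link{phylogeny}}.
#' @return A single Newick string (terminated by \code{";"}).
#' @export
to_newick <- function(phylo) {
  D <- divergence_matrix(phylo)
  Tnow <- phylo$time
  fmt <- function(x) sprintf("%.15g", x)
  clade <- function(tips, stem_start) {
    if (length(tips) == 1L)
      return(sprintf("S%d:%s", phylo$extant[tips], fmt(Tnow - stem_start)))
    sub <- D[tips, tips, drop = FALSE]
    t0 <- min(sub[upper.tri(sub)])
    groups <- split_at_time(sub, t0)
    inner <- vapply(groups, function(g) clade(tips[g], t0), "")
    sprintf("(%s):%s", paste(inner, collapse = ","), fmt(t0 - stem_start))
  }
  n <- length(phylo$extant)
  if (n == 1L)
    return(sprintf("(S%d:%s);", phylo$extant, fmt(Tnow)))
  paste0(clade(seq_len(n), 0), ";")
}

# connected components of "divergence strictly later than t0" = daughter clades
split_at_time <- function(D, t0) {
  n <- nrow(D)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(D[v, ] > t0 & comp == 0L))
    }
  }
  split(seq_len(n), comp)
}

#' Branching times of the extant-species tree
#'
#' Internal-node times of the reconstructed (extinct-pruned) ultrametric
#' tree, sorted increasing; a multifurcation into k daughters contributes
#' k - 1 identical times, so a tree with n tips always yields n - 1 values.
#'
#' @param phylo A \code{\link{phylogeny}}.
#' @return Numeric vector of node times (time units since the origin).
#' @export
branching_times <- function(phylo) {
  n <- length(phylo$extant)
  if (n < 2L) return(numeric(0))
  D <- divergence_matrix(phylo)
  out <- numeric(0)
  rec <- function(tips) {
    if (length(tips) == 1L) return(invisible())
    sub <- D[tips, tips, drop = FALSE]
    t0 <- min(sub[upper.tri(sub)])
    groups <- split_at_time(sub, t0)
    out <<- c(out, rep(t0, length(groups) - 1L))
    for (g in groups) rec(tips[g])
  }
  rec(seq_len(n))
  sort(out)
}

#' Pybus--Harvey gamma statistic
#'
#' Measures the temporal distribution of branching events in an ultrametric
#' tree from its internode intervals.  Under a constant-rate pure-birth
#' process gamma is asymptotically standard normal; negative values
#' indicate branching concentrated early in the tree's history, positive
#' values a late burst.
#'
#' @param btimes Branching (node) times of the reconstructed tree, as from
#'   \code{\link{branching_times}}; the smallest is the root.
#' @param time Present time (depth of the tips).
#' @return The gamma statistic (dimensionless).  At least 3 tips (2
#'   branching events) are required; otherwise an error is signaled.
#' @export
gamma_statistic <- function(btimes, time) {
  btimes <- sort(as.numeric(btimes))
  n <- length(btimes) + 1L            # number of tips
  if (n < 3L) stop("gamma statistic requires at least 3 extant species")
  if (time < btimes[length(btimes)]) stop("branching times exceed the present")
  g <- diff(c(btimes, time))          # g[k-1] = interval with k lineages
  k <- 2:n
  kg <- k * g
  Tt <- sum(kg)
  inner <- cumsum(kg)[seq_len(n - 2L)]  # sums up to i = 2..n-1
  (mean(inner) - Tt / 2) / (Tt * sqrt(1 / (12 * (n - 2))))
}
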