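#' Cluster trait values by the gap rule
#'
#' Sorts trait values and splits wherever two adjacent values are more than
#' \code{threshold} apart.  Equivalent to single-linkage clustering cut at
#' \code{threshold} on the line.
#'
#' @param z Numeric trait values.
#' @param threshold Maximal within-cluster adjacent gap (a gap strictly
#'   larger splits).
#' @return Integer cluster memberships (1-based, ordered by increasing
#'   cluster mean trait), same length as \code{z}.
#' @export
trait_gap_clusters <- function(z, threshold) {
  n <- length(z)
  if (n == 0L) return(integer(0))
  o <- order(z)
  breaks <- which(diff(z[o]) > threshold)
  cl_sorted <- rep.int(seq_len(length(breaks) + 1L),
                       diff(c(0L, breaks, n)))
  cl <- integer(n)
  cl[o] <- cl_sorted
  cl
}

#' Assign populations to species and register speciation events
#'
#' A species is a set of populations of common descent with a continuous
#' trait distribution: no gap between adjacent traits larger than
#' \code{3 * sigma_mu}.  Each existing species is re-examined; when its
#' trait distribution has split into several clusters, the cluster with the
#' largest total abundance keeps the parental species id (ties broken by
#' the cluster mean trait closest to the parental mean, then by the lower
#' mean trait) and every other cluster becomes a new species, each split
#' registered as one speciation event at the current time.
#'
#' @param state A \code{\link{community_state}}.
#' @param params A \code{\link{model_params}} object (only
#'   \code{sigma_mu} is used).
#' @param time Time stamped on emitted events (defaults to
#'   \code{state$time}).
#' @return A list with the relabeled \code{state} and \code{events}, a
#'   data.frame with columns \code{time}, \code{parent}, \code{child} (zero
#'   rows if nothing split).
#' @export
assign_species <- function(state, params, time = state$time) {
  threshold <- 3 * params$sigma_mu
  events <- list()
  for (sp in sort(unique(state$species_id))) {
    idx <- which(state$species_id == sp)
    if (length(idx) < 2L) next
    cl <- trait_gap_clusters(state$z[idx], threshold)
    k <- max(cl)
    if (k == 1L) next
    totN <- vapply(seq_len(k), function(c) sum(state$N[idx[cl == c]]), 1.0)
    wmean <- vapply(seq_len(k), function(c) {
      i <- idx[cl == c]
      sum(state$z[i] * state$N[i]) / sum(state$N[i])
    }, 1.0)
    parent_mean <- sum(state$z[idx] * state$N[idx]) / sum(state$N[idx])
    # parental label goes to the heaviest cluster
    keep <- order(-totN, abs(wmean - parent_mean), wmean)[1L]
    for (c in setdiff(order(wmean), keep)) {
      new_id <- state$next_species_id
      state$next_species_id <- new_id + 1L
      state$species_id[idx[cl == c]] <- new_id
      events[[length(events) + 1L]] <-
        data.frame(time = time, parent = sp, child = new_id)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else empty_event_log()
  list(state = state, events = events)
}

empty_event_log <- function() {
  data.frame(time = numeric(0), parent = integer(0), child = integer(0))
}
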