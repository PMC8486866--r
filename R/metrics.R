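#' Mean pairwise phylogenetic distance (MPD)
#'
#' Arithmetic mean of the patristic distance over all unordered pairs of
#' extant species.
#'
#' @param phylo A \code{\link{phylogeny}} with at least 2 extant species.
#' @return MPD in time units; fewer than 2 species signal an error (the
#'   metric is undefined, not zero).
#' @export
mpd <- function(phylo) {
  P <- need_pairs(patristic_matrix(phylo))
  mean(P[upper.tri(P)])
}

#' Mean nearest-neighbor phylogenetic distance (NNPD)
#'
#' Mean over extant species of the patristic distance to the closest other
#' species.
#'
#' @inheritParams mpd
#' @return NNPD in time units.
#' @export
nnpd <- function(phylo) {
  P <- need_pairs(patristic_matrix(phylo))
  diag(P) <- Inf
  mean(apply(P, 1L, min))
}

need_pairs <- function(M) {
  if (nrow(M) < 2L)
    stop("metric undefined for fewer than 2 species")
  M
}

#' Mean pairwise trait distance (MTD)
#'
#' Mean absolute difference between species mean traits over all unordered
#' pairs.
#'
#' @param traits Numeric vector of species mean traits (length >= 2).
#' @return MTD in trait units.
#' @export
mtd <- function(traits) {
  if (length(traits) < 2L) stop("metric undefined for fewer than 2 species")
  d <- abs(outer(traits, traits, "-"))
  mean(d[upper.tri(d)])
}

#' Mean nearest trait distance (MNTD)
#'
#' Mean over species of the absolute trait distance to the nearest other
#' species.
#'
#' @inheritParams mtd
#' @return MNTD in trait units.
#' @export
mntd <- function(traits) {
  if (length(traits) < 2L) stop("metric undefined for fewer than 2 species")
  d <- abs(outer(traits, traits, "-"))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' One row of community-structure metrics
#'
#' Computes richness, MPD, NNPD, MTD, MNTD and gamma for a community and
#' its phylogeny at one time point.  Metrics that are undefined at the
#' current richness (pair metrics below 2 species, gamma below 3) are
#' reported as \code{NA}, never as 0.
#'
#' @param state A \code{\link{community_state}}.
#' @param phylo The \code{\link{phylogeny}} of its extant species.
#' @param params A \code{\link{model_params}} object.
#' @param replicate Replicate id stored in the record.
#' @return A one-row data.frame with columns \code{time}, \code{replicate},
#'   \code{sigma_con}, \code{richness}, \code{MPD}, \code{NNPD},
#'   \code{MTD}, \code{MNTD}, \code{gamma}.
#' @export
metrics_record <- function(state, phylo, params, replicate = 1L) {
  ss <- species_summary(state)
  n <- nrow(ss)
  rec <- data.frame(time = state$time, replicate = replicate,
                    sigma_con = params$sigma_con, richness = n,
                    MPD = NA_real_, NNPD = NA_real_,
                    MTD = NA_real_, MNTD = NA_real_, gamma = NA_real_)
  if (n >= 2L) {
    rec$MPD <- mpd(phylo)
    rec$NNPD <- nnpd(phylo)
    rec$MTD <- mtd(ss$mean_trait)
    rec$MNTD <- mntd(ss$mean_trait)
  }
  if (n >= 3L)
    rec$gamma <- gamma_statistic(branching_times(phylo), phylo$time)
  rec
}

#' Scale metric series to a baseline niche width
#'
#' Divides each scenario's metric series, pointwise in snapshot time, by
#' the value of the baseline scenario at the same time, turning absolute
#' metrics into change factors relative to the reference niche width
#' (default \code{sigma_con = 0.1}).  The baseline scenario maps to 1
#' wherever it is defined; time points where the baseline is undefined are
#' missing in the output.
#'
#' @param metrics Data.frame with at least columns \code{time},
#'   \code{sigma_con} and the metric column.
#' @param column Name of the metric column to scale.
#' @param baseline Niche width used as reference.
#' @return The input data.frame with an added column
#'   \code{<column>_scaled}.
#' @export
scale_to_baseline <- function(metrics, column = "MPD", baseline = 0.1) {
  stopifnot(column %in% names(metrics))
  base <- metrics[metrics$sigma_con == baseline, c("time", column)]
  if (nrow(base) == 0L) stop("baseline sigma_con = ", baseline, " not present")
  ref <- base[[column]][match(metrics$time, base$time)]
  ref[!is.na(ref) & ref == 0] <- NA_real_
  metrics[[paste0(column, "_scaled")]] <- metrics[[column]] / ref
  metrics
}

#' Write a metrics table as TSV
#'
#' Tab-delimited UTF-8 table with a header row and a fixed column order
#' (\code{time}, \code{replicate}, \code{sigma_con}, \code{richness},
#' \code{MPD}, \code{NNPD}, \code{MTD}, \code{MNTD}, \code{gamma});
#' undefined metrics are written as empty fields.
#'
#' @param metrics Metrics data.frame (rows from
#'   \code{\link{metrics_record}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  cols <- c("time", "replicate", "sigma_con", "richness",
            "MPD", "NNPD", "MTD", "MNTD", "gamma")
  stopifnot(all(cols %in% names(metrics)))
  utils::write.table(metrics[, cols], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}
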