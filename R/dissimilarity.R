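#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|a - b|) / sum(a + b)`: 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param a,b non-negative numeric vectors of equal length, not both zero.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("Bray-Curtis undefined: both vectors are all-zero")
  sum(abs(a - b)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Distances between all sample pairs of a count or group table, computed
#' with [vegan::vegdist()]; returned as a symmetric matrix with zero
#' diagonal.
#'
#' @param table a [count_table()] or `group_table` (or a plain matrix with
#'   samples in columns).
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
bc_distance_matrix <- function(table) {
  m <- if (inherits(table, "count_table")) table$counts
       else if (inherits(table, "group_table")) table$abundance
       else as.matrix(table)
  if (ncol(m) < 2) stop("Need at least 2 samples for a distance matrix")
  zero <- colSums(m) == 0
  if (any(zero))
    stop("All-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Bray-Curtis trajectories from a reference month
#'
#' For each size-fraction, the dissimilarity between the reference month's
#' sample of that fraction and the same fraction at every other sampling
#' date — the within-fraction temporal trajectory. The reference defaults
#' to the maximum-gamma month (the survey's criterion: "the sample with
#' higher diversity"; in the two-year design that was January of the second
#' winter).
#'
#' @param table a [count_table()] (typically rarefied).
#' @param reference c(year, month), or NULL to auto-select the month with
#'   maximal gamma richness.
#' @return data.frame: fraction, fraction_rank, year, month, calendar
#'   ordering columns, and `bc`; the reference sample itself is excluded.
#' @export
reference_trajectory <- function(table, reference = NULL) {
  stopifnot(inherits(table, "count_table"))
  meta <- table$meta
  if (is.null(reference)) {
    ps <- partition_series(table)
    best <- ps[which.max(ps$gamma), ]
    reference <- c(best$year, best$month)
  }
  ref_sel <- meta$year == reference[1] & meta$month == reference[2]
  if (!any(ref_sel))
    stop("Reference month ", reference[1], "-", reference[2], " not sampled")
  out <- list()
  for (fr in sort(unique(meta$fraction_rank))) {
    ref_j <- which(ref_sel & meta$fraction_rank == fr)
    if (length(ref_j) == 0) {
      warning("Reference month missing fraction rank ", fr, "; skipped")
      next
    }
    others <- which(meta$fraction_rank == fr & !ref_sel)
    if (length(others) == 0) next
    bc <- vapply(others, function(j)
      bray_curtis(table$counts[, ref_j], table$counts[, j]), numeric(1))
    out[[length(out) + 1]] <- data.frame(
      fraction = meta$fraction[ref_j], fraction_rank = fr,
      year = meta$year[others], month = meta$month[others],
      ordinal_date = meta$ordinal_date[others], bc = bc)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$fraction_rank, res$month, res$year), ]
  rownames(res) <- NULL
  attr(res, "reference") <- reference
  res
}

#' Warm/cold period composition summaries
#'
#' Mean percent composition per group, per size-fraction, in the warm
#' (May-October) and cold (November-April) periods — the two community
#' regimes of the temperate annual cycle.
#'
#' @param groups a `group_table` (percent scale, dominant groups selected).
#' @param warm_months integer months of the warm period (default 5:10).
#' @return data.frame: period, fraction, fraction_rank, group,
#'   mean_percent; per (period, fraction) the means sum to 100.
#' @export
period_composition <- function(groups, warm_months = 5:10) {
  stopifnot(inherits(groups, "group_table"))
  meta <- groups$meta
  period <- ifelse(meta$month %in% warm_months, "warm", "cold")
  out <- list()
  for (p in c("cold", "warm")) {
    for (fr in sort(unique(meta$fraction_rank))) {
      sel <- period == p & meta$fraction_rank == fr
      if (!any(sel)) next
      mu <- rowMeans(groups$abundance[, sel, drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        period = p, fraction = meta$fraction[which(sel)[1]],
        fraction_rank = fr, group = names(mu), mean_percent = unname(mu))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
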