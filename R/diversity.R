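#' OTU richness of one sample
#'
#' Number of OTUs with a strictly positive count (diversity of order 0).
#'
#' @param sample_counts non-negative numeric vector.
#' @return integer richness.
#' @export
richness <- function(sample_counts) {
  stopifnot(all(sample_counts >= 0))
  sum(sample_counts > 0)
}

#' Multiplicative diversity partition of one month
#'
#' True diversities of the month's community set across size-fractions,
#' richness-based: alpha is the mean per-fraction richness, gamma the
#' richness of the pooled community, and beta = gamma / alpha the
#' taxonomic differentiation between fractions (1 = identical fractions,
#' up to the number of fractions for fully disjoint ones).
#'
#' @param samples list (or matrix columns) of count vectors over a shared
#'   OTU index, one per fraction; at least 2.
#' @return list(alpha, beta, gamma, n_fractions).
#' @export
partition_month <- function(samples) {
  if (is.matrix(samples)) samples <- lapply(seq_len(ncol(samples)),
                                            function(j) samples[, j])
  if (length(samples) < 2)
    stop("Diversity partition undefined for fewer than 2 fractions")
  len <- unique(lengths(samples))
  if (length(len) != 1) stop("Count vectors must share one OTU index")
  alpha <- mean(vapply(samples, richness, numeric(1)))
  gamma <- richness(Reduce(`+`, samples))
  list(alpha = alpha, beta = gamma / alpha, gamma = gamma,
       n_fractions = length(samples))
}

#' Diversity partition series over all sampled months
#'
#' One multiplicative partition per (year, month) sampling, computed across
#' that month's size-fractions, chronologically ordered. Computed on the
#' table as given — rarefy first so richness is depth-comparable.
#'
#' @param table a [count_table()] (typically rarefied).
#' @return data.frame: year, month, ordinal_date, alpha, beta, gamma,
#'   n_fractions.
#' @export
partition_series <- function(table) {
  stopifnot(inherits(table, "count_table"))
  meta <- table$meta
  key <- unique(meta[, c("year", "month", "ordinal_date")])
  key <- key[order(key$year, key$month), , drop = FALSE]
  res <- lapply(seq_len(nrow(key)), function(i) {
    sel <- meta$year == key$year[i] & meta$month == key$month[i]
    if (sum(sel) < 2) {
      warning("Month ", key$year[i], "-", key$month[i],
              " has fewer than 2 fractions; skipped")
      return(NULL)
    }
    p <- partition_month(lapply(which(sel), function(j) table$counts[, j]))
    data.frame(year = key$year[i], month = key$month[i],
               ordinal_date = key$ordinal_date[i],
               alpha = p$alpha, beta = p$beta, gamma = p$gamma,
               n_fractions = p$n_fractions)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
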