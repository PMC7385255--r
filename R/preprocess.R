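#' Remove OTUs whose lineage matches banned terms
#'
#' Drops OTUs carrying any of the banned terms (case-insensitive substring
#' match on any taxonomic rank). The default list removes chloroplast,
#' mitochondrial and eukaryotic sequences, the standard unwanted reads of a
#' bacterial 16S survey.
#'
#' @param table a [count_table()].
#' @param banned_terms character vector of terms.
#' @return filtered count_table.
#' @export
filter_taxa <- function(table,
                        banned_terms = c("chloroplast", "mitochondria", "eukaryota")) {
  stopifnot(inherits(table, "count_table"))
  if (length(banned_terms) == 0) return(table)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  lineage <- do.call(paste, c(table$taxonomy[ranks], sep = ";"))
  hit <- Reduce(`|`, lapply(banned_terms, function(term)
    grepl(term, lineage, ignore.case = TRUE, fixed = FALSE)))
  if (all(hit)) stop("filter_taxa would remove every OTU")
  subset_count_table(table, otus = !hit)
}

#' Remove low-total OTUs
#'
#' Keeps OTUs whose total count across all samples is at least `min_total`
#' (strictly-less-than rule: an OTU totalling `min_total - 1` is removed,
#' one totalling `min_total` is kept).
#'
#' @param table a [count_table()].
#' @param min_total minimum total count (default 5).
#' @return filtered count_table.
#' @export
filter_min_total <- function(table, min_total = 5L) {
  stopifnot(inherits(table, "count_table"), min_total >= 1)
  keep <- rowSums(table$counts) >= min_total
  if (!any(keep)) stop("filter_min_total would remove every OTU")
  subset_count_table(table, otus = keep)
}

#' Rarefy a count table to a common depth
#'
#' Exact without-replacement subsampling of every sample's reads down to
#' `depth` (or, with `depth = "min"`, to the smallest sample total), the
#' standard normalization making richness comparable across samples. The
#' subsampling is delegated to [vegan::rrarefy()] under a fixed seed.
#'
#' @param table a [count_table()].
#' @param depth integer target depth, or "min".
#' @param seed integer seed (mandatory for reproducibility).
#' @return rarefied count_table; all column sums equal `depth`.
#' @export
rarefy_counts <- function(table, depth = "min", seed) {
  stopifnot(inherits(table, "count_table"))
  if (missing(seed)) stop("rarefy_counts requires an explicit seed")
  totals <- colSums(table$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  low <- totals < depth
  if (any(low))
    stop("Sample(s) below rarefaction depth ", depth, ": ",
         paste(names(totals)[low], collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # vegan warns when it guesses the input might not be raw counts; the
  # count_table class already guarantees integer observed counts
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(table$counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(rar) <- "integer"
  out <- table
  out$counts <- rar
  # rarefaction can zero out OTU rows; keep them so OTU indexing is stable
  out
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts over all OTUs sharing the same taxon at `rank` and converts
#' to percent of the sample total. OTUs with an empty entry at that rank go
#' to an "Unclassified" group. A `mixed_rules` list allows a custom
#' mixed-rank grouping (as used for dominance tables whose groups span
#' phylum to genus): each rule is `list(name =, rank =, match =)` and OTUs
#' are assigned to the first rule whose `match` equals their taxon at
#' `rank` (case-insensitive); unmatched OTUs fall back to the plain
#' single-rank aggregation.
#'
#' @param table a [count_table()].
#' @param rank one of "phylum", "class", "order", "family", "genus".
#' @param mixed_rules optional list of mixed-rank rules.
#' @return object of class `group_table`: list(abundance = percent matrix
#'   group x sample, counts = count matrix, meta, rank).
#' @export
aggregate_taxonomy <- function(table, rank = "genus", mixed_rules = NULL) {
  stopifnot(inherits(table, "count_table"),
            rank %in% c("phylum", "class", "order", "family", "genus"))
  tax <- table$taxonomy
  group <- as.character(tax[[rank]])
  group[is.na(group) | group == ""] <- "Unclassified"
  if (!is.null(mixed_rules)) {
    assigned <- rep(NA_character_, nrow(tax))
    for (rule in mixed_rules) {
      hit <- is.na(assigned) &
        tolower(as.character(tax[[rule$rank]])) == tolower(rule$match)
      assigned[hit] <- rule$name
    }
    group[!is.na(assigned)] <- assigned[!is.na(assigned)]
  }
  counts <- rowsum(table$counts, group)
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  structure(list(abundance = pct, counts = counts, meta = table$meta,
                 rank = rank),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat("group_table:", nrow(x$abundance), "groups x", ncol(x$abundance),
      "samples (percent scale)\n")
  invisible(x)
}

#' Select dominant groups, pooling the rest as "Other bacteria"
#'
#' Retains groups whose relative abundance exceeds `threshold_pct` percent
#' (strictly) in at least one sample of any size-fraction; all remaining
#' groups are summed into a single "Other bacteria" group, so column totals
#' are preserved.
#'
#' @param groups a `group_table` (percent scale).
#' @param threshold_pct dominance threshold in percent (default 1).
#' @param other_label label for the pooled group.
#' @return a `group_table` with the retained groups plus the pooled group.
#' @export
select_abundant <- function(groups, threshold_pct = 1.0,
                            other_label = "Other bacteria") {
  stopifnot(inherits(groups, "group_table"))
  keep <- apply(groups$abundance, 1, max) > threshold_pct
  if (!any(keep))
    warning("No group exceeds ", threshold_pct, "%; all pooled into '",
            other_label, "'")
  pooled_abund <- rbind(groups$abundance[keep, , drop = FALSE],
                        colSums(groups$abundance[!keep, , drop = FALSE]))
  pooled_counts <- rbind(groups$counts[keep, , drop = FALSE],
                         colSums(groups$counts[!keep, , drop = FALSE]))
  rownames(pooled_abund)[nrow(pooled_abund)] <- other_label
  rownames(pooled_counts)[nrow(pooled_counts)] <- other_label
  structure(list(abundance = pooled_abund, counts = pooled_counts,
                 meta = groups$meta, rank = groups$rank,
                 threshold_pct = threshold_pct),
            class = "group_table")
}

#' Average group abundances into a group x fraction x month cube
#'
#' Builds `x(g, f, m)`: the percent relative abundance of group `g` in
#' fraction `f` and calendar month `m`, averaged over all years sampled
#' (so a month sampled in both years contributes the mean of its two
#' percent profiles; June of the two-year design contributes three). Cells
#' with no observation are NA, with `n_obs` recording coverage.
#'
#' @param groups a `group_table` (percent scale; metadata attached).
#' @return object of class `abundance_cube`: list(x = 3-d array
#'   group x fraction x month, n_obs = fraction x month matrix,
#'   fractions, groups).
#' @export
month_average_cube <- function(groups) {
  stopifnot(inherits(groups, "group_table"))
  meta <- groups$meta
  stopifnot(all(c("month", "fraction_rank") %in% names(meta)))
  gnames <- rownames(groups$abundance)
  franks <- sort(unique(meta$fraction_rank))
  x <- array(NA_real_, dim = c(length(gnames), length(franks), 12),
             dimnames = list(gnames, paste0("F", franks), month.name))
  n_obs <- matrix(0L, length(franks), 12,
                  dimnames = list(paste0("F", franks), month.name))
  for (fi in seq_along(franks)) {
    for (m in 1:12) {
      sel <- meta$fraction_rank == franks[fi] & meta$month == m
      if (any(sel)) {
        x[, fi, m] <- rowMeans(groups$abundance[, sel, drop = FALSE])
        n_obs[fi, m] <- sum(sel)
      }
    }
  }
  if (any(n_obs == 0))
    warning("Empty (fraction, month) cell(s); HDI for those months will ",
            "use observed fractions only")
  structure(list(x = x, n_obs = n_obs, fraction_ranks = franks,
                 groups = gnames),
            class = "abundance_cube")
}

#' Construct an abundance cube from an array
#'
#' Low-level constructor for the group x fraction x calendar-month percent
#' array, for cubes built directly rather than via [month_average_cube()].
#'
#' @param x numeric array group x fraction x 12 (NA for unobserved cells).
#' @param n_obs optional fraction x 12 observation-count matrix; defaults
#'   to 1 where any group value is observed.
#' @return an `abundance_cube`.
#' @export
abundance_cube <- function(x, n_obs = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] == 12)
  if (is.null(dimnames(x)[[1]])) dimnames(x)[[1]] <- paste0("g", seq_len(dim(x)[1]))
  if (is.null(n_obs))
    n_obs <- 1L * apply(!is.na(x), c(2, 3), any)
  structure(list(x = x, n_obs = n_obs,
                 fraction_ranks = seq_len(dim(x)[2]),
                 groups = dimnames(x)[[1]]),
            class = "abundance_cube")
}

#' Standard preprocessing chain
#'
#' filter_taxa -> filter_min_total -> rarefy -> aggregate -> select_abundant,
#' with the survey's standard settings (minimum total 5, rarefaction to the
#' minimum depth, 1 percent dominance threshold).
#'
#' @param table a [count_table()].
#' @param seed rarefaction seed.
#' @param min_total,rarefy_depth,rank,threshold_pct,banned_terms see the
#'   individual stages.
#' @return list(rarefied = count_table, groups = group_table).
#' @export
preprocess_pipeline <- function(table, seed, min_total = 5L,
                                rarefy_depth = "min", rank = "genus",
                                threshold_pct = 1.0,
                                banned_terms = c("chloroplast", "mitochondria",
                                                 "eukaryota")) {
  tb <- filter_taxa(table, banned_terms)
  tb <- filter_min_total(tb, min_total)
  tb <- rarefy_counts(tb, rarefy_depth, seed = seed)
  grp <- aggregate_taxonomy(tb, rank)
  grp <- select_abundant(grp, threshold_pct)
  list(rarefied = tb, groups = grp)
}
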