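#' Construct a validated count table
#'
#' The package's central container: an integer OTU x sample matrix together
#' with per-sample metadata (sampling date, size-fraction) and per-OTU
#' ranked taxonomy.
#'
#' @param counts non-negative integer matrix, rows = OTUs (rownames set),
#'   columns = samples (colnames set).
#' @param meta data.frame with columns `sample_id`, `date` (ISO 8601) and
#'   `fraction` (a label resolvable against [size_fractions()] or against
#'   `fractions`). Derived columns year/month/ordinal_date/fraction_rank are
#'   added.
#' @param taxonomy data.frame with column `otu_id` plus ranked lineage
#'   columns `domain`, `phylum`, `class`, `order`, `family`, `genus`
#'   (empty strings allowed).
#' @param fractions fraction definition table, default [size_fractions()].
#' @return object of class `count_table`: list(counts, meta, taxonomy,
#'   fractions).
#' @export
count_table <- function(counts, meta, taxonomy, fractions = size_fractions()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (any(counts != round(counts)) || any(is.na(counts)))
    stop("counts must be integers with no missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("Negative count at OTU '", rownames(counts)[neg[1, 1]],
         "', sample '", colnames(counts)[neg[1, 2]], "'")
  storage.mode(counts) <- "integer"
  if (any(colSums(counts) == 0))
    stop("Sample(s) with zero total counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))

  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta) > 0)
    stop("No metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  d <- parse_iso_date(meta$date)
  meta$year <- d$year
  meta$month <- d$month
  meta$ordinal_date <- d$ordinal_date
  meta$fraction <- normalize_fraction_label(meta$fraction)
  meta$fraction_rank <- fraction_rank(meta$fraction, fractions)
  rownames(meta) <- NULL
  key <- paste(meta$year, meta$month, meta$fraction_rank)
  if (anyDuplicated(key))
    stop("Duplicate (year, month, fraction) sampling event: ",
         key[duplicated(key)][1])

  missing_tax <- setdiff(rownames(counts), taxonomy$otu_id)
  if (length(missing_tax) > 0)
    stop("No taxonomy for OTU(s): ", paste(utils::head(missing_tax, 5), collapse = ", "))
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  for (r in setdiff(ranks, names(taxonomy))) taxonomy[[r]] <- ""
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu_id),
                       c("otu_id", ranks), drop = FALSE]
  taxonomy[ranks] <- lapply(taxonomy[ranks], function(x) {
    x <- as.character(x); x[is.na(x)] <- ""; x
  })
  rownames(taxonomy) <- NULL

  structure(list(counts = counts, meta = meta, taxonomy = taxonomy,
                 fractions = fractions),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples\n")
  cat("  fractions:", paste(sort(unique(x$meta$fraction)), collapse = ", "), "\n")
  cat("  dates:", min(x$meta$date), "to", max(x$meta$date), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from three TSV files
#'
#' @param counts_path TSV: first column `otu_id`, remaining columns one per
#'   sample, integer cells.
#' @param taxonomy_path TSV: `otu_id` plus columns
#'   `domain,phylum,class,order,family,genus`.
#' @param meta_path TSV: columns `sample_id,date,fraction` with ISO 8601
#'   dates.
#' @param fractions fraction definition table.
#' @return a [count_table()].
#' @export
read_count_table <- function(counts_path, taxonomy_path, meta_path,
                             fractions = size_fractions()) {
  for (p in c(counts_path, taxonomy_path, meta_path))
    if (!file.exists(p)) stop("File not found: ", p)
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  if (names(raw)[1] != "otu_id") stop("counts TSV must start with an 'otu_id' column")
  otu_ids <- raw[[1]]
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(otu_ids, names(raw)[-1]))
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("Non-integer or negative count at OTU '", otu_ids[bad[1, 1]],
         "', sample '", colnames(num)[bad[1, 2]], "'")
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            colClasses = "character", comment.char = "#")
  taxonomy <- utils::read.delim(taxonomy_path, check.names = FALSE,
                                colClasses = "character", comment.char = "#",
                                na.strings = NULL)
  count_table(num, meta, taxonomy, fractions)
}

#' Write a count table to three TSV files
#'
#' Inverse of [read_count_table()]: writes `counts.tsv`, `taxonomy.tsv` and
#' `meta.tsv` into `out_dir` such that reading them back reproduces the
#' table exactly (counts, sample order, metadata and taxonomy, including
#' empty lineage fields).
#'
#' @param table a [count_table()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_count_table <- function(table, out_dir) {
  stopifnot(inherits(table, "count_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("counts.tsv", "taxonomy.tsv", "meta.tsv"))
  cdf <- data.frame(otu_id = rownames(table$counts), table$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$taxonomy, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$meta[, c("sample_id", "date", "fraction")],
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Documented environmental variable dictionary (column name -> units).
.env_vars <- c(
  day_length_h = "hours", sst_c = "degrees C", salinity = "PSU",
  secchi_m = "m", chl = "ug/L", po4 = "uM", no3 = "uM", nh4 = "uM",
  si = "uM", poc = "uM", toc = "uM", bact_abund = "cells/mL",
  bact_prod = "ugC/L/d"
)

#' Environmental variable dictionary
#'
#' Recognized column names of the environment table and their units.
#' @return named character vector (name -> unit).
#' @export
env_variable_dictionary <- function() .env_vars

#' Read an environment table
#'
#' One row per monthly sampling event; columns `date` (ISO 8601) plus any
#' subset of the documented variable dictionary ([env_variable_dictionary()]).
#' Missing values are written "NA" and kept as NA, never coerced to zero.
#'
#' @param path TSV path.
#' @return data.frame with `year`, `month`, `ordinal_date` and the numeric
#'   variable columns; class `env_table`.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           na.strings = "NA")
  if (!"date" %in% names(raw)) stop("env TSV must have a 'date' column")
  unknown <- setdiff(names(raw), c("date", names(.env_vars)))
  if (length(unknown) > 0)
    warning("Ignoring unrecognized env column(s): ", paste(unknown, collapse = ", "))
  d <- parse_iso_date(as.character(raw$date))
  key <- paste(d$year, d$month)
  if (anyDuplicated(key))
    stop("Duplicate (year, month) row in env table: ", key[duplicated(key)][1])
  vars <- intersect(names(.env_vars), names(raw))
  out <- data.frame(date = as.character(raw$date), year = d$year,
                    month = d$month, ordinal_date = d$ordinal_date,
                    stringsAsFactors = FALSE)
  for (v in vars) out[[v]] <- as.numeric(raw[[v]])
  if ("day_length_h" %in% vars) {
    dl <- out$day_length_h
    if (any(!is.na(dl) & (dl <= 0 | dl > 24)))
      stop("day_length_h out of (0, 24]")
  }
  class(out) <- c("env_table", "data.frame")
  out
}

#' Write an environment table
#' @param env an env_table (or compatible data.frame with a `date` column).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_env_table <- function(env, path) {
  keep <- c("date", intersect(names(.env_vars), names(env)))
  utils::write.table(env[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Subset a count table by samples or OTUs
#' @param table a count_table.
#' @param otus optional character/logical/integer index of OTUs to keep.
#' @param samples optional index of samples to keep.
#' @return a count_table.
#' @export
subset_count_table <- function(table, otus = NULL, samples = NULL) {
  stopifnot(inherits(table, "count_table"))
  counts <- table$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  if (nrow(counts) == 0) stop("Subset removed every OTU")
  meta <- table$meta[match(colnames(counts), table$meta$sample_id), , drop = FALSE]
  tax <- table$taxonomy[match(rownames(counts), table$taxonomy$otu_id), , drop = FALSE]
  rownames(meta) <- rownames(tax) <- NULL
  structure(list(counts = counts, meta = meta, taxonomy = tax,
                 fractions = table$fractions),
            class = "count_table")
}
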