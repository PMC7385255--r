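# Small in-code fixtures shared across test files.

# A tiny valid count table: n_otu OTUs x one sample per (month, fraction)
# combination given. Counts are deterministic (no RNG) unless jitter is set.
toy_table <- function(n_otu = 3, months = list(c(2012, 1)),
                      fractions = c("0.2-0.8", "0.8-3.0"),
                      base = 10L, jitter = 0L) {
  combos <- expand.grid(mi = seq_along(months), fr = fractions,
                        stringsAsFactors = FALSE)
  sample_ids <- sprintf("s%02d", seq_len(nrow(combos)))
  counts <- outer(seq_len(n_otu), seq_len(nrow(combos)),
                  function(i, j) base + i + 2L * j)
  if (jitter > 0) counts <- counts + matrix(
    sample.int(jitter, length(counts), replace = TRUE), nrow = n_otu)
  dimnames(counts) <- list(paste0("otu", seq_len(n_otu)), sample_ids)
  meta <- data.frame(
    sample_id = sample_ids,
    date = vapply(combos$mi, function(i)
      sprintf("%04d-%02d-15", months[[i]][1], months[[i]][2]), character(1)),
    fraction = combos$fr,
    stringsAsFactors = FALSE)
  tax <- data.frame(otu_id = rownames(counts), domain = "Bacteria",
                    phylum = "Proteobacteria", class = "",
                    order = "", family = "",
                    genus = paste0("Genus", seq_len(n_otu)),
                    stringsAsFactors = FALSE)
  count_table(counts, meta, tax)
}

# write a count table's three TSVs into a fresh temp dir and return paths
toy_tsvs <- function(table) {
  dir <- tempfile("fixt")
  paths <- write_count_table(table, dir)
  names(paths) <- c("counts", "taxonomy", "meta")
  paths
}

# test-local phase helpers, independent of the package internals
wrap_phase_test <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  if (y <= -pi) y + 2 * pi else y
}
phase_for_peak_test <- function(peak) wrap_phase_test(-2 * pi * peak / 365)

# a random abundance cube whose (fraction, month) columns sum to 100
random_cube <- function(n_groups, n_fractions, rng = NULL) {
  x <- array(NA_real_, dim = c(n_groups, n_fractions, 12))
  for (f in seq_len(n_fractions)) for (m in 1:12) {
    v <- stats::runif(n_groups)
    x[, f, m] <- 100 * v / sum(v)
  }
  dimnames(x) <- list(paste0("g", seq_len(n_groups)), NULL, month.name)
  abundance_cube(x)
}
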