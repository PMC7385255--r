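make_tax_table <- function() {
  counts <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L), nrow = 3,
                   dimnames = list(c("o1", "o2", "o3"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"),
                     date = c("2012-03-15", "2012-03-15"),
                     fraction = c("0.2-0.8", "0.8-3.0"))
  tax <- data.frame(otu_id = c("o1", "o2", "o3"),
                    domain = "Bacteria",
                    phylum = c("Cyanobacteria", "Cyanobacteria", "Bacteroidetes"),
                    class = c("Chloroplast", "", "Flavobacteria"),
                    order = "", family = "",
                    genus = c("", "Synechococcus", "Flavo1"))
  count_table(counts, meta, tax)
}

test_that("taxon filtering removes banned lineages by substring", {
  tb <- make_tax_table()
  out <- filter_taxa(tb)
  expect_setequal(rownames(out$counts), c("o2", "o3"))  # Chloroplast gone
  # 'Cyanobacteria; Synechococcus' lineage is kept
  expect_true("o2" %in% rownames(out$counts))
  # empty banned list is the identity
  expect_identical(filter_taxa(tb, character(0))$counts, tb$counts)
  expect_error(filter_taxa(tb, "bacteria"), "every OTU")
})

test_that("minimum-total filter uses a strict less-than rule over all samples", {
  counts <- matrix(c(2L, 4L, 5L, 3L, 0L, 0L), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"),
                     date = "2012-01-15", fraction = c("0.2-0.8", "0.8-3.0"))
  tax <- data.frame(otu_id = c("a", "b", "c"), genus = "G")
  tb <- count_table(counts, meta, tax)
  out <- filter_min_total(tb, 5)
  # a totals 2+3=5 (kept, spanning samples); b totals 4 (removed); c totals 5
  expect_setequal(rownames(out$counts), c("a", "c"))
  expect_identical(rownames(filter_min_total(tb, 1)$counts),
                   rownames(tb$counts))
})

test_that("rarefaction conserves depth, is monotone and seed-reproducible", {
  tb <- toy_table(n_otu = 8, months = list(c(2012, 1)), base = 40L)
  r1 <- rarefy_counts(tb, 100, seed = 4)
  r2 <- rarefy_counts(tb, 100, seed = 4)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(colSums(r1$counts) == 100))
  expect_true(all(r1$counts <= tb$counts))
  expect_error(rarefy_counts(tb, 10^6, seed = 1), "s01")
  expect_error(rarefy_counts(tb, 100), "seed")
  # depth "min" equalizes all samples at the smallest total
  rmin <- rarefy_counts(tb, "min", seed = 1)
  expect_true(all(colSums(rmin$counts) == min(colSums(tb$counts))))
})

test_that("rarefied counts follow hypergeometric expectations", {
  # one sample with counts (600, 400) subsampled to 500: the first OTU is
  # hypergeometric with mean 300; the empirical mean over seeded resamples
  # must sit within 3 standard errors of 300
  counts <- matrix(c(600L, 400L), nrow = 2,
                   dimnames = list(c("x", "y"), "s1"))
  meta <- data.frame(sample_id = "s1", date = "2012-01-15",
                     fraction = "0.2-0.8")
  tax <- data.frame(otu_id = c("x", "y"), genus = "G")
  tb <- count_table(counts, meta, tax)
  n_rep <- 1000
  draws <- vapply(seq_len(n_rep),
                  function(s) rarefy_counts(tb, 500, seed = s)$counts["x", 1],
                  numeric(1))
  sd_hyper <- sqrt(500 * 0.6 * 0.4 * (1000 - 500) / (1000 - 1))
  se_mean <- sd_hyper / sqrt(n_rep)
  expect_lt(abs(mean(draws) - 300), 3 * se_mean)
})

test_that("taxonomic aggregation sums, labels unclassified, and normalizes", {
  tb <- make_tax_table()
  counts <- tb$counts
  counts["o1", ] <- c(5L, 5L)
  tb <- count_table(counts, tb$meta, tb$taxonomy)
  g <- aggregate_taxonomy(tb, "phylum")
  expect_equal(g$counts["Cyanobacteria", "s1"], 5 + 20)
  expect_equal(unname(colSums(g$abundance)), c(100, 100), tolerance = 1e-9)
  gg <- aggregate_taxonomy(tb, "genus")
  expect_true("Unclassified" %in% rownames(gg$abundance))  # o1 empty genus
  # mixed-rank rules override the plain rank grouping
  gm <- aggregate_taxonomy(tb, "genus", mixed_rules = list(
    list(name = "Flavobacteria", rank = "class", match = "Flavobacteria")))
  expect_true("Flavobacteria" %in% rownames(gm$abundance))
  expect_false("Flavo1" %in% rownames(gm$abundance))
})

test_that("dominance selection pools sub-threshold groups losslessly", {
  ab <- matrix(c(97.5, 1.5, 0.6, 0.4,
                 98.8, 0.3, 0.5, 0.4), ncol = 2,
               dimnames = list(c("big", "once", "small1", "small2"),
                               c("s1", "s2")))
  g <- structure(list(abundance = ab, counts = ab,
                      meta = data.frame(sample_id = c("s1", "s2")),
                      rank = "genus"),
                 class = "group_table")
  out <- select_abundant(g, 1.0)
  # 'once' exceeds 1% in a single sample and is retained;
  # groups peaking at <=1% are pooled
  expect_setequal(rownames(out$abundance), c("big", "once", "Other bacteria"))
  expect_equal(unname(colSums(out$abundance)), c(100, 100), tolerance = 1e-9)
  expect_equal(out$abundance["Other bacteria", "s1"], 1.0)
  expect_warning(select_abundant(g, 99.9), "No group")
})

test_that("month averaging pools years and preserves composition sums", {
  tb <- toy_table(n_otu = 4,
                  months = list(c(2011, 6), c(2012, 6), c(2013, 6)),
                  fractions = "0.2-0.8", jitter = 0)
  g <- aggregate_taxonomy(tb, "genus")
  cube <- suppressWarnings(month_average_cube(g))
  expect_equal(cube$n_obs[1, 6], 3)           # three Junes averaged
  expect_equal(sum(cube$x[, 1, 6]), 100, tolerance = 1e-9)
  expect_equal(cube$x[, 1, 6],
               rowMeans(g$abundance), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(is.na(cube$x[, , 7])))      # unsampled month flagged NA
})
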