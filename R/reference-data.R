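#' Published monthly HDI reference values
#'
#' The published monthly HDI table for the 17 dominant taxonomic groups of
#' the two-year size-fractionated survey at the Blanes Bay Microbial
#' Observatory, shipped as a plain-text fixture. Used to validate the
#' package's HDI aggregation (row averages and grand average) against the
#' printed values.
#'
#' @return list: `monthly` (17 x 12 matrix, groups x January..December),
#'   `category` (named character vector of size-preference classes),
#'   `published_average` (named vector of the printed one-decimal row
#'   averages).
#' @export
hdi_reference_table <- function() {
  path <- system.file("extdata", "bbmo_hdi_reference.tsv",
                      package = "sizeseason")
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  monthly <- as.matrix(df[, month.name])
  rownames(monthly) <- df$group
  list(monthly = monthly,
       category = stats::setNames(df$category, df$group),
       published_average = stats::setNames(df$published_average, df$group))
}
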