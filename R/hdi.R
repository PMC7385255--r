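#' Annual-mean size-fraction profile of a group
#'
#' `A(g, f)`: the mean over the 12 calendar months of the group's percent
#' abundance in fraction `f` (the "annual average" reference profile).
#' Missing (fraction, month) cells are excluded from the mean.
#'
#' @param cube an `abundance_cube` from [month_average_cube()].
#' @param group group name.
#' @return numeric vector over fractions.
#' @export
annual_mean_profile <- function(cube, group) {
  stopifnot(inherits(cube, "abundance_cube"), group %in% cube$groups)
  xg <- cube$x[group, , , drop = TRUE]           # fraction x month
  if (any(is.na(xg)))
    warning("Missing cells excluded from the annual mean of '", group, "'")
  apply(xg, 1, mean, na.rm = TRUE)
}

#' Monthly Heterogeneous Distribution Index of a group
#'
#' The HDI for group `g` in calendar month `m`: the sum over size-fractions
#' of the absolute deviation of the group's abundance from its annual-mean
#' profile, `HDI(g, m) = sum_f |x(g, f, m) - A(g, f)|`, in percentage
#' points. Zero when the month's distribution across fractions equals the
#' annual average (the group keeps its size-fraction preference); large
#' when the distribution shifts.
#'
#' @param cube an `abundance_cube`.
#' @param group group name.
#' @param month calendar month 1..12.
#' @return non-negative HDI value.
#' @export
monthly_hdi <- function(cube, group, month) {
  stopifnot(inherits(cube, "abundance_cube"), month %in% 1:12)
  A <- annual_mean_profile(cube, group)
  xm <- cube$x[group, , month]
  if (all(is.na(xm))) stop("Month ", month, " has no observations")
  sum(abs(xm - A), na.rm = TRUE)
}

#' Aggregate a monthly HDI matrix
#'
#' Row means give each group's annual HDI; column means over groups give
#' the monthly community HDI; the grand average is the mean of the annual
#' (row-mean) values. Used internally by [hdi_table()] and directly when
#' aggregating an externally supplied monthly HDI matrix.
#'
#' @param monthly numeric matrix, groups x 12 calendar months.
#' @return list(monthly, annual = named row means, community = named column
#'   means, grand_average).
#' @export
hdi_aggregate <- function(monthly) {
  monthly <- as.matrix(monthly)
  stopifnot(ncol(monthly) == 12)
  annual <- rowMeans(monthly, na.rm = TRUE)
  community <- colMeans(monthly, na.rm = TRUE)
  list(monthly = monthly, annual = annual, community = community,
       grand_average = mean(annual))
}

#' Full HDI table for all groups and months
#'
#' Computes the monthly HDI matrix (groups x January..December), the
#' per-group annual averages ("Average" column), the per-month community
#' averages ("Average all groups together" row) and the grand average.
#'
#' @param cube an `abundance_cube` covering 12 calendar months.
#' @param exclude optional group names to drop (e.g. a pooled
#'   "Other bacteria" group, conventionally excluded from dominance
#'   tables).
#' @return object of class `hdi_result`: list(monthly, annual, community,
#'   grand_average, annual_profiles).
#' @export
hdi_table <- function(cube, exclude = character(0)) {
  stopifnot(inherits(cube, "abundance_cube"))
  groups <- setdiff(cube$groups, exclude)
  if (length(groups) == 0) stop("No groups left after exclusion")
  A <- t(vapply(groups, function(g) annual_mean_profile(cube, g),
                numeric(dim(cube$x)[2])))
  monthly <- vapply(1:12, function(m) {
    xm <- cube$x[groups, , m, drop = FALSE][, , 1]
    if (length(groups) == 1) xm <- matrix(xm, nrow = 1)
    rowSums(abs(xm - A), na.rm = TRUE)
  }, numeric(length(groups)))
  if (length(groups) == 1) monthly <- matrix(monthly, nrow = 1)
  dimnames(monthly) <- list(groups, month.name)
  observed <- apply(!is.na(cube$x), 3, any)
  monthly[, !observed] <- NA_real_
  agg <- hdi_aggregate(monthly)
  structure(c(agg, list(annual_profiles = A)), class = "hdi_result")
}

#' @export
print.hdi_result <- function(x, ...) {
  cat("HDI table:", nrow(x$monthly), "groups x 12 months\n")
  cat("  grand average:", round(x$grand_average, 2), "\n")
  rng <- range(x$annual)
  cat("  annual HDI range:", round(rng[1], 2), "-", round(rng[2], 2), "\n")
  invisible(x)
}

#' Write an HDI result as TSV tables
#'
#' `hdi_table.tsv` is the wide dominance-table layout (group rows, month
#' columns, an Average column and a community-average row, values rounded
#' to 2 decimals); `hdi_long.tsv` is tidy (group, month, hdi) at full
#' precision.
#'
#' @param result an `hdi_result`.
#' @param out_dir output directory.
#' @return invisibly, the two paths.
#' @export
write_hdi_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "hdi_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wide <- data.frame(group = rownames(result$monthly),
                     round(result$monthly, 2),
                     Average = round(result$annual, 2),
                     check.names = FALSE)
  wide <- rbind(wide, c(group = "Average all groups together",
                        as.list(round(result$community, 2)),
                        Average = round(result$grand_average, 2)))
  p1 <- file.path(out_dir, "hdi_table.tsv")
  utils::write.table(wide, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- expand.grid(group = rownames(result$monthly), month = 1:12,
                      stringsAsFactors = FALSE)
  long$hdi <- result$monthly[cbind(match(long$group, rownames(result$monthly)),
                                   long$month)]
  p2 <- file.path(out_dir, "hdi_long.tsv")
  utils::write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
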