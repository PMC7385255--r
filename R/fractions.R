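#' Canonical size-fractions of the particulate-matter continuum
#'
#' The six sequential-filtration intervals used throughout the package:
#' 0.2-0.8, 0.8-3.0, 3.0-5.0, 5.0-10, 10-20 and 20-200 um. The smallest
#' fraction approximates free-living cells; larger fractions approximate
#' increasingly large particles and their attached communities.
#'
#' @return A data.frame with columns `label`, `lower_um`, `upper_um`, `rank`
#'   (1 = smallest), one row per fraction, ordered by rank.
#' @export
size_fractions <- function() {
  data.frame(
    label = c("0.2-0.8", "0.8-3.0", "3.0-5.0", "5.0-10", "10-20", "20-200"),
    lower_um = c(0.2, 0.8, 3.0, 5.0, 10, 20),
    upper_um = c(0.8, 3.0, 5.0, 10, 20, 200),
    rank = 1:6,
    stringsAsFactors = FALSE
  )
}

#' Normalize a size-fraction label
#'
#' Strips whitespace and unifies dash characters (en/em dashes, minus) to
#' a plain hyphen so that labels written with typographic dashes resolve to
#' the same fraction.
#'
#' @param label character vector of fraction labels.
#' @return normalized character vector.
#' @export
normalize_fraction_label <- function(label) {
  x <- gsub("\\s+", "", as.character(label))
  # unify unicode dashes to '-'
  gsub("[‐‑‒–—―−]", "-", x)
}

#' Resolve fraction labels to ranks
#'
#' @param label character vector of labels.
#' @param fractions fraction table as from [size_fractions()].
#' @return integer vector of ranks.
#' @keywords internal
fraction_rank <- function(label, fractions = size_fractions()) {
  lab <- normalize_fraction_label(label)
  idx <- match(lab, normalize_fraction_label(fractions$label))
  if (anyNA(idx)) {
    bad <- unique(lab[is.na(idx)])
    stop("Unknown size-fraction label(s): ", paste(bad, collapse = ", "),
         ". Valid labels: ", paste(fractions$label, collapse = ", "))
  }
  fractions$rank[idx]
}

# Fixed 365-day calendar used for all ordinal dates (harmonic period is 365).
.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_offset <- c(0L, cumsum(.month_days))[1:12]

#' Ordinal date on a fixed 365-day calendar
#'
#' 29 February is folded onto ordinal 59 (the 28 February slot) so that all
#' years share the same 1..365 scale, consistent with the fixed 365-day
#' period of the harmonic model.
#'
#' @param month integer 1..12.
#' @param day integer day of month.
#' @return integer ordinal in 1..365.
#' @export
ordinal_date <- function(month, day) {
  stopifnot(all(month %in% 1:12))
  day <- ifelse(month == 2 & day > 28, 28L, as.integer(day))
  bad <- day < 1 | day > .month_days[month]
  if (any(bad)) stop("Invalid day of month: ", paste(day[bad], collapse = ", "))
  .month_offset[month] + day
}

#' Parse ISO 8601 dates into (year, month, day, ordinal)
#' @param date character vector "YYYY-MM-DD".
#' @return data.frame with year, month, day, ordinal_date.
#' @keywords internal
parse_iso_date <- function(date) {
  m <- regmatches(date, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", date))
  ok <- lengths(m) == 4
  if (!all(ok)) stop("Unparseable ISO date(s): ", paste(date[!ok], collapse = ", "))
  year <- vapply(m, function(p) as.integer(p[2]), integer(1))
  month <- vapply(m, function(p) as.integer(p[3]), integer(1))
  day <- vapply(m, function(p) as.integer(p[4]), integer(1))
  data.frame(year = year, month = month, day = day,
             ordinal_date = ordinal_date(month, day))
}
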