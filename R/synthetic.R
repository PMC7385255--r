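#' Astronomical day length from the sunrise equation
#'
#' Daylight duration for a latitude and ordinal date using solar
#' declination delta = 23.44 deg * sin(2*pi*(284 + n)/365) and hour angle H
#' from cos H = (sin h0 - sin phi sin delta)/(cos phi cos delta), where the
#' horizon altitude h0 is -0.833 deg with atmospheric refraction (and solar
#' disc radius) or 0 deg without. Day length is 2H/15 hours. cos H is
#' clamped to [-1, 1], so polar day/night return 24 or 0 hours and the
#' function is total.
#'
#' @param latitude_deg latitude in degrees; values beyond +-66.5 are valid
#'   and may yield the clamped 0/24 h extremes.
#' @param n ordinal date (integer vector, 1..365).
#' @param refraction logical; use the refraction-corrected horizon
#'   (default TRUE).
#' @return day length in hours (vector over `n`).
#' @export
day_length <- function(latitude_deg, n, refraction = TRUE) {
  stopifnot(all(n >= 1 & n <= 365))
  deg <- pi / 180
  delta <- 23.44 * deg * sin(2 * pi * (284 + n) / 365)
  phi <- latitude_deg * deg
  h0 <- if (refraction) -0.833 * deg else 0
  cosH <- (sin(h0) - sin(phi) * sin(delta)) / (cos(phi) * cos(delta))
  cosH <- pmin(1, pmax(-1, cosH))
  2 * (acos(cosH) / deg) / 15
}

#' Harmonic parameter triple
#'
#' Parameters of the annual cosine model
#' `Y = b1 + b2 * cos(2*pi*t/365 + b3)`: `b1` the annual mean, `b2` the
#' amplitude (>= 0), `b3` the phase in radians in (-pi, pi].
#'
#' @param b1,b2,b3 numeric scalars.
#' @return object of class `harmonic_params`.
#' @export
harmonic_params <- function(b1, b2, b3) {
  stopifnot(is.finite(b1), is.finite(b2), is.finite(b3), b2 >= 0)
  b3 <- wrap_phase(b3)
  structure(list(b1 = b1, b2 = b2, b3 = b3), class = "harmonic_params")
}

# wrap an angle into (-pi, pi]
wrap_phase <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

#' Phase whose annual maximum falls on a given ordinal date
#' @param peak_ordinal ordinal date (1..365) of the annual maximum.
#' @return phase b3 in radians, in (-pi, pi].
#' @export
phase_for_peak <- function(peak_ordinal) wrap_phase(-2 * pi * peak_ordinal / 365)

#' Sea surface temperature model
#'
#' Annual cosine `b1 + b2 * cos(2*pi*t/365 + b3)`. The default parameters
#' reproduce the Blanes Bay climatology: maximum 24.1 C in mid-August
#' (ordinal 227) and minimum 12.5 C in late winter, i.e. b1 = 18.3,
#' b2 = 5.8.
#'
#' @param t ordinal date (vector).
#' @param params a [harmonic_params()]; default the Blanes Bay SST cycle.
#' @return temperature in degrees C.
#' @export
sst_model <- function(t, params = harmonic_params(18.3, 5.8, phase_for_peak(227))) {
  params$b1 + params$b2 * cos(2 * pi * t / 365 + params$b3)
}

#' Specification of one synthetic taxonomic group
#'
#' @param name group name.
#' @param baseline_profile numeric vector, one expected relative-abundance
#'   weight per size-fraction (rank order, smallest first).
#' @param seasonal_amplitude numeric vector in [0, 1], one per fraction;
#'   multiplicative annual-cosine modulation depth.
#' @param peak_ordinal ordinal date (1..365) at which the group's seasonal
#'   modulation peaks.
#' @param preference one of "small", "small_not_smallest", "indifferent",
#'   "large" (the group's size-fraction preference class).
#' @return object of class `group_spec`.
#' @export
group_spec <- function(name, baseline_profile, seasonal_amplitude,
                       peak_ordinal, preference = "indifferent") {
  stopifnot(length(baseline_profile) == length(seasonal_amplitude),
            all(baseline_profile >= 0),
            all(seasonal_amplitude >= 0 & seasonal_amplitude <= 1),
            peak_ordinal >= 1, peak_ordinal <= 365,
            preference %in% c("small", "small_not_smallest", "indifferent", "large"))
  structure(list(name = name, baseline_profile = baseline_profile,
                 seasonal_amplitude = seasonal_amplitude,
                 peak_ordinal = peak_ordinal, preference = preference),
            class = "group_spec")
}

# per-preference fraction weight shapes (rank 1..6, smallest first)
.preference_shapes <- list(
  small = c(6, 3, 1.5, 1, 0.8, 0.6),
  small_not_smallest = c(0.5, 6, 3, 1.5, 1, 0.8),
  indifferent = c(1, 1, 1, 1, 1, 1),
  large = c(0.5, 0.8, 1.2, 2, 3.5, 3)
)

#' Default group specifications
#'
#' Seventeen dominant groups plus one "rare pool" group, mirroring the
#' preference-class composition observed at the study site (2 small-fraction
#' specialists, 1 small-but-not-smallest, 3 indifferent, 11 large-fraction
#' specialists). Group masses decay geometrically so a few groups dominate;
#' peak ordinals alternate between a warm (late July - September) and a cold
#' (January - February) season so that warm and cold communities differ.
#'
#' @param amplitude_grows_with_size logical; if TRUE each group's seasonal
#'   amplitude is scaled by a non-decreasing per-fraction multiplier, so
#'   larger size-fractions oscillate more strongly over the year.
#' @return list of [group_spec()] objects.
#' @export
default_group_specs <- function(amplitude_grows_with_size = TRUE) {
  prefs <- c(rep("small", 2), "small_not_smallest", rep("indifferent", 3),
             rep("large", 11))
  n <- length(prefs)
  mass <- exp(-0.18 * seq_len(n))
  mass <- 0.92 * mass / sum(mass)
  base_amp <- 0.35 + 0.5 * ((seq_len(n) * 7) %% n) / n
  frac_mult <- if (amplitude_grows_with_size)
    c(0.15, 0.30, 0.45, 0.60, 0.80, 0.80) else rep(0.5, 6)
  peaks <- ifelse(seq_len(n) %% 2 == 1,
                  200 + 10 * (seq_len(n) %% 5),   # warm season peaks
                  20 + 8 * (seq_len(n) %% 4))     # cold season peaks
  specs <- lapply(seq_len(n), function(i) {
    shape <- .preference_shapes[[prefs[i]]]
    group_spec(
      name = sprintf("group_%02d_%s", i, prefs[i]),
      baseline_profile = mass[i] * shape / sum(shape) * 6,
      seasonal_amplitude = pmin(1, base_amp[i] * frac_mult),
      peak_ordinal = peaks[i],
      preference = prefs[i]
    )
  })
  specs[[n + 1]] <- group_spec("rare_pool", rep(0.08 / 6, 6) * 6, rep(0, 6),
                               peak_ordinal = 1, preference = "indifferent")
  specs
}

#' Simulation design for the monthly six-fraction sampling scheme
#'
#' Defines the sampling calendar (monthly, mid-month, spanning `n_years`
#' from June of `start_year` — the default reproduces the 25-sampling
#' June 2011 - June 2013 design), the size-fractions, the taxonomic groups
#' and their seasonal behaviour, sequencing depths and the
#' Dirichlet-multinomial overdispersion.
#'
#' @param n_years number of years spanned (default 2, giving 25 monthly
#'   samplings inclusive of both endpoints).
#' @param start_year first calendar year (default 2011; sampling starts in
#'   June).
#' @param latitude_deg site latitude (default 41.67, Blanes Bay).
#' @param fractions fraction table, default [size_fractions()].
#' @param groups list of [group_spec()]; default [default_group_specs()].
#' @param depth_range integer c(min, max) reads per sample; min >= 1000 by
#'   default, the rarefaction floor of the sampling design.
#' @param otus_per_group number of OTUs within each group.
#' @param dispersion Dirichlet concentration scale (larger = closer to
#'   multinomial).
#' @param diversity_truth named list of [harmonic_params()] for the alpha,
#'   beta and gamma diversity series used by
#'   [generate_diversity_series()]; their default peaks (310, 250, 280) are
#'   staggered after the SST peak as observed at the site.
#' @param seed integer seed driving all randomness.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_years = 2, start_year = 2011,
                              latitude_deg = 41.67,
                              fractions = size_fractions(),
                              groups = default_group_specs(),
                              depth_range = c(1000L, 20000L),
                              otus_per_group = 12L,
                              dispersion = 200,
                              diversity_truth = list(
                                alpha = harmonic_params(120, 25, phase_for_peak(310)),
                                beta = harmonic_params(2.2, 0.35, phase_for_peak(250)),
                                gamma = harmonic_params(260, 60, phase_for_peak(280))),
                              seed = 1L) {
  stopifnot(depth_range[1] >= 1, depth_range[1] <= depth_range[2],
            length(groups) >= 2, otus_per_group >= 1, dispersion > 0)
  yrs <- start_year:(start_year + n_years)
  cal <- expand.grid(month = 1:12, year = yrs)
  cal <- cal[order(cal$year, cal$month), ]
  start_idx <- which(cal$year == start_year & cal$month == 6)
  end_idx <- which(cal$year == start_year + n_years & cal$month == 6)
  cal <- cal[start_idx:end_idx, , drop = FALSE]
  cal$ordinal_date <- ordinal_date(cal$month, 15)
  rownames(cal) <- NULL
  structure(list(months = cal, fractions = fractions, groups = groups,
                 latitude_deg = latitude_deg, depth_range = as.integer(depth_range),
                 otus_per_group = as.integer(otus_per_group),
                 dispersion = dispersion, diversity_truth = diversity_truth,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate a synthetic environmental table
#'
#' Day length is deterministic (sunrise equation at the design latitude);
#' SST follows the annual cosine climatology plus Gaussian noise; nutrients
#' and chlorophyll follow winter-peaking cosines, secchi depth a
#' summer-peaking cosine, salinity is near-constant — each plus Gaussian
#' noise with the given standard deviations.
#'
#' @param design a [simulation_design()].
#' @param noise_sd named numeric vector of per-variable noise standard
#'   deviations (names among the env dictionary); unnamed variables use
#'   defaults. Set to 0 for noiseless series.
#' @param seed integer; defaults to the design seed.
#' @return an `env_table` data.frame, one row per design month.
#' @export
generate_env_series <- function(design, noise_sd = NULL, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"), nrow(design$months) > 0)
  sd0 <- c(sst_c = 0.6, salinity = 0.15, secchi_m = 1.5, chl = 0.15,
           po4 = 0.02, no3 = 0.3, nh4 = 0.1, si = 0.3, poc = 1.5,
           toc = 4, bact_abund = 1.2e5, bact_prod = 0.08)
  if (!is.null(noise_sd)) {
    if (length(noise_sd) == 1 && is.null(names(noise_sd)))
      sd0[] <- noise_sd
    else sd0[names(noise_sd)] <- noise_sd
  }
  m <- design$months
  t <- m$ordinal_date
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cosw <- function(peak, amp, mean) mean + amp * cos(2 * pi * (t - peak) / 365)
  env <- data.frame(
    date = sprintf("%04d-%02d-15", m$year, m$month),
    year = m$year, month = m$month, ordinal_date = t,
    day_length_h = day_length(design$latitude_deg, t),
    sst_c = sst_model(t) + stats::rnorm(length(t), 0, sd0["sst_c"]),
    salinity = 38 + stats::rnorm(length(t), 0, sd0["salinity"]),
    secchi_m = cosw(210, 4, 14) + stats::rnorm(length(t), 0, sd0["secchi_m"]),
    chl = pmax(0.02, cosw(50, 0.4, 0.6) + stats::rnorm(length(t), 0, sd0["chl"])),
    po4 = pmax(0.005, cosw(40, 0.05, 0.1) + stats::rnorm(length(t), 0, sd0["po4"])),
    no3 = pmax(0.01, cosw(40, 1.2, 1.5) + stats::rnorm(length(t), 0, sd0["no3"])),
    nh4 = pmax(0.01, cosw(40, 0.25, 0.5) + stats::rnorm(length(t), 0, sd0["nh4"])),
    si = pmax(0.01, cosw(40, 0.8, 1.5) + stats::rnorm(length(t), 0, sd0["si"])),
    poc = pmax(0.5, cosw(210, 3, 8) + stats::rnorm(length(t), 0, sd0["poc"])),
    toc = pmax(40, cosw(230, 8, 85) + stats::rnorm(length(t), 0, sd0["toc"])),
    bact_abund = pmax(1e5, cosw(220, 3e5, 9e5) +
                        stats::rnorm(length(t), 0, sd0["bact_abund"])),
    bact_prod = pmax(0.01, cosw(150, 0.3, 0.5) +
                       stats::rnorm(length(t), 0, sd0["bact_prod"])),
    stringsAsFactors = FALSE
  )
  class(env) <- c("env_table", "data.frame")
  env
}

# save/restore global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Expected group proportions for one sampling event
#'
#' The deterministic core of the generator: baseline per-fraction weights
#' modulated multiplicatively by each group's annual cosine,
#' `w_g * (1 + a_g * cos(2*pi*(t - peak_g)/365))`, then renormalized over
#' groups within the fraction.
#'
#' @param design a [simulation_design()].
#' @param ordinal_date sampling ordinal date.
#' @param fraction_rank fraction rank 1..6.
#' @return named numeric vector of expected group proportions (sums to 1).
#' @export
expected_group_proportions <- function(design, ordinal_date, fraction_rank) {
  w <- vapply(design$groups, function(g) {
    mod <- 1 + g$seasonal_amplitude[fraction_rank] *
      cos(2 * pi * (ordinal_date - g$peak_ordinal) / 365)
    g$baseline_profile[fraction_rank] * max(0, mod)
  }, numeric(1))
  names(w) <- vapply(design$groups, `[[`, character(1), "name")
  s <- sum(w)
  if (s <= 0) stop("Degenerate simplex: all expected group weights are zero")
  w / s
}

#' Generate a synthetic dataset
#'
#' For every (month, fraction) sampling event, draws a community:
#' expected group proportions from [expected_group_proportions()], split
#' into per-OTU proportions by fixed geometric within-group weights, then
#' counts from a Dirichlet-multinomial (Dirichlet concentration =
#' `dispersion` x expected proportions) at a depth drawn uniformly from
#' `depth_range`. Fully reproducible from the design seed.
#'
#' @param design a [simulation_design()].
#' @return list with elements `table` (a [count_table()]), `env` (an
#'   `env_table` from [generate_env_series()]) and `truth` (a data.frame of
#'   expected group proportions per sample, for recovery tests).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)

  groups <- design$groups
  gnames <- vapply(groups, `[[`, character(1), "name")
  k <- design$otus_per_group
  # fixed geometric within-group OTU weights
  within <- 0.7^(seq_len(k) - 1)
  within <- within / sum(within)
  otu_ids <- as.vector(t(outer(gnames, seq_len(k),
                               function(g, j) sprintf("%s_otu%02d", g, j))))
  otu_group <- rep(gnames, each = k)

  m <- design$months
  events <- expand.grid(mi = seq_len(nrow(m)), fr = design$fractions$rank)
  counts <- matrix(0L, nrow = length(otu_ids), ncol = nrow(events),
                   dimnames = list(otu_ids, NULL))
  sample_ids <- character(nrow(events))
  truth <- vector("list", nrow(events))
  for (e in seq_len(nrow(events))) {
    mi <- events$mi[e]; fr <- events$fr[e]
    sid <- sprintf("S%04d%02d_F%d", m$year[mi], m$month[mi], fr)
    sample_ids[e] <- sid
    p_grp <- expected_group_proportions(design, m$ordinal_date[mi], fr)
    p_otu <- as.vector(vapply(seq_along(gnames),
                              function(i) p_grp[i] * within, numeric(k)))
    depth <- design$depth_range[1] +
      sample.int(design$depth_range[2] - design$depth_range[1] + 1L, 1) - 1L
    gam <- stats::rgamma(length(p_otu), shape = design$dispersion * p_otu)
    if (sum(gam) <= 0) gam <- p_otu  # all-zero gamma draw: fall back to mean
    counts[, e] <- as.integer(stats::rmultinom(1, depth, gam / sum(gam)))
    truth[[e]] <- data.frame(sample_id = sid, group = gnames,
                             expected_proportion = unname(p_grp),
                             stringsAsFactors = FALSE)
  }
  colnames(counts) <- sample_ids
  meta <- data.frame(
    sample_id = sample_ids,
    date = sprintf("%04d-%02d-15", m$year[events$mi], m$month[events$mi]),
    fraction = design$fractions$label[match(events$fr, design$fractions$rank)],
    stringsAsFactors = FALSE
  )
  # taxonomy: group name doubles as the genus-level lineage entry
  taxonomy <- data.frame(
    otu_id = otu_ids, domain = "Bacteria", phylum = otu_group,
    class = "", order = "", family = "", genus = otu_group,
    stringsAsFactors = FALSE
  )
  tb <- count_table(counts, meta, taxonomy, design$fractions)
  env <- generate_env_series(design, seed = design$seed + 1L)
  list(table = tb, env = env, truth = do.call(rbind, truth))
}

#' Generate synthetic diversity series with known harmonic truth
#'
#' Alpha, beta and gamma diversity series over the design months, each an
#' annual cosine with the design's `diversity_truth` parameters plus
#' Gaussian noise of `noise_frac` x amplitude. These series carry an exact
#' harmonic phase, so peak-date recovery can be checked against truth.
#'
#' @param design a [simulation_design()].
#' @param noise_frac noise standard deviation as a fraction of each series'
#'   amplitude (default 0.1).
#' @param seed integer; defaults to the design seed.
#' @return data.frame: series, year, month, ordinal_date, value; the truth
#'   parameters are attached as attribute `truth`.
#' @export
generate_diversity_series <- function(design, noise_frac = 0.1,
                                      seed = design$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 17L)
  m <- design$months
  out <- lapply(names(design$diversity_truth), function(nm) {
    p <- design$diversity_truth[[nm]]
    mu <- harmonic_predict(p, m$ordinal_date)
    data.frame(series = nm, year = m$year, month = m$month,
               ordinal_date = m$ordinal_date,
               value = mu + stats::rnorm(nrow(m), 0, noise_frac * p$b2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "truth") <- design$diversity_truth
  res
}
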