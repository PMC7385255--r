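#' Default pipeline configuration
#'
#' All analysis defaults in one list: minimum OTU total 5, rarefaction to
#' the minimum depth, genus-level aggregation, 1 percent dominance
#' threshold, warm period May-October, automatic (max-gamma) reference
#' month, 999 PERMANOVA permutations with Spearman bioenv.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    simulate = TRUE,
    counts = NULL, taxonomy = NULL, meta = NULL, env = NULL,
    min_total = 5L,
    rarefy_depth = "min",
    rank = "genus",
    threshold_pct = 1.0,
    banned_terms = c("chloroplast", "mitochondria", "eukaryota"),
    warm_months = 5:10,
    reference = NULL,         # NULL = auto-select max-gamma month
    n_perm = 999L,
    bioenv_max_subset = 3L,
    seed = 1L
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)  # yaml::read_yaml also parses JSON
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  if (!isTRUE(cfg$simulate)) {
    for (key in c("counts", "taxonomy", "meta")) {
      if (is.null(cfg[[key]]))
        stop("Config key '", key, "' is required when simulate is FALSE")
    }
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain: input (synthetic generation or TSV files)
#' -> preprocessing (taxon filter, minimum-total filter, rarefaction,
#' aggregation, dominant-group selection) -> diversity partition series ->
#' Bray-Curtis distance matrix, reference trajectories, warm/cold period
#' composition -> monthly abundance cube and HDI tables -> harmonic fits
#' of day length, SST and the diversity series with peak-date ordering ->
#' PERMANOVA (by size-fraction, month and warm/cold cluster) and bioenv.
#' All randomness derives from the single config seed; the run is
#' deterministic and a provenance log records every parameter.
#'
#' @param config a config list (see [default_config()]) or the path of a
#'   YAML/JSON config file.
#' @param out_dir output directory for TSV artifacts; NULL to skip
#'   writing.
#' @return invisibly, a list with every intermediate result (table,
#'   groups, diversity, dist, trajectory, periods, cube, hdi, harmonic,
#'   permanova, bioenv, config).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- read_pipeline_config(config)

  if (isTRUE(cfg$simulate)) {
    design <- simulation_design(seed = cfg$seed)
    sim <- generate_dataset(design)
    tb <- sim$table
    env <- sim$env
  } else {
    tb <- read_count_table(cfg$counts, cfg$taxonomy, cfg$meta)
    env <- if (!is.null(cfg$env)) read_env_table(cfg$env) else NULL
  }

  pre <- preprocess_pipeline(tb, seed = cfg$seed, min_total = cfg$min_total,
                             rarefy_depth = cfg$rarefy_depth,
                             rank = cfg$rank,
                             threshold_pct = cfg$threshold_pct,
                             banned_terms = cfg$banned_terms)

  div <- partition_series(pre$rarefied)
  d <- bc_distance_matrix(pre$rarefied)
  traj <- reference_trajectory(pre$rarefied, cfg$reference)
  periods <- period_composition(pre$groups, cfg$warm_months)
  cube <- month_average_cube(pre$groups)
  hdi <- hdi_table(cube, exclude = "Other bacteria")

  series <- list(
    alpha = list(t = div$ordinal_date, y = div$alpha),
    beta = list(t = div$ordinal_date, y = div$beta),
    gamma = list(t = div$ordinal_date, y = div$gamma)
  )
  if (!is.null(env)) {
    if ("day_length_h" %in% names(env))
      series$day_length <- list(t = env$ordinal_date, y = env$day_length_h)
    if ("sst_c" %in% names(env))
      series$sst <- list(t = env$ordinal_date, y = env$sst_c)
  }
  harm <- fit_all(series)

  meta <- pre$rarefied$meta
  perm <- list(
    fraction = permanova(d, meta$fraction, cfg$n_perm, seed = cfg$seed),
    month = permanova(d, meta$month, cfg$n_perm, seed = cfg$seed + 1L),
    cluster = permanova(d, ifelse(meta$month %in% cfg$warm_months,
                                  "warm", "cold"),
                        cfg$n_perm, seed = cfg$seed + 2L)
  )
  bio <- NULL
  if (!is.null(env)) {
    # align one env row per sample via (year, month)
    idx <- match(paste(meta$year, meta$month),
                 paste(env$year, env$month))
    if (!anyNA(idx))
      bio <- bioenv_search(d, env[idx, , drop = FALSE],
                           max_subset = cfg$bioenv_max_subset)
  }

  res <- list(table = tb, groups = pre$groups, rarefied = pre$rarefied,
              diversity = div, dist = d, trajectory = traj,
              periods = periods, cube = cube, hdi = hdi, harmonic = harm,
              permanova = perm, bioenv = bio, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(res$diversity, "diversity.tsv")
  dm <- data.frame(sample_id = rownames(res$dist), res$dist,
                   check.names = FALSE)
  w(dm, "distance_matrix.tsv")
  w(res$trajectory, "trajectory.tsv")
  w(res$periods, "period_composition.tsv")
  write_hdi_tables(res$hdi, out_dir)
  w(res$harmonic, "harmonic_fits.tsv")
  perm_df <- do.call(rbind, lapply(names(res$permanova), function(nm) {
    p <- res$permanova[[nm]]
    data.frame(factor = nm, n = p$n, k = p$k, r2 = p$r2,
               pseudo_f = p$pseudo_f, p_value = p$p_value,
               n_perm = p$n_perm)
  }))
  w(perm_df, "permanova.tsv")
  if (!is.null(res$bioenv)) {
    bio_df <- do.call(rbind, lapply(res$bioenv$per_size, function(e)
      data.frame(size = e$size, rho = e$rho,
                 variables = paste(e$variables, collapse = ","))))
    w(bio_df, "bioenv.tsv")
  }
  prov <- c(
    paste0("# sizeseason ", as.character(utils::packageVersion("sizeseason"))),
    paste0("# R ", R.version.string),
    paste0("# seed: ", res$config$seed),
    paste0("# config: ", paste(names(res$config), collapse = ", ")),
    vapply(names(res$config), function(k)
      paste0(k, " = ", paste(format(res$config[[k]]), collapse = " ")),
      character(1))
  )
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}
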