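#' Load and validate a run configuration
#'
#' Configurations are plain lists (or YAML files parsed into lists).
#' Every stochastic run must carry an explicit integer `seed`; missing or
#' non-numeric seeds fail validation before any computation. Unknown
#' fields are rejected to catch typos.
#'
#' @param config a named list, or the path to a YAML file.
#' @param required names that must be present.
#' @param defaults named list of defaults merged in for absent fields.
#' @return The validated, completed configuration list.
#' @export
load_config <- function(config, required = "seed", defaults = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop("config validation: config must be a named list or YAML path")
  missing_req <- setdiff(required, names(config))
  if (length(missing_req) > 0L)
    stop("config validation: missing required field(s): ",
         paste(missing_req, collapse = ", "))
  if ("seed" %in% required &&
      (!is.numeric(config$seed) || length(config$seed) != 1L ||
       config$seed != round(config$seed)))
    stop("config validation: seed must be a single integer")
  unknown <- setdiff(names(config), union(required, names(defaults)))
  if (length(unknown) > 0L)
    stop("config validation: unknown field(s): ",
         paste(unknown, collapse = ", "))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

# Stable hash of a config: canonical JSON via tools::md5sum on a temp file.
config_hash <- function(config) {
  config <- config[order(names(config))]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

report_meta <- function(config) {
  list(config = config,
       config_hash = config_hash(config),
       package_version = as.character(utils::packageVersion("nodescale")))
}

write_report_json <- function(report, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Nodal-density scaling analysis on synthetic cells
#'
#' Figure-level closure of the scaling pipeline: generate a population of
#' cells across the length range, compute each cell's model steady state,
#' emit a noisy synthetic medial profile, quantify the medial band
#' intensity, bin by length, and re-fit the model's free prefactor to the
#' binned densities.
#'
#' @param config list (or YAML path) with fields: `seed` (required),
#'   `n` (cells, default 100), `noise` (fractional, 0.05),
#'   `L_range` (c(7, 14)), `R` (1.5), `w_nod` (3), `model` ("uniform"),
#'   `out_dir` (optional; CSV + JSON written there).
#' @return A report list: per-cell table, binned table, `prefactor`,
#'   `r_squared`, predicted curve, and config metadata.
#' @export
run_scaling_analysis <- function(config) {
  cfg <- load_config(config, required = "seed",
                     defaults = list(n = 100, noise = 0.05,
                                     L_range = c(7, 14), R = 1.5,
                                     w_nod = 3, model = "uniform",
                                     band_shape = "uniform",
                                     out_dir = NULL))
  set.seed(cfg$seed)
  params <- switch(cfg$model,
    uniform = uniform_params(),
    modification = modification_params(),
    `direct-null` = uniform_params(),
    stop("config validation: unknown model '", cfg$model, "'"))
  L <- stats::runif(cfg$n, cfg$L_range[1], cfg$L_range[2])
  profile_seeds <- sample.int(.Machine$integer.max, cfg$n)
  value <- vapply(seq_len(cfg$n), function(i) {
    g <- spherocylinder(L[i], cfg$R,
                        w_nod = min(cfg$w_nod, L[i] - 2 * cfg$R))
    ss <- switch(cfg$model,
      uniform = model1_closed_form(params, g),
      modification = model2_closed_form(params, g),
      `direct-null` = model1_direct_null(params, g))
    p <- gen_cdr2_profile(list(L = L[i], R = cfg$R), ss,
                          noise = cfg$noise, seed = profile_seeds[i],
                          band_shape = cfg$band_shape)
    medial_band_intensity(p, width = 3)$mean
  }, numeric(1))
  cells <- data.frame(length_um = L, value = value)
  binned <- bin_by_length(cells, bin_width = 1)
  fit <- fit_scaling_prefactor(binned$bin_lo + 0.5, binned$mean,
                               model = cfg$model, params = params,
                               R = cfg$R, w_nod = cfg$w_nod)
  report <- c(list(
    analysis = "scaling",
    n_cells = cfg$n,
    prefactor = fit$prefactor,
    r_squared = fit$r_squared,
    binned = binned,
    predicted = data.frame(L_um = binned$bin_lo + 0.5,
                           density = fit$fitted)),
    report_meta(cfg))
  if (!is.null(cfg$out_dir)) {
    utils::write.csv(cells, file.path(cfg$out_dir, "scaling_cells.csv"),
                     row.names = FALSE)
    write_report_json(report, cfg$out_dir, "scaling_report")
  }
  report
}

#' Division-size analysis across strains of different widths
#'
#' Generates populations for three strains of different radii dividing
#' under a common rule, measures each cell, normalizes per-quantity means
#' to the fat strain, and compares the per-strain distributions of
#' length, area and volume by pairwise Jensen-Shannon distance. Under an
#' area-sizer rule the area distributions overlap most (smallest JS
#' distances).
#'
#' @param config list (or YAML path) with fields: `seed` (required),
#'   `n_per_strain` (100), `rule` ("sizer-area"), `threshold` (150, in
#'   the rule's units), `threshold_cv` (0.05), `radii` (named list/vector
#'   wt/fat/thin = 1.5/1.75/1.3), `out_dir` (optional).
#' @return A report list with per-strain means (raw and normalized to the
#'   fat strain), the pairwise JS-distance table, and the quantity with
#'   the smallest mean JS distance.
#' @export
run_division_size_analysis <- function(config) {
  cfg <- load_config(config, required = "seed",
                     defaults = list(n_per_strain = 100,
                                     rule = "sizer-area",
                                     threshold = 150,
                                     threshold_cv = 0.05,
                                     radii = c(wt = 1.5, fat = 1.75,
                                               thin = 1.3),
                                     out_dir = NULL))
  radii <- unlist(cfg$radii)
  pops <- lapply(seq_along(radii), function(i) {
    spec <- strain_spec(names(radii)[i], R_mean = radii[[i]],
                        division_rule = cfg$rule,
                        threshold = cfg$threshold,
                        threshold_cv = cfg$threshold_cv)
    gen_population(spec, cfg$n_per_strain, seed = cfg$seed + i)
  })
  cells <- do.call(rbind, pops)
  quantities <- c(length = "length_um", area = "area_um2",
                  volume = "volume_um3")
  means <- sapply(quantities, function(col)
    tapply(cells[[col]], cells$strain, mean))
  ref <- if ("fat" %in% rownames(means)) "fat" else rownames(means)[1L]
  normalized <- sweep(means, 2, means[ref, ], "/")
  strains <- unique(cells$strain)
  pairs <- utils::combn(strains, 2, simplify = FALSE)
  js <- do.call(rbind, lapply(names(quantities), function(qn) {
    col <- quantities[[qn]]
    do.call(rbind, lapply(pairs, function(pr) {
      a <- cells[[col]][cells$strain == pr[1L]]
      b <- cells[[col]][cells$strain == pr[2L]]
      data.frame(quantity = qn, strain_a = pr[1L], strain_b = pr[2L],
                 js_distance = js_distance(shared_histogram(a, b)))
    }))
  }))
  mean_js <- tapply(js$js_distance, js$quantity, mean)
  report <- c(list(
    analysis = "division-size",
    rule = cfg$rule,
    means = as.data.frame(means),
    normalized_means = as.data.frame(normalized),
    normalization_strain = ref,
    js_distances = js,
    mean_js_by_quantity = as.list(mean_js),
    most_similar_quantity = names(which.min(mean_js))),
    report_meta(cfg))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(cfg$out_dir, "division_cells.csv"),
                     row.names = FALSE)
    write_report_json(report, cfg$out_dir, "division_size_report")
  }
  report
}

#' Sizer-versus-timer discrimination on growth tracks
#'
#' Contrasts growing cells with growth-arrested cells: a size-coupled
#' (sizer) reporter stops accumulating when growth stops, while a
#' time-coupled (timer) reporter keeps accumulating. Reports mean
#' accumulation rates in both conditions and the Monte-Carlo robustness
#' of the growth/accumulation correlation in the growing population.
#'
#' @param config list (or YAML path) with fields: `seed` (required),
#'   `coupling` ("sizer" or "timer"), `n` (21), `n_reps` (1e5),
#'   `growth_rate_mean` (1.5), `growth_rate_sd` (0.8),
#'   `growth_err` (0.2), `accumulation_err` (0.3), `out_dir` (optional).
#' @return A report list with mean accumulation rates (growing and
#'   arrested), the observed slope, and `p_no_positive` from
#'   [correlation_robustness()].
#' @export
run_sizer_timer_test <- function(config) {
  cfg <- load_config(config, required = "seed",
                     defaults = list(coupling = "sizer", n = 21,
                                     n_reps = 1e5,
                                     growth_rate_mean = 1.5,
                                     growth_rate_sd = 0.8,
                                     growth_err = 0.2,
                                     accumulation_err = 0.3,
                                     out_dir = NULL))
  growing <- gen_growth_tracks(cfg$n, coupling = cfg$coupling,
                               growth_rate_mean = cfg$growth_rate_mean,
                               growth_rate_sd = cfg$growth_rate_sd,
                               growth_err = cfg$growth_err,
                               accumulation_err = cfg$accumulation_err,
                               seed = cfg$seed)
  arrested <- gen_growth_tracks(cfg$n, coupling = cfg$coupling,
                                growth_rate_mean = 1e-9,
                                growth_rate_sd = 0,
                                growth_err = cfg$growth_err,
                                accumulation_err = cfg$accumulation_err,
                                seed = cfg$seed + 1)
  rob <- correlation_robustness(growing, n_reps = cfg$n_reps,
                                seed = cfg$seed + 2)
  report <- c(list(
    analysis = "sizer-timer",
    coupling = cfg$coupling,
    mean_accumulation_growing = mean(growing$accumulation_rate),
    mean_accumulation_arrested = mean(arrested$accumulation_rate),
    observed_slope = rob$observed_slope,
    p_no_positive = rob$p_no_positive,
    n_reps = rob$n_reps),
    report_meta(cfg))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(growing, file.path(cfg$out_dir, "tracks_growing.csv"),
                     row.names = FALSE)
    utils::write.csv(arrested,
                     file.path(cfg$out_dir, "tracks_arrested.csv"),
                     row.names = FALSE)
    write_report_json(report, cfg$out_dir, "sizer_timer_report")
  }
  report
}
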