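#' Strain specification for synthetic populations
#'
#' Describes a strain for the division-size generator: radius
#' distribution, growth rate, and the division rule. Cells divide when
#' the rule's quantity (membrane area, volume, length, or elapsed time)
#' crosses a per-cell threshold drawn as
#' `threshold * lognormal(mean 1, cv = threshold_cv)`.
#'
#' Default strain radii used in the three-strain analyses are
#' wild-type 1.5 um, fat 1.75 um, thin 1.3 um, which with a shared
#' 150 um^2 area threshold give mean division lengths of about 15.9,
#' 13.6 and 18.4 um respectively.
#'
#' @param name strain label.
#' @param R_mean,R_sd cell radius distribution (um).
#' @param growth_rate_mean,growth_rate_sd length growth rate (um h^-1).
#' @param division_rule one of `"sizer-area"`, `"sizer-volume"`,
#'   `"sizer-length"`, `"timer"`.
#' @param threshold division threshold in the rule's units (um^2, um^3,
#'   um, or h).
#' @param threshold_cv coefficient of variation of the per-cell
#'   threshold (< 0.5).
#' @return A list of class `strain_spec`.
#' @export
strain_spec <- function(name, R_mean = 1.5, R_sd = 0.05,
                        growth_rate_mean = 2, growth_rate_sd = 0.3,
                        division_rule = c("sizer-area", "sizer-volume",
                                          "sizer-length", "timer"),
                        threshold = 150, threshold_cv = 0.05) {
  division_rule <- match.arg(division_rule)
  stopifnot(R_mean > 0, R_sd >= 0, growth_rate_mean > 0,
            growth_rate_sd >= 0, threshold > 0, threshold_cv >= 0,
            threshold_cv < 0.5)
  structure(list(name = name, R_mean = R_mean, R_sd = R_sd,
                 growth_rate_mean = growth_rate_mean,
                 growth_rate_sd = growth_rate_sd,
                 division_rule = division_rule, threshold = threshold,
                 threshold_cv = threshold_cv),
            class = "strain_spec")
}

# lognormal multiplier with mean 1 and given cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cell population at division
#'
#' Draws per-cell radii and growth rates, then records each cell's
#' dimensions at the moment its division rule's quantity crosses its
#' (noisy) threshold. Sizer rules fix the division size directly
#' (growth rate does not affect final size); the timer rule divides
#' after a fixed time, so division size spreads with growth rate
#' (symmetric division: birth length is half of division length).
#'
#' @param spec a [strain_spec()].
#' @param n number of cells.
#' @param seed integer seed (same seed + spec give identical output).
#' @return A data.frame with columns `cell_id`, `strain`, `length_um`,
#'   `radius_um`, `area_um2`, `volume_um3`, `growth_rate`,
#'   `threshold_drawn`; generator truth (the strain specification) is attached as
#'   attribute `"truth"`.
#' @export
gen_population <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "strain_spec"), n >= 1)
  set.seed(seed)
  R <- stats::rnorm(n, spec$R_mean, spec$R_sd)
  R <- pmax(R, 0.5 * spec$R_mean)  # guard against unphysical draws
  g <- pmax(stats::rnorm(n, spec$growth_rate_mean, spec$growth_rate_sd),
            0.1 * spec$growth_rate_mean)
  thr <- spec$threshold * rlnorm_mean1(n, spec$threshold_cv)
  L <- switch(spec$division_rule,
    `sizer-area` = thr / (2 * pi * R),
    `sizer-volume` = (thr - (4 / 3) * pi * R^3) / (pi * R^2) + 2 * R,
    `sizer-length` = thr,
    timer = 2 * g * thr  # L_div = L_birth + g*T with L_birth = L_div/2
  )
  L <- pmax(L, 2 * R)
  d <- data.frame(
    cell_id = paste0(spec$name, "_", seq_len(n)),
    strain = spec$name,
    length_um = L,
    radius_um = R,
    area_um2 = 2 * pi * R * L,
    volume_um3 = pi * R^2 * (L - 2 * R) + (4 / 3) * pi * R^3,
    growth_rate = g,
    threshold_drawn = thr,
    stringsAsFactors = FALSE)
  attr(d, "truth") <- spec
  d
}

#' Generate a synthetic medial cdr2p axial profile
#'
#' Builds an axial-band intensity profile for one cell from a model
#' steady state (or spatial solution): a uniform cortical baseline plus
#' a medial nodal band, with multiplicative Gaussian noise and a known
#' additive background. For a scalar `steady_state`, the nodal signal is
#' painted as a Gaussian of width `omega(L)` whose integral preserves
#' the model's per-circumference nodal content (`rho_nod * w_nod`); for
#' a `spatial_solution`, the solved profiles are used directly.
#'
#' With `discrete_nodes = TRUE`, the nodal band is instead composed of
#' individual nodes: a Poisson number (expectation `N_nod /
#' molecules_per_node`) of diffraction-limited spots placed at
#' Gaussian-distributed axial positions.
#'
#' @param cell list (or one-row data.frame) with `length_um` and
#'   `radius_um` (aliases `L`, `R` accepted).
#' @param model a `steady_state` or `spatial_solution` object.
#' @param noise fractional (multiplicative Gaussian) noise, default 0.05.
#' @param seed integer seed.
#' @param step axial sampling step (um).
#' @param scale intensity per unit density (a.u.).
#' @param background additive background level (a.u.).
#' @param band_shape `"gaussian"` paints the nodal signal as a Gaussian
#'   of width `omega(L)` (the imaged band shape); `"uniform"` paints a
#'   flat band of density `rho_nod` over the model's `w_nod` window (the
#'   model's own nodal-region geometry). Ignored for spatial solutions.
#' @param discrete_nodes paint individual nodes instead of a smooth band.
#' @param molecules_per_node molecules per node for the discrete variant.
#' @param psf_sd Gaussian spot width for the discrete variant (um).
#' @return An `intensity_profile` of kind `"axial-band"` with the
#'   generating parameters attached as attribute `"truth"`.
#' @export
gen_cdr2_profile <- function(cell, model, noise = 0.05, seed = 1,
                             step = 0.05, scale = 1, background = 0.1,
                             band_shape = c("gaussian", "uniform"),
                             discrete_nodes = FALSE,
                             molecules_per_node = 90, psf_sd = 0.15) {
  band_shape <- match.arg(band_shape)
  L <- cell$length_um %||% cell$L
  R <- cell$radius_um %||% cell$R
  stopifnot(is.finite(L), is.finite(R), L >= 2 * R)
  set.seed(seed)
  x <- seq(-L / 2, L / 2, by = step)
  if (inherits(model, "spatial_solution")) {
    cor_x <- stats::approx(model$x, model$rho_cor_x, xout = x, rule = 2)$y
    nod_x <- stats::approx(model$x, model$rho_nod_x, xout = x, rule = 2)$y
    truth_band <- trapz(model$x, model$rho_nod_x)
  } else if (inherits(model, "steady_state")) {
    w <- omega(L)
    cor_x <- rep(model$rho_cor, length(x))
    if (discrete_nodes) {
      n_nodes <- stats::rpois(1L, max(model$N_nod / molecules_per_node, 0))
      pos <- stats::rnorm(n_nodes, 0, w)
      pos <- pos[abs(pos) <= L / 2 - psf_sd]
      nod_x <- rep(0, length(x))
      for (p0 in pos)
        nod_x <- nod_x + molecules_per_node / (2 * pi * R) *
          stats::dnorm(x, p0, psf_sd)
      truth_band <- length(pos) * molecules_per_node / (2 * pi * R)
      attr_nodes <- length(pos)
    } else if (band_shape == "uniform") {
      nod_x <- ifelse(abs(x) <= model$geom$w_nod / 2 + 1e-12,
                      model$rho_nod, 0)
      truth_band <- model$rho_nod * model$geom$w_nod
    } else {
      band_content <- model$rho_nod * model$geom$w_nod  # per circumference
      amp <- band_content / (w * sqrt(2 * pi))
      nod_x <- amp * exp(-x^2 / (2 * w^2))
      truth_band <- band_content
    }
  } else stop("model must be a steady_state or spatial_solution object")
  signal <- scale * (cor_x + nod_x)
  I <- signal * (1 + noise * stats::rnorm(length(x))) + background
  p <- intensity_profile(x, I, background = background, L = L,
                         kind = "axial-band")
  attr(p, "truth") <- list(model = model, noise = noise, seed = seed,
                           scale = scale, background = background,
                           band_shape = band_shape,
                           band_content = truth_band,
                           discrete_nodes = discrete_nodes,
                           n_nodes = if (discrete_nodes &&
                                         !inherits(model, "spatial_solution"))
                             attr_nodes else NA_integer_)
  p
}

#' Generate a synthetic cortical-loop profile
#'
#' Paints an intensity pattern onto the cell outline in the mid focal
#' plane (a stadium: two semicircles joined by straight lines), sampled
#' at uniformly spaced angles from the cell center. The default pattern
#' is a tip gradient `exp(-d/lambda)` in the distance `d` from the
#' nearer tip along the cortex.
#'
#' @param cell list with `length_um`/`L` and `radius_um`/`R`.
#' @param lambda tip-gradient decay length (um); `Inf` gives a uniform
#'   loop.
#' @param noise fractional multiplicative noise.
#' @param seed integer seed.
#' @param n_points number of samples around the loop.
#' @param background additive background.
#' @return An `intensity_profile` of kind `"cortical-loop"` (x = angle in
#'   radians) with truth attached.
#' @export
gen_cortical_loop <- function(cell, lambda = 1.5, noise = 0.05, seed = 1,
                              n_points = 400, background = 0.1) {
  L <- cell$length_um %||% cell$L
  R <- cell$radius_um %||% cell$R
  stopifnot(L >= 2 * R, R > 0)
  set.seed(seed)
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  half_perim <- (L - 2 * R) + pi * R
  d0 <- stadium_tip_distance(theta, L, R)
  d_near <- pmin(d0, half_perim - d0)  # distance from the nearer tip
  signal <- if (is.finite(lambda)) exp(-d_near / lambda) else
    rep(1, length(theta))
  I <- signal * (1 + noise * stats::rnorm(length(theta))) + background
  p <- intensity_profile(theta, I, background = background, L = L,
                         kind = "cortical-loop")
  attr(p, "truth") <- list(lambda = lambda, noise = noise, seed = seed,
                           R = R, background = background)
  p
}

#' Generate synthetic polar tip-gradient profiles
#'
#' Emulates cortical gradient measurements from a tip: intensity
#' `exp(-x/lambda) * (1 + noise) + background` sampled from the tip
#' outward, with per-point multiplicative fluctuations.
#'
#' @param lambda decay length (um), recycled over `n` (a vector gives a
#'   per-profile sweep).
#' @param fluctuation_cv fractional point-to-point noise.
#' @param n number of profiles.
#' @param seed integer seed.
#' @param step,x_max sampling step and extent from the tip (um).
#' @param background additive background.
#' @return A list of tip-gradient `intensity_profile`s, each with its
#'   generating `lambda` attached as attribute `"truth"`.
#' @export
gen_pom1_profiles <- function(lambda, fluctuation_cv = 0.05, n = 1,
                              seed = 1, step = 0.05, x_max = 6,
                              background = 0.1) {
  stopifnot(all(lambda > 0), n >= 1)
  set.seed(seed)
  lam <- rep_len(lambda, n)
  x <- seq(0, x_max, by = step)
  lapply(seq_len(n), function(i) {
    I <- exp(-x / lam[i]) * (1 + fluctuation_cv * stats::rnorm(length(x))) +
      background
    p <- intensity_profile(x, I, background = background,
                           kind = "tip-gradient")
    attr(p, "truth") <- list(lambda = lam[i], fluctuation_cv = fluctuation_cv)
    p
  })
}

#' Generate synthetic FRAP recovery curves
#'
#' Emulates post-bleach recovery traces
#' `I(t) = A * (1 - exp(-k*t)) + c` with multiplicative Gaussian noise.
#'
#' @param k recovery rate (s^-1); `t_half = ln(2)/k`.
#' @param noise fractional noise.
#' @param n number of curves.
#' @param seed integer seed.
#' @param t_max trace duration (s).
#' @param n_points time points per trace.
#' @param A,c0 recovery amplitude and post-bleach offset (a.u.).
#' @return A list of curves, each a list with `t`, `I` and a `"truth"`
#'   attribute carrying `k`.
#' @export
gen_frap <- function(k = log(2) / 180, noise = 0.05, n = 1, seed = 1,
                     t_max = 720, n_points = 30, A = 1, c0 = 0.2) {
  stopifnot(k > 0, n >= 1, n_points >= 5)
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  lapply(seq_len(n), function(i) {
    clean <- A * (1 - exp(-k * t)) + c0
    curve <- list(t = t, I = clean * (1 + noise * stats::rnorm(n_points)))
    attr(curve, "truth") <- list(k = k, t_half = log(2) / k, A = A,
                                 c0 = c0, noise = noise)
    curve
  })
}

#' Generate paired growth-rate / accumulation-rate tracks
#'
#' Emulates per-cell (growth rate, nodal accumulation rate) pairs with
#' per-cell measurement errors. Under `"sizer"` coupling the
#' accumulation rate is proportional to the growth rate (protein levels
#' track size, so arrested cells stop accumulating); under `"timer"`
#' coupling the accumulation rate is a constant independent of growth
#' (levels track elapsed time).
#'
#' @param n number of cells.
#' @param coupling `"sizer"` or `"timer"`.
#' @param growth_rate_mean,growth_rate_sd growth-rate distribution
#'   (um h^-1); a highly variable-growth population uses a large sd.
#' @param accumulation_per_um accumulation per um of growth (sizer
#'   coupling; a.u. um^-1).
#' @param timer_rate constant accumulation rate (timer coupling;
#'   a.u. h^-1).
#' @param growth_err,accumulation_err per-cell measurement error
#'   magnitudes (scalars or length-n).
#' @param seed integer seed.
#' @return A data.frame with `growth_rate`, `accumulation_rate`,
#'   `growth_err`, `accumulation_err` (observed values already include
#'   one draw of measurement noise); truth attached as attribute.
#' @export
gen_growth_tracks <- function(n, coupling = c("sizer", "timer"),
                              growth_rate_mean = 1.5,
                              growth_rate_sd = 0.8,
                              accumulation_per_um = 1,
                              timer_rate = 1.5,
                              growth_err = 0.2, accumulation_err = 0.3,
                              seed = 1) {
  coupling <- match.arg(coupling)
  stopifnot(n >= 3)
  set.seed(seed)
  g_true <- pmax(stats::rnorm(n, growth_rate_mean, growth_rate_sd), 0)
  a_true <- switch(coupling,
    sizer = accumulation_per_um * g_true,
    timer = rep(timer_rate, n))
  ge <- rep_len(growth_err, n)
  ae <- rep_len(accumulation_err, n)
  d <- data.frame(
    growth_rate = g_true + stats::rnorm(n, 0, ge),
    accumulation_rate = a_true + stats::rnorm(n, 0, ae),
    growth_err = ge,
    accumulation_err = ae)
  attr(d, "truth") <- list(coupling = coupling, g_true = g_true,
                           a_true = a_true, seed = seed)
  d
}
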