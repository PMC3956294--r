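#' 1D fluorescence intensity profile
#'
#' The universal measurement record: intensity sampled along a line, with
#' its background level and source-cell metadata. Three kinds are used:
#' `"tip-gradient"` (distance from a cell tip along the cortex, for polar
#' gradients), `"axial-band"` (position along the long axis, cell-centered,
#' for the medial node band), and `"cortical-loop"` (angular coordinate
#' around the cell outline in the mid focal plane).
#'
#' @param x positions (um for linear kinds; radians in `[0, 2*pi)` for
#'   cortical loops). Must be monotone increasing for linear kinds.
#' @param I intensities (arbitrary units), finite.
#' @param background scalar background level (a.u.), subtracted by the
#'   quantification routines that need it.
#' @param L source cell length (um), or `NA`.
#' @param kind profile kind tag.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(x, I, background = 0, L = NA_real_,
                              kind = c("tip-gradient", "cortical-loop",
                                       "axial-band")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x), is.numeric(I))
  if (length(x) != length(I))
    stop("profile: x and I must have the same length")
  if (any(!is.finite(I)))
    stop("profile: intensities must be finite")
  if (kind != "cortical-loop" && any(diff(x) <= 0))
    stop("profile: x must be strictly increasing for ", kind, " profiles")
  structure(list(x = as.numeric(x), I = as.numeric(I),
                 background = background, L = L, kind = kind),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile (%s), %d samples, x in [%.3g, %.3g], background = %.3g\n",
              x$kind, length(x$x), min(x$x), max(x$x), x$background))
  invisible(x)
}

#' Fit the decay length of a polar tip gradient
#'
#' Normalizes the profile to 1 at the tip after shifting so the intensity
#' is zero at `fit_range` um from the tip, then fits `exp(-x/lambda)` by
#' nonlinear least squares over `[0, fit_range]`. A non-decreasing
#' profile (no gradient) is flagged as a fit failure rather than fitted.
#'
#' @param p a tip-gradient [intensity_profile()] covering at least
#'   `fit_range` um from the tip.
#' @param fit_range fitting window from the tip (um); also the position
#'   at which the shifted intensity is pinned to zero.
#' @return An object of class `decay_fit`: `lam` (decay length, um),
#'   `fit_rmse` (a.u., on the normalized scale), `ok` (logical),
#'   `reason` (on failure).
#' @export
fit_decay_length <- function(p, fit_range = 5) {
  stopifnot(inherits(p, "intensity_profile"))
  if (p$kind != "tip-gradient")
    stop("decay-length fit requires a tip-gradient profile")
  if (max(p$x) < fit_range)
    stop("profile must cover at least the fit range (", fit_range, " um)")
  x0 <- min(p$x)
  I_tip <- p$I[which.min(p$x)]
  I_far <- stats::approx(p$x, p$I, xout = x0 + fit_range)$y
  if (!(I_tip > I_far)) {
    return(structure(list(lam = NA_real_, fit_rmse = NA_real_, ok = FALSE,
                          reason = "profile does not decay from the tip"),
                     class = "decay_fit"))
  }
  keep <- p$x <= x0 + fit_range
  xs <- p$x[keep] - x0
  In <- (p$I[keep] - I_far) / (I_tip - I_far)
  # crude log-linear start, refined by nonlinear least squares
  pos <- In > 0.05
  lam0 <- tryCatch(
    -1 / stats::coef(stats::lm(log(In[pos]) ~ xs[pos]))[[2]],
    error = function(e) fit_range / 3)
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- fit_range / 3
  # the model curve passes through the same pin-to-zero normalization as
  # the data, so a clean exponential is recovered without tail bias
  fit <- tryCatch(
    minpack.lm::nlsLM(
      In ~ (exp(-xs / lam) - exp(-fit_range / lam)) /
        (1 - exp(-fit_range / lam)),
      start = list(lam = lam0), lower = c(lam = 1e-6)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(lam = NA_real_, fit_rmse = NA_real_, ok = FALSE,
                          reason = "nonlinear fit did not converge"),
                     class = "decay_fit"))
  }
  lam <- stats::coef(fit)[["lam"]]
  structure(list(lam = lam,
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 ok = TRUE, reason = NA_character_),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("Tip-gradient decay fit: lambda = %.4g um (rmse %.3g)\n",
                x$lam, x$fit_rmse))
  else cat("Tip-gradient decay fit FAILED:", x$reason, "\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(lam = object$lam)

#' Fit a Gaussian to the medial node band, with quality filter
#'
#' Fits `a * exp(-(x - x0)^2 / (2*sigma^2)) + b` to an axial profile by
#' nonlinear least squares. A fit is `accepted` only if the goodness of
#' fit reaches `quality_min` (r-squared) and the fitted width exceeds
#' `sigma_min` — narrow widths indicate distorted fits dominated by one
#' very bright nodal spot rather than the band.
#'
#' @param p an axial-band [intensity_profile()] spanning the node band,
#'   at least 5 points.
#' @param sigma_min minimum accepted band width (um).
#' @param quality_min minimum accepted r-squared.
#' @return An object of class `node_band_fit`: `a`, `x0`, `sigma`, `b`,
#'   `r_squared`, `accepted`, `reason` (why a fit was rejected, or `NA`).
#' @export
fit_node_band <- function(p, sigma_min = 0.5, quality_min = 0.8) {
  stopifnot(inherits(p, "intensity_profile"))
  if (length(p$x) < 5L)
    stop("node-band fit requires at least 5 points (got ", length(p$x), ")")
  x <- p$x
  I <- p$I
  b0 <- min(I)
  a0 <- max(I) - b0
  x00 <- x[which.max(I)]
  # an exactly-zero start defeats the relative-step numeric Jacobian
  if (x00 == 0) x00 <- 1e-4 * diff(range(x))
  w <- pmax(I - b0, 0)
  s0 <- if (sum(w) > 0) sqrt(sum(w * (x - x00)^2) / sum(w)) else diff(range(x)) / 4
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ a * exp(-(x - x0)^2 / (2 * sigma^2)) + b,
                      start = list(a = a0, x0 = x00, sigma = s0, b = b0),
                      lower = c(a = 0, x0 = min(x), sigma = 1e-3, b = -Inf),
                      upper = c(a = Inf, x0 = max(x), sigma = diff(range(x)),
                                b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, x0 = NA_real_, sigma = NA_real_,
                          b = NA_real_, r_squared = NA_real_,
                          accepted = FALSE,
                          reason = "fit did not converge"),
                     class = "node_band_fit"))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((I - mean(I))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  reason <- NA_character_
  accepted <- TRUE
  if (!is.finite(r2) || r2 < quality_min) {
    accepted <- FALSE
    reason <- sprintf("poor fit quality (r^2 = %.3f < %.2f)", r2, quality_min)
  } else if (cf[["sigma"]] <= sigma_min) {
    accepted <- FALSE
    reason <- sprintf("band width sigma = %.3f um <= %.2f um (distorted fit)",
                      cf[["sigma"]], sigma_min)
  }
  structure(list(a = cf[["a"]], x0 = cf[["x0"]], sigma = cf[["sigma"]],
                 b = cf[["b"]], r_squared = r2, accepted = accepted,
                 reason = reason),
            class = "node_band_fit")
}

#' @export
print.node_band_fit <- function(x, ...) {
  cat(sprintf("Node-band Gaussian fit: a = %.4g, x0 = %.3f, sigma = %.3f um, b = %.4g (r^2 = %.3f)\n",
              x$a, x$x0, x$sigma, x$b, x$r_squared))
  cat(if (x$accepted) "  accepted\n" else paste0("  REJECTED: ", x$reason, "\n"))
  invisible(x)
}

#' @export
coef.node_band_fit <- function(object, ...) {
  c(a = object$a, x0 = object$x0, sigma = object$sigma, b = object$b)
}

#' Background-subtracted intensity in the medial band
#'
#' Sums (and averages) the background-subtracted intensity over the
#' central band `|x - center| <= width/2`, emulating a fixed medial
#' measurement window (3 um by default) over the nodal region.
#'
#' @param p an [intensity_profile()] covering the band.
#' @param width band width (um).
#' @param center band center; defaults to the midpoint of the profile's
#'   x-range.
#' @return List with `total` (sum of background-subtracted samples),
#'   `mean`, and `n` (samples in the band).
#' @export
medial_band_intensity <- function(p, width = 3, center = NULL) {
  stopifnot(inherits(p, "intensity_profile"), width > 0)
  if (is.null(center)) center <- (min(p$x) + max(p$x)) / 2
  eps <- 1e-9
  if (center - width / 2 < min(p$x) - eps ||
      center + width / 2 > max(p$x) + eps)
    stop("band [", center - width / 2, ", ", center + width / 2,
         "] exceeds profile extent [", min(p$x), ", ", max(p$x), "]")
  in_band <- abs(p$x - center) <= width / 2 + eps
  v <- p$I[in_band] - p$background
  list(total = sum(v), mean = mean(v), n = sum(in_band))
}

#' Detect nodes as thresholded local maxima
#'
#' Finds local intensity maxima exceeding `threshold_factor` times the
#' background; each maximum counts as one node. Plateaus count once, at
#' their leftmost point. Because nodes closer than the resolution of the
#' profile merge into single maxima, the returned count is a lower-bound
#' estimate of the true node number.
#'
#' @param p an [intensity_profile()] with a meaningful `background`.
#' @param threshold_factor multiple of the background a maximum must
#'   exceed (default 2, i.e. about twice the mean background).
#' @return List with `count`, `positions`, `intensities` (possibly empty).
#' @export
find_nodes <- function(p, threshold_factor = 2.0) {
  stopifnot(inherits(p, "intensity_profile"), threshold_factor >= 0)
  I <- p$I
  r <- rle(I)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(vals)
  is_max <- logical(m)
  for (i in seq_len(m)) {
    up_left <- i == 1L || vals[i] > vals[i - 1L]
    up_right <- i == m || vals[i] > vals[i + 1L]
    is_max[i] <- up_left && up_right
  }
  thr <- threshold_factor * p$background
  keep <- is_max & vals > thr
  idx <- starts[keep]  # leftmost point of each plateau
  list(count = length(idx), positions = p$x[idx], intensities = I[idx])
}

#' Fit a FRAP recovery curve
#'
#' Fits `I(t) = A * (1 - exp(-k*t)) + c` to a fluorescence recovery
#' trace by nonlinear least squares; the turnover half-time is
#' `t_half = ln(2)/k`. A non-recovering (flat or decreasing) trace is
#' flagged as a fit failure.
#'
#' @param t times (s), increasing, at least 5 points.
#' @param I intensities (a.u.).
#' @return An object of class `frap_fit`: `k` (s^-1), `t_half` (s),
#'   `plateau` (`A + c`, a.u.), `ok`, `reason`.
#' @export
fit_frap <- function(t, I) {
  stopifnot(is.numeric(t), is.numeric(I), length(t) == length(I))
  if (length(t) < 5L)
    stop("FRAP fit requires at least 5 time points")
  if (any(diff(t) <= 0))
    stop("FRAP fit requires strictly increasing times")
  slope <- stats::cov(t, I) / stats::var(t)
  if (slope <= 0) {
    return(structure(list(k = NA_real_, t_half = NA_real_,
                          plateau = NA_real_, ok = FALSE,
                          reason = "trace does not recover"),
                     class = "frap_fit"))
  }
  c0 <- I[1L]
  if (c0 == 0) c0 <- 1e-6 * max(abs(I))  # avoid zero-start Jacobian step
  A0 <- max(I) - c0
  if (A0 <= 0) A0 <- abs(slope) * diff(range(t))
  k0 <- 2 / diff(range(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A * (1 - exp(-k * t)) + cc,
                      start = list(A = A0, k = k0, cc = c0),
                      lower = c(A = 0, k = 1e-8, cc = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(k = NA_real_, t_half = NA_real_,
                          plateau = NA_real_, ok = FALSE,
                          reason = "nonlinear fit did not converge"),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(k = cf[["k"]], t_half = log(2) / cf[["k"]],
                 plateau = cf[["A"]] + cf[["cc"]], ok = TRUE,
                 reason = NA_character_),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("FRAP fit: k = %.4g s^-1, t_half = %.1f s, plateau = %.4g\n",
                x$k, x$t_half, x$plateau))
  else cat("FRAP fit FAILED:", x$reason, "\n")
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(k = object$k, t_half = object$t_half, plateau = object$plateau)
}

#' Molecule counting by intensity-ratio calibration
#'
#' Converts fluorescence intensity to molecule counts by ratio against a
#' calibrated standard (e.g. bacterial flagellar-motor GFP spots at 22
#' molecules per dot, or a whole-cell standard of known copy number):
#' `molecules = sample_intensity / standard_intensity * standard_count`.
#'
#' @param sample_intensity measured intensity (a.u.); vectorized.
#' @param standard_intensity intensity of the calibration standard
#'   (a.u.), `> 0`.
#' @param standard_count molecules per standard unit (default 22).
#' @return Estimated molecule count(s).
#' @export
count_molecules <- function(sample_intensity, standard_intensity,
                            standard_count = 22) {
  if (!(standard_intensity > 0))
    stop("standard intensity must be positive")
  stopifnot(standard_count > 0)
  sample_intensity / standard_intensity * standard_count
}

#' Convert a cortical loop profile to a tip-distance profile
#'
#' Bins a closed-loop cortical profile (angular coordinate measured at
#' the cell center, with the chosen tip at angle 0) into equal angular
#' sectors, averages the intensity per sector, and converts each sector's
#' central angle into the distance from the tip along the cortex. The
#' mid-plane outline is approximated as two semicircles of radius `R`
#' connected by straight lines (total length `L`), so the opposing tip
#' (angle `pi`) maps to the half-perimeter `(L - 2*R) + pi*R`.
#'
#' @param loop a cortical-loop [intensity_profile()] whose `x` are angles
#'   in radians (any values; reduced modulo `2*pi`).
#' @param sectors number of angular sectors (default 100).
#' @param L,R mean cell length and radius (um) for the conversion;
#'   default to the profile's `L` and 1.5 um.
#' @return A data.frame with `angle` (sector center, rad), `distance_um`
#'   (from the tip along the cortex), `intensity` (sector mean; `NA` with
#'   `missing = TRUE` for empty sectors), `n`.
#' @export
cortical_profile_by_angle <- function(loop, sectors = 100, L = loop$L,
                                      R = 1.5) {
  stopifnot(inherits(loop, "intensity_profile"))
  if (loop$kind != "cortical-loop")
    stop("angle binning requires a cortical-loop profile")
  stopifnot(is.finite(L), L >= 2 * R, R > 0, sectors >= 2)
  theta <- loop$x %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = sectors + 1L)
  bin <- findInterval(theta, edges, rightmost.closed = TRUE)
  centers <- (edges[-1L] + edges[-(sectors + 1L)]) / 2
  means <- rep(NA_real_, sectors)
  counts <- integer(sectors)
  agg <- tapply(loop$I, factor(bin, levels = seq_len(sectors)), mean)
  cnt <- tapply(rep(1L, length(bin)), factor(bin, levels = seq_len(sectors)),
                sum)
  means[] <- as.numeric(agg)
  counts[] <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  data.frame(angle = centers,
             distance_um = stadium_tip_distance(centers, L, R),
             intensity = means, n = counts,
             missing = counts == 0L)
}

# Arc length along a stadium outline (two semicircles radius R joined by
# straight lines, total length L) from the tip at polar angle 0 to the
# boundary point seen at polar angle theta from the cell center.
stadium_tip_distance <- function(theta, L, R) {
  c_half <- (L - 2 * R) / 2
  half_perim <- (L - 2 * R) + pi * R
  one <- function(th) {
    th <- th %% (2 * pi)
    if (th > pi) th <- 2 * pi - th   # lower half mirrors the upper
    if (c_half == 0) return(R * th)  # circular limit
    th_corner <- atan2(R, c_half)
    if (th <= th_corner) {
      # right cap: ray hits circle centered (c_half, 0)
      t <- c_half * cos(th) + sqrt(pmax(R^2 - c_half^2 * sin(th)^2, 0))
      phi <- atan2(t * sin(th), t * cos(th) - c_half)
      R * phi
    } else if (th < pi - th_corner) {
      u <- R / tan(th)               # straight segment y = R
      R * pi / 2 + (c_half - u)
    } else {
      thm <- pi - th                 # mirror onto the right cap
      t <- c_half * cos(thm) + sqrt(pmax(R^2 - c_half^2 * sin(thm)^2, 0))
      phi <- atan2(t * sin(thm), t * cos(thm) - c_half)
      half_perim - R * phi
    }
  }
  vapply(theta, one, numeric(1))
}

#' Read / write intensity profiles as CSV
#'
#' Plain-text interchange: commented metadata header rows
#' (`# cell_id,...`, `# length_um,...`, `# background,...`, `# kind,...`)
#' followed by columns `x_um, intensity`.
#'
#' @param path file path.
#' @return `read_profile_csv` returns an [intensity_profile()] (with
#'   attribute `cell_id`); `write_profile_csv` returns `path` invisibly.
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ",")[[1L]]
    if (length(kv) >= 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  d <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                         value = TRUE), collapse = "\n"))
  num_or_na <- function(v) {
    if (is.null(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  p <- intensity_profile(d$x_um, d$intensity,
                         background = num_or_na(meta$background %||% 0),
                         L = num_or_na(meta$length_um),
                         kind = meta$kind %||% "axial-band")
  attr(p, "cell_id") <- meta$cell_id
  p
}

#' @rdname read_profile_csv
#' @param p an [intensity_profile()].
#' @param cell_id identifier written into the metadata header.
#' @export
write_profile_csv <- function(p, path, cell_id = "cell") {
  stopifnot(inherits(p, "intensity_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# cell_id,", cell_id),
               paste0("# length_um,", p$L),
               paste0("# background,", p$background),
               paste0("# kind,", p$kind),
               "x_um,intensity",
               paste(p$x, p$I, sep = ",")), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
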