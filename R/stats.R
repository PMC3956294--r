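#' Pair of binned probability distributions on shared edges
#'
#' Validates that `p` and `q` are probability mass vectors on the same
#' bin edges: non-negative and each summing to 1 within `1e-9`.
#' No silent renormalization is performed.
#'
#' @param p,q probability masses per bin (equal length).
#' @param edges optional shared bin edges (`length(p) + 1`).
#' @return A list of class `distribution_pair`.
#' @export
distribution_pair <- function(p, q, edges = NULL) {
  stopifnot(is.numeric(p), is.numeric(q))
  if (length(p) != length(q))
    stop("p and q must be binned on the same edges (unequal lengths)")
  if (any(p < 0) || any(q < 0))
    stop("probability masses must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("p and q must each sum to 1 (within 1e-9); got sums ",
         signif(sum(p), 10), " and ", signif(sum(q), 10),
         " - renormalize explicitly before comparing")
  if (!is.null(edges) && length(edges) != length(p) + 1L)
    stop("edges must have length(p) + 1 elements")
  structure(list(p = p, q = q, edges = edges), class = "distribution_pair")
}

#' Jensen-Shannon distance between two binned distributions
#'
#' The square root of the Jensen-Shannon divergence
#' `JSD(p, q) = H(m) - (H(p) + H(q))/2` with `m = (p + q)/2` and Shannon
#' entropies `H` taken with base-2 logarithms, so the distance lies in
#' `[0, 1]`: 0 for identical distributions, 1 for distributions with no
#' shared information (disjoint supports). The convention `0 * log 0 = 0`
#' applies.
#'
#' @param d a [distribution_pair()], or `p` if `q` is supplied.
#' @param q optional second distribution (then `d` is taken as `p`).
#' @return The Jensen-Shannon distance, a number in `[0, 1]`.
#' @examples
#' js_distance(c(1, 0), c(0, 1))  # 1: disjoint supports
#' js_distance(c(1, 0), c(0.5, 0.5))  # 0.5579
#' @export
js_distance <- function(d, q = NULL) {
  if (!inherits(d, "distribution_pair"))
    d <- distribution_pair(d, q)
  p <- d$p
  q <- d$q
  m <- (p + q) / 2
  jsd <- shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
  jsd <- min(max(jsd, 0), 1)  # clip roundoff at the exact endpoints
  sqrt(jsd)
}

shannon_entropy <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Bin two samples onto shared histogram edges
#'
#' Convenience for comparing continuous measurements (lengths, areas,
#' volumes) with [js_distance()]: shared edges spanning both samples,
#' with bin width chosen by the Freedman-Diaconis rule on the pooled
#' sample.
#'
#' @param a,b numeric samples.
#' @return A [distribution_pair()].
#' @export
shared_histogram <- function(a, b) {
  pooled <- c(a, b)
  bw <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  if (bw <= 0) bw <- diff(range(pooled)) / 10
  if (bw <= 0) bw <- 1
  lo <- floor(min(pooled) / bw) * bw
  hi <- ceiling(max(pooled) / bw + 1e-9) * bw
  edges <- seq(lo, hi + bw / 2, by = bw)
  pa <- graphics::hist(a, breaks = edges, plot = FALSE)$counts
  pb <- graphics::hist(b, breaks = edges, plot = FALSE)$counts
  pa <- pa / sum(pa)
  pb <- pb / sum(pb)
  # guard against roundoff in the normalized masses
  pa[length(pa)] <- pa[length(pa)] + (1 - sum(pa))
  pb[length(pb)] <- pb[length(pb)] + (1 - sum(pb))
  distribution_pair(pa, pb, edges = edges)
}

#' Ordinary least-squares line fit
#'
#' Thin wrapper around `stats::lm` returning the slope, intercept,
#' r-squared and the standard error of the slope.
#'
#' @param x,y numeric vectors, at least 3 points, `var(x) > 0`.
#' @return List with `slope`, `intercept`, `r_squared`, `slope_se`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L)
    stop("linear fit requires at least 3 points")
  if (stats::var(x) == 0)
    stop("linear fit requires variation in x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence R's perfect-fit notice
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       slope_se = sm$coefficients[2L, 2L])
}

#' Monte-Carlo robustness of a positive rate correlation
#'
#' Tests whether a positive correlation between per-cell growth rates and
#' accumulation rates is robust to the per-cell measurement errors: for
#' each replicate, every (growth, accumulation) pair is perturbed by
#' Gaussian noise with its own measured errors (both members of the
#' pair), an ordinary least-squares slope is fitted, and the returned
#' probability is the fraction of replicates in which the positive slope
#' is absent (slope <= 0).
#'
#' @param pairs a data.frame with columns `growth_rate`,
#'   `accumulation_rate`, `growth_err`, `accumulation_err` (errors >= 0),
#'   at least 3 rows.
#' @param n_reps number of Monte-Carlo replicates (default `1e6`).
#' @param seed integer seed; the same seed gives an identical result.
#' @param chunk internal vectorization chunk size.
#' @return List with `p_no_positive` (fraction of replicates with slope
#'   <= 0), `observed_slope` (on the unperturbed data), `n_reps`.
#' @export
correlation_robustness <- function(pairs, n_reps = 1e6, seed = 1,
                                   chunk = 5e4) {
  need <- c("growth_rate", "accumulation_rate", "growth_err",
            "accumulation_err")
  stopifnot(all(need %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3L) stop("at least 3 rate pairs are required")
  if (any(!is.finite(as.matrix(pairs[need]))))
    stop("rate pairs and errors must be finite")
  if (any(pairs$growth_err < 0) || any(pairs$accumulation_err < 0))
    stop("measurement errors must be >= 0")
  if (stats::var(pairs$growth_rate) == 0 && all(pairs$growth_err == 0))
    stop("no variation in growth rate: slope undefined")
  gx <- pairs$growth_rate
  gy <- pairs$accumulation_rate
  ex <- pairs$growth_err
  ey <- pairs$accumulation_err
  obs <- ols_slope(gx, gy)
  set.seed(seed)
  n_reps <- as.integer(n_reps)
  bad <- 0L
  done <- 0L
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    X <- matrix(stats::rnorm(n * m, mean = gx, sd = ex), nrow = n)
    Y <- matrix(stats::rnorm(n * m, mean = gy, sd = ey), nrow = n)
    xc <- X - matrix(colMeans(X), nrow = n, ncol = m, byrow = TRUE)
    yc <- Y - matrix(colMeans(Y), nrow = n, ncol = m, byrow = TRUE)
    slopes <- colSums(xc * yc) / colSums(xc * xc)
    bad <- bad + sum(slopes <= 0)
    done <- done + m
  }
  list(p_no_positive = bad / n_reps, observed_slope = obs,
       n_reps = n_reps)
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Bin per-cell values by cell length
#'
#' Half-open 1-um bins `[k, k + bin_width)` by default (a length of
#' exactly 9.0 um falls in the 9-10 um bin); empty bins are omitted.
#'
#' @param cells a data.frame with columns `length_um` and `value`.
#' @param bin_width bin width (um).
#' @return A data.frame with `bin_lo`, `bin_hi`, `mean`, `sd`, `sem`, `n`.
#' @export
bin_by_length <- function(cells, bin_width = 1) {
  stopifnot(all(c("length_um", "value") %in% names(cells)), bin_width > 0)
  lo <- floor(cells$length_um / bin_width) * bin_width
  sp <- split(cells$value, lo)
  d <- data.frame(
    bin_lo = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL)
  d$bin_hi <- d$bin_lo + bin_width
  d$sem <- d$sd / sqrt(d$n)
  d[order(d$bin_lo), c("bin_lo", "bin_hi", "mean", "sd", "sem", "n")]
}

#' Select strain subsets matched on area or volume
#'
#' To compare strains at equal size, selects from each strain the cells
#' whose matching quantity lies within a window `pooled mean * (1 +/- f)`,
#' scanning the window half-width `f` over 10-20% per strain so that the
#' cross-strain subset means of the matching quantity agree to within 1%.
#' If no combination of windows achieves 1%, the best achievable windows
#' are returned with a warning flag.
#'
#' @param cells a data.frame with columns `strain`, `area_um2`,
#'   `volume_um3` (and any others, carried through).
#' @param quantity `"area"` or `"volume"`: the quantity to match on.
#' @param f_range window half-width range scanned (fractions).
#' @param f_step scan step.
#' @return List with `subset` (selected rows), `achieved_f` (named per
#'   strain), `subset_means`, `max_rel_diff` (largest pairwise relative
#'   difference of subset means), `ok` (TRUE if within 1%).
#' @export
select_matched_subset <- function(cells, quantity = c("area", "volume"),
                                  f_range = c(0.10, 0.20),
                                  f_step = 0.005) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "area") "area_um2" else "volume_um3"
  stopifnot(all(c("strain", col) %in% names(cells)))
  strains <- unique(cells$strain)
  if (length(strains) < 2L)
    stop("matched-subset selection requires records from at least 2 strains")
  center <- mean(cells[[col]])
  fs <- seq(f_range[1L], f_range[2L], by = f_step)
  # per strain, the window half-width whose subset mean is closest to the
  # pooled center
  achieved_f <- numeric(length(strains))
  names(achieved_f) <- strains
  subset_means <- numeric(length(strains))
  names(subset_means) <- strains
  keep_rows <- logical(nrow(cells))
  for (s in strains) {
    rows <- which(cells$strain == s)
    v <- cells[[col]][rows]
    best <- NULL
    for (f in fs) {
      sel <- abs(v - center) <= f * center
      if (!any(sel)) next
      m <- mean(v[sel])
      if (is.null(best) || abs(m - center) < best$dev)
        best <- list(f = f, sel = sel, mean = m,
                     dev = abs(m - center))
    }
    if (is.null(best)) {
      # nothing inside even the widest window: take the single closest cell
      j <- which.min(abs(v - center))
      best <- list(f = f_range[2L], sel = seq_along(v) == j,
                   mean = v[j], dev = abs(v[j] - center))
    }
    achieved_f[s] <- best$f
    subset_means[s] <- best$mean
    keep_rows[rows[best$sel]] <- TRUE
  }
  rel <- abs(outer(subset_means, subset_means, "-")) /
    mean(subset_means)
  max_rel_diff <- max(rel)
  ok <- max_rel_diff <= 0.01
  if (!ok)
    warning("matched-subset means differ by ",
            sprintf("%.2f%%", 100 * max_rel_diff),
            " (> 1%); reporting best achievable windows")
  list(subset = cells[keep_rows, , drop = FALSE],
       achieved_f = achieved_f, subset_means = subset_means,
       max_rel_diff = max_rel_diff, ok = ok)
}
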