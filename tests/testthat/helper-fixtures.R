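# Shared fixtures: canonical geometries and parameter sets used across
# test files. All synthetic inputs are generated in code at test time.

geom7 <- function() spherocylinder(7, 1.5, w_nod = 3)
geom14 <- function() spherocylinder(14, 1.5, w_nod = 3)

# constant-cytoplasm variants isolate the geometric scaling
params1_const <- function(...) uniform_params(cyt_slope = 0, ...)
params2_const <- function(...) modification_params(cyt_slope = 0, ...)

# brute-force Jensen-Shannon distance straight from the definition
# (base-2 KL divergences to the mixture), independent of js_distance()
jsd_bruteforce <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

# textbook OLS slope/intercept from the closed-form normal equations
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
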