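#' Parameters of the uniform-cortex accumulation model (Model I)
#'
#' Rate constants for the three-compartment quasi-steady-state model in
#' which cytoplasmic protein associates uniformly with the cell membrane,
#' cortical protein is taken up into a medial nodal region, and both
#' cortical and nodal protein dissociate back into the cytoplasm.
#'
#' Defaults are the measured/constrained values: nodal dissociation
#' `eta = 5e-3 s^-1` (from a ~3 min FRAP turnover), uptake
#' `alpha = 1.0 s^-1` (bounded below by the observed nodal/cortical
#' density contrast), cortical dissociation `nu = 5e-3 s^-1` (equal to
#' `eta`), and a slight linear decrease of the cytoplasmic concentration
#' with length, relative slope `-0.01 um^-1`. The association parameter
#' `beta` enters every density only as a multiplicative prefactor, so its
#' default is 1 in arbitrary units.
#'
#' @param beta cytoplasm-to-membrane association parameter (um s^-1).
#' @param nu cortical dissociation rate (s^-1).
#' @param alpha cortical-to-nodal uptake rate (s^-1).
#' @param eta nodal dissociation rate (s^-1).
#' @param rho_cyt_ref reference cytoplasmic concentration
#'   (molecules um^-3; arbitrary units allowed).
#' @param cyt_slope relative change of the cytoplasmic concentration per
#'   um of cell length (um^-1); 0 gives a strictly constant cytoplasm.
#' @param L_ref length at which the cytoplasmic concentration equals
#'   `rho_cyt_ref` (um).
#' @return A list of class `uniform_model_params`.
#' @export
uniform_params <- function(beta = 1, nu = 5e-3, alpha = 1.0, eta = 5e-3,
                           rho_cyt_ref = 1, cyt_slope = -0.01,
                           L_ref = 10.5) {
  stopifnot(beta >= 0, nu >= 0, alpha > 0, eta > 0, rho_cyt_ref >= 0,
            L_ref > 0)
  structure(list(beta = beta, nu = nu, alpha = alpha, eta = eta,
                 rho_cyt_ref = rho_cyt_ref, cyt_slope = cyt_slope,
                 L_ref = L_ref),
            class = "uniform_model_params")
}

#' Parameters of the modification-intermediate model (Model II)
#'
#' In this variant, membrane-bound protein is released as a modified
#' cytoplasmic form which binds the nodal region directly (binding
#' constant `alpha`, um s^-1) or spontaneously reverts to the unmodified
#' cytoplasmic pool at rate `mu`. Defaults: `nu = 0.5 s^-1` (keeps
#' cortical levels low), `alpha = 0.5 um s^-1`, `eta = 5e-3 s^-1` (FRAP),
#' `mu = 0.03 s^-1`.
#'
#' @inheritParams uniform_params
#' @param alpha modified-cytoplasm-to-node binding constant (um s^-1).
#' @param mu spontaneous reversion rate of the modified cytoplasmic form
#'   (s^-1).
#' @return A list of class `modification_model_params`.
#' @export
modification_params <- function(beta = 1, nu = 0.5, alpha = 0.5,
                                eta = 5e-3, mu = 0.03,
                                rho_cyt_ref = 1, cyt_slope = -0.01,
                                L_ref = 10.5) {
  stopifnot(beta >= 0, nu >= 0, alpha >= 0, eta > 0, mu >= 0,
            rho_cyt_ref >= 0, L_ref > 0)
  structure(list(beta = beta, nu = nu, alpha = alpha, eta = eta, mu = mu,
                 rho_cyt_ref = rho_cyt_ref, cyt_slope = cyt_slope,
                 L_ref = L_ref),
            class = "modification_model_params")
}

#' Cytoplasmic concentration at a given cell length
#'
#' Linear trend `rho_cyt_ref * (1 + cyt_slope * (L - L_ref))`, clamped at
#' zero. With `cyt_slope = 0` the cytoplasm is strictly constant.
#'
#' @param params a [uniform_params()] or [modification_params()] object
#'   (any list carrying `rho_cyt_ref`, `cyt_slope`, `L_ref`).
#' @param L cell length (um), `> 0`; vectorized.
#' @return Cytoplasmic concentration(s), same units as `rho_cyt_ref`.
#' @export
rho_cyt_at <- function(params, L) {
  stopifnot(all(L > 0))
  pmax(params$rho_cyt_ref * (1 + params$cyt_slope * (L - params$L_ref)), 0)
}

new_steady_state <- function(rho_cyt, rho_cor, rho_nod, geom,
                             rho_cyt_mod = NA_real_, model = "uniform") {
  structure(list(
    rho_cyt = rho_cyt, rho_cor = rho_cor, rho_nod = rho_nod,
    rho_cyt_mod = rho_cyt_mod,
    N_cor = rho_cor * geom$A_cor,
    N_nod = rho_nod * geom$A_nod,
    geom = geom, model = model
  ), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Quasi-steady state (%s model), L = %.2f um\n",
              x$model, x$geom$L))
  cat(sprintf("  rho_cyt = %.4g um^-3  rho_cor = %.4g um^-2  rho_nod = %.4g um^-2\n",
              x$rho_cyt, x$rho_cor, x$rho_nod))
  if (is.finite(x$rho_cyt_mod))
    cat(sprintf("  rho_cyt_mod = %.4g um^-3\n", x$rho_cyt_mod))
  cat(sprintf("  N_cor = %.4g  N_nod = %.4g\n", x$N_cor, x$N_nod))
  invisible(x)
}

#' Model I closed-form steady state
#'
#' Exact solution of the two mass-action balances of the uniform-cortex
#' model:
#' `rho_nod = rho_cyt * (beta/eta) / (nu/alpha + A_nod/A_cor)` and
#' `rho_cor = rho_nod * eta / alpha`. With `nu = 0` this reduces to
#' `rho_nod = rho_cyt * (beta/eta) * (A_cor/A_nod)`, i.e. the nodal
#' density reads out the total membrane area.
#'
#' @param params a [uniform_params()] object.
#' @param geom a [spherocylinder()] geometry.
#' @return A `steady_state` object.
#' @export
model1_closed_form <- function(params, geom) {
  stopifnot(inherits(params, "uniform_model_params"),
            inherits(geom, "cell_geometry"))
  denom <- params$nu / params$alpha + geom$A_nod / geom$A_cor
  if (denom == 0)
    stop("singular model: A_nod = 0 and nu = 0 leave the nodal balance undefined")
  rho_cyt <- rho_cyt_at(params, geom$L)
  rho_nod <- rho_cyt * (params$beta / params$eta) / denom
  rho_cor <- rho_nod * params$eta / params$alpha
  new_steady_state(rho_cyt, rho_cor, rho_nod, geom, model = "uniform")
}

#' Direct-to-node null model
#'
#' If cytoplasmic protein can only associate with the membrane by direct
#' uptake into the nodes, balancing arrival (`beta`) against departure
#' (`eta`) gives `rho_nod = (beta/eta) * rho_cyt` — independent of cell
#' size for a constant cytoplasm. This null model shows that membrane
#' localization alone does not produce size sensing.
#'
#' @inheritParams model1_closed_form
#' @return A `steady_state` object with `rho_cor = 0`.
#' @export
model1_direct_null <- function(params, geom) {
  stopifnot(inherits(params, "uniform_model_params"),
            inherits(geom, "cell_geometry"))
  rho_cyt <- rho_cyt_at(params, geom$L)
  rho_nod <- (params$beta / params$eta) * rho_cyt
  new_steady_state(rho_cyt, 0, rho_nod, geom, model = "direct-null")
}

#' Model II closed-form steady state
#'
#' Exact solution of the three balances of the modification model:
#' `rho_nod = (beta/eta) * (A_cor/A_nod) * rho_cyt / (mu*V/(alpha*A_nod) + 1)`,
#' `rho_cor = beta * rho_cyt / nu`, and the modified cytoplasmic pool
#' `rho_cyt_mod = beta * A_cor * rho_cyt / (V * (mu + alpha*A_nod/V))`.
#' With `mu = 0` (no spontaneous reversion) the nodal density reduces to
#' `(beta/eta) * (A_cor/A_nod) * rho_cyt`, a pure area read-out; the
#' reversion correction is negligible whenever `alpha*A_nod >> mu*V`.
#'
#' @param params a [modification_params()] object.
#' @param geom a [spherocylinder()] geometry with `A_nod > 0`.
#' @return A `steady_state` object (with `rho_cyt_mod` populated).
#' @export
model2_closed_form <- function(params, geom) {
  stopifnot(inherits(params, "modification_model_params"),
            inherits(geom, "cell_geometry"))
  if (geom$A_nod <= 0)
    stop("singular model: A_nod = 0 (no nodal region) in the modification model")
  if (params$nu <= 0)
    stop("singular model: nu = 0 leaves the cortical balance undefined")
  rho_cyt <- rho_cyt_at(params, geom$L)
  rho_cor <- params$beta * rho_cyt / params$nu
  sink_rate <- params$mu + params$alpha * geom$A_nod / geom$V
  if (sink_rate <= 0)
    stop("singular model: alpha = 0 and mu = 0 leave the modified pool undefined")
  N_cyt_mod <- params$beta * geom$A_cor * rho_cyt / sink_rate
  rho_cyt_mod <- N_cyt_mod / geom$V
  if (params$alpha == 0) {
    rho_nod <- 0  # flux to the nodes is cut, not singular
  } else {
    rho_nod <- (params$beta / params$eta) * (geom$A_cor / geom$A_nod) *
      rho_cyt / (params$mu * geom$V / (params$alpha * geom$A_nod) + 1)
  }
  new_steady_state(rho_cyt, rho_cor, rho_nod, geom,
                   rho_cyt_mod = rho_cyt_mod, model = "modification")
}

# Damped Newton for steady-state balance systems. The residuals are
# linear in the copy numbers, so this converges immediately; the
# iteration and residual check guard against mis-specified systems.
newton_steady <- function(resid_fn, jac_fn, n_unknowns, flux_scale,
                          tol = 1e-12, max_iter = 50L) {
  N <- rep(1, n_unknowns)
  for (iter in seq_len(max_iter)) {
    F <- resid_fn(N)
    if (max(abs(F)) <= tol * flux_scale) break
    step <- solve(jac_fn(N), -F)
    damp <- 1
    repeat {
      N_new <- N + damp * step
      if (all(is.finite(resid_fn(N_new)))) break
      damp <- damp / 2
      if (damp < 1e-8)
        stop("numeric steady-state solve failed: damping underflow")
    }
    N <- N_new
  }
  F <- resid_fn(N)
  if (max(abs(F)) > tol * flux_scale)
    stop("numeric steady-state solve did not converge; residuals = ",
         paste(signif(F, 4), collapse = ", "))
  N
}

#' Model I numeric steady state
#'
#' Solves the two mass-action balance equations of the uniform-cortex
#' model directly by damped Newton iteration with analytic Jacobian
#' (converging to relative residual `1e-12` of the largest flux term),
#' as an independent check on [model1_closed_form()].
#'
#' @inheritParams model1_closed_form
#' @return A `steady_state` object.
#' @export
model1_numeric <- function(params, geom) {
  stopifnot(inherits(params, "uniform_model_params"),
            inherits(geom, "cell_geometry"))
  rho_cyt <- rho_cyt_at(params, geom$L)
  N_cyt <- rho_cyt * geom$V
  if (params$beta == 0 || N_cyt == 0)
    return(new_steady_state(rho_cyt, 0, 0, geom, model = "uniform"))
  a_in <- params$beta * (geom$A_cor / geom$V) * N_cyt
  frac <- geom$A_nod / geom$A_cor
  if (params$nu == 0 && frac == 0)
    stop("singular model: A_nod = 0 and nu = 0 leave the nodal balance undefined")
  resid_fn <- function(N) c(
    a_in - params$nu * N[1] - params$alpha * frac * N[1],
    params$alpha * frac * N[1] - params$eta * N[2]
  )
  jac_fn <- function(N) matrix(c(
    -params$nu - params$alpha * frac, 0,
    params$alpha * frac, -params$eta
  ), nrow = 2, byrow = TRUE)
  N <- newton_steady(resid_fn, jac_fn, 2L, flux_scale = a_in)
  if (geom$A_nod > 0) {
    rho_nod <- N[2] / geom$A_nod
  } else {
    rho_nod <- 0
  }
  new_steady_state(rho_cyt, N[1] / geom$A_cor, rho_nod, geom,
                   model = "uniform")
}

#' Model II numeric steady state
#'
#' Solves the three balance equations of the modification model (cortical,
#' modified-cytoplasmic and nodal pools) by damped Newton iteration with
#' analytic Jacobian, as an independent check on [model2_closed_form()].
#'
#' @inheritParams model2_closed_form
#' @return A `steady_state` object.
#' @export
model2_numeric <- function(params, geom) {
  stopifnot(inherits(params, "modification_model_params"),
            inherits(geom, "cell_geometry"))
  if (geom$A_nod <= 0)
    stop("singular model: A_nod = 0 (no nodal region) in the modification model")
  if (params$nu <= 0)
    stop("singular model: nu = 0 leaves the cortical balance undefined")
  rho_cyt <- rho_cyt_at(params, geom$L)
  N_cyt <- rho_cyt * geom$V
  if (params$beta == 0 || N_cyt == 0)
    return(new_steady_state(rho_cyt, 0, 0, geom, rho_cyt_mod = 0,
                            model = "modification"))
  if (params$alpha == 0 && params$mu == 0)
    stop("singular model: alpha = 0 and mu = 0 leave the modified pool undefined")
  a_in <- params$beta * (geom$A_cor / geom$V) * N_cyt
  nod_rate <- params$alpha * geom$A_nod / geom$V
  # unknowns: N_cor, N_cyt_mod, N_nod
  resid_fn <- function(N) c(
    a_in - params$nu * N[1],
    params$nu * N[1] - params$mu * N[2] - nod_rate * N[2],
    nod_rate * N[2] - params$eta * N[3]
  )
  jac_fn <- function(N) matrix(c(
    -params$nu, 0, 0,
    params$nu, -params$mu - nod_rate, 0,
    0, nod_rate, -params$eta
  ), nrow = 3, byrow = TRUE)
  N <- newton_steady(resid_fn, jac_fn, 3L, flux_scale = a_in)
  new_steady_state(rho_cyt, N[1] / geom$A_cor, N[3] / geom$A_nod, geom,
                   rho_cyt_mod = N[2] / geom$V, model = "modification")
}

#' Fit the scaling-curve prefactor to density-vs-length data
#'
#' The steady-state models predict nodal density as a function of cell
#' length up to a single free multiplicative prefactor (the association
#' parameter times the reference cytoplasmic concentration, in arbitrary
#' fluorescence units). This fits that prefactor by least squares to
#' measured (length, density) pairs, holding all rate constants fixed.
#'
#' @param L cell lengths (um), at least 3.
#' @param density measured nodal densities (arbitrary units), positive
#'   somewhere.
#' @param model one of `"uniform"`, `"modification"`, `"direct-null"`.
#' @param params model parameters ([uniform_params()] or
#'   [modification_params()]); defaults to the model's default parameters.
#' @param R cell radius used to build geometries (um).
#' @param w_nod nodal band width used for `A_nod` (um); held constant
#'   across lengths (the medial measurement band).
#' @return An object of class `scaling_fit` with elements `prefactor`,
#'   `fitted`, `r_squared`, `model`, and the inputs; `coef()` returns the
#'   prefactor, `predict()` evaluates the fitted curve at new lengths.
#' @export
fit_scaling_prefactor <- function(L, density,
                                  model = c("uniform", "modification",
                                            "direct-null"),
                                  params = NULL, R = 1.5, w_nod = 3) {
  model <- match.arg(model)
  stopifnot(length(L) == length(density))
  if (length(L) < 3L)
    stop("scaling fit requires at least 3 (L, density) points")
  if (all(density == 0))
    stop("scaling fit: all densities are zero")
  if (any(density < 0))
    stop("scaling fit: densities must be non-negative")
  if (is.null(params)) {
    params <- switch(model,
      uniform = uniform_params(),
      modification = modification_params(),
      `direct-null` = uniform_params())
  }
  shape_at <- function(Lv) {
    vapply(Lv, function(l) {
      g <- spherocylinder(l, R, w_nod = min(w_nod, l - 2 * R))
      ss <- switch(model,
        uniform = model1_closed_form(params, g),
        modification = model2_closed_form(params, g),
        `direct-null` = model1_direct_null(params, g))
      ss$rho_nod
    }, numeric(1))
  }
  s <- shape_at(L)
  prefactor <- sum(s * density) / sum(s^2)
  fitted <- prefactor * s
  ss_res <- sum((density - fitted)^2)
  ss_tot <- sum((density - mean(density))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(prefactor = prefactor, fitted = fitted, r_squared = r2,
                 model = model, params = params, R = R, w_nod = w_nod,
                 L = L, density = density, shape_at = shape_at),
            class = "scaling_fit")
}

#' @export
coef.scaling_fit <- function(object, ...) c(prefactor = object$prefactor)

#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$L else
    if (is.list(newdata)) newdata$L else newdata
  object$prefactor * object$shape_at(L)
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling-curve fit (%s model)\n", x$model))
  cat(sprintf("  prefactor = %.4g, r^2 = %.4f, n = %d\n",
              x$prefactor, x$r_squared, length(x$L)))
  invisible(x)
}

#' Write steady states along a length series as CSV
#'
#' Columns `L_um, rho_cyt, rho_cor, rho_nod, N_cor, N_nod`.
#'
#' @param states list of `steady_state` objects.
#' @param path file path.
#' @export
write_steady_states_csv <- function(states, path) {
  d <- do.call(rbind, lapply(states, function(s) data.frame(
    L_um = s$geom$L, rho_cyt = s$rho_cyt, rho_cor = s$rho_cor,
    rho_nod = s$rho_nod, N_cor = s$N_cor, N_nod = s$N_nod)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
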