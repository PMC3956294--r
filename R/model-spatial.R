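#' Parameters of the 1D spatial cortical-diffusion model
#'
#' Extends the uniform-cortex model with explicit cortical diffusion along
#' the long axis and a spatially localized nodal uptake rate
#' `alpha(x) = alpha0 * exp(-x^2 / (2*omega^2))` centered at mid-cell,
#' where the nodal-region width `omega` saturates with cell length (see
#' [omega()]). Defaults: `D_cor = 0.2 um^2 s^-1` (large enough that the
#' diffusional reach of cortical protein exceeds the half-cell, see
#' [diffusional_reach()]), `D_nod = 0` (nodes are essentially immobile),
#' `alpha0 = 0.5 s^-1`, `a = 2.2 um`, `s = 7 um`, `nu = eta = 5e-3 s^-1`,
#' cortical lifetime `tau = 180 s`.
#'
#' @param D_cor cortical diffusion coefficient (um^2 s^-1), `> 0`.
#' @param D_nod nodal diffusion coefficient (um^2 s^-1), `>= 0`.
#' @param alpha0 peak nodal uptake rate at mid-cell (s^-1).
#' @param a saturating nodal half-width (um).
#' @param s width-saturation length scale (um).
#' @param beta,nu,eta as in [uniform_params()].
#' @param tau cortical protein lifetime used for reach checks (s).
#' @return A list of class `spatial_model_params`.
#' @export
spatial_params <- function(D_cor = 0.2, D_nod = 0, alpha0 = 0.5,
                           a = 2.2, s = 7, beta = 1, nu = 5e-3,
                           eta = 5e-3, tau = 180) {
  stopifnot(D_cor > 0, D_nod >= 0, alpha0 >= 0, a > 0, s > 0,
            beta >= 0, nu >= 0, eta > 0, tau > 0)
  structure(list(D_cor = D_cor, D_nod = D_nod, alpha0 = alpha0,
                 a = a, s = s, beta = beta, nu = nu, eta = eta,
                 tau = tau),
            class = "spatial_model_params")
}

#' Saturating width of the nodal region
#'
#' `omega(L) = a * (1 - exp(-L/s))`: the fitted axial width of the nodal
#' uptake region grows with cell length but saturates at `a`.
#'
#' @param L cell length (um), `> 0`; vectorized.
#' @param a saturating half-width (um).
#' @param s saturation length scale (um).
#' @return Width(s) in um.
#' @examples
#' omega(14)  # 2.2 * (1 - exp(-2)) = 1.902 um
#' @export
omega <- function(L, a = 2.2, s = 7) {
  stopifnot(all(L > 0))
  a * (1 - exp(-L / s))
}

#' Typical diffusional displacement of a cortical protein
#'
#' `sqrt(2 * D * tau)`: the root-mean-square axial displacement of a
#' membrane-bound protein with diffusion coefficient `D` over its
#' lifetime `tau`. For nodal density to read out the whole membrane area,
#' this reach must exceed the tip-to-node distance (about 5 um).
#'
#' @param D diffusion coefficient (um^2 s^-1), `>= 0`.
#' @param tau lifetime (s), `> 0`.
#' @return Displacement in um.
#' @examples
#' diffusional_reach(0.2, 180)  # 8.49 um
#' @export
diffusional_reach <- function(D, tau) {
  stopifnot(all(D >= 0), all(tau > 0))
  sqrt(2 * D * tau)
}

#' Solve the 1D quasi-steady-state reaction-diffusion equations
#'
#' Solves, on the axial domain `[-L/2, L/2]` with zero-flux (reflecting)
#' boundaries at the cell tips,
#' \deqn{0 = D_{cor} \rho_{cor}'' - \nu \rho_{cor} - \alpha(x)\rho_{cor}
#'       + \beta \rho_{cyt}}
#' for the cortical density, and then the nodal density: pointwise
#' `rho_nod(x) = alpha(x) * rho_cor(x) / eta` when `D_nod = 0`, or the
#' analogous diffusion equation
#' `0 = D_nod rho_nod'' + alpha(x) rho_cor - eta rho_nod` when
#' `D_nod > 0`. Discretization is second-order central finite differences
#' with mirrored ghost points at the tips; the linear system is solved
#' directly (sparse tridiagonal).
#'
#' Two tip boundary conditions are supported. `"reflecting"` (the
#' default) imposes zero flux: molecules cannot leave through the cell
#' tips and total protein is conserved between the cytoplasmic influx
#' and the two dissociation channels. `"absorbing"` pins the cortical
#' density to zero at the tips, so some protein is lost at the
#' boundaries; this is the configuration under which the central-band
#' nodal density rises monotonically with cell length at the default
#' parameters (with reflecting tips the strongly absorbing nodal band
#' depletes its own center and the 3-um band mean is nearly flat, even
#' though total nodal content still grows; see the methods vignette).
#'
#' Densities are per membrane area; the circumferential dimension is
#' collapsed, with the factor `2*pi*R` applied only when integrating to
#' copy numbers (see [nodal_metrics()]).
#'
#' @param params a [spatial_params()] object.
#' @param L cell length (um).
#' @param rho_cyt cytoplasmic concentration driving membrane association.
#' @param grid_step grid spacing (um), `<= 0.05`.
#' @param boundary tip boundary condition for the cortical (and, when
#'   `D_nod > 0`, nodal) equation: `"reflecting"` (zero flux) or
#'   `"absorbing"` (zero density).
#' @return An object of class `spatial_solution`: list with `x` (grid,
#'   cell-centered), `rho_cor_x`, `rho_nod_x`, `grid_step`, `L`, `params`,
#'   `rho_cyt`, `boundary`.
#' @export
solve_spatial <- function(params, L, rho_cyt = 1, grid_step = 0.02,
                          boundary = c("reflecting", "absorbing")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "spatial_model_params"), L > 0,
            rho_cyt >= 0)
  if (grid_step > 0.05)
    stop("grid_step must be <= 0.05 um for adequate resolution")
  n <- max(4L, round(L / grid_step))
  h <- L / n
  x <- seq(-L / 2, L / 2, length.out = n + 1L)
  w <- omega(L, params$a, params$s)
  alpha_x <- params$alpha0 * exp(-x^2 / (2 * w^2))

  rho_cor <- solve_helmholtz_1d(params$D_cor, params$nu + alpha_x,
                                rep(params$beta * rho_cyt, n + 1L), h,
                                boundary)
  if (any(!is.finite(rho_cor)))
    stop("spatial solve produced non-finite cortical densities; ",
         "the linear system is singular or ill-conditioned")
  uptake <- alpha_x * rho_cor
  if (params$D_nod == 0) {
    rho_nod <- uptake / params$eta
  } else {
    rho_nod <- solve_helmholtz_1d(params$D_nod, rep(params$eta, n + 1L),
                                  uptake, h, boundary)
  }
  structure(list(x = x, rho_cor_x = rho_cor, rho_nod_x = rho_nod,
                 grid_step = h, L = L, params = params,
                 rho_cyt = rho_cyt, boundary = boundary),
            class = "spatial_solution")
}

# Solve 0 = D u'' - k(x) u + f(x) on a uniform grid. Second-order
# central differences; reflecting BC via mirrored ghost points
# (u_0 = u_2, u_{n+2} = u_n), absorbing BC via u = 0 at both ends.
# Sparse tridiagonal direct solve.
solve_helmholtz_1d <- function(D, k, f, h, boundary = "reflecting") {
  n <- length(f)
  if (boundary == "absorbing") {
    ki <- k[2:(n - 1L)]
    fi <- f[2:(n - 1L)]
    m <- n - 2L
    A <- Matrix::bandSparse(m, m, k = c(-1L, 0L, 1L), diagonals = list(
      rep(D / h^2, m - 1L), -2 * D / h^2 - ki, rep(D / h^2, m - 1L)))
    return(c(0, as.numeric(Matrix::solve(A, -fi)), 0))
  }
  main <- -2 * D / h^2 - k
  off <- rep(D / h^2, n - 1L)
  up <- off
  lo <- off
  up[1L] <- 2 * D / h^2       # ghost mirror at left tip
  lo[n - 1L] <- 2 * D / h^2   # ghost mirror at right tip
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(lo, main, up))
  as.numeric(Matrix::solve(A, -f))
}

#' @export
print.spatial_solution <- function(x, ...) {
  cat(sprintf("1D cortical/nodal steady-state solution, L = %.2f um, h = %.3g um\n",
              x$L, x$grid_step))
  cat(sprintf("  peak rho_cor = %.4g, peak rho_nod = %.4g (per um^2)\n",
              max(x$rho_cor_x), max(x$rho_nod_x)))
  invisible(x)
}

#' Nodal copy number and central-band density from a spatial solution
#'
#' Integrates the nodal density profile circumferentially
#' (`2*pi*R * integral of rho_nod dx`, trapezoid rule) for the total
#' nodal copy number, and averages the nodal density over the central
#' band `|x| <= band/2` (the medial measurement window).
#'
#' @param sol a [solve_spatial()] solution.
#' @param geom a [spherocylinder()] geometry supplying the radius `R`.
#' @param band central band width (um), default 3; must not exceed `L`.
#' @return List with `N_nod_total` and `band_mean_density`.
#' @export
nodal_metrics <- function(sol, geom, band = 3) {
  stopifnot(inherits(sol, "spatial_solution"),
            inherits(geom, "cell_geometry"))
  if (band > sol$L)
    stop("band width exceeds cell length")
  total <- 2 * pi * geom$R * trapz(sol$x, sol$rho_nod_x)
  in_band <- abs(sol$x) <= band / 2 + 1e-12
  band_mean <- mean(sol$rho_nod_x[in_band])
  list(N_nod_total = total, band_mean_density = band_mean)
}

trapz <- function(x, y) {
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Write a spatial solution as CSV
#'
#' Columns `x_um, rho_cor, rho_nod`.
#'
#' @param sol a [solve_spatial()] solution.
#' @param path file path.
#' @export
write_spatial_csv <- function(sol, path) {
  utils::write.csv(data.frame(x_um = sol$x, rho_cor = sol$rho_cor_x,
                              rho_nod = sol$rho_nod_x),
                   path, row.names = FALSE)
  invisible(path)
}
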