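#' Hamiltonian parameters for the cellular Potts engine
#'
#' Bundles every coefficient of the GGH Hamiltonian: the symmetric interface
#' (adhesion) energy table over the entity classes \{cell, fibre (ECM),
#' fluid\}, the area and perimeter constraints, the Boltzmann noise strength
#' and the active-motility term. Internal units: energies in kT, lengths in
#' pixels (1 px = 2 um), so `a0 = 100` px^2 corresponds to a 400 um^2 cell
#' and `p0 = 17.5` px to a 35 um target perimeter. Contact energies are
#' charged per first-order lattice edge.
#'
#' Lower `J` means stronger adhesion. The literature values for the J table
#' are `(J_cc, J_ce, J_cf, J_ef, J_ee, J_ff) = (1-40, 16, 32, 35, 5, 35)`,
#' with `J_cc` in \{1, 16, 40\} spanning high, medium and low cell-cell
#' adhesion.
#'
#' The defaults for `T_m` and `mu0` are this package's calibration of the
#' noise and motility scales, obtained by the same two phenomenological
#' criteria used to set them in the source model: confined cells must
#' exhibit persistent rotation, and cells migrating along pre-existing
#' fibre-free paths must reach ~23 um/h. See the methods vignette for why
#' the literature pair `(T_m = 0.01, mu0 = 50)` is not dynamically viable
#' under a per-edge Hamiltonian, and for the calibration procedure. The
#' literature pair remains loadable by passing it explicitly.
#'
#' @param J_cc,J_ce,J_cf,J_ef,J_ee,J_ff interface energies (kT per lattice
#'   edge) for cell-cell, cell-ECM, cell-fluid, ECM-fluid, ECM-ECM and
#'   fluid-fluid contacts.
#' @param lambda_a area-constraint coefficient (kT / px^4).
#' @param lambda_p perimeter-constraint coefficient (kT / px^2).
#' @param a0 target cell area in pixels (100 px = 400 um^2).
#' @param p0 target cell perimeter in pixel edges (17.5 px = 35 um).
#' @param T_m Boltzmann noise strength (kT); effective membrane-fluctuation
#'   magnitude of the copy dynamics.
#' @param mu0 motility strength (kT / px of centroid displacement).
#' @param tau polarity timescale: number of past per-MCS displacements
#'   averaged into the polarity vector.
#' @return An object of class `cpm_energy_params` (a named list).
#' @examples
#' p <- energy_params(J_cc = 40)
#' p$J["cell", "fluid"]
#' @export
energy_params <- function(J_cc = 1, J_ce = 16, J_cf = 32, J_ef = 35,
                          J_ee = 5, J_ff = 35,
                          lambda_a = 1.0, lambda_p = 0.5,
                          a0 = 100, p0 = 17.5,
                          T_m = 12, mu0 = 600, tau = 10) {
  vals <- c(J_cc = J_cc, J_ce = J_ce, J_cf = J_cf, J_ef = J_ef,
            J_ee = J_ee, J_ff = J_ff, lambda_a = lambda_a,
            lambda_p = lambda_p, a0 = a0, p0 = p0, T_m = T_m, mu0 = mu0)
  if (!all(is.finite(vals))) stop("all energy parameters must be finite")
  if (T_m <= 0) stop("T_m must be > 0")
  if (a0 <= 0 || p0 <= 0) stop("a0 and p0 must be positive")
  if (tau < 1 || tau != round(tau)) stop("tau must be a positive integer")
  J <- matrix(c(J_cc, J_ce, J_cf,
                J_ce, J_ee, J_ef,
                J_cf, J_ef, J_ff), 3, 3,
              dimnames = list(c("cell", "fibre", "fluid"),
                              c("cell", "fibre", "fluid")))
  structure(list(J = J, J_cc = J_cc, J_ce = J_ce, J_cf = J_cf, J_ef = J_ef,
                 J_ee = J_ee, J_ff = J_ff, lambda_a = lambda_a,
                 lambda_p = lambda_p, a0 = a0, p0 = p0, T_m = T_m,
                 mu0 = mu0, tau = as.integer(tau)),
            class = "cpm_energy_params")
}

#' @export
print.cpm_energy_params <- function(x, ...) {
  cat("CPM energy parameters (kT, px units)\n")
  cat(sprintf("  J: cc=%g ce=%g cf=%g ef=%g ee=%g ff=%g\n",
              x$J_cc, x$J_ce, x$J_cf, x$J_ef, x$J_ee, x$J_ff))
  cat(sprintf("  lambda_a=%g a0=%g | lambda_p=%g p0=%g\n",
              x$lambda_a, x$a0, x$lambda_p, x$p0))
  cat(sprintf("  T_m=%g mu0=%g tau=%d\n", x$T_m, x$mu0, x$tau))
  invisible(x)
}

#' MMP field parameters
#'
#' Parameters of the secretion / diffusion / decay dynamics of the soluble
#' MMP field, solved by forward Euler on the pixel grid with zero-flux
#' boundaries. One Monte Carlo step corresponds to 36 s of real time and
#' the 1-s PDE substep is applied 36 times per MCS. The default diffusion
#' coefficient 0.1 um^2/s (= 1.0e-9 cm^2/s) gives a stability number
#' `r = D dt / dx^2 = 0.025`, well inside the 2D forward-Euler bound 0.25.
#'
#' @param D diffusion coefficient in um^2/s.
#' @param delta_mmp first-order decay rate (1/s).
#' @param lambda secretion rate (1/s) deposited at each fibre pixel in
#'   contact with a cell; the plausible biological range explored is
#'   0.01-0.1.
#' @param dt PDE substep in seconds.
#' @param substeps PDE substeps per MCS (36 x 1 s = one 36-s MCS).
#' @param dx pixel size in um.
#' @return An object of class `cpm_mmp_params`.
#' @examples
#' mmp_params()$stability
#' @export
mmp_params <- function(D = 0.1, delta_mmp = 0.002, lambda = 0.05,
                       dt = 1, substeps = 36, dx = 2) {
  if (D < 0 || delta_mmp < 0 || lambda < 0) {
    stop("D, delta_mmp and lambda must be non-negative")
  }
  r <- D * dt / dx^2
  if (r > 0.25) {
    stop(sprintf("stability number D*dt/dx^2 = %g exceeds the forward-Euler bound 0.25", r))
  }
  structure(list(D = D, delta_mmp = delta_mmp, lambda = lambda, dt = dt,
                 substeps = as.integer(substeps), dx = dx, stability = r),
            class = "cpm_mmp_params")
}

#' @export
print.cpm_mmp_params <- function(x, ...) {
  cat(sprintf("MMP field: D=%g um^2/s, delta=%g /s, lambda=%g /s, dt=%g s x %d substeps/MCS (r=%g)\n",
              x$D, x$delta_mmp, x$lambda, x$dt, x$substeps, x$stability))
  invisible(x)
}
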