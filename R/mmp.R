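#' MMP secretion at cell-fibre contacts
#'
#' Every fibre pixel with at least one cell pixel among its 8 neighbours
#' (Moore neighbourhood) gains `lambda * dt` MMP units, once per 1-s
#' substep, regardless of how many cell pixels touch it; all other pixels
#' are unchanged. This is the ECM-density-dependent secretion rule: denser
#' meshes expose more cell-fibre contact and so receive more MMP.
#'
#' @param field numeric matrix, the MMP field.
#' @param lattice a `sim_lattice` (or bare sigma matrix).
#' @param lambda secretion rate (1/s).
#' @param dt substep length (s).
#' @return The updated field matrix.
#' @examples
#' fx <- make_fixture("secretion_unit")
#' sum(secrete(fx$field, fx$lattice, lambda = 0.05))
#' @export
secrete <- function(field, lattice, lambda, dt = 1) {
  sigma <- if (inherits(lattice, "sim_lattice")) lattice$sigma else lattice
  stopifnot(lambda >= 0, all(dim(field) == dim(sigma)))
  cpp_secrete(field, sigma, lambda, dt)
}

#' Forward-Euler diffusion/decay substep of the MMP field
#'
#' Applies `n` explicit substeps of `dv/dt = D lap(v) - delta_mmp v` with
#' the 5-point Laplacian, pixel spacing `dx` and zero-flux boundaries.
#' Negative values (which cannot arise inside the stability bound) are
#' clamped at zero; values exceeding 1e6 abort with a diagnostics error.
#'
#' @param field numeric matrix.
#' @param mpar [mmp_params()] supplying `D`, `delta_mmp`, `dt`, `dx`.
#' @param n number of substeps to apply.
#' @return The updated field matrix.
#' @examples
#' f <- matrix(0, 11, 11); f[6, 6] <- 10
#' sum(diffuse_decay_step(f, mmp_params(delta_mmp = 0), n = 100))  # mass kept
#' @export
diffuse_decay_step <- function(field, mpar = mmp_params(), n = 1) {
  stopifnot(inherits(mpar, "cpm_mmp_params"), n >= 0)
  if (n == 0) return(field)
  r <- mpar$D * mpar$dt / mpar$dx^2
  cpp_diffuse_decay(field, r, mpar$delta_mmp * mpar$dt, as.integer(n))
}

#' Threshold-based ECM degradation
#'
#' Applied once per MCS after the diffusion substeps: every fibre pixel
#' whose MMP count is >= 1 becomes a fluid pixel and its MMP count is
#' reduced by 1. Non-fibre pixels are never altered.
#'
#' @param field numeric matrix.
#' @param lattice a `sim_lattice`.
#' @return List with the updated `lattice`, `field`, and `events` (a
#'   data.frame of 1-based degraded pixel coordinates `i`, `j`).
#' @examples
#' fx <- make_fixture("secretion_unit")
#' f <- fx$field; f[fx$fibre_pixel] <- 1.2
#' degrade_ecm(f, fx$lattice)$events
#' @export
degrade_ecm <- function(field, lattice) {
  stopifnot(inherits(lattice, "sim_lattice"),
            all(dim(field) == dim(lattice$sigma)))
  out <- cpp_degrade_ecm(lattice$sigma, field)
  list(lattice = sim_lattice(out$sigma, dx = lattice$dx,
                             removed_fibre_px = lattice$removed_fibre_px),
       field = out$field,
       events = as.data.frame(out$events))
}
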