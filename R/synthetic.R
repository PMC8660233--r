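## Analytic stand-ins for solver outputs: background wall-FSS profiles with
## a prescribed linear gradient, and cell-surface FSS fields with a
## prescribed polarization amplitude.  These make every analytics stage
## testable without running a PDE solve; their oracle is direct quadrature
## of the closed-form field, never the Stokes solver.

#' Specification of a synthetic FSS field
#'
#' The synthetic surface model factorizes elevation and azimuth:
#' `FSS(node) = tau0 * s(theta_e) * (1 + eps * cos(phi)) + noise`, with
#' `s(theta) = sin(theta)^shape_exponent` a monotone elevation shape that
#' vanishes towards the contact line (mimicking the apex-high, base-low
#' pattern of the solved fields).  Background profiles are
#' `tau_w(x) = tau0 + g * x + noise`.
#'
#' @param tau0 Base FSS (Pa), > 0.
#' @param g Transverse gradient (Pa/m) for background profiles.
#' @param eps Polarization amplitude in [0, 1).
#' @param shape_exponent Elevation-shape exponent (default 1: `sin`).
#' @param sigma Gaussian noise SD (Pa), >= 0.
#' @param seed RNG seed; required whenever `sigma > 0`.
#' @return A `synth_field_spec`.
#' @export
synth_field_spec <- function(tau0 = 0.4, g = 0, eps = 0, shape_exponent = 1,
                             sigma = 0, seed = NULL) {
  if (tau0 <= 0 || eps < 0 || eps >= 1 || sigma < 0)
    stop_gradfss("need tau0 > 0, 0 <= eps < 1, sigma >= 0",
                 "gradfss_spec_error")
  if (sigma > 0 && is.null(seed))
    stop_gradfss("a seed is required when sigma > 0", "gradfss_spec_error")
  structure(list(tau0 = tau0, g = g, eps = eps,
                 shape_exponent = shape_exponent, sigma = sigma,
                 seed = seed),
            class = "synth_field_spec")
}

#' Synthetic background wall-FSS profile
#'
#' `tau_w(x) = tau0 + g x (+ noise)`, the analytic stand-in for a solved
#' floor-shear profile; feed it to [fit_fss_gradient()].
#'
#' @param spec A [synth_field_spec()].
#' @param x_samples Width positions (m).
#' @return `data.frame(x, tau)` with `x` in metres and `tau` in Pa.
#' @export
synth_background_profile <- function(spec, x_samples) {
  stopifnot(inherits(spec, "synth_field_spec"))
  tau <- spec$tau0 + spec$g * x_samples
  if (any(tau <= 0))
    stop_gradfss("profile would be non-positive inside the sample range",
                 "gradfss_spec_error")
  if (spec$sigma > 0)
    tau <- tau + with_seed(spec$seed,
                           rnorm(length(x_samples), 0, spec$sigma))
  data.frame(x = x_samples, tau = tau)
}

#' Synthetic cell-surface FSS field with prescribed polarization
#'
#' Generates a `surface_fss_field` on an existing mesh from the closed-form
#' model of [synth_field_spec()].  The azimuthal modulation `eps * cos(phi)`
#' is measured from the +x (gradient) direction, so the prescribed
#' polarization drives SHFSS above SLFSS by a known, quadrature-computable
#' amount.  Interchangeable with solver outputs downstream.
#'
#' @param mesh A [mesh_cell_surface()] mesh.
#' @param spec A [synth_field_spec()].
#' @param cutoff_deg Contact-line exclusion elevation (default 2 degrees),
#'   as for solved fields.
#' @return A `surface_fss_field`.
#' @export
synth_surface_field <- function(mesh, spec, cutoff_deg = 2) {
  stopifnot(inherits(mesh, "cell_surface_mesh"),
            inherits(spec, "synth_field_spec"))
  th <- deg2rad(mesh$theta_e_deg)
  ph <- deg2rad(mesh$phi_deg)
  fss <- spec$tau0 * pmax(sin(th), 0)^spec$shape_exponent *
    (1 + spec$eps * cos(ph))
  if (spec$sigma > 0)
    fss <- pmax(fss + with_seed(spec$seed,
                                rnorm(length(fss), 0, spec$sigma)), 0)
  ## traction along the local azimuthal-flow tangent, magnitude = fss
  tdir <- cbind(-sin(th) * cos(ph) * 0, rep(1, length(th)), 0)  # +y nominal
  tdir <- tdir - mesh$normals * rowSums(tdir * mesh$normals)
  nrm <- sqrt(rowSums(tdir^2))
  nrm[nrm == 0] <- 1
  traction <- tdir / nrm * fss
  structure(list(mesh = mesh, traction = traction, fss = fss,
                 valid = mesh$theta_e_deg >= cutoff_deg,
                 probe_dist = 0, cutoff_deg = cutoff_deg,
                 synthetic = TRUE, spec = spec),
            class = "surface_fss_field")
}
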