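#' Generate a synthetic exchange-coupling dataset
#'
#' Samples the angular exchange model J(r, alpha) = J_F(r) +
#' J_AF0(r) cos^2(alpha) on a grid and optionally perturbs each value with
#' relative Gaussian noise, J -> J * (1 + N(0, sigma)). The noise model is
#' a package invention for testing fit recovery; the underlying curves are
#' noise-free model laws.
#'
#' @param ferro,antiferro0 [exponential_law()] objects.
#' @param r_grid Distances, Angstrom.
#' @param alpha_grid Angles, degrees; default 0 only (radial dataset).
#' @param noise_sigma_rel Relative noise standard deviation, >= 0.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed) and leaves the global RNG state untouched.
#' @return A data.frame with columns `r`, `alpha`, `j`.
#' @examples
#' laws <- exchange_reference_laws()
#' gen_exchange_dataset(laws$ferro, laws$antiferro0,
#'                      r_grid = 3:5, alpha_grid = c(0, 45, 90),
#'                      noise_sigma_rel = 0.01, seed = 1)
#' @export
gen_exchange_dataset <- function(ferro, antiferro0, r_grid,
                                 alpha_grid = 0, noise_sigma_rel = 0,
                                 seed = 1) {
  stopifnot(length(r_grid) >= 1, length(alpha_grid) >= 1,
            noise_sigma_rel >= 0)
  model <- angular_exchange_model(ferro, antiferro0)
  grid <- expand.grid(r = r_grid, alpha = alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  j <- eval_angular(model, grid$r, grid$alpha)
  if (noise_sigma_rel > 0) {
    j <- withr::with_seed(seed, {
      j * (1 + stats::rnorm(length(j), sd = noise_sigma_rel))
    })
  }
  data.frame(r = grid$r, alpha = grid$alpha, j = j)
}

#' Generate a synthetic cutoff convergence series
#'
#' Builds the three component-energy series E(e_cut) = E0 + a exp(-b
#' e_cut) for the two monomers and the complex, optionally adding absolute
#' Gaussian noise (a package invention for robustness tests).
#'
#' @param components A list of three `c(e0, a, b)` triples named `e_a`,
#'   `e_b`, `e_ab` (energies in hartree, b > 0 per a.u. of e_cut).
#' @param e_cut_grid Cutoffs, a.u.
#' @param noise_sigma_abs Absolute noise sd, hartree, >= 0.
#' @param seed Integer seed.
#' @return A [convergence_series()]; its true infinite-cutoff interaction
#'   energy (kcal/mol) is attached as attribute `de_inf_true`.
#' @export
gen_convergence_series <- function(components, e_cut_grid,
                                   noise_sigma_abs = 0, seed = 1) {
  stopifnot(all(c("e_a", "e_b", "e_ab") %in% names(components)),
            noise_sigma_abs >= 0)
  if (length(e_cut_grid) < 2) {
    stop("e_cut_grid must have at least 2 points; a single row cannot ",
         "constrain the extrapolation law")
  }
  evalc <- function(p) {
    if (!(p[3] > 0)) stop("decay rate b must be positive")
    p[1] + p[2] * exp(-p[3] * e_cut_grid)
  }
  ea <- evalc(components$e_a)
  eb <- evalc(components$e_b)
  eab <- evalc(components$e_ab)
  if (noise_sigma_abs > 0) {
    noise <- withr::with_seed(seed, {
      matrix(stats::rnorm(3 * length(e_cut_grid), sd = noise_sigma_abs),
             ncol = 3)
    })
    ea <- ea + noise[, 1]; eb <- eb + noise[, 2]; eab <- eab + noise[, 3]
  }
  s <- suppressWarnings(convergence_series(e_cut_grid, ea, eb, eab))
  attr(s, "de_inf_true") <-
    (components$e_ab[1] - components$e_a[1] - components$e_b[1]) *
    spin_constants()$hartree_to_kcal
  s
}

#' Generate reference D/E curves from a point-dipole model
#'
#' Computes the zero-field-splitting parameters of the colinear dimer on a
#' distance grid with the requested point-spin model; used as the truth
#' curve for lobe-offset fit-recovery tests.
#'
#' @param model A [point_dipole_model()].
#' @param r_grid Oxygen-oxygen separations, Angstrom, positive.
#' @param alpha Lobe angle, degrees.
#' @return A data.frame with columns `r_oo`, `d`, `e` (cm^-1).
#' @examples
#' gen_reference_zfs_curves(point_dipole_model("two_point"), r_grid = 6:10)
#' @export
gen_reference_zfs_curves <- function(model, r_grid, alpha = 0) {
  stopifnot(inherits(model, "point_dipole_model"), all(r_grid > 0))
  z <- lapply(r_grid, dimer_zfs, alpha = alpha, model = model)
  data.frame(
    r_oo = r_grid,
    d = vapply(z, function(p) p$d, numeric(1)),
    e = vapply(z, function(p) p$e, numeric(1))
  )
}
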