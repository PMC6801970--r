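#' Broken-symmetry energies for the Yamaguchi estimate
#'
#' Container for the high-spin (HS) and broken-symmetry (BS) single-point
#' energies and their spin-squared expectation values, the four quantities
#' entering the Yamaguchi formula for the Heisenberg exchange coupling.
#'
#' @param e_hs,e_bs High-spin and broken-symmetry energies. Units are given
#'   by `unit`.
#' @param s2_hs,s2_bs Expectation values of S^2 in the HS and BS
#'   determinants (dimensionless). Must differ, otherwise the Yamaguchi
#'   denominator is zero.
#' @param unit `"hartree"` or `"cm-1"`, the unit of the two energies.
#' @return An object of class `bs_energies`.
#' @seealso [yamaguchi_j()]
#' @export
bs_energies <- function(e_hs, e_bs, s2_hs, s2_bs, unit = c("hartree", "cm-1")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(e_hs), is.numeric(e_bs),
            is.numeric(s2_hs), is.numeric(s2_bs))
  if (isTRUE(all.equal(s2_hs, s2_bs, tolerance = 0))) {
    stop("degenerate denominator: s2_hs == s2_bs (", s2_hs, ")")
  }
  structure(list(e_hs = e_hs, e_bs = e_bs, s2_hs = s2_hs, s2_bs = s2_bs,
                 unit = unit),
            class = "bs_energies")
}

#' Exchange coupling from the Yamaguchi broken-symmetry formula
#'
#' Computes the Heisenberg exchange coupling
#' \deqn{J = -\frac{E_{HS} - E_{BS}}{\langle S^2\rangle_{HS} -
#'   \langle S^2\rangle_{BS}}}
#' from high-spin and broken-symmetry energies. Energies supplied in
#' hartree are converted to cm^-1 with the CODATA constant from
#' [spin_constants()].
#'
#' @param b A [bs_energies()] object, or a list with the same fields.
#' @return Exchange coupling J in cm^-1 (positive = ferromagnetic).
#' @examples
#' yamaguchi_j(bs_energies(-300.1, -300.1, 2.005, 1.005))        # 0
#' yamaguchi_j(bs_energies(1, 0, 2, 1, unit = "cm-1"))           # -1
#' @export
yamaguchi_j <- function(b) {
  if (!inherits(b, "bs_energies")) {
    b <- bs_energies(b$e_hs, b$e_bs, b$s2_hs, b$s2_bs,
                     unit = if (is.null(b$unit)) "hartree" else b$unit)
  }
  if (b$s2_hs == b$s2_bs) {
    stop("degenerate denominator: s2_hs == s2_bs")
  }
  num <- b$e_hs - b$e_bs
  if (b$unit == "hartree") num <- num * .const("hartree_to_cm1")
  -num / (b$s2_hs - b$s2_bs)
}

#' Single-exponential magneto-structural law
#'
#' The radial exchange law J(r) = j0 * exp(-a * r), the functional form
#' that fits both the ferromagnetic (orthogonal-lobe) and the
#' antiferromagnetic (parallel-lobe) branches of the colinear nitroxide
#' dimer. Optional asymptotic standard errors follow the reporting style
#' "value +/- abs (pct%)".
#'
#' @param j0 Prefactor, cm^-1. May be negative (antiferromagnetic branch).
#' @param a Decay constant, 1/Angstrom; must be positive.
#' @param j0_err,a_err Optional asymptotic standard errors.
#' @return An object of class `exponential_law`.
#' @examples
#' ferro <- exponential_law(7663.86, 2.812)
#' eval_exponential(ferro, 3)
#' @export
exponential_law <- function(j0, a, j0_err = NA_real_, a_err = NA_real_) {
  stopifnot(is.numeric(j0), is.numeric(a))
  if (!(a > 0)) stop("decay constant 'a' must be positive, got ", a)
  structure(list(j0 = j0, a = a, j0_err = j0_err, a_err = a_err),
            class = "exponential_law")
}

#' @export
print.exponential_law <- function(x, ...) {
  fmt <- function(v, e) {
    if (is.na(e)) sprintf("%.6g", v)
    else sprintf("%.6g +/- %.4g (%.3g%%)", v, e, 100 * abs(e / v))
  }
  cat("Exponential exchange law J(r) = j0 * exp(-a * r)\n")
  cat("  j0 [cm^-1]    :", fmt(x$j0, x$j0_err), "\n")
  cat("  a  [1/Angstrom]:", fmt(x$a, x$a_err), "\n")
  invisible(x)
}

#' Evaluate an exponential exchange law
#'
#' @param law An [exponential_law()].
#' @param r Oxygen-oxygen distance(s), Angstrom; must be positive.
#' @return J(r) in cm^-1, vectorized over `r`.
#' @export
eval_exponential <- function(law, r) {
  stopifnot(inherits(law, "exponential_law"))
  if (any(r <= 0)) stop("'r' must be positive")
  law$j0 * exp(-law$a * r)
}

#' Angular exchange model J(r, alpha)
#'
#' Combines a ferromagnetic radial law J_F(r) and the maximal-overlap
#' antiferromagnetic law J_AF0(r) into the full magneto-structural model
#' \deqn{J(r, \alpha) = J_F(r) + J_{AF}^0(r)\,\cos^2\alpha,}
#' where alpha is the angle between the p-type lobes of the two monomers
#' (90 degrees = orthogonal lobes, purely ferromagnetic; 0 = maximal
#' pi-pi overlap).
#'
#' @param ferro [exponential_law()] for J_F(r); prefactor must be >= 0.
#' @param antiferro0 [exponential_law()] for J_AF0(r); prefactor must
#'   be <= 0.
#' @return An object of class `angular_exchange_model`.
#' @examples
#' m <- angular_exchange_model(exponential_law(7663.86, 2.812),
#'                             exponential_law(-193496, 3.080))
#' eval_angular(m, r = 4, alpha = 90)  # pure ferromagnetic margin
#' @export
angular_exchange_model <- function(ferro, antiferro0) {
  stopifnot(inherits(ferro, "exponential_law"),
            inherits(antiferro0, "exponential_law"))
  if (ferro$j0 < 0) stop("ferromagnetic prefactor must be >= 0")
  if (antiferro0$j0 > 0) stop("antiferromagnetic prefactor must be <= 0")
  structure(list(ferro = ferro, antiferro0 = antiferro0),
            class = "angular_exchange_model")
}

#' Evaluate the angular exchange model
#'
#' @param model An [angular_exchange_model()].
#' @param r Distance(s), Angstrom, positive.
#' @param alpha Lobe angle(s), degrees, in `[0, 90]`.
#' @return J in cm^-1, vectorized over `r` and `alpha` (recycled).
#' @export
eval_angular <- function(model, r, alpha) {
  stopifnot(inherits(model, "angular_exchange_model"))
  if (any(r <= 0)) stop("'r' must be positive")
  if (any(alpha < 0 | alpha > 90)) stop("'alpha' must lie in [0, 90] degrees")
  eval_exponential(model$ferro, r) +
    eval_exponential(model$antiferro0, r) * cos(alpha * pi / 180)^2
}

#' Fit a single-exponential law to (r, J) data
#'
#' Nonlinear least squares of J(r) = j0 * exp(-a * r). All J values must
#' carry the same sign (a single exponential cannot change sign). The fit
#' is initialized from the ordinary least-squares line through
#' log|J| versus r and refined with Levenberg-Marquardt; with exactly two
#' points the closed-form interpolating law is returned.
#'
#' @param r Distances, Angstrom.
#' @param j Exchange couplings, cm^-1; same sign throughout (zeros allowed
#'   only alongside at least two nonzero points and are dropped from the
#'   log-linear initialization).
#' @param weights Optional least-squares weights, one per point. For data
#'   whose noise is relative (a constant fraction of each J), pass
#'   `1 / j^2` so that the reported standard errors are calibrated; the
#'   default unweighted fit is appropriate for absolute noise.
#' @return An [exponential_law()] with asymptotic standard errors filled in
#'   (NA for the two-point exact mode).
#' @examples
#' r <- c(3, 3.25, 3.5, 4, 5)
#' j <- 7663.86 * exp(-2.812 * r)
#' fit_exponential(r, j)
#' @export
fit_exponential <- function(r, j, weights = NULL) {
  stopifnot(length(r) == length(j), is.numeric(r), is.numeric(j))
  keep <- j != 0
  if (sum(keep) < 2) stop("need at least 2 nonzero points")
  sgn <- sign(j[keep])
  if (length(unique(sgn)) > 1) {
    stop("sign-mixed J values: a single exponential cannot change sign")
  }
  s <- sgn[1]
  if (length(r) == 2) {
    # exact interpolating law
    a <- log(j[1] / j[2]) / (r[2] - r[1])
    j0 <- j[1] / exp(-a * r[1])
    return(exponential_law(j0, a))
  }
  if (length(r) < 3) stop("need at least 3 points (or exactly 2 for the exact mode)")
  # log-linear initialization on the nonzero points
  init <- stats::lm(log(abs(j[keep])) ~ r[keep])
  a0 <- -unname(stats::coef(init)[2])
  j00 <- s * exp(unname(stats::coef(init)[1]))
  if (!(a0 > 0)) a0 <- 1e-3
  dat <- data.frame(r = r, j = j,
                    w = if (is.null(weights)) rep(1, length(r)) else weights)
  fit <- minpack.lm::nlsLM(
    j ~ j0 * exp(-a * r), data = dat,
    start = list(j0 = j00, a = a0), weights = dat$w,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$convInfo$isConv) {
    stop("exponential fit did not converge; final residuals: ",
         paste(signif(stats::residuals(fit), 4), collapse = ", "))
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  exponential_law(est[["j0"]], est[["a"]],
                  j0_err = unname(se[1]), a_err = unname(se[2]))
}

#' Extract the antiferromagnetic law by subtracting the ferromagnetic part
#'
#' Implements the decomposition of the parallel-lobe (maximal overlap)
#' exchange curve: the ferromagnetic component J_F(r_i) is subtracted from
#' each datum and the residual antiferromagnetic part is itself fitted
#' with a single exponential, yielding J_AF0(r).
#'
#' @param r,j Parallel-lobe (alpha = 0) exchange data, as in
#'   [fit_exponential()].
#' @param ferro An [exponential_law()] for the ferromagnetic component.
#' @param weights Optional least-squares weights, passed to
#'   [fit_exponential()].
#' @return The antiferromagnetic [exponential_law()] (negative prefactor).
#' @export
decompose_antiferro <- function(r, j, ferro, weights = NULL) {
  stopifnot(inherits(ferro, "exponential_law"))
  resid <- j - eval_exponential(ferro, r)
  if (all(resid == 0)) {
    stop("null antiferromagnetic component: all residuals are zero after ",
         "subtracting the ferromagnetic law")
  }
  fit_exponential(r, resid, weights = weights)
}

#' Angular curve from the two margin values
#'
#' Given the exchange couplings measured at the alpha = 0 (parallel lobes)
#' and alpha = 90 degrees (orthogonal lobes) margins at one distance,
#' returns the interpolating angular curve
#' J(alpha) = J(90) + (J(0) - J(90)) * cos^2(alpha), i.e. the margins are
#' identified with J_F and J_F + J_AF0 without any new fit. No sign
#' policing is applied: slightly negative alpha = 90 margins (as occur for
#' solvent-bridged pairs) are accepted as the ferromagnetic component.
#'
#' @param j_at_alpha0 J at alpha = 0, cm^-1.
#' @param j_at_alpha90 J at alpha = 90 degrees, cm^-1.
#' @return A function of alpha (degrees) returning J in cm^-1.
#' @examples
#' curve <- margins_to_model(-5, 2)
#' curve(45)  # -1.5
#' @export
margins_to_model <- function(j_at_alpha0, j_at_alpha90) {
  force(j_at_alpha0); force(j_at_alpha90)
  function(alpha) {
    j_at_alpha90 + (j_at_alpha0 - j_at_alpha90) * cos(alpha * pi / 180)^2
  }
}

#' Format an estimate in "value +/- abs (pct%)" style
#'
#' @param value Estimate.
#' @param err Absolute standard error.
#' @return A character string.
#' @export
format_estimate <- function(value, err) {
  if (is.na(err)) return(sprintf("%.6g", value))
  sprintf("%.6g ± %.4g (%.4g%%)", value, err, 100 * abs(err / value))
}
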