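#' Component energies for one complexation record
#'
#' Holds the monomer energies E_A, E_B and the complex energy E_AB (one
#' shared unit), plus the optional monomer-in-dimer-basis energies E_A*,
#' E_B* needed for the counterpoise correction and an optional dispersion
#' shift used for bookkeeping of Grimme-type increments.
#'
#' @param e_a,e_b,e_ab Core energies, in `unit`.
#' @param e_a_star,e_b_star Optional monomer energies recomputed in the
#'   full dimer basis, same unit.
#' @param unit `"hartree"` or `"kcal/mol"`.
#' @param dispersion_shift Optional shift in kcal/mol (e.g. the amount
#'   added to remove a Grimme D2 contribution).
#' @return An object of class `counterpoise_record`.
#' @export
counterpoise_record <- function(e_a, e_b, e_ab,
                                e_a_star = NA_real_, e_b_star = NA_real_,
                                unit = c("hartree", "kcal/mol"),
                                dispersion_shift = NA_real_) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(e_a), is.numeric(e_b), is.numeric(e_ab))
  structure(list(e_a = e_a, e_b = e_b, e_ab = e_ab,
                 e_a_star = e_a_star, e_b_star = e_b_star,
                 unit = unit, dispersion_shift = dispersion_shift),
            class = "counterpoise_record")
}

.to_kcal <- function(x, unit) {
  if (unit == "hartree") x * .const("hartree_to_kcal") else x
}

#' Brute interaction energy
#'
#' Delta E = E_AB - E_A - E_B, reported in kcal/mol (hartree inputs are
#' converted with 627.5095 kcal/mol per hartree).
#'
#' @param rec A [counterpoise_record()].
#' @return Delta E in kcal/mol.
#' @examples
#' interaction_energy(counterpoise_record(
#'   e_a = -89.752721, e_b = -666.521144, e_ab = -756.272743))  # 0.704
#' @export
interaction_energy <- function(rec) {
  stopifnot(inherits(rec, "counterpoise_record"))
  .to_kcal(rec$e_ab - rec$e_a - rec$e_b, rec$unit)
}

#' Counterpoise-corrected interaction energy
#'
#' Delta E_corr = E_AB - E_A* - E_B*, with the monomers evaluated in the
#' full dimer basis, plus the implied BSSE increment
#' Delta E_corr - Delta E.
#'
#' @param rec A [counterpoise_record()] with starred energies present.
#' @return A list with `de_corr`, `de` and `bsse_increment`, all kcal/mol.
#' @export
counterpoise_corrected <- function(rec) {
  stopifnot(inherits(rec, "counterpoise_record"))
  if (is.na(rec$e_a_star) || is.na(rec$e_b_star)) {
    stop("monomer-in-dimer-basis energies (e_a_star, e_b_star) are required")
  }
  de <- interaction_energy(rec)
  de_corr <- .to_kcal(rec$e_ab - rec$e_a_star - rec$e_b_star, rec$unit)
  list(de_corr = de_corr, de = de, bsse_increment = de_corr - de)
}

#' Apply a dispersion (Grimme-increment) shift
#'
#' Element-wise addition of a constant shift to a vector of interaction
#' energies, used to move between dispersion treatments (e.g. removing a
#' D2 contribution, or switching to the D3 bookkeeping). The shift is
#' recorded as an attribute for provenance.
#'
#' @param values Numeric vector, kcal/mol.
#' @param shift Scalar shift, kcal/mol.
#' @param label Optional provenance label for the shift.
#' @return Shifted vector with attributes `shift` and `shift_label`.
#' @examples
#' apply_dispersion_shift(c(3.91, 24.55), 64.51, "remove Grimme D2, CB[6]")
#' @export
apply_dispersion_shift <- function(values, shift, label = NULL) {
  stopifnot(is.numeric(values), is.numeric(shift), length(shift) == 1)
  out <- values + shift
  attr(out, "shift") <- shift
  attr(out, "shift_label") <- label
  out
}

#' Plane-wave cutoff convergence series
#'
#' Table of total energies of the two monomers and the complex as a
#' function of the plane-wave kinetic-energy cutoff e_cut. Energies behave
#' variationally: each column decreases monotonically as the cutoff grows.
#'
#' @param e_cut Cutoffs, hartree (a.u.), strictly increasing.
#' @param e_a,e_b,e_ab Total energies, hartree.
#' @param labels Optional system labels, e.g. `c(a = "TEMPO", b = "CB[6]")`.
#' @return A data.frame of class `convergence_series`.
#' @export
convergence_series <- function(e_cut, e_a, e_b, e_ab, labels = NULL) {
  n <- length(e_cut)
  stopifnot(length(e_a) == n, length(e_b) == n, length(e_ab) == n)
  if (n > 1 && any(diff(e_cut) <= 0)) {
    stop("e_cut must be strictly increasing")
  }
  for (col in list(e_a = e_a, e_b = e_b, e_ab = e_ab)) {
    if (n > 1 && any(diff(col) > 1e-12)) {
      warning("non-monotone energy column: series is expected to decrease ",
              "with e_cut (variational behaviour)")
      break
    }
  }
  structure(data.frame(e_cut = e_cut, e_a = e_a, e_b = e_b, e_ab = e_ab),
            labels = labels,
            class = c("convergence_series", "data.frame"))
}

# Deterministic starting values for E0 + a exp(-b e_cut) from the geometric
# structure of the increments; exact when the data are exactly exponential
# and the grid equally spaced.
.exp_start <- function(x, y) {
  n <- length(y)
  d <- diff(y)
  # use the last three points for the local geometric ratio
  r <- d[n - 1] / d[n - 2]
  h <- x[n] - x[n - 1]
  if (!is.finite(r) || r <= 0 || r >= 1) {
    b0 <- 1 / (max(x) - min(x))
  } else {
    b0 <- -log(r) / h
  }
  a0 <- d[n - 1] / (exp(-b0 * x[n]) - exp(-b0 * x[n - 1]))
  q <- exp(-b0 * h)
  e0 <- y[n] + d[n - 1] * q / (1 - q)    # project the geometric tail
  list(e0 = e0, a = a0, b = b0)
}

#' Fit the cutoff-extrapolation law to one energy series
#'
#' Fits E(e_cut) = E0 + a * exp(-b * e_cut) by Levenberg-Marquardt least
#' squares, initialized from the geometric structure of the last energy
#' increments (exact for noise-free exponential data on an equally spaced
#' grid). E0 is the extrapolated energy at infinite cutoff.
#'
#' @param e_cut Cutoffs, a.u., >= 4 points.
#' @param energy Energies, hartree (or any single unit).
#' @return A list of class `extrapolation_result` with `e0`, `a`, `b`,
#'   `rms` (root-mean-square residual) and `fitted`.
#' @examples
#' ec <- c(10, 15, 20, 25, 30)
#' fit_exponential_series(ec, -100 + 5 * exp(-0.2 * ec))$e0  # -100
#' @export
fit_exponential_series <- function(e_cut, energy) {
  stopifnot(length(e_cut) == length(energy))
  if (length(e_cut) < 4) {
    stop("need at least 4 points to fit the 3-parameter extrapolation law")
  }
  st <- .exp_start(e_cut, energy)
  dat <- data.frame(x = e_cut, y = energy)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ e0 + a * exp(-b * x), data = dat,
                      start = list(e0 = st$e0, a = st$a, b = st$b),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("cutoff extrapolation failed to converge: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  if (!(cf[["b"]] > 0)) {
    stop("cutoff extrapolation produced a non-decaying fit (b <= 0)")
  }
  structure(list(e0 = cf[["e0"]], a = cf[["a"]], b = cf[["b"]],
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "extrapolation_result")
}

#' Extrapolate a convergence series to infinite cutoff
#'
#' Either fits each component energy series (E_A, E_B, E_AB) independently
#' and combines the extrapolated values into
#' Delta E_inf = E_AB(inf) - E_A(inf) - E_B(inf) (`per_component`, the
#' default), or fits the interaction-energy series directly
#' (`on_difference`).
#'
#' @param series A [convergence_series()] (finite rows only).
#' @param mode `"per_component"` or `"on_difference"`.
#' @return A list of class `extrapolation_result` with `de_inf` (kcal/mol),
#'   `mode`, and per-component results in `components` (hartree) for the
#'   per_component mode.
#' @examples
#' s <- spinpair_fixture("table2")
#' fit_cutoff_extrapolation(convergence_series(
#'   s$e_cut[is.finite(s$e_cut)], s$e_a[is.finite(s$e_cut)],
#'   s$e_b[is.finite(s$e_cut)], s$e_ab[is.finite(s$e_cut)]))$de_inf
#' @export
fit_cutoff_extrapolation <- function(series,
                                     mode = c("per_component",
                                              "on_difference")) {
  stopifnot(inherits(series, "convergence_series"))
  mode <- match.arg(mode)
  if (mode == "per_component") {
    comps <- list()
    for (nm in c("e_a", "e_b", "e_ab")) {
      comps[[nm]] <- tryCatch(
        fit_exponential_series(series$e_cut, series[[nm]]),
        error = function(e) stop("component '", nm, "': ",
                                 conditionMessage(e)))
    }
    de_inf <- (comps$e_ab$e0 - comps$e_a$e0 - comps$e_b$e0) *
      .const("hartree_to_kcal")
    structure(list(de_inf = de_inf, mode = mode, components = comps),
              class = "extrapolation_result")
  } else {
    de <- (series$e_ab - series$e_a - series$e_b) * .const("hartree_to_kcal")
    f <- fit_exponential_series(series$e_cut, de)
    structure(list(de_inf = f$e0, mode = mode, components = list(de = f)),
              class = "extrapolation_result")
  }
}

#' Infinite-cutoff interaction energy of a series
#'
#' Convenience wrapper: per-component extrapolation of a convergence
#' series, returning the combined interaction energy in kcal/mol with the
#' per-component extrapolated energies and residual diagnostics attached.
#'
#' @param series A [convergence_series()].
#' @return Delta E at infinite cutoff, kcal/mol, with attribute `detail`
#'   carrying the full [fit_cutoff_extrapolation()] result.
#' @export
extrapolated_interaction <- function(series) {
  res <- fit_cutoff_extrapolation(series, mode = "per_component")
  structure(res$de_inf, detail = res)
}
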