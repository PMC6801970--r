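#!/usr/bin/env Rscript
# Magneto-structural exchange laws of the colinear TEMPO dimer.
#
# Reproduces the fitting stage of the exchange analysis: regenerates the
# ferromagnetic (orthogonal-lobe) and antiferromagnetic (parallel-lobe)
# J(r) curves from the published exponential parameters, refits them to
# demonstrate round-trip self-consistency, decomposes the parallel-lobe
# curve into ferro + antiferro parts, and tabulates the angular model
# J(r, alpha) = J_F(r) + J_AF0(r) cos^2(alpha).

suppressPackageStartupMessages(library(spinpair))
dir.create("results", showWarnings = FALSE)

laws <- exchange_reference_laws()
cat("Published exchange laws:\n")
cat("  J_F  :", format_estimate(laws$ferro$j0, laws$ferro$j0_err),
    "cm^-1, a =", format_estimate(laws$ferro$a, laws$ferro$a_err), "1/A\n")
cat("  J_AF0:", format_estimate(laws$antiferro0$j0, laws$antiferro0$j0_err),
    "cm^-1, a =",
    format_estimate(laws$antiferro0$a, laws$antiferro0$a_err), "1/A\n\n")

# --- round-trip refit of noise-free samples -------------------------------
r <- c(3, 3.25, 3.5, 4, 5)
ferro_data <- gen_exchange_dataset(laws$ferro, laws$antiferro0,
                                   r_grid = r, alpha_grid = 90)
ferro_fit <- fit_exponential(ferro_data$r, ferro_data$j)
cat(sprintf("Refit of the ferromagnetic branch: j0 = %.2f cm^-1, a = %.4f 1/A\n",
            ferro_fit$j0, ferro_fit$a))

config2_data <- gen_exchange_dataset(laws$ferro, laws$antiferro0,
                                     r_grid = r, alpha_grid = 0)
config2_fit <- fit_exponential(config2_data$r, config2_data$j)
cat(sprintf("Direct fit of the parallel-lobe branch: j0 = %.0f cm^-1, a = %.4f 1/A\n",
            config2_fit$j0, config2_fit$a))
cat("  (compare the published whole-curve parameters -193935, 3.112)\n")

antiferro_fit <- decompose_antiferro(config2_data$r, config2_data$j,
                                     laws$ferro)
cat(sprintf("Antiferromagnetic part after subtracting J_F: j0 = %.0f cm^-1, a = %.4f 1/A\n\n",
            antiferro_fit$j0, antiferro_fit$a))

fits <- data.frame(
  branch = c("ferro_refit", "config2_direct", "antiferro_decomposed"),
  j0_cm1 = c(ferro_fit$j0, config2_fit$j0, antiferro_fit$j0),
  a_inv_angstrom = c(ferro_fit$a, config2_fit$a, antiferro_fit$a)
)
utils::write.csv(fits, "results/exchange_fits.csv", row.names = FALSE)

# --- angular structure ----------------------------------------------------
grid <- gen_exchange_dataset(laws$ferro, laws$antiferro0,
                             r_grid = seq(3, 5, by = 0.25),
                             alpha_grid = seq(0, 90, by = 15))
utils::write.csv(grid, "results/exchange_angular_grid.csv",
                 row.names = FALSE)
crossings <- vapply(unique(grid$r), function(ri) {
  js <- grid$j[grid$r == ri]
  all(js[grid$alpha[grid$r == ri] == 0] < 0) &&
    all(js[grid$alpha[grid$r == ri] == 90] > 0)
}, logical(1))
cat("Sign structure J(r,0) < 0 < J(r,90) holds at every r in [3,5]:",
    all(crossings), "\n")

# --- margin interpolation for a solvent-bridged case ----------------------
# Example margins: a slightly negative alpha=90 value, as reported for
# bridged radical pairs, is accepted as the ferromagnetic component.
curve <- margins_to_model(j_at_alpha0 = -18.712, j_at_alpha90 = 2.692)
alpha <- seq(0, 90, by = 10)
utils::write.csv(data.frame(alpha_deg = alpha, j_cm1 = curve(alpha)),
                 "results/exchange_margin_curve.csv", row.names = FALSE)
cat("Margin-interpolated bridged-pair curve written",
    "(J(0) = -18.712, J(90) = 2.692 cm^-1 at r = 7 A).\n")
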