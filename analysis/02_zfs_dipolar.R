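#!/usr/bin/env Rscript
# Zero-field splitting of the TEMPO-pair triplet from point-dipole models.
#
# Computes D(r_OO) and E(r_OO) with the two-point model (spins at the NO
# bond midpoints) and the four-point model (spins at the pi-lobe
# barycentres), compares the long-range values against the published
# ab initio D at 8 and 9 Angstrom, and demonstrates recovery of the lobe
# offsets by least squares on a model-generated reference curve.

suppressPackageStartupMessages(library(spinpair))
dir.create("results", showWarnings = FALSE)

r_grid <- c(5, 5.5, 6, 6.5, 7, 8, 9, 10, 12)

two <- gen_reference_zfs_curves(point_dipole_model("two_point"), r_grid)
four0 <- gen_reference_zfs_curves(point_dipole_model("four_point"), r_grid,
                                  alpha = 0)   # parallel lobes
four90 <- gen_reference_zfs_curves(point_dipole_model("four_point"), r_grid,
                                   alpha = 90) # orthogonal lobes

curves <- data.frame(
  r_oo = r_grid,
  d_two_point_formula = point_dipole_D(r_grid),
  d_four_point_parallel = four0$d,
  e_four_point_parallel = four0$e,
  d_four_point_orthogonal = four90$d,
  e_four_point_orthogonal = four90$e
)
utils::write.csv(curves, "results/zfs_curves.csv", row.names = FALSE)

cat("Two-point |D| at long range (cm^-1):\n")
printed <- spinpair_fixture("zfs_printed")
for (r in c(8, 9)) {
  model <- point_dipole_D(r)
  refs <- printed[printed$r_oo_angstrom == r & printed$d_cm1 > 0, ]
  cat(sprintf("  r_OO = %g A: model %.3e vs ab initio %s\n", r, model,
              paste(sprintf("%.2e (%s)", refs$d_cm1, refs$configuration),
                    collapse = ", ")))
}
cat("\nE is zero by symmetry for orthogonal lobes: max|E| =",
    max(abs(four90$e)), "cm^-1\n")

# Long-range 1/r^3 behaviour
r_far <- seq(8, 20, by = 1)
d_far <- abs(gen_reference_zfs_curves(point_dipole_model("four_point"),
                                      r_far)$d)
slope <- unname(stats::coef(stats::lm(log(d_far) ~ log(r_far + 1.28)))[2])
cat(sprintf("log-log slope of |D| vs r_mid over 8-20 A: %.4f (expect -3)\n\n",
            slope))

# --- lobe-offset recovery ---------------------------------------------------
truth <- point_dipole_model("four_point")      # 0.574 / 0.461 A
reference <- gen_reference_zfs_curves(truth, c(5, 5.5, 6, 7, 8, 9),
                                      alpha = 0)
fit <- fit_lobe_offsets(reference,
                        template = point_dipole_model("four_point",
                                                      l_pi_n = 0.3,
                                                      l_pi_o = 0.3),
                        alpha = 0)
cat(sprintf("Lobe offsets recovered from the reference curve: l_piN = %.4f A, l_piO = %.4f A\n",
            fit$l_pi_n, fit$l_pi_o))
cat("  (generating values 0.574 and 0.461 A)\n")

write_result_json(list(
  d_two_point_9A = list(value = point_dipole_D(9), unit = "cm^-1"),
  d_four_point_9A_parallel = list(value = four0$d[r_grid == 9],
                                  unit = "cm^-1"),
  loglog_slope = list(value = slope, unit = "dimensionless"),
  lobe_fit = list(l_pi_n = fit$l_pi_n, l_pi_o = fit$l_pi_o,
                  unit = "Angstrom")
), "results/zfs_summary.json")
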