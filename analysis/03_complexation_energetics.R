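#!/usr/bin/env Rscript
# Host-guest complexation energetics of TEMPO@CB[6] and TEMPO@beta-CD.
#
# Verifies the counterpoise table arithmetic (BSSE increments, dispersion
# shift bookkeeping), reproduces every interaction-energy cell of the
# plane-wave cutoff tables from their component energies, and extrapolates
# the cutoff series to the infinite-basis limit with component-wise
# exponential fits.

suppressPackageStartupMessages(library(spinpair))
dir.create("results", showWarnings = FALSE)

# --- counterpoise bookkeeping (GTO table) ----------------------------------
t1 <- spinpair_fixture("table1")
shifts <- spinpair_fixture("dispersion_shifts")
shift_of <- function(sys, lab) shifts$shift_kcal[shifts$system == sys &
                                                   shifts$label == lab]

t1$bsse_cb6 <- t1$de_corr_cb6_kcal - t1$de_cb6_kcal
t1$bsse_bcd <- t1$de_corr_bcd_kcal - t1$de_bcd_kcal
t1$de_corr_cb6_no_d2 <- as.numeric(apply_dispersion_shift(
  t1$de_corr_cb6_kcal, shift_of("cb6", "remove_d2_gto")))
t1$de_corr_bcd_no_d2 <- as.numeric(apply_dispersion_shift(
  t1$de_corr_bcd_kcal, shift_of("bcd", "remove_d2_gto")))
utils::write.csv(t1, "results/counterpoise_bookkeeping.csv",
                 row.names = FALSE)

cat("BSSE increments, TEMPO@CB[6]: ",
    sprintf("%.2f-%.2f kcal/mol\n", min(t1$bsse_cb6), max(t1$bsse_cb6)))
cat("Corrected complexation energy ranges (kcal/mol):\n")
cat(sprintf("  TEMPO@CB[6]:   %.2f to %.2f (unbound)\n",
            min(t1$de_corr_cb6_kcal), max(t1$de_corr_cb6_kcal)))
cat(sprintf("  TEMPO@beta-CD: %.2f to %.2f (bound)\n",
            min(t1$de_corr_bcd_kcal), max(t1$de_corr_bcd_kcal)))
cat(sprintf("  beta-CD without D2: %.2f to %.2f (slightly unbound)\n\n",
            min(t1$de_corr_bcd_no_d2), max(t1$de_corr_bcd_no_d2)))

# --- plane-wave cutoff tables ----------------------------------------------
summary_rows <- list()
for (spec in list(list(name = "table2", system = "TEMPO@CB[6]"),
                  list(name = "table3", system = "TEMPO@beta-CD"))) {
  tab <- spinpair_fixture(spec$name)
  de <- vapply(seq_len(nrow(tab)), function(i)
    interaction_energy(counterpoise_record(tab$e_a_hartree[i],
                                           tab$e_b_hartree[i],
                                           tab$e_ab_hartree[i])),
    numeric(1))
  stopifnot(all(abs(de - tab$de_kcal) <= 1e-3))
  cat(spec$system, ": all", nrow(tab),
      "printed interaction energies reproduced to 0.001 kcal/mol\n")

  series <- as_convergence_series(tab)
  inf_row <- attr(series, "inf_row")
  de_inf_arith <- interaction_energy(counterpoise_record(
    inf_row$e_a_hartree, inf_row$e_b_hartree, inf_row$e_ab_hartree))
  fit <- fit_cutoff_extrapolation(series, mode = "per_component")
  cat(sprintf("  infinite-cutoff row (arithmetic): %.3f kcal/mol\n",
              de_inf_arith))
  cat(sprintf("  component-wise extrapolation fit: %.3f kcal/mol\n",
              fit$de_inf))
  summary_rows[[spec$name]] <- data.frame(
    system = spec$system, de_inf_row_kcal = de_inf_arith,
    de_inf_fit_kcal = fit$de_inf,
    b_e_ab_per_au = fit$components$e_ab$b)
}
# The beta-CD series has non-geometric early increments; its fit is
# reported for completeness but the printed row is the reference there.
utils::write.csv(do.call(rbind, summary_rows),
                 "results/extrapolation_summary.csv", row.names = FALSE)
cat("\nSummary written to results/extrapolation_summary.csv\n")
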