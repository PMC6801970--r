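#' Names of the packaged reference tables
#'
#' The package carries, as read-only CSV fixtures, the published reference
#' tables the analysis layer reproduces arithmetically: the counterpoise
#' complexation-energy table for TEMPO@CB[6] and TEMPO@beta-CD
#' (`table1`), the plane-wave cutoff convergence series of both complexes
#' including their infinite-cutoff rows (`table2`, `table3`), the fitted
#' exponential exchange-law parameters (`exchange_params`), the reported
#' point-dipole D values at selected separations (`zfs_printed`), the
#' fitted pi-lobe offsets and spin populations (`lobe_params`), and the
#' dispersion-shift bookkeeping constants (`dispersion_shifts`).
#'
#' @return Character vector of fixture names accepted by
#'   [spinpair_fixture()].
#' @export
spinpair_fixtures <- function() {
  names(.fixture_files)
}

.fixture_files <- c(
  table1            = "table1_counterpoise.csv",
  table2            = "table2_cb6_pw.csv",
  table3            = "table3_bcd_pw.csv",
  exchange_params   = "exchange_params.csv",
  zfs_printed       = "zfs_printed.csv",
  lobe_params       = "lobe_params.csv",
  dispersion_shifts = "dispersion_shifts.csv"
)

#' Load a packaged reference table
#'
#' @param name One of [spinpair_fixtures()].
#' @return A data.frame with attributes `fixture_file` (the source CSV
#'   path) and `md5` (checksum of the packaged file).
#' @examples
#' head(spinpair_fixture("table2"))
#' @export
spinpair_fixture <- function(name) {
  name <- match.arg(name, spinpair_fixtures())
  path <- system.file("extdata", .fixture_files[[name]],
                      package = "spinpair", mustWork = TRUE)
  df <- read_numeric_csv(path)
  attr(df, "fixture_file") <- path
  attr(df, "md5") <- unname(tools::md5sum(path))
  df
}

#' Convergence series from a packaged or user table
#'
#' Converts a cutoff-energy table (columns `e_cut_au`, `e_a_hartree`,
#' `e_b_hartree`, `e_ab_hartree`) into a [convergence_series()], keeping
#' only the finite-cutoff rows; the infinite-cutoff row, when present, is
#' returned in the `inf_row` attribute.
#'
#' @param table A data.frame as returned by `spinpair_fixture("table2")`,
#'   or a path to a CSV file with those columns.
#' @return A [convergence_series()] with attribute `inf_row`.
#' @export
as_convergence_series <- function(table) {
  if (is.character(table)) table <- read_numeric_csv(table)
  need <- c("e_cut_au", "e_a_hartree", "e_b_hartree", "e_ab_hartree")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  fin <- is.finite(table$e_cut_au)
  s <- convergence_series(table$e_cut_au[fin], table$e_a_hartree[fin],
                          table$e_b_hartree[fin], table$e_ab_hartree[fin])
  attr(s, "inf_row") <- if (any(!fin)) table[!fin, , drop = FALSE] else NULL
  s
}

#' Published exchange laws as model objects
#'
#' @return A list with [exponential_law()] objects `ferro`, `config2` and
#'   `antiferro0`, plus the [angular_exchange_model()] `angular` built
#'   from the ferro and antiferro0 laws.
#' @examples
#' laws <- exchange_reference_laws()
#' eval_angular(laws$angular, r = 4, alpha = 45)
#' @export
exchange_reference_laws <- function() {
  p <- spinpair_fixture("exchange_params")
  row <- function(nm) p[p$law == nm, , drop = FALSE]
  law <- function(nm) {
    r <- row(nm)
    exponential_law(r$j0_cm1, r$a_inv_angstrom,
                    j0_err = r$j0_err_cm1, a_err = r$a_err_inv_angstrom)
  }
  ferro <- law("ferro")
  antiferro0 <- law("antiferro0")
  list(ferro = ferro, config2 = law("config2"), antiferro0 = antiferro0,
       angular = angular_exchange_model(ferro, antiferro0))
}
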