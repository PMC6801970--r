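#' Read a numeric CSV table, normalizing typographic minus signs
#'
#' Shared CSV reader: comma separator, dot decimal, mandatory header.
#' Unicode minus (U+2212) and en-dash signs occasionally found in
#' published tables are normalized to the ASCII hyphen-minus before
#' parsing, and `Inf` is accepted in numeric columns.
#'
#' @param path CSV file path.
#' @return A data.frame; columns that parse fully as numbers become
#'   numeric.
#' @export
read_numeric_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  txt <- gsub("−|–", "-", txt)
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num[trimws(v) != ""])) df[[nm]] <- num
    }
  }
  df
}

#' Read an exchange-coupling table
#'
#' Expects columns `r_angstrom`, `j_cm1` and optionally `alpha_deg`.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `r`, `j` and optionally `alpha`.
#' @export
read_exchange_csv <- function(path) {
  df <- read_numeric_csv(path)
  if (!all(c("r_angstrom", "j_cm1") %in% names(df))) {
    stop("exchange CSV must have columns r_angstrom, j_cm1")
  }
  out <- data.frame(r = df$r_angstrom, j = df$j_cm1)
  if ("alpha_deg" %in% names(df)) out$alpha <- df$alpha_deg
  out
}

#' Write a result list as JSON with provenance fields
#'
#' All results carry explicit units inside `result`; the wrapper adds the
#' package version, the constants registry in force, an optional seed and
#' input checksums, so that re-running on the same inputs reproduces the
#' file (timestamps are deliberately not recorded).
#'
#' @param result A named list (values with explicit unit fields).
#' @param path Output path.
#' @param seed Optional integer seed used to produce the result.
#' @param inputs Optional character vector of input file paths; md5
#'   checksums are recorded.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, seed = NULL, inputs = NULL) {
  payload <- list(
    package = "spinpair",
    version = as.character(utils::packageVersion("spinpair")),
    constants = spin_constants(),
    seed = seed,
    input_md5 = if (!is.null(inputs)) {
      as.list(tools::md5sum(inputs))
    },
    result = result
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
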