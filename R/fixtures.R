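#' Load a packaged compound acidity table
#'
#' Three tables of weak NH acids (conjugated nitrogen heterocycles and
#' aromatic amines) are shipped with the package:
#'
#' * `table2` -- acidities in different solvents and the gas phase:
#'   pKa(MeCN), pKa(DMSO), pKa(H2O) where available, experimental and
#'   computational gas-phase acidities, and the structural descriptors
#'   used by the conversion equations (40 compounds).
#' * `table3` -- the conversion benchmark: experimental pKa(MeCN)
#'   together with the published predictions from pKa(DMSO) via the
#'   NH-specific and universal equations and their differences
#'   (15 compounds).
#' * `table4` -- recommended pKa(MeCN) values for five heterocycles
#'   estimated from pKa(DMSO) along three routes (direct correlation,
#'   NH-specific and universal equations), with descriptors and GA
#'   values (5 compounds).
#'
#' Multiple experimental GA values for one compound are kept as a
#' semicolon-separated list in `ga_exp`, never averaged.
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`.
#' @return A data frame; attribute `provenance` describes the table.
#' @examples
#' t2 <- load_fixture("table2")
#' t2$pka_mecn[t2$name == "Indole"]
#' @export
load_fixture <- function(name = c("table2", "table3", "table4")) {
  name <- match.arg(name)
  meta <- switch(name,
    table2 = list(file = "table2_acidities.csv", rows = 40L,
                  provenance = "acidities in MeCN, DMSO, H2O and the gas phase with conversion descriptors"),
    table3 = list(file = "table3_conversion_benchmark.csv", rows = 15L,
                  provenance = "pKa(MeCN) conversion benchmark: experimental values and published predictions from pKa(DMSO)"),
    table4 = list(file = "table4_recommended.csv", rows = 5L,
                  provenance = "recommended pKa(MeCN) values for five heterocycles estimated from pKa(DMSO)"))
  path <- system.file("extdata", meta$file, package = "acidladder",
                      mustWork = TRUE)
  cc <- if ("ga_exp" %in% scan_header(path)) c(ga_exp = "character") else NA
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  if (nrow(d) != meta$rows)
    stop(sprintf("fixture %s corrupted: expected %d rows, found %d",
                 name, meta$rows, nrow(d)), call. = FALSE)
  attr(d, "provenance") <- meta$provenance
  attr(d, "fixture") <- name
  d
}

scan_header <- function(path) {
  strsplit(readLines(path, n = 1L), ",")[[1]]
}
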