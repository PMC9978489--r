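#' Path to a packaged example dataset
#'
#' Two literature-curated example networks ship with the package:
#' `"fig7_ezh2_ptma"` (the six-axis sponge network around EZH2 and
#' PTMA) and `"fig6_tp53_ccnd1_ctnnb1"` (the hub-gene networks around
#' TP53, CCND1 and CTNNB1). Each directory holds `expression.tsv`,
#' `mir_targets.tsv` and `lnc_mir.tsv`.
#'
#' @param name Example name, or `""` for the extdata root.
#' @return Filesystem path.
#' @export
example_path <- function(name = "") {
  p <- system.file("extdata", name, package = "ceRNAxis")
  if (!nzchar(p)) cx_abort(sprintf("no packaged example named '%s'", name))
  p
}

#' Load a packaged example dataset
#'
#' @param name See [example_path()].
#' @return A list: `evidence`, `mir_catalog`, `lnc_catalog`, and the
#'   consensus `calls` derived from the evidence.
#' @export
load_example <- function(name) {
  dir <- example_path(name)
  evidence <- read_expression_table(file.path(dir, "expression.tsv"))
  list(
    evidence = evidence,
    mir_catalog = read_mir_target_table(file.path(dir, "mir_targets.tsv")),
    lnc_catalog = read_lnc_mir_table(file.path(dir, "lnc_mir.tsv")),
    calls = consensus_table(evidence)
  )
}
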