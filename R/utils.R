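#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Controlled vocabularies used across the catalog types.
MOLECULE_CLASSES <- c("lncRNA", "miRNA", "mRNA", "protein")
CONFIDENCE_LEVELS <- c("observed", "predicted")
EVIDENCE_TIERS <- c("strong", "less_strong")
STRONG_EVIDENCE_METHODS <- c("reporter_assay", "western_blot", "qpcr")

cx_abort <- function(msg, class = "cernaxis_validation_error", ...) {
  abort(msg, class = c(class, "cernaxis_error"), ...)
}

cx_assert <- function(cond, msg, class = "cernaxis_contract_error") {
  if (!isTRUE(cond)) cx_abort(msg, class = class)
  invisible(TRUE)
}

match_class <- function(molecule_class) {
  match.arg(molecule_class, MOLECULE_CLASSES)
}

#' Parse heterogeneous direction tokens
#'
#' Accepts `up`/`down` in any case and signed numerics (`+1`, `-1`, `2`,
#' `-0.5`), mapping numerics by sign. Anything else (including `0` and
#' `unchanged`) is rejected: only molecules with a definite direction
#' enter the pipeline.
#'
#' @param x Character vector of raw direction tokens.
#' @return Character vector with values `"up"` or `"down"`.
#' @export
parse_direction <- function(x) {
  x <- stringr::str_trim(as.character(x))
  out <- rep(NA_character_, length(x))
  lower <- tolower(x)
  out[lower == "up"] <- "up"
  out[lower == "down"] <- "down"
  num <- suppressWarnings(as.numeric(x))
  out[is.na(out) & !is.na(num) & num > 0] <- "up"
  out[is.na(out) & !is.na(num) & num < 0] <- "down"
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    cx_abort(sprintf(
      "unknown direction token(s): %s (rows %s); expected up/down or signed numeric",
      paste(unique(x[bad]), collapse = ", "),
      paste(bad, collapse = ", ")
    ))
  }
  out
}

# Split a semicolon-joined evidence string into a canonical sorted set.
split_methods <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    sort(unique(tolower(stringr::str_trim(strsplit(s, ";", fixed = TRUE)[[1]]))))
  })
}

join_methods <- function(sets) {
  vapply(sets, function(s) paste(sort(unique(s)), collapse = ";"), character(1))
}

# Union of two semicolon-joined method strings, canonicalized.
union_methods <- function(a, b) {
  join_methods(Map(function(x, y) union(x, y), split_methods(a), split_methods(b)))
}
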