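#' Inverse-expression pairing filter
#'
#' Retains exactly the candidate miRNA-target edges whose miRNA and
#' target both carry a definite consensus call and whose directions are
#' opposite (miRNA up / target down, or miRNA down / target up) — the
#' expected signature of a repressive miRNA-target relationship. Edges
#' referencing a molecule with no call are dropped silently and
#' counted.
#'
#' @param edges Tibble of candidate miRNA-target edges
#'   (`mirna_id`, `target_symbol`, `confidence`, `cwcs`,
#'   `evidence_methods`).
#' @param mirna_calls,target_calls Consensus tables containing only
#'   definite `up`/`down` calls (see [usable_calls()]).
#' @return The retained edges annotated with `mirna_direction` and
#'   `target_direction`.
#' @export
expression_pair <- function(edges, mirna_calls, target_calls) {
  cx_assert(all(mirna_calls$direction %in% c("up", "down")) &&
              all(target_calls$direction %in% c("up", "down")),
            "consensus calls must be pre-filtered to definite up/down")
  md <- stats::setNames(mirna_calls$direction, mirna_calls$molecule_id)
  td <- stats::setNames(target_calls$direction, target_calls$molecule_id)
  out <- edges
  out$mirna_direction <- unname(md[out$mirna_id])
  out$target_direction <- unname(td[out$target_symbol])
  unmapped <- is.na(out$mirna_direction) | is.na(out$target_direction)
  if (any(unmapped)) {
    inform(sprintf("expression_pair: dropped %d edge(s) with unmapped molecules",
                   sum(unmapped)))
  }
  out <- out[!unmapped & out$mirna_direction != out$target_direction, , drop = FALSE]
  as_tibble(out)
}

#' Interaction-confidence filter
#'
#' Keeps an edge iff it is experimentally observed, or predicted with a
#' TargetScan cumulative weighted context score (CWCS) at or below the
#' cutoff (default -0.4; the boundary is inclusive — more negative
#' means stronger predicted repression).
#'
#' @param edges Tibble of miRNA-target edges.
#' @param cwcs_cutoff Maximum CWCS for predicted edges.
#' @return Filtered copy of `edges`.
#' @export
confidence_filter <- function(edges, cwcs_cutoff = -0.4) {
  bad <- edges$confidence == "predicted" & is.na(edges$cwcs)
  if (any(bad)) {
    cx_abort(sprintf("confidence_filter: %d predicted edge(s) without a CWCS", sum(bad)))
  }
  keep <- edges$confidence == "observed" |
    (edges$confidence == "predicted" & edges$cwcs <= cwcs_cutoff)
  edges[keep, , drop = FALSE]
}

#' Integrate transcript- and protein-derived interaction layers
#'
#' Unions two already paired and confidence-filtered interaction sets —
#' one where target directions came from mRNA consensus calls, one
#' where they came from protein-level calls — into a non-redundant
#' catalog keyed by `(mirna_id, target_symbol)`. Merged edges carry the
#' union of layers and evidence methods, and are `observed` if either
#' layer says so. An edge retained in both layers marks its target as
#' differentially expressed at both the mRNA and protein level
#' (`dual_level`); `dual_concordant` additionally requires the two
#' target calls to agree in direction. A between-layer direction
#' conflict is flagged `discordant`, kept in the catalog, and excluded
#' from `dual_concordant` with a warning.
#'
#' @param transcript_set,protein_set Outputs of [expression_pair()] +
#'   [confidence_filter()] for the two layers (either may be empty or
#'   `NULL`).
#' @return The integrated catalog with `layers`, `dual_level`,
#'   `dual_concordant` and `discordant` columns.
#' @export
integrate_layers <- function(transcript_set, protein_set) {
  empty <- tibble(
    mirna_id = character(0), target_symbol = character(0),
    confidence = character(0), cwcs = numeric(0), evidence_methods = character(0),
    mirna_direction = character(0), target_direction = character(0)
  )
  tx <- if (is.null(transcript_set) || nrow(transcript_set) == 0) empty else transcript_set
  pr <- if (is.null(protein_set) || nrow(protein_set) == 0) empty else protein_set
  tx$layers <- if (nrow(tx)) "transcript" else character(0)
  pr$layers <- if (nrow(pr)) "protein" else character(0)
  both <- dplyr::bind_rows(tx, pr) %>%
    dplyr::group_by(.data$mirna_id, .data$target_symbol) %>%
    dplyr::summarise(
      confidence = if (any(.data$confidence == "observed")) "observed" else "predicted",
      cwcs = if (all(is.na(.data$cwcs))) NA_real_ else min(.data$cwcs, na.rm = TRUE),
      evidence_methods = join_methods(list(unique(unlist(split_methods(.data$evidence_methods))))),
      discordant = dplyr::n_distinct(.data$target_direction) > 1,
      mirna_direction = .data$mirna_direction[1],
      target_direction = .data$target_direction[1],
      layers = paste(sort(unique(.data$layers)), collapse = ";"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      dual_level = .data$layers == "protein;transcript",
      dual_concordant = .data$dual_level & !.data$discordant
    ) %>%
    dplyr::arrange(.data$mirna_id, .data$target_symbol)
  if (any(both$discordant)) {
    warn(sprintf("integrate_layers: %d edge(s) with conflicting target direction between layers",
                 sum(both$discordant)))
  }
  both
}

#' Experimentally observed subset of an integrated catalog
#'
#' @param catalog Output of [integrate_layers()] (or any miRNA-target
#'   edge tibble with a `confidence` column).
#' @return A list: `edges` (observed edges), `n_targets` (distinct
#'   target symbols among them).
#' @export
observed_subset <- function(catalog) {
  obs <- catalog[catalog$confidence == "observed", , drop = FALSE]
  list(edges = obs, n_targets = dplyr::n_distinct(obs$target_symbol))
}
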