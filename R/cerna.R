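#' Expand a miRNA id to its mature arms
#'
#' Interaction databases index the two mature strands of a pre-miRNA
#' hairpin (-3p and -5p) separately. An id that already names an arm is
#' returned as-is; an arm-less id expands to both arms so that lncRNA
#' partners of either strand can be found. The operation is idempotent
#' on its own outputs.
#'
#' @param mirna_id A single normalized miRNA id.
#' @return Character vector of arm-resolved ids (length 1 or 2).
#' @examples
#' expand_arms("hsa-miR-125b")     # both arms
#' expand_arms("hsa-miR-34a-5p")   # unchanged
#' @export
expand_arms <- function(mirna_id) {
  cx_assert(length(mirna_id) == 1, "expand_arms takes a single id")
  if (grepl("-(3p|5p)$", mirna_id)) return(mirna_id)
  paste0(mirna_id, c("-3p", "-5p"))
}

#' Evidence tier of a miRNA-target edge
#'
#' miRTarBase-style tiering: `strong` iff the edge carries at least one
#' functionally validated method (reporter assay, western blot, qPCR);
#' high-throughput-only support (microarray, NGS, pSILAC, CLIP-seq,
#' ...) and absent annotation are `less_strong`.
#'
#' @param evidence_methods Character vector of semicolon-joined method
#'   strings (one per edge).
#' @return Character vector of tiers.
#' @export
tier_mir_target <- function(evidence_methods) {
  vapply(split_methods(evidence_methods), function(m) {
    if (length(intersect(m, STRONG_EVIDENCE_METHODS)) > 0) "strong" else "less_strong"
  }, character(1))
}

#' Assemble sponge-consistent lncRNA-miRNA-mRNA triads
#'
#' For each anchor gene: take its retained miRNA partners (candidate
#' edges inverse to the anchor's direction that pass the confidence
#' filter), expand each partner miRNA to its mature arms for the
#' lncRNA join, join against the lncRNA-miRNA catalog, and keep the
#' triads in which all three molecules have definite direction calls
#' and the sponge pattern holds: the lncRNA moves with the mRNA
#' (positive relation) while the miRNA opposes both. Each triad carries
#' both evidence tiers and a flag recording whether the arm-resolved
#' miRNA id arose from expansion. Anchors with no consistent triad are
#' reported explicitly.
#'
#' @param anchors Character vector of target gene symbols; each must
#'   have a direction call.
#' @param mir_catalog Tibble of candidate miRNA-target edges.
#' @param lnc_catalog Tibble of lncRNA-miRNA edges (`lncrna_id`,
#'   `mirna_id` arm-resolved, `tier`).
#' @param calls Consensus table covering the lncRNA, miRNA and
#'   mRNA/protein classes (ambiguous calls are ignored).
#' @param cwcs_cutoff Passed to [confidence_filter()].
#' @param anchor_class Class whose calls direction the anchors
#'   (default `"mRNA"`).
#' @return A list: `triads` (tibble of consistent triads),
#'   `anchors_without_triads` (character vector).
#' @export
assemble_triads <- function(anchors, mir_catalog, lnc_catalog, calls,
                            cwcs_cutoff = -0.4, anchor_class = "mRNA") {
  calls <- calls[calls$direction %in% c("up", "down"), , drop = FALSE]
  dir_of <- function(ids, cls) {
    sub <- calls[calls$molecule_class == cls, , drop = FALSE]
    unname(stats::setNames(sub$direction, sub$molecule_id)[ids])
  }
  anchors <- unique(normalize_id(anchors, "mRNA"))
  anchor_dir <- dir_of(anchors, anchor_class)
  if (any(is.na(anchor_dir))) {
    cx_abort(sprintf("anchor(s) without a direction call: %s",
                     paste(anchors[is.na(anchor_dir)], collapse = ", ")))
  }
  edges <- confidence_filter(mir_catalog, cwcs_cutoff = cwcs_cutoff)
  edges <- edges[edges$target_symbol %in% anchors, , drop = FALSE]
  edges$mir_direction <- dir_of(edges$mirna_id, "miRNA")
  edges$target_direction <- unname(stats::setNames(anchor_dir, anchors)[edges$target_symbol])
  edges <- edges[!is.na(edges$mir_direction) &
                   edges$mir_direction != edges$target_direction, , drop = FALSE]
  triads <- purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    e <- edges[i, ]
    arms <- expand_arms(e$mirna_id)
    hits <- lnc_catalog[lnc_catalog$mirna_id %in% arms, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    tibble(
      lncrna_id = hits$lncrna_id,
      mirna_id = hits$mirna_id,
      target_symbol = e$target_symbol,
      lnc_direction = dir_of(hits$lncrna_id, "lncRNA"),
      mir_direction = e$mir_direction,
      target_direction = e$target_direction,
      mir_target_tier = tier_mir_target(e$evidence_methods),
      lnc_mir_tier = hits$tier,
      arm_expanded = hits$mirna_id != e$mirna_id
    )
  })
  if (nrow(triads) > 0) {
    triads$consistent <- !is.na(triads$lnc_direction) &
      triads$lnc_direction == triads$target_direction &
      triads$mir_direction != triads$target_direction
    triads <- triads[triads$consistent, , drop = FALSE]
    triads <- dplyr::distinct(triads) %>%
      dplyr::arrange(.data$target_symbol, .data$mirna_id, .data$lncrna_id)
  } else {
    triads <- empty_triads()
  }
  missing <- setdiff(anchors, unique(triads$target_symbol))
  if (length(missing) > 0) {
    inform(sprintf("no consistent triad found for anchor(s): %s",
                   paste(sort(missing), collapse = ", ")))
  }
  list(triads = triads, anchors_without_triads = sort(missing))
}

empty_triads <- function() {
  tibble(
    lncrna_id = character(0), mirna_id = character(0),
    target_symbol = character(0), lnc_direction = character(0),
    mir_direction = character(0), target_direction = character(0),
    mir_target_tier = character(0), lnc_mir_tier = character(0),
    arm_expanded = logical(0), consistent = logical(0)
  )
}

#' Export a triad list as a tri-partite attributed network
#'
#' Nodes carry `node_class` (lncRNA/miRNA/mRNA) and `direction`
#' (up/down; consumers conventionally render these red/green); edges
#' carry `relation` (`sponges` for lncRNA-miRNA, `targets` for
#' miRNA-mRNA) and `evidence_tier` (consumers may style strong edges
#' thick and less-strong edges dashed).
#'
#' @param triads Nonempty triad tibble from [assemble_triads()].
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_cerna_network <- function(triads, path, format = c("sif", "graphml", "tsv")) {
  cx_assert(nrow(triads) > 0, "cannot export an empty triad list")
  nodes <- dplyr::bind_rows(
    tibble(id = triads$lncrna_id, node_class = "lncRNA", direction = triads$lnc_direction),
    tibble(id = triads$mirna_id, node_class = "miRNA", direction = triads$mir_direction),
    tibble(id = triads$target_symbol, node_class = "mRNA", direction = triads$target_direction)
  ) %>% dplyr::distinct()
  edges <- dplyr::bind_rows(
    tibble(from = triads$lncrna_id, to = triads$mirna_id,
           relation = "sponges", evidence_tier = triads$lnc_mir_tier),
    tibble(from = triads$mirna_id, to = triads$target_symbol,
           relation = "targets", evidence_tier = triads$mir_target_tier)
  ) %>% dplyr::distinct()
  write_network(nodes, edges, path, format = format)
}
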