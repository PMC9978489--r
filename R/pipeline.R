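#' Build a validated pipeline configuration
#'
#' Collects every input path (or in-memory table) and threshold the
#' pipeline uses. Defaults are the method's stated operating points:
#' CWCS cutoff -0.4, PPI combined-score minimum 900 ("highest
#' confidence" 0.9), top-10 per centrality, alpha 0.05.
#'
#' @param expression Expression-evidence TSV path or tibble (must cover
#'   the miRNA and mRNA classes; protein and lncRNA classes as
#'   available).
#' @param mir_targets miRNA-target catalog path or tibble.
#' @param lnc_mir lncRNA-miRNA catalog path or tibble.
#' @param ppi Scored PPI edge table path or tibble (optional).
#' @param gene_sets GMT path or named list (optional).
#' @param anchors Explicit anchor genes (required when `anchor_mode =
#'   "explicit"`).
#' @param anchor_mode How the triad anchors are chosen: `"hubs_dual"`
#'   (hub genes plus dual-concordant targets; the default),
#'   `"hubs"`, `"dual_level"`, or `"explicit"`.
#' @param cwcs_cutoff,ppi_min_score,top_k,alpha Stage thresholds.
#' @param ppi_nodes `"observed_targets"` restricts the PPI graph to
#'   the experimentally observed miRNA targets (whitelisted, so
#'   isolated targets stay); `"all"` uses the full table.
#' @param closeness_mode Passed to [closeness_centrality()].
#' @param outdir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param seed Seed recorded in the summary (the core pipeline is
#'   deterministic; the seed matters only for synthetic inputs).
#' @return A `cernaxis_config` list.
#' @export
run_config <- function(expression, mir_targets, lnc_mir, ppi = NULL,
                       gene_sets = NULL, anchors = NULL,
                       anchor_mode = c("hubs_dual", "hubs", "dual_level", "explicit"),
                       cwcs_cutoff = -0.4, ppi_min_score = 900, top_k = 10,
                       alpha = 0.05, ppi_nodes = c("observed_targets", "all"),
                       closeness_mode = "harmonic", outdir = NULL, seed = 1) {
  anchor_mode <- match.arg(anchor_mode)
  ppi_nodes <- match.arg(ppi_nodes)
  cx_assert(cwcs_cutoff <= 0, "cwcs_cutoff must be <= 0 (CWCS is a repression score)")
  cx_assert(ppi_min_score >= 0 && ppi_min_score <= 1000,
            "ppi_min_score must lie in [0, 1000]")
  cx_assert(top_k >= 1, "top_k must be >= 1")
  cx_assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  if (anchor_mode == "explicit") {
    cx_assert(length(anchors) > 0, "anchor_mode 'explicit' needs a nonempty anchors vector")
  }
  structure(list(
    expression = expression, mir_targets = mir_targets, lnc_mir = lnc_mir,
    ppi = ppi, gene_sets = gene_sets, anchors = anchors,
    anchor_mode = anchor_mode, cwcs_cutoff = cwcs_cutoff,
    ppi_min_score = ppi_min_score, top_k = top_k, alpha = alpha,
    ppi_nodes = ppi_nodes, closeness_mode = closeness_mode,
    outdir = outdir, seed = seed
  ), class = "cernaxis_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [run_config()]; path entries are
#' resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `cernaxis_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("expression", "mir_targets", "lnc_mir", "ppi", "gene_sets")) {
    if (!is.null(raw[[key]]) && is.character(raw[[key]]) &&
        !file.exists(raw[[key]])) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  do.call(run_config, raw)
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) return(reader(x))
  x
}

#' Run the full ceRNA-axis discovery pipeline
#'
#' Executes the stages in order: consensus direction calling ->
#' inverse-expression pairing and confidence filtering (transcript and
#' protein layers) -> layer integration and observed-subset extraction
#' -> hub identification on the PPI graph -> over-representation
#' analysis of the observed targets -> triad assembly for the selected
#' anchors. The returned report carries the stage-by-stage counts
#' (evidence rows, consensus calls and exclusions, paired edges per
#' layer, integrated catalog size, observed interactions and distinct
#' targets, dual-level targets, hubs, significant gene sets, triads).
#' With an `outdir`, stage tables, network exports and a
#' `summary.json` are written; a rerun with the same config reproduces
#' them byte-for-byte.
#'
#' @param config A `cernaxis_config` from [run_config()].
#' @return A list of stage results plus `summary`.
#' @export
run_all <- function(config) {
  cx_assert(inherits(config, "cernaxis_config"), "config must come from run_config()")
  evidence <- resolve_input(config$expression, read_expression_table)
  mir_edges <- resolve_input(config$mir_targets, read_mir_target_table)
  lnc_edges <- resolve_input(config$lnc_mir, read_lnc_mir_table)
  ppi_edges <- resolve_input(config$ppi, read_ppi_table)
  collection <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets) else
    config$gene_sets

  stage <- "consensus"
  res <- tryCatch({
    calls <- consensus_table(evidence)
    ok <- usable_calls(calls)
    mirna_calls <- ok[ok$molecule_class == "miRNA", ]
    mrna_calls <- ok[ok$molecule_class == "mRNA", ]
    protein_calls <- ok[ok$molecule_class == "protein", ]

    stage <- "pairing"
    tx <- confidence_filter(expression_pair(mir_edges, mirna_calls, mrna_calls),
                            cwcs_cutoff = config$cwcs_cutoff)
    pr <- if (nrow(protein_calls) > 0) {
      confidence_filter(expression_pair(mir_edges, mirna_calls, protein_calls),
                        cwcs_cutoff = config$cwcs_cutoff)
    } else {
      NULL
    }
    catalog <- integrate_layers(tx, pr)
    obs <- observed_subset(catalog)

    stage <- "netcent"
    hubs <- NULL
    if (!is.null(ppi_edges)) {
      g <- if (config$ppi_nodes == "observed_targets") {
        targets <- unique(obs$edges$target_symbol)
        build_graph(ppi_edges[ppi_edges$protein_a %in% targets &
                                ppi_edges$protein_b %in% targets, ],
                    min_score = config$ppi_min_score, keep_nodes = targets)
      } else {
        build_graph(ppi_edges, min_score = config$ppi_min_score)
      }
      hubs <- hub_intersection(g, k = config$top_k,
                               closeness_mode = config$closeness_mode)
    }

    stage <- "enrich"
    ora <- NULL
    if (!is.null(collection) && nrow(obs$edges) > 0) {
      ora <- run_ora(unique(obs$edges$target_symbol), collection,
                     alpha = config$alpha)
    }

    stage <- "cerna"
    anchors <- switch(config$anchor_mode,
      explicit = config$anchors,
      hubs = hubs$hubs %||% character(0),
      dual_level = unique(catalog$target_symbol[catalog$dual_level]),
      hubs_dual = unique(c(hubs$hubs %||% character(0),
                           catalog$target_symbol[catalog$dual_concordant]))
    )
    anchors <- unique(normalize_id(anchors %||% character(0), "mRNA"))
    uncalled <- setdiff(anchors, mrna_calls$molecule_id)
    if (config$anchor_mode != "explicit" && length(uncalled) > 0) {
      inform(sprintf("run_all: %d auto-selected anchor(s) without an mRNA call skipped: %s",
                     length(uncalled), paste(sort(uncalled), collapse = ", ")))
      anchors <- setdiff(anchors, uncalled)
    }
    cerna <- if (length(anchors) > 0) {
      assemble_triads(anchors, catalog, lnc_edges, calls,
                      cwcs_cutoff = config$cwcs_cutoff)
    } else {
      list(triads = empty_triads(), anchors_without_triads = character(0))
    }

    list(calls = calls, transcript_pairs = tx, protein_pairs = pr,
         catalog = catalog, observed = obs, hubs = hubs, ora = ora,
         anchors = anchors, cerna = cerna)
  }, cernaxis_error = function(e) {
    cx_abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
             class = "cernaxis_stage_error")
  })

  summary <- list(
    n_evidence_rows = nrow(evidence),
    n_calls = nrow(res$calls),
    n_excluded_ambiguous = sum(res$calls$excluded),
    n_paired_transcript = nrow(res$transcript_pairs),
    n_paired_protein = if (is.null(res$protein_pairs)) 0L else nrow(res$protein_pairs),
    n_catalog = nrow(res$catalog),
    n_observed = nrow(res$observed$edges),
    n_observed_targets = res$observed$n_targets,
    n_dual_level = sum(res$catalog$dual_level),
    n_dual_concordant = sum(res$catalog$dual_concordant),
    hubs = res$hubs$hubs %||% character(0),
    top_gene_set = if (is.null(res$ora)) NA_character_ else res$ora$set_name[1],
    n_significant_sets = if (is.null(res$ora)) 0L else sum(res$ora$significant),
    anchors = sort(res$anchors),
    anchors_without_triads = res$cerna$anchors_without_triads,
    n_triads = nrow(res$cerna$triads),
    seed = config$seed
  )
  res$summary <- summary

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(res$calls, file.path(config$outdir, "consensus_calls.tsv"))
    write_tsv_plain(res$catalog, file.path(config$outdir, "integrated_catalog.tsv"))
    if (!is.null(res$hubs)) {
      write_tsv_plain(res$hubs$scores, file.path(config$outdir, "centrality_scores.tsv"))
    }
    if (!is.null(res$ora)) {
      write_tsv_plain(res$ora, file.path(config$outdir, "enrichment.tsv"))
    }
    write_tsv_plain(res$cerna$triads, file.path(config$outdir, "triads.tsv"))
    if (nrow(res$cerna$triads) > 0) {
      export_cerna_network(res$cerna$triads,
                           file.path(config$outdir, "cerna_network.graphml"),
                           format = "graphml")
      export_cerna_network(res$cerna$triads,
                           file.path(config$outdir, "cerna_network.sif"),
                           format = "sif")
    }
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
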