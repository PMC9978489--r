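#' Plant a ground-truth molecule roster and ceRNA axes
#'
#' Builds the shared ground truth the other generators consume: a
#' roster of lncRNAs, miRNAs and target genes with true up/down
#' directions, and `n_axes` planted sponge axes that are
#' direction-consistent by construction (target and lncRNA move
#' together, miRNA opposes both).
#'
#' @param n_axes Number of planted lncRNA-miRNA-mRNA axes.
#' @param n_extra_targets Additional non-axis target genes (hub / decoy
#'   material).
#' @param seed Integer seed.
#' @return A list: `molecules` (tibble with `molecule_id`,
#'   `molecule_class`, `true_direction`), `true_directions` (named
#'   vector), `planted_axes` (tibble `lncrna_id`, `mirna_id`,
#'   `target_symbol`), `seed`.
#' @export
gen_ground_truth <- function(n_axes = 5, n_extra_targets = 20, seed = 1) {
  set.seed(seed)
  lnc <- sprintf("LNC%03d", seq_len(n_axes))
  mir <- sprintf("hsa-miR-%d-5p", 900 + seq_len(n_axes))
  tgt <- sprintf("GENE%03d", seq_len(n_axes))
  extra <- sprintf("GENE%03d", n_axes + seq_len(n_extra_targets))
  tgt_dir <- sample(c("up", "down"), n_axes, replace = TRUE)
  molecules <- dplyr::bind_rows(
    tibble(molecule_id = lnc, molecule_class = "lncRNA", true_direction = tgt_dir),
    tibble(molecule_id = mir, molecule_class = "miRNA",
           true_direction = ifelse(tgt_dir == "up", "down", "up")),
    tibble(molecule_id = tgt, molecule_class = "mRNA", true_direction = tgt_dir),
    tibble(molecule_id = extra, molecule_class = "mRNA",
           true_direction = sample(c("up", "down"), n_extra_targets, replace = TRUE))
  )
  list(
    molecules = molecules,
    true_directions = stats::setNames(molecules$true_direction, molecules$molecule_id),
    planted_axes = tibble(lncrna_id = lnc, mirna_id = mir, target_symbol = tgt),
    seed = seed
  )
}

#' Simulate per-study up/down calls with flip noise
#'
#' Each of `n_studies` studies reports every molecule's true direction,
#' flipped independently with probability `flip_noise` — emulating the
#' between-study disagreement that the majority rule is meant to
#' absorb. `flip_noise` must stay below 0.5 or the majority rule is
#' uninformative.
#'
#' @param molecules Tibble with `molecule_id`, `molecule_class` and
#'   optionally `true_direction` (drawn at random when absent).
#' @param n_studies Number of studies (>= 1).
#' @param flip_noise Per-study flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return A list: `evidence` (expression-evidence tibble),
#'   `truth` (`true_directions`, `seed`).
#' @export
gen_expression_studies <- function(molecules, n_studies = 5, flip_noise = 0.2,
                                   seed = 1) {
  cx_assert(n_studies >= 1, "n_studies must be >= 1")
  if (flip_noise < 0 || flip_noise >= 0.5) {
    cx_abort("flip_noise must lie in [0, 0.5): at 0.5 the majority rule is uninformative")
  }
  set.seed(seed)
  if (is.character(molecules)) {
    molecules <- tibble(molecule_id = molecules, molecule_class = "mRNA")
  }
  if (!"true_direction" %in% names(molecules)) {
    molecules$true_direction <- sample(c("up", "down"), nrow(molecules), replace = TRUE)
  }
  n_mol <- nrow(molecules)
  evidence <- purrr::map_dfr(seq_len(n_studies), function(s) {
    flip <- stats::runif(n_mol) < flip_noise
    tibble(
      molecule_id = molecules$molecule_id,
      molecule_class = molecules$molecule_class,
      study_id = sprintf("S%02d", s),
      direction = ifelse(flip,
                         ifelse(molecules$true_direction == "up", "down", "up"),
                         molecules$true_direction),
      transcript_id = NA_character_
    )
  })
  list(
    evidence = evidence,
    truth = list(
      true_directions = stats::setNames(molecules$true_direction, molecules$molecule_id),
      seed = seed
    )
  )
}

#' Generate interaction catalogs with planted axes and labeled decoys
#'
#' Planted axes appear as experimentally observed, strong-evidence
#' (reporter assay) miRNA-target edges whose directions are inverse
#' under the ground truth, with a matching strong lncRNA-miRNA edge.
#' Decoys are adversarial by retention predicate rather than uniform
#' noise: each decoy edge violates exactly one predicate —
#' `wrong_sign` (miRNA and target move together), `high_cwcs`
#' (predicted with CWCS above -0.4) or `no_lnc_partner` (a retainable
#' edge whose miRNA has no lncRNA partner) — and the manifest records
#' which, so every filter has dedicated violators.
#'
#' @param truth Output of [gen_ground_truth()].
#' @param n_decoy_edges Total decoys, split across the three
#'   categories round-robin.
#' @param seed Integer seed.
#' @return A list: `mir_catalog`, `lnc_catalog`, `decoy_manifest`
#'   (tibble `mirna_id`, `target_symbol`, `category`), plus extra
#'   decoy molecules under `decoy_molecules` (with true directions) so
#'   expression tables can cover them.
#' @export
gen_interaction_catalogs <- function(truth, n_decoy_edges = 30, seed = 1) {
  cx_assert(nrow(truth$planted_axes) > 0, "ground truth has no planted axes")
  set.seed(seed)
  axes <- truth$planted_axes
  dirs <- truth$true_directions
  mir_rows <- tibble(
    mirna_id = axes$mirna_id, target_symbol = axes$target_symbol,
    confidence = "observed", cwcs = NA_real_,
    evidence_methods = "reporter_assay;qpcr"
  )
  lnc_rows <- tibble(lncrna_id = axes$lncrna_id, mirna_id = axes$mirna_id,
                     tier = "strong")
  categories <- c("wrong_sign", "high_cwcs", "no_lnc_partner")
  decoy_mol <- tibble(molecule_id = character(0), molecule_class = character(0),
                      true_direction = character(0))
  manifest <- tibble(mirna_id = character(0), target_symbol = character(0),
                     category = character(0))
  for (i in seq_len(n_decoy_edges)) {
    cat_i <- categories[(i - 1) %% 3 + 1]
    mir_id <- sprintf("hsa-miR-%d-3p", 2000 + i)
    tgt_id <- sprintf("DECOY%03d", i)
    tgt_dir <- sample(c("up", "down"), 1)
    mir_dir <- if (cat_i == "wrong_sign") tgt_dir else
      ifelse(tgt_dir == "up", "down", "up")
    lnc_id <- sprintf("LNCD%03d", i)
    decoy_mol <- dplyr::bind_rows(decoy_mol, tibble(
      molecule_id = c(mir_id, tgt_id, lnc_id),
      molecule_class = c("miRNA", "mRNA", "lncRNA"),
      true_direction = c(mir_dir, tgt_dir, tgt_dir)
    ))
    mir_rows <- dplyr::bind_rows(mir_rows, tibble(
      mirna_id = mir_id, target_symbol = tgt_id,
      confidence = if (cat_i == "high_cwcs") "predicted" else "observed",
      cwcs = if (cat_i == "high_cwcs") stats::runif(1, -0.39, -0.05) else NA_real_,
      evidence_methods = "microarray"
    ))
    if (cat_i != "no_lnc_partner") {
      lnc_rows <- dplyr::bind_rows(lnc_rows, tibble(
        lncrna_id = lnc_id, mirna_id = mir_id, tier = "less_strong"
      ))
    }
    manifest <- dplyr::bind_rows(manifest, tibble(
      mirna_id = mir_id, target_symbol = tgt_id, category = cat_i
    ))
  }
  list(
    mir_catalog = mir_rows,
    lnc_catalog = lnc_rows,
    decoy_manifest = manifest,
    decoy_molecules = decoy_mol,
    seed = seed
  )
}

#' Generate a PPI edge table with planted high-degree hubs
#'
#' Background nodes form an Erdos-Renyi graph whose retained edges all
#' carry scores at or above 900; each planted hub is wired to
#' `hub_degree` random background nodes, again above threshold. The
#' score threshold itself is exercised by `n_subthreshold` extra decoy
#' edges with scores below 900 that a correct [build_graph()] must
#' discard. `hub_degree` must dominate the expected background degree
#' (at least 4 x `n_background` x `background_edge_prob`) or hub
#' recovery is not identifiable.
#'
#' @param n_background Number of background nodes.
#' @param background_edge_prob Erdos-Renyi edge probability.
#' @param n_hubs Number of planted hubs.
#' @param hub_degree Neighbors wired to each hub.
#' @param n_subthreshold Sub-threshold decoy edges.
#' @param seed Integer seed.
#' @return A list: `edges` (scored PPI tibble), `truth`
#'   (`planted_hubs`, `seed`).
#' @export
gen_ppi <- function(n_background = 60, background_edge_prob = 0.05, n_hubs = 3,
                    hub_degree = 30, n_subthreshold = 30, seed = 1) {
  if (hub_degree < 4 * n_background * background_edge_prob) {
    cx_abort("hub_degree must be >= 4 * n_background * background_edge_prob")
  }
  cx_assert(hub_degree <= n_background, "hub_degree cannot exceed n_background")
  set.seed(seed)
  bg <- sprintf("BG%03d", seq_len(n_background))
  hubs <- sprintf("HUB%d", seq_len(n_hubs))
  pairs <- utils::combn(bg, 2)
  pick <- stats::runif(ncol(pairs)) < background_edge_prob
  edges <- tibble(
    protein_a = pairs[1, pick], protein_b = pairs[2, pick],
    combined_score = sample(900:1000, sum(pick), replace = TRUE)
  )
  for (h in hubs) {
    nb <- sample(bg, hub_degree)
    edges <- dplyr::bind_rows(edges, tibble(
      protein_a = pmin(h, nb), protein_b = pmax(h, nb),
      combined_score = sample(900:1000, hub_degree, replace = TRUE)
    ))
  }
  all_nodes <- c(bg, hubs)
  sub <- tibble(
    protein_a = sample(all_nodes, n_subthreshold, replace = TRUE),
    protein_b = sample(all_nodes, n_subthreshold, replace = TRUE),
    combined_score = sample(1:899, n_subthreshold, replace = TRUE)
  )
  sub <- sub[sub$protein_a != sub$protein_b, , drop = FALSE]
  edges <- dplyr::bind_rows(edges, tibble(
    protein_a = pmin(sub$protein_a, sub$protein_b),
    protein_b = pmax(sub$protein_a, sub$protein_b),
    combined_score = sub$combined_score
  )) %>%
    dplyr::group_by(.data$protein_a, .data$protein_b) %>%
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop")
  list(edges = edges, truth = list(planted_hubs = hubs, seed = seed))
}

#' Generate a gene-set collection with one planted enriched set
#'
#' The planted set shares at least `planted_query_overlap` genes with
#' the planted query; the overlap is raised as needed so that the
#' planted upper-tail p-value is below 1e-4 under the generated sizes
#' (the realized p is returned in the truth manifest). The remaining
#' sets are uniform draws from the universe.
#'
#' @param universe Character vector of gene symbols.
#' @param n_sets Number of gene sets.
#' @param planted_query_overlap Minimum genes shared between query and
#'   planted set.
#' @param query_size,set_size Sizes of the query and of each set.
#' @param seed Integer seed.
#' @return A list: `collection` (named list), `query`, `truth`
#'   (`planted_enriched_set`, `planted_p`, `seed`).
#' @export
gen_gene_sets <- function(universe, n_sets = 20, planted_query_overlap = 10,
                          query_size = 20, set_size = 25, seed = 1) {
  universe <- unique(normalize_id(universe, "mRNA"))
  cx_assert(planted_query_overlap <= min(query_size, set_size),
            "overlap cannot exceed query or set size")
  cx_assert(length(universe) >= query_size + set_size,
            "universe too small for the requested sizes")
  set.seed(seed)
  # the planted signal must be unambiguous: grow the overlap beyond the
  # requested minimum until the upper-tail p-value clears 1e-4
  repeat {
    p_ok <- hypergeom_test(planted_query_overlap, set_size, query_size,
                           length(universe)) < 1e-4
    if (p_ok || planted_query_overlap >= min(query_size, set_size)) break
    planted_query_overlap <- planted_query_overlap + 1
  }
  if (!p_ok) {
    cx_abort("cannot plant an enriched set with p < 1e-4 at these sizes")
  }
  query <- sample(universe, query_size)
  planted <- c(sample(query, planted_query_overlap),
               sample(setdiff(universe, query), set_size - planted_query_overlap))
  collection <- stats::setNames(
    c(list(sort(planted)),
      lapply(seq_len(n_sets - 1), function(i) sort(sample(universe, set_size)))),
    c("PLANTED_SET", sprintf("RANDOM_SET_%02d", seq_len(n_sets - 1)))
  )
  planted_p <- hypergeom_test(planted_query_overlap, set_size, query_size,
                              length(universe))
  list(
    collection = collection,
    query = query,
    truth = list(planted_enriched_set = "PLANTED_SET", planted_p = planted_p,
                 seed = seed)
  )
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates and writes every input the pipeline consumes — expression
#' evidence, miRNA-target and lncRNA-miRNA catalogs, a scored PPI
#' table, a GMT collection — plus a `truth.json` manifest of the
#' planted structure. One integer seed drives all generators (sub-seeds
#' are derived by small offsets), so the same seed always reproduces
#' the same bundle. The `default` preset carries noise-free direction
#' calls (the curated multi-study calls the pipeline ingests are
#' literature assertions, not raw measurements); flip noise is a knob
#' for dedicated consensus-recovery experiments.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param preset One of `"small"`, `"default"`, `"stress"`.
#' @return Invisibly, a list with the generated pieces and `paths`.
#' @export
gen_bundle <- function(outdir, seed = 1, preset = c("default", "small", "stress")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    small = list(n_axes = 3, n_extra = 8, n_studies = 3, flip = 0, decoys = 9,
                 ppi = list(n_bg = 30, prob = 0.08, hubs = 2, deg = 15, sub = 10),
                 sets = list(n = 8, overlap = 8, q = 15, s = 18)),
    default = list(n_axes = 5, n_extra = 20, n_studies = 5, flip = 0, decoys = 30,
                   ppi = list(n_bg = 60, prob = 0.05, hubs = 3, deg = 30, sub = 30),
                   sets = list(n = 20, overlap = 10, q = 20, s = 25)),
    stress = list(n_axes = 12, n_extra = 60, n_studies = 9, flip = 0.1, decoys = 90,
                  ppi = list(n_bg = 120, prob = 0.04, hubs = 4, deg = 40, sub = 60),
                  sets = list(n = 40, overlap = 12, q = 30, s = 30))
  )
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- gen_ground_truth(n_axes = p$n_axes, n_extra_targets = p$n_extra,
                            seed = seed)
  cats <- gen_interaction_catalogs(truth, n_decoy_edges = p$decoys, seed = seed + 1)
  roster <- dplyr::bind_rows(truth$molecules, cats$decoy_molecules)
  expr <- gen_expression_studies(roster, n_studies = p$n_studies,
                                 flip_noise = p$flip, seed = seed + 2)
  ppi <- gen_ppi(n_background = p$ppi$n_bg, background_edge_prob = p$ppi$prob,
                 n_hubs = p$ppi$hubs, hub_degree = p$ppi$deg,
                 n_subthreshold = p$ppi$sub, seed = seed + 3)
  gene_universe <- unique(c(ppi$edges$protein_a, ppi$edges$protein_b,
                            roster$molecule_id[roster$molecule_class == "mRNA"]))
  sets <- gen_gene_sets(gene_universe, n_sets = p$sets$n,
                        planted_query_overlap = p$sets$overlap,
                        query_size = p$sets$q, set_size = p$sets$s,
                        seed = seed + 4)
  paths <- list(
    expression = file.path(outdir, "expression.tsv"),
    mir_targets = file.path(outdir, "mir_targets.tsv"),
    lnc_mir = file.path(outdir, "lnc_mir.tsv"),
    ppi = file.path(outdir, "ppi.tsv"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    query = file.path(outdir, "ora_query.txt"),
    truth = file.path(outdir, "truth.json")
  )
  ev <- expr$evidence
  names(ev)[names(ev) == "molecule_class"] <- "class"
  write_tsv_plain(ev, paths$expression)
  write_tsv_plain(cats$mir_catalog, paths$mir_targets)
  write_tsv_plain(cats$lnc_catalog, paths$lnc_mir)
  write_tsv_plain(ppi$edges, paths$ppi)
  write_gmt(sets$collection, paths$gene_sets)
  writeLines(sets$query, paths$query)
  manifest <- list(
    seed = seed, preset = preset,
    true_directions = as.list(truth$true_directions),
    planted_axes = truth$planted_axes,
    planted_hubs = ppi$truth$planted_hubs,
    planted_enriched_set = sets$truth$planted_enriched_set,
    decoy_manifest = cats$decoy_manifest
  )
  jsonlite::write_json(manifest, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(truth = truth, catalogs = cats, expression = expr, ppi = ppi,
                 gene_sets = sets, paths = paths, preset = preset))
}
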