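#' Canonicalize molecule identifiers
#'
#' All joins across catalogs are string-keyed, so every identifier is
#' brought to one canonical form per molecule class at load time:
#'
#' * gene / protein / lncRNA symbols: surrounding whitespace stripped,
#'   upper-cased (`"tp53 "` becomes `"TP53"`).
#' * miRNA ids: a lower-case `hsa-` prefix is enforced, `mir`/`MIR`
#'   casing is canonicalized to `miR` (`let` ids keep `let`), and the
#'   remainder is lower-cased so that `"HSA-MIR-125B-5P"` becomes
#'   `"hsa-miR-125b-5p"`. An arm suffix (`-3p`/`-5p`) is preserved when
#'   present and never guessed when absent; arm expansion is an explicit
#'   step in triad assembly (see [expand_arms()]).
#'
#' The transform is idempotent: `normalize_id(normalize_id(x)) ==
#' normalize_id(x)`.
#'
#' @param raw Character vector of raw identifiers.
#' @param molecule_class One of `"lncRNA"`, `"miRNA"`, `"mRNA"`,
#'   `"protein"`.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_id("HSA-MIR-125B-5P", "miRNA")
#' normalize_id("tp53 ", "mRNA")
#' @export
normalize_id <- function(raw, molecule_class) {
  molecule_class <- match_class(molecule_class)
  x <- stringr::str_trim(as.character(raw))
  empty <- which(is.na(x) | !nzchar(x))
  if (length(empty) > 0) {
    cx_abort(sprintf("empty identifier at row(s) %s", paste(empty, collapse = ", ")))
  }
  if (molecule_class != "miRNA") {
    return(toupper(x))
  }
  x <- tolower(x)
  x <- sub("^hsa-", "", x)
  x <- paste0("hsa-", x)
  # mature-miRNA stems: mir-NNN -> miR-NNN; let-7 family keeps "let"
  sub("^hsa-mir-", "hsa-miR-", x)
}

#' Apply a user alias table before normalization
#'
#' Synonym resolution across heterogeneous source tables (e.g. `p53` vs
#' `TP53`) is delegated to an explicit two-column alias table rather
#' than a bundled synonym source; aliases are matched case-insensitively
#' on the trimmed raw token.
#'
#' @param raw Character vector of raw identifiers.
#' @param aliases A data frame with columns `alias` and `canonical`, or
#'   `NULL` for a no-op.
#' @return Character vector with aliases substituted (not yet
#'   normalized).
#' @export
apply_aliases <- function(raw, aliases = NULL) {
  if (is.null(aliases)) return(raw)
  cx_assert(all(c("alias", "canonical") %in% names(aliases)),
            "alias table needs columns 'alias' and 'canonical'")
  key <- tolower(stringr::str_trim(as.character(raw)))
  idx <- match(key, tolower(stringr::str_trim(aliases$alias)))
  out <- as.character(raw)
  out[!is.na(idx)] <- aliases$canonical[idx[!is.na(idx)]]
  out
}

#' Read a two-column identifier alias table
#'
#' @param path TSV with columns `alias`, `canonical`.
#' @return A tibble.
#' @export
read_alias_table <- function(path) {
  df <- read_tsv_checked(path, c("alias", "canonical"))
  as_tibble(df[c("alias", "canonical")])
}

# Shared TSV reader: UTF-8, tab-delimited, "#" comment lines ignored.
read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) cx_abort(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = c("NA", "")),
    error = function(e) cx_abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0 && ncol(df) == 0) cx_abort(sprintf("empty file: %s", path))
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    cx_abort(sprintf("%s: missing required column(s): %s",
                     path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read an expression-evidence table
#'
#' Expected columns: `molecule_id`, `study_id`, `direction`, plus either
#' a `class` column or the `molecule_class` argument; `transcript_id` is
#' optional. Direction tokens are parsed case-insensitively (see
#' [parse_direction()]); rows that duplicate an existing
#' `(molecule_id, molecule_class, study_id, transcript_id)` key exactly
#' are collapsed with a warning.
#'
#' @param path Path to a UTF-8 TSV (lines starting with `#` ignored).
#' @param molecule_class Class applied to every row when the file has no
#'   `class` column.
#' @param aliases Optional alias table (see [apply_aliases()]).
#' @return A tibble of expression evidence with one row per retained
#'   (molecule, class, study, transcript) call.
#' @export
read_expression_table <- function(path, molecule_class = NULL, aliases = NULL) {
  df <- read_tsv_checked(path, c("molecule_id", "study_id", "direction"))
  if (!"class" %in% names(df)) {
    if (is.null(molecule_class)) {
      cx_abort(sprintf("%s has no 'class' column and no molecule_class was given", path))
    }
    df$class <- match_class(molecule_class)
  }
  bad_class <- setdiff(unique(df$class), MOLECULE_CLASSES)
  if (length(bad_class) > 0) {
    cx_abort(sprintf("%s: unknown molecule class(es): %s",
                     path, paste(bad_class, collapse = ", ")))
  }
  ev <- tibble(
    molecule_id = apply_aliases(df$molecule_id, aliases),
    molecule_class = df$class,
    study_id = as.character(df$study_id),
    direction = parse_direction(df$direction),
    transcript_id = if ("transcript_id" %in% names(df)) {
      as.character(df$transcript_id)
    } else {
      NA_character_
    }
  )
  ev$molecule_id <- unlist(Map(normalize_id, ev$molecule_id, ev$molecule_class),
                           use.names = FALSE)
  n0 <- nrow(ev)
  ev <- dplyr::distinct(ev)
  if (nrow(ev) < n0) {
    warn(sprintf("%s: collapsed %d exact duplicate row(s)", path, n0 - nrow(ev)))
  }
  inform(sprintf("%s: %d expression-evidence row(s) loaded", path, nrow(ev)))
  ev
}

#' Read a miRNA-target interaction catalog
#'
#' Expected columns: `mirna_id`, `target_symbol`, `confidence`
#' (`observed`/`predicted`), `cwcs` (TargetScan cumulative weighted
#' context score; may be empty for observed edges), `evidence_methods`
#' (semicolon-separated, e.g. `reporter_assay;microarray`). Predicted
#' edges must carry a CWCS. Duplicate `(mirna_id, target_symbol)` pairs
#' merge: evidence methods by union, confidence `observed` if any row
#' says so, CWCS the most negative value present.
#'
#' @inheritParams read_expression_table
#' @return A tibble with one row per miRNA-target pair.
#' @export
read_mir_target_table <- function(path, aliases = NULL) {
  df <- read_tsv_checked(path, c("mirna_id", "target_symbol", "confidence"))
  conf <- tolower(stringr::str_trim(df$confidence))
  bad <- setdiff(unique(conf), CONFIDENCE_LEVELS)
  if (length(bad) > 0) {
    cx_abort(sprintf("%s: unknown confidence value(s): %s",
                     path, paste(bad, collapse = ", ")))
  }
  cwcs <- if ("cwcs" %in% names(df)) suppressWarnings(as.numeric(df$cwcs)) else
    rep(NA_real_, nrow(df))
  no_score <- which(conf == "predicted" & is.na(cwcs))
  if (length(no_score) > 0) {
    cx_abort(sprintf("%s: predicted edge(s) without a CWCS at data row(s) %s",
                     path, paste(no_score, collapse = ", ")))
  }
  edges <- tibble(
    mirna_id = normalize_id(apply_aliases(df$mirna_id, aliases), "miRNA"),
    target_symbol = normalize_id(apply_aliases(df$target_symbol, aliases), "mRNA"),
    confidence = conf,
    cwcs = cwcs,
    evidence_methods = if ("evidence_methods" %in% names(df)) {
      join_methods(split_methods(as.character(df$evidence_methods)))
    } else {
      ""
    }
  )
  merge_mir_target_edges(edges)
}

# Non-redundant (mirna_id, target_symbol) catalog: evidence union,
# observed wins over predicted, most negative CWCS kept.
merge_mir_target_edges <- function(edges) {
  edges %>%
    dplyr::group_by(.data$mirna_id, .data$target_symbol) %>%
    dplyr::summarise(
      confidence = if (any(.data$confidence == "observed")) "observed" else "predicted",
      cwcs = if (all(is.na(.data$cwcs))) NA_real_ else min(.data$cwcs, na.rm = TRUE),
      evidence_methods = join_methods(list(unique(unlist(split_methods(.data$evidence_methods))))),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$mirna_id, .data$target_symbol)
}

#' Read a lncRNA-miRNA interaction catalog
#'
#' Expected columns: `lncrna_id`, `mirna_id`, `tier` (`strong` /
#' `less_strong`). Duplicate pairs keep the stronger tier.
#'
#' @inheritParams read_expression_table
#' @return A tibble with one row per lncRNA-miRNA pair.
#' @export
read_lnc_mir_table <- function(path, aliases = NULL) {
  df <- read_tsv_checked(path, c("lncrna_id", "mirna_id", "tier"))
  tier <- tolower(stringr::str_trim(df$tier))
  bad <- setdiff(unique(tier), EVIDENCE_TIERS)
  if (length(bad) > 0) {
    cx_abort(sprintf("%s: unknown tier value(s): %s", path, paste(bad, collapse = ", ")))
  }
  tibble(
    lncrna_id = normalize_id(apply_aliases(df$lncrna_id, aliases), "lncRNA"),
    mirna_id = normalize_id(apply_aliases(df$mirna_id, aliases), "miRNA"),
    tier = tier
  ) %>%
    dplyr::group_by(.data$lncrna_id, .data$mirna_id) %>%
    dplyr::summarise(
      tier = if (any(.data$tier == "strong")) "strong" else "less_strong",
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$lncrna_id, .data$mirna_id)
}

#' Read a scored protein-protein edge table
#'
#' Expected columns: `protein_a`, `protein_b`, `combined_score`.
#' Scores follow the STRING convention: integers in \[0, 1000\]. Scores
#' given as 0-1 floats (at most 1) are multiplied by 1000 and rounded,
#' so a published cutoff of "0.9" and a file carrying 900 agree. Edges
#' are stored undirected with the lexicographically smaller symbol
#' first; self-loops are dropped with a warning and duplicate pairs keep
#' the maximum score.
#'
#' @inheritParams read_expression_table
#' @return A tibble of undirected scored edges.
#' @export
read_ppi_table <- function(path, aliases = NULL) {
  df <- read_tsv_checked(path, c("protein_a", "protein_b", "combined_score"))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score))) {
    cx_abort(sprintf("%s: non-numeric combined_score at data row(s) %s",
                     path, paste(which(is.na(score)), collapse = ", ")))
  }
  score <- ifelse(score <= 1, round(score * 1000), score)
  if (any(score < 0 | score > 1000)) {
    cx_abort(sprintf("%s: combined_score outside [0, 1000] after scaling", path))
  }
  a <- normalize_id(apply_aliases(df$protein_a, aliases), "protein")
  b <- normalize_id(apply_aliases(df$protein_b, aliases), "protein")
  self <- a == b
  if (any(self)) {
    warn(sprintf("%s: dropped %d self-loop edge(s)", path, sum(self)))
  }
  tibble(
    protein_a = pmin(a, b),
    protein_b = pmax(a, b),
    combined_score = as.integer(round(score))
  )[!self, ] %>%
    dplyr::group_by(.data$protein_a, .data$protein_b) %>%
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop") %>%
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' normalized as gene symbols and deduplicated; empty sets are dropped
#' with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) cx_abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) cx_abort(sprintf("empty GMT file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) {
    warn(sprintf("%s: dropped %d set(s) with no members", path, sum(short)))
    parts <- parts[!short]
  }
  sets <- lapply(parts, function(p) sort(unique(normalize_id(p[-(1:2)], "mRNA"))))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    cx_abort(sprintf("%s: duplicated gene-set name(s)", path))
  }
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- network export -------------------------------------------------------

#' Export an attributed network
#'
#' Writes a node/edge network in a Cytoscape-importable format. `nodes`
#' is a data frame whose first column (`id`) names the node and whose
#' remaining columns become node attributes; `edges` needs columns
#' `from`, `to` and `relation` (the SIF interaction token, e.g.
#' `targets`, `sponges`, `ppi`), with any further columns (such as
#' `evidence_tier`) exported as edge attributes.
#'
#' Formats: `"sif"` (one `from relation to` line per edge; attributes
#' not representable), `"graphml"` (full attributes, round-trip safe via
#' [read_network_graphml()]), `"tsv"` (edge-attribute table plus a
#' `<path>.nodes.tsv` node-attribute table).
#'
#' @param nodes Data frame of nodes (first column `id`).
#' @param edges Data frame of edges (`from`, `to`, `relation`, ...).
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(nodes, edges, path, format = c("sif", "graphml", "tsv")) {
  if (!is.character(format) || !all(format %in% c("sif", "graphml", "tsv"))) {
    cx_abort(sprintf("unknown network format '%s'; supported: sif, graphml, tsv",
                     paste(format, collapse = ",")))
  }
  format <- match.arg(format)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0) warn("writing an empty network")
  if (nrow(edges) > 0) {
    cx_assert(all(c("from", "to", "relation") %in% names(edges)),
              "edges need columns from, to, relation")
  }
  if (format == "sif") {
    lines <- if (nrow(edges) > 0) {
      paste(edges$from, edges$relation, edges$to, sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edges) > 0) edges else data.frame(from = character(0), to = character(0)),
      directed = FALSE,
      vertices = if (nrow(nodes) > 0) nodes else NULL
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a GraphML network written by [write_network()]
#'
#' @param path GraphML file.
#' @return A list with tibbles `nodes` (column `id` plus attributes) and
#'   `edges` (`from`, `to` plus attributes).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  if ("name" %in% names(nd)) names(nd)[names(nd) == "name"] <- "id"
  nd <- nd[, setdiff(names(nd), "id_attr"), drop = FALSE]
  rownames(nd) <- NULL
  list(nodes = as_tibble(nd), edges = as_tibble(ed))
}

#' Write a tibble as a plain TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
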