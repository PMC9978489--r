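test_that("identifier normalization canonicalizes each molecule class", {
  expect_equal(normalize_id("HSA-MIR-125B-5P", "miRNA"), "hsa-miR-125b-5p")
  expect_equal(normalize_id("miR-34a-5p", "miRNA"), "hsa-miR-34a-5p")
  expect_equal(normalize_id("mir-21", "miRNA"), "hsa-miR-21")
  expect_equal(normalize_id("LET-7A-5P", "miRNA"), "hsa-let-7a-5p")
  expect_equal(normalize_id("tp53 ", "mRNA"), "TP53")
  expect_equal(normalize_id(" malat1", "lncRNA"), "MALAT1")
  expect_error(normalize_id("  ", "protein"), "empty identifier")
})

test_that("normalization is idempotent over a random-case corpus", {
  set.seed(42)
  stems <- c("hsa-miR-125b-5p", "hsa-miR-34a", "hsa-let-7a-3p", "miR-1-3p",
             "mir-200a", "TP53", "ccnd1", "MALAT1 ")
  flip_case <- function(s) {
    chars <- strsplit(s, "")[[1]]
    flip <- stats::runif(length(chars)) < 0.5
    chars[flip] <- toupper(chars[flip])
    chars[!flip] <- tolower(chars[!flip])
    paste(chars, collapse = "")
  }
  for (cls in c("miRNA", "mRNA")) {
    pool <- if (cls == "miRNA") stems[1:5] else stems[6:8]
    variants <- replicate(5000, flip_case(sample(pool, 1)))
    once <- normalize_id(variants, cls)
    expect_identical(normalize_id(once, cls), once)
  }
})

test_that("direction tokens parse case-insensitively and by numeric sign", {
  expect_equal(parse_direction(c("UP", "Down", "down", "up")),
               c("up", "down", "down", "up"))
  expect_equal(parse_direction(c("+1", "-1", "2", "-0.5")),
               c("up", "down", "up", "down"))
  expect_error(parse_direction(c("up", "unchanged")), "unknown direction")
  expect_error(parse_direction("0"), "unknown direction")
})

test_that("expression tables load, validate, and collapse duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment line",
    "molecule_id\tclass\tstudy_id\tdirection",
    "tp53\tmRNA\ts1\tUP",
    "ccnd1\tmRNA\ts1\tdown",
    "ccnd1\tmRNA\ts2\tDown",
    "tp53\tmRNA\ts1\tup"   # exact duplicate after normalization
  ), path)
  expect_warning(ev <- read_expression_table(path), "duplicate")
  expect_equal(nrow(ev), 3)
  expect_setequal(ev$molecule_id, c("TP53", "CCND1"))
  expect_true(all(ev$direction %in% c("up", "down")))
})

test_that("expression loader rejects malformed files with typed errors", {
  bad_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("molecule_id\tstudy_id", "A\ts1"), bad_col)
  expect_error(read_expression_table(bad_col, "mRNA"), "missing required column")

  bad_tok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("molecule_id\tstudy_id\tdirection", "A\ts1\tsideways"), bad_tok)
  expect_error(read_expression_table(bad_tok, "mRNA"), "unknown direction")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_expression_table(empty, "mRNA"))
  expect_error(read_expression_table("no/such/file.tsv", "mRNA"), "not found")
})

test_that("alias tables apply before normalization", {
  aliases <- tibble::tibble(alias = c("p53", "beta-catenin"),
                            canonical = c("TP53", "CTNNB1"))
  expect_equal(normalize_id(apply_aliases(c("p53", "MYC"), aliases), "mRNA"),
               c("TP53", "MYC"))
})

test_that("miRNA-target tables enforce the predicted-needs-CWCS invariant and merge duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mirna_id\ttarget_symbol\tconfidence\tcwcs\tevidence_methods",
    "miR-21-5p\ttp53\tobserved\tNA\treporter_assay",
    "miR-21-5p\tTP53\tpredicted\t-0.55\tmicroarray",
    "miR-1-3p\tptma\tpredicted\t-0.41\t"
  ), path)
  cat <- read_mir_target_table(path)
  expect_equal(nrow(cat), 2)
  merged <- cat[cat$mirna_id == "hsa-miR-21-5p", ]
  expect_equal(merged$confidence, "observed")
  expect_equal(merged$cwcs, -0.55)
  expect_equal(merged$evidence_methods, "microarray;reporter_assay")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mirna_id\ttarget_symbol\tconfidence\tcwcs\tevidence_methods",
    "miR-21-5p\tTP53\tpredicted\tNA\t"
  ), bad)
  expect_error(read_mir_target_table(bad), "without a CWCS")
})

test_that("PPI tables scale 0-1 scores, canonicalize edge order, drop self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_a\tprotein_b\tcombined_score",
    "B\ta\t0.9",
    "A\tb\t905",
    "C\tC\t999",
    "D\te\t0.123"
  ), path)
  expect_warning(ppi <- read_ppi_table(path), "self-loop")
  expect_equal(nrow(ppi), 2)
  ab <- ppi[ppi$protein_a == "A", ]
  expect_equal(ab$protein_b, "B")
  expect_equal(ab$combined_score, 905L)  # duplicate pair keeps the max
  expect_equal(ppi$combined_score[ppi$protein_a == "D"], 123L)
})

test_that("GMT collections round-trip with normalized, deduplicated members", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "SET_A\tdesc\ttp53\tCCND1\tTP53",
    "SET_B\tdesc\tmyc",
    "EMPTY\tdesc"
  ), path)
  expect_warning(sets <- read_gmt(path), "no members")
  expect_equal(names(sets), c("SET_A", "SET_B"))
  expect_equal(sets$SET_A, c("CCND1", "TP53"))
  back <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, back)
  expect_equal(read_gmt(back), sets)
})

test_that("network export writes SIF lines and survives a GraphML round trip", {
  nodes <- tibble::tibble(id = c("L1", "m1", "G1"),
                          node_class = c("lncRNA", "miRNA", "mRNA"),
                          direction = c("up", "down", "up"))
  edges <- tibble::tibble(from = c("L1", "m1"), to = c("m1", "G1"),
                          relation = c("sponges", "targets"),
                          evidence_tier = c("strong", "less_strong"))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(nodes, edges, sif, "sif")
  expect_equal(readLines(sif), c("L1\tsponges\tm1", "m1\ttargets\tG1"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(nodes, edges, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_setequal(back$nodes$id, nodes$id)
  expect_equal(nrow(back$edges), 2)
  expect_setequal(back$edges$evidence_tier, edges$evidence_tier)
  expect_equal(back$nodes$node_class[match(nodes$id, back$nodes$id)],
               nodes$node_class)

  expect_error(write_network(nodes, edges, sif, "xgmml"), "unknown network format")
  expect_warning(write_network(nodes[0, ], edges[0, ], sif, "sif"), "empty network")
})

test_that("packaged examples reload identically after a write/read cycle", {
  fx <- suppressMessages(load_example("fig7_ezh2_ptma"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  ev <- fx$evidence
  names(ev)[names(ev) == "molecule_class"] <- "class"
  write_tsv_plain(ev, tmp)
  expect_equal(suppressMessages(read_expression_table(tmp)), fx$evidence)
  write_tsv_plain(fx$mir_catalog, tmp)
  expect_equal(read_mir_target_table(tmp), fx$mir_catalog)
  write_tsv_plain(fx$lnc_catalog, tmp)
  expect_equal(read_lnc_mir_table(tmp), fx$lnc_catalog)
})
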