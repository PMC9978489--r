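test_that("arm expansion follows the -3p/-5p rule and is idempotent", {
  expect_equal(expand_arms("hsa-miR-34a-5p"), "hsa-miR-34a-5p")
  expect_setequal(expand_arms("hsa-miR-125b"),
                  c("hsa-miR-125b-3p", "hsa-miR-125b-5p"))
  for (arm in expand_arms("hsa-miR-125b")) {
    expect_equal(expand_arms(arm), arm)
  }
})

test_that("evidence tiering needs at least one functionally validated method", {
  expect_equal(tier_mir_target("reporter_assay;microarray"), "strong")
  expect_equal(tier_mir_target("western_blot"), "strong")
  expect_equal(tier_mir_target("qpcr"), "strong")
  expect_equal(tier_mir_target("clip_seq"), "less_strong")
  expect_equal(tier_mir_target(""), "less_strong")
  expect_equal(tier_mir_target(c("qpcr", "ngs;psilac")),
               c("strong", "less_strong"))
})

test_that("the packaged EZH2/PTMA example assembles exactly its six reported axes", {
  fx <- suppressMessages(load_example("fig7_ezh2_ptma"))
  res <- suppressMessages(
    assemble_triads(c("EZH2", "PTMA"), fx$mir_catalog, fx$lnc_catalog, fx$calls))
  expect_equal(nrow(res$triads), 6)
  expect_equal(res$anchors_without_triads, character(0))
  expect_true(all(res$triads$consistent))
  expect_true(all(res$triads$mir_target_tier == "strong"))
  key <- paste(res$triads$lncrna_id, res$triads$mirna_id, res$triads$target_symbol)
  expect_setequal(key, c(
    "TUG1 hsa-miR-26a-5p EZH2", "MALAT1 hsa-miR-26a-5p EZH2",
    "NEAT1 hsa-miR-101-3p EZH2", "MALAT1 hsa-miR-101-3p EZH2",
    "TUG1 hsa-miR-1-3p PTMA", "MALAT1 hsa-miR-1-3p PTMA"
  ))
})

test_that("a lncRNA moving against the anchor breaks sponge consistency", {
  fx <- suppressMessages(load_example("fig7_ezh2_ptma"))
  calls <- fx$calls
  calls$direction[calls$molecule_id == "TUG1"] <- "down"
  res <- suppressMessages(
    assemble_triads(c("EZH2", "PTMA"), fx$mir_catalog, fx$lnc_catalog, calls))
  expect_equal(nrow(res$triads), 4)
  expect_false("TUG1" %in% res$triads$lncrna_id)
})

test_that("anchors without a direction call raise an error naming them", {
  fx <- suppressMessages(load_example("fig7_ezh2_ptma"))
  expect_error(
    suppressMessages(assemble_triads(c("EZH2", "NOVEL1"), fx$mir_catalog,
                                     fx$lnc_catalog, fx$calls)),
    "NOVEL1")
})

random_cerna_instance <- function(seed) {
  set.seed(seed)
  mirs <- c(sprintf("hsa-miR-%d-5p", 1:4), sprintf("hsa-miR-%d", 5:6))
  genes <- sprintf("G%d", 1:4)
  lncs <- sprintf("L%d", 1:4)
  arms <- unique(unlist(lapply(mirs, expand_arms)))
  mir_catalog <- tibble::tibble(
    mirna_id = sample(mirs, 12, replace = TRUE),
    target_symbol = sample(genes, 12, replace = TRUE),
    confidence = sample(c("observed", "predicted"), 12, replace = TRUE),
    evidence_methods = sample(c("reporter_assay", "microarray", ""), 12, replace = TRUE)
  )
  mir_catalog$cwcs <- ifelse(mir_catalog$confidence == "predicted",
                             stats::runif(12, -0.8, -0.1), NA_real_)
  mir_catalog <- dplyr::distinct(mir_catalog, .data$mirna_id,
                                 .data$target_symbol, .keep_all = TRUE)
  lnc_catalog <- dplyr::distinct(tibble::tibble(
    lncrna_id = sample(lncs, 10, replace = TRUE),
    mirna_id = sample(arms, 10, replace = TRUE),
    tier = sample(c("strong", "less_strong"), 10, replace = TRUE)
  ), .data$lncrna_id, .data$mirna_id, .keep_all = TRUE)
  calls <- tibble::tibble(
    molecule_id = c(mirs, arms, genes, lncs),
    molecule_class = c(rep("miRNA", length(mirs) + length(arms)),
                       rep("mRNA", length(genes)), rep("lncRNA", length(lncs))),
    direction = sample(c("up", "down"), length(mirs) + length(arms) +
                         length(genes) + length(lncs), replace = TRUE)
  )
  calls <- dplyr::distinct(calls, .data$molecule_id, .data$molecule_class,
                           .keep_all = TRUE)
  list(mir_catalog = mir_catalog, lnc_catalog = lnc_catalog, calls = calls,
       anchors = genes)
}

test_that("triad assembly equals a brute-force triple-loop oracle on random catalogs", {
  for (seed in 1:100) {
    inst <- random_cerna_instance(seed)
    res <- suppressMessages(
      assemble_triads(inst$anchors, inst$mir_catalog, inst$lnc_catalog,
                      inst$calls))
    expect_equal(nrow(res$triads),
                 oracle_triads(inst$anchors, inst$mir_catalog,
                               inst$lnc_catalog, inst$calls))
  }
})

test_that("reversing every direction call leaves the consistent triad set unchanged", {
  for (seed in 1:20) {
    inst <- random_cerna_instance(seed)
    res <- suppressMessages(
      assemble_triads(inst$anchors, inst$mir_catalog, inst$lnc_catalog, inst$calls))
    flipped <- inst$calls
    flipped$direction <- ifelse(flipped$direction == "up", "down", "up")
    res2 <- suppressMessages(
      assemble_triads(inst$anchors, inst$mir_catalog, inst$lnc_catalog, flipped))
    key <- function(tr) sort(paste(tr$lncrna_id, tr$mirna_id, tr$target_symbol))
    expect_equal(key(res2$triads), key(res$triads))
  }
})

test_that("removing a lncRNA never increases the triad count", {
  for (seed in 1:20) {
    inst <- random_cerna_instance(seed)
    res <- suppressMessages(
      assemble_triads(inst$anchors, inst$mir_catalog, inst$lnc_catalog, inst$calls))
    drop_lnc <- inst$lnc_catalog[inst$lnc_catalog$lncrna_id != "L1", ]
    res2 <- suppressMessages(
      assemble_triads(inst$anchors, inst$mir_catalog, drop_lnc, inst$calls))
    expect_lte(nrow(res2$triads), nrow(res$triads))
  }
})

test_that("triad export produces an attributed tri-partite network", {
  fx <- suppressMessages(load_example("fig7_ezh2_ptma"))
  res <- suppressMessages(
    assemble_triads(c("EZH2", "PTMA"), fx$mir_catalog, fx$lnc_catalog, fx$calls))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_cerna_network(res$triads, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_equal(sum(back$nodes$node_class == "lncRNA"), 3)
  expect_equal(sum(back$nodes$node_class == "miRNA"), 3)
  expect_equal(sum(back$nodes$node_class == "mRNA"), 2)
  expect_setequal(unique(back$edges$relation), c("sponges", "targets"))
  expect_true(all(back$edges$evidence_tier %in% c("strong", "less_strong")))

  one <- res$triads[1, ]
  sif <- withr::local_tempfile(fileext = ".sif")
  export_cerna_network(one, sif, "sif")
  expect_length(readLines(sif), 2)
  expect_error(export_cerna_network(res$triads[0, ], sif, "sif"), "empty triad")
})
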