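test_that("AMR and VF retention honors the published thresholds inclusively", {
  amr <- safety_panel("AMR"); vf <- safety_panel("VF")
  mk <- function(cov, id) data.frame(genome_id = "G", gene = "tet(M)",
                                     coverage = cov, identity = id)
  expect_true(filter_alignment_hits(mk(0.50, 90.0), amr)$retained)
  expect_false(filter_alignment_hits(mk(0.49, 99), amr)$retained)
  expect_false(filter_alignment_hits(mk(0.80, 89.9), amr)$retained)
  expect_true(filter_alignment_hits(mk(0.70, 90.0), vf)$retained)
  expect_false(filter_alignment_hits(mk(0.69, 99), vf)$retained)
  # malformed rows are rejected with a reason, not an error
  bad <- filter_alignment_hits(mk(NA, 95), amr)
  expect_false(bad$retained)
  expect_equal(bad$reason, "MALFORMED")
})

test_that("raising min_identity never grows the retained set", {
  set.seed(19)
  raw <- data.frame(genome_id = "G", gene = letters[1:50],
                    coverage = runif(50), identity = runif(50, 60, 100))
  pan <- safety_panel("AMR")
  prev <- NULL
  for (thr in c(80, 85, 90, 95, 99)) {
    pan$min_identity <- thr
    kept <- which(filter_alignment_hits(raw, pan)$retained)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("term screens hit gene symbols and synonyms with boundary guards", {
  ba <- safety_panel("BA"); hem <- safety_panel("HEMOLYSIN")
  g <- annotated_genome(
    products = c("Histidine decarboxylase", "hypothetical protein",
                 "crystallin", "hypothetical protein"),
    genes = c("hdcA", "hlyIII", NA, "cylA"))
  hb <- screen_terms(g, ba)
  expect_equal(unique(hb$gene), "hdcA")
  hh <- screen_terms(g, hem)
  expect_setequal(hh$gene, c("hly", "cyl"))
  # "crystallin" must not trigger the cyl pattern
  expect_false(g$features$locus_tag[3] %in% hh$locus_tag)
})

test_that("species prevalence is genome-deduplicated percentage", {
  meta <- data.frame(genome_id = sprintf("G%02d", 1:32),
                     species = rep("L. iners", 32))
  # 7 genomes carry msr(D), one of them twice
  hits <- data.frame(genome_id = c(sprintf("G%02d", 1:7), "G01"),
                     panel_id = "AMR", gene = "msr(D)", retained = TRUE)
  prof <- safety_profile(hits, meta)
  expect_equal(prof$prevalence, 100 * 7 / 32)  # 21.875 ~ printed 21.9
  expect_equal(round(prof$prevalence, 1), 21.9)

  # a gene carried only by another species keeps a 0% row here
  meta2 <- rbind(meta, data.frame(genome_id = "H01", species = "L. reuteri"))
  hits2 <- rbind(hits, data.frame(genome_id = "H01", panel_id = "AMR",
                                  gene = "tet(M)", retained = TRUE))
  prof2 <- safety_profile(hits2, meta2)
  row0 <- prof2[prof2$species == "L. iners" & prof2$gene == "tet(M)", ]
  expect_equal(nrow(row0), 1L)
  expect_equal(row0$prevalence, 0)
})

test_that("retention matches the manifest on planted safety genes", {
  co <- tiny_cohort()
  res <- safety_screen_cohort(co$genomes, co$safety_hits, co$metadata)
  sf <- co$truth$safety
  al <- sf[sf$panel %in% c("AMR", "VF"), , drop = FALSE]
  for (i in seq_len(nrow(al))) {
    pan <- safety_panel(al$panel[i])
    # planted values are >= 2 points from every boundary by design
    expected <- al$realized_coverage[i] >= pan$min_coverage &&
      al$realized_identity[i] >= pan$min_identity
    got <- res$hits[res$hits$genome_id == al$genome_id[i] &
                      res$hits$gene == al$gene_name[i] &
                      res$hits$panel_id == al$panel[i], ]
    expect_true(expected %in% got$retained,
                label = paste(al$genome_id[i], al$gene_name[i]))
  }
  # term-planted genes all recovered
  tm <- sf[!(sf$panel %in% c("AMR", "VF")), , drop = FALSE]
  for (i in seq_len(nrow(tm))) {
    got <- res$hits[res$hits$genome_id == tm$genome_id[i] &
                      res$hits$gene == tm$gene_name[i], ]
    expect_gte(nrow(got), 1L)
  }
})

test_that("the internal nucleotide aligner reproduces planted identity/coverage", {
  co <- tiny_cohort()
  sf <- co$truth$safety
  al <- sf[sf$panel %in% c("AMR", "VF"), , drop = FALSE]
  expect_gt(nrow(al), 0)
  i <- 1L
  g <- co$genomes[[al$genome_id[i]]]
  frag <- substr(g$contigs[[al$contig_id[i]]], al$start[i], al$end[i])
  refs <- synthetic_safety_panel()
  ref <- refs$sequence[refs$gene_name == al$gene_name[i]]
  st <- local_align_nt(frag, ref)
  expect_equal(st$percent_identity, al$realized_identity[i], tolerance = 0.02)
  # planted fragment aligns end to end, so subject-side coverage equals
  # the planted truncation fraction
  expect_equal(st$query_coverage, 1.0, tolerance = 0.02)
})
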