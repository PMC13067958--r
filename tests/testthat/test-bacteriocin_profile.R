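mk_hit <- function(start, end, name = "Plantaricin E", role = "structural",
                   score = 100, genome = "G1", contig = "c1") {
  data.frame(genome_id = genome, contig_id = contig, start = start,
             end = end, name = name, role = role, score = score,
             stringsAsFactors = FALSE)
}

test_that("overlapping same-name structural hits consolidate to one locus", {
  two <- rbind(mk_hit(100, 400, score = 90), mk_hit(150, 420, score = 80))
  loci <- consolidate(two)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 100)  # highest-scoring span kept
  # different names stay distinct even when adjacent
  ab <- rbind(mk_hit(100, 400, "Plantaricin E"),
              mk_hit(401, 700, "Plantaricin F"))
  expect_equal(nrow(consolidate(ab)), 2L)
  # non-structural roles never create loci
  sat <- rbind(mk_hit(100, 400), mk_hit(500, 900, role = "immunity"),
               mk_hit(1000, 1400, role = "transport"))
  expect_equal(nrow(consolidate(sat)), 1L)
})

test_that("consolidation agrees with an all-pairs overlap oracle and is idempotent", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    starts <- sample(1:3000, n, replace = TRUE)
    hits <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_hit(starts[i], starts[i] + sample(80:400, 1),
             name = sample(c("Plantaricin E", "Pediocin"), 1),
             role = sample(c("structural", "immunity"), 1, prob = c(0.8, 0.2)),
             score = runif(1, 10, 100))))
    loci <- consolidate(hits)
    expect_equal(nrow(loci), consolidate_oracle_count(hits))
    # idempotence: re-consolidating the loci changes nothing
    again <- consolidate(cbind(loci[, c("genome_id", "contig_id", "start",
                                        "end", "name", "score")],
                               role = "structural"))
    expect_equal(nrow(again), nrow(loci))
  }
})

test_that("ten raw hits with four span+name duplicates give six loci", {
  hits <- rbind(
    mk_hit(100, 300), mk_hit(100, 300),          # duplicate pair 1
    mk_hit(1000, 1200), mk_hit(1005, 1195),      # duplicate pair 2
    mk_hit(2000, 2300, "Pediocin"), mk_hit(2010, 2310, "Pediocin"),
    mk_hit(3000, 3200, "Nisin A"), mk_hit(3005, 3205, "Nisin A"),
    mk_hit(5000, 5200, "Enterolysin A"),
    mk_hit(6000, 6200, "Helveticin J"))
  loci <- consolidate(hits)
  expect_equal(nrow(loci), 6L)
  expect_equal(nrow(loci), consolidate_oracle_count(hits))
})

test_that("subclass assignment is normalized lookup with 'other' fallback", {
  expect_equal(assign_subclass("Nisin A"), "I")
  expect_equal(assign_subclass("Pediocin"), "IIa")
  expect_equal(assign_subclass("Enterolysin A"), "III")
  expect_equal(assign_subclass("  enterolysin   a "), "III")
  expect_equal(assign_subclass("Completely Unknown Peptide"), "other")
})

test_that("species summaries follow the published schema", {
  meta <- data.frame(genome_id = c("G1", "G2", "G3", "G4"),
                     species = "SpA")
  loci <- rbind(mk_hit(1, 100, "Plantaricin E", genome = "G1"),
                mk_hit(200, 300, "Plantaricin E", genome = "G2"),
                mk_hit(400, 500, "Pediocin", genome = "G2"))
  loci$role <- NULL
  s <- species_summary(loci, meta)
  expect_equal(s$pct_with_any, 50.0)  # 2 of 4 genomes
  expect_equal(s$total_abundance, 3L)
  expect_equal(s$unique_types, 2L)
  expect_equal(s$dominant, "Plantaricin E; Pediocin")
  # zero-loci species
  meta0 <- data.frame(genome_id = "H1", species = "SpB")
  s0 <- species_summary(loci[0, ], meta0)
  expect_equal(s0$total_abundance, 0L)
  expect_equal(s0$unique_types, 0L)
  expect_equal(s0$dominant, "None")
  expect_equal(s0$tier, "low_none")
})

test_that("the tier rule reproduces every published species note", {
  tab <- read_tsv_strict(system.file(
    "extdata", "lactobacillaceae_bacteriocin_summary.tsv",
    package = "probioscreen"))
  expect_equal(nrow(tab), 35L)
  expected <- c("Strong producer" = "strong", "Moderate" = "moderate",
                "Low/none" = "low_none")[tab$notes]
  expect_equal(bacteriocin_tier(tab$total_abundance), unname(expected))
})

test_that("subclass composition rows are proportions that recover counts", {
  meta <- data.frame(genome_id = c("G1", "G2"), species = c("SpA", "SpB"))
  loci <- rbind(mk_hit(1, 100, "Plantaricin E"),      # IIb
                mk_hit(200, 300, "Plantaricin F"),    # IIb
                mk_hit(400, 500, "Plantaricin J"),    # IIb
                mk_hit(600, 700, "Enterolysin A"))    # III
  loci$role <- NULL
  comp <- subclass_composition(loci, meta)
  expect_equal(unname(comp["SpA", "IIb"]), 0.75)
  expect_equal(unname(comp["SpA", "III"]), 0.25)
  expect_equal(sum(comp["SpA", ]), 1)
  # counts recovered from proportions x abundance
  expect_equal(unname(comp["SpA", ] * 4), c(I = 0, IIa = 0, IIb = 3, IIc = 0,
                                            IId = 0, III = 1, other = 0),
               ignore_attr = TRUE)
  # zero-loci species flagged, all-zero row
  expect_equal(attr(comp, "no_loci"), "SpB")
  expect_equal(sum(comp["SpB", ]), 0)
})

test_that("cohort composition equals the manifest's planted frequencies", {
  co <- tiny_cohort()
  loci <- consolidate(co$bacteriocin_hits)
  truth <- co$truth$bacteriocins
  # conservation: one locus per planted structural gene
  expect_equal(nrow(loci), nrow(truth))
  s <- species_summary(loci, co$metadata)
  expect_equal(sum(s$total_abundance), nrow(loci))
  comp <- subclass_composition(loci, co$metadata)
  for (sp in unique(co$metadata$species)) {
    ids <- co$metadata$genome_id[co$metadata$species == sp]
    tr <- truth[truth$genome_id %in% ids, ]
    if (!nrow(tr)) next
    expected <- table(factor(tr$subclass, levels = colnames(comp))) / nrow(tr)
    expect_equal(unname(comp[sp, ]), as.numeric(expected),
                 label = sp)
  }
})
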