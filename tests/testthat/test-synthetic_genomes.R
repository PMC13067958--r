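test_that("simulation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_species = 1, genomes_per_species = 2,
                       genome_length_range = c(8000, 12000),
                       pangenome_plan = list(n_core_families = 5,
                                             accessory_pool = 0,
                                             accessory_rate = 0,
                                             unique_gene_rate = 2),
                       seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("a degenerate GC range pins contig GC within one point", {
  cfg <- cohort_config(n_species = 1, genomes_per_species = 3,
                       genome_length_range = c(20000, 25000),
                       gc_range = c(0.40, 0.40),
                       pangenome_plan = list(n_core_families = 15,
                                             accessory_pool = 0,
                                             accessory_rate = 0,
                                             unique_gene_rate = 5),
                       seed = 9)
  co <- simulate_cohort(cfg)
  for (g in co$genomes) {
    m <- compute_metrics(g)
    expect_true(abs(m$gc_percent / 100 - 0.40) < 0.01)
  }
})

test_that("probability-one plants appear in every genome's manifest", {
  plan <- data.frame(marker_id = "bsh", plant_mode = "exact",
                     target_identity = NA, probability = 1)
  cfg <- cohort_config(n_species = 2, genomes_per_species = 10,
                       genome_length_range = c(8000, 12000),
                       marker_plan = plan, bacteriocin_plan = NULL,
                       safety_plan = NULL,
                       pangenome_plan = list(n_core_families = 4,
                                             accessory_pool = 0,
                                             accessory_rate = 0,
                                             unique_gene_rate = 1),
                       seed = 5)
  co <- simulate_cohort(cfg)
  mk <- co$truth$markers
  expect_equal(nrow(mk), 20L)
  expect_setequal(mk$genome_id, names(co$genomes))
  expect_true(all(mk$marker_id == "bsh" & mk$mode == "exact"))
})

test_that("every planted feature is discoverable and none is phantom", {
  co <- tiny_cohort()
  for (tab in list(co$truth$markers, co$truth$bacteriocins)) {
    if (is.null(tab)) next
    for (i in seq_len(nrow(tab))) {
      g <- co$genomes[[tab$genome_id[i]]]
      expect_true(tab$locus_tag[i] %in% g$features$locus_tag)
    }
  }
  # safety segments land inside their contigs
  sf <- co$truth$safety
  al <- sf[!is.na(sf$start), , drop = FALSE]
  for (i in seq_len(nrow(al))) {
    g <- co$genomes[[al$genome_id[i]]]
    expect_lte(al$end[i], nchar(g$contigs[[al$contig_id[i]]]))
  }
  # no phantom locus tags
  all_tags <- unlist(lapply(co$genomes, function(g) g$features$locus_tag))
  planted <- c(co$truth$markers$locus_tag, co$truth$bacteriocins$locus_tag,
               sf$locus_tag[!is.na(sf$locus_tag)])
  expect_true(all(planted %in% all_tags))
})

test_that("plant_marker controls mode, identity and annotation text", {
  set.seed(31)
  refs <- synthetic_reference_panel()
  ref <- refs$sequence[refs$marker_id == "bsh"][1]
  co <- tiny_cohort()
  g <- co$genomes[[1]]

  ex <- plant_marker(g, ref, "exact", "bsh")
  expect_equal(ex$truth$realized_identity, 100)
  expect_equal(as.character(extract_protein(ex$genome, ex$truth$locus_tag)),
               ref)

  ref200 <- random_peptide(200)
  dv <- plant_marker(g, ref200, "diverged", "bsh", target_identity = 50)
  expect_gte(dv$truth$realized_identity, 47)
  expect_lte(dv$truth$realized_identity, 53)

  dc <- plant_marker(g, ref, "decoy", "bsh")
  prod <- dc$genome$features$product[dc$genome$features$locus_tag ==
                                       dc$truth$locus_tag]
  panel <- load_panel()
  expect_true(grepl(panel$pattern[panel$marker_id == "bsh"], prod,
                    ignore.case = TRUE, perl = TRUE))

  expect_error(plant_marker(g, ref, "diverged", "bsh", target_identity = 3),
               "5%")
})

test_that("planted genes are written and recoverable through the GFF3 path", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  id <- co$truth$markers$genome_id[1]
  g <- read_annotated_genome(
    file.path(dir, "genomes", paste0(id, ".gff3")),
    file.path(dir, "genomes", paste0(id, ".fna")),
    file.path(dir, "genomes", paste0(id, ".faa")), genome_id = id)
  tags <- co$truth$markers$locus_tag[co$truth$markers$genome_id == id]
  expect_true(all(tags %in% g$features$locus_tag))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
})

test_that("infeasible plans are rejected as config errors", {
  cfg <- cohort_config(n_species = 1, genomes_per_species = 1,
                       genome_length_range = c(500, 600),
                       pangenome_plan = list(n_core_families = 100,
                                             accessory_pool = 0,
                                             accessory_rate = 0,
                                             unique_gene_rate = 0),
                       seed = 2)
  expect_error(simulate_cohort(cfg), "infeasible")
})
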