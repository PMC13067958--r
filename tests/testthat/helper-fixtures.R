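# Fixture builders. Heavy cohorts are cached for the duration of a test
# run so several test files can share them.

.fix_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) assign(key, builder(), envir = .fix_cache)
  .fix_cache[[key]]
}

# small mixed cohort exercising every planted feature type
tiny_cohort <- function() cached_fixture("tiny", function() {
  simulate_cohort(cohort_config(
    n_species = 2, genomes_per_species = c(4, 3),
    genome_length_range = c(15000, 25000),
    pangenome_plan = list(n_core_families = 10, accessory_pool = 10,
                          accessory_rate = 0.5, unique_gene_rate = 3),
    seed = 42))
})

# study-condition cohort for planted-marker recovery: 3 species x 12
# genomes, ~150 genes each; every plant deterministic (probability 1) so
# recovery ratios are exact.
recall_cohort <- function() cached_fixture("recall", function() {
  plan <- data.frame(
    marker_id = c("bsh", "gadB", "atpA", "dnaK", "srtA", "clpP", "dltA",
                  "bsh", "dnaK", "srtA", "gadB", "atpA", "clpP"),
    plant_mode = c(rep("exact", 7), rep("decoy", 3), "diverged", "diverged",
                   "diverged"),
    target_identity = c(rep(NA, 10), 60, 60, 20),
    probability = 1,
    stringsAsFactors = FALSE)
  simulate_cohort(cohort_config(
    n_species = 3, genomes_per_species = 12,
    genome_length_range = c(60000, 120000),
    marker_plan = plan, seed = 271828))
})

# pan-genome recovery fixture: 20 core families + 5 unique genes per
# genome across 15 genomes, no planted extras.
pangenome_cohort <- function() cached_fixture("pangenome", function() {
  simulate_cohort(cohort_config(
    n_species = 1, genomes_per_species = 15,
    genome_length_range = c(18000, 24000),
    marker_plan = NULL, bacteriocin_plan = NULL, safety_plan = NULL,
    pangenome_plan = list(n_core_families = 20, accessory_pool = 0,
                          accessory_rate = 0, unique_gene_rate = 5),
    seed = 1415))
})

# a minimal hand-built genome with controlled annotation text
annotated_genome <- function(products, genes = NA_character_,
                             notes = NA_character_, id = "GX01") {
  n <- length(products)
  genes <- rep_len(genes, n); notes <- rep_len(notes, n)
  aa <- vapply(rep(40, n), random_peptide, "")
  # placeholder spans on a random contig; annotation text is what matters
  contig <- paste(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""), ""),
    collapse = "")
  feats <- data.frame(
    locus_tag = sprintf("%s_%04d", id, seq_len(n)),
    contig_id = "c1",
    start = (seq_len(n) - 1L) * 500L + 1L,
    end = (seq_len(n) - 1L) * 500L + 120L,
    strand = "+", gene_name = genes, product = products, note = notes,
    translation = aa, translation_source = "self",
    stringsAsFactors = FALSE)
  genome_record(id, "Species_T", "Genus_T", "human",
                c(c1 = contig), feats, 99, 0.5)
}

# write a small GFF3+FASTA fixture by hand; returns the three paths
write_gff3_fixture <- function(dir, contigs, rows, protein_fasta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "fx.gff3")
  fna <- file.path(dir, "fx.fna")
  writeLines(c("##gff-version 3", rows), gff)
  writeLines(unlist(lapply(names(contigs), function(nm)
    c(paste0(">", nm), contigs[[nm]]))), fna)
  faa <- NULL
  if (!is.null(protein_fasta)) {
    faa <- file.path(dir, "fx.faa")
    writeLines(unlist(lapply(names(protein_fasta), function(nm)
      c(paste0(">", nm), protein_fasta[[nm]]))), faa)
  }
  list(gff3 = gff, fna = fna, faa = faa)
}
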