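# Seeded synthetic cohorts with planted, labeled features.
#
# The generator emulates the cohort structure of a family-wide LAB survey
# at desk scale: several species with uneven genome counts, genome sizes
# and GC spanning the observed ranges (scaled down), six isolation-source
# categories, planted probiotic-marker genes (exact, diverged and decoy
# variants), planted bacteriocin loci with known subclasses, planted
# safety genes with controlled identity/coverage, and a gene-family
# structure (core/accessory/unique) that yields an open pan-genome.
# Background sequence is i.i.d. at the configured GC; divergence is by
# substitution only, so realized coverage stays 100% unless a coverage
# target truncates a safety plant.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.code11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("11")
    cache
  }
})

.random_protein <- function(len) paste(sample(.aa_alphabet, len, TRUE), collapse = "")

# vectorized translation (table 11, trailing stop trimmed)
.translate_batch <- function(nts) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nts),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

.random_dna <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, TRUE, prob = p), collapse = "")
}

# n_codons stop-free random codons at base composition gc
.random_codons <- function(n_codons, gc) {
  code <- .code11()
  stops <- names(code)[code == "*"]
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(n) {
    m <- matrix(sample(names(p), 3 * n, TRUE, prob = p), ncol = 3)
    paste0(m[, 1], m[, 2], m[, 3])
  }
  codons <- draw(n_codons)
  bad <- codons %in% stops
  while (any(bad)) {
    codons[bad] <- draw(sum(bad))
    bad <- codons %in% stops
  }
  codons
}

# resample `rate` of codons (new stop-free codons at gc); the per-copy
# divergence is capped at max_frac of codons so any two copies of a family
# reference stay within 2 * max_frac of each other (>= 98% identity at the
# default), keeping planted families well inside the clustering threshold
.mutate_codons <- function(nt, rate, gc, max_frac = 0.01) {
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  n <- length(codons)
  k <- min(rbinom(1, n, rate), floor(max_frac * n))
  if (k > 0) {
    idx <- sample.int(n, k)
    codons[idx] <- .random_codons(k, gc)
  }
  paste(codons, collapse = "")
}

# synonymous codon sampled with stationary weights at base composition gc
.reverse_translate <- function(aa, gc) {
  code <- .code11()
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  syn <- split(names(code)[code != "*"], code[code != "*"])
  w <- lapply(syn, function(cs) {
    vapply(cs, function(cd) prod(p[strsplit(cd, "")[[1]]]), 0)
  })
  res <- strsplit(aa, "")[[1]]
  .assert(all(res %in% names(syn)), "cannot reverse-translate residue(s): ",
          paste(setdiff(res, names(syn)), collapse = ","))
  codons <- vapply(res, function(r) sample(syn[[r]], 1L, prob = w[[r]]), "")
  paste0(paste(codons, collapse = ""), "TAA")
}

# substitute exactly k positions to a different residue
.substitute_aa <- function(aa, k) {
  res <- strsplit(aa, "")[[1]]
  if (k == 0) return(aa)
  idx <- sample.int(length(res), k)
  res[idx] <- vapply(res[idx], function(r)
    sample(setdiff(.aa_alphabet, r), 1L), "")
  paste(res, collapse = "")
}

# substitute exactly k nucleotide positions to a different base
.substitute_nt <- function(nt, k) {
  res <- strsplit(nt, "")[[1]]
  if (k == 0) return(nt)
  idx <- sample.int(length(res), k)
  res[idx] <- vapply(res[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(res, collapse = "")
}

# -- plans and config -------------------------------------------------------

#' Default planting plans for synthetic cohorts
#'
#' The default marker plan exercises the seven sequence-validated markers
#' with a mix of exact plants, 60%-identity diverged plants and decoys
#' (marker-like product on an unrelated sequence). The bacteriocin plan
#' spans the six subclasses; the safety plan places AMR/VF genes on both
#' sides of the published retention thresholds plus term-screen plants.
#'
#' @return A `data.frame` describing the plan.
#' @export
default_marker_plan <- function() {
  data.frame(
    marker_id = c("bsh", "gadB", "atpA", "dnaK", "srtA", "clpP", "dltA",
                  "bsh", "gadB", "bsh", "dnaK", "srtA"),
    plant_mode = c(rep("exact", 7), "diverged", "diverged", rep("decoy", 3)),
    target_identity = c(rep(NA, 7), 60, 60, rep(NA, 3)),
    probability = c(rep(0.9, 7), 0.3, 0.3, rep(0.2, 3)),
    stringsAsFactors = FALSE)
}

#' @rdname default_marker_plan
#' @export
default_bacteriocin_plan <- function() {
  data.frame(
    name = c("Plantaricin E", "Plantaricin F", "Pediocin", "Nisin A",
             "Enterolysin A", "Helveticin J", "Sakacin P", "Acidocin B",
             "Lacticin Z"),
    subclass = c("IIb", "IIb", "IIa", "I", "III", "III", "IIa", "IIc", "IId"),
    probability = c(0.5, 0.4, 0.3, 0.1, 0.6, 0.3, 0.2, 0.1, 0.1),
    stringsAsFactors = FALSE)
}

#' @rdname default_marker_plan
#' @export
default_safety_plan <- function() {
  data.frame(
    panel = c("AMR", "AMR", "AMR", "AMR", "VF", "VF", "BA", "BA", "HEMOLYSIN"),
    gene_name = c("tet(M)", "erm(B)", "msr(D)", "aadD", "efaA", "cbpA",
                  "hdcA", "tyrP", "hly"),
    target_identity = c(98, 95, 92, 80, 95, 96, NA, NA, NA),
    target_coverage = c(0.90, 0.80, 0.60, 0.90, 0.75, 0.60, NA, NA, NA),
    probability = c(0.2, 0.15, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' Defaults describe the scaled-down study conditions: three species of
#' twelve genomes each, roughly 150 genes per genome, genome sizes of
#' 60-120 kb, GC spanning 32.5-53%, and a source mix matching the survey's
#' category fractions.
#'
#' @param n_species Number of species.
#' @param genomes_per_species Integer vector (recycled) of genome counts.
#' @param genome_length_range Target genome length range in bp.
#' @param gc_range GC-content range (fraction).
#' @param source_mix Named weights over the six source categories.
#' @param marker_plan,bacteriocin_plan,safety_plan Planting plans (see
#'   [default_marker_plan()]); `NULL` disables a plan.
#' @param pangenome_plan List: `n_core_families` (in every genome),
#'   `accessory_pool` and `accessory_rate` (each pool family carried with
#'   that probability per genome), `unique_gene_rate` (genome-private
#'   genes per genome).
#' @param contig_range Contigs per genome (uniform integer range).
#' @param completeness_range,contamination_range Simulated CheckM-style
#'   metadata ranges (percent).
#' @param mutation_rate Per-codon resampling rate within gene families
#'   (keeps within-family identity near 99%).
#' @param seed Integer; fixes all randomness of [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_species = 3,
                          genomes_per_species = 12,
                          genome_length_range = c(60000, 120000),
                          gc_range = c(0.325, 0.53),
                          source_mix = c(fermentation = 0.18, environment = 0.08,
                                         human = 0.22, animal = 0.12,
                                         other = 0.14, missing = 0.26),
                          marker_plan = default_marker_plan(),
                          bacteriocin_plan = default_bacteriocin_plan(),
                          safety_plan = default_safety_plan(),
                          pangenome_plan = list(n_core_families = 60,
                                                accessory_pool = 120,
                                                accessory_rate = 0.5,
                                                unique_gene_rate = 25),
                          contig_range = c(1, 4),
                          completeness_range = c(96, 100),
                          contamination_range = c(0, 2),
                          mutation_rate = 0.01,
                          seed = 1L) {
  genomes_per_species <- rep_len(as.integer(genomes_per_species), n_species)
  .assert(all(genomes_per_species >= 1), "need >= 1 genome per species")
  .assert(length(genome_length_range) == 2 && all(genome_length_range > 0),
          "genome_length_range must be two positive lengths")
  .assert(all(gc_range >= 0 & gc_range <= 1) && gc_range[1] <= gc_range[2],
          "gc_range must be fractions in [0,1]")
  .assert(all(names(source_mix) %in% SOURCE_CATEGORIES) && all(source_mix >= 0),
          "source_mix must be non-negative weights over the six categories")
  for (plan in list(marker_plan, bacteriocin_plan, safety_plan))
    if (!is.null(plan) && nrow(plan) > 0)
      .assert(all(plan$probability >= 0 & plan$probability <= 1),
              "plan probabilities must lie in [0,1]")
  structure(list(n_species = n_species,
                 genomes_per_species = genomes_per_species,
                 genome_length_range = genome_length_range,
                 gc_range = gc_range, source_mix = source_mix,
                 marker_plan = marker_plan,
                 bacteriocin_plan = bacteriocin_plan,
                 safety_plan = safety_plan,
                 pangenome_plan = pangenome_plan,
                 contig_range = contig_range,
                 completeness_range = completeness_range,
                 contamination_range = contamination_range,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# -- synthetic reference panels --------------------------------------------

#' Synthetic marker reference panel
#'
#' Deterministic stand-in for a curated reference-protein database (the
#' survey's NCBI-derived panel is not redistributable): one random
#' reference protein per marker, fixed by `seed`. Planted exact/diverged
#' markers in [simulate_cohort()] are copies of these references, so
#' alignment confirmation has a consistent target.
#'
#' @param marker_ids Markers to cover; defaults to the packaged panel.
#' @param seed Seed fixing the panel (default is the package-wide panel
#'   seed so cohorts and confirmation agree).
#' @return `data.frame` with `accession`, `marker_id`, `sequence`.
#' @export
synthetic_reference_panel <- function(marker_ids = load_panel()$marker_id,
                                      seed = 20260101L) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lens <- sample(180:320, length(marker_ids), replace = TRUE)
  data.frame(accession = sprintf("SYNP%03d", seq_along(marker_ids)),
             marker_id = marker_ids,
             sequence = vapply(lens, .random_protein, ""),
             stringsAsFactors = FALSE)
}

#' Synthetic safety-gene reference panel (nucleotide)
#'
#' Deterministic random nucleotide references for the AMR and VF genes the
#' safety plan can plant; a stand-in for ResFinder/VFDB-style databases.
#'
#' @param seed Seed fixing the panel.
#' @return `data.frame` with `panel`, `gene_name`, `sequence`.
#' @export
synthetic_safety_panel <- function(seed = 20260102L) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  genes <- data.frame(
    panel = c(rep("AMR", 7), rep("VF", 3)),
    gene_name = c("tet(M)", "tet(L)", "erm(B)", "msr(D)", "aadD", "cat",
                  "blaTEM-116", "efaA", "cbpA", "esp"),
    stringsAsFactors = FALSE)
  genes$sequence <- vapply(sample(900:1500, nrow(genes), TRUE),
                           function(l) .random_dna(3 * (l %/% 3), 0.40), "")
  genes
}

# -- planting helpers -------------------------------------------------------

.lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lx <- read_tsv_strict(.pkg_file("marker_lexicon.tsv"))
      lx$gene_name[lx$gene_name == "NA"] <- NA_character_
      cache <<- lx
    }
    cache
  }
})

# build the planted protein for a marker and mode; returns list(aa, realized_identity)
.planted_protein <- function(reference_aa, mode, target_identity = NA) {
  L <- nchar(reference_aa)
  if (mode == "exact") {
    list(aa = reference_aa, realized_identity = 100)
  } else if (mode == "diverged") {
    .assert(!is.na(target_identity) && target_identity >= 5,
            "diverged target identity below 5% cannot be controlled")
    k <- round((1 - target_identity / 100) * L)
    list(aa = .substitute_aa(reference_aa, k),
         realized_identity = 100 * (L - k) / L)
  } else if (mode == "decoy") {
    list(aa = .random_protein(L), realized_identity = NA_real_)
  } else stop("unknown plant mode: ", mode)
}

#' Plant a marker gene into a genome
#'
#' Appends a new CDS carrying the marker's annotation text to the end of
#' the last contig (after a >= 50 bp spacer). `exact` copies the reference
#' protein; `diverged` substitutes residues so realized identity is within
#' half a residue of the target; `decoy` attaches a marker-consistent
#' product string to an unrelated random protein of the same length.
#'
#' @param genome A [genome_record()].
#' @param reference_protein Reference amino-acid sequence.
#' @param mode `"exact"`, `"diverged"` or `"decoy"`.
#' @param marker_id Marker whose lexicon entry supplies gene/product text.
#' @param target_identity Percent identity target for `diverged`.
#' @param gc GC fraction used for codon choice (default 0.42).
#' @return List with elements `genome` (updated) and `truth` (one-row
#'   `data.frame`: `marker_id`, `locus_tag`, `mode`, `target_identity`,
#'   `realized_identity`).
#' @export
plant_marker <- function(genome, reference_protein, mode, marker_id,
                         target_identity = NA, gc = 0.42) {
  pp <- .planted_protein(reference_protein, mode, target_identity)
  lx <- .lexicon()
  le <- lx[lx$marker_id == marker_id, , drop = FALSE]
  .assert(nrow(le) == 1, "marker absent from lexicon: ", marker_id)
  product <- sample(strsplit(le$products, "|", fixed = TRUE)[[1]], 1L)
  nt <- .reverse_translate(pp$aa, gc)
  ctg <- length(genome$contigs)
  spacer <- .random_dna(sample(50:150, 1L), gc)
  start <- nchar(genome$contigs[[ctg]]) + nchar(spacer) + 1L
  genome$contigs[[ctg]] <- paste0(genome$contigs[[ctg]], spacer, nt)
  locus_tag <- sprintf("%s_%04d", genome$genome_id, nrow(genome$features) + 1L)
  feat <- data.frame(locus_tag = locus_tag,
                     contig_id = names(genome$contigs)[ctg],
                     start = start, end = start + nchar(nt) - 1L,
                     strand = "+", gene_name = le$gene_name,
                     product = product, note = NA_character_,
                     translation = pp$aa, translation_source = "self",
                     stringsAsFactors = FALSE)
  genome$features <- rbind(genome$features, feat)
  rownames(genome$features) <- NULL
  list(genome = genome,
       truth = data.frame(marker_id = marker_id, locus_tag = locus_tag,
                          mode = mode, target_identity = target_identity,
                          realized_identity = pp$realized_identity,
                          stringsAsFactors = FALSE))
}

# -- cohort simulation ------------------------------------------------------

#' Simulate an annotated cohort with ground truth
#'
#' Generates `sum(genomes_per_species)` annotated genomes plus a
#' ground-truth manifest listing every planted marker (with mode and
#' realized identity), bacteriocin locus (with subclass), safety gene
#' (with realized identity/coverage) and the gene-family membership of
#' every background protein. Raw BAGEL-style bacteriocin hits (with
#' redundant overlapping duplicates and non-structural satellite rows),
#' ABRicate-style safety hits (planted values plus sub-threshold chaff)
#' and DIAMOND-style CAZyme hits (top-hit structure with decoy secondary
#' hits and above-cutoff chaff) are emitted alongside, so every consumer
#' stage has a fixture. Deterministic: identical `config` (including
#' `config$seed`) gives byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `genomes` (named list of
#'   [genome_record()]), `metadata`, `truth` (manifest), raw hit tables
#'   `bacteriocin_hits`, `safety_hits`, `cazyme_hits`, and `config`.
#' @export
simulate_cohort <- function(config) {
  .assert(is(config, "cohort_config"), "config must come from cohort_config()")
  set.seed(config$seed)

  pg <- config$pangenome_plan
  refs <- synthetic_reference_panel()
  safety_refs <- synthetic_safety_panel()

  # cohort-wide family references (stop-free codon strings at the
  # mid-range GC, since shared genes cannot track every genome's GC)
  fam_gc <- mean(config$gc_range)
  fam_len <- function(n) sample(80:300, n, replace = TRUE)
  n_core <- pg$n_core_families %||% 0L
  n_pool <- pg$accessory_pool %||% 0L
  core_nt <- lapply(fam_len(n_core), function(l)
    paste(.random_codons(l, fam_gc), collapse = ""))
  pool_nt <- lapply(fam_len(n_pool), function(l)
    paste(.random_codons(l, fam_gc), collapse = ""))
  core_ids <- sprintf("CORE%04d", seq_len(n_core))
  pool_ids <- sprintf("ACC%04d", seq_len(n_pool))

  # feasibility: coding budget must fit the genome length cap
  est_genes <- n_core + n_pool + (pg$unique_gene_rate %||% 0L) +
    sum(config$marker_plan$probability %||% 0) +
    sum(config$bacteriocin_plan$probability %||% 0) +
    sum(config$safety_plan$probability %||% 0)
  if (est_genes * (3 * 80 + 50) > 1.5 * max(config$genome_length_range))
    stop("infeasible plan: expected gene content exceeds genome_length_range")

  species <- sprintf("Species_%02d", seq_len(config$n_species))
  genus <- sprintf("Genus_%02d", seq_len(config$n_species))
  species_gc <- runif(config$n_species, config$gc_range[1], config$gc_range[2])

  genomes <- list()
  meta_rows <- list()
  tr_markers <- list(); tr_bact <- list(); tr_safety <- list(); tr_fam <- list()
  raw_bact <- list(); raw_safety <- list(); raw_caz <- list(); tr_caz <- list()

  # CAZyme catalog: family, class and a base weight per species tilt
  caz_families <- c("GH1", "GH13", "GH23", "GH25", "GH73", "GH78", "GH109",
                    "GT2", "GT4", "GT8", "GT26", "GT28", "GT35",
                    "CBM34", "CBM48", "CBM50", "CE4", "AA3", "PL8")
  caz_base_w <- c(8, 10, 9, 7, 6, 3, 3, 10, 9, 5, 4, 4, 3, 3, 3, 4, 2, 1, 1)

  g_idx <- 0L
  for (sp in seq_len(config$n_species)) {
    sp_tilt <- runif(length(caz_families), 0.5, 1.5)
    for (rep_i in seq_len(config$genomes_per_species[sp])) {
      g_idx <- g_idx + 1L
      genome_id <- sprintf("G%03d", g_idx)
      gc <- min(max(species_gc[sp] + runif(1, -0.01, 0.01), 0.05), 0.95)
      target_len <- round(runif(1, config$genome_length_range[1],
                                config$genome_length_range[2]))
      n_contigs <- sample(config$contig_range[1]:config$contig_range[2], 1L)

      entries <- list()  # CDS entries
      add_entry <- function(nt, aa, gene, product, note, kind, label) {
        entries[[length(entries) + 1L]] <<-
          list(nt = nt, aa = aa, gene = gene, product = product, note = note,
               kind = kind, label = label)
      }

      # background gene families: core + accessory draw + unique
      # (aa left NA here and batch-translated once per genome)
      for (i in seq_len(n_core)) {
        nt <- .mutate_codons(core_nt[[i]], config$mutation_rate, gc)
        add_entry(paste0(nt, "TAA"), NA_character_,
                  NA_character_, "hypothetical protein", NA_character_,
                  "family", core_ids[i])
      }
      if (n_pool > 0) {
        carried <- which(runif(n_pool) < (pg$accessory_rate %||% 0))
        for (i in carried) {
          nt <- .mutate_codons(pool_nt[[i]], config$mutation_rate, gc)
          add_entry(paste0(nt, "TAA"), NA_character_,
                    NA_character_, "hypothetical protein", NA_character_,
                    "family", pool_ids[i])
        }
      }
      n_uni <- pg$unique_gene_rate %||% 0L
      for (i in seq_len(n_uni)) {
        nt <- paste(.random_codons(sample(80:300, 1L), gc), collapse = "")
        add_entry(paste0(nt, "TAA"), NA_character_,
                  NA_character_, "hypothetical protein", NA_character_,
                  "family", sprintf("UNIQ_%s_%03d", genome_id, i))
      }

      # planted markers
      mk_truth <- list()
      mp <- config$marker_plan
      if (!is.null(mp)) for (i in seq_len(nrow(mp))) {
        if (runif(1) >= mp$probability[i]) next
        ref <- refs$sequence[refs$marker_id == mp$marker_id[i]][1]
        pp <- .planted_protein(ref, mp$plant_mode[i], mp$target_identity[i])
        lx <- .lexicon(); le <- lx[lx$marker_id == mp$marker_id[i], ]
        product <- sample(strsplit(le$products, "|", fixed = TRUE)[[1]], 1L)
        add_entry(.reverse_translate(pp$aa, gc), pp$aa, le$gene_name, product,
                  NA_character_, "marker",
                  paste(mp$marker_id[i], mp$plant_mode[i], sep = ":"))
        mk_truth[[length(mk_truth) + 1L]] <- data.frame(
          genome_id = genome_id, marker_id = mp$marker_id[i],
          mode = mp$plant_mode[i], target_identity = mp$target_identity[i],
          realized_identity = pp$realized_identity, entry = length(entries),
          stringsAsFactors = FALSE)
      }

      # planted bacteriocin loci (short structural peptides)
      bc_truth <- list()
      bp <- config$bacteriocin_plan
      if (!is.null(bp)) for (i in seq_len(nrow(bp))) {
        if (runif(1) >= bp$probability[i]) next
        aa <- .random_protein(sample(40:90, 1L))
        add_entry(.reverse_translate(aa, gc), aa, NA_character_,
                  paste("Bacteriocin", bp$name[i]), NA_character_,
                  "bacteriocin", bp$name[i])
        bc_truth[[length(bc_truth) + 1L]] <- data.frame(
          genome_id = genome_id, name = bp$name[i], subclass = bp$subclass[i],
          entry = length(entries), stringsAsFactors = FALSE)
      }

      # planted safety genes
      sf_truth <- list()
      segments <- list()  # raw nucleotide inserts (alignment panels)
      sp_plan <- config$safety_plan
      if (!is.null(sp_plan)) for (i in seq_len(nrow(sp_plan))) {
        if (runif(1) >= sp_plan$probability[i]) next
        pan <- sp_plan$panel[i]; gene <- sp_plan$gene_name[i]
        if (pan %in% c("AMR", "VF")) {
          ref <- safety_refs$sequence[safety_refs$gene_name == gene][1]
          .assert(!is.na(ref), "safety gene absent from reference panel: ", gene)
          keep <- round(sp_plan$target_coverage[i] * nchar(ref))
          frag <- substr(ref, 1, keep)
          k <- round((1 - sp_plan$target_identity[i] / 100) * keep)
          frag <- .substitute_nt(frag, k)
          segments[[length(segments) + 1L]] <-
            list(nt = frag, gene = gene, panel = pan,
                 identity = 100 * (keep - k) / keep,
                 coverage = keep / nchar(ref))
          sf_truth[[length(sf_truth) + 1L]] <- data.frame(
            genome_id = genome_id, panel = pan, gene_name = gene,
            realized_identity = 100 * (keep - k) / keep,
            realized_coverage = keep / nchar(ref),
            segment = length(segments), entry = NA_integer_,
            stringsAsFactors = FALSE)
        } else {
          txt <- switch(gene,
            hdcA = c("hdcA", "Histidine decarboxylase"),
            tdc = c("tdc", "Tyrosine decarboxylase"),
            odc = c("odc", "Ornithine decarboxylase"),
            cadA = c("cadA", "Lysine decarboxylase"),
            tyrP = c("tyrP", "Tyrosine permease"),
            hly = c("hlyIII", "Hemolysin III"),
            cyl = c("cylA", "Cytolysin"),
            stop("unknown term-panel gene: ", gene))
          aa <- .random_protein(sample(100:250, 1L))
          add_entry(.reverse_translate(aa, gc), aa, txt[1], txt[2],
                    NA_character_, "safety_term", gene)
          sf_truth[[length(sf_truth) + 1L]] <- data.frame(
            genome_id = genome_id, panel = pan, gene_name = gene,
            realized_identity = NA_real_, realized_coverage = NA_real_,
            segment = NA_integer_, entry = length(entries),
            stringsAsFactors = FALSE)
        }
      }

      # batch-translate background genes (single vectorized call)
      need_aa <- which(vapply(entries, function(e) is.na(e$aa), TRUE))
      if (length(need_aa)) {
        aas <- .translate_batch(vapply(entries[need_aa], `[[`, "", "nt"))
        for (j in seq_along(need_aa)) entries[[need_aa[j]]]$aa <- aas[j]
      }

      # ---- layout ----
      built <- .layout_genome(genome_id, entries, segments, n_contigs,
                              gc, target_len)
      genome <- genome_record(
        genome_id, species[sp], genus[sp],
        sample(SOURCE_CATEGORIES, 1L, prob = config$source_mix[SOURCE_CATEGORIES]),
        built$contigs, built$features,
        completeness = round(runif(1, config$completeness_range[1],
                                   config$completeness_range[2]), 2),
        contamination = round(runif(1, config$contamination_range[1],
                                    config$contamination_range[2]), 2))
      genomes[[genome_id]] <- genome
      meta_rows[[genome_id]] <- data.frame(
        genome_id = genome_id, species = species[sp], genus = genus[sp],
        source_category = genome$source_category,
        completeness = genome$completeness,
        contamination = genome$contamination, stringsAsFactors = FALSE)

      # resolve entry indices -> locus tags / coordinates
      entry_tags <- built$entry_locus_tags
      f <- built$features
      if (length(mk_truth)) {
        mk <- do.call(rbind, mk_truth)
        mk$locus_tag <- entry_tags[mk$entry]; mk$entry <- NULL
        tr_markers[[genome_id]] <- mk
      }
      if (length(bc_truth)) {
        bc <- do.call(rbind, bc_truth)
        bc$locus_tag <- entry_tags[bc$entry]
        ii <- match(bc$locus_tag, f$locus_tag)
        bc$contig_id <- f$contig_id[ii]; bc$start <- f$start[ii]; bc$end <- f$end[ii]
        bc$entry <- NULL
        tr_bact[[genome_id]] <- bc
        raw_bact[[genome_id]] <- .bagel_hits(bc, gc)
      }
      if (length(sf_truth)) {
        sf <- do.call(rbind, sf_truth)
        sf$locus_tag <- ifelse(is.na(sf$entry), NA_character_, entry_tags[sf$entry])
        seg_coords <- built$segment_coords
        sf$contig_id <- ifelse(is.na(sf$segment), NA_character_,
                               seg_coords$contig_id[sf$segment])
        sf$start <- ifelse(is.na(sf$segment), NA_integer_,
                           seg_coords$start[sf$segment])
        sf$end <- ifelse(is.na(sf$segment), NA_integer_,
                         seg_coords$end[sf$segment])
        sf$segment <- NULL; sf$entry <- NULL
        tr_safety[[genome_id]] <- sf
      }
      # raw ABRicate-style rows: planted alignment hits + chaff below threshold
      raw_safety[[genome_id]] <- .abricate_hits(
        genome_id, tr_safety[[genome_id]], safety_refs)

      # family membership
      fam_idx <- which(vapply(entries, `[[`, "", "kind") == "family")
      if (length(fam_idx))
        tr_fam[[genome_id]] <- data.frame(
          genome_id = genome_id, protein_id = entry_tags[fam_idx],
          family_id = vapply(entries[fam_idx], `[[`, "", "label"),
          stringsAsFactors = FALSE)

      # CAZyme raw hits
      cz <- .cazyme_hits(genome_id, caz_families, caz_base_w * sp_tilt)
      raw_caz[[genome_id]] <- cz$hits
      tr_caz[[genome_id]] <- cz$truth
    }
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else NULL
  out <- list(genomes = genomes,
              metadata = do.call(rbind, unname(meta_rows)),
              truth = list(markers = bind(tr_markers),
                           bacteriocins = bind(tr_bact),
                           safety = bind(tr_safety),
                           families = bind(tr_fam),
                           cazymes = bind(tr_caz)),
              bacteriocin_hits = bind(raw_bact),
              safety_hits = bind(raw_safety),
              cazyme_hits = bind(raw_caz),
              config = config)
  rownames(out$metadata) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genomes, %d species, seed %d\n",
              length(x$genomes), length(unique(x$metadata$species)),
              x$config$seed))
  invisible(x)
}

# place entries (CDS) and raw segments on contigs with >= 50 bp spacers
.layout_genome <- function(genome_id, entries, segments, n_contigs, gc,
                           target_len) {
  items <- c(lapply(seq_along(entries), function(i) list(type = "cds", i = i)),
             lapply(seq_along(segments), function(i) list(type = "seg", i = i)))
  items <- items[sample.int(length(items))]
  contig_of <- rep(seq_len(n_contigs), length.out = max(length(items), 1L))

  contig_names <- sprintf("%s_c%02d", genome_id, seq_len(n_contigs))
  seqs <- setNames(rep("", n_contigs), contig_names)
  gc_cnt <- setNames(rep(0, n_contigs), contig_names)
  gc_of <- function(s) nchar(gsub("[^GCgc]", "", s))
  # spacers act as a running GC corrector: each spacer's composition pulls
  # the contig back toward the genome's GC target despite coding bias
  corrected_spacer <- function(ci, len) {
    want <- gc * (nchar(seqs[ci]) + len) - gc_cnt[ci]
    .random_dna(len, min(max(want / len, 0.02), 0.98))
  }
  feats <- list(); entry_tags <- character(length(entries))
  seg_coords <- data.frame(contig_id = character(length(segments)),
                           start = integer(length(segments)),
                           end = integer(length(segments)),
                           stringsAsFactors = FALSE)
  tag_n <- 0L
  for (k in seq_along(items)) {
    it <- items[[k]]; ci <- contig_of[k]
    spacer <- corrected_spacer(ci, sample(50:150, 1L))
    seqs[ci] <- paste0(seqs[ci], spacer)
    gc_cnt[ci] <- gc_cnt[ci] + gc_of(spacer)
    pos <- nchar(seqs[ci]) + 1L
    if (it$type == "cds") {
      e <- entries[[it$i]]
      strand <- sample(c("+", "-"), 1L)
      insert <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(e$nt)))
      else e$nt
      seqs[ci] <- paste0(seqs[ci], insert)
      gc_cnt[ci] <- gc_cnt[ci] + gc_of(insert)
      tag_n <- tag_n + 1L
      tag <- sprintf("%s_%04d", genome_id, tag_n)
      entry_tags[it$i] <- tag
      feats[[length(feats) + 1L]] <- data.frame(
        locus_tag = tag, contig_id = contig_names[ci],
        start = pos, end = pos + nchar(insert) - 1L, strand = strand,
        gene_name = e$gene, product = e$product, note = e$note,
        translation = e$aa, translation_source = "self",
        stringsAsFactors = FALSE)
    } else {
      s <- segments[[it$i]]
      seqs[ci] <- paste0(seqs[ci], s$nt)
      gc_cnt[ci] <- gc_cnt[ci] + gc_of(s$nt)
      seg_coords$contig_id[it$i] <- contig_names[ci]
      seg_coords$start[it$i] <- pos
      seg_coords$end[it$i] <- pos + nchar(s$nt) - 1L
    }
  }
  # trailing spacer, then pad toward the target length (both corrected)
  for (ci in seq_len(n_contigs)) {
    sp <- corrected_spacer(ci, sample(50:150, 1L))
    seqs[ci] <- paste0(seqs[ci], sp)
    gc_cnt[ci] <- gc_cnt[ci] + gc_of(sp)
  }
  deficit <- target_len - sum(nchar(seqs))
  if (deficit > 0) {
    pad <- tabulate(sample.int(n_contigs, deficit, replace = TRUE), n_contigs)
    for (ci in seq_len(n_contigs))
      if (pad[ci] > 0) {
        sp <- corrected_spacer(ci, pad[ci])
        seqs[ci] <- paste0(seqs[ci], sp)
        gc_cnt[ci] <- gc_cnt[ci] + gc_of(sp)
      }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    .normalize_features(NULL)
  list(contigs = seqs, features = features, entry_locus_tags = entry_tags,
       segment_coords = seg_coords)
}

# BAGEL-style raw hit rows for planted loci: one structural hit per locus,
# an overlapping redundant duplicate for some, and satellite
# immunity/transport rows that must never form loci.
.bagel_hits <- function(bc, gc) {
  rows <- list()
  for (i in seq_len(nrow(bc))) {
    s <- bc$start[i]; e <- bc$end[i]
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = bc$genome_id[i], contig_id = bc$contig_id[i],
      start = s, end = e, name = bc$name[i], role = "structural",
      score = round(runif(1, 80, 200), 1), stringsAsFactors = FALSE)
    if (runif(1) < 0.5)  # redundant overlapping duplicate
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = bc$genome_id[i], contig_id = bc$contig_id[i],
        start = s + 5L, end = e - 3L, name = bc$name[i], role = "structural",
        score = round(runif(1, 40, 79), 1), stringsAsFactors = FALSE)
    if (runif(1) < 0.7)  # satellite gene, non-structural
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = bc$genome_id[i], contig_id = bc$contig_id[i],
        start = e + 20L, end = e + 350L, name = bc$name[i],
        role = sample(c("immunity", "transport", "biosynthetic"), 1L),
        score = round(runif(1, 20, 90), 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ABRicate-style rows: planted alignment hits at realized values + chaff
# guaranteed below the retention thresholds of its panel.
.abricate_hits <- function(genome_id, sf, safety_refs) {
  rows <- list()
  if (!is.null(sf)) {
    al <- sf[sf$panel %in% c("AMR", "VF"), , drop = FALSE]
    for (i in seq_len(nrow(al)))
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genome_id, panel = al$panel[i], gene = al$gene_name[i],
        coverage = al$realized_coverage[i], identity = al$realized_identity[i],
        contig_id = al$contig_id[i], start = al$start[i], end = al$end[i],
        stringsAsFactors = FALSE)
  }
  n_chaff <- sample(0:2, 1L)
  for (j in seq_len(n_chaff)) {
    g <- safety_refs[sample.int(nrow(safety_refs), 1L), ]
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genome_id, panel = g$panel, gene = g$gene_name,
      coverage = round(runif(1, 0.10, 0.40), 3),
      identity = round(runif(1, 60, 85), 1),
      contig_id = NA_character_, start = NA_integer_, end = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# DIAMOND-style tabular CAZyme hits with a known top-1 structure
.cazyme_hits <- function(genome_id, families, weights) {
  n_real <- max(rbinom(1, 60, 0.5), 1L)
  fam <- sample(families, n_real, replace = TRUE, prob = weights)
  rows <- list(); truth <- list()
  dialect <- function(f, i) switch(sample.int(3L, 1L),
    f, paste0(f, "_", sample(1:40, 1L)),
    paste0("CAZ", sprintf("%05d", i), "|", f, "(", sample(1:200, 1L), "-",
           sample(201:500, 1L), ")"))
  q_n <- 0L
  for (i in seq_len(n_real)) {
    q_n <- q_n + 1L
    qid <- sprintf("%s_P%04d", genome_id, q_n)
    best_bits <- round(runif(1, 350, 700), 1)
    best_e <- 10^-runif(1, 103, 180)
    rows[[length(rows) + 1L]] <- .caz_row(qid, dialect(fam[i], i), best_e, best_bits)
    if (runif(1) < 0.3) {  # weaker secondary hit on another family
      f2 <- sample(setdiff(families, fam[i]), 1L)
      rows[[length(rows) + 1L]] <- .caz_row(
        qid, dialect(f2, i), best_e * 10^runif(1, 2, 20),
        best_bits - round(runif(1, 20, 150), 1))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      genome_id = genome_id, protein_id = qid, family = fam[i],
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(sample(2:6, 1L))) {  # chaff above the E cutoff
    q_n <- q_n + 1L
    rows[[length(rows) + 1L]] <- .caz_row(
      sprintf("%s_P%04d", genome_id, q_n),
      dialect(sample(families, 1L), 999L),
      10^-runif(1, 10, 101), round(runif(1, 50, 200), 1))
  }
  hits <- do.call(rbind, rows)
  hits <- cbind(genome_id = genome_id, hits, stringsAsFactors = FALSE)
  list(hits = hits, truth = do.call(rbind, truth))
}

.caz_row <- function(qid, slabel, evalue, bits) {
  data.frame(qseqid = qid, sseqid = slabel,
             pident = round(runif(1, 30, 100), 1),
             length = sample(80:400, 1L), mismatch = sample(0:50, 1L),
             gapopen = sample(0:5, 1L), qstart = 1L, qend = sample(80:400, 1L),
             sstart = 1L, send = sample(80:400, 1L),
             evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
}

# -- cohort serialization ---------------------------------------------------

#' Write a synthetic cohort to disk
#'
#' Per-genome GFF3 + nucleotide FASTA + protein FASTA, cohort
#' `metadata.tsv`, raw hit TSVs, and the ground-truth `manifest.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in cohort$genomes) write_genome(g, file.path(dir, "genomes"))
  write_tsv_strict(cohort$metadata, file.path(dir, "metadata.tsv"))
  for (nm in c("bacteriocin_hits", "safety_hits", "cazyme_hits"))
    if (!is.null(cohort[[nm]]))
      write_tsv_strict(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
  jsonlite::write_json(cohort$truth, file.path(dir, "manifest.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
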