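# Assembly metrics and the cohort inclusion gate.
#
# The gate mirrors the retrieval-time inclusion criteria of family-wide LAB
# surveys: an assembly-level whitelist and MAG/single-cell exclusion arrive
# as metadata flags; contiguity and CheckM-style quality are computed or
# consumed here. All thresholds are inclusive on their stated side.

QC_THRESHOLDS <- list(max_contigs = 200L, min_n50 = 50000L,
                      min_completeness = 95, max_contamination = 5)

#' Compute assembly metrics for a genome
#'
#' N50 is the smallest contig length L such that contigs of length >= L sum
#' to at least half the assembly; GC% counts unambiguous A/C/G/T only
#' (ambiguity codes are excluded from numerator and denominator).
#'
#' @param genome A [genome_record()], or a named character vector of contig
#'   sequences.
#' @param assembly_level One of `complete`, `chromosome`, `scaffold`,
#'   `contig` (metadata flag, criterion (a)).
#' @param excluded_origin `TRUE` for MAG or single-cell assemblies
#'   (metadata flag, criterion (b)).
#' @return A one-row `data.frame` of class `assembly_metrics` with columns
#'   `genome_id`, `total_length`, `gc_percent`, `contig_count`, `n50`,
#'   `completeness`, `contamination`, `assembly_level`, `excluded_origin`.
#' @export
compute_metrics <- function(genome, assembly_level = "contig",
                            excluded_origin = FALSE) {
  if (is(genome, "genome_record")) {
    contigs <- genome$contigs
    completeness <- genome$completeness
    contamination <- genome$contamination
    genome_id <- genome$genome_id
  } else {
    contigs <- genome
    completeness <- NA_real_; contamination <- NA_real_
    genome_id <- NA_character_
  }
  .assert(length(contigs) >= 1L && all(nchar(contigs) > 0), "empty genome")
  .assert(assembly_level %in% c("complete", "chromosome", "scaffold", "contig"),
          "unknown assembly_level: ", assembly_level)
  lens <- nchar(contigs)
  dss <- Biostrings::DNAStringSet(toupper(contigs))
  counts <- Biostrings::letterFrequency(dss, c("A", "C", "G", "T"))
  gc <- sum(counts[, c("C", "G")])
  acgt <- sum(counts)
  data.frame(genome_id = genome_id,
             total_length = sum(lens),
             gc_percent = if (acgt > 0) 100 * gc / acgt else 0,
             contig_count = length(contigs),
             n50 = n50(lens),
             completeness = completeness,
             contamination = contamination,
             assembly_level = assembly_level,
             excluded_origin = excluded_origin,
             stringsAsFactors = FALSE)
}

#' N50 of a set of contig lengths
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The smallest length L such that contigs >= L cover at least half
#'   of the total assembly length.
#' @export
n50 <- function(lengths) {
  .assert(length(lengths) >= 1L && all(lengths > 0), "need positive contig lengths")
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(lengths)
  lengths[which(cum >= sum(lengths) / 2)[1]]
}

#' Apply the inclusion gate to assembly metrics
#'
#' Fails when the assembly is MAG/single-cell derived (`EXCLUDED_ORIGIN`),
#' when `contig_count > 200` without rescuing contiguity `n50 >= 50000`
#' (`CONTIG_COUNT`), when `completeness < 95` (`COMPLETENESS`), or when
#' `contamination > 5` (`CONTAMINATION`). Boundary values pass.
#'
#' @param metrics One or more rows as returned by [compute_metrics()].
#' @param thresholds Gate parameters; defaults to the published criteria.
#' @return `data.frame` with columns `genome_id`, `passed`, `reasons`
#'   (`;`-joined failed-criterion codes, empty when passed).
#' @export
apply_gate <- function(metrics, thresholds = QC_THRESHOLDS) {
  out <- lapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    reasons <- character(0)
    if (isTRUE(m$excluded_origin)) reasons <- c(reasons, "EXCLUDED_ORIGIN")
    if (m$contig_count > thresholds$max_contigs && m$n50 < thresholds$min_n50)
      reasons <- c(reasons, "CONTIG_COUNT")
    if (is.na(m$completeness) || m$completeness < thresholds$min_completeness)
      reasons <- c(reasons, "COMPLETENESS")
    if (is.na(m$contamination) || m$contamination > thresholds$max_contamination)
      reasons <- c(reasons, "CONTAMINATION")
    data.frame(genome_id = m$genome_id, passed = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Retain species with enough passing genomes
#'
#' A species is kept iff its number of gate-passing genomes is at least
#' `min_genomes`; genomes of dropped species are excluded downstream.
#'
#' @param decisions Output of [apply_gate()] covering every genome.
#' @param metadata Cohort metadata with `genome_id` and `species` columns.
#' @param min_genomes Minimum passing genomes per species (default 10).
#' @return Character vector of retained species names.
#' @export
filter_species_representation <- function(decisions, metadata, min_genomes = 10L) {
  .assert(all(metadata$genome_id %in% decisions$genome_id),
          "decisions must cover every genome in metadata")
  passed <- decisions$genome_id[decisions$passed]
  counts <- table(metadata$species[metadata$genome_id %in% passed])
  retained <- names(counts)[counts >= min_genomes]
  if (length(retained) == 0L)
    stop("no species has >= ", min_genomes,
         " passing genomes; cohort is empty after filtering")
  sort(retained)
}

#' Per-cohort QC report
#'
#' @param genomes List of [genome_record()] objects.
#' @param metadata Optional cohort metadata (defaults to
#'   [cohort_metadata()] of `genomes`).
#' @param min_genomes Species-representation threshold.
#' @return List with `metrics`, `decisions`, `retained_species`, and
#'   `retained_genomes` (passing genomes of retained species).
#' @export
qc_cohort <- function(genomes, metadata = NULL, min_genomes = 10L) {
  metadata <- metadata %||% cohort_metadata(genomes)
  metrics <- do.call(rbind, lapply(genomes, compute_metrics))
  decisions <- apply_gate(metrics)
  retained_species <- filter_species_representation(decisions, metadata, min_genomes)
  keep <- decisions$passed &
    metadata$species[match(decisions$genome_id, metadata$genome_id)] %in% retained_species
  list(metrics = metrics, decisions = decisions,
       retained_species = retained_species,
       retained_genomes = decisions$genome_id[keep])
}
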