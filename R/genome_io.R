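# Uniform in-memory genome model plus GFF3/FASTA reading and writing.
#
# Coordinates are 1-based inclusive everywhere in this package; any
# conversion to half-open intervals is confined to this file.

SOURCE_CATEGORIES <- c("fermentation", "environment", "human", "animal",
                       "other", "missing")

#' Construct a genome record
#'
#' An annotated assembly: contig sequences, CDS features with their
#' annotation text and translations, and the per-genome metadata the
#' pipeline consumes (species label, isolation source, CheckM-style
#' completeness/contamination estimates).
#'
#' @param genome_id Unique identifier within a cohort.
#' @param species_label,genus_label Taxon labels.
#' @param source_category One of `fermentation`, `environment`, `human`,
#'   `animal`, `other`, `missing`.
#' @param contigs Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences.
#' @param features `data.frame` with columns `locus_tag`, `contig_id`,
#'   `start`, `end`, `strand`, `gene_name`, `product`, `note`,
#'   `translation`, `translation_source`.
#' @param completeness,contamination Percent estimates in `[0, 100]`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, species_label, genus_label = NA_character_,
                          source_category = "missing", contigs, features,
                          completeness = NA_real_, contamination = NA_real_) {
  if (is(contigs, "DNAStringSet")) contigs <- setNames(as.character(contigs), names(contigs))
  .assert(is.character(contigs) && length(contigs) >= 1L && !is.null(names(contigs)),
          "contigs must be a named character vector with at least one contig")
  .assert(source_category %in% SOURCE_CATEGORIES,
          "unknown source_category: ", source_category)
  features <- .normalize_features(features)
  if (anyDuplicated(features$locus_tag))
    stop("duplicate locus_tag in genome ", genome_id)
  bad <- !(features$contig_id %in% names(contigs))
  if (any(bad))
    stop("feature ", features$locus_tag[which(bad)[1]],
         " references missing contig ", features$contig_id[which(bad)[1]])
  lens <- nchar(contigs)[features$contig_id]
  if (nrow(features) && any(features$start < 1 | features$end > lens |
                            features$start > features$end))
    stop("feature coordinates outside contig bounds in genome ", genome_id)
  for (p in c(completeness, contamination))
    if (!is.na(p)) .assert(p >= 0 && p <= 100, "percent estimates must lie in [0,100]")
  structure(list(genome_id = genome_id, species_label = species_label,
                 genus_label = genus_label, source_category = source_category,
                 contigs = contigs, features = features,
                 completeness = completeness, contamination = contamination),
            class = "genome_record")
}

.feature_cols <- c("locus_tag", "contig_id", "start", "end", "strand",
                   "gene_name", "product", "note", "translation",
                   "translation_source")

.normalize_features <- function(features) {
  if (is.null(features)) features <- data.frame()
  for (col in .feature_cols)
    if (is.null(features[[col]]))
      features[[col]] <- if (col %in% c("start", "end")) integer(0) else character(0)
  features <- features[, .feature_cols, drop = FALSE]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  .assert(all(features$strand %in% c("+", "-")), "strand must be '+' or '-'")
  rownames(features) <- NULL
  features
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %d contig(s), %s bp, %d CDS\n",
              x$genome_id, x$species_label, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","), nrow(x$features)))
  invisible(x)
}

# -- translation ------------------------------------------------------------

# Bacterial/archaeal code (table 11); annotated first residue is kept as
# translated (no forced Met) so self-translations agree with supplied
# protein FASTA files. Ambiguous codons become X; trailing stop is trimmed.
translate_cds <- function(nt) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

.cds_nt <- function(contig_seq, start, end, strand) {
  s <- substr(contig_seq, start, end)
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# -- GFF3 + FASTA reading ---------------------------------------------------

#' Read an annotated genome from GFF3 + FASTA
#'
#' Parses CDS features from a GFF3 file (version-3 pragma required),
#' attaches contig sequences from the nucleotide FASTA, and takes protein
#' translations from the protein FASTA when supplied (matching on locus
#' tag). Features absent from the protein FASTA -- or all features when no
#' protein FASTA is given -- are self-translated from the nucleotide span
#' with translation table 11; such translations are flagged
#' `translation_source = "self"`. CDS spans whose length is not a multiple
#' of three are skipped with a warning.
#'
#' GFF3 attribute keys `gene`, `product` and `note` are honored
#' case-insensitively; multi-valued attributes are joined with `"; "`.
#'
#' @param gff3_path Path to a GFF3 annotation file.
#' @param nucleotide_fasta_path Path to the contig FASTA.
#' @param protein_fasta_path Optional path to a protein FASTA whose record
#'   names are locus tags.
#' @param genome_id,species_label,genus_label,source_category,completeness,contamination
#'   Metadata passed through to [genome_record()]; `genome_id` defaults to
#'   the GFF3 file stem.
#' @return A [genome_record()].
#' @export
read_annotated_genome <- function(gff3_path, nucleotide_fasta_path,
                                  protein_fasta_path = NULL,
                                  genome_id = NULL, species_label = NA_character_,
                                  genus_label = NA_character_,
                                  source_category = "missing",
                                  completeness = NA_real_, contamination = NA_real_) {
  first <- readLines(gff3_path, n = 1L)
  if (!grepl("^##gff-version[ \t]+3", first))
    stop("not a GFF3 file (missing '##gff-version 3' pragma): ", gff3_path)
  genome_id <- genome_id %||% sub("\\.(gff3?|gff)$", "", basename(gff3_path))

  contigs <- Biostrings::readDNAStringSet(nucleotide_fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  contigs <- setNames(as.character(contigs), names(contigs))

  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  mc <- S4Vectors::mcols(gr)
  attr_field <- function(key) {
    hit <- which(tolower(names(mc)) == tolower(key))
    if (!length(hit)) return(rep(NA_character_, length(gr)))
    v <- mc[[hit[1]]]
    if (is(v, "List") || is.list(v))
      v <- vapply(v, function(e) if (length(e)) paste(e, collapse = "; ") else NA_character_, "")
    as.character(v)
  }
  locus <- attr_field("ID")
  if (anyNA(locus)) locus[is.na(locus)] <- attr_field("locus_tag")[is.na(locus)]
  if (anyNA(locus)) stop("CDS feature without ID/locus_tag attribute in ", gff3_path)

  feats <- data.frame(
    locus_tag = locus,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_name = attr_field("gene"), product = attr_field("product"),
    note = attr_field("note"),
    translation = NA_character_, translation_source = NA_character_,
    stringsAsFactors = FALSE)
  .assert(all(feats$strand %in% c("+", "-")),
          "CDS with unstranded ('.') feature in ", gff3_path)

  bad <- !(feats$contig_id %in% names(contigs))
  if (any(bad))
    stop("feature ", feats$locus_tag[which(bad)[1]], " references contig ",
         feats$contig_id[which(bad)[1]], " absent from ", nucleotide_fasta_path)

  prot <- NULL
  if (!is.null(protein_fasta_path)) {
    prot <- Biostrings::readAAStringSet(protein_fasta_path)
    names(prot) <- sub("\\s.*$", "", names(prot))
    prot <- setNames(as.character(prot), names(prot))
  }

  keep <- rep(TRUE, nrow(feats))
  for (i in seq_len(nrow(feats))) {
    lt <- feats$locus_tag[i]
    if (!is.null(prot) && lt %in% names(prot)) {
      feats$translation[i] <- prot[[lt]]
      feats$translation_source[i] <- "protein_fasta"
    } else {
      len <- feats$end[i] - feats$start[i] + 1L
      if (len %% 3L != 0L) {
        warning("skipping CDS ", lt, ": span length ", len,
                " not divisible by 3", call. = FALSE)
        keep[i] <- FALSE
        next
      }
      nt <- .cds_nt(contigs[[feats$contig_id[i]]], feats$start[i],
                    feats$end[i], feats$strand[i])
      feats$translation[i] <- translate_cds(nt)
      feats$translation_source[i] <- "self"
    }
  }
  feats <- feats[keep, , drop = FALSE]

  genome_record(genome_id, species_label, genus_label, source_category,
                contigs, feats, completeness, contamination)
}

#' Extract a stored protein translation by locus tag
#'
#' Returns the translation recorded when the genome was read or simulated;
#' translations taken from a protein FASTA are never recomputed. The
#' `translation_source` attribute on the result says whether the sequence
#' came from the protein FASTA or from self-translation.
#'
#' @param genome A [genome_record()].
#' @param locus_tag CDS identifier.
#' @return Amino-acid sequence (character scalar) with attribute `source`.
#' @export
extract_protein <- function(genome, locus_tag) {
  i <- match(locus_tag, genome$features$locus_tag)
  if (is.na(i)) stop("unknown locus_tag: ", locus_tag)
  structure(genome$features$translation[i],
            source = genome$features$translation_source[i])
}

# -- writing ----------------------------------------------------------------

#' Write a genome record as GFF3 + nucleotide FASTA + protein FASTA
#'
#' Emits `<genome_id>.gff3`, `<genome_id>.fna` and `<genome_id>.faa` into
#' `dir`. Reading the trio back with [read_annotated_genome()] reproduces
#' the features (coordinates, strand, attributes, translations).
#'
#' @param genome A [genome_record()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, genome$genome_id)
  paths <- c(gff3 = paste0(base, ".gff3"), fna = paste0(base, ".fna"),
             faa = paste0(base, ".faa"))

  nt <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(nt, paths["fna"], width = 80L)
  f <- genome$features
  if (nrow(f)) {
    aa <- Biostrings::AAStringSet(setNames(f$translation, f$locus_tag))
    Biostrings::writeXStringSet(aa, paths["faa"], width = 80L)
  } else writeLines(character(0), paths["faa"])

  gr <- GenomicRanges::GRanges(
    seqnames = f$contig_id,
    ranges = IRanges::IRanges(f$start, f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- rep("CDS", nrow(f))
  S4Vectors::mcols(gr)$phase <- rep(0L, nrow(f))
  S4Vectors::mcols(gr)$ID <- f$locus_tag
  S4Vectors::mcols(gr)$gene <- f$gene_name
  S4Vectors::mcols(gr)$product <- f$product
  S4Vectors::mcols(gr)$note <- f$note
  rtracklayer::export(gr, paths["gff3"], format = "gff3")
  invisible(paths)
}

# -- cohort metadata --------------------------------------------------------

#' Build the per-cohort metadata table from genome records
#'
#' @param genomes List of [genome_record()] objects.
#' @return `data.frame` with columns `genome_id`, `species`, `genus`,
#'   `source_category`, `completeness`, `contamination`.
#' @export
cohort_metadata <- function(genomes) {
  .assert(length(genomes) > 0, "empty cohort")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  .assert(!anyDuplicated(ids), "duplicate genome_id in cohort")
  data.frame(
    genome_id = ids,
    species = vapply(genomes, `[[`, "", "species_label"),
    genus = vapply(genomes, `[[`, "", "genus_label"),
    source_category = vapply(genomes, `[[`, "", "source_category"),
    completeness = vapply(genomes, `[[`, 0, "completeness"),
    contamination = vapply(genomes, `[[`, 0, "contamination"),
    stringsAsFactors = FALSE)
}
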