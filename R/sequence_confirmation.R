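# Local-alignment confirmation of regex-derived marker candidates.
#
# Candidates are aligned with exact Smith-Waterman (affine gaps) against a
# curated per-marker reference set; BLOSUM62 with gap open 11 / extend 1
# matches protein-BLAST defaults, so the published decision thresholds
# (identity >= 40%, query coverage >= 70%, E <= 1e-5) transfer unchanged.
# E-values use the Karlin-Altschul form E = K*m*n*exp(-lambda*S) with the
# standard gapped BLOSUM62 constants; m is the query length and n the total
# residue count of the marker's reference set.

CONFIRM_THRESHOLDS <- list(min_identity = 40, min_coverage = 0.70,
                           max_evalue = 1e-5)
KA_GAPPED_BLOSUM62 <- c(lambda = 0.267, K = 0.041)

.check_aa <- function(x, who) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", x)
  if (!all(ok)) stop(who, " contains non-residue characters (20 aa + X allowed)")
  invisible(x)
}

#' Optimal local protein alignment with affine gaps
#'
#' Exact Smith-Waterman under BLOSUM62 with affine gap costs (open 11,
#' extend 1; a gap of length L costs 11 + L). Percent identity counts
#' identical aligned residue pairs over all alignment columns, gap columns
#' included; query coverage is the aligned query span divided by the query
#' length.
#'
#' @param query,subject Amino-acid sequences (characters; 20 residues + X).
#' @param db_residues Total residue count of the reference set the subject
#'   belongs to, used as `n` in the E-value; defaults to `nchar(subject)`.
#' @return One-row `data.frame`: `percent_identity`, `query_coverage`,
#'   `raw_score`, `e_value`, `align_length`, `query_start`, `query_end`.
#' @export
local_align <- function(query, subject, db_residues = nchar(subject)) {
  .assert(nchar(query) > 0 && nchar(subject) > 0, "sequences must be non-empty")
  .check_aa(query, "query"); .check_aa(subject, "subject")
  mat <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 11, gapExtension = 1)
  .align_stats(aln, nchar(query), db_residues)
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

.align_stats <- function(aln, query_len, db_residues) {
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  cols <- nchar(p)  # alignment columns incl. gap columns
  if (cols == 0L) {  # no positive-scoring local alignment exists
    sc0 <- max(Biostrings::score(aln), 0)
    return(data.frame(percent_identity = 0, query_coverage = 0,
                      raw_score = sc0,
                      e_value = KA_GAPPED_BLOSUM62[["K"]] * query_len *
                        db_residues,
                      align_length = 0L, query_start = 0L, query_end = 0L))
  }
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n_ident <- sum(pc == sc & pc != "-")
  qs <- Biostrings::start(Biostrings::pattern(aln))
  qe <- Biostrings::end(Biostrings::pattern(aln))
  sc_raw <- Biostrings::score(aln)
  ev <- KA_GAPPED_BLOSUM62[["K"]] * query_len * db_residues *
    exp(-KA_GAPPED_BLOSUM62[["lambda"]] * sc_raw)
  data.frame(percent_identity = 100 * n_ident / cols,
             query_coverage = (qe - qs + 1) / query_len,
             raw_score = sc_raw, e_value = ev,
             align_length = cols, query_start = qs, query_end = qe)
}

#' Optimal local nucleotide alignment (safety-screen scoring scheme)
#'
#' Same Smith-Waterman core with match +2 / mismatch -3, gap open 5 /
#' extend 2; identity and coverage definitions as in [local_align()]. Used
#' by the internal path of the safety screen; no E-value is attached.
#'
#' @param query,subject Nucleotide sequences.
#' @return One-row `data.frame` as in [local_align()] minus `e_value`.
#' @export
local_align_nt <- function(query, subject) {
  .assert(nchar(query) > 0 && nchar(subject) > 0, "sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  out <- .align_stats(aln, nchar(query), nchar(subject))
  out$e_value <- NULL
  out
}

# -- reference panels -------------------------------------------------------

#' Read a marker reference panel FASTA
#'
#' Headers follow `accession|marker_id`.
#'
#' @param path FASTA of reference proteins.
#' @return `data.frame` with `accession`, `marker_id`, `sequence`.
#' @export
read_reference_panel <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(aa)), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("reference header not of form 'accession|marker_id': ",
                     names(aa)[which(bad)[1]])
  data.frame(accession = vapply(parts, `[`, "", 1L),
             marker_id = vapply(parts, `[`, "", 2L),
             sequence = as.character(aa), stringsAsFactors = FALSE)
}

#' Write a marker reference panel FASTA
#'
#' @param refs `data.frame` as returned by [read_reference_panel()].
#' @param path Output FASTA path.
#' @export
write_reference_panel <- function(refs, path) {
  aa <- Biostrings::AAStringSet(setNames(refs$sequence,
                                         paste(refs$accession, refs$marker_id, sep = "|")))
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

# -- confirmation -----------------------------------------------------------

#' Confirmation decision rule
#'
#' A candidate is confirmed iff `identity >= 40`, `coverage >= 0.70` and
#' `e_value <= 1e-5`; all three thresholds are inclusive.
#'
#' @param identity Percent identity.
#' @param coverage Query-coverage fraction.
#' @param e_value Alignment E-value.
#' @param thresholds Threshold list (defaults published).
#' @return Logical (vectorized).
#' @export
confirmation_decision <- function(identity, coverage, e_value,
                                  thresholds = CONFIRM_THRESHOLDS) {
  identity >= thresholds$min_identity &
    coverage >= thresholds$min_coverage &
    e_value <= thresholds$max_evalue
}

#' Confirm regex marker hits by alignment against a reference panel
#'
#' Each candidate protein is aligned against every reference sequence for
#' its marker; the best alignment is the one with the highest raw score
#' (ties broken by lowest E-value, then lexicographic accession). A hit is
#' confirmed iff identity >= 40%, query coverage >= 0.70 and E <= 1e-5
#' (boundary values confirm). Markers without references yield unconfirmed
#' outcomes with reason `NO_REFERENCE`.
#'
#' @param hits Marker hit table ([screen_genome()] rows).
#' @param genomes Named list of [genome_record()] objects (names =
#'   genome_id) or a single record.
#' @param reference_db Reference panel `data.frame` (`accession`,
#'   `marker_id`, `sequence`).
#' @param thresholds Confirmation thresholds (defaults published).
#' @return `data.frame`: hit columns plus `best_accession`,
#'   `percent_identity`, `query_coverage`, `e_value`, `raw_score`,
#'   `confirmed`, `reason`.
#' @export
confirm_hits <- function(hits, genomes, reference_db,
                         thresholds = CONFIRM_THRESHOLDS) {
  if (is(genomes, "genome_record")) genomes <- setNames(list(genomes), genomes$genome_id)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  db_n <- tapply(nchar(reference_db$sequence), reference_db$marker_id, sum)

  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    out <- data.frame(h, best_accession = NA_character_,
                      percent_identity = NA_real_, query_coverage = NA_real_,
                      e_value = NA_real_, raw_score = NA_real_,
                      confirmed = FALSE, reason = "", stringsAsFactors = FALSE)
    refs <- reference_db[reference_db$marker_id == h$marker_id, , drop = FALSE]
    if (!nrow(refs)) { out$reason <- "NO_REFERENCE"; return(out) }
    qry <- as.character(extract_protein(genomes[[h$genome_id]], h$locus_tag))
    res <- do.call(rbind, lapply(seq_len(nrow(refs)), function(j)
      local_align(qry, refs$sequence[j], db_residues = db_n[[h$marker_id]])))
    ord <- order(-res$raw_score, res$e_value, refs$accession)
    b <- ord[1]
    out$best_accession <- refs$accession[b]
    out$percent_identity <- res$percent_identity[b]
    out$query_coverage <- res$query_coverage[b]
    out$e_value <- res$e_value[b]
    out$raw_score <- res$raw_score[b]
    out$confirmed <- confirmation_decision(res$percent_identity[b],
                                           res$query_coverage[b],
                                           res$e_value[b], thresholds)
    if (!out$confirmed) out$reason <- "BELOW_THRESHOLDS"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regex/alignment concordance per marker
#'
#' Concordance is the percentage of regex candidates confirmed by
#' alignment. Markers listed in `markers` but absent from `outcomes` are
#' reported with zero candidates and `NA` concordance (never 0).
#'
#' @param outcomes Output of [confirm_hits()].
#' @param markers Optional character vector fixing the reported marker set.
#' @return `data.frame`: `marker_id`, `n_candidates`, `n_confirmed`,
#'   `concordance`.
#' @export
concordance <- function(outcomes, markers = NULL) {
  markers <- markers %||% sort(unique(outcomes$marker_id))
  rows <- lapply(markers, function(m) {
    sub <- outcomes[outcomes$marker_id == m, , drop = FALSE]
    n <- nrow(sub); k <- sum(sub$confirmed)
    data.frame(marker_id = m, n_candidates = n, n_confirmed = k,
               concordance = if (n > 0) 100 * k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Import external tabular alignments (12-column BLAST-style format)
#'
#' Adapter for pipelines that ran an external aligner: columns qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore. Query coverage is computed from the aligned span when
#' query lengths are supplied.
#'
#' @param path Tab-separated alignment file without header.
#' @param query_lengths Optional named vector of query lengths.
#' @return `data.frame` with standard alignment-result columns.
#' @export
import_external_alignments <- function(path, query_lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  .assert(ncol(x) == 12L, "expected 12 tab-separated columns in ", path)
  names(x) <- cols
  cov <- rep(NA_real_, nrow(x))
  if (!is.null(query_lengths)) {
    ql <- query_lengths[x$qseqid]
    cov <- (x$qend - x$qstart + 1) / ql
  }
  data.frame(query_id = x$qseqid, subject_id = x$sseqid,
             percent_identity = x$pident, query_coverage = cov,
             raw_score = x$bitscore, e_value = x$evalue,
             stringsAsFactors = FALSE)
}
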