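# Bacteriocin hit consolidation, subclass assignment, and the per-species
# abundance/diversity summaries and composition tables.
#
# Only structural-role hits found loci; overlapping same-name structural
# hits are merged (overlap > 50% of the shorter span by default, a
# configurable parameter since the underlying surveys say only
# "overlapping or redundant"). Total abundance counts structural loci.

BACTERIOCIN_SUBCLASSES <- c("I", "IIa", "IIb", "IIc", "IId", "III", "other")

#' Consolidate raw bacteriocin hits into loci
#'
#' Structural hits on the same genome/contig sharing a name whose spans
#' overlap by more than `min_overlap` of the shorter span merge into one
#' locus keeping the highest-scoring span; identical duplicates collapse.
#' Non-structural roles (immunity, transport, biosynthetic) never create
#' loci. Idempotent.
#'
#' @param raw_hits `data.frame`: `genome_id`, `contig_id`, `start`, `end`,
#'   `name`, `role`, `score`.
#' @param min_overlap Overlap fraction of the shorter span above which two
#'   hits are redundant (default 0.5).
#' @return Loci `data.frame`: `genome_id`, `contig_id`, `start`, `end`,
#'   `name`, `score`.
#' @export
consolidate <- function(raw_hits, min_overlap = 0.5) {
  empty <- data.frame(genome_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      name = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(raw_hits) || nrow(raw_hits) == 0L) return(empty)
  .assert(all(raw_hits$start <= raw_hits$end), "hit with start > end")
  h <- raw_hits[raw_hits$role == "structural", , drop = FALSE]
  if (!nrow(h)) return(empty)
  h <- h[order(h$genome_id, h$contig_id, h$name, h$start, h$end), , drop = FALSE]

  out <- list()
  key <- paste(h$genome_id, h$contig_id, h$name, sep = "\r")
  for (grp in split(seq_len(nrow(h)), key)) {
    sub <- h[grp, , drop = FALSE]
    # single-linkage over the pairwise redundancy relation
    n <- nrow(sub); comp <- seq_len(n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      ov <- min(sub$end[i], sub$end[j]) - max(sub$start[i], sub$start[j]) + 1
      shorter <- min(sub$end[i] - sub$start[i], sub$end[j] - sub$start[j]) + 1
      if (ov > min_overlap * shorter) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
    for (cid in unique(comp)) {
      mem <- sub[comp == cid, , drop = FALSE]
      best <- which.max(mem$score)
      out[[length(out) + 1L]] <- data.frame(
        genome_id = mem$genome_id[1], contig_id = mem$contig_id[1],
        start = mem$start[best], end = mem$end[best], name = mem$name[1],
        score = mem$score[best], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$genome_id, out$contig_id, out$start, out$name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the bacteriocin name-to-subclass mapping
#'
#' @param path Mapping TSV (`bacteriocin_name`, `subclass`); defaults to
#'   the packaged curation covering the named LAB bacteriocins
#'   (plantaricins, nisins, enterolysin A, helveticin J, pediocin-like
#'   peptides, ...).
#' @return `data.frame` with normalized lookup keys.
#' @export
load_subclass_map <- function(path = .pkg_file("bacteriocin_subclass_map.tsv")) {
  m <- read_tsv_strict(path)
  .assert(all(c("bacteriocin_name", "subclass") %in% names(m)),
          "mapping needs columns bacteriocin_name, subclass")
  .assert(all(m$subclass %in% BACTERIOCIN_SUBCLASSES),
          "subclass outside the fixed scheme")
  m$key <- .normalize_bname(m$bacteriocin_name)
  m
}

.normalize_bname <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Assign a bacteriocin subclass by name lookup
#'
#' Exact-name lookup after whitespace/case normalization; unmapped names
#' fall into `"other"`.
#'
#' @param bacteriocin_name Character vector of names.
#' @param mapping_table A [load_subclass_map()] result.
#' @return Character vector of subclasses in
#'   `r paste(BACTERIOCIN_SUBCLASSES, collapse = ", ")`.
#' @export
assign_subclass <- function(bacteriocin_name, mapping_table = load_subclass_map()) {
  i <- match(.normalize_bname(bacteriocin_name), mapping_table$key)
  out <- mapping_table$subclass[i]
  out[is.na(out)] <- "other"
  out
}

#' Species-level bacteriocin abundance and diversity summary
#'
#' One row per species: percentage of genomes with at least one locus
#' (one decimal), total structural-locus count, number of distinct
#' bacteriocin names, the top-3 dominant names by count (ties broken
#' lexicographically; `"None"` when empty), and a production tier from
#' [bacteriocin_tier()].
#'
#' @param loci [consolidate()] output.
#' @param metadata Cohort metadata (`genome_id`, `species`).
#' @return `data.frame`: `species`, `n_genomes`, `pct_with_any`,
#'   `total_abundance`, `unique_types`, `dominant`, `tier`.
#' @export
species_summary <- function(loci, metadata) {
  species <- sort(unique(metadata$species))
  rows <- lapply(species, function(sp) {
    ids <- metadata$genome_id[metadata$species == sp]
    if (!length(ids)) return(NULL)
    sub <- loci[loci$genome_id %in% ids, , drop = FALSE]
    with_any <- length(unique(sub$genome_id))
    counts <- sort(table(sub$name), decreasing = TRUE)
    dominant <- if (!length(counts)) "None" else {
      ord <- order(-as.integer(counts), names(counts))
      paste(head(names(counts)[ord], 3L), collapse = "; ")
    }
    data.frame(species = sp, n_genomes = length(ids),
               pct_with_any = round(100 * with_any / length(ids), 1),
               total_abundance = nrow(sub),
               unique_types = length(unique(sub$name)),
               dominant = dominant,
               tier = bacteriocin_tier(nrow(sub)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Production tier from total bacteriocin abundance
#'
#' Thresholds inferred so the rule reproduces the printed species notes of
#' the family-wide survey on all 35 species: `strong` when total abundance
#' is at least 500 loci, `moderate` when strictly between 50 and 500, else
#' `low_none`.
#'
#' @param total_abundance Locus count (vectorized).
#' @return Character vector of tiers.
#' @export
bacteriocin_tier <- function(total_abundance) {
  ifelse(total_abundance >= 500, "strong",
         ifelse(total_abundance > 50, "moderate", "low_none"))
}

#' Per-species subclass composition
#'
#' Proportions over the fixed subclass scheme; species with no loci emit
#' an all-zero row flagged in attribute `no_loci`.
#'
#' @param loci [consolidate()] output.
#' @param metadata Cohort metadata.
#' @param mapping_table Subclass mapping (default packaged).
#' @return Numeric matrix species x subclass, rows summing to 1 (or 0 for
#'   flagged species).
#' @export
subclass_composition <- function(loci, metadata,
                                 mapping_table = load_subclass_map()) {
  species <- sort(unique(metadata$species))
  m <- matrix(0, length(species), length(BACTERIOCIN_SUBCLASSES),
              dimnames = list(species, BACTERIOCIN_SUBCLASSES))
  if (nrow(loci)) {
    sp <- metadata$species[match(loci$genome_id, metadata$genome_id)]
    cl <- assign_subclass(loci$name, mapping_table)
    tab <- table(factor(sp, levels = species),
                 factor(cl, levels = BACTERIOCIN_SUBCLASSES))
    m[] <- as.numeric(tab)
  }
  tot <- rowSums(m)
  no_loci <- rownames(m)[tot == 0]
  tot[tot == 0] <- 1
  m <- m / tot
  attr(m, "no_loci") <- no_loci
  m
}
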