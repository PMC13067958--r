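# Desk-scale supra-pan-genome: greedy centroid clustering of proteins at
# >= 95% amino-acid identity (coverage of the shorter sequence >= 80% so
# domain-level matches cannot chain families), prevalence partitioning
# into soft-core/shell/cloud, gene-accumulation curves, and per-genome
# unique-gene counts.
#
# The greedy pass scans proteins by decreasing length (ties: lexicographic
# id); each joins the first existing centroid it matches, else founds a
# new family named after itself. A shared-12-mer prefilter (short-word
# filter in the CD-HIT tradition) skips alignments against centroids that
# cannot plausibly reach the identity threshold.

PANGENOME_THRESHOLDS <- list(soft_core = 0.95, shell = 0.15)

.kmers <- function(seq, k = 12L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Cluster proteins into ortholog families (greedy centroid, >= 95% id)
#'
#' @param proteins `data.frame` with columns `protein_id`, `genome_id`,
#'   `sequence` (amino acids).
#' @param identity_threshold Percent identity for family membership
#'   (default 95).
#' @param min_short_coverage Minimum aligned fraction of the shorter
#'   sequence (default 0.8).
#' @return `data.frame`: `family_id` (centroid protein id), `protein_id`,
#'   `genome_id`; attribute `n_genomes` records the cohort size.
#' @export
cluster_families <- function(proteins, identity_threshold = 95,
                             min_short_coverage = 0.8) {
  if (is.null(proteins) || nrow(proteins) == 0L) {
    out <- data.frame(family_id = character(0), protein_id = character(0),
                      genome_id = character(0), stringsAsFactors = FALSE)
    attr(out, "n_genomes") <- 0L
    return(out)
  }
  .assert(!anyDuplicated(proteins$protein_id), "protein_id must be unique")
  mat <- .blosum62()
  p <- proteins[order(-nchar(proteins$sequence), proteins$protein_id), ,
                drop = FALSE]

  cent_id <- character(0); cent_seq <- character(0); cent_len <- integer(0)
  kmer_index <- new.env(parent = emptyenv())
  assign_fam <- character(nrow(p))

  for (i in seq_len(nrow(p))) {
    s <- p$sequence[i]; L <- nchar(s)
    kms <- .kmers(s)
    cand <- unique(unlist(lapply(kms, function(km)
      get0(km, envir = kmer_index, ifnotfound = NULL))))
    hit <- NA_integer_
    if (length(cand)) {
      cand <- sort(cand)  # first-founded centroid wins
      for (ci in cand) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(s), Biostrings::AAString(cent_seq[ci]),
          type = "local", substitutionMatrix = mat,
          gapOpening = 11, gapExtension = 1)
        st <- .align_stats(aln, L, nchar(cent_seq[ci]))
        short_cov <- (st$query_end - st$query_start + 1) / min(L, cent_len[ci])
        if (st$percent_identity >= identity_threshold &&
            short_cov >= min_short_coverage) { hit <- ci; break }
      }
    }
    if (is.na(hit)) {
      cent_id <- c(cent_id, p$protein_id[i])
      cent_seq <- c(cent_seq, s)
      cent_len <- c(cent_len, L)
      ci_new <- length(cent_id)
      for (km in kms)
        assign(km, c(get0(km, envir = kmer_index, ifnotfound = NULL), ci_new),
               envir = kmer_index)
      assign_fam[i] <- p$protein_id[i]
    } else assign_fam[i] <- cent_id[hit]
  }
  out <- data.frame(family_id = assign_fam, protein_id = p$protein_id,
                    genome_id = p$genome_id, stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_genomes") <- length(unique(proteins$genome_id))
  out
}

#' Family prevalence across genomes
#'
#' Paralogs within one genome share a family; prevalence counts distinct
#' genomes with at least one member.
#'
#' @param families [cluster_families()] output.
#' @param n_genomes Cohort size (defaults to the attribute recorded by
#'   [cluster_families()]).
#' @return `data.frame`: `family_id`, `n_members`, `n_genomes_present`,
#'   `prevalence`.
#' @export
family_prevalence_table <- function(families,
                                    n_genomes = attr(families, "n_genomes")) {
  .assert(!is.null(n_genomes) && n_genomes >= 1, "n_genomes must be >= 1")
  sp <- split(families$genome_id, families$family_id)
  data.frame(family_id = names(sp),
             n_members = lengths(sp),
             n_genomes_present = vapply(sp, function(g) length(unique(g)), 0L),
             prevalence = vapply(sp, function(g) length(unique(g)), 0L) / n_genomes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Soft-core / shell / cloud partition census
#'
#' Soft-core: prevalence >= 95% of genomes; shell: 15% <= prevalence
#' < 95%; cloud: prevalence < 15%.
#'
#' @param families [cluster_families()] output.
#' @param n_genomes Cohort size.
#' @param thresholds List with `soft_core` and `shell` prevalence cutoffs.
#' @return List: `census` (named counts summing to the number of
#'   families) and `table` (per-family partition).
#' @export
partition <- function(families, n_genomes = attr(families, "n_genomes"),
                      thresholds = PANGENOME_THRESHOLDS) {
  prev <- family_prevalence_table(families, n_genomes)
  part <- ifelse(prev$prevalence >= thresholds$soft_core, "soft_core",
                 ifelse(prev$prevalence >= thresholds$shell, "shell", "cloud"))
  prev$partition <- part
  census <- c(soft_core = sum(part == "soft_core"),
              shell = sum(part == "shell"),
              cloud = sum(part == "cloud"))
  list(census = census, table = prev)
}

#' Gene-family accumulation curve
#'
#' For each of `n_permutations` random genome orderings, the cumulative
#' number of distinct families after each added genome; reports mean and
#' quartiles per step. Deterministic under `seed`.
#'
#' @param families [cluster_families()] output.
#' @param n_permutations Number of genome-order permutations (default 100).
#' @param seed Integer seed.
#' @return `data.frame`: `n_genomes`, `mean_families`, `q25`, `median`,
#'   `q75`.
#' @export
accumulation_curve <- function(families, n_permutations = 100, seed = 1L) {
  genomes <- sort(unique(families$genome_id))
  .assert(length(genomes) >= 2, "need >= 2 genomes for an accumulation curve")
  fam_by_genome <- lapply(genomes, function(g)
    unique(families$family_id[families$genome_id == g]))
  names(fam_by_genome) <- genomes
  set.seed(seed)
  curves <- matrix(0L, n_permutations, length(genomes))
  for (p in seq_len(n_permutations)) {
    ord <- sample(genomes)
    seen <- character(0)
    for (k in seq_along(ord)) {
      seen <- unique(c(seen, fam_by_genome[[ord[k]]]))
      curves[p, k] <- length(seen)
    }
  }
  data.frame(n_genomes = seq_along(genomes),
             mean_families = colMeans(curves),
             q25 = apply(curves, 2, quantile, 0.25),
             median = apply(curves, 2, median),
             q75 = apply(curves, 2, quantile, 0.75),
             row.names = NULL)
}

#' Per-genome counts of genome-private families
#'
#' A family is private when exactly one genome carries members. Species
#' roll-ups are means of per-genome counts.
#'
#' @param families [cluster_families()] output.
#' @param metadata Optional cohort metadata for the species roll-up.
#' @return `data.frame` `genome_id`, `unique_families`; when `metadata`
#'   is given, attribute `by_species` holds the species means.
#' @export
unique_genes <- function(families, metadata = NULL) {
  prev <- family_prevalence_table(families,
                                  n_genomes = max(1L, attr(families, "n_genomes")))
  private <- prev$family_id[prev$n_genomes_present == 1L]
  genomes <- sort(unique(families$genome_id))
  cnt <- vapply(genomes, function(g)
    length(unique(families$family_id[families$genome_id == g &
                                       families$family_id %in% private])), 0L)
  out <- data.frame(genome_id = genomes, unique_families = cnt,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    sp <- metadata$species[match(out$genome_id, metadata$genome_id)]
    attr(out, "by_species") <- tapply(out$unique_families, sp, mean)
  }
  out
}

#' Presence/absence matrix of families across genomes
#'
#' @param families [cluster_families()] output.
#' @return Logical matrix families x genomes.
#' @export
family_presence_absence <- function(families) {
  fams <- sort(unique(families$family_id))
  genomes <- sort(unique(families$genome_id))
  m <- matrix(FALSE, length(fams), length(genomes),
              dimnames = list(fams, genomes))
  m[cbind(match(families$family_id, fams),
          match(families$genome_id, genomes))] <- TRUE
  m
}

#' Collect cohort proteins for clustering
#'
#' @param genomes Named list of [genome_record()] objects.
#' @return `data.frame` `protein_id` (genome-qualified locus tag),
#'   `genome_id`, `sequence`.
#' @export
cohort_proteins <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    if (!nrow(f)) return(NULL)
    data.frame(protein_id = f$locus_tag, genome_id = g$genome_id,
               sequence = f$translation, stringsAsFactors = FALSE)
  }))
}
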