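# Independent brute-force oracles used to check the package's
# implementations. They deliberately share no code with the package paths
# they verify.

# Affine-gap Smith-Waterman (Gotoh) on small sequences; a gap of length L
# costs open + L * ext, matching the aligner's convention.
sw_oracle <- function(query, subject, mat, open = 11, ext = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (consume query)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (consume subject)
  best <- 0
  for (i in 1 + seq_len(n)) {
    for (j in 1 + seq_len(m)) {
      sub <- mat[q[i - 1], s[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sub, Ix[i - 1, j - 1] + sub,
                     Iy[i - 1, j - 1] + sub)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# N50 by enumerating every candidate cutoff
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

# Tie-corrected Kruskal-Wallis H computed from first principles
kruskal_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Single-linkage clustering over the all-pairs identity relation, using
# the same pairwise statistics but exhaustive linkage instead of the
# greedy centroid pass.
single_linkage_oracle <- function(proteins, identity_threshold = 95,
                                  min_short_coverage = 0.8) {
  n <- nrow(proteins)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    st <- local_align(proteins$sequence[i], proteins$sequence[j])
    short <- min(nchar(proteins$sequence[i]), nchar(proteins$sequence[j]))
    cov <- (st$query_end - st$query_start + 1) / short
    if (st$percent_identity >= identity_threshold && cov >= min_short_coverage) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  split(proteins$protein_id, comp)
}

# Pairwise-overlap consolidation oracle: single linkage over the
# "redundant" relation among structural same-name hits, count components.
consolidate_oracle_count <- function(hits, min_overlap = 0.5) {
  h <- hits[hits$role == "structural", , drop = FALSE]
  if (!nrow(h)) return(0L)
  key <- paste(h$genome_id, h$contig_id, h$name)
  total <- 0L
  for (k in unique(key)) {
    sub <- h[key == k, , drop = FALSE]
    n <- nrow(sub); comp <- seq_len(n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      ov <- min(sub$end[i], sub$end[j]) - max(sub$start[i], sub$start[j]) + 1
      shorter <- min(sub$end[i] - sub$start[i], sub$end[j] - sub$start[j]) + 1
      if (ov > min_overlap * shorter) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
    total <- total + length(unique(comp))
  }
  total
}

# BLOSUM62 matrix for the oracle
blosum62_matrix <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}
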