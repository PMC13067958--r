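# CAZyme search-output filtering (DIAMOND-workflow cutoff: E < 1e-102
# strict, top hit per query) and family/class aggregation.

CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM")
CAZY_EVALUE_CUTOFF <- 1e-102

# parse a subject label into (family, subfamily); supports "GH13",
# "GH13_31" and "ACC|GH13(1-300)" dialects. NA family when unparsable.
.parse_cazy_label <- function(label) {
  x <- sub("^.*\\|", "", label)         # strip accession prefix
  x <- sub("\\(.*$", "", x)             # strip coordinate suffix
  m <- regmatches(x, regexec("^([A-Z]+)([0-9]+)(?:_([0-9]+))?$", x))[[1]]
  if (length(m) == 0 || !(m[2] %in% CAZY_CLASSES))
    return(c(family = NA_character_, subfamily = NA_character_))
  c(family = paste0(m[2], m[3]),
    subfamily = if (m[4] == "") NA_character_ else m[4])
}

#' Filter DIAMOND-style CAZyme hits and assign families
#'
#' Per query only the single best hit is kept (highest bit score; ties by
#' lowest E-value, then lexicographic subject label), then hits survive
#' iff `evalue < 1e-102` (strict). The family is parsed from the subject
#' label (base family; subfamily suffix reported separately) and the class
#' is its alphabetic prefix. Rows with unparsable subject labels are
#' dropped with a warning.
#'
#' @param raw_tabular_hits 12-column BLAST-style `data.frame` (qseqid,
#'   sseqid, ..., evalue, bitscore), optionally with a `genome_id` column.
#' @return Assignments `data.frame`: `protein_id`, `genome_id`, `family`,
#'   `subfamily`, `cazy_class`, `e_value`.
#' @export
filter_and_assign <- function(raw_tabular_hits) {
  x <- raw_tabular_hits
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  .assert(all(need %in% names(x)), "hits need columns: ",
          paste(need, collapse = ", "))
  if (is.null(x$genome_id)) x$genome_id <- rep(NA_character_, nrow(x))
  if (!nrow(x))
    return(data.frame(protein_id = character(0), genome_id = character(0),
                      family = character(0), subfamily = character(0),
                      cazy_class = character(0), e_value = numeric(0),
                      stringsAsFactors = FALSE))

  parsed <- t(vapply(x$sseqid, .parse_cazy_label,
                     c(family = "", subfamily = "")))
  bad <- is.na(parsed[, "family"])
  if (any(bad)) {
    warning(sum(bad), " hit(s) with unparsable CAZy subject label dropped",
            call. = FALSE)
    x <- x[!bad, , drop = FALSE]
    parsed <- parsed[!bad, , drop = FALSE]
  }
  x$family <- parsed[, "family"]
  x$subfamily <- parsed[, "subfamily"]

  # deterministic top-1 per query
  ord <- order(x$qseqid, -x$bitscore, x$evalue, x$sseqid)
  x <- x[ord, , drop = FALSE]
  x <- x[!duplicated(x$qseqid), , drop = FALSE]
  x <- x[x$evalue < CAZY_EVALUE_CUTOFF, , drop = FALSE]

  out <- data.frame(protein_id = x$qseqid, genome_id = x$genome_id,
                    family = x$family, subfamily = x$subfamily,
                    cazy_class = sub("[0-9].*$", "", x$family),
                    e_value = x$evalue, stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CAZyme class counts per genome or species
#'
#' @param assignments [filter_and_assign()] output.
#' @param metadata Cohort metadata; required for `grouping = "species"`.
#' @param grouping `"genome"` or `"species"`.
#' @return Long `data.frame`: `group`, `cazy_class`, `count`, plus
#'   `mean_per_genome` when grouping by species.
#' @export
class_counts <- function(assignments, metadata = NULL,
                         grouping = c("genome", "species")) {
  grouping <- match.arg(grouping)
  grp <- if (grouping == "genome") assignments$genome_id else {
    .assert(!is.null(metadata), "metadata required for species grouping")
    metadata$species[match(assignments$genome_id, metadata$genome_id)]
  }
  levels_grp <- sort(unique(grp))
  tab <- table(factor(grp, levels = levels_grp),
               factor(assignments$cazy_class, levels = CAZY_CLASSES))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "cazy_class", "count")
  if (grouping == "species") {
    n_gen <- vapply(levels_grp, function(sp)
      length(unique(metadata$genome_id[metadata$species == sp])), 0L)
    out$mean_per_genome <- out$count / n_gen[out$group]
  }
  out
}

#' Per-species prevalence of CAZyme families
#'
#' Prevalence is the percentage of a species' genomes carrying at least
#' one assignment of the family. Dense output: every observed family is
#' reported for every species (0% rows included).
#'
#' @param assignments [filter_and_assign()] output (with `genome_id`).
#' @param metadata Cohort metadata.
#' @return Long `data.frame`: `species`, `family`, `cazy_class`,
#'   `n_genomes`, `n_carrying`, `prevalence`.
#' @export
family_prevalence <- function(assignments, metadata) {
  fams <- sort(unique(assignments$family))
  species <- sort(unique(metadata$species))
  rows <- list()
  for (sp in species) {
    ids <- metadata$genome_id[metadata$species == sp]
    sub <- assignments[assignments$genome_id %in% ids, , drop = FALSE]
    for (fam in fams) {
      k <- length(unique(sub$genome_id[sub$family == fam]))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, family = fam, cazy_class = sub("[0-9].*$", "", fam),
        n_genomes = length(ids), n_carrying = k,
        prevalence = 100 * k / length(ids), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(species = character(0), family = character(0),
                      cazy_class = character(0), n_genomes = integer(0),
                      n_carrying = integer(0), prevalence = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
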