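# Safety-relevant gene screening: threshold retention for alignment-based
# AMR and virulence-factor hits, annotation-term screens for biogenic-amine
# decarboxylases and hemolysin/cytolysin genes, and per-species prevalence
# roll-ups. Coverage is query-relative (flagged in output headers).

#' Safety panel definitions
#'
#' `AMR` and `VF` are alignment panels with the published retention
#' thresholds (AMR: coverage >= 50%, identity >= 90%; VF: coverage >= 70%,
#' identity >= 90%; boundaries retained). `BA` and `HEMOLYSIN` are
#' annotation-term panels over gene symbols and product-name synonyms
#' (hdcA/tdc/odc/cadA decarboxylases plus tyrP; hly*/cyl* with hemolysin
#' and cytolysin product terms).
#'
#' @param panel_id One of `AMR`, `VF`, `BA`, `HEMOLYSIN`.
#' @return A `safety_panel` list: `panel_id`, `detection`, and either
#'   `min_coverage`/`min_identity` or `term_patterns` (named by canonical
#'   gene symbol).
#' @export
safety_panel <- function(panel_id = c("AMR", "VF", "BA", "HEMOLYSIN")) {
  panel_id <- match.arg(panel_id)
  out <- switch(panel_id,
    AMR = list(panel_id = "AMR", detection = "alignment",
               min_coverage = 0.50, min_identity = 90),
    VF = list(panel_id = "VF", detection = "alignment",
              min_coverage = 0.70, min_identity = 90),
    BA = list(panel_id = "BA", detection = "annotation_terms",
              term_patterns = c(
                hdcA = "\\b(hdcA?|histidine decarboxylase)\\b",
                tdc = "\\b(tdc|tyrDC|tyrosine decarboxylase)\\b",
                odc = "\\b(odc|ornithine decarboxylase)\\b",
                cadA = "\\b(cadA|lysine decarboxylase)\\b",
                tyrP = "\\b(tyrP|tyrosine permease)\\b")),
    HEMOLYSIN = list(panel_id = "HEMOLYSIN", detection = "annotation_terms",
                     term_patterns = c(
                       hly = "\\bhly[A-Za-z0-9]*\\b|\\bhemolysin\\b",
                       cyl = "\\bcyl[A-Za-z0-9]*\\b|\\bcytolysin\\b")))
  class(out) <- "safety_panel"
  out
}

#' Filter alignment-based safety hits by panel thresholds
#'
#' A hit is retained iff `coverage >= min_coverage` and
#' `identity >= min_identity`; boundary values are retained. Rows missing
#' coverage or identity are rejected with reason `MALFORMED`.
#'
#' @param raw_hits `data.frame` with at least `genome_id`, `gene`,
#'   `coverage` (query-relative fraction) and `identity` (percent).
#' @param panel A [safety_panel()] with `detection = "alignment"`.
#' @return `raw_hits` plus `panel_id`, `retained` and `reason` columns.
#' @export
filter_alignment_hits <- function(raw_hits, panel) {
  .assert(is(panel, "safety_panel") && panel$detection == "alignment",
          "panel must be an alignment safety panel")
  if (is.null(raw_hits) || nrow(raw_hits) == 0L)
    return(data.frame(genome_id = character(0), gene = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      panel_id = character(0), retained = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  malformed <- is.na(raw_hits$coverage) | is.na(raw_hits$identity)
  retained <- !malformed &
    raw_hits$coverage >= panel$min_coverage &
    raw_hits$identity >= panel$min_identity
  out <- raw_hits
  out$panel_id <- panel$panel_id
  out$retained <- retained
  out$reason <- ifelse(malformed, "MALFORMED",
                       ifelse(retained, "", "BELOW_THRESHOLDS"))
  out
}

#' Screen a genome's annotation text for term-panel safety genes
#'
#' Same matching semantics as the marker screen: case-insensitive regex
#' over gene and product fields, one hit per (CDS, gene symbol).
#'
#' @param genome A [genome_record()].
#' @param panel A [safety_panel()] with `detection = "annotation_terms"`.
#' @return `data.frame`: `genome_id`, `panel_id`, `gene` (canonical
#'   symbol), `locus_tag`, `matched_field`, `retained` (always `TRUE`).
#' @export
screen_terms <- function(genome, panel) {
  .assert(is(panel, "safety_panel") && panel$detection == "annotation_terms",
          "panel must be an annotation-term safety panel")
  f <- genome$features
  rows <- list()
  for (sym in names(panel$term_patterns)) {
    pat <- panel$term_patterns[[sym]]
    for (fld in c("gene", "product")) {
      v <- if (fld == "gene") f$gene_name else f$product
      idx <- which(.regex_hit(pat, v))
      for (i in idx)
        rows[[paste(sym, f$locus_tag[i])]] <- data.frame(
          genome_id = genome$genome_id, panel_id = panel$panel_id,
          gene = sym, locus_tag = f$locus_tag[i], matched_field = fld,
          retained = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(0), panel_id = character(0),
               gene = character(0), locus_tag = character(0),
               matched_field = character(0), retained = logical(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$locus_tag, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-species prevalence of retained safety genes
#'
#' Prevalence is the percentage of a species' genomes carrying at least
#' one retained hit for the gene; a genome counts once per gene no matter
#' how many copies it carries. Genes observed anywhere are reported for
#' every species (0% rows retained in the long output).
#'
#' @param hits Retained hits: columns `genome_id`, `panel_id`, `gene`,
#'   `retained`.
#' @param metadata Cohort metadata (`genome_id`, `species`).
#' @return Long `data.frame`: `species`, `panel_id`, `gene`, `n_genomes`,
#'   `n_carrying`, `prevalence`.
#' @export
safety_profile <- function(hits, metadata) {
  hits <- hits[hits$retained, , drop = FALSE]
  genes <- unique(hits[, c("panel_id", "gene")])
  n_by_species <- table(metadata$species)
  rows <- list()
  for (sp in sort(names(n_by_species))) {
    ids <- metadata$genome_id[metadata$species == sp]
    for (i in seq_len(nrow(genes))) {
      sub <- hits[hits$panel_id == genes$panel_id[i] &
                    hits$gene == genes$gene[i] &
                    hits$genome_id %in% ids, , drop = FALSE]
      k <- length(unique(sub$genome_id))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, panel_id = genes$panel_id[i], gene = genes$gene[i],
        n_genomes = as.integer(n_by_species[[sp]]), n_carrying = k,
        prevalence = 100 * k / n_by_species[[sp]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(species = character(0), panel_id = character(0),
                      gene = character(0), n_genomes = integer(0),
                      n_carrying = integer(0), prevalence = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Run the full safety screen on a cohort
#'
#' Alignment panels consume external-style tabular hits; term panels scan
#' the genomes' annotation text.
#'
#' @param genomes Named list of [genome_record()] objects.
#' @param raw_hits ABRicate-style table with `genome_id`, `panel`, `gene`,
#'   `coverage`, `identity` (e.g. a synthetic cohort's `safety_hits`).
#' @param metadata Cohort metadata.
#' @return List: `hits` (all panels, retained and rejected rows) and
#'   `profile` (species prevalence of retained genes).
#' @export
safety_screen_cohort <- function(genomes, raw_hits, metadata) {
  parts <- list()
  for (pid in c("AMR", "VF")) {
    sub <- if (is.null(raw_hits)) NULL else
      raw_hits[raw_hits$panel == pid, , drop = FALSE]
    filt <- filter_alignment_hits(sub, safety_panel(pid))
    if (nrow(filt))
      parts[[pid]] <- filt[, c("genome_id", "panel_id", "gene", "coverage",
                               "identity", "retained", "reason")]
  }
  for (pid in c("BA", "HEMOLYSIN")) {
    pan <- safety_panel(pid)
    hits <- do.call(rbind, lapply(genomes, screen_terms, panel = pan))
    if (!is.null(hits) && nrow(hits)) {
      hits$coverage <- NA_real_; hits$identity <- NA_real_; hits$reason <- ""
      parts[[pid]] <- hits[, c("genome_id", "panel_id", "gene", "coverage",
                               "identity", "retained", "reason")]
    }
  }
  all_hits <- if (length(parts)) do.call(rbind, parts) else
    data.frame(genome_id = character(0), panel_id = character(0),
               gene = character(0), coverage = numeric(0),
               identity = numeric(0), retained = logical(0),
               reason = character(0), stringsAsFactors = FALSE)
  rownames(all_hits) <- NULL
  list(hits = all_hits, profile = safety_profile(all_hits, metadata))
}
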