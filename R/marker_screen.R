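# Regex screening of CDS annotation text against the probiotic marker panel,
# and presence/count/proportion matrices at marker, subcategory or category
# level. Matching semantics live entirely in the panel patterns (explicit
# word boundaries there, case-insensitive engine here).

#' The fixed category taxonomy of the packaged marker panel
#'
#' Major functional categories used to collapse marker subcategories:
#' stress tolerance, defense/CRISPR-Cas, carbohydrate utilization,
#' cell envelope/EPS, acid tolerance and energy metabolism, amino acid and
#' general metabolism, vitamin/cofactor biosynthesis, and bacteriocin and
#' antimicrobial peptide production.
#'
#' @return Character vector of category names.
#' @export
marker_categories <- function() {
  c("Cold and heat stress tolerance",
    "Defense systems and CRISPR-Cas",
    "Carbohydrate utilization and transport",
    "Cell envelope and EPS biosynthesis",
    "Acid tolerance and energy metabolism",
    "Amino acid and general metabolism",
    "Vitamin and cofactor biosynthesis",
    "Bacteriocin and antimicrobial peptide production")
}

#' Load a marker pattern panel
#'
#' The panel TSV has columns `marker_id`, `pattern` (a case-insensitive
#' Perl regular expression with its own word boundaries), `fields` (a
#' `|`-separated subset of `gene`, `product`, `note`), `category` and
#' `subcategory`. Every pattern is compiled at load time; malformed rows
#' and duplicate marker ids raise errors naming the offending row.
#'
#' @param path Panel TSV; defaults to the packaged panel covering the
#'   curated probiotic-marker list (bsh, gad, srtA/LPXTG, pili, EPS,
#'   chaperones, oxidative stress, vitamins, atpA-H, arcA-T, adhesins,
#'   S-layer, bacteriocin terms, reuterin, PTS/sugar transport, cas, ...).
#' @return `data.frame` of class `marker_panel`.
#' @export
load_panel <- function(path = default_marker_panel()) {
  panel <- read_tsv_strict(path)
  need <- c("marker_id", "pattern", "fields", "category", "subcategory")
  .assert(all(need %in% names(panel)),
          "panel must have columns: ", paste(need, collapse = ", "))
  .assert(nrow(panel) > 0, "empty panel file: ", path)
  dup <- panel$marker_id[duplicated(panel$marker_id)]
  if (length(dup)) stop("duplicate marker_id in panel: ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(panel))) {
    ok <- tryCatch({ grepl(panel$pattern[i], "x", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("malformed regex in panel row ", i, " (", panel$marker_id[i], ")")
    flds <- strsplit(panel$fields[i], "|", fixed = TRUE)[[1]]
    if (!length(flds) || !all(flds %in% c("gene", "product", "note")))
      stop("invalid fields in panel row ", i, " (", panel$marker_id[i],
           "): must be subset of gene|product|note")
  }
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' @rdname load_panel
#' @export
default_marker_panel <- function() .pkg_file("marker_panel.tsv")

#' Screen one genome's CDS annotation text against a marker panel
#'
#' Every (CDS, pattern) pair where the pattern matches any of its target
#' fields yields one hit; a CDS may hit several markers but never the same
#' marker twice. Output is sorted by (locus_tag, marker_id) so results do
#' not depend on feature order.
#'
#' @param genome A [genome_record()].
#' @param panel A [load_panel()] result.
#' @return `data.frame` with columns `genome_id`, `locus_tag`, `marker_id`,
#'   `matched_field`, `matched_text`.
#' @export
screen_genome <- function(genome, panel) {
  f <- genome$features
  .assert(nrow(f) > 0, "genome ", genome$genome_id, " has no features")
  field_vals <- list(gene = f$gene_name, product = f$product, note = f$note)
  hits <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    flds <- strsplit(panel$fields[i], "|", fixed = TRUE)[[1]]
    matched_field <- rep(NA_character_, nrow(f))
    # first matching field wins for reporting; the hit itself is per marker
    for (fld in flds) {
      m <- .regex_hit(panel$pattern[i], field_vals[[fld]])
      matched_field[is.na(matched_field) & m] <- fld
    }
    idx <- which(!is.na(matched_field))
    if (length(idx))
      hits[[i]] <- data.frame(
        genome_id = genome$genome_id,
        locus_tag = f$locus_tag[idx],
        marker_id = panel$marker_id[i],
        matched_field = matched_field[idx],
        matched_text = vapply(idx, function(j)
          field_vals[[matched_field[j]]][j], ""),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(genome_id = character(0), locus_tag = character(0),
                      marker_id = character(0), matched_field = character(0),
                      matched_text = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$locus_tag, out$marker_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen every genome in a cohort
#'
#' @param genomes List of [genome_record()] objects.
#' @inheritParams screen_genome
#' @return Row-bound hits across genomes.
#' @export
screen_cohort <- function(genomes, panel = load_panel()) {
  out <- do.call(rbind, unname(lapply(genomes, screen_genome, panel = panel)))
  rownames(out) <- NULL
  out
}

#' Build a presence/count/proportion matrix from marker hits
#'
#' @param hits Hit table from [screen_genome()]/[screen_cohort()].
#' @param panel The panel used for screening (supplies the
#'   marker/subcategory/category taxonomy and the full column universe).
#' @param metadata Cohort metadata (`genome_id`, `species`); required when
#'   `grouping = "species"`. Row universe is taken from `metadata` when
#'   given, else from the hits.
#' @param grouping `"genome"` or `"species"` rows.
#' @param level `"marker"`, `"subcategory"` or `"category"` columns.
#' @param mode `"presence"` (any-hit logical), `"count"` (hits summed over
#'   the group) or `"proportion"` (counts divided by the row total; all-zero
#'   rows stay zero and are listed in attribute `zero_rows`).
#' @return Numeric (or logical) matrix with row/column names; attribute
#'   `mode` records the mode.
#' @export
build_matrix <- function(hits, panel, metadata = NULL,
                         grouping = c("genome", "species"),
                         level = c("marker", "subcategory", "category"),
                         mode = c("presence", "count", "proportion")) {
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (grouping == "species")
    .assert(!is.null(metadata), "metadata required for species grouping")

  col_map <- switch(level,
    marker = setNames(panel$marker_id, panel$marker_id),
    subcategory = setNames(panel$subcategory, panel$marker_id),
    category = setNames(panel$category, panel$marker_id))
  col_ids <- unique(unname(col_map))

  row_of_genome <- if (grouping == "genome") identity else
    function(g) metadata$species[match(g, metadata$genome_id)]
  row_ids <- if (!is.null(metadata)) {
    if (grouping == "genome") metadata$genome_id else unique(metadata$species)
  } else unique(row_of_genome(hits$genome_id))

  m <- matrix(0, nrow = length(row_ids), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(hits)) {
    unknown <- setdiff(hits$marker_id, names(col_map))
    if (length(unknown)) stop("hits reference markers absent from panel: ",
                              paste(unknown, collapse = ", "))
    rr <- row_of_genome(hits$genome_id)
    cc <- unname(col_map[hits$marker_id])
    tab <- table(factor(rr, levels = row_ids), factor(cc, levels = col_ids))
    m[] <- as.numeric(tab)
  }
  if (mode == "presence") {
    m <- m > 0
  } else if (mode == "proportion") {
    tot <- rowSums(m)
    zero <- rownames(m)[tot == 0]
    tot[tot == 0] <- 1
    m <- m / tot
    attr(m, "zero_rows") <- zero
  }
  attr(m, "mode") <- mode
  m
}
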