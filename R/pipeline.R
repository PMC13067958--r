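# Pipeline orchestration: run stages in dependency order over a cohort
# (simulated or read from disk), emit every table as UTF-8 TSV, and record
# a run manifest sufficient to reproduce the bundle. A single top-level
# seed deterministically derives per-stage seeds.

PIPELINE_STAGES <- c("qc", "screen", "confirm", "safety", "bacteriocin",
                     "cazyme", "pangenome", "summaries")

#' Compare genome sizes across isolation-source categories
#'
#' Kruskal-Wallis rank test (tie-corrected H, chi-square approximation
#' with groups - 1 degrees of freedom) of total assembly length across
#' source categories, with per-category medians. The `missing` category
#' is excluded by default.
#'
#' @param metrics [compute_metrics()] rows (needs `genome_id`,
#'   `total_length`).
#' @param metadata Cohort metadata (`genome_id`, `source_category`).
#' @param include_missing Keep the `missing` category (default `FALSE`).
#' @return List: `statistic` (H), `df`, `p_value`, `medians` (named),
#'   `n` (named group sizes).
#' @export
compare_sizes_by_source <- function(metrics, metadata,
                                    include_missing = FALSE) {
  src <- metadata$source_category[match(metrics$genome_id, metadata$genome_id)]
  size <- metrics$total_length
  keep <- !is.na(src) & (include_missing | src != "missing")
  src <- factor(src[keep]); size <- size[keep]
  if (nlevels(droplevels(src)) < 2)
    stop("NOT_COMPARABLE: need >= 2 non-empty source categories")
  src <- droplevels(src)
  kw <- kruskal.test(size, src)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       medians = tapply(size, src, median),
       n = table(src))
}

#' Run the full screening pipeline over a cohort
#'
#' Stages run in dependency order (qc, screen, confirm, safety,
#' bacteriocin, cazyme, pangenome, summaries); any stage can be skipped.
#' Identical config + inputs give byte-identical output bundles.
#'
#' @param cohort A [simulate_cohort()] result, or a list with elements
#'   `genomes`, `metadata` and (optionally) the raw hit tables
#'   `bacteriocin_hits`, `safety_hits`, `cazyme_hits`.
#' @param out_dir Output directory for the TSV bundle (`NULL` for none).
#' @param seed Top-level seed; per-stage seeds derive from it.
#' @param skip Character vector of stage names to skip.
#' @param min_genomes_per_species Species-representation threshold
#'   (default 10, the survey's rule; lower it for miniature cohorts).
#' @param panel Marker panel (default packaged).
#' @param reference_db Confirmation reference panel (default the
#'   deterministic synthetic panel matching the cohort generator).
#' @param n_permutations Accumulation-curve permutations.
#' @return List of stage results (`qc`, `marker_hits`, `matrices`,
#'   `confirmation`, `concordance`, `safety`, `bacteriocin`, `cazyme`,
#'   `pangenome`, `summaries`, `manifest`), invisibly written to
#'   `out_dir` as TSVs when given.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, seed = 1L,
                         skip = character(0),
                         min_genomes_per_species = 10L,
                         panel = load_panel(),
                         reference_db = synthetic_reference_panel(),
                         n_permutations = 100L) {
  .assert(all(skip %in% PIPELINE_STAGES),
          "unknown stage in skip: ", paste(setdiff(skip, PIPELINE_STAGES),
                                           collapse = ", "))
  genomes <- cohort$genomes
  metadata <- cohort$metadata
  seeds <- derive_seeds(seed, PIPELINE_STAGES)
  res <- list()
  run <- function(stage) !(stage %in% skip)
  emit <- function(x, name) {
    if (!is.null(out_dir) && !is.null(x)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      if (is.matrix(x))
        x <- data.frame(row_id = rownames(x), x, check.names = FALSE,
                        stringsAsFactors = FALSE)
      write_tsv_strict(x, file.path(out_dir, paste0(name, ".tsv")))
    }
  }

  active <- genomes
  if (run("qc")) {
    res$qc <- tryCatch(
      qc_cohort(genomes, metadata, min_genomes = min_genomes_per_species),
      error = function(e) stop("stage qc failed: ", conditionMessage(e),
                               call. = FALSE))
    active <- genomes[res$qc$retained_genomes]
    qc_tab <- merge(res$qc$metrics,
                    res$qc$decisions[, c("genome_id", "passed", "reasons")],
                    by = "genome_id")
    emit(qc_tab[order(qc_tab$genome_id), ], "qc_report")
  }
  active_meta <- metadata[metadata$genome_id %in% names(active), , drop = FALSE]

  if (run("screen")) {
    res$marker_hits <- screen_cohort(active, panel)
    emit(res$marker_hits, "marker_hits")
    res$matrices <- list(
      species_category_prop = build_matrix(
        res$marker_hits, panel, active_meta, "species", "category", "proportion"),
      genome_marker_presence = build_matrix(
        res$marker_hits, panel, active_meta, "genome", "marker", "presence"))
    emit(res$matrices$species_category_prop * 1, "marker_category_proportions")
    emit(res$matrices$genome_marker_presence * 1, "marker_presence")
  }

  if (run("confirm")) {
    .assert(!is.null(res$marker_hits), "confirm requires the screen stage")
    validated <- intersect(unique(res$marker_hits$marker_id),
                           unique(reference_db$marker_id))
    cand <- res$marker_hits[res$marker_hits$marker_id %in% validated, ,
                            drop = FALSE]
    res$confirmation <- confirm_hits(cand, active, reference_db)
    res$concordance <- concordance(res$confirmation, markers = validated)
    emit(res$confirmation, "confirmation")
    emit(res$concordance, "concordance")
  }

  if (run("safety")) {
    raw <- cohort$safety_hits
    if (!is.null(raw)) raw <- raw[raw$genome_id %in% names(active), , drop = FALSE]
    res$safety <- safety_screen_cohort(active, raw, active_meta)
    emit(res$safety$hits, "safety_hits_filtered")
    emit(res$safety$profile, "safety_prevalence")
  }

  if (run("bacteriocin")) {
    raw <- cohort$bacteriocin_hits
    if (!is.null(raw)) raw <- raw[raw$genome_id %in% names(active), , drop = FALSE]
    loci <- consolidate(raw)
    res$bacteriocin <- list(
      loci = loci,
      summary = species_summary(loci, active_meta),
      composition = subclass_composition(loci, active_meta))
    emit(loci, "bacteriocin_loci")
    emit(res$bacteriocin$summary, "bacteriocin_species_summary")
    emit(res$bacteriocin$composition, "bacteriocin_composition")
  }

  if (run("cazyme")) {
    raw <- cohort$cazyme_hits
    if (!is.null(raw)) {
      raw <- raw[raw$genome_id %in% names(active) | is.na(raw$genome_id), ,
                 drop = FALSE]
      assignments <- filter_and_assign(raw)
      res$cazyme <- list(
        assignments = assignments,
        class_counts = class_counts(assignments, active_meta, "species"),
        prevalence = family_prevalence(assignments, active_meta))
      emit(assignments, "cazyme_assignments")
      emit(res$cazyme$class_counts, "cazyme_class_counts")
      emit(res$cazyme$prevalence, "cazyme_family_prevalence")
    }
  }

  if (run("pangenome")) {
    prots <- cohort_proteins(active)
    fams <- cluster_families(prots)
    res$pangenome <- list(
      families = fams,
      partition = partition(fams),
      curve = accumulation_curve(fams, n_permutations = n_permutations,
                                 seed = seeds[["pangenome"]]),
      unique_genes = unique_genes(fams, active_meta))
    emit(fams, "pangenome_families")
    emit(data.frame(partition = names(res$pangenome$partition$census),
                    n_families = as.integer(res$pangenome$partition$census)),
         "pangenome_census")
    emit(res$pangenome$curve, "pangenome_curve")
    emit(res$pangenome$unique_genes, "pangenome_unique_genes")
    pa <- family_presence_absence(fams)
    emit(pa * 1, "pangenome_presence_absence")
  }

  if (run("summaries")) {
    metrics <- if (!is.null(res$qc)) res$qc$metrics else
      do.call(rbind, lapply(genomes, compute_metrics))
    metrics <- metrics[metrics$genome_id %in% names(active), , drop = FALSE]
    kw <- tryCatch(compare_sizes_by_source(metrics, active_meta),
                   error = function(e) NULL)
    res$summaries <- list(size_by_source = kw)
    if (!is.null(kw))
      emit(data.frame(statistic = kw$statistic, df = kw$df,
                      p_value = kw$p_value), "genome_size_by_source")
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("probioscreen")),
    seed = seed, stage_seeds = as.list(seeds), skipped = skip,
    n_genomes = length(genomes), n_active = length(active),
    min_genomes_per_species = min_genomes_per_species)
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
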