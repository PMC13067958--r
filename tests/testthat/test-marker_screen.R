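test_that("the packaged panel loads, compiles and covers the lexicon", {
  panel <- load_panel()
  expect_gt(nrow(panel), 50)
  expect_true(all(panel$category %in% marker_categories()))
  # every lexicon product must match its own marker's pattern, or planted
  # markers could not be recalled
  lex <- read_tsv_strict(system.file("extdata", "marker_lexicon.tsv",
                                     package = "probioscreen"))
  for (i in seq_len(nrow(lex))) {
    pat <- panel$pattern[panel$marker_id == lex$marker_id[i]]
    expect_length(pat, 1)
    for (p in strsplit(lex$products[i], "|", fixed = TRUE)[[1]])
      expect_true(grepl(pat, p, ignore.case = TRUE, perl = TRUE),
                  label = paste(lex$marker_id[i], p))
  }
})

test_that("panel loading rejects malformed input", {
  dir <- withr::local_tempdir()
  hdr <- "marker_id\tpattern\tfields\tcategory\tsubcategory"
  dup <- file.path(dir, "dup.tsv")
  writeLines(c(hdr,
               "bsh\t\\bbsh\\b\tgene\tAcid tolerance and energy metabolism\tx",
               "bsh\t\\bbsh2\\b\tgene\tAcid tolerance and energy metabolism\tx"),
             dup)
  expect_error(load_panel(dup), "duplicate")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c(hdr, "m1\t([unclosed\tgene\tc\tx"), bad)
  expect_error(load_panel(bad), "malformed regex")
  empty <- file.path(dir, "empty.tsv")
  writeLines(hdr, empty)
  expect_error(load_panel(empty), "empty")
  badf <- file.path(dir, "badf.tsv")
  writeLines(c(hdr, "m1\t\\bx\\b\tgene|nonsense\tc\tx"), badf)
  expect_error(load_panel(badf), "fields")
})

test_that("annotation-text screening matches products, genes and notes", {
  panel <- load_panel()
  set.seed(101)
  g <- annotated_genome(
    products = c("Glutamate decarboxylase beta", "hypothetical protein",
                 "Bile salt hydrolase"),
    genes = c(NA, NA, NA),
    notes = c(NA, NA, NA))
  hits <- screen_genome(g, panel)
  expect_setequal(hits$marker_id, c("gadB", "bsh"))
  expect_true(all(hits$matched_field == "product"))
  # gene-field matching
  g2 <- annotated_genome(products = "hypothetical protein", genes = "srtA")
  h2 <- screen_genome(g2, panel)
  expect_equal(h2$marker_id, "srtA")
  expect_equal(h2$matched_field, "gene")
})

test_that("screening equals a brute-force scan on a planted+decoy fixture", {
  # 5 planted markers and 3 decoys (marker-like products on random genes)
  set.seed(77)
  products <- c("Choloylglycine hydrolase", "Chaperone protein DnaK",
                "ATP synthase subunit alpha", "Sortase A",
                "Glutamate decarboxylase beta",
                "Bile salt hydrolase", "Chaperone protein DnaK", "Sortase A",
                "hypothetical protein", "hypothetical protein")
  g <- annotated_genome(products)
  panel <- load_panel()
  hits <- screen_genome(g, panel)
  # independent brute force over all (CDS, pattern, field) triples
  expected <- 0L
  for (i in seq_len(nrow(panel))) {
    flds <- strsplit(panel$fields[i], "|", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(g$features))) {
      vals <- c(gene = g$features$gene_name[j], product = g$features$product[j],
                note = g$features$note[j])[flds]
      if (any(!is.na(vals) & grepl(panel$pattern[i], vals,
                                   ignore.case = TRUE, perl = TRUE)))
        expected <- expected + 1L
    }
  }
  expect_equal(nrow(hits), expected)
  expect_equal(expected, 8L)  # the 5 plants + 3 decoys, one marker each
})

test_that("screening output is independent of feature order", {
  co <- tiny_cohort()
  panel <- load_panel()
  g <- co$genomes[[2]]
  h1 <- screen_genome(g, panel)
  set.seed(13)
  g2 <- g
  g2$features <- g2$features[sample.int(nrow(g2$features)), ]
  h2 <- screen_genome(g2, panel)
  rownames(h1) <- rownames(h2) <- NULL
  expect_equal(h1, h2)
})

test_that("matrices aggregate consistently across modes and levels", {
  co <- tiny_cohort()
  panel <- load_panel()
  hits <- screen_cohort(co$genomes, panel)
  meta <- co$metadata

  cnt <- build_matrix(hits, panel, meta, "genome", "marker", "count")
  # column sums equal raw per-marker hit counts
  raw <- table(factor(hits$marker_id, levels = colnames(cnt)))
  expect_equal(unname(colSums(cnt)), as.numeric(raw))

  pres <- build_matrix(hits, panel, meta, "genome", "marker", "presence")
  expect_type(pres, "logical")
  expect_equal(pres, cnt > 0, ignore_attr = TRUE)

  prop <- build_matrix(hits, panel, meta, "species", "category", "proportion")
  nz <- setdiff(rownames(prop), attr(prop, "zero_rows"))
  expect_true(all(abs(rowSums(prop[nz, , drop = FALSE]) - 1) < 1e-9))

  # collapsing the subcategory matrix by taxonomy equals the category matrix
  subc <- build_matrix(hits, panel, meta, "species", "subcategory", "count")
  catm <- build_matrix(hits, panel, meta, "species", "category", "count")
  tax <- unique(panel[, c("subcategory", "category")])
  collapsed <- sapply(colnames(catm), function(ct) {
    subs <- tax$subcategory[tax$category == ct]
    rowSums(subc[, colnames(subc) %in% subs, drop = FALSE])
  })
  expect_equal(collapsed[rownames(catm), colnames(catm)],
               unclass(catm)[, ], ignore_attr = TRUE)
})

test_that("simple normalization and presence examples hold", {
  panel <- load_panel()
  hits <- data.frame(genome_id = c("A"), locus_tag = "A_1",
                     marker_id = "bsh", matched_field = "product",
                     matched_text = "Bile salt hydrolase")
  meta <- data.frame(genome_id = c("A", "B"), species = c("s1", "s1"))
  m <- build_matrix(hits, panel, meta, "genome", "marker", "presence")
  expect_true(m["A", "bsh"])
  expect_false(m["B", "bsh"])
  # proportions: counts 30/70 -> 0.3/0.7
  h2 <- rbind(
    do.call(rbind, replicate(30, data.frame(
      genome_id = "A", locus_tag = "x", marker_id = "cspA",
      matched_field = "product", matched_text = "t"), simplify = FALSE)),
    do.call(rbind, replicate(70, data.frame(
      genome_id = "A", locus_tag = "y", marker_id = "lac",
      matched_field = "product", matched_text = "t"), simplify = FALSE)))
  p <- build_matrix(h2, panel, meta, "genome", "category", "proportion")
  expect_equal(unname(p["A", "Cold and heat stress tolerance"]), 0.3)
  expect_equal(unname(p["A", "Carbohydrate utilization and transport"]), 0.7)
})
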