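test_that("clustering degenerate cases behave", {
  set.seed(55)
  p <- random_peptide(120)
  two <- data.frame(protein_id = c("a", "b"), genome_id = c("g1", "g2"),
                    sequence = c(p, p))
  fams <- cluster_families(two)
  expect_equal(length(unique(fams$family_id)), 1L)
  expect_equal(family_prevalence_table(fams)$prevalence, 1.0)

  unrel <- data.frame(protein_id = c("a", "b"), genome_id = c("g1", "g2"),
                      sequence = c(random_peptide(100), random_peptide(100)))
  expect_equal(length(unique(cluster_families(unrel)$family_id)), 2L)

  empty <- cluster_families(NULL)
  expect_equal(nrow(empty), 0L)
})

test_that("every protein lands in exactly one family (conservation)", {
  co <- pangenome_cohort()
  prots <- cohort_proteins(co$genomes)
  fams <- cluster_families(prots)
  expect_equal(nrow(fams), nrow(prots))
  expect_setequal(fams$protein_id, prots$protein_id)
})

test_that("greedy clustering equals single linkage on a separated fixture", {
  # 5 families, within-family identity >= 98%, between-family unrelated,
  # spread over 10 genomes
  set.seed(808)
  fam_refs <- vapply(rep(150, 5), random_peptide, "")
  rows <- list()
  for (g in 1:10) for (f in 1:5) {
    aa <- strsplit(fam_refs[f], "")[[1]]
    k <- sample(0:3, 1)  # <= 2% divergence
    if (k > 0) {
      idx <- sample(150, k)
      aa[idx] <- vapply(aa[idx], function(r)
        sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], r), 1), "")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = sprintf("g%02d_f%d", g, f), genome_id = sprintf("g%02d", g),
      sequence = paste(aa, collapse = ""))
  }
  prots <- do.call(rbind, rows)
  fams <- cluster_families(prots)
  expect_equal(length(unique(fams$family_id)), 5L)
  oracle <- single_linkage_oracle(prots)
  expect_equal(length(oracle), 5L)
  # identical partitions: same member sets
  got <- lapply(split(fams$protein_id, fams$family_id), sort)
  want <- lapply(oracle, sort)
  expect_setequal(unname(lapply(got, paste, collapse = ",")),
                  unname(lapply(want, paste, collapse = ",")))
})

test_that("partition thresholds are inclusive on the published sides", {
  fams <- do.call(rbind, lapply(1:3, function(f) {
    n <- c(96, 50, 10)[f]
    data.frame(family_id = paste0("F", f),
               protein_id = sprintf("F%d_%03d", f, 1:n),
               genome_id = sprintf("g%03d", 1:n))
  }))
  attr(fams, "n_genomes") <- 100L
  pt <- partition(fams)
  tab <- pt$table
  expect_equal(tab$partition[tab$family_id == "F1"], "soft_core")  # 0.96
  expect_equal(tab$partition[tab$family_id == "F2"], "shell")      # 0.50
  expect_equal(tab$partition[tab$family_id == "F3"], "cloud")      # 0.10
  expect_equal(sum(pt$census), 3L)
  # exact boundaries
  b <- data.frame(family_id = rep(c("A", "B"), c(95, 15)),
                  protein_id = sprintf("p%03d", 1:110),
                  genome_id = c(sprintf("g%03d", 1:95), sprintf("g%03d", 1:15)))
  attr(b, "n_genomes") <- 100L
  tb <- partition(b)$table
  expect_equal(tb$partition[tb$family_id == "A"], "soft_core")  # exactly 0.95
  expect_equal(tb$partition[tb$family_id == "B"], "shell")      # exactly 0.15
  # raising the soft-core cutoff never increases the soft-core count
  prev <- Inf
  for (thr in c(0.90, 0.95, 0.99)) {
    cen <- partition(b, thresholds = list(soft_core = thr, shell = 0.15))$census
    expect_lte(cen[["soft_core"]], prev)
    prev <- cen[["soft_core"]]
  }
})

test_that("accumulation curves behave on degenerate repertoires", {
  # all genomes identical: flat after the first genome
  same <- do.call(rbind, lapply(1:6, function(g)
    data.frame(family_id = paste0("F", 1:8),
               protein_id = sprintf("g%d_p%d", g, 1:8),
               genome_id = paste0("g", g))))
  cv <- accumulation_curve(same, n_permutations = 20, seed = 4)
  expect_equal(cv$mean_families, rep(8, 6))
  # fully unique genomes: exactly linear
  uniq <- do.call(rbind, lapply(1:6, function(g)
    data.frame(family_id = sprintf("g%d_F%d", g, 1:8),
               protein_id = sprintf("g%d_p%d", g, 1:8),
               genome_id = paste0("g", g))))
  cv2 <- accumulation_curve(uniq, n_permutations = 20, seed = 4)
  expect_equal(cv2$mean_families, 8 * (1:6))
  # non-decreasing in every permutation quantile
  co <- pangenome_cohort()
  fams <- cluster_families(cohort_proteins(co$genomes))
  cv3 <- accumulation_curve(fams, n_permutations = 30, seed = 9)
  expect_true(all(diff(cv3$mean_families) >= 0))
  expect_true(all(diff(cv3$q25) >= 0))
  # deterministic under seed
  cv4 <- accumulation_curve(fams, n_permutations = 30, seed = 9)
  expect_identical(cv3, cv4)
})

test_that("unique-gene counts recover the planted private genes", {
  co <- pangenome_cohort()
  fams <- cluster_families(cohort_proteins(co$genomes))
  ug <- unique_genes(fams, co$metadata)
  # generator plants exactly 5 private genes per genome
  expect_equal(ug$unique_families, rep(5L, 15), ignore_attr = TRUE)
  # identity: sum of unique counts = number of single-genome families
  prev <- family_prevalence_table(fams)
  expect_equal(sum(ug$unique_families), sum(prev$n_genomes_present == 1))
})

test_that("presence/absence matrix mirrors family membership", {
  fams <- data.frame(family_id = c("F1", "F1", "F2"),
                     protein_id = c("p1", "p2", "p3"),
                     genome_id = c("g1", "g2", "g1"))
  m <- family_presence_absence(fams)
  expect_true(m["F1", "g1"] && m["F1", "g2"] && m["F2", "g1"])
  expect_false(m["F2", "g2"])
})
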