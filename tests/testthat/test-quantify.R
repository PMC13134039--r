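test_that("shared-gene counts split proportionally to single-pathway evidence", {
  ctx <- tibble::tibble(pathway_id = c("A", "B"), sh_s = c(30, 70))
  got <- apportion_multi_pathway(100, ctx)
  expect_equal(got, c(A = 30, B = 70))
  # zero observed count propagates zeros
  expect_equal(apportion_multi_pathway(0, ctx), c(A = 0, B = 0))
  # no single-pathway evidence: documented equal-split fallback, conserved
  ctx0 <- tibble::tibble(pathway_id = c("A", "B"), sh_s = c(0, 0))
  expect_warning(got0 <- apportion_multi_pathway(100, ctx0), "equally")
  expect_equal(got0, c(A = 50, B = 50))
  expect_equal(sum(got0), 100)
  # explicit sh_m denominator is honored
  ctx_m <- tibble::tibble(pathway_id = c("A", "B"), sh_s = c(30, 50), sh_m = 100)
  expect_equal(apportion_multi_pathway(100, ctx_m), c(A = 30, B = 50))
})

test_that("apportionment conserves the observed count", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    ctx <- tibble::tibble(pathway_id = LETTERS[1:k],
                          sh_s = rpois(k, 20))
    h_o <- rpois(1, 50)
    got <- suppressWarnings(apportion_multi_pathway(h_o, ctx))
    expect_lt(abs(sum(got) - h_o), 1e-9)
  }
})

test_that("the estimator reproduces the worked two-gene example", {
  reg <- new_registry(
    pathways = list(list(id = "PX", product = "butyrate", genes = c("ga", "gb"))),
    model_scores = list(ga = c(m = 100), gb = c(m = 100)),
    require_complete = FALSE
  )
  catalog <- tibble::tibble(
    catalog_id = c("e1", "e2"), gene = c("ga", "gb"),
    pathways = list("PX", "PX"), length = c(900L, 1200L),
    sources = list("gA", "gA")
  )
  rplb <- tibble::tibble(catalog_id = "r1", length = 830L, sources = list("gA"))
  gc <- tibble::tibble(sample_id = "s1", catalog_id = c("e1", "e2"),
                       count = c(90, 60))
  rc <- tibble::tibble(sample_id = "s1", catalog_id = "r1", count = 100)
  res <- pathway_abundance(gc, rc, catalog, rplb, reg)
  # ((90/900 + 60/1200)/2) / (100/830) * 100 = 62.25
  expect_equal(res$p_genomes, 62.25, tolerance = 1e-12)
  # no pathway hits: exactly zero, not missing
  res0 <- pathway_abundance(gc[0, ], rc, catalog, rplb, reg)
  expect_equal(res0$p_genomes, 0)
  expect_false(res0$rplb_missing)
})

test_that("a fully-carried single-gene pathway at rplB-equal depth reads 100%", {
  reg <- new_registry(
    pathways = list(list(id = "PX", product = "butyrate", genes = "ga")),
    model_scores = list(ga = c(m = 100)), require_complete = FALSE
  )
  catalog <- tibble::tibble(catalog_id = "e1", gene = "ga", pathways = list("PX"),
                            length = 830L, sources = list("gA"))
  rplb <- tibble::tibble(catalog_id = "r1", length = 830L, sources = list("gA"))
  gc <- tibble::tibble(sample_id = "s1", catalog_id = "e1", count = 100)
  rc <- tibble::tibble(sample_id = "s1", catalog_id = "r1", count = 100)
  expect_equal(pathway_abundance(gc, rc, catalog, rplb, reg)$p_genomes, 100)
})

test_that("zero rplB signal is reported missing, never as zero", {
  fix <- random_quantify_fixture(1, n_samples = 1)
  rc0 <- fix$rplb_counts
  rc0$count <- 0
  expect_warning(
    res <- pathway_abundance(fix$gene_counts, rc0, fix$catalog,
                             fix$rplb_catalog, fix$registry),
    "rplB"
  )
  expect_true(all(is.na(res$p_genomes)))
  expect_true(all(res$rplb_missing))
})

test_that("estimator is invariant to a global count rescaling", {
  fix <- random_quantify_fixture(7)
  base <- suppressWarnings(pathway_abundance(fix$gene_counts, fix$rplb_counts,
                                             fix$catalog, fix$rplb_catalog,
                                             fix$registry))
  gc10 <- fix$gene_counts; gc10$count <- gc10$count * 10
  rc10 <- fix$rplb_counts; rc10$count <- rc10$count * 10
  scaled <- suppressWarnings(pathway_abundance(gc10, rc10, fix$catalog,
                                               fix$rplb_catalog, fix$registry))
  expect_equal(scaled$p_genomes, base$p_genomes, tolerance = 1e-12)
})

test_that("estimator matches the naive loop oracle on random fixtures", {
  for (seed in 1:20) {
    fix <- random_quantify_fixture(seed)
    res <- suppressWarnings(
      pathway_abundance(fix$gene_counts, fix$rplb_counts, fix$catalog,
                        fix$rplb_catalog, fix$registry))
    for (s in unique(res$sample_id)) {
      want <- suppressWarnings(
        oracle_p_genomes(fix$gene_counts, fix$rplb_counts, fix$catalog,
                         fix$rplb_catalog, fix$registry, s))
      got <- res$p_genomes[res$sample_id == s]
      names(got) <- res$pathway_id[res$sample_id == s]
      expect_equal(got[names(want)], want, tolerance = 1e-12)
    }
  }
})

test_that("product totals sum member pathways and the wide table carries them", {
  fix <- random_quantify_fixture(3, n_samples = 1)
  res <- suppressWarnings(pathway_abundance(fix$gene_counts, fix$rplb_counts,
                                            fix$catalog, fix$rplb_catalog,
                                            fix$registry))
  tot <- product_totals(res)
  expect_equal(tot$butyrate,
               sum(res$p_genomes[res$product == "butyrate"]))
  expect_equal(tot$combined, sum(res$p_genomes))
  wide <- abundance_wide(res)
  expect_equal(wide$B1, res$p_genomes[res$pathway_id == "B1"])
  expect_equal(wide$combined, tot$combined)
})

test_that("SAM counting keeps primary mapped alignments only and matches TSV input", {
  ref <- c(e1 = paste(rep("ACGT", 25), collapse = ""),
           e2 = paste(rep("GGCC", 25), collapse = ""))
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:e1\tLN:100",
    "@SQ\tSN:e2\tLN:100",
    # primary mapped on e1 (counted)
    "r1\t0\te1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********",
    # secondary on e2 (ignored)
    "r1\t256\te2\t1\t60\t10M\t*\t0\t0\t*\t*",
    # supplementary on e1 (ignored)
    "r2\t2048\te1\t5\t60\t10M\t*\t0\t0\t*\t*",
    # primary mapped on e1 (counted)
    "r3\t16\te1\t11\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********",
    # unmapped (ignored)
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t**********"
  )
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  counts <- read_sam_counts(f, sample_id = "s1")
  expect_setequal(counts$catalog_id, c("e1", "e2"))
  expect_equal(counts$count[counts$catalog_id == "e1"], 2L)
  expect_equal(counts$count[counts$catalog_id == "e2"], 0L)

  # equivalent pre-made TSV yields the same abundance
  reg <- new_registry(
    pathways = list(list(id = "PX", product = "butyrate", genes = c("ga", "gb"))),
    model_scores = list(ga = c(m = 1), gb = c(m = 1)), require_complete = FALSE
  )
  catalog <- tibble::tibble(catalog_id = c("e1", "e2"), gene = c("ga", "gb"),
                            pathways = list("PX", "PX"), length = c(100L, 100L),
                            sources = list("gA", "gB"))
  rplb <- tibble::tibble(catalog_id = "r1", length = 100L, sources = list("gA"))
  rc <- tibble::tibble(sample_id = "s1", catalog_id = "r1", count = 5)
  tsv_counts <- tibble::tibble(sample_id = "s1", catalog_id = c("e1", "e2"),
                               count = c(2, 0))
  expect_equal(
    pathway_abundance(counts, rc, catalog, rplb, reg)$p_genomes,
    pathway_abundance(tsv_counts, rc, catalog, rplb, reg)$p_genomes
  )
})

test_that("count tables referencing unknown catalog ids are rejected", {
  fix <- random_quantify_fixture(2, n_samples = 1)
  bad <- fix$gene_counts
  bad$catalog_id[1] <- "nonexistent"
  expect_error(
    pathway_abundance(bad, fix$rplb_counts, fix$catalog, fix$rplb_catalog,
                      fix$registry),
    "nonexistent"
  )
})
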