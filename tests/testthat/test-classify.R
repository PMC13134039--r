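make_hits <- function(genome, genes, scores, descriptions = NULL) {
  tibble::tibble(
    genome_id = genome, gene = genes,
    subject_id = paste0(genome, "|", genes),
    score = scores, length = NA_integer_,
    description = if (is.null(descriptions)) rep("x", length(genes)) else descriptions
  )
}

test_that("score filter keeps hits at or above half the lowest model score", {
  scores <- list(but = c(s1 = 200, s2 = 150, s3 = 180))  # cutoff 75
  h <- make_hits("g1", rep("but", 3), c(80, 74.9, 75))
  kept <- filter_hits(h, scores)
  expect_equal(kept$score, c(80, 75))
  # empty input maps to empty output
  expect_equal(nrow(filter_hits(h[0, ], scores)), 0)
  # a gene without model scores is a hard error naming the gene
  expect_error(filter_hits(make_hits("g1", "mystery", 10), scores), "mystery")
})

test_that("score filter is idempotent, order-independent and matches the per-hit oracle", {
  reg <- tiny_registry()
  for (seed in 1:5) {
    h <- random_hits(reg, seed = seed)
    kept <- filter_hits(h, reg)
    expect_equal(kept, oracle_filter(h, reg$model_scores))
    expect_equal(filter_hits(kept, reg), kept)
    shuffled <- h[sample(nrow(h)), ]
    kept_sh <- filter_hits(shuffled, reg)
    expect_equal(dplyr::arrange(kept_sh, subject_id),
                 dplyr::arrange(kept, subject_id))
  }
})

test_that("pathway completeness requires every required gene", {
  reg <- tiny_registry()
  # all B1 genes except one: B1 absent
  h <- make_hits("gA", c("g1", "g2"), c(500, 500))
  expect_equal(call_complete_pathways(h, reg)$complete[[1]], character(0))
  # full B2 and P1 gene sets: both called, independently
  h2 <- make_hits("gB", c("g3", "g_sh", "g4", "g5"), rep(500, 4))
  expect_setequal(call_complete_pathways(h2, reg)$complete[[1]], c("B2", "P1"))
})

test_that("completeness calls match the brute-force set-cover oracle", {
  reg <- default_registry()
  genes <- registry_genes(reg)
  set.seed(42)
  for (i in 1:60) {
    gs <- sample(genes, sample(0:length(genes), 1))
    h <- make_hits(sprintf("g%03d", i), gs, rep(1000, length(gs)))
    got <- if (length(gs) == 0) character(0) else
      call_complete_pathways(h, reg)$complete[[1]]
    expect_setequal(got, oracle_complete(gs, reg))
  }
})

test_that("completeness is monotone under added hits", {
  reg <- default_registry()
  genes <- registry_genes(reg)
  set.seed(7)
  for (i in 1:20) {
    gs <- sample(genes, sample(length(genes), 1))
    extra <- unique(c(gs, sample(genes, 3)))
    before <- oracle_complete(gs, reg)
    h <- make_hits("g1", extra, rep(1000, length(extra)))
    after <- call_complete_pathways(h, reg)$complete[[1]]
    expect_true(all(before %in% after))
  }
})

test_that("single-pathway resolution follows the mean score-ratio rule", {
  reg <- tiny_registry()
  # clear winner
  expect_equal(resolve_single_pathway(c(SP = 0.95, Pro = 0.60),
                                      default_registry(), tie_margin = 0.1),
               "SP")
  # within-margin tie retains both (multi-pathway carrier)
  expect_setequal(resolve_single_pathway(c(SP = 0.95, Pro = 0.90),
                                         default_registry(), tie_margin = 0.1),
                  c("Pro", "SP"))
  # a single complete pathway passes through unchanged
  expect_equal(resolve_single_pathway(c(B1 = 0.4), reg), "B1")
  # products resolve independently: one butyrate and one propionate survive
  got <- resolve_single_pathway(c(B1 = 0.9, B2 = 0.5, P1 = 0.7), reg,
                                tie_margin = 0.1)
  expect_setequal(got, c("B1", "P1"))
})

test_that("tie margin limits behave as all-or-one", {
  reg <- default_registry()
  ratios <- c(Glu = 0.8, Ace = 0.95, Lys = 0.7, SP = 0.5, WWC = 0.5)
  expect_setequal(resolve_single_pathway(ratios, reg, tie_margin = Inf),
                  names(ratios))
  zero <- resolve_single_pathway(ratios, reg, tie_margin = 0)
  expect_equal(zero, c("Ace", "WWC"))  # exact SP/WWC tie broken by registry order
  expect_length(zero, 2)
})

test_that("assigned pathways never leave the complete set and ratios drive assignment", {
  reg <- tiny_registry()
  set.seed(11)
  for (i in 1:25) {
    h <- random_hits(reg, n_genomes = 5, n_hits = 60, seed = i)
    prof <- suppressWarnings(classify_genomes(h, reg))
    for (j in seq_len(nrow(prof))) {
      expect_true(all(prof$assigned[[j]] %in% prof$complete[[j]]))
      expect_setequal(names(prof$ratios[[j]]), prof$complete[[j]])
    }
  }
})

test_that("classification recovers simulated genotypes", {
  cfg <- simulation_config(seed = 21, n_genomes = 50)
  comm <- simulate_community(cfg)
  hits <- simulate_genome_hits(comm)
  prof <- classify_genomes(hits, comm$registry,
                           genomes = comm$truth$genome_id)
  expect_setequal(prof$genome_id, comm$truth$genome_id)
  prof <- prof[match(comm$truth$genome_id, prof$genome_id), ]
  # complete calls equal the truth: hits cover carried pathways only
  for (i in seq_len(nrow(prof))) {
    expect_setequal(prof$complete[[i]], comm$truth$pathways[[i]])
    expect_true(all(prof$assigned[[i]] %in% comm$truth$pathways[[i]]))
  }
})

test_that("HMMER tblout parsing extracts gene, subject, score and description", {
  tbl <- c(
    "#                                               --- full sequence ---- ...",
    "# target name  accession  query name accession  E-value score bias ...",
    paste("seq_0001 - bcd - 1.2e-100 412.3 0.1 1.3e-99 410.0 0.1",
          "1 1 0 0 1 1 1 1 butyryl-CoA dehydrogenase"),
    paste("seq_0002 - but - 3e-50 201.7 0.0 4e-50 200.1 0.0",
          "1 1 0 0 1 1 1 1 butyryl-CoA:acetate CoA-transferase")
  )
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(tbl, f)
  hits <- read_hmmer_tblout(f, genome_id = "gX")
  expect_equal(hits$gene, c("bcd", "but"))
  expect_equal(hits$subject_id, c("seq_0001", "seq_0002"))
  expect_equal(hits$score, c(412.3, 201.7))
  expect_equal(hits$description[1], "butyryl-CoA dehydrogenase")
  expect_equal(hits$genome_id, c("gX", "gX"))
  # truncated lines are flagged with their line number
  writeLines(c(tbl, "seq_0003 - bcd short"), f)
  expect_error(read_hmmer_tblout(f, "gX"), "line 5")
})

test_that("profiles survive a TSV round trip", {
  cfg <- simulation_config(seed = 3, n_genomes = 15)
  comm <- simulate_community(cfg)
  prof <- classify_genomes(simulate_genome_hits(comm), comm$registry,
                           genomes = comm$truth$genome_id)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(prof, f)
  back <- read_profiles(f)
  expect_equal(back$genome_id, prof$genome_id)
  expect_equal(back$complete, prof$complete)
  expect_equal(back$assigned, prof$assigned)
  for (i in seq_len(nrow(prof))) {
    expect_equal(back$ratios[[i]], prof$ratios[[i]], tolerance = 1e-9)
  }
})
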