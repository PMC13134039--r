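# Small registries and randomized fixtures built in code.

# Three-pathway registry with one shared gene (g_sh) between the two
# butyrate pathways; every gene carries model scores.
tiny_registry <- function() {
  new_registry(
    pathways = list(
      list(id = "B1", product = "butyrate", genes = c("g1", "g2", "g_sh")),
      list(id = "B2", product = "butyrate", genes = c("g3", "g_sh")),
      list(id = "P1", product = "propionate", genes = c("g4", "g5"))
    ),
    model_scores = list(
      g1 = c(a = 200, b = 150, c = 180), g2 = c(a = 300, b = 250),
      g3 = c(a = 120, b = 160), g4 = c(a = 400), g5 = c(a = 220, b = 260),
      g_sh = c(a = 500, b = 450)
    ),
    require_complete = FALSE
  )
}

# single-product registry with k single-copy genes, for pathway-length
# invariance experiments
k_gene_registry <- function(k, pathway_id = "PK") {
  genes <- sprintf("gk%02d", seq_len(k))
  scores <- lapply(genes, function(g) c(m1 = 300, m2 = 360))
  names(scores) <- genes
  new_registry(
    pathways = list(list(id = pathway_id, product = "butyrate", genes = genes)),
    model_scores = scores,
    require_complete = FALSE
  )
}

random_hits <- function(registry, n_genomes = 10, n_hits = 80, seed = 1) {
  set.seed(seed)
  genes <- registry_genes(registry)
  tibble::tibble(
    genome_id = sprintf("g%02d", sample(n_genomes, n_hits, replace = TRUE)),
    gene = sample(genes, n_hits, replace = TRUE),
    subject_id = sprintf("sub%03d", seq_len(n_hits)),
    score = round(runif(n_hits, 10, 600), 1),
    length = sample(600:2000, n_hits, replace = TRUE),
    description = "generic annotation"
  )
}

# random quantify fixture: catalog (some shared-pathway genes), counts, rplB
random_quantify_fixture <- function(seed, n_samples = 2) {
  set.seed(seed)
  registry <- tiny_registry()
  genes <- registry_genes(registry)
  n_entries <- sample(8:20, 1)
  entry_genes <- sample(genes, n_entries, replace = TRUE)
  catalog <- tibble::tibble(
    catalog_id = sprintf("c%03d", seq_len(n_entries)),
    gene = entry_genes,
    pathways = unname(registry_memberships(registry, entry_genes)),
    length = sample(500:2500, n_entries, replace = TRUE),
    sources = as.list(sprintf("src%03d", seq_len(n_entries)))
  )
  rplb_catalog <- tibble::tibble(
    catalog_id = sprintf("r%02d", 1:3),
    length = sample(700:900, 3, replace = TRUE),
    sources = as.list(sprintf("src%03d", 1:3))
  )
  samples <- sprintf("s%02d", seq_len(n_samples))
  gene_counts <- dplyr::bind_rows(lapply(samples, function(s) {
    tibble::tibble(sample_id = s, catalog_id = catalog$catalog_id,
                   count = rpois(n_entries, 40))
  }))
  rplb_counts <- dplyr::bind_rows(lapply(samples, function(s) {
    tibble::tibble(sample_id = s, catalog_id = rplb_catalog$catalog_id,
                   count = rpois(3, 60) + 1L)
  }))
  list(registry = registry, catalog = catalog, rplb_catalog = rplb_catalog,
       gene_counts = gene_counts, rplb_counts = rplb_counts)
}
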