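# Independent brute-force reimplementations used as oracles. Plain loops,
# no shared code paths with the package internals.

# naive per-hit threshold filter
oracle_filter <- function(hits, model_scores, score_frac = 0.5) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cutoff <- score_frac * min(model_scores[[hits$gene[i]]])
    keep[i] <- hits$score[i] >= cutoff
  }
  hits[keep, , drop = FALSE]
}

# brute-force set-cover completeness check for one genome's gene set
oracle_complete <- function(genes, registry) {
  out <- character(0)
  for (i in seq_len(nrow(registry$pathways))) {
    roster <- registry$pathways$genes[[i]]
    ok <- TRUE
    for (g in roster) if (!(g %in% genes)) ok <- FALSE
    if (ok) out <- c(out, registry$pathways$pathway_id[i])
  }
  out
}

# naive estimator: loops over pathways, genes and rplB entries; apportions
# shared-gene counts by single-pathway evidence
oracle_p_genomes <- function(gene_counts, rplb_counts, catalog, rplb_catalog,
                             registry, sample) {
  gc <- gene_counts[gene_counts$sample_id == sample, ]
  rc <- rplb_counts[rplb_counts$sample_id == sample, ]
  denom <- 0
  for (i in seq_len(nrow(rc))) {
    len <- rplb_catalog$length[rplb_catalog$catalog_id == rc$catalog_id[i]]
    denom <- denom + rc$count[i] / len
  }
  count_of <- function(id) {
    v <- gc$count[gc$catalog_id == id]
    if (length(v) == 0) 0 else sum(v)
  }
  sh_s_of <- function(p) {
    tot <- 0
    for (j in seq_len(nrow(catalog))) {
      if (length(catalog$pathways[[j]]) == 1 && catalog$pathways[[j]] == p) {
        tot <- tot + count_of(catalog$catalog_id[j])
      }
    }
    tot
  }
  res <- numeric(nrow(registry$pathways))
  names(res) <- registry$pathways$pathway_id
  for (k in seq_len(nrow(registry$pathways))) {
    p <- registry$pathways$pathway_id[k]
    num <- 0
    for (j in seq_len(nrow(catalog))) {
      memb <- catalog$pathways[[j]]
      if (!(p %in% memb)) next
      h <- count_of(catalog$catalog_id[j])
      if (length(memb) > 1) {
        sh_m <- 0
        for (q in memb) sh_m <- sh_m + sh_s_of(q)
        h <- if (sh_m == 0) h / length(memb) else h * sh_s_of(p) / sh_m
      }
      num <- num + h / catalog$length[j]
    }
    num <- num / registry$pathways$l_pathway[k]
    res[k] <- if (denom > 0) 100 * num / denom else NA_real_
  }
  res
}
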