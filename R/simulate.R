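#' Simulation configuration for synthetic communities
#'
#' Defines the study conditions the simulator emulates: a community of
#' genomes carrying at most one butyrate and one propionate pathway each
#' (occasionally two of the same product), long-tailed species abundances,
#' single-copy pathway genes with a configurable copy-number violation
#' rate, and Poisson read counts whose mean is proportional to genome
#' abundance, gene length and sequencing depth (longer genes recruit more
#' reads).
#'
#' @param seed integer seed fixing all randomness.
#' @param n_genomes number of genomes/species in the community.
#' @param n_samples number of metagenomic samples to draw.
#' @param carriage named per-pathway carriage probabilities; defaults give
#'   roughly a fifth of genomes a butyrate pathway (mostly Ace) and a sixth
#'   a propionate pathway (mostly SP), the prevalences typical of gut
#'   strain collections.
#' @param gene_length_range range (bp) of simulated pathway gene lengths.
#' @param rplb_length rplB gene length (bp, default 831).
#' @param depth mean sequencing depth in reads per bp of a genome at
#'   abundance 1.
#' @param copy_number_violation_rate probability a genome-gene pair is
#'   duplicated (mechanism behind estimates exceeding 100%).
#' @param multi_pathway_rate probability a pathway-carrying genome carries a
#'   second pathway of the same product.
#' @param abundance_model `"longtail"` (Dirichlet-like, few dominant
#'   species) or `"equal"`.
#' @param abundance_shape gamma shape for the long-tailed model (<1 gives a
#'   heavy tail).
#' @param carriage_mode `"bernoulli"` draws carriers independently;
#'   `"fixed"` makes the carrier count exactly `round(p * n_genomes)` per
#'   pathway (useful when the community-level carrier fraction must be
#'   exact).
#' @param overdispersion optional negative-binomial size parameter; `NULL`
#'   keeps Poisson counts.
#' @param unassigned_fraction community fraction left taxonomically
#'   unassigned (abundances then sum to 1 minus this).
#' @return an `scfa_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genomes = 60L,
                              n_samples = 1L,
                              carriage = NULL,
                              gene_length_range = c(600L, 2400L),
                              rplb_length = 831L,
                              depth = 0.5,
                              copy_number_violation_rate = 0,
                              multi_pathway_rate = 0.02,
                              abundance_model = c("longtail", "equal"),
                              abundance_shape = 0.3,
                              carriage_mode = c("bernoulli", "fixed"),
                              overdispersion = NULL,
                              unassigned_fraction = 0.02) {
  if (is.null(carriage)) {
    carriage <- c(Glu = 0.02, Ace = 0.12, Lys = 0.04, `4-Ami` = 0.03,
                  Pro = 0.05, Acr = 0.01, WWC = 0.02, SP = 0.10)
  }
  stopifnot(all(carriage >= 0), all(carriage <= 1), depth >= 0,
            n_genomes >= 1, n_samples >= 1,
            copy_number_violation_rate >= 0, copy_number_violation_rate <= 1,
            multi_pathway_rate >= 0, multi_pathway_rate <= 1,
            unassigned_fraction >= 0, unassigned_fraction < 1)
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    n_samples = as.integer(n_samples), carriage = carriage,
    gene_length_range = gene_length_range, rplb_length = rplb_length,
    depth = depth, copy_number_violation_rate = copy_number_violation_rate,
    multi_pathway_rate = multi_pathway_rate,
    abundance_model = match.arg(abundance_model),
    abundance_shape = abundance_shape,
    carriage_mode = match.arg(carriage_mode),
    overdispersion = overdispersion,
    unassigned_fraction = unassigned_fraction
  ), class = "scfa_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Families used for synthetic taxonomy; producers are placed preferentially
# in families where their product dominates in the gut.
.sim_taxa <- list(
  butyrate = data.frame(family = c("Lachnospiraceae", "Oscillospiraceae", "Eubacteriaceae"),
                        phylum = "Bacillota"),
  propionate = data.frame(family = c("Bacteroidaceae", "Prevotellaceae"),
                          phylum = "Bacteroidota"),
  none = data.frame(family = c("Enterobacteriaceae", "Akkermansiaceae"),
                    phylum = c("Pseudomonadota", "Verrucomicrobiota"))
)

#' Simulate a synthetic community with known pathway genotypes
#'
#' Draws genomes, their true pathway carriage, long-tailed relative
#' abundances with synthetic taxonomy, per-genome gene sequences for every
#' carried pathway (unique random nucleotide sequences, so the derived
#' catalog has one entry per genome-gene), and an rplB entry per genome.
#' Everything is deterministic under the config seed.
#'
#' @param config an `scfa_sim_config`.
#' @param registry an `scfa_registry` (default: the bundled eight-pathway
#'   registry).
#' @return an `scfa_community` list with elements `truth` (genome ->
#'   pathways), `abundances` (species/family/phylum/abundance), `genes`
#'   (genome, gene, catalog_id, length, copies, sequence), `rplb`
#'   (genome-level rplB entries), `registry`, `config`.
#' @export
simulate_community <- function(config, registry = default_registry()) {
  set.seed(config$seed)
  n <- config$n_genomes
  ids <- sprintf("g%04d", seq_len(n))
  carriage <- config$carriage
  unknown <- setdiff(names(carriage), registry$pathways$pathway_id)
  if (length(unknown) > 0) {
    stop_scfa("carriage names pathway(s) absent from the registry: %s",
              paste(unknown, collapse = ", "))
  }
  prod_of <- setNames(registry$pathways$product, registry$pathways$pathway_id)

  draw_product <- function(prod) {
    p <- carriage[names(carriage)[prod_of[names(carriage)] == prod]]
    if (length(p) == 0 || sum(p) == 0) return(rep(list(character(0)), n))
    if (sum(p) > 1) p <- p / sum(p)
    if (config$carriage_mode == "fixed") {
      slots <- rep(list(character(0)), n)
      pool <- sample(n)  # carriers drawn without replacement across pathways
      taken <- 0
      for (pw in names(p)) {
        k <- round(p[[pw]] * n)
        if (k == 0) next
        pick <- pool[(taken + 1):min(taken + k, n)]
        taken <- taken + length(pick)
        for (i in pick) slots[[i]] <- pw
      }
      slots
    } else {
      lapply(seq_len(n), function(i) {
        u <- runif(1)
        cum <- cumsum(p)
        hit <- which(u < cum)
        pw <- if (length(hit) == 0) character(0) else names(p)[hit[1]]
        if (length(pw) == 1 && runif(1) < config$multi_pathway_rate &&
            length(p) > 1) {
          pw <- c(pw, sample(setdiff(names(p), pw), 1))
        }
        pw
      })
    }
  }
  but <- draw_product("butyrate")
  pro <- draw_product("propionate")
  truth <- tibble::tibble(
    genome_id = ids, species_id = ids,
    pathways = mapply(function(a, b) c(a, b), but, pro, SIMPLIFY = FALSE)
  )

  ab <- switch(config$abundance_model,
    longtail = rgamma(n, shape = config$abundance_shape, rate = 1),
    equal = rep(1, n)
  )
  ab <- ab / sum(ab) * (1 - config$unassigned_fraction)
  fam <- character(n); phy <- character(n)
  for (i in seq_len(n)) {
    pws <- truth$pathways[[i]]
    prods <- unique(unname(prod_of[pws]))
    group <- if (length(prods) == 0) "none"
             else if (length(prods) == 2) sample(c("butyrate", "propionate"), 1)
             else prods
    if (runif(1) > 0.9) group <- sample(names(.sim_taxa), 1)  # taxonomy is not destiny
    tax <- .sim_taxa[[group]]
    j <- sample(nrow(tax), 1)
    fam[i] <- tax$family[j]; phy[i] <- tax$phylum[j]
  }
  abundances <- tibble::tibble(species_id = ids, family = fam, phylum = phy,
                               abundance = ab)

  gene_rows <- list()
  for (i in seq_len(n)) {
    genes <- unique(unlist(lapply(truth$pathways[[i]], function(p) {
      registry$pathways$genes[[match(p, registry$pathways$pathway_id)]]
    })))
    for (g in genes) {
      len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]), 1)
      seqc <- random_dna(len)
      gene_rows[[length(gene_rows) + 1]] <- tibble::tibble(
        genome_id = ids[i], gene = g,
        catalog_id = catalog_id_for(g, seqc),
        length = len,
        copies = 1L + stats::rbinom(1, 1, config$copy_number_violation_rate),
        sequence = seqc
      )
    }
  }
  genes <- if (length(gene_rows) > 0) dplyr::bind_rows(gene_rows) else {
    tibble::tibble(genome_id = character(), gene = character(),
                   catalog_id = character(), length = integer(),
                   copies = integer(), sequence = character())
  }
  rplb_seq <- vapply(seq_len(n), function(i) random_dna(config$rplb_length),
                     character(1))
  rplb <- tibble::tibble(
    genome_id = ids,
    catalog_id = catalog_id_for("rplB", rplb_seq),
    length = as.integer(config$rplb_length),
    copies = 1L,
    score = round(runif(n, 450, 900), 1),
    sequence = rplb_seq
  )
  structure(list(truth = truth, abundances = abundances, genes = genes,
                 rplb = rplb, registry = registry, config = config),
            class = "scfa_community")
}

#' Pathway-gene catalog of a simulated community
#'
#' @param community an `scfa_community`.
#' @return catalog tibble in the shape [pathway_abundance()] expects.
#' @export
community_catalog <- function(community) {
  g <- community$genes
  memberships <- registry_memberships(community$registry, unique(g$gene))
  keep <- !duplicated(g$catalog_id)
  tibble::tibble(
    catalog_id = g$catalog_id[keep],
    gene = g$gene[keep],
    pathways = unname(memberships[g$gene[keep]]),
    length = g$length[keep],
    sources = as.list(g$genome_id[keep]),
    sequence = g$sequence[keep]
  )
}

#' rplB catalog of a simulated community
#' @param community an `scfa_community`.
#' @return rplB catalog tibble.
#' @export
community_rplb_catalog <- function(community) {
  r <- community$rplb
  tibble::tibble(catalog_id = r$catalog_id, length = r$length,
                 sources = as.list(r$genome_id), score = r$score,
                 sequence = r$sequence)
}

#' Simulate per-sample read counts for a community
#'
#' Counts per catalog gene are Poisson (optionally negative-binomial) with
#' mean `depth * abundance * length * copies`; rplB counts likewise with
#' single copies. The closed-form expectation of the abundance estimator on
#' these counts is [expected_abundance()].
#'
#' @param community an `scfa_community`.
#' @param config simulation config (defaults to the community's).
#' @param sample_ids sample names (default `s001..`).
#' @return list with tibbles `gene_counts` and `rplb_counts`.
#' @export
simulate_sample_counts <- function(community, config = community$config,
                                   sample_ids = NULL) {
  set.seed(config$seed + 3L)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(config$n_samples))
  }
  ab <- setNames(community$abundances$abundance, community$abundances$species_id)
  g <- community$genes
  r <- community$rplb
  mu_gene <- config$depth * ab[g$genome_id] * g$length * g$copies
  mu_rplb <- config$depth * ab[r$genome_id] * r$length * r$copies
  draw <- function(mu) {
    if (is.null(config$overdispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = config$overdispersion)
  }
  gene_counts <- dplyr::bind_rows(lapply(sample_ids, function(s) {
    tibble::tibble(sample_id = s, catalog_id = g$catalog_id,
                   count = draw(mu_gene))
  }))
  rplb_counts <- dplyr::bind_rows(lapply(sample_ids, function(s) {
    tibble::tibble(sample_id = s, catalog_id = r$catalog_id,
                   count = draw(mu_rplb))
  }))
  list(gene_counts = gene_counts, rplb_counts = rplb_counts)
}

#' Expected (noise-free) count tables of a simulated community
#'
#' Returns the Poisson means of [simulate_sample_counts()] as one
#' deterministic "sample". Feeding these to [pathway_abundance()] gives the
#' estimator's infinite-depth plug-in value, which differs from the
#' true-attribution expectation of [expected_abundance()] exactly where the
#' shared-gene apportionment rule reallocates counts between same-product
#' pathways.
#'
#' @param community an `scfa_community`.
#' @param config simulation config (defaults to the community's).
#' @param sample_id name of the emitted pseudo-sample.
#' @return list with tibbles `gene_counts` and `rplb_counts` (non-integer
#'   expected counts).
#' @export
expected_counts <- function(community, config = community$config,
                            sample_id = "expected") {
  ab <- setNames(community$abundances$abundance, community$abundances$species_id)
  g <- community$genes
  r <- community$rplb
  list(
    gene_counts = tibble::tibble(
      sample_id = sample_id, catalog_id = g$catalog_id,
      count = config$depth * unname(ab[g$genome_id]) * g$length * g$copies),
    rplb_counts = tibble::tibble(
      sample_id = sample_id, catalog_id = r$catalog_id,
      count = config$depth * unname(ab[r$genome_id]) * r$length * r$copies)
  )
}

#' Closed-form expected pathway abundance of a simulated community
#'
#' Under the simulator's count model with true pathway assignment of every
#' read, the expected estimate for pathway *p* is
#' `100 * sum over carriers of (abundance * mean gene copy number) / sum of
#' all abundances` — the abundance-weighted carrier fraction, inflated by
#' copy-number violations.
#'
#' @param community an `scfa_community`.
#' @return tibble `pathway_id`, `product`, `expected_p`.
#' @export
expected_abundance <- function(community) {
  reg <- community$registry
  ab <- setNames(community$abundances$abundance, community$abundances$species_id)
  denom <- sum(ab)
  g <- community$genes
  rows <- lapply(seq_len(nrow(reg$pathways)), function(i) {
    p <- reg$pathways$pathway_id[i]
    roster <- reg$pathways$genes[[i]]
    carriers <- community$truth$genome_id[
      vapply(community$truth$pathways, function(x) p %in% x, logical(1))]
    contrib <- vapply(carriers, function(gm) {
      copies <- g$copies[g$genome_id == gm & g$gene %in% roster]
      ab[[gm]] * mean(copies)
    }, double(1))
    tibble::tibble(pathway_id = p, product = reg$pathways$product[i],
                   expected_p = 100 * sum(contrib) / denom)
  })
  dplyr::bind_rows(rows)
}

#' Simulate literature phenotypes from a truth table
#'
#' Each species' true producer status per product is reported faithfully
#' with probability `1 - error_rate`, flipped with probability
#' `error_rate`, and masked to `"unknown"` with probability
#' `unknown_rate`.
#'
#' @param community an `scfa_community` (or a truth tibble with
#'   `species_id` and `pathways`).
#' @param error_rate probability a reported phenotype contradicts the truth.
#' @param unknown_rate probability a phenotype is unreported.
#' @param seed seed for the reporting noise.
#' @param registry registry used to map pathways to products (defaults to
#'   the community's).
#' @return tibble `species_id`, `butyrate`, `propionate` (yes/no/unknown),
#'   `citation` tag.
#' @export
simulate_phenotypes <- function(community, error_rate = 0, unknown_rate = 0,
                                seed = 1L, registry = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1, unknown_rate >= 0, unknown_rate <= 1)
  if (inherits(community, "scfa_community")) {
    truth <- community$truth
    registry <- registry %||% community$registry
  } else {
    truth <- community
    registry <- registry %||% default_registry()
  }
  set.seed(seed)
  prod_of <- setNames(registry$pathways$product, registry$pathways$pathway_id)
  report <- function(is_producer) {
    n <- length(is_producer)
    val <- ifelse(xor(is_producer, runif(n) < error_rate), "yes", "no")
    ifelse(runif(n) < unknown_rate, "unknown", val)
  }
  but <- vapply(truth$pathways, function(x) any(prod_of[x] == "butyrate"), logical(1))
  pro <- vapply(truth$pathways, function(x) any(prod_of[x] == "propionate"), logical(1))
  tibble::tibble(
    species_id = if ("species_id" %in% names(truth)) truth$species_id else truth$genome_id,
    butyrate = report(but),
    propionate = report(pro),
    citation = "synthetic-truth"
  )
}

# canonical hit descriptions; genes under curation rules get descriptions
# their include keywords accept
gene_description <- function(gene) {
  canned <- c(
    bcd = "butyryl-CoA dehydrogenase",
    but = "butyryl-CoA:acetate CoA-transferase",
    hbd = "3-hydroxybutyryl-CoA dehydrogenase",
    ptb = "phosphate butyryltransferase"
  )
  ifelse(gene %in% names(canned), canned[gene], paste(gene, "pathway gene"))
}

#' Simulate homology-search hit tables for a community
#'
#' Every gene of every carried pathway receives a hit scoring 75%-105% of
#' the gene's mean model-strain score (comfortably above the 50%-of-minimum
#' cutoff). Background noise is added: sub-cutoff decoy hits on random
#' genes, and occasional high-scoring bcd hits whose description fails
#' keyword curation.
#'
#' @param community an `scfa_community`.
#' @param decoy_rate per-genome probability of a sub-cutoff decoy hit per
#'   random gene draw.
#' @param miscurated_rate per-genome probability of a non-specific
#'   high-scoring bcd-like hit.
#' @return hits tibble consumable by [classify_genomes()].
#' @export
simulate_genome_hits <- function(community, decoy_rate = 0.3,
                                 miscurated_rate = 0.1) {
  reg <- community$registry
  set.seed(community$config$seed + 1L)
  all_genes <- registry_genes(reg)
  rows <- list()
  g <- community$genes
  for (i in seq_len(nrow(community$truth))) {
    gm <- community$truth$genome_id[i]
    mine <- g[g$genome_id == gm, , drop = FALSE]
    if (nrow(mine) > 0) {
      base <- vapply(mine$gene, function(x) mean(reg$model_scores[[x]]), double(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        genome_id = gm, gene = mine$gene,
        subject_id = paste0(gm, "|", mine$gene),
        score = round(base * runif(nrow(mine), 0.75, 1.05), 1),
        length = mine$length,
        description = unname(gene_description(mine$gene))
      )
    }
    # every genome yields at least one (possibly weak) hit, so the profile
    # table covers the whole strain collection
    pool <- setdiff(all_genes, mine$gene)
    if ((runif(1) < decoy_rate || nrow(mine) == 0) && length(pool) > 0) {
      dg <- sample(pool, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        genome_id = gm, gene = dg,
        subject_id = paste0(gm, "|decoy|", dg),
        score = round(min(reg$model_scores[[dg]]) * runif(1, 0.1, 0.45), 1),
        length = NA_integer_,
        description = unname(gene_description(dg))
      )
    }
    if ("bcd" %in% all_genes && runif(1) < miscurated_rate) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        genome_id = gm, gene = "bcd",
        subject_id = paste0(gm, "|nonspecific|bcd"),
        score = round(mean(reg$model_scores[["bcd"]]) * runif(1, 0.8, 1.0), 1),
        length = NA_integer_,
        description = "acyl-CoA dehydrogenase, short-chain specific"
      )
    }
  }
  dplyr::bind_rows(rows)
}
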