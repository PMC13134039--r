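#' Apportion a multi-pathway gene count across its pathways
#'
#' A read count observed on a gene shared by several pathways cannot be
#' attributed directly. It is divided proportionally to the single-pathway
#' evidence in the same sample: the share of pathway *p* is
#' `h_o * sum(h_s of p) / sum(h_m)`, where `h_s` are counts of
#' single-pathway genes of *p* and `h_m` the counts of single-pathway genes
#' across all pathways containing the shared gene. When no single-pathway
#' evidence exists (`sum(h_m) == 0`) the count is split equally with a
#' warning, which preserves count conservation.
#'
#' @param h_o observed count of the multi-pathway gene (>= 0).
#' @param contexts tibble or data.frame with columns `pathway_id` and `sh_s`
#'   (summed single-pathway gene counts for that pathway) and optionally
#'   `sh_m` (the shared denominator; defaults to `sum(sh_s)` and must be
#'   identical across rows when supplied).
#' @return named numeric vector of apportioned counts per pathway.
#' @export
apportion_multi_pathway <- function(h_o, contexts) {
  stopifnot(h_o >= 0, nrow(contexts) >= 1)
  sh_s <- contexts$sh_s
  if ("sh_m" %in% names(contexts)) {
    sh_m <- unique(contexts$sh_m)
    if (length(sh_m) != 1) {
      stop_scfa("sh_m must be identical across the contexts of one gene")
    }
    if (sh_m < max(sh_s)) {
      stop_scfa("sh_m (%g) is smaller than a pathway's sh_s (%g)", sh_m, max(sh_s))
    }
  } else {
    sh_m <- sum(sh_s)
  }
  if (h_o == 0) {
    return(setNames(rep(0, nrow(contexts)), contexts$pathway_id))
  }
  if (sh_m == 0) {
    warn_scfa("no single-pathway evidence for a shared gene; splitting %g equally among %d pathway(s)",
              h_o, nrow(contexts))
    return(setNames(rep(h_o / nrow(contexts), nrow(contexts)), contexts$pathway_id))
  }
  setNames(h_o * sh_s / sh_m, contexts$pathway_id)
}

# Apportion all counts of one sample at catalog-entry level.
# Returns the per-entry, per-pathway effective counts (long form).
apportion_sample <- function(counts, catalog) {
  if (anyDuplicated(counts$catalog_id)) {
    counts <- counts |>
      dplyr::group_by(.data$catalog_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  n_memb <- lengths(catalog$pathways)
  idx <- match(counts$catalog_id, catalog$catalog_id)
  single <- n_memb[idx] == 1
  # single-pathway evidence per pathway, from raw counts
  sh_s <- tapply(counts$count[single],
                 vapply(catalog$pathways[idx[single]], `[[`, character(1), 1),
                 sum)
  get_sh_s <- function(p) if (!is.null(sh_s) && p %in% names(sh_s)) sh_s[[p]] else 0
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    memb <- catalog$pathways[[idx[i]]]
    if (length(memb) == 1) {
      eff <- setNames(counts$count[i], memb)
    } else {
      ctx <- tibble::tibble(pathway_id = memb,
                            sh_s = vapply(memb, get_sh_s, double(1)))
      eff <- apportion_multi_pathway(counts$count[i], ctx)
    }
    tibble::tibble(catalog_id = counts$catalog_id[i],
                   pathway_id = names(eff),
                   h_gene = unname(eff),
                   l_gene = catalog$length[idx[i]])
  })
  dplyr::bind_rows(rows)
}

#' Per-sample pathway abundance (percentage of genomes encoding a pathway)
#'
#' Implements the genome-equivalent estimator: for each pathway,
#' `P_genomes = 100 * [ sum_g (h_gene/l_gene) / l_pathway ] /
#' [ sum_r (h_rplB/l_rplB) ]`, where the numerator sums over the pathway's
#' catalog genes (counts of shared genes apportioned first) and the
#' denominator over the rplB housekeeping catalog. Dividing by gene length
#' removes the length bias of read recruitment, dividing by the pathway gene
#' count bases the estimate on average per-gene evidence, and the rplB ratio
#' converts to genome equivalents. Values can exceed 100 when genomes carry
#' multiple gene copies or several pathways; they are reported unclipped.
#'
#' @param gene_counts tibble `sample_id`, `catalog_id`, `count` of primary
#'   mapped reads per catalog gene. Catalog entries absent from a sample
#'   count as zero.
#' @param rplb_counts tibble `sample_id`, `catalog_id`, `count` for the rplB
#'   catalog.
#' @param catalog pathway-gene catalog (needs `catalog_id`, `pathways`,
#'   `length`).
#' @param rplb_catalog rplB catalog (needs `catalog_id`, `length`).
#' @param registry an `scfa_registry` (provides `l_pathway` and products).
#' @return long tibble: `sample_id`, `pathway_id`, `product`, `p_genomes`,
#'   `rplb_missing`. Samples with zero rplB signal get `p_genomes = NA` and
#'   `rplb_missing = TRUE` (never a silent 0).
#' @export
pathway_abundance <- function(gene_counts, rplb_counts, catalog, rplb_catalog,
                              registry) {
  check_counts(gene_counts, catalog, "gene counts")
  check_counts(rplb_counts, rplb_catalog, "rplB counts")
  samples <- sort(unique(c(gene_counts$sample_id, rplb_counts$sample_id)))
  if (length(samples) == 0) stop_scfa("no samples in the count tables")
  per_sample <- lapply(samples, function(s) {
    gc <- gene_counts[gene_counts$sample_id == s, , drop = FALSE]
    rc <- rplb_counts[rplb_counts$sample_id == s, , drop = FALSE]
    denom <- sum(rc$count / rplb_catalog$length[match(rc$catalog_id,
                                                     rplb_catalog$catalog_id)])
    numer <- setNames(rep(0, nrow(registry$pathways)), registry$pathways$pathway_id)
    if (nrow(gc) > 0) {
      eff <- apportion_sample(gc, catalog)
      if (nrow(eff) > 0) {
        contrib <- tapply(eff$h_gene / eff$l_gene, eff$pathway_id, sum)
        l_p <- setNames(registry$pathways$l_pathway, registry$pathways$pathway_id)
        numer[names(contrib)] <- unlist(contrib) / l_p[names(contrib)]
      }
    }
    if (denom <= 0) {
      warn_scfa("sample %s has no rplB signal; pathway abundance undefined", s)
      p <- rep(NA_real_, length(numer))
      missing <- TRUE
    } else {
      p <- 100 * numer / denom
      missing <- FALSE
    }
    tibble::tibble(sample_id = s,
                   pathway_id = registry$pathways$pathway_id,
                   product = registry$pathways$product,
                   p_genomes = unname(p),
                   rplb_missing = missing)
  })
  dplyr::bind_rows(per_sample)
}

check_counts <- function(counts, catalog, what) {
  required <- c("sample_id", "catalog_id", "count")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    stop_scfa("%s table is missing column(s): %s", what,
              paste(missing, collapse = ", "))
  }
  if (any(!is.finite(counts$count)) || any(counts$count < 0)) {
    stop_scfa("%s table contains negative or non-finite counts", what)
  }
  unknown <- !counts$catalog_id %in% catalog$catalog_id
  if (any(unknown)) {
    stop_scfa("%s table references id(s) absent from the catalog: %s", what,
              paste(unique(counts$catalog_id[unknown])[1:min(3, sum(unknown))],
                    collapse = ", "))
  }
  invisible(counts)
}

#' Product-level abundance totals per sample
#'
#' @param abundance long tibble from [pathway_abundance()].
#' @return tibble `sample_id`, `butyrate`, `propionate`, `combined` (each the
#'   sum of its member pathway percentages).
#' @export
product_totals <- function(abundance) {
  abundance |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      butyrate = sum(.data$p_genomes[.data$product == "butyrate"]),
      propionate = sum(.data$p_genomes[.data$product == "propionate"]),
      combined = sum(.data$p_genomes),
      .groups = "drop"
    )
}

#' Wide per-sample abundance table
#'
#' One row per sample, one column per pathway, plus butyrate/propionate/
#' combined totals.
#' @param abundance long tibble from [pathway_abundance()].
#' @return wide tibble.
#' @export
abundance_wide <- function(abundance) {
  wide <- abundance |>
    dplyr::select("sample_id", "pathway_id", "p_genomes") |>
    tidyr::pivot_wider(names_from = "pathway_id", values_from = "p_genomes")
  dplyr::left_join(wide, product_totals(abundance), by = "sample_id")
}

#' Read a per-sample gene count TSV
#'
#' Expected columns: `sample_id`, `catalog_id`, `count`.
#' @param path TSV file.
#' @return counts tibble.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop_scfa("counts file not found: %s", path)
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sample_id", "catalog_id", "count"), names(counts))
  if (length(missing) > 0) {
    stop_scfa("counts file %s is missing column(s): %s", path,
              paste(missing, collapse = ", "))
  }
  counts$sample_id <- as.character(counts$sample_id)
  counts
}

#' Count primary mapped reads per catalog sequence from SAM/BAM
#'
#' Counts alignments that are mapped and neither secondary nor
#' supplementary, so each read contributes at most once. All references in
#' the file header are reported, with zero for references receiving no
#' reads.
#'
#' @param path SAM or BAM file mapped against a catalog FASTA.
#' @param sample_id sample the file belongs to.
#' @return tibble `sample_id`, `catalog_id`, `count` covering every header
#'   reference.
#' @export
read_sam_counts <- function(path, sample_id) {
  if (!file.exists(path)) stop_scfa("alignment file not found: %s", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = "rname")
  rname <- Rsamtools::scanBam(bam, param = param)[[1]]$rname
  refs <- levels(rname)
  counts <- table(rname)
  tibble::tibble(sample_id = sample_id,
                 catalog_id = refs,
                 count = as.integer(counts[refs]))
}
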