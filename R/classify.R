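#' Read homology hits from a generic TSV
#'
#' Expected columns: `genome_id`, `gene`, `subject_id`, `score`, `length`,
#' `description` (header required; extra columns are kept).
#'
#' @param path TSV file path.
#' @return tibble of gene hits.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop_scfa("hits file not found: %s", path)
  hits <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  # tolerate the short column names some hit exporters use
  alias <- c(genome = "genome_id", subject = "subject_id")
  for (a in names(alias)) {
    if (a %in% names(hits) && !alias[[a]] %in% names(hits)) {
      names(hits)[names(hits) == a] <- alias[[a]]
    }
  }
  required <- c("genome_id", "gene", "score")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0) {
    stop_scfa("hits file %s is missing column(s): %s", path,
              paste(missing, collapse = ", "))
  }
  if (!"subject_id" %in% names(hits)) hits$subject_id <- NA_character_
  if (!"length" %in% names(hits)) hits$length <- NA_integer_
  if (!"description" %in% names(hits)) hits$description <- ""
  check_hit_scores(hits, path)
  hits
}

check_hit_scores <- function(hits, path = "hits") {
  bad <- !is.finite(hits$score) | hits$score < 0
  if (any(bad)) {
    stop_scfa("%s: line %d has a non-finite or negative bit score", path,
              which(bad)[1])
  }
  invisible(hits)
}

#' Read homology hits from HMMER per-sequence tabular output (tblout)
#'
#' Parses the whitespace-delimited `--tblout` format of `hmmsearch`. The
#' query (HMM) name is taken as the gene symbol, the target name as the
#' subject sequence id, and the full-sequence bit score as the hit score.
#'
#' @param path tblout file.
#' @param genome_id genome the file was searched against (one file per
#'   genome).
#' @return tibble of gene hits with `length = NA` (tblout does not report
#'   target length; supply sequences separately for catalog building).
#' @export
read_hmmer_tblout <- function(path, genome_id) {
  if (!file.exists(path)) stop_scfa("tblout file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(genome_id = character(), gene = character(),
                          subject_id = character(), score = double(),
                          length = integer(), description = character()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n_bad <- which(lengths(fields) < 18)
  if (length(n_bad) > 0) {
    stop_scfa("%s: line %d has fewer than the 18 tblout fields", path,
              which(keep)[n_bad[1]])
  }
  hits <- tibble::tibble(
    genome_id = genome_id,
    gene = vapply(fields, `[[`, character(1), 3),
    subject_id = vapply(fields, `[[`, character(1), 1),
    score = as.numeric(vapply(fields, `[[`, character(1), 6)),
    length = NA_integer_,
    description = vapply(fields, function(f) {
      if (length(f) > 18) paste(f[19:length(f)], collapse = " ") else ""
    }, character(1))
  )
  check_hit_scores(hits, path)
  hits
}

#' Apply keyword curation rules to a hit table
#'
#' @param hits tibble of gene hits (needs `gene`, `description`).
#' @param registry an `scfa_registry` carrying the curation rules.
#' @return the hits that pass curation.
#' @export
curate_hits <- function(hits, registry) {
  if (nrow(hits) == 0) return(hits)
  hits[apply_curation(hits$description, hits$gene, registry), , drop = FALSE]
}

#' Filter hits by the model-strain score cutoff
#'
#' A hit is retained iff its bit score is at least `score_frac` (default
#' 0.5) times the lowest model-strain score recorded for its gene.
#'
#' @param hits tibble of gene hits.
#' @param model_scores an `scfa_registry` or a named list gene -> numeric
#'   model-strain scores.
#' @param score_frac fraction of the lowest model-strain score used as the
#'   cutoff.
#' @return the retained hits.
#' @export
filter_hits <- function(hits, model_scores, score_frac = 0.5) {
  if (inherits(model_scores, "scfa_registry")) model_scores <- model_scores$model_scores
  if (nrow(hits) == 0) return(hits)
  genes <- unique(hits$gene)
  has_scores <- vapply(genes, function(g) {
    s <- model_scores[[g]]
    !is.null(s) && length(s) > 0
  }, logical(1))
  if (any(!has_scores)) {
    stop_scfa("no model-strain scores for gene(s): %s",
              paste(genes[!has_scores], collapse = ", "))
  }
  cutoff <- vapply(genes, function(g) score_frac * min(model_scores[[g]]),
                   double(1))
  hits[hits$score >= cutoff[hits$gene], , drop = FALSE]
}

#' Call complete pathways per genome
#'
#' A pathway is complete for a genome iff every gene of its required roster
#' has at least one surviving hit in that genome.
#'
#' @param hits filtered hit tibble (needs `genome_id`, `gene`).
#' @param registry an `scfa_registry`.
#' @return tibble with `genome_id` and list-column `complete` of pathway ids.
#' @export
call_complete_pathways <- function(hits, registry) {
  genomes <- unique(hits$genome_id)
  genes_by_genome <- split(hits$gene, factor(hits$genome_id, levels = genomes))
  complete <- lapply(genes_by_genome, function(genes) {
    genes <- unique(genes)
    ok <- vapply(registry$pathways$genes, function(roster) all(roster %in% genes),
                 logical(1))
    registry$pathways$pathway_id[ok]
  })
  tibble::tibble(genome_id = genomes, complete = unname(complete))
}

#' Per-pathway mean score ratios for one genome
#'
#' For each candidate pathway, the mean over its required genes of (best
#' surviving hit score for the gene) / (mean model-strain score for the
#' gene). Used to resolve genomes positive for several same-product
#' pathways.
#'
#' @param hits filtered hits of a single genome.
#' @param pathway_ids candidate pathway ids.
#' @param registry an `scfa_registry`.
#' @return named numeric vector of mean score ratios.
#' @export
pathway_score_ratios <- function(hits, pathway_ids, registry) {
  best <- tapply(hits$score, hits$gene, max)
  ratios <- vapply(pathway_ids, function(p) {
    roster <- registry$pathways$genes[[match(p, registry$pathways$pathway_id)]]
    mean(vapply(roster, function(g) {
      best[[g]] / mean(registry$model_scores[[g]])
    }, double(1)))
  }, double(1))
  names(ratios) <- pathway_ids
  ratios
}

#' Resolve same-product multi-pathway calls to the best-supported pathway
#'
#' Among the complete pathways of one product, retains the pathway with the
#' highest mean score ratio together with any pathway whose ratio is within
#' `tie_margin` of it (the genome is then a genuine multi-pathway carrier).
#' With `tie_margin = Inf` all complete pathways are retained; with
#' `tie_margin = 0` exactly one pathway per product is returned, exact ties
#' broken by registry order. Resolution is applied independently per
#' product, so a genome may keep one butyrate and one propionate pathway.
#'
#' @param ratios named numeric vector of mean score ratios for the complete
#'   pathways of one genome (both products may be mixed; they are resolved
#'   separately).
#' @param registry an `scfa_registry`.
#' @param tie_margin retain pathways whose ratio is within this distance of
#'   the top ratio (default 0.1).
#' @return character vector of assigned pathway ids, in registry order.
#' @export
resolve_single_pathway <- function(ratios, registry, tie_margin = 0.1) {
  ids <- registry$pathways$pathway_id
  ratios <- ratios[order(match(names(ratios), ids))]
  assigned <- character(0)
  for (prod in c("butyrate", "propionate")) {
    prod_ids <- ids[registry$pathways$product == prod]
    cand <- ratios[names(ratios) %in% prod_ids]
    if (length(cand) == 0) next
    if (length(cand) == 1) {
      assigned <- c(assigned, names(cand))
      next
    }
    top <- max(cand)
    if (tie_margin <= 0) {
      keep <- names(cand)[which(cand == top)[1]]  # registry order tie-break
    } else {
      keep <- names(cand)[top - cand < tie_margin]
    }
    assigned <- c(assigned, keep)
  }
  assigned[order(match(assigned, ids))]
}

#' Classify genomes into pathway-presence profiles
#'
#' Runs the full genotype-calling chain: keyword curation, the
#' 50%-of-lowest-model-strain score filter, the complete-gene-set
#' requirement, and per-product single-pathway resolution.
#'
#' @param hits tibble of gene hits for any number of genomes.
#' @param registry an `scfa_registry`.
#' @param tie_margin see [resolve_single_pathway()].
#' @param score_frac see [filter_hits()].
#' @param curate apply keyword curation first (default `TRUE`).
#' @param genomes optional character vector of all queried genomes; genomes
#'   without any surviving hit then still get a (negative) profile row.
#' @return tibble with one row per genome: `genome_id`, list-columns
#'   `complete`, `assigned` (pathway id sets) and `ratios` (named mean score
#'   ratios over complete pathways).
#' @export
classify_genomes <- function(hits, registry, tie_margin = 0.1,
                             score_frac = 0.5, curate = TRUE,
                             genomes = NULL) {
  genomes <- union(genomes, unique(hits$genome_id))
  known <- hits$gene %in% registry_genes(registry)
  if (any(!known)) {
    warn_scfa("dropping %d hit(s) for gene symbols absent from the registry: %s",
              sum(!known), paste(unique(hits$gene[!known]), collapse = ", "))
    hits <- hits[known, , drop = FALSE]
  }
  if (curate) hits <- curate_hits(hits, registry)
  hits <- filter_hits(hits, registry, score_frac = score_frac)
  profiles <- call_complete_pathways(hits, registry)
  absent <- setdiff(genomes, profiles$genome_id)
  if (length(absent) > 0) {
    profiles <- dplyr::bind_rows(
      profiles,
      tibble::tibble(genome_id = absent,
                     complete = rep(list(character(0)), length(absent)))
    )
    profiles <- profiles[order(match(profiles$genome_id, genomes)), , drop = FALSE]
  }
  hits_by_genome <- split(hits, factor(hits$genome_id, levels = profiles$genome_id))
  profiles$ratios <- lapply(seq_len(nrow(profiles)), function(i) {
    pathway_score_ratios(hits_by_genome[[i]], profiles$complete[[i]], registry)
  })
  profiles$assigned <- lapply(profiles$ratios, resolve_single_pathway,
                              registry = registry, tie_margin = tie_margin)
  profiles[, c("genome_id", "complete", "assigned", "ratios")]
}

#' Write genome pathway profiles as TSV
#'
#' Set-valued columns are comma-joined; score ratios are written as
#' `pathway=ratio` pairs.
#' @param profiles tibble from [classify_genomes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- tibble::tibble(
    genome_id = profiles$genome_id,
    complete = join_set(profiles$complete),
    assigned = join_set(profiles$assigned),
    ratios = vapply(profiles$ratios, function(r) {
      if (length(r) == 0) return("")
      paste(sprintf("%s=%.12g", names(r), r), collapse = ",")
    }, character(1))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read genome pathway profiles written by [write_profiles()]
#' @param path TSV path.
#' @return profiles tibble with list-columns restored.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_scfa("profiles file not found: %s", path)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  tibble::tibble(
    genome_id = raw$genome_id,
    complete = split_set(raw$complete),
    assigned = split_set(raw$assigned),
    ratios = lapply(raw$ratios, function(s) {
      if (is.na(s) || !nzchar(s)) return(setNames(numeric(0), character(0)))
      parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      setNames(as.numeric(vapply(parts, `[[`, character(1), 2)),
               vapply(parts, `[[`, character(1), 1))
    })
  )
}
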