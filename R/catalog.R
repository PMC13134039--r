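catalog_id_for <- function(gene, sequence) {
  paste0(gene, "_", hash_string(sequence))
}

#' Build the nonredundant pathway-gene catalog
#'
#' Compiles the retained gene sequences of pathway-positive genomes into a
#' mapping reference. Nonredundancy is exact: byte-identical sequences of
#' the same gene are merged into one entry whose source list is the union of
#' the contributing genomes. Catalog ids are deterministic
#' (`<gene>_<content hash>`), so rebuilding from the same inputs yields the
#' same reference.
#'
#' @param seqs tibble with columns `genome_id`, `gene`, `sequence`
#'   (nucleotide).
#' @param registry an `scfa_registry`; pathway memberships of each entry are
#'   looked up here.
#' @param profiles optional profiles tibble from [classify_genomes()]; when
#'   given, only genomes with at least one assigned pathway contribute, and
#'   only genes belonging to their assigned pathways.
#' @return catalog tibble: `catalog_id`, `gene`, `pathways` (list), `length`,
#'   `sources` (list), `sequence`.
#' @export
build_catalog <- function(seqs, registry, profiles = NULL) {
  if (!is.null(profiles)) {
    positive <- profiles$genome_id[lengths(profiles$assigned) > 0]
    seqs <- seqs[seqs$genome_id %in% positive, , drop = FALSE]
    assigned <- setNames(profiles$assigned, profiles$genome_id)
    keep <- vapply(seq_len(nrow(seqs)), function(i) {
      memb <- registry_memberships(registry, seqs$gene[i])[[1]]
      length(intersect(memb, assigned[[seqs$genome_id[i]]])) > 0
    }, logical(1))
    seqs <- seqs[keep, , drop = FALSE]
  }
  if (nrow(seqs) == 0) {
    warn_scfa("no sequences to catalog; returning an empty catalog")
    return(tibble::tibble(catalog_id = character(), gene = character(),
                          pathways = list(), length = integer(),
                          sources = list(), sequence = character()))
  }
  unknown <- !seqs$gene %in% registry_genes(registry)
  if (any(unknown)) {
    stop_scfa("sequence table lists gene(s) absent from the registry: %s",
              paste(unique(seqs$gene[unknown]), collapse = ", "))
  }
  key <- paste(seqs$gene, seqs$sequence, sep = "\r")
  groups <- split(seq_len(nrow(seqs)), key)
  # deterministic order: by gene then content hash
  first <- vapply(groups, `[[`, integer(1), 1)
  ids <- catalog_id_for(seqs$gene[first], seqs$sequence[first])
  ord <- order(seqs$gene[first], ids)
  groups <- groups[ord]
  first <- first[ord]
  memberships <- registry_memberships(registry, unique(seqs$gene))
  tibble::tibble(
    catalog_id = ids[ord],
    gene = seqs$gene[first],
    pathways = unname(memberships[seqs$gene[first]]),
    length = nchar(seqs$sequence[first]),
    sources = unname(lapply(groups, function(idx) sort(unique(seqs$genome_id[idx])))),
    sequence = seqs$sequence[first]
  )
}

#' Build the rplB housekeeping catalog
#'
#' Retains candidate rplB sequences whose homology-search score is at least
#' `min_score` (default 400) and deduplicates exactly as [build_catalog()].
#'
#' @param candidates tibble with columns `genome_id`, `sequence`, `score`.
#' @param min_score qualifying bit score (default 400).
#' @return tibble: `catalog_id`, `length`, `sources` (list), `score` (best
#'   qualifying score among merged duplicates), `sequence`.
#' @export
build_rplb_catalog <- function(candidates, min_score = 400) {
  keep <- candidates[candidates$score >= min_score, , drop = FALSE]
  if (nrow(keep) == 0) {
    if (nrow(candidates) > 0) {
      warn_scfa("no rplB candidate reached the score threshold %g", min_score)
    }
    return(tibble::tibble(catalog_id = character(), length = integer(),
                          sources = list(), score = double(),
                          sequence = character()))
  }
  groups <- split(seq_len(nrow(keep)), keep$sequence)
  first <- vapply(groups, `[[`, integer(1), 1)
  ids <- catalog_id_for("rplB", keep$sequence[first])
  ord <- order(ids)
  groups <- groups[ord]
  first <- first[ord]
  tibble::tibble(
    catalog_id = ids[ord],
    length = nchar(keep$sequence[first]),
    sources = unname(lapply(groups, function(idx) sort(unique(keep$genome_id[idx])))),
    score = unname(vapply(groups, function(idx) max(keep$score[idx]), double(1))),
    sequence = keep$sequence[first]
  )
}

#' Write a catalog as FASTA plus a sidecar TSV
#'
#' @param catalog tibble from [build_catalog()] or [build_rplb_catalog()].
#' @param fasta_path output FASTA (mapping reference).
#' @param tsv_path optional sidecar TSV (`catalog_id`, `gene`, `pathways`,
#'   `length`, `sources`); pass `NULL` to skip.
#' @return `fasta_path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, fasta_path, tsv_path = NULL) {
  dna <- Biostrings::DNAStringSet(setNames(catalog$sequence, catalog$catalog_id))
  Biostrings::writeXStringSet(dna, fasta_path)
  if (!is.null(tsv_path)) write_catalog_tsv(catalog, tsv_path)
  invisible(fasta_path)
}

#' Write the catalog sidecar TSV
#' @param catalog catalog tibble.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  out <- tibble::tibble(
    catalog_id = catalog$catalog_id,
    gene = if ("gene" %in% names(catalog)) catalog$gene else "rplB",
    pathways = if ("pathways" %in% names(catalog)) {
      join_set(catalog$pathways)
    } else "",
    length = catalog$length,
    sources = join_set(catalog$sources)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a catalog sidecar TSV
#' @param path TSV written by [write_catalog_tsv()].
#' @return catalog tibble (without sequences).
#' @export
read_catalog_tsv <- function(path) {
  if (!file.exists(path)) stop_scfa("catalog file not found: %s", path)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    catalog_id = raw$catalog_id,
    gene = raw$gene,
    pathways = split_set(as.character(raw$pathways)),
    length = as.integer(raw$length),
    sources = split_set(as.character(raw$sources))
  )
}
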