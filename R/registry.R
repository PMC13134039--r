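#' Pathway products for the eight canonical SCFA biosynthesis routes
#'
#' The four butyrate routes (glutarate, acetyl-CoA, lysine,
#' 4-aminobutyrate/succinate) and four propionate routes (propanediol,
#' acrylate, Wood-Werkman cycle, sodium-pumping succinate), named by primary
#' entry metabolite.
#' @export
pathway_products <- c(
  Glu = "butyrate", Ace = "butyrate", Lys = "butyrate", `4-Ami` = "butyrate",
  Pro = "propionate", Acr = "propionate", WWC = "propionate", SP = "propionate"
)

#' Construct a pathway registry
#'
#' The registry is the single source of truth for pathway definitions: the
#' required gene roster per pathway (whose size is `l_pathway`, the pathway
#' length used for abundance normalization), the product each pathway yields,
#' the shared-gene map (genes in two or more rosters), keyword curation rules,
#' the excluded-gene list, and per-gene model-strain reference bit scores
#' used for the hit-score cutoff.
#'
#' @param pathways list of lists, each with elements `id`, `product`
#'   (`"butyrate"` or `"propionate"`) and `genes` (character vector).
#' @param curation_rules list of lists with `gene`, `include`, `exclude`.
#' @param excluded_genes character vector of genes banned from all rosters.
#' @param model_scores named list: gene symbol -> named numeric vector of
#'   model-strain bit scores.
#' @param shared_genes optional named list gene -> pathway ids; when given it
#'   is checked against the map derived from the rosters.
#' @param require_complete if `TRUE`, require exactly the eight canonical
#'   pathway ids with their fixed product assignment.
#' @return an object of class `scfa_registry`.
#' @export
new_registry <- function(pathways, curation_rules = list(),
                         excluded_genes = character(),
                         model_scores = list(),
                         shared_genes = NULL,
                         require_complete = TRUE) {
  if (length(pathways) == 0) stop_scfa("registry must define at least one pathway")
  ids <- vapply(pathways, function(p) as.character(p$id), character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_scfa("duplicate pathway id in registry: %s", paste(unique(dup), collapse = ", "),
              class = "scfapath_config_error")
  }
  products <- vapply(pathways, function(p) as.character(p$product), character(1))
  bad_prod <- !products %in% c("butyrate", "propionate")
  if (any(bad_prod)) {
    stop_scfa("pathway %s has unknown product '%s'", ids[bad_prod][1],
              products[bad_prod][1], class = "scfapath_config_error")
  }
  if (require_complete) {
    missing <- setdiff(names(pathway_products), ids)
    if (length(missing) > 0) {
      stop_scfa("registry is missing required pathway(s): %s",
                paste(missing, collapse = ", "), class = "scfapath_config_error")
    }
    extra <- setdiff(ids, names(pathway_products))
    if (length(extra) > 0) {
      stop_scfa("registry lists unknown pathway id(s): %s",
                paste(extra, collapse = ", "), class = "scfapath_config_error")
    }
  }
  # product fixed by id for the canonical eight
  canon <- ids %in% names(pathway_products)
  wrong <- canon & products != unname(pathway_products[ids])
  if (any(wrong)) {
    stop_scfa("pathway %s must have product '%s', got '%s'",
              ids[wrong][1], pathway_products[[ids[wrong][1]]], products[wrong][1],
              class = "scfapath_config_error")
  }
  gene_sets <- lapply(pathways, function(p) unique(as.character(p$genes)))
  n_genes <- lengths(gene_sets)
  if (any(n_genes < 1)) {
    stop_scfa("pathway %s has an empty gene roster", ids[n_genes < 1][1],
              class = "scfapath_config_error")
  }
  excluded_genes <- as.character(excluded_genes)
  for (i in seq_along(ids)) {
    clash <- intersect(gene_sets[[i]], excluded_genes)
    if (length(clash) > 0) {
      stop_scfa("gene %s is listed both as required (pathway %s) and excluded",
                clash[1], ids[i], class = "scfapath_config_error")
    }
  }

  tab <- tibble::tibble(
    pathway_id = ids, product = products,
    genes = gene_sets, l_pathway = as.integer(n_genes)
  )
  derived_shared <- derive_shared_genes(tab)
  if (!is.null(shared_genes)) {
    shared_genes <- lapply(shared_genes, function(v) sort(as.character(v)))
    if (!identical(shared_genes[order(names(shared_genes))],
                   derived_shared[order(names(derived_shared))])) {
      stop_scfa("shared_genes map disagrees with the map derived from the rosters",
                class = "scfapath_config_error")
    }
  }

  rules <- list()
  for (r in curation_rules) {
    inc <- as.character(r$include %||% character())
    exc <- as.character(r$exclude %||% character())
    if (length(inc) == 0 && length(exc) == 0) {
      stop_scfa("curation rule for gene %s has neither include nor exclude keywords",
                r$gene, class = "scfapath_config_error")
    }
    rules[[as.character(r$gene)]] <- list(include = inc, exclude = exc)
  }

  model_scores <- lapply(model_scores, function(s) {
    v <- unlist(s)
    storage.mode(v) <- "double"
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_scfa("model-strain scores must be finite and >= 0",
                class = "scfapath_config_error")
    }
    v
  })

  structure(
    list(
      pathways = tab,
      shared_genes = derived_shared,
      curation_rules = rules,
      excluded_genes = excluded_genes,
      model_scores = model_scores
    ),
    class = "scfa_registry"
  )
}

derive_shared_genes <- function(pathway_tab) {
  long <- tibble::tibble(
    gene = unlist(pathway_tab$genes),
    pathway_id = rep(pathway_tab$pathway_id, lengths(pathway_tab$genes))
  )
  by_gene <- split(long$pathway_id, long$gene)
  shared <- by_gene[lengths(by_gene) >= 2]
  lapply(shared, function(v) sort(unique(v)))
}

#' Load a pathway registry from a YAML or JSON config file
#'
#' @param path config file with keys `pathways`, `curation_rules`,
#'   `excluded_genes`, `model_strain_scores` and optionally `shared_genes`.
#' @param require_complete require the full eight-pathway registry
#'   (default). Set to `FALSE` for reduced registries used in simulations.
#' @return an `scfa_registry` object.
#' @export
load_registry <- function(path, require_complete = TRUE) {
  if (!file.exists(path)) stop_scfa("registry config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pathways)) {
    stop_scfa("registry config %s has no 'pathways' key", path,
              class = "scfapath_config_error")
  }
  new_registry(
    pathways = cfg$pathways,
    curation_rules = cfg$curation_rules %||% list(),
    excluded_genes = cfg$excluded_genes %||% character(),
    model_scores = cfg$model_strain_scores %||% list(),
    shared_genes = cfg$shared_genes,
    require_complete = require_complete
  )
}

#' Write a registry back to a YAML config file
#'
#' `load_registry(write_registry(r, f))` reproduces `r` exactly.
#' @param registry an `scfa_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  cfg <- list(
    pathways = lapply(seq_len(nrow(registry$pathways)), function(i) {
      list(id = registry$pathways$pathway_id[i],
           product = registry$pathways$product[i],
           genes = registry$pathways$genes[[i]])
    }),
    excluded_genes = registry$excluded_genes,
    curation_rules = lapply(names(registry$curation_rules), function(g) {
      r <- registry$curation_rules[[g]]
      list(gene = g, include = r$include, exclude = r$exclude)
    }),
    model_strain_scores = lapply(registry$model_scores, as.list)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Path to the bundled default registry
#'
#' The bundled config carries the eight canonical pathways; its model-strain
#' scores are synthetic reference values (see the file header).
#' @return filesystem path of the installed YAML config.
#' @export
default_registry_path <- function() {
  system.file("extdata", "registry_synthetic_scores.yaml", package = "scfapath",
              mustWork = TRUE)
}

.registry_cache <- new.env(parent = emptyenv())

#' Load (and cache) the bundled default registry
#' @return an `scfa_registry`.
#' @export
default_registry <- function() {
  if (is.null(.registry_cache$default)) {
    .registry_cache$default <- load_registry(default_registry_path())
  }
  .registry_cache$default
}

#' @export
print.scfa_registry <- function(x, ...) {
  cat(sprintf("<scfa_registry> %d pathways (%d butyrate, %d propionate)\n",
              nrow(x$pathways), sum(x$pathways$product == "butyrate"),
              sum(x$pathways$product == "propionate")))
  for (i in seq_len(nrow(x$pathways))) {
    cat(sprintf("  %-6s %-10s l=%d: %s\n", x$pathways$pathway_id[i],
                x$pathways$product[i], x$pathways$l_pathway[i],
                paste(x$pathways$genes[[i]], collapse = " ")))
  }
  if (length(x$shared_genes) > 0) {
    cat("shared genes:", paste(names(x$shared_genes), collapse = " "), "\n")
  }
  invisible(x)
}

#' All genes known to a registry
#' @param registry an `scfa_registry`.
#' @return character vector of gene symbols in any roster.
#' @export
registry_genes <- function(registry) {
  unique(unlist(registry$pathways$genes))
}

#' Pathway membership for gene symbols
#' @param registry an `scfa_registry`.
#' @param genes character vector of gene symbols.
#' @return named list gene -> character vector of pathway ids (possibly empty).
#' @export
registry_memberships <- function(registry, genes) {
  res <- lapply(genes, function(g) {
    registry$pathways$pathway_id[
      vapply(registry$pathways$genes, function(set) g %in% set, logical(1))]
  })
  names(res) <- genes
  res
}

#' Keyword curation of hit descriptions
#'
#' A hit is kept iff its description matches at least one include keyword of
#' its gene's rule (when the rule lists any) and matches no exclude keyword.
#' Genes without a rule always pass. Matching is case-insensitive substring
#' matching.
#'
#' @param description character vector of free-text hit descriptions.
#' @param gene character vector of gene symbols (recycled if length 1).
#' @param rules curation rules: an `scfa_registry` or its `curation_rules`
#'   list.
#' @return logical vector, `TRUE` to keep.
#' @export
apply_curation <- function(description, gene, rules) {
  if (inherits(rules, "scfa_registry")) rules <- rules$curation_rules
  if (length(gene) == 1) gene <- rep(gene, length(description))
  stopifnot(length(gene) == length(description))
  desc_lc <- tolower(description)
  mapply(function(d, g) {
    rule <- rules[[g]]
    if (is.null(rule)) return(TRUE)
    inc <- tolower(rule$include)
    exc <- tolower(rule$exclude)
    if (length(inc) > 0 &&
        !any(vapply(inc, function(k) grepl(k, d, fixed = TRUE), logical(1)))) {
      return(FALSE)
    }
    !any(vapply(exc, function(k) grepl(k, d, fixed = TRUE), logical(1)))
  }, desc_lc, gene, USE.NAMES = FALSE)
}
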