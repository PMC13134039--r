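#' Collapse genome-level profiles to species-level producer predictions
#'
#' A species is predicted a producer of a product if any of its genomes
#' carries at least one assigned pathway for that product (disagreements
#' between genomes of one species are logged). Species whose assignment
#' retains two or more pathways for the same product are flagged as
#' multi-pathway-ambiguous so that validation can exclude them.
#'
#' @param profiles tibble from [classify_genomes()]; an optional
#'   `species_id` column maps genomes to species (defaults to the genome
#'   id).
#' @param registry an `scfa_registry`.
#' @return tibble: `species_id`, `butyrate`, `propionate` (logical
#'   predictions), `multi_pathway` (logical ambiguity flag).
#' @export
species_predictions <- function(profiles, registry) {
  species <- if ("species_id" %in% names(profiles)) profiles$species_id else profiles$genome_id
  prod_of <- setNames(registry$pathways$product, registry$pathways$pathway_id)
  per_genome <- tibble::tibble(
    species_id = species,
    butyrate = vapply(profiles$assigned,
                      function(a) any(prod_of[a] == "butyrate"), logical(1)),
    propionate = vapply(profiles$assigned,
                        function(a) any(prod_of[a] == "propionate"), logical(1)),
    multi_pathway = vapply(profiles$assigned, function(a) {
      any(table(prod_of[a]) >= 2)
    }, logical(1))
  )
  out <- per_genome |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      disagree = (any(.data$butyrate) && !all(.data$butyrate)) ||
        (any(.data$propionate) && !all(.data$propionate)),
      butyrate = any(.data$butyrate),
      propionate = any(.data$propionate),
      multi_pathway = any(.data$multi_pathway),
      .groups = "drop"
    )
  n_dis <- sum(out$disagree & out$n_genomes > 1)
  if (n_dis > 0) {
    message(sprintf("%d species have genomes with disagreeing predictions; using any-positive", n_dis))
  }
  out[, c("species_id", "butyrate", "propionate", "multi_pathway")]
}

#' Validate pathway predictions against literature phenotypes
#'
#' Confronts species-level producer predictions with reported fermentation
#' phenotypes: TP = predicted and reported producer, FP = predicted but
#' reported non-producer, TN/FN symmetric. Species with unknown phenotype
#' are counted but never enter the rates. When a species abundance table is
#' given, each category is additionally reported as summed relative
#' abundance (percent of total community abundance), so concordant plus
#' discordant percentages sum to the evaluated share of the community.
#'
#' @param profiles tibble from [classify_genomes()].
#' @param phenotypes tibble: `species_id`, `butyrate`, `propionate` (each
#'   `"yes"`, `"no"` or `"unknown"`).
#' @param registry an `scfa_registry`.
#' @param abundances optional tibble `species_id`, `abundance` (relative
#'   abundance, fractions of the community).
#' @param exclude_multi drop species flagged multi-pathway-ambiguous
#'   (default `TRUE`).
#' @return tibble with one row per product: counts `tp`, `fp`, `tn`, `fn`,
#'   `unknown`, `n_evaluated`, rates `tp_rate_predicted` (share of true
#'   positives among predicted producers) and `tn_rate_unpredicted`, and,
#'   when abundances are given, `concordant_abundance_pct` /
#'   `discordant_abundance_pct`.
#' @export
validate_predictions <- function(profiles, phenotypes, registry,
                                 abundances = NULL, exclude_multi = TRUE) {
  preds <- species_predictions(profiles, registry)
  if (exclude_multi) preds <- preds[!preds$multi_pathway, , drop = FALSE]
  joined <- dplyr::inner_join(preds, phenotypes, by = "species_id",
                              suffix = c("_pred", "_pheno"))
  if (nrow(joined) == 0) stop_scfa("no species shared between predictions and phenotypes")
  if (!is.null(abundances)) {
    joined <- dplyr::left_join(joined, abundances[, c("species_id", "abundance")],
                               by = "species_id")
    joined$abundance[is.na(joined$abundance)] <- 0
  }
  res <- lapply(c("butyrate", "propionate"), function(prod) {
    pred <- joined[[paste0(prod, "_pred")]]
    pheno <- joined[[paste0(prod, "_pheno")]]
    known <- pheno %in% c("yes", "no")
    reported <- pheno == "yes"
    tp <- pred & known & reported
    fp <- pred & known & !reported
    tn <- !pred & known & !reported
    fn <- !pred & known & reported
    row <- tibble::tibble(
      product = prod,
      tp = sum(tp), fp = sum(fp), tn = sum(tn), fn = sum(fn),
      unknown = sum(!known),
      n_evaluated = sum(known),
      tp_rate_predicted = if (sum(pred & known) > 0) sum(tp) / sum(pred & known) else NA_real_,
      tn_rate_unpredicted = if (sum(!pred & known) > 0) sum(tn) / sum(!pred & known) else NA_real_
    )
    if (!is.null(abundances)) {
      row$concordant_abundance_pct <- 100 * sum(joined$abundance[tp | tn])
      row$discordant_abundance_pct <- 100 * sum(joined$abundance[fp | fn])
    }
    row
  })
  out <- dplyr::bind_rows(res)
  if (all(out$n_evaluated == 0)) {
    stop_scfa("no evaluable species: all phenotypes are unknown")
  }
  out
}

#' Aggregate producer predictions by taxon
#'
#' @param profiles tibble from [classify_genomes()].
#' @param abundances tibble `species_id`, `family`, `phylum`, `abundance`.
#' @param registry an `scfa_registry`.
#' @param rank `"family"` or `"phylum"`.
#' @return per-taxon tibble: `n_species`, fractions of species predicted
#'   butyrate/propionate producers, total abundance, and producer-weighted
#'   abundance per product.
#' @export
aggregate_by_taxon <- function(profiles, abundances, registry,
                               rank = c("family", "phylum")) {
  rank <- match.arg(rank)
  preds <- species_predictions(profiles, registry)
  joined <- dplyr::inner_join(preds, abundances, by = "species_id")
  no_tax <- is.na(joined[[rank]]) | !nzchar(joined[[rank]])
  if (any(no_tax)) {
    warn_scfa("excluding %d species without %s-level taxonomy", sum(no_tax), rank)
    joined <- joined[!no_tax, , drop = FALSE]
  }
  joined |>
    dplyr::group_by(taxon = .data[[rank]]) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      frac_butyrate = mean(.data$butyrate),
      frac_propionate = mean(.data$propionate),
      total_abundance = sum(.data$abundance),
      butyrate_abundance = sum(.data$abundance[.data$butyrate]),
      propionate_abundance = sum(.data$abundance[.data$propionate]),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_abundance))
}

#' Community abundance shares of predicted producers
#'
#' Partitions the classified community abundance into butyrate-only,
#' propionate-only, dual-producer and non-producer shares (percent of total
#' community abundance; the four shares sum to 100 times the classified
#' abundance).
#'
#' @param profiles tibble from [classify_genomes()].
#' @param abundances tibble `species_id`, `abundance`.
#' @param registry an `scfa_registry`.
#' @return tibble with columns `category` and `abundance_pct`.
#' @export
producer_abundance_share <- function(profiles, abundances, registry) {
  cats <- c("butyrate_only", "propionate_only", "both", "neither")
  if (nrow(profiles) == 0) {
    warn_scfa("no profiles given; all producer shares are zero")
    return(tibble::tibble(category = cats, abundance_pct = 0))
  }
  preds <- species_predictions(profiles, registry)
  joined <- dplyr::inner_join(preds, abundances, by = "species_id")
  category <- ifelse(joined$butyrate & joined$propionate, "both",
              ifelse(joined$butyrate, "butyrate_only",
              ifelse(joined$propionate, "propionate_only", "neither")))
  pct <- vapply(cats, function(cc) 100 * sum(joined$abundance[category == cc]),
                double(1))
  tibble::tibble(category = cats, abundance_pct = unname(pct))
}
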