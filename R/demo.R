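#' Run the full pipeline end-to-end on a simulated workspace
#'
#' Chains the five stages — simulate, classify, build-catalog, quantify,
#' report — through the same entry points the command line uses, writing
#' each stage's outputs (plus a manifest) into a numbered subdirectory.
#' Every random draw derives from `seed`, so two runs with the same seed
#' produce byte-identical payload files (manifests differ only in their
#' timestamp).
#'
#' @param dir workspace directory to create.
#' @param seed integer seed.
#' @param n_genomes,n_samples,depth simulation size knobs.
#' @return named list of stage directories, invisibly.
#' @export
run_demo <- function(dir, seed = 1L, n_genomes = 60L, n_samples = 3L,
                     depth = 0.5) {
  stages <- list(
    simulate = file.path(dir, "01_simulate"),
    classify = file.path(dir, "02_classify"),
    catalog = file.path(dir, "03_catalog"),
    quantify = file.path(dir, "04_quantify"),
    report = file.path(dir, "05_report")
  )
  run <- function(argv) {
    status <- scfapath_cli(argv)
    if (status != 0L) stop_scfa("pipeline stage failed: %s", argv[1])
  }
  run(c("simulate", "--seed", as.character(seed),
        "--n-genomes", as.character(n_genomes),
        "--n-samples", as.character(n_samples),
        "--depth", as.character(depth),
        "--out", stages$simulate))
  run(c("classify", "--hits", file.path(stages$simulate, "hits.tsv"),
        "--out", stages$classify))
  run(c("build-catalog",
        "--profiles", file.path(stages$classify, "profiles.tsv"),
        "--seqs", file.path(stages$simulate, "gene_seqs.tsv"),
        "--rplb-candidates", file.path(stages$simulate, "rplb_candidates.tsv"),
        "--out", stages$catalog))
  run(c("quantify",
        "--counts", file.path(stages$simulate, "gene_counts.tsv"),
        "--rplb-counts", file.path(stages$simulate, "rplb_counts.tsv"),
        "--catalog", file.path(stages$catalog, "catalog.tsv"),
        "--rplb-catalog", file.path(stages$catalog, "rplb_catalog.tsv"),
        "--out", stages$quantify))
  run(c("report",
        "--profiles", file.path(stages$classify, "profiles.tsv"),
        "--phenotypes", file.path(stages$simulate, "phenotypes.tsv"),
        "--abundances", file.path(stages$simulate, "abundances.tsv"),
        "--out", stages$report))
  invisible(stages)
}
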