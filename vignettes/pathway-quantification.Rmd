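---
title: "Quantifying butyrate and propionate pathway abundance in gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying butyrate and propionate pathway abundance in gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfapath)
```

## The problem

Butyrate and propionate, the two short-chain fatty acids most consequential
for host physiology, are produced by a restricted subset of gut bacteria
through eight well-characterized biosynthesis routes, named here by their
primary entry metabolite: four butyrate routes (glutarate, **Glu**;
acetyl-CoA, **Ace**; lysine, **Lys**; 4-aminobutyrate/succinate, **4-Ami**)
and four propionate routes (propanediol, **Pro**; acrylate, **Acr**;
Wood-Werkman cycle, **WWC**; sodium-pumping succinate, **SP**). Fecal SCFA
concentrations are poor proxies for production because of rapid host uptake,
so a genome-resolved route is needed: detect which genomes carry a complete
pathway, then estimate what fraction of the genomes in a metagenomic sample
encode each pathway.

`scfapath` implements that pipeline in five stages: genotype classification
from homology-search hits, mapping-catalog construction, per-sample
abundance estimation, community-level validation/aggregation, and a
synthetic-community simulator that generates every input the other stages
consume.

## Genotype calling

A genome is called positive for a pathway only when **every** gene of the
pathway's required roster has at least one surviving homology hit. Three
filters precede the completeness call:

* **Keyword curation.** Annotations for a handful of genes (`bcd`, `but`,
  `ptb`, `hbd`) are notoriously non-specific; free-text descriptions are
  screened with per-gene include/exclude keyword lists (case-insensitive
  substring matching — the minimal reading of a keyword rule, with no regex
  semantics to surprise config authors).
* **Score cutoff.** A hit survives iff its bit score is at least half the
  lowest score attained by the experimentally characterized model strains
  for that gene (`score_frac = 0.5`, configurable). The boundary is
  inclusive: a hit exactly at the cutoff is retained.
* **Excluded genes.** Genes whose public-database annotations are too
  inconsistent to support presence calls (`etfAB`, `acrC`, `mmdD` by
  default) are banned from every roster at registry-validation time.

Genomes complete for several pathways of the *same* product are resolved by
comparing mean score ratios: for each candidate pathway, the mean over its
required genes of (best hit score) / (mean model-strain score). The
top-ratio pathway is assigned, together with any pathway within `tie_margin`
(default 0.1) of it — so genuinely multi-pathway genomes are retained rather
than forced into a single call. `tie_margin = 0` yields exactly one pathway
per product (exact ties broken by registry order, for reproducibility);
`tie_margin = Inf` keeps all complete pathways. Butyrate and propionate are
resolved independently, since dual producers carrying one pathway of each
product are well documented. When a genome has several surviving hits for
one gene, the best-scoring hit represents the gene in the ratio.

The registry itself — rosters, products, curation rules, exclusions, model
scores — ships as an editable YAML config rather than hard-coded tables,
because roster curation is a judgment users may revisit. The bundled config
carries the eight canonical pathways; its model-strain scores are *synthetic*
reference values with realistic magnitudes (the file says so in its header)
and should be replaced for production use.

## The abundance estimator

For a metagenomic sample, the percentage of genomes encoding pathway $p$ is

$$
P_{\mathrm{genomes}}(p) \;=\; 100 \cdot
\frac{\sum_{g \in p} (h_g / l_g) \,/\, l_p}
     {\sum_{r \in \mathrm{rplB}} h_r / l_r}
$$

where $h_g$ is the mapped-read count of catalog gene $g$, $l_g$ its length
in bp, $l_p$ the number of genes in the pathway, and the denominator sums
length-normalized counts over the rplB housekeeping catalog. Each term has a
job: dividing by $l_g$ removes the length bias of read recruitment; dividing
by $l_p$ bases the estimate on average per-gene evidence so pathways with
long rosters are not overrepresented; and the rplB ratio converts read
depth into genome equivalents, because rplB is near-universal and
near-single-copy in gut taxa (mean copy number about 1.03). Under
single-copy genes the estimator is independent of pathway length and of
overall sequencing depth — both properties are enforced by tests.

Counts for genes shared between pathways (the "gray" genes: `bcd`, `but`
among butyrate routes; `pct`, `mutA`, `mutB`, `mce` among propionate routes)
cannot be attributed directly. An observed count $h_o$ is divided in
proportion to single-pathway evidence in the same sample:

$$ h_{\mathrm{gene}} = h_o \cdot \frac{\sum h_s}{\sum h_m} $$

with $\sum h_s$ the summed counts of the target pathway's single-pathway
genes and $\sum h_m$ the same sum over all pathways containing the shared
gene. Apportionment always conserves $h_o$. When $\sum h_m = 0$ the formula
is undefined; the package splits the count equally among the gene's pathways
and warns, the only conservation-preserving fallback that requires no
imputation.

Two behaviours deserve emphasis:

* **Values above 100% are reported, not clipped.** They arise legitimately
  when genomes carry duplicated pathway genes or several pathways; the
  simulator can reproduce the mechanism via its copy-number violation rate.
* **Zero rplB signal makes the estimate undefined**, and it is reported as
  missing with an error flag — never silently as 0. The command-line
  `quantify` stage refuses outright when all rplB counts are zero.

### What apportionment does and does not recover

The proportional rule allocates shared-gene counts by *raw* single-pathway
gene counts, which weight a pathway by (carrier abundance x number of
single-pathway genes x their lengths) rather than by carrier abundance
alone. When several same-product pathways are present in one sample, a
pathway with few unique genes (Ace, with three, once `bcd` and `but` are
shared) receives systematically less of the shared counts than true
attribution would give it. The package therefore distinguishes two
reference values in its tests: the *plug-in* value (the estimator applied to
noise-free expected counts — what the estimator converges to) and the
*true-attribution* expectation (the abundance-weighted carrier fraction).
They coincide exactly when at most one pathway per shared-gene group is
present, and in single-pathway simulations the estimator recovers the
carrier fraction unbiasedly; with co-occurring same-product pathways the
two can differ by a few percent of the pathway's value. This is a property
of the estimator, not of the implementation.

## Catalogs

Mapping references are nonredundant at exact sequence identity: within a
gene symbol, byte-identical sequences merge into one entry whose source list
is the union of contributing genomes. The conservative exact-dedup reading
was chosen because no clustering threshold is part of the method; a
similarity-clustering hook would change mapping behaviour and is left out.
Catalog ids are deterministic (`<gene>_<FNV-1a hash of the sequence>`), so
rebuilding from the same inputs yields byte-identical references.
Nucleotide sequences are catalogued, matching end-to-end read alignment
downstream. rplB candidates qualify at a bit score of at least 400
(inclusive), then deduplicate the same way.

## Validation and aggregation

Predictions are validated at species level: a species is a predicted
producer of a product if any of its genomes keeps at least one assigned
pathway for it. Comparison against literature phenotypes yields TP/FP/TN/FN
counts per product; unknown phenotypes never enter rates, and species whose
resolution retained two or more same-product pathways can be excluded as
ambiguous. When species relative abundances are supplied, concordant and
discordant sets are also reported as percent of total community abundance,
and `producer_abundance_share()` partitions the classified community into
butyrate-only / propionate-only / both / neither shares.
`aggregate_by_taxon()` summarizes producer fractions and producer-weighted
abundance per family or phylum; the family "fraction of producers" uses
species as denominator (one representative prediction per species), the
configurable-default reading of a strain-vs-species ambiguity.

## The simulator

`simulate_community()` and friends generate every input the pipeline reads,
with the statistical structure the estimator assumes:

* genomes carry at most one butyrate and one propionate pathway, with a
  small same-product multi-carriage rate (default 0.02);
* default carriage probabilities put roughly a fifth of genomes on a
  butyrate pathway (mostly Ace) and a sixth on a propionate pathway (mostly
  SP), the prevalences typical of gut strain collections;
* abundances are long-tailed (normalized Gamma draws, shape 0.3), mirroring
  communities where a few species hold most biomass; an `equal` mode and a
  `fixed` carriage mode exist for experiments that need the carrier
  fraction to be exact;
* read counts are Poisson with mean `depth x abundance x length x copies`
  (negative-binomial overdispersion available), the simplest model
  consistent with length-proportional read recruitment; gene lengths are
  uniform on 600-2400 bp and rplB is fixed at 831 bp;
* hit tables score carried genes at 75-105% of the gene's mean model score
  (safely above the 50%-of-minimum cutoff) and add sub-cutoff decoys plus
  occasional miscurated high-scoring hits, so both filters do real work in
  tests;
* phenotype tables report the truth with a configurable flip rate and
  unknown-masking rate.

All randomness derives from the config seed (community, hits, counts and
phenotypes use distinct fixed offsets of it), so any stage can be
regenerated independently and a full workspace rerun is byte-identical.
What the simulator does **not** emulate: real homology score distributions,
annotation errors beyond keyword-curable ones, strain-level gene content
variation within species, mapping ambiguity between homologous catalog
entries, and compositional noise in abundance estimates. Passing tests
therefore certify the pipeline's arithmetic and contracts, not performance
on real gut metagenomes.

## Numerical and design choices

* Score filtering uses full-sequence bit scores from tabular homology
  output; domain-level scores are ignored.
* The score cutoff and the rplB threshold are inclusive (`>=`).
* SAM/BAM counting keeps primary mapped alignments only (no secondary,
  supplementary or unmapped records), so each read counts at most once.
* Count tables referencing ids absent from the catalog are an error, not a
  silent drop; catalog genes absent from a sample contribute zero (no
  imputation).
* Multiple rplB entries pool in the denominator exactly as written; there
  is no per-taxon rplB matching.
* Exact resolution ties break by registry order; catalog ids are
  content-hashed — both choices exist purely for reproducibility.
* The "observed score drop-off" sometimes used alongside the 50% rule is
  not quantifiable from the method description; only the 50% rule is
  implemented, with `score_frac` as the override.

## Problem sizes in the test-suite experiments

The packaged experiments use communities of 20-60 genomes (2000 for the
validation-noise check), up to 50 samples per condition, and depths of
0.1-5 reads/bp — sizes chosen so the full suite exercises every contract in
about a minute while leaving Monte-Carlo standard errors well below the
tolerances tested. Carrier-fraction recovery is checked at f in {0, 0.1,
0.5, 1} with equal abundances and fixed carrier counts, where the expected
estimate is exactly 100 f.

## Limitations

Pathway presence is metabolic *potential*: regulation, substrate
availability and ecological context decide realized flux, and no
genomic estimator observes them. The single-pathway resolution rule
reflects the rarity of same-product multi-pathway gut genomes; in clades
where that assumption fails, widen `tie_margin`. The bundled registry's
model-strain scores are synthetic stand-ins, and the shipped rosters
transcribe standard pathway descriptions — both are config, not code, and
production use should substitute curated values.
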