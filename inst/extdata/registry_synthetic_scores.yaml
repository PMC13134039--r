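# Default pathway registry for scfapath.
#
# Eight butyrate/propionate biosynthesis routes named by their primary entry
# metabolite. Gene rosters follow the standard pathway descriptions used for
# gut SCFA gene screens; genes appearing in more than one roster are the
# shared ("gray") genes whose read counts must be apportioned downstream.
#
# model_strain_scores are SYNTHETIC reference bit scores standing in for
# per-gene scores of experimentally characterized model strains. They have
# realistic magnitudes and spread but are not measured values; replace them
# with real model-strain scores for production analyses.
pathways:
  - id: Glu
    product: butyrate
    genes: [gctA, gctB, hgdA, hgdB, hgdC, gcdA, bcd, but]
  - id: Ace
    product: butyrate
    genes: [thl, hbd, crt, bcd, but]
  - id: Lys
    product: butyrate
    genes: [kamA, kamD, kamE, kdd, kce, kal, atoA, atoD, but]
  - id: 4-Ami
    product: butyrate
    genes: [abfH, abfD, isom, 4hbt]
  - id: Pro
    product: propionate
    genes: [pduC, pduD, pduE, pduP, pduL, pduW]
  - id: Acr
    product: propionate
    genes: [lcdA, lcdB, lcdC, pct]
  - id: WWC
    product: propionate
    genes: [mutA, mutB, mce, pccA, pccB, pct]
  - id: SP
    product: propionate
    genes: [mutA, mutB, mce, mmdA, sctA]

# Genes dropped from every roster because public-database annotations for
# them are too inconsistent to support presence calls.
excluded_genes: [etfAB, acrC, mmdD]

# Keyword filters applied to hit descriptions before score filtering.
# Matching is case-insensitive substring: keep iff the description matches at
# least one include keyword (when any are given) and no exclude keyword.
curation_rules:
  - gene: bcd
    include: ["butyryl-CoA dehydrogenase"]
    exclude: ["short-chain", "isovaleryl", "crotonobetainyl"]
  - gene: but
    include: ["butyryl-CoA:acetate CoA-transferase", "butyryl-CoA:acetate CoA transferase"]
    exclude: ["4-hydroxybutyrate"]
  - gene: ptb
    include: ["phosphate butyryltransferase", "phosphotransbutyrylase"]
    exclude: []
  - gene: hbd
    include: ["3-hydroxybutyryl-CoA dehydrogenase"]
    exclude: ["dehydratase"]

# SYNTHETIC per-gene reference scores for three model strains per gene.
# The hit-score cutoff for a gene is score_frac (default 0.5) times the
# minimum of these values.
model_strain_scores:
  gctA: {Acidaminococcus_fermentans_DSM20731: 420, Clostridium_sporosphaeroides_DSM1294: 370, Fusobacterium_varium_ATCC27725: 470}
  gctB: {Acidaminococcus_fermentans_DSM20731: 390, Clostridium_sporosphaeroides_DSM1294: 343, Fusobacterium_varium_ATCC27725: 437}
  hgdA: {Acidaminococcus_fermentans_DSM20731: 510, Clostridium_sporosphaeroides_DSM1294: 449, Fusobacterium_varium_ATCC27725: 571}
  hgdB: {Acidaminococcus_fermentans_DSM20731: 300, Clostridium_sporosphaeroides_DSM1294: 264, Fusobacterium_varium_ATCC27725: 336}
  hgdC: {Acidaminococcus_fermentans_DSM20731: 280, Clostridium_sporosphaeroides_DSM1294: 246, Fusobacterium_varium_ATCC27725: 314}
  gcdA: {Acidaminococcus_fermentans_DSM20731: 450, Clostridium_sporosphaeroides_DSM1294: 396, Fusobacterium_varium_ATCC27725: 504}
  bcd:  {Faecalibacterium_prausnitzii_A2-165: 520, Roseburia_intestinalis_L1-82: 458, Eubacterium_rectale_ATCC33656: 582}
  but:  {Faecalibacterium_prausnitzii_A2-165: 480, Roseburia_intestinalis_L1-82: 422, Eubacterium_rectale_ATCC33656: 538}
  thl:  {Faecalibacterium_prausnitzii_A2-165: 430, Roseburia_intestinalis_L1-82: 378, Eubacterium_rectale_ATCC33656: 482}
  hbd:  {Faecalibacterium_prausnitzii_A2-165: 410, Roseburia_intestinalis_L1-82: 361, Eubacterium_rectale_ATCC33656: 459}
  crt:  {Faecalibacterium_prausnitzii_A2-165: 330, Roseburia_intestinalis_L1-82: 290, Eubacterium_rectale_ATCC33656: 370}
  kamA: {Intestinimonas_butyriciproducens_AF211: 540, Clostridioides_difficile_630: 475, Fusobacterium_nucleatum_ATCC25586: 605}
  kamD: {Intestinimonas_butyriciproducens_AF211: 500, Clostridioides_difficile_630: 440, Fusobacterium_nucleatum_ATCC25586: 560}
  kamE: {Intestinimonas_butyriciproducens_AF211: 470, Clostridioides_difficile_630: 414, Fusobacterium_nucleatum_ATCC25586: 526}
  kdd:  {Intestinimonas_butyriciproducens_AF211: 360, Clostridioides_difficile_630: 317, Fusobacterium_nucleatum_ATCC25586: 403}
  kce:  {Intestinimonas_butyriciproducens_AF211: 340, Clostridioides_difficile_630: 299, Fusobacterium_nucleatum_ATCC25586: 381}
  kal:  {Intestinimonas_butyriciproducens_AF211: 380, Clostridioides_difficile_630: 334, Fusobacterium_nucleatum_ATCC25586: 426}
  atoA: {Intestinimonas_butyriciproducens_AF211: 310, Clostridioides_difficile_630: 273, Fusobacterium_nucleatum_ATCC25586: 347}
  atoD: {Intestinimonas_butyriciproducens_AF211: 320, Clostridioides_difficile_630: 282, Fusobacterium_nucleatum_ATCC25586: 358}
  abfH: {Clostridioides_difficile_630: 460, Clostridium_kluyveri_DSM555: 405, Porphyromonas_gingivalis_W83: 515}
  abfD: {Clostridioides_difficile_630: 530, Clostridium_kluyveri_DSM555: 466, Porphyromonas_gingivalis_W83: 594}
  isom: {Clostridioides_difficile_630: 400, Clostridium_kluyveri_DSM555: 352, Porphyromonas_gingivalis_W83: 448}
  4hbt: {Clostridioides_difficile_630: 350, Clostridium_kluyveri_DSM555: 308, Porphyromonas_gingivalis_W83: 392}
  pduC: {Roseburia_inulinivorans_DSM16841: 610, Salmonella_enterica_LT2: 537, Lactobacillus_reuteri_DSM20016: 683}
  pduD: {Roseburia_inulinivorans_DSM16841: 370, Salmonella_enterica_LT2: 326, Lactobacillus_reuteri_DSM20016: 414}
  pduE: {Roseburia_inulinivorans_DSM16841: 290, Salmonella_enterica_LT2: 255, Lactobacillus_reuteri_DSM20016: 325}
  pduP: {Roseburia_inulinivorans_DSM16841: 490, Salmonella_enterica_LT2: 431, Lactobacillus_reuteri_DSM20016: 549}
  pduL: {Roseburia_inulinivorans_DSM16841: 310, Salmonella_enterica_LT2: 273, Lactobacillus_reuteri_DSM20016: 347}
  pduW: {Roseburia_inulinivorans_DSM16841: 330, Salmonella_enterica_LT2: 290, Lactobacillus_reuteri_DSM20016: 370}
  lcdA: {Coprococcus_catus_GD7: 440, Megasphaera_elsdenii_DSM20460: 387, Clostridium_propionicum_DSM1682: 493}
  lcdB: {Coprococcus_catus_GD7: 420, Megasphaera_elsdenii_DSM20460: 370, Clostridium_propionicum_DSM1682: 470}
  lcdC: {Coprococcus_catus_GD7: 390, Megasphaera_elsdenii_DSM20460: 343, Clostridium_propionicum_DSM1682: 437}
  pct:  {Coprococcus_catus_GD7: 470, Megasphaera_elsdenii_DSM20460: 414, Propionibacterium_freudenreichii_DSM4902: 526}
  mutA: {Propionibacterium_freudenreichii_DSM4902: 600, Bacteroides_fragilis_NCTC9343: 528, Prevotella_copri_DSM18205: 672}
  mutB: {Propionibacterium_freudenreichii_DSM4902: 580, Bacteroides_fragilis_NCTC9343: 510, Prevotella_copri_DSM18205: 650}
  mce:  {Propionibacterium_freudenreichii_DSM4902: 320, Bacteroides_fragilis_NCTC9343: 282, Prevotella_copri_DSM18205: 358}
  pccA: {Propionibacterium_freudenreichii_DSM4902: 560, Bacteroides_fragilis_NCTC9343: 493, Prevotella_copri_DSM18205: 627}
  pccB: {Propionibacterium_freudenreichii_DSM4902: 540, Bacteroides_fragilis_NCTC9343: 475, Prevotella_copri_DSM18205: 605}
  mmdA: {Bacteroides_fragilis_NCTC9343: 430, Prevotella_copri_DSM18205: 378, Veillonella_parvula_DSM2008: 482}
  sctA: {Bacteroides_fragilis_NCTC9343: 410, Prevotella_copri_DSM18205: 361, Veillonella_parvula_DSM2008: 459}
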