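# pairtcr

Paired single-cell TCR (scTCR-seq) and gene-expression (scRNA-seq)
repertoire analysis for follicular T cells in a two-condition design,
built as a reusable R package plus a numbered analysis workflow. It is
aimed at immunologists comparing repertoires between an autoimmune and a
non-autoimmune (immunized) cohort who want every step — from 10x contig
tables to antigen predictions — scripted, seeded and testable without
any external downloads.

## What it computes

* **Clonotypes** — cells with full-length productive TRA+TRB chains are
  paired (highest-UMI contig per chain) and grouped by identical
  (CDR3α, CDR3β) amino-acid pairs; clone size = number of cell barcodes.
* **Repertoire statistics** — Shannon diversity *H* = −Σ pᵢ ln pᵢ;
  exact hypergeometric rarefaction E[S(m)] = Σᵢ (1 − C(N−nᵢ, m)/C(N, m));
  public-clonotype detection; Bray–Curtis + NMDS ordination (Kruskal
  stress-1, seeded restarts); sample–clonotype networks of expanded
  clones; expansion labels log₂FC = log₂((b+1)/(a+1)) with the display
  cuts |log₂FC| > 3 & size > 10 (clonotypes) and |log₂FC| > 2.5 &
  size > 10 (specificity groups).
* **Specificity groups** — GLIPH-style clustering by enriched interior
  CDR3β k-mers (k ∈ {3,4}, one-sided Fisher vs. a reference repertoire,
  Bonferroni-adjusted motif component) and by single conservative
  (BLOSUM62 ≥ 0) substitutions at equal length; V-gene-bias and
  length-concentration tests; filter: ≥ 4 clonotypes from ≥ 3 samples,
  V-bias p < 0.05, final score < 10⁻⁵.
* **Antigen annotation** — a harmonized CDR3β→antigen database (IUPAC
  filter, dedup, disease classes); exact CDR3β matching; motif-level
  annotation transfer from database groups to query groups.
* **Profile-based antigen search** — 9-mer peptides of expanded
  annotated clonotypes (clone size > 3), weighted by clone size ×
  2^|log₂FC|, build a 9×20 PWM of positional enrichment ratios
  f(j,a)/background(a); every proteome window is scored by the log-sum
  of ratios with empirical (all-windows or composition-null) p-values
  and Bonferroni correction.
* **Expression linkage** — barcode joining, counts-per-10k
  log-normalization, Spearman correlation of every gene with clone
  size, Wilcoxon rank-sum differential expression (Bonferroni; display
  filter adj. p < 0.01 & |log₂FC| > 0.2), per-clonotype average raw
  counts, and binned-control module scores.
* **Synthetic data** — a seeded generator planting ground-truth motifs,
  public clonotypes, size-correlated genes and proteome target peptides,
  so the whole pipeline is testable end to end.

## Worked example

The one-command demo generates a full synthetic dataset (10 samples,
5 planted CDR3β motifs, 8 public clonotypes, expression panel, reference
database, toy proteome), writes it to disk, and runs every stage on the
files:

```r
library(pairtcr)
res <- run_demo("demo", seed = 1)
sum(res$specificity$groups$passes_filter)
res$annotation$exact$matched_fraction
```

The same analysis, stage by stage and with narrative output, is in
`analysis/01_simulate.R` … `analysis/07_expression_link.R`; run them in
order from the repository root. Representative output (seed 1):

```
02: cells with paired productive chains: 5423 of 5708 (95.0%)
    clonotypes: 2976
03: public clonotypes: 8 | shared between conditions: 8
    NMDS stress: 0.0499 (< 0.1)
04: candidate groups: 65 | passing the full filter: 56
    planted motifs recovered: 5 of 5
05: exact CDR3beta match: 2.69% of unique CDR3betas (80 annotations)
    annotated specificity groups: 20 of 56 passing
07: planted size-correlated genes with correct rho sign: 20 of 20
    DE display hits (WT over AU): 12 genes; planted condition-shifted
    among them: 10 of 10
```

Reading it: 95% of cells survive the pairing filter (the 5% decoys are
discarded); all five planted specificity motifs yield filter-passing
groups whose membership matches the planted carriers; about 2.7% of
unique CDR3βs hit the reference database exactly, seeding the PWM
proteome scan; and the planted expression effects are recovered with the
correct signs. Rerunning with the same seed reproduces every file
byte-for-byte.

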