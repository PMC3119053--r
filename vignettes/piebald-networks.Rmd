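---
title: "Dissecting piebald pigmentation with regulatory and epistatic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting piebald pigmentation with regulatory and epistatic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Piebald is an asymmetric white-spotting phenotype of Merino sheep with no
single gene of large effect: association signals, expression differences and
transcription-factor regulation each carry part of the picture. `piebaldnet`
implements an integrated analysis that combines three data types — a
case-control SNP panel, a five-variety two-colour skin microarray, and
precomputed transcription factor binding site (TFBS) predictions — and asks
which genes sit at the intersection of a TFBS-derived regulatory network and
an epistasis-derived gene network.

```{r setup}
library(piebaldnet)
```

## The cohort and matched-control design

Cases are compared against controls drawn from a much larger genotyped pool.
To remove population structure unrelated to the phenotype, controls are
matched on genome-wide identity-by-state (IBS) sharing,

$$s_{ij} = \frac{1}{|M_{ij}|}\sum_{m \in M_{ij}} \frac{2 - |g_{im} - g_{jm}|}{2},$$

where $g \in \{0,1,2\}$ counts copies of the B allele and $M_{ij}$ is the set
of SNPs called in both animals; pairs with no jointly observed SNP are
missing. `select_controls()` walks the cases in input order and greedily
takes, for each, the `k_per_case = 3` unselected candidates with the highest
sharing, without replacement. The procedure is deterministic: ties break by
candidate order in the matrix. Matching happens on the full marker panel;
quality filters (`filter_snps()`: call rate, minor allele frequency,
polymorphism within the labelled cohort) are applied afterwards, to the
matched cohort, before any testing.

## Single-SNP association and the dual significance rule

For each SNP, `snp_association()` builds the 2x2 allele-count table (B vs b
by case/control over non-missing calls) and computes the Pearson chi-square
without continuity correction (1 df) and the allelic odds ratio
$\mathrm{OR} = ad/bc$, oriented so that $\mathrm{OR} \ge 1$; a zero cell
yields a missing OR rather than a pseudo-count. The per-SNP effect summary is
the genotype-mean difference (cases minus controls on the 0-2 scale).
`significant_snps()` applies the dual rule: a SNP is significant when its
genotype difference lies more than `sd_multiplier = 3` standard deviations
from the mean of the genome-wide genotype-difference distribution **and**
the chi-square p-value is below `p_threshold = 0.001`. The standard deviation
is the sample SD across all finite records, and the deviation is absolute
(two-sided); both choices are deliberate where the rule leaves room.

The worked example below reconstructs an allele-count table from published
group frequencies (24 cases = 48 alleles at frequency 0.54; 72 controls =
144 alleles at 0.88):

```{r}
calls <- cbind(s1 = c(rep(2L, 13), rep(0L, 11), rep(2L, 63), rep(0L, 9)))
rownames(calls) <- c(sprintf("case%02d", 1:24), sprintf("ctrl%02d", 1:72))
gt <- genotype_table(calls, data.frame(snp_id = "s1", chrom = "chr6", pos = 1),
                     setNames(rep(c("case", "control"), c(24, 72)),
                              rownames(calls)))
snp_association(gt)[, c("freq_case", "freq_control", "chi2", "p_value", "odds_ratio")]
```

## The two-locus epistasis scan

`epistasis_scan()` tests every unordered pair of the significant SNPs with a
9x2 contingency table: nine joint two-locus genotypes by case/control,
counted over animals non-missing at both loci. The Pearson statistic is
referred to a chi-square with the degrees of freedom **fixed at 8**
regardless of empty rows — cells with zero expected count contribute
nothing. This is a deliberate fidelity choice: the test is the saturated
9-cell comparison, not a reduced-df variant. Pairs closer than 100 kb on one
chromosome are flagged (`proximity_flag`) because their signal may reflect
linkage disequilibrium rather than epistasis; flagged pairs are kept by
default and can be excluded from network input (`exclude_proximal`).
`ld_r2()` provides the composite (genotype-correlation) $r^2$ to inspect
such pairs.

Because the scan conditions on marginally associated SNPs, a pair of two
strongly associated but independent loci is often itself significant: the
9x2 statistic aggregates marginal and interaction signal. The hub-reduction
step downstream is what concentrates attention on loci with many partners.

At the study's cohort size (24 cases), the expected counts of many joint
genotype cells are below one, and the chi-square reference is conservative
in the far tail. The calibration tests therefore run on null cohorts of
200/600 animals with a MAF >= 0.3 filter, where the asymptotics hold at the
0.1% tail; the aggregation runs over ten independent simulated panels
because pairs sharing a SNP are positively dependent and a single panel
over-disperses the significant fraction.

## Microarray acquisition and mixed-model normalization

The expression data come from a 20-hybridisation dye-swap loop over five
skin varieties: normal white (NOR), piebald white and black (PBW, PBB), and
recessive-black white and black (RSW, RSB). Every variety pair is hybridised
twice with dyes swapped between biological replicates, so each sample enters
four hybridisations, twice per dye. `acquire()` applies the two acquisition
rules — probes with signal-to-noise below 2 in *every* hybridisation are
undetectable (one passing hybridisation suffices), and multi-probe genes
collapse to the most abundant probe (highest mean background-corrected
intensity) — then background-corrects with a floor of 1 and log2-transforms.

`fit_normalization_model()` fits

$$y = \mu + C + G + AG + DG + VG + e,$$

with the comparison group $C$ (all measurements from one array slide,
printing block and dye channel) fixed, and gene, array x gene, dye x gene,
variety x gene and residual as independent zero-mean random effects.
Variance components are estimated by EM-REML; the implementation exploits
the fact that all random effects nest within gene, so the phenotypic
covariance matrix is block diagonal by gene and genes sharing a design
pattern share one small (40 x 40 in the full design) block inverse per
iteration. Components are truncated at zero, the REML log-likelihood is
recorded each iteration (it is non-decreasing, which the tests assert), and
convergence requires a relative change below `tol = 1e-6` in every
component. Near a zero-variance boundary (e.g. noise-free data) EM
approaches the boundary geometrically and may exhaust `max_iter`; the fit is
then returned with `converged = FALSE` and a warning, and the solutions are
still accurate, as the zero-noise tests show. The EM fit agrees with an
independent REML implementation (`lme4`) to at least four decimals on shared
test data.

The best linear unbiased predictions of the variety-x-gene effect are the
normalized expression, reported on the intensity scale as
$\hat\mu + \hat G + \widehat{VG}$ so values are comparable to raw log2
intensities; the contrasts difference out $\mu$ and $G$, so this choice does
not affect any downstream result. Note that BLUPs shrink towards zero: a
lone planted effect in an otherwise quiet panel is recovered slightly
attenuated (a few percent at the default scale).

## Differential expression and colours

`compute_contrasts()` evaluates seven named linear combinations (DE1-DE7) of
the five variety values, e.g. DE3 = PBW - NOR ("piebald vs normal within
white") and DE7 = (PBB+RSB)/2 - (NOR+PBW+RSW)/3 ("black vs white").
`call_de()` standardizes each contrast across genes and flags |z| >= 2.57
(the conventional two-tailed 1% point, kept verbatim as 2.57 rather than
recomputed as 2.576). The SD here is the across-gene SD of the contrast, not
a model-based standard error — a deliberate interpretation where the rule
could be read either way. `contrast_correlations()` reports the 21 pairwise
contrast correlations; the piebald-facing contrasts DE3, DE5 and DE6 are the
most correlated under a shared piebald signal, and their per-gene mean (the
*piebald score*) drives the network colour: over-expressed (red),
under-expressed (green), unchanged (orange), absent from the array (blue).

## SNP-to-gene annotation and the piebald gene call

`map_snps_to_genes()` measures the distance from a SNP to the nearer edge of
each same-chromosome gene interval (1-based inclusive, strand ignored; 0
when intragenic) and classifies it: intragenic, cis (<= 2.5 kb), proximal
(<= 20 kb), distal. Ties go to the gene with the smaller start.
`call_piebald_genes()` merges expression with association: a gene qualifies
when (i) it is DE in at least one contrast and has a SNP within 2.5 kb, or
(ii) it is not DE but a SNP passing the dual significance rule lies within
1 Mb of its interval. "Within 1 Mb" is interpreted as gene-edge distance
<= 1,000,000 bp throughout, and criterion (ii) requires the dual-rule
significant set, not nominal significance. Each gene is reported once with
its most associated SNP within 1 Mb.

## Networks, hubs and the intersecting landscape

`build_regulatory_network()` keeps TFBS records with core **and** matrix
similarity at 100% confidence (threshold 1.0) targeting candidate
(piebald-associated) genes; an edge links each gene to the TF whose binding
site it contains. All candidate genes remain as nodes (isolated if nothing
binds them) so the exported network carries the full colour map. The minimum
number of targets for a TF to enter is exposed (`min_targets`, default 1):
the observation that a few TFs bind 20 or more candidate genes is treated as
a result, not a rule.

`build_epistatic_network()` turns each significant SNP pair into an edge
between the two SNPs' nearest genes. Pair counts per gene are tallied before
edges collapse (multiple SNP pairs between one gene pair become a single
edge with an `n_pairs` annotation; pairs collapsing onto one gene are
self-edges and dropped). A *hub* is a gene in strictly more than
`hub_threshold = 20` significant pairs, and the reduced network keeps the
edges incident to at least one hub. Counting pairs per gene (after mapping)
rather than per SNP is a documented choice where either reading is
possible.

`intersect_networks()` reports the gene-typed nodes present in both
networks. Because every epistatic-network gene lies near a significant SNP
and is therefore itself a candidate (hence a node of the regulatory
network), a literal node-set intersection would return the whole epistatic
gene set; the meaningful landscape is the genes *connected* in both
networks, so only nodes with degree >= 1 on each side count
(`connected_only = TRUE`, switchable). TF nodes never count. Networks export
as SIF, GraphML and node-attribute TSV, all loadable in Cytoscape and
round-tripping through `read_sif()` / `read_network_graphml()`.

## The synthetic-data generator

`sim_config()` fixes the study conditions every test runs under: 24 cases
with a pool of 199 candidate controls (72 matched), five chromosomes of
100 Mb carrying 2,000 SNPs and 60 genes, the 20-hybridisation loop design,
and planted signals:

* **Relatedness.** Animals belong to `n_families = 12` blocks whose per-SNP
  allele frequencies follow a Balding-Nichols Beta distribution
  (F = 0.05) around a global frequency drawn uniform on (0.1, 0.9). The
  cohort has no published generative model; any exchangeable block structure
  suffices to give the sharing matrix something to match on, and the
  matching stage itself then equalizes family composition between cases and
  controls.
* **Association.** `n_assoc_snps = 20` SNPs are drawn with a case/control
  frequency difference of `assoc_freq_delta = 0.4` (alternating direction),
  each placed inside its own gene. The default of 0.4 gives per-SNP power
  around 95% under the dual rule at 24/72, so planted-signal recovery is
  informative rather than borderline.
* **Epistasis.** Planted pairs share a single hub SNP (star topology), so
  the hub gene accumulates pair counts as the published hubs do. Joint
  genotypes are drawn retrospectively from a saturated 3x3 penetrance table;
  the default table (`epistasis_penetrance()`) is constructed from target
  marginals (case frequency 0.78 vs control 0.28, prevalence 0.25) plus a
  comonotone coupling (rho = 0.4), so the pair carries both strong marginal
  association — the scan only ever sees marginally significant SNPs — and a
  genuine dependence between loci. A saturated table rather than a
  parametric interaction matches the saturated 9-cell test downstream.
* **Expression.** Each log2 foreground value is built exactly from the
  normalization model's components at configurable SDs; planted DE genes
  receive a +/- `de_effect_sd = 2` shift in the piebald varieties (PBW,
  PBB). Backgrounds give each probe a fixed signal-to-noise ratio, below 2
  everywhere for `snr_fail_fraction` of probes (exercising the acquisition
  filter without perturbing the variance structure), and a fraction of genes
  carry a second, weaker probe to exercise the collapse rule.
* **TFBS.** Planted TF memberships get core and matrix similarity exactly
  1.0; decoys are strictly below 1 and vanish at the default confidence
  threshold. Membership targets are the planted intersection genes (the
  epistatic hub plus leaves) and two SNP-free "far" genes, which keeps the
  planted intersecting landscape exactly recoverable and gives the
  intersection test genuine negatives on both sides.

What the generator does **not** emulate: linkage disequilibrium decay and
recombination maps (SNPs are exchangeable within family blocks), sequence
promoters, array spatial artefacts, and intensity-dependent dye bias. A
passing suite therefore demonstrates the statistics and the pipeline
plumbing under the stated model, not robustness to those real-data features.

## Numerical choices and scale

Deterministic behaviour is part of the contract: every generator consumes an
explicit seed (with fixed offsets per generator), greedy matching and
nearest-gene ties have documented tie-breaks, and re-running a pipeline
configuration reproduces byte-identical tables. Problem sizes in the test
suite and acceptance script — 2,000-SNP cohorts, 200-gene arrays, 20
replicate seeds for recovery rates, ten 110-SNP null panels for the
epistasis calibration — were chosen as the smallest scales at which the
asymptotic references and recovery rates are stable.

Known limitations: the EM-REML fit assumes every retained probe is observed
in all hybridisations (the balanced loop); heavily unbalanced data will fall
back to per-gene block patterns and run slower. The published dataset-level
tallies (226 associated SNPs, 645 significant pairs, the 121-node reduced
network, the thirteen intersection genes) depend on the real genotype and
expression data and are not reproduced by simulation; the package instead
verifies the rules that produced them on planted ground truth.

## Running the pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(simulate = sim_config(seed = 11), seed = 11,
                       outdir = "piebald_run")
res <- run_pipeline(cfg)
res$intersection$genes
```

Every stage is also exposed as a plain function (`allele_sharing()`,
`select_controls()`, `snp_association()`, `epistasis_scan()`, `acquire()`,
`fit_normalization_model()`, `compute_contrasts()`, `call_de()`,
`map_snps_to_genes()`, `call_piebald_genes()`, `build_regulatory_network()`,
`build_epistatic_network()`, `intersect_networks()`), and a YAML
configuration plus the thin wrapper in `inst/scripts/run_pipeline.R` provide
a shell entry point.
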