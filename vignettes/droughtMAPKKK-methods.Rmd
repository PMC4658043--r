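---
title: "Methods and design notes for droughtMAPKKK"
author: "droughtMAPKKK authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for droughtMAPKKK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtMAPKKK)
```

This vignette documents the statistical procedures the package implements,
the parameters that matter, the design choices that were genuinely open, and
what the synthetic-data generators do and do not emulate.

# Family identification

## The membership rule

A candidate protein is called a MAPKKK family member when at least
`minHits = 5` distinct query sequences — known MAPKKKs from related grasses
and Arabidopsis — each align to it with pairwise identity strictly above
`identityThreshold = 0.25`. The threshold comparison is strict and the
hit-count comparison inclusive; both are exposed as parameters of
`identifyFamily()`.

## Alignment and the identity denominator

Alignment is local Smith–Waterman with affine gaps (a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$, defaults 11 and 1) under BLOSUM62,
implemented in C++. Because several alignments can share the optimal score,
the aligner optimises lexicographically — score, then identical pairs, then
shorter alignment — so the reported identity is a deterministic function of
its inputs and can be checked against an independent dynamic-programming
oracle, which the test suite does.

Two identity denominators are supported, and the choice matters more than it
may appear:

* **aligned span** (`denominator = "alignment"`, the `pairwiseIdentity()`
  default): identical pairs divided by alignment length, gap columns
  included. This measures similarity *within* the locally aligned segment
  only. For two unrelated full-length proteins the optimal local alignment is
  a short segment whose internal identity is typically 20–40% — far above
  zero — so a 25% threshold on this scale does not separate homologs from
  noise.
* **shortest sequence** (`denominator = "shortest"`): identical pairs divided
  by the length of the shorter sequence, a coverage-aware identity in the
  spirit of whole-query BLAT identity. Unrelated 300-residue proteins score
  ≈ 0.03–0.08 on this scale while genuine family members retain ≈ 0.5, so
  the 25% membership threshold is meaningful. `identifyFamily()` therefore
  uses this denominator by default.

## Subfamily motifs

The three kinase-domain signatures are degenerate patterns over fixed
residues, wildcards and alternative sets:

```{r}
mapkkkMotifs()
```

`scanMotif()` reports all (possibly overlapping) 1-based match start
positions. Classification is a label *set*: the Raf pattern
`GTxx(W/Y)MAPE` genuinely subsumes MEKK instantiations that pick `T` and `W`
(e.g. `GTPAWMAPEV`), so a sequence can legitimately carry more than one
label, and no tie-break priority is imposed.

# Differential expression

Fold change is computed on replicate-mean FPKM with a pseudocount,
$(\bar d + \varepsilon)/(\bar c + \varepsilon)$ with $\varepsilon = 0.1$
FPKM, which bounds behaviour at zero expression and reuses the same floor
that defines "expressed". The replicate test is a two-sided Welch $t$ on
$\log_2(\mathrm{FPKM}+1)$, with each group's variance floored at $10^{-8}$
so that zero-variance replicate sets (common in simulated or deterministic
data) give a defined statistic: equal means then yield $p = 1$. The gene is
called when the fold change is strictly above 2 (or strictly below 1/2) and
$p \le 0.05$ — strict on fold change, inclusive on $p$. Raw p-values are used deliberately: FDR control
enters only at the enrichment stage. A negative-binomial count model
(Cuffdiff-style) is out of scope; the selection rule, not the test, is what
this module fixes.

`overlapPartition()` gives the exact seven-region partition of three
per-tissue DEG sets, and `directionConcordance()` the fraction of
triple-intersection genes whose up/down direction is not unanimous.

# Enrichment

`seaEnrich()` is singular enrichment analysis over flat gene sets: the
hypergeometric upper tail $P[X \ge k]$ for $k$ study hits among $n$ study
genes against a term of size $K$ in a background of $N$, adjusted across
terms by Benjamini–Hochberg (configurable to Benjamini–Yekutieli), flagged
at FDR ≤ 0.05. No GO-DAG propagation is performed; terms are flat sets.

`pagemanZ()` converts a two-sided Wilcoxon rank-sum comparison of a
category's log2 fold changes against the background into a signed z-score,
$z = \mathrm{sign}(\tilde x_{bin} - \tilde x_{bg})\cdot|\Phi^{-1}(p/2)|$,
with two zeroing rules: $p > 0.05 \Rightarrow z = 0$, and bins smaller than
`minSize = 3` report $z = 0$ rather than erroring (tiny bins are
uninformative in PageMan-style displays). The sign follows the *median*
difference — the rank statistic itself is median-like, and PageMan-style
displays colour by direction of the bulk shift. The exact rank-sum
distribution is used whenever both samples have fewer than 50 tie-free
values, otherwise the normal approximation with continuity correction; an
exact-enumeration oracle in the test suite pins the small-sample behaviour.

# Pathway co-expression Z

Transcripts are filtered to FPKM > 0.1 in **all** six tissue×condition cells
(replicates averaged first); "at least one cell" is available via
`scope = "any"` but the all-six reading is the default. The network weight is
the unsigned soft-threshold adjacency $|r|^\beta$ with $\beta = 6$, the
conventional unsigned default; no topological-overlap transform or module
detection is performed.

The pathway statistic is
$$Z = (S_m - \mu)\,\frac{m}{\delta},$$
where the candidate pairs are all (pathway DEG, regulator) pairs, the
selected pairs are those with weight strictly above `cutoff = 0.2`, $S_m$ is
the mean selected weight and $m$ the number of distinct regulators selected.
Two genuinely open choices were fixed as follows:

* **$m$ vs $\sqrt m$**: the conventional standardisation would use
  $\sqrt m$; the statistic is implemented with $m$, as defined. A consequence
  worth knowing: $Z$ is linear in the number of selected regulators, so
  multi-regulator pathways are strongly favoured.
* **the background population ($\mu$, $\delta$)**: computed over all
  regulator × network-gene candidate weights (self-pairs excluded,
  regulator–regulator pairs counted once) — the population the selected
  pairs are drawn from. `background = "all_pairs"` switches to all
  $\binom{n}{2}$ network pairs.

If no pair clears the cutoff, $m = 0$ and $Z = 0$ by convention. A
degenerate background ($\delta = 0$) is an error, not a silent zero. Note
also that the block size of a pathway does not enter $Z$ directly — $m$
counts regulators, not pathway genes — so $Z$ comparisons across pathways of
different sizes are driven by selection counts and mean weights only.

With only six observations per profile, the correlation estimates behind the
weights are intrinsically noisy; the observation count is a property of the
input, not a constant, so richer designs sharpen the network automatically.

# qPCR and phenotype correlation

Relative expression is plain ΔΔCt with amplification efficiency fixed at 2:
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ref}$ per condition,
and the drought/control ratio is $2^{-\Delta\Delta Ct}$. The drought
tolerance index is the drought/control biomass ratio, scale-invariant in the
measurement units. Pearson correlations use the two-sided $t$ transform,
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom; the significance
star is strict ($p < 0.05$). At $n = 8$ lines the implied two-sided 5%
boundary is $|r| \approx 0.7067$.

The packaged eight-line panel reproduces the published dry-biomass
correlation row exactly at two decimals. Three fresh-biomass cells
(MAPKKK19, MAPKKK20, MAPKKK22) recompute from the printed inputs to values
0.01 below the published ones (0.65, 0.70, 0.22 vs 0.66, 0.71, 0.23) —
most plausibly the original analysis used higher-precision biomass values
than the three printed decimals. The package reports the recomputed values;
its tests assert them, not the three divergent printed cells.

# Synthetic data: what is emulated, and what is not

All generators are pure functions of one integer seed plus parameters; the
global RNG state is saved and restored around each call, and every
zero-noise limit reduces to an exactly computable closed form.

**Proteomes** (`genProteins`). Each subfamily gets a random seed protein
with exactly one planted motif instance; members and queries are
substitution-mutated copies (rates 0.25 and 0.2) with the motif region
re-planted, so member–query coverage identity sits near 0.5 and background
near 0.05 — cleanly separated by the 0.25 threshold. Planted instances use
cross-family-safe residue choices (e.g. MEKK plants `GSPAFMAPEV`, not a
`T`/`W` instantiation that the Raf pattern would also match), because the
three signatures genuinely overlap; the generator avoids the ambiguity so
that label round-trips are exact, but real proteomes need not. Six query
variants per subfamily are emitted so the 5-hit rule is satisfiable. No
indels, no compositional bias, no domain architecture — the generator tests
the thresholding rule, not alignment robustness.

**Expression** (`genExpression`). Baseline FPKM is log-normal
($2^{N(3, 2)}$), the heavy-tailed range typical of RNA-seq summaries. DEGs
are planted independently per tissue (10% by default) with
$|\mathrm{lfc}| > 1$ drawn around `lfcMean = 3`, and replicate noise is
multiplicative log-normal (`noiseSd = 0.1` log2 units) — chosen as the
technical-replicate scale at which the default thresholds recover ≥ 95% of
planted effects with essentially no false calls. Real data have correlated
genes, dispersion–mean trends and library-size effects, none of which are
modelled, so passing recovery tests demonstrates the selection rule's
correctness, not robustness to real-world artefacts.

**Gene sets** (`genGenesets`). One designated term is packed with study ids;
the rest are uniform draws. This plants a single unambiguous enrichment
signal and makes "exactly the packed term at FDR ≤ 0.05" a fair expectation.

**qPCR/biomass** (`genQpcrBiomass`). Per-line relative expression and DTI
come from a bivariate normal with the requested correlation, on the raw
scales where Pearson r is computed, so the planted `trueRho` is the
population value of the measured statistic. Ct values are back-computed so
ΔΔCt inverts exactly at zero noise; noise is additive on the Ct scale
(default sd 0.05 cycles), where the method is linear. With $n = 8$ lines the
sample correlation is biased slightly low ($\approx \rho(1-\rho^2)/2n$), so
the Monte-Carlo mean over seeds lands near 0.78 for a planted 0.8 — within
the tolerance a parameter-recovery check should allow.

**Co-expression** (`genCoexpression`). Block genes are exact affine copies
of a latent six-point profile; regulators are Gram–Schmidt constructions
whose *sample* correlation with the block is exactly `rho = 0.95`. All
regulators (default 3) are planted as co-expressed with the block: because
$Z$ is linear in $m$, a single-regulator signal can be out-scored by chance
multi-regulator selections, whereas the multi-regulator planting mirrors the
biology (many family kinases co-expressed with a responsive pathway) and
makes the ranking test meaningful. Background genes default to profiles
orthogonalised against the latent profile — the zero-noise idealisation of
independence, since an independent profile has population correlation zero
and orthogonality places the six-point sample correlation at that value;
this bounds any background gene's regulator weight by
$(1-\rho^2)^{\beta/2} \approx 0.001$, so no spurious selection can occur.
`orthogonalBackground = FALSE` restores plain independent draws, whose
six-point chance correlations are occasionally as large as the planted one —
instructive for seeing why small designs make co-expression networks noisy.

# Numerical and interface conventions

* Motif positions are 1-based, following R and Bioconductor convention.
* An empty optimal local alignment (no positive-scoring residue pair)
  reports identity 0.
* FPKM containers are `FpkmExperiment` objects (a `SummarizedExperiment`
  subclass) with validity checks: non-negative finite FPKM, drought/control
  conditions, ≥ 2 replicates per tissue×condition cell.
* Generators' tables round-trip bytewise through the TSV writers, so fixture
  files regenerate identically from a seed.
* Test problem sizes (2000-gene matrices, 10 seeds; five 35-protein
  proteomes; 500 qPCR seeds) keep the full suite near a minute while leaving
  the recovery margins wide.

# Known limitations

* No read-level simulation or FPKM estimation; analyses start from FPKM
  summaries, so no particular experiment's DEG counts can be reproduced
  without its raw data.
* No phylogenetic tree construction, subcellular-localisation prediction,
  GO-DAG handling or pathway-diagram rendering.
* The co-expression module computes no topological overlap or modules, and
  with six observations its weights should be read as coarse screening
  scores, not estimates of network topology.
* The Welch-on-log2 replicate test is a pragmatic stand-in for count-model
  inference and will be anti-conservative for low counts with few
  replicates.
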