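---
title: "mitocub: models, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitocub: models, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

This vignette is the package's own account of its science: the
statistics it computes, the conventions it pins down where the field is
ambiguous, what the synthetic-data generator does and does not emulate,
and the numerical choices at the edges. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## Genetic codes and synonymous families

All internal codon keys are uppercase RNA. Two code tables are
registered: the standard code (NCBI table 1) and the mold mitochondrial
code (table 4), in which UGA encodes tryptophan and AUA remains
isoleucine; fungal mitochondria use the latter. Custom tables load from
plain text. The choice is configuration, not inference: published
discussions of fungal mitochondrial codon families occasionally group
AUR as methionine, which is inconsistent with table 4 — rather than
guess which table an upstream tool applied, every result records its
`code_id`.

Synonymous families come in two flavours:

* **RSCU families** follow a `family_policy()`. By default sixfold
  families (Leu, Ser, Arg) are split into their fourfold + twofold
  sub-families and single-codon families are excluded. The split
  matters: a gene using serine twice, both UCC, scores RSCU(UCC) = 4
  under the split policy (UCC is the sole used codon of the UCN
  sub-family) and 6 unsplit. The split default reproduces the behaviour
  of the common RSCU tooling in this field.
* **ENc classes** always use Wright's unsplit partition, regardless of
  the RSCU policy: for the standard code 2 singletons, 9 twofold, 1
  threefold (Ile), 5 fourfold, 3 sixfold; table 4 moves Trp into the
  twofold class, leaving Met as the only singleton.

Codon counting trims one trailing stop codon silently (annotated CDS
conventionally include it), treats an internal stop as a fatal error
naming the gene (it signals a frame problem), and skips codons with
ambiguity characters, tallying them in `n_skipped`.

## RSCU

For codon $j$ in a family of size $k$ with family total $N$,
$\mathrm{RSCU}_j = X_j / (N/k)$. Families with $N = 0$ are `NA` in the
vector and become 0 under the multivariate fill policy (recorded as an
attribute of the matrix). Within any observed family the values sum to
$k$ exactly; RSCU is invariant to scaling all counts.

## ENc and the neutrality plot

Per unsplit family with $n \ge 2$ observations and within-family
proportions $\hat p$, the homozygosity estimate is
$\hat F = (n \sum \hat p^2 - 1)/(n - 1)$. Per degeneracy class $k$ the
package averages the valid $\hat F$; Wright's gene-level summary is

$$\mathrm{ENc} = m_1 + \sum_k m_k / \bar F_k,$$

with $m_k$ the number of families in class $k$ (of the code, so the
singleton term is constant). The theoretical range is 20 (one codon per
amino acid, standard code) to the code maximum (61 standard, 62 for
table 4) reached when every $\bar F_k = 1/k$.

Edge handling is explicit because mitochondrial genes can be very short
(tens of codons): families with $n < 2$ or $\hat F \le 0$ are dropped
from their class mean; a class with no valid family borrows the mean of
its nearest available neighbour classes (the threefold class borrows the
average of the two- and fourfold means), falling back to the uniform
$1/k$ only when no class has data; imputed classes are reported and a
gene with more than two imputed classes is flagged `low_confidence`.
Finite-sample noise can push the raw sum above the code maximum, so
`enc` is capped to $[1, \mathrm{enc\_max}]$ with the uncapped value kept
in `enc_raw`.

The neutral expectation is $\hat g(s) = 2 + s + 29/(s^2 + (1-s)^2)$,
evaluated at **GC3s** — third-position GC over codons of degenerate
families only (Met, Trp and stops excluded), the synonymous-sites
convention of the neutral model; plain GC3 is also reported. The fit
statistic is computed against the curve itself, not a refitted
regression: $R^2 = 1 - \sum(\mathrm{ENc} - \hat g)^2 /
\sum(\mathrm{ENc} - \overline{\mathrm{ENc}})^2$, and can be negative
when the cloud sits far from the curve (strongly selected gene sets do
exactly this). The per-gene selection proxy is the relative deviation
$(\hat g - \mathrm{ENc})/\hat g$.

## Correspondence analysis and clustering

RSCU values within a family are linearly dependent, which is why the
multivariate stage uses correspondence analysis rather than PCA.
The implementation is the standard one: correspondence matrix
$P = X/n$, standardised residuals
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, SVD, principal coordinates
scaled by singular values; eigenvalues are squared singular values and
sum to the table's $\chi^2/n$. All-zero columns are dropped and
reported; axis signs are fixed by forcing the largest-magnitude column
coordinate positive per dimension, so results are reproducible to the
sign. Contributions are $\text{mass} \times \text{coord}^2 /
\lambda_d$ and sum to 1 per dimension.

Genome-profile clustering defaults to Euclidean distance with average
linkage (UPGMA) — the field's common default for RSCU dendrograms; the
method names are recorded in the result and Newick output carries the
merge heights. Rows are sorted by id before clustering so the tree is
invariant to input order. Published inertia percentages and tree shapes
for real datasets depend on the exact gene sets fed in (accessory gene
inclusion, NA handling), so they are validation-level quantities here,
not unit-test targets.

## tRNA adaptation and the S-test

Anticodons are written 5'→3'; position 34 is the first character and
pairs the codon's third base (the antiparallel reverse-complement
convention — pinned explicitly because it is the most common silent bug
in this domain). The absolute adaptiveness of codon $c$ is

$$W_c = \sum_{\text{pairing tRNAs}} (1 - s_{\text{pairing}}) \cdot
\mathrm{tGCN},$$

over Watson–Crick pairs plus the recognised wobble classes G34:U3,
U34:G3 and, treating A34 as inosine, I:C and I:A. The constraint vector
$s$ ships as editable configuration
(`inst/extdata/s_vector_default.tsv`) with the widely used defaults of
the reference tAI implementation (G:U 0.41, I:C 0.28, I:A 0.9999, U:G
0.68); the paper trail for these numbers belongs to that tool, not to
this package, hence config rather than hard-coding. $w_i = W/\max W$;
codons with $W = 0$ (undecodable under these classes) are replaced by
the geometric mean of the nonzero $w_i$ and flagged — a conventional
regularisation that keeps the geometric mean defined without letting
undecodable codons dominate. Gene-level tAI is the count-weighted
geometric mean of $w_i$, stops excluded.

The S statistic is the correlation (Pearson by default, Spearman by
flag) between per-gene tAI and per-gene ENc deviation. Its null
distribution comes from permutations that reassign the *multiset* of
$w_i$ values across sense codons uniformly at random, recomputing every
tAI and the correlation each time; `n_perm` defaults to 100. The
empirical p-value uses the add-one correction
$p = (1 + \#\{S_{\pi} \ge S\})/(n_{\text{perm}} + 1)$ and significance
is declared at $p \le 0.05$ — the "top 5 % of the permutation
distribution" rule stated coherently in terms of the reported p. Under
exchangeability the exact type-I rate of this rule is
$5/101 \approx 4.95\%$ at $n_{\text{perm}} = 100$. Mitochondrial tests
must use exclusively mitochondrial tRNA counts and nuclear tests nuclear
counts; the pipeline enforces the separation through per-genome tRNA
sources.

### Optimising the constraint vector

`optimize_s_vector()` hill-climbs the non-Watson–Crick constraints with
coordinate steps of shrinking size; accepted steps never decrease the
objective and the trace is seed-reproducible. The objective is
pluggable, with two built-ins, and the choice matters more than one
might expect:

* `"s_correlation"` (default, the documented behaviour of the upstream
  species-specific tAI tools): maximise S itself. Measured on synthetic
  data this objective is **not** a consistent estimator of the
  generating constraints — pushing a wobble constraint towards 1
  stretches the within-family $w_i$ contrast, which stretches the tAI
  spread and inflates the tAI–deviation correlation, so the optimum
  lands near strong constraints regardless of the truth.
* `"usage_contrast"`: split genes at the median deviation, take the
  family-centred log-usage contrast of the high versus low group, and
  correlate it with the family-centred $w_i$. Mutational bias is an
  additive per-codon term in log usage identical in both groups, so
  centring cancels it; this objective recovers a perturbed U:G
  constraint to within 0.15 in the test suite.

## Wobble decodability and versatility

Three rule modes: `strict` (Watson–Crick only), `crick` (G34 reads C/U,
U34 reads A/G, C34 reads G, A34 reads U) and `extended` (crick plus
inosine A34 reading U/C/A). They are nested by construction, and the
decodability report records the mode used rather than asserting any
particular published undecodable-codon list — no single mode reproduces
every such list exactly (published lists sometimes include codons like
UGG whose status depends on unstated assumptions about U34 reading), so
the mode is a reported parameter, not a hidden constant. The
versatility check asks, per family, whether the observed wobble base
maximises the number of family codons readable under crick rules (G34
for NNY families, U34 for NNR and fourfold families), flagging
exceptions with an explanatory note.

## The synthetic world

The generator exists so that every stage — including the permutation
test's calibration — is testable without downloads. Per gene,
`gene_length` amino acids are drawn uniformly over the degenerate
families; the codon within a family is drawn with probability

$$p(c) \propto m(c) \cdot e^{\beta g \, w_c},$$

where the mutational weight $m(c)$ puts $\pi/2$ on G and C and
$(1-\pi)/2$ on A and U at the third position ($\pi$ = `gc3_target`;
positions 1–2 uniform across a family's stems), $g$ is the gene's
expression weight and $\beta$ the selection strength. $\beta = 0$ is
exactly the mutational null; large $\beta$ concentrates on the optimal
codon. This is the simplest generative model with both limits correct.

Defaults and why:

* **Gene length 300 codons** — the scale of mitochondrial core genes
  (a few hundred codons; the shortest, *atp8*-like, are far shorter and
  are exercised separately in edge-case tests).
* **`gc3_target = 0.35`** in the packaged scenarios — mitochondrial-like
  AT bias.
* **Expression weights log-normal(0, 1)** in the selected scenario — the
  S statistic detects selection through *between-gene variation* in
  selection intensity; with identical weights every gene is tilted
  equally and the correlation has nothing to grip. A right-skewed
  positive distribution is the conventional stand-in for expression.
* **Mutational bias is genome-level.** The neutral calibration scenario
  gives all genes one `gc3_target`. An earlier draft spread GC3 across
  genes within the "genome", and the calibration failed in an
  instructive way: with a sparse tRNAome, tAI is mechanically a function
  of GC3 (A-ending codons decode best), the ENc deviation also varies
  with GC3, and the observed S becomes systematically negative while the
  permutation null stays centred — the top-5 % rule then fired in ~0 %
  of null genomes instead of ~5 %. That is a real confounding, not a
  bug, and mirrors a caveat for real AT-rich mitogenomes: S compares an
  observed wi-to-codon assignment against random ones, and any shared
  GC3 dependence of tAI and deviation shifts the observed value without
  shifting the null. Per-gene GC3 spreads remain available through
  `synthetic_spec()` and are used for the ENc–GC3 neutrality-cloud
  checks, where they are the point.
* **Sparse tRNAomes** pick one anticodon per amino acid, the
  versatility-maximising one for the largest sub-family — emulating the
  minimal mitochondrial tRNAome and leaving pyrimidine-ending codons
  undecodable, as observed in real fungal mitogenomes.

What a green test establishes, and what it does not: the generator has
uniform amino-acid composition over degenerate families, no sequence
autocorrelation, no introns, no phylogenetic correlation between
genomes, and selection that acts only through the synonymous tilt.
Calibration results (type-I ≈ 5 %, power > 95 % at $\beta = 2$,
monotone median S over the $\beta$ grid, neutral clouds tracking
$\hat g$ with $R^2 \ge 0.8$ at 1000-codon genes) are statements about
this stated world, not about any real genome.

## Numerical and format conventions

* GenBank coordinates are 1-based inclusive; exons of a `join()` are
  concatenated in annotation order and `complement()` applies to the
  assembled sequence. tRNA anticodons come from `/anticodon` or a 3-mer
  in `/note`; a tRNA with neither is counted but flagged rather than
  guessed from the product name. GenBank parsing is implemented
  in-package (no maintained R parser for the flat format was available)
  and verified against hand-spliced fixtures.
* Organelle labels come from run configuration, never from header
  heuristics.
* Tables are written with 6-significant-digit floats, UTF-8, fixed
  column order; every pipeline output embeds the run seed and a config
  hash, so identical configuration and inputs give identical bundles.
* All randomness (simulation, permutation, optimisation) flows through
  explicit integer seeds; RNG state is restored after each seeded
  computation, so library calls never perturb a caller's stream.

## Known limitations

* The S-test conditions on the tRNAome; it cannot distinguish
  translational selection from any other force that couples codon usage
  to the same wi ordering (the GC3 confounding above is the concrete
  example).
* tGCN is a gene-copy proxy for tRNA abundance; modified or imported
  tRNAs are invisible to it, which is precisely the gap the
  decodability report is meant to surface.
* `"s_correlation"` optimisation should be read as "the constraint
  vector that maximises the selection signal", not as an estimate of
  physical wobble efficiencies; use `"usage_contrast"` for recovery.
* CA on RSCU inherits RSCU's insensitivity to amino-acid composition but
  not to gene length: very short genes produce extreme RSCU vectors
  (the 4/4/1.33 pattern) and appear as outliers, which is faithful to
  how such genes behave in published analyses.
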