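---
title: "Methods: differential expression and ceRNA inference for two-region RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and ceRNA inference for two-region RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaflow)
```

## The problem

Chronic constriction injury of the infraorbital nerve (IoN-CCI) is a mouse
model of trigeminal neuropathic pain. Transcriptome studies of this model
profile two tissues along the pain pathway — the trigeminal ganglion (TG)
and the spinal trigeminal subnucleus caudalis (Sp5C) — in injured versus
sham-operated animals, and ask three questions: which mRNAs, lncRNAs and
circRNAs respond to the injury in each region; how those responses relate to
curated disease gene lists (pain, anxiety, depression, inflammation,
apoptosis, immunity) and to annotation terms; and which lncRNA/circRNA
transcripts plausibly act as competing endogenous RNAs (ceRNAs) — molecular
sponges that sequester shared miRNAs and thereby de-repress specific mRNAs.

`cernaflow` implements that analysis sequence as a tested, seeded workflow.
Because the original sequencing data are not redistributable at desk scale,
the package ships a synthetic-data module that generates the full input
bundle with known ground truth, so every stage can be validated by planted-
truth recovery rather than by eyeballing.

## Normalisation and differential expression

Counts are normalised to RPKM,
$\mathrm{RPKM}(g,s) = 10^9\, C(g,s) / (N_s L_g)$, with the per-sample total
$N_s$ taken as the column sum of the supplied matrix. The aligner's "total
mapped reads" is unavailable after the fact, and the column sum makes the
transform self-contained and order-independent. A `by_biotype` switch
computes $N_s$ within biotype panels instead; the default is global.
miRNA rows are length-normalised like everything else — biologically
meaningless for 22-nt species, but uniform and explicitly documented.

Differential expression uses the joint threshold filter that defines DE
genes in this literature: raw $p \le \alpha$ (default 0.05) **and** fold
change $\ge$ 2 in either direction, i.e. $|\log_2 FC| \ge 1$. The fold
change is computed on pseudocounted group means of RPKM. The underlying
test is not specified by the upstream tooling this emulates (a commercial
workbench); we chose Welch's unequal-variance $t$ on
$\log_2(\mathrm{RPKM} + c)$ with pseudocount $c = 1$ because it is standard,
closed-form, and independently checkable against `stats::t.test`. No
multiple-testing correction enters the filter (mirroring the raw-$p$
convention); BH q-values are reported as an extra column. Conventions for
degenerate genes: single-replicate groups get `NA` p-values and can never be
significant; two constant equal groups give $p = 1$; constant unequal
groups give $p = 0$.

Two small source inconsistencies are worth recording: the study text reports
both 5,202/3,933 and 5,205/3,934 DE mRNAs for TG/Sp5C in different places,
and its category-proportion section swaps the two regions' DEG totals. These
counts are data-dependent and not reproducible here; nothing in the package
asserts them. Percentage denominators for the category mapping are defined
explicitly as the table's significant DEGs (optionally restricted to one
biotype).

## Overlap accounting, enrichment, hubs

Cross-region Venn accounting intersects the up- and down-regulated
significant sets per biotype. Category mapping takes curated lists as given
files (GMT); any proprietary relevance-score curation is upstream of this
package. Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for an overlap of $k$ query genes with a $K$-member set among
$n$ query genes drawn from an $M$-gene background, computed with
`stats::phyper` and cross-checked in the tests against exhaustive
enumeration of all $\binom{M}{n}$ draws. The default background is the
expression matrix intersected with the union of the annotation sets —
self-contained, standard ORA practice — and is overridable.

The PPI stage induces the subgraph of a supplied edge list on the
significant genes, then ranks nodes by plain (unweighted) degree — the
"connection degree" of network-viewer pipelines — taking the top 50 per
region with ties broken by $|\log_2 FC|$ then gene id, coloured red/blue
for up/down. Hub selection happens per region after induction.

## ceRNA inference

For each pair of a significant ceRNA (lncRNA or circRNA) and a significant
mRNA sharing at least one miRNA in the target map, four pieces of evidence
are combined:

1. **Shared-miRNA surprise.** With $K$ miRNAs targeting the ceRNA, $n$
   targeting the mRNA, and $M$ distinct miRNAs in the map, the probability
   of sharing $\ge k$ by chance is the same hypergeometric upper tail as in
   the enrichment module (the two code paths are cross-checked to 1e-15 in
   the tests). $M$ defaults to the distinct miRNAs of the supplied map —
   the smallest self-contained universe — and can be overridden.
2. **Expression correlation.** Pearson correlation of
   $\log_2(\mathrm{RPKM}+1)$ across all samples of the region, conditions
   pooled, with the $t$-based p-value
   $t = r\sqrt{(n-2)/(1-r^2)}$.
3. **Direction concordance.** Sponge and target must be regulated the same
   way.
4. **Thresholds.** A pair passes when hypergeometric $p \le 0.05$,
   $\mathrm{PPC} \ge 0.5$, correlation $p \le 0.05$ and the directions are
   concordant. Strict $\mathrm{PPC} \ge 0.5$ is enforced; no
   negative-correlation exceptions.

When a region pools fewer than three samples, no correlation can be
estimated and the workflow degrades to the hypergeometric-plus-concordance
rule (the "two groups without replication" branch); the output flags this
mode. Candidate genes with zero expression variance are skipped with a
message. Whether miRNAs should additionally be required to be DE themselves
is left as an opt-in filter (`de_mirnas`), since the workflow does not model
a small-RNA quantification protocol.

Network degrees count distinct passing partners (for ceRNAs and mRNAs) or
mediated passing pairs (for miRNAs); top-10 ceRNA and top-2 miRNA lists are
ranked by degree with ties broken by the node's best hypergeometric p, then
id. lncRNA- and circRNA-axes can be reported separately by filtering the
pair table on `cerna_biotype`.

## What the generator emulates — and what it does not

`generate_counts()` draws negative-binomial counts (`size = 1/dispersion`,
default dispersion 0.1) around log-normal baseline means (median 200
counts, log-sd 1) for a 2 region × 2 condition design. The defaults mirror
the emulated study where it states them: two regions, CCI vs sham, and
three libraries per cell (nine animals pooled three-to-one). Planted DE
genes split their condition means symmetrically, so the expected CCI/sham
ratio is exactly $2^{\Delta}$ for planted $\log_2 FC = \Delta$; planted
effects must satisfy $|\Delta| \ge 1$ so that truth and filter agree on
what "DE" means. Gene lengths are uniform on 200–10,000 bases and recorded.

Planted ceRNA triplets add a shared latent log-scale factor (default sd 1.2
log2 units) to the ceRNA and mRNA of each triplet, with loadings
$\sqrt{|r|}$ chosen so the latent correlation equals the target $r$
(default 0.8, sign respected); the realised sample correlation varies
around it. Triplet genes are planted concordantly DE (default
$|\log_2 FC| = 3$) on a solid baseline, because a sponge axis that cannot
be detected as DE can never be recovered and would make "recall" measure
the DE filter twice.

Two identifiability choices are deliberate and worth knowing:

* **Planted miRNAs are exclusive.** A planted miRNA targets only its own
  (ceRNA, mRNA) pair, and triplet genes are excluded from background target
  sampling. Ground truth is therefore unambiguous: a planted pair shares
  its miRNA only because of the plant. Without this, "planted" and
  "coincidental" pairs blur and recall is ill-defined.
* **Stage-level false-positive fixtures.** In a full count simulation, two
  genes that are both (truly) upregulated are positively correlated across
  pooled conditions through the condition term itself — a real property of
  the published method, not a bug, and `recover_truth()` reports it
  honestly (pipeline-level precision is visibly below 1 for this reason).
  A meaningful false-positive-rate check therefore needs null pairs with
  *independent* expression, which `generate_cerna_fixture()` provides by
  assigning DE status directly and drawing null expression as independent
  log-normal noise. That fixture — 20 planted axes among several hundred
  null candidate pairs at 9 replicates per cell — is what the acceptance
  checks use.

The generator does not model read-level artefacts (no FASTQ, no mapping
bias), splice structure, strand, genomic coordinates, batch effects, or a
real miRNA quantification protocol; miRNA counts simply live in the same
matrix, flagged as a provenance gap. Passing tests therefore demonstrate
the *logic* of every stage under a faithful overdispersed count model, not
robustness to alignment artefacts or annotation error in real data.

## Numerical and reproducibility choices

* One global integer seed fans out to fixed per-stage substreams, and the
  RNG kind is pinned (Mersenne-Twister / Inversion / Rejection), so a seed
  determines every output byte across platforms. Output files carry the
  seed in `# key=value` headers; timestamps are confined to the run log.
* Ties are broken deterministically everywhere (documented per function),
  so rankings are permutation-invariant.
* `hypergeom_tail(0, ...)` is 1 by total probability; BH is delegated to
  `stats::p.adjust` behind a validating wrapper.
* Correlations are clamped to $[-1, 1]$ before the $t$ transform;
  $|r| = 1$ maps to $p = 0$.

## Problem sizes

The validation suite runs at the scales its checks are defined for: DE
recovery and null calibration on 2,000-gene matrices with 100 planted
effects at 9 replicates per cell, medians over 5 seeds; ceRNA recovery on
fixtures of 20 planted axes among ~1,300 candidate pairs, medians over
5 seeds; hypergeometric enumeration over every configuration with
$M \le 12$. The demonstration workflow in `analysis/` uses the
study-like default of 3 libraries per cell, where the correlation filter
pools only 6 samples — the smallest correlation significant at
$p \le 0.05$ is then $r = 0.81$, so sponge recall is power-limited at that
depth. This is a property of the design being emulated, reported rather
than hidden.

## A worked miniature

```{r mini}
study <- simulate_study(seed = 1, replicates_per_cell = 9,
                        n_per_biotype = c(mRNA = 200, lncRNA = 60,
                                          circRNA = 60, miRNA = 60),
                        n_de = 60, n_triplets = 6,
                        n_mirna_background = 40, targets_per_mirna = 3)
expr <- compute_rpkm(study$counts)
de <- list(TG = call_de(expr, study$design, "TG"),
           Sp5C = call_de(expr, study$design, "Sp5C"))
de_counts(de$TG)

pairs <- call_pairs(de$TG, expr, study$design, "TG", study$targets)
recover_truth(de, list(TG = pairs), study$truth)
```

## Known limitations

* The threshold filter with raw p-values is reproduced faithfully; it is
  not an error-rate-controlling procedure, and the reported q-values are
  the honest alternative.
* Pooling conditions for the correlation filter confounds co-regulation
  with co-response to injury (see above); partial correlation given
  condition would be a methodological change beyond this package's scope.
* The hypergeometric miRNA universe $M$ is the supplied map's miRNA count;
  with very sparse maps any sharing is "surprising", so the correlation
  and concordance filters carry the specificity burden there.
* Gene-set construction realises prescribed pairwise overlaps exactly but
  leaves unspecified pairs disjoint; it does not target higher-order
  overlap structure.
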