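---
title: "Methods: staged lncRNA analysis and ceRNA network inference"
author: "ceRNAforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged lncRNA analysis and ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAforge)
```

# The analysis

Bulk RNA-seq studies of developing tissue frequently profile three RNA
layers — long noncoding RNAs (lncRNAs), miRNAs and mRNAs — across several
developmental stages and then ask which lncRNAs shape a phenotype
(here: intramuscular fat and fatty-acid composition of skeletal muscle
across four ages, with 4 replicates per stage). ceRNAforge implements the
full desk side of such a study as composable, tested steps:

1. **Novel lncRNA identification.** Assembled transcripts (StringTie-style
   GTF) are screened by assembler class code (the seven novel codes
   `i, j, x, u, c, e, o`), transcript length (> 200 bp), exon count
   (>= 2), same-strand exonic overlap with protein-coding mRNAs,
   database-annotation status, and the *intersection* of two
   coding-potential predictors (both must call the transcript noncoding).
   Surviving lncRNAs get one of five positional classes: sense
   overlapping, antisense, intronic, bidirectional, intergenic.
2. **Staged differential expression.** FPKM
   ($\mathrm{FPKM} = c \cdot 10^9 / (L \cdot N)$ for count $c$, length $L$,
   library size $N$), Welch's t on $\log_2(\mathrm{FPKM}+1)$ per
   contiguous-stage comparison plus first-vs-last, Benjamini–Hochberg FDR;
   a feature is differential iff FDR < 0.05 and $|\log_2 FC| > 1$.
3. **Target prediction.** *Cis*: genes whose span lies within 100 kb of a
   lncRNA span (gap measured between whole spans, boundary inclusive).
   *Trans*: genes with $|r| > 0.999$ across all samples (Pearson on
   $\log_2(\mathrm{FPKM}+1)$; Spearman available).
4. **ceRNA network.** (a) Spearman screen: lncRNA–miRNA and mRNA–miRNA
   pairs with SCC < −0.7; (b) Pearson screen: lncRNA–mRNA pairs with
   PCC > 0.9; (c) for each co-expressed pair, an exact upper-tail
   hypergeometric test on the overlap of the two sponge-miRNA sets; pairs
   with P < 0.05 and at least one shared miRNA become triads, and the
   union of their lncRNA–miRNA and miRNA–mRNA edges is the network,
   exported as SIF + attribute TSV.
5. **Enrichment.** Generic over-representation of a gene set against a
   term-to-gene table, sharing the identical hypergeometric machinery
   (a single internal function serves both; the test suite asserts the
   equality).
6. **Validation statistics.** 2^−ΔΔCt qPCR quantification against a
   constant reference gene, two-tailed Pearson correlations between
   lncRNA expression and traits, Duncan's multiple range test with letter
   groupings, and fatty-acid class sums/ratios (PUFA/SFA, n-6/n-3).

# The sponge test

For a candidate (lncRNA, mRNA) pair, let $N$ be the size of the miRNA
universe, $K$ and $M$ the sizes of the two genes' sponge-miRNA sets and
$x$ their overlap. Under the null that the two sets are independent
draws, $X \sim \mathrm{Hypergeometric}(N, K, M)$ and the reported
p-value is the exact upper tail

$$P(X \ge x) \;=\; \sum_{i = x}^{\min(K, M)}
  \frac{\binom{K}{i}\binom{N-K}{M-i}}{\binom{N}{M}},$$

computed through `stats::phyper` (exact and numerically stable; no
normal approximation). The test suite checks it against brute-force
enumeration of all $\binom{N}{M}$ draws for every configuration with
$N \le 12$, to within $10^{-12}$.

**Sponge-set membership** requires both lines of evidence: a miRNA
belongs to a gene's sponge set iff it targets the gene *and* forms a
retained negative-correlation pair with it. This is the stricter of the
two possible readings of the sequential screen, and the default;
requiring only target-set co-occurrence would admit miRNAs whose
expression contradicts the sponge model. **The universe $N$** defaults
to the miRNAs expressed in at least one sample — the self-contained,
conservative choice — and can be set to the full annotated set. The
sponge test is applied at raw P < 0.05 (the conventional choice for this
screen); a BH-adjusted mode exists and is off by default.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `minLength` | 200 | bp | keep transcripts strictly longer |
| `minExons` | 2 | exons | keep transcripts with at least this many |
| `alphaFdr` | 0.05 | — | DE FDR threshold |
| `minAbsLog2fc` | 1 | log2 units | DE fold-change threshold |
| `cisWindow` | 100000 | bp | cis span-gap window, inclusive |
| `transR` | 0.999 | — | trans absolute-correlation cutoff, strict |
| `sccCut` | −0.7 | — | Spearman cutoff, strict (`<`) |
| `pccCut` | 0.9 | — | Pearson cutoff, strict (`>`) |
| `alpha` | 0.05 | — | sponge-test significance, strict |
| `bidiWindow` | 1000 | bp | divergent-promoter window |
| `pseudocount` | 1 | FPKM | added before log2 for testing/fold change |

Two open conventions were fixed as follows. The exon rule is
"at least 2" by default because two-exon spliced transcripts are the
canonical reliable novel isoforms; a strict mode (`strictExons = TRUE`,
more than 2) is available. Coding overlap is tested on exons, same
strand, at >= 1 bp; `ignoreStrand = TRUE` switches to any-strand.
Database-annotation exclusion is a per-transcript boolean input, not a
live lookup, so the cascade is testable offline.

# Numerical choices

* **Coordinates.** All intervals are `GRanges` (1-based, closed), the
  Bioconductor convention; GTF I/O converts at the boundary via
  rtracklayer, and all window arithmetic goes through IRanges. The
  semantics match half-open gap definitions exactly: exons `[101,200]`
  and `[201,300]` do not overlap, and a span gap of exactly 100000 bp is
  a cis pair while 100001 is not (both asserted by tests).
* **Strict inequalities.** The screening rules quote strict cutoffs
  (SCC < −0.7, PCC > 0.9, |r| > 0.999). A statistic that equals a cutoff
  up to floating-point error must not squeak through, so comparisons use
  a 1e-9 guard band: `statistic < cut - 1e-9` (resp. `>`). A Spearman
  coefficient of exactly −0.7 (a rank permutation with
  $\sum d_i^2 = 34$, $n = 5$) is excluded, as is a constructed Pearson
  coefficient of exactly 0.9.
* **Degenerate inputs.** Zero-variance features are skipped with a
  warning in every correlation screen (their correlation is undefined);
  features with all-zero abundance in both groups are excluded before DE
  testing (their fold change is undefined and they would dilute the
  FDR); sponge candidates with zero shared miRNAs are discarded before
  testing (their p-value is 1 by construction); terms annotating no
  universe gene are untestable and skipped.
* **Pseudocount.** Testing and fold changes operate on
  $\log_2(\mathrm{FPKM}+1)$, matching the field's display convention.
  The +1 compresses fold changes of low-abundance features, so a planted
  4-fold change on a feature with baseline FPKM below about 1.4 falls
  under the $|\log_2 FC| > 1$ threshold — visible in the synthetic
  study, where planted-DE recall reflects exactly this attenuation. This
  is a property of the convention, not a defect of the test.
* **Duncan's test.** One-way ANOVA MSE with residual df; harmonic-mean
  group size for unbalanced layouts; least significant range for a
  stretch of $p$ ordered means uses the studentized range quantile at
  Duncan's protected level $1-(1-\alpha)^{p-1}$ (`stats::qtukey`). The
  step-down recursion marks a stretch homogeneous and stops; letters are
  read off the maximal homogeneous stretches, so letter sharing is
  exactly the non-separation relation (asserted against a brute-force
  enumeration over all covering stretches). With zero residual variance
  the ranges are degenerate and groups separate iff their means differ.
* **ΔΔCt calibrator.** Defaults to the earliest stage; by construction
  the calibrator group's geometric-mean fold change is exactly 1, and
  results are invariant to global Ct shifts.
* **Determinism.** A single integer seed drives the generator; each
  operation derives a fixed sub-seed, so outputs are bit-identical for
  identical configs regardless of call order, and pipeline reruns
  produce byte-identical files (writers sort rows in C-locale order and
  emit no timestamps).

# The synthetic study

`simulateCeRNAStudy()` emulates the study design the package targets:
4 stages × 4 replicates, 200 mRNAs, 20 known + 20 novel lncRNAs,
50 miRNAs. What it plants, and why:

* **Annotation geometry.** Genes are spaced 2 Mb apart on one
  chromosome; mRNAs are 2–10 kb with 4–20 exons and ORFs of roughly a
  third of their length; lncRNAs are 0.3–3 kb with 2–4 exons and ORFs
  under 300 nt, so the structural contrasts the filter relies on are
  present by construction. Cis pairs are planted at gaps drawn within
  the 100-kb window and decoy loci beyond it; intronic, antisense and
  divergent-promoter placements exercise the positional classifier; one
  decoy per filter rule violates exactly that rule, with the label
  recorded in the truth ledger.
* **Expression.** Log-normal baselines with lncRNA means below mRNA
  means (and novel lncRNAs slightly above known ones). Each planted
  triad shares a latent factor $f \sim N(0,1)$ per sample: its lncRNA
  and mRNA load $+e$, its sponge miRNAs $-e$, plus $N(0, \sigma^2)$
  noise on the log2 scale, giving a population lncRNA–mRNA correlation
  of $e^2/(e^2+\sigma^2)$ (about 0.989 at the defaults $e = 0.95$,
  $\sigma = 0.1$) and equally strong negative miRNA correlations. In the
  limit $e \to 1$, $\sigma \to 0$ the correlations are exactly ±1. The
  latent-factor construction is deliberate: the pipeline only ever sees
  correlations, so this is the minimal structure that makes its
  thresholds meaningful; no kinetic model is implied.
* **Planted DE** features (2 per comparison by default, disjoint from
  triad members so a stage shift cannot corrupt planted correlation
  structure) are shifted by ±2 log2 units in one stage.
* **Targets, traits, qPCR.** Each triad's miRNAs target both its
  partners; background targets are sprinkled at density 0.02. Planted
  lncRNA–trait pairs are generated with population correlation ±0.65
  (magnitudes typical of reported expression–fatty-acid panels); traits
  carry SFA/MUFA/PUFA and n-3/n-6 labels. Ct values follow
  $Ct = 25 - \log_2(\mathrm{abundance}) + \varepsilon$ with a
  constant-abundance reference gene.

**What it does not emulate** — and hence what green tests do *not*
demonstrate about real data: count-level sampling noise
(negative-binomial overdispersion), library-size and batch effects,
isoform ambiguity and assembly errors, miRNA target-prediction error,
correlated backgrounds (co-regulation unrelated to sponging), and
realistic network topology (hub miRNAs shared across many triads).
Passing recovery tests shows the machinery implements its rules
correctly at the stated thresholds, not that those thresholds are
optimal for any particular tissue.

# Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated
data: the hypergeometric sweep enumerates every configuration up to a
12-miRNA universe; triad recovery runs the full default study (260+
transcripts, 16 samples, 10 triads); the null-FDR property re-simulates
200 studies of 20 lncRNAs at 4 vs 4 replicates; correlation calibration
uses 10,000 null pairs and 500 planted-correlation replicates. These
sizes were chosen to give the properties sharp expectations (Monte-Carlo
standard errors well below the asserted margins) while keeping a full
run in the minutes range on one core.

# Known limitations

* The DE test is Welch's t on log-transformed FPKM — transparent and
  robust at n = 4, but less powerful than count-based negative-binomial
  models; the statistic is deliberately simple and the surrounding
  machinery (thresholds, BH, summaries) does not depend on it.
* Trans prediction at |r| > 0.999 with 16 samples is an extremely sharp
  screen; on noisy data it returns few or no pairs. That is the method's
  stated rule, reproduced faithfully.
* The enrichment module performs plain hypergeometric
  over-representation with BH q-values; it does not reproduce
  EASE-style score modifications or ontology-graph propagation.
* Amplification-efficiency correction (Pfaffl-style) is out of scope for
  the ΔΔCt module.
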