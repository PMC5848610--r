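---
title: "Methods: promoter architecture of CpG-island-binding zinc-finger factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter architecture of CpG-island-binding zinc-finger factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The scientific setting

Most oncogenic transcription factors act through distal enhancers. ZFX — a
C2H2 zinc-finger factor whose expression tracks proliferation and poor
outcome across several cancers — does the opposite: the large majority of its
ChIP-seq binding sites fall inside promoters, and specifically inside
CpG-island promoters that are active in the assayed cell line. Three
quantitative observations characterise this binding mode:

1. **Position.** Peak summits concentrate near **+240 bp downstream of the
   TSS**, between the transcription pre-initiation complex and the first
   downstream nucleosome. A minority of promoters (< 10%) instead carry a
   peak at −240 bp, and some carry both.
2. **Sequence.** An 8-nt consensus, `AGGCCTAG`, occurs in the vast majority
   of peaks and is enriched **symmetrically** at ±240 bp around the TSS of
   CpG-island promoters — so the motif is necessary but not sufficient;
   binding selects the downstream copy.
3. **Function.** Genes whose promoters are bound are expressed more highly,
   and on siRNA knockdown the down-regulated genes are far more often bound
   than the up-regulated ones — the signature of a direct activator. A
   closely related factor (ZNF711) binds almost exactly the same promoter
   repertoire, more weakly, and partially substitutes on double knockdown.
   NOMe-seq places the bound factor inside the nucleosome-depleted region
   (NDR) downstream of the TSS.

`promarch` implements the full analysis pipeline behind these observations —
peak annotation, CpG-island promoter classification, motif positional
profiling with scrambled nulls, summit architecture, knockdown integration,
and NDR calling — together with a seeded synthetic-data generator that plants
all of the structure above, so that every stage can be tested against ground
truth without any external download.

# Coordinates and formats

Internally every interval is a `GenomicRanges::GRanges` (1-based, closed),
the native convention of the Bioconductor stack this package is built on.
All on-disk formats use BED conventions (0-based half-open intervals,
0-based positions), and each reader/writer converts exactly once at the
boundary, so `read -> write -> read` is the identity on every format:
BED3/BED6, 10-column ENCODE narrowPeak (column 10 = summit offset, −1 for
absent), bedGraph, FASTA (upper-cased on read), a tabular methylation-call
format (`chrom, pos, strand, context ∈ {HCG, GCH}, n_methylated, n_total`)
and a DE table (`gene_id, expression, log2fc, fdr`). Malformed records fail
with the offending line number; chromosome names are matched verbatim, and a
validation pass warns when peak chromosomes are absent from the TSS
annotation, because silent namespace mismatches are the classic interval
bug. Unsorted input is accepted everywhere; writers emit sorted records.

# Annotation model

* **Promoter window**: ±`half_width` (default 2000 bp) around the TSS,
  strand-symmetric, clipped at the chromosome start. The ±2 kb default is
  the window used throughout the analyses this package reproduces.
* **Peak categories** partition every peak set with the priority
  `promoter > distal_enhancer > distal_insulator > other`: any peak touching
  a promoter window is a promoter peak regardless of chromatin marks
  ("distal" qualifies the other classes); a distal peak overlapping H3K27ac
  is a distal enhancer; CTCF without H3K27ac is a distal insulator.
  Assignment uses any-bp overlap of the whole peak (a summit-only switch is
  available), because category counts are defined over whole peaks.
* **CpG-island promoters** are defined by the TSS base falling inside an
  island interval — a binary promoter property, deliberately not a
  window-overlap property.
* **Nearest TSS** ties (equidistant) break toward the smaller coordinate
  (5′-most on the chromosome) so output is deterministic.
* **Active** means expression strictly above `active_threshold` (default 0,
  i.e. any detectable expression; configurable).
* A gene with several TSSs is *bound* if any of its promoter windows is
  bound, matching the promoter-level granularity of the annotation.

# Motif scanning and positional profiles

The consensus is an IUPAC string (default `AGGCCTAG`). Both strands are
scanned by matching the pattern and its reverse complement against the
forward sequence (`Biostrings::matchPattern(fixed = "subject")`); all
overlapping occurrences are reported at their leftmost base. The matching
rule is: a sequence letter matches a motif code iff its identity is among
the bases the code denotes; an ambiguous `N` in the *sequence* matches only
the motif code `N` — an unknown base is never allowed to satisfy a concrete
motif position.

For TSS-relative work each hit is represented by its **midpoint** (a
half-integer for even-length motifs), which symmetrizes forward and reverse
hits of the same site. Profiles bin signed offsets (downstream positive in
the transcription direction; minus-strand anchors are sign-flipped) into
20-bp bins across ±2 kb by default. Every anchor contributes all of its
in-window items, so a hit between two close TSSs counts toward both — the
same convention as any metagene average. Windows with more than 10%
ambiguous bases are dropped and logged. Palindromic double counts (a forward
and reverse hit at the same midpoint) are counted once by midpoint
de-duplication of planted sites; `AGGCCTAG` itself is non-palindromic.

Two mode summaries are reported. The raw modal bin is what a histogram
shows; at desk scale (a few hundred summits) neighbouring 20-bp bins differ
by only a few counts, so the profile also carries `mode_kde`, the mode of a
Gaussian kernel density estimate (bandwidth = one bin) of the same offsets,
which is the stable estimator at these sample sizes.

## Scrambled-motif nulls

`scramble_motif` draws seeded letter permutations with identical nucleotide
composition, rejecting the identity and the reverse complement of the
original (a homopolymer therefore errors). The control contract is that the
true motif shows ±240 bp structure while every scramble is flat. Flatness is
summarised as max/mean bin count — but computed at a **1-kb control
resolution** (4 bins across the window, configurable via `flat_bin`): a
specific scrambled 8-mer occurs only ~0.1 times per 4-kb window in
composition-realistic sequence, so at 20-bp resolution the null counts are
Poisson with mean ≪ 1 and the max/mean ratio of even a perfectly flat
profile is dominated by shot noise. At 1 kb the per-bin expectation is large
enough for the ratio to be meaningful. Mode *location* for the true motif is
still assessed at 20 bp.

# Summit architecture

`summit_offsets` emits one signed offset per (peak, overlapping promoter)
pair; peaks without a recorded summit fall back to the interval midpoint
(logged). `select_single_tss_promoters` keeps a TSS iff no other TSS on the
same chromosome is closer than the half-width — the clean subset on which
upstream/downstream assignment is unambiguous. The rule classifier labels a
promoter `upstream_only`/`downstream_only` when **all** of its offsets fall
strictly beyond a ±50-bp dead zone on that side, and `both` otherwise; the
dead zone avoids knife-edge labels for summits essentially at the TSS. The
alternative k-means route (k = 3, fixed seed, 10 restarts) clusters
row-normalised 500-bp offset histograms and maps clusters to labels by their
mean offset; 500-bp feature bins keep the ±240 classes in separate bins
despite summit jitter, which makes the unsupervised route agree with the
rule on well-separated data.

Metaplots average a piecewise-constant signal track per base over anchors
(zeros where the track is empty, strand-flipped), then bin; tracks must be
non-overlapping within themselves, and normalisation is the caller's
responsibility (tag tracks are assumed pre-normalised). Tag correlation is
Spearman's ρ with mid-ranks on ties; zero-variance samples yield `NA` for
their pairs.

# Knockdown integration

`select_de_genes` applies the strict thresholds `fdr < 0.05` and linear
|fold change| > 1.5 (`|log2fc| > log2 1.5`). `de_binding_overlap` forms the
2×2 table (down, up) × (bound, unbound) and reports: the bound percentage of
each class (rounded to one decimal, half away from zero — applied once, at
reporting), the **sample** odds ratio `(a·d)/(b·c)` (0 when the numerator is
0, `Inf` when only the denominator is), a two-sided Fisher exact p-value
(with a one-sided hypergeometric option, `alternative = "greater"`), and a
one-sided hypergeometric **mid-p**.

The mid-p deserves a note. The p-value of any exact conditional test is
discrete and conservative: under the null it is stochastically *larger*
than uniform, and with a few hundred replicates a Kolmogorov–Smirnov test
will reliably say so. That is a property of exact tests, not a bug. The
standard calibrated variant is the mid-p correction
(`P(X > a) + P(X = a)/2`), which is close to uniform under independence;
the package's null-calibration property test therefore asserts KS-uniformity
of the mid-p and, separately, validity (type-I error at most nominal) of the
exact p. Inference defaults to the exact p; the mid-p is reported alongside
as the calibration diagnostic.

`combinatorial_kd_overlap` is pure set arithmetic: bound-down genes of the
double knockdown minus bound-down genes of either single knockdown — the
redundancy signature of a substituting paralog — plus the full membership
table.

# NOMe-seq NDR calling

Methylation levels always **pool** read counts (`Σ methylated / Σ total`),
never average per-site ratios. The NDR caller realises "GCH methylation
elevated over background, at least 140 bp long" as the simplest defensible
procedure, every piece configurable:

1. background = genome-wide pooled GCH rate (a local-flank variant can be
   had by passing `background` explicitly);
2. slide a 100-bp window every 20 bp; windows with < 3 calls are skipped
   (logged); one-sided binomial test of pooled counts against background;
3. Benjamini–Hochberg across all tested windows, keep q < 0.05;
4. merge significant windows that overlap or abut within one step;
5. **trim** each merged region to its outermost individually elevated calls
   (one-sided binomial p < 0.01 against background) that have another
   elevated call within 40 bp. Without trimming, window-width slop pads
   every region by up to a window; without the support requirement a single
   noisy background call (at depth 20 and background 0.1, ~0.2% of calls
   are nominally elevated at p < 0.01) can stretch a region past any length
   floor;
6. report regions with trimmed length ≥ 140 bp and pooled level strictly
   above background.

The reported NDR count is monotone non-increasing in `min_length` and in a
stricter `q_max`, and every reported region satisfies
`mean_gch > background` by construction. `peak_ndr_overlap` measures the
fraction of peaks (optionally restricted to summit-to-TSS offsets in
[140, 340] bp, the "near +240" band) sharing at least one bp with an NDR.
NOMe metaplots pool counts per bin across anchors for HCG and GCH
separately.

# The synthetic generator

`sim_config()` fixes the study conditions; `generate_bundle()` emits a
complete, mutually consistent input bundle (FASTA genome, TSS table,
CpG-island BED, narrowPeak per factor and chromatin mark, methylation call
table, bedGraph per factor, DE tables for two single and one double
knockdown) plus a per-promoter truth table. Everything is deterministic
given the seed; two runs are byte-identical.

Defaults, chosen once from the structure the pipeline is designed to
recover, at a scale (2 chromosomes × 2 Mb, 400 promoters) where the full
acceptance run takes minutes on one CPU:

| parameter | default | rationale |
|---|---|---|
| CpG-island fraction | 0.70 | most promoters in the emulated system are CpG-island promoters |
| active fraction | 0.90 | broadly active CpG promoters; inactive genes get expression 0 |
| bound fraction | 0.60 of active CpG promoters | the observed ~60% bound share |
| summit offsets | N(+240, 60) bp | downstream preference with realistic summit jitter |
| architecture mix | 0.82 / 0.08 / 0.10 down/up/both | < 10% upstream-only promoters |
| motif placement | N(±240, 50), equal weights; plus one motif under every planted summit | symmetric enrichment; the consensus recruits the factor, so peaks contain it |
| motif counts | Poisson(4) CpG / Poisson(1) non-CpG windows | more motifs in CpG-island promoters |
| NDR | width 300 bp at [+40, +340), GCH 0.7 vs 0.1, depth 20, 10-bp spacing, 85% of bound promoters | accessible region between TSS and first nucleosome |
| HCG | 0.75 background, 0.05 within ±500 bp of active CpG TSSs | unmethylated active islands |
| knockdown | P(down) 0.35 bound / 0.05 unbound; P(up) 0.03 / 0.10 | bound genes preferentially down-regulated |
| redundancy | 30 bound genes down only in the double knockdown | paralog substitution |
| second factor | 144 co-located peaks, 1 promoter-only, 1 distal | near-complete co-binding (98.6% of sites, ~99% of promoters) |
| latent tag correlation | 0.92 | yields a realized Spearman ρ ≈ 0.85 between window tag sums after zero-truncation and mixture effects |

Background sequence is i.i.d. uniform A/C/G/T; islands are generated
GC-rich (G+C ≈ 0.65) with forced CpG dinucleotides so island classification
is non-trivial. Before planting, every promoter window is scrubbed of
spurious exact consensus matches (scrubbing precedes all planting because
divergent promoter pairs have overlapping windows); planted spans are
tracked genome-wide so plantings never overwrite each other. DE values are
drawn so that the emitted tables reproduce the planted DE classes exactly
under the default thresholds (effect sizes are truncated away from the
fold-change boundary, null genes away from it), making truth comparison
exact rather than approximate.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level noise and mappability artifacts, peak
callers' boundary uncertainty, sequence composition beyond a two-state
island model, copy-number and batch effects in expression, bisulfite
conversion failure, fragment-level correlation between neighbouring
methylation calls, and any genome-scale count (the miniature genome has 400
promoters, not 57,820). Recovery of planted structure demonstrates the
*estimators*, not the biology.

# Pipeline and reproducibility

`run_all()` executes every stage from a config (R list or YAML), writes
tab-separated tables and an NDR BED, logs stage-tagged progress to stderr,
aborts naming the failing stage, and emits a JSON manifest with the package
version, seed, every effective parameter (defaults included) and MD5
checksums of all inputs. Reruns with the same config are byte-identical. A
thin command-line wrapper (`inst/scripts/promoter-architect`) exposes
`simulate`, `run-all`, per-stage subcommands and `report`; the R functions
are the primary interface.

Problem sizes used in the shipped checks: the default bundle above for all
recovery properties; 30–60-element random instances across 20 seeds for the
brute-force oracle equivalences (peak classification, set overlap,
single-TSS selection, motif scanning, per-base metaplots); 200 seeded
replicates of 1000-gene tables for the null calibration of the exact test;
500 + 500 genes for the expression-contrast recovery.

# Known limitations

* The NDR caller is a deliberately simple windowed binomial scan; it
  assumes calls are independent given the local rate and a single global
  background. Strongly varying coverage or methylation heterogeneity would
  warrant the local-background option and a beta-binomial likelihood.
* Motif scanning is exact-consensus (IUPAC); there is no PWM scoring, by
  design — the analyses this package supports are defined on the consensus.
* `classify_promoters` treats binding as binary per window; no peak-strength
  weighting.
* The k-means clustering route is provided for parity with the unsupervised
  analysis it mirrors, but the rule classifier is the primary, fully
  deterministic path.
* Percentages are rounded half-away-from-zero to one decimal at reporting
  only; all internal arithmetic is unrounded.
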