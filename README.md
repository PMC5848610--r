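# promarch

Promoter-architecture analysis of CpG-island-binding zinc-finger
transcription factors, built around the unusual binding mode of ZFX and its
paralog ZNF711: unlike most oncogenic factors, which act at distal
enhancers, these factors bind *inside* promoters — at CpG-island promoters,
with peak summits concentrated **+240 bp downstream of the TSS**, in the
nucleosome-depleted region between the pre-initiation complex and the first
downstream nucleosome.

`promarch` is for regulatory genomicists who have ChIP-seq peaks (with
summits), a TSS annotation, knockdown RNA-seq differential-expression
tables and (optionally) NOMe-seq methylation calls, and want the complete
promoter-centric analysis:

* **Annotation** — classify peaks into `promoter` (±2 kb of a TSS, with
  priority over marks), `distal_enhancer` (H3K27ac), `distal_insulator`
  (CTCF not in enhancers) and `other`; classify promoters by CpG-island
  status, per-factor binding and activity.
* **Motif positional analysis** — strand-aware IUPAC scanning for the
  `AGGCCTAG` consensus, TSS-relative frequency profiles
  (counts per 20-bp bin of the signed offset *d*, downstream positive),
  and scrambled-motif null controls with identical nucleotide composition.
* **Summit architecture** — signed summit-to-TSS offsets, single-TSS
  promoter selection, clustering into upstream-only / downstream-only /
  both classes, metaplots, Spearman tag correlation between factors.
* **Knockdown integration** — for down- and up-regulated genes
  (FDR < 0.05, |FC| > 1.5) the bound share of each class, the 2×2 table
  (down, up) × (bound, unbound) with sample odds ratio
  *OR = ad/bc* and Fisher's exact test, and the double-knockdown
  redundancy count (bound-down genes unique to the double knockdown).
* **NOMe-seq** — nucleosome-depleted region (NDR) calling from GCH
  methylation: sliding-window binomial test against the pooled background
  rate, BH correction, merge, trim, report regions ≥ 140 bp; peak–NDR
  overlap restricted to summits near +240 bp.
* **Synthetic data** — a seeded generator that emits a complete miniature
  input bundle (genome FASTA, TSS, CpG islands, narrowPeak, methylation
  calls, bedGraph, DE tables) with all of the structure above planted, plus
  the ground truth to score recovery against.

## Worked example

The central knockdown statistic, computed from the published C4-2B count
table (1271 down-regulated genes of which 744 bound; 1249 up-regulated of
which 143 bound):

```r
library(promarch)
down  <- sprintf("down%04d", 1:1271)
up    <- sprintf("up%04d",   1:1249)
bound <- c(down[1:744], up[1:143])
de_binding_overlap(down, up, bound)
#> down-regulated: 744/1271 bound (58.5%); up-regulated: 143/1249 bound (11.4%)
#> odds ratio 10.9, exact p = 4.12e-144
```

58.5% of down-regulated genes have bound promoters against 11.4% of
up-regulated ones — an eleven-fold enrichment in odds, the signature of a
direct transcriptional activator.

End-to-end on synthetic data with planted ground truth:

```r
b  <- generate_bundle(sim_config(seed = 1))
so <- summit_offsets(b$peaks$ZFX, b$tss)     # signed summit-to-TSS offsets
positional_profile(so$offset, anchors = b$tss)
#> positional_profile: 182 hits over 400 anchors, 200 bins of 20 bp
#>   modal bin [220, 240), kde mode 225.7 bp

ndrs <- call_ndrs(b$calls)                   # GCH-based NDR calling
truth_compare(list(ndrs = ndrs), b$truth)
#>   class precision recall n_true n_called
#> 1   ndr         1      1    128      128
```

The summit profile recovers the planted +240 bp downstream mode (182
summit–promoter pairs across 400 promoters), and the NDR caller recovers
all 128 planted 300-bp accessible regions with no false positives.

The full pipeline — annotation through metaplots, with a JSON run manifest —
is one call (`run_all(config, out_dir)`), or from a shell via the thin
wrapper in `inst/scripts/promoter-architect`. The methods vignette
(`vignettes/promoter-architecture.Rmd`) documents the model, every tunable
parameter, and the numerical choices.

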