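---
title: "chromstack: methods and statistical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromstack: methods and statistical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

chromstack analyzes genome-wide histone-mark ChIP data in compact,
gene-dense genomes: it calls broad enriched domains ("islands") from tag
libraries, annotates them onto genes, transposable elements (TEs) and
intergenic space, assigns combinatorial chromatin states together with
bisulfite methylation calls, profiles marks over length-normalized genes,
clusters within-gene marking positions, and compares two conditions. A
seeded simulation module generates complete datasets with known ground
truth, so every statistical claim in this vignette is checkable by running
the package against its own generator.

```{r load}
library(chromstack)
suppressPackageStartupMessages(library(GenomicRanges))
```

All internal coordinates are Bioconductor `GRanges` (1-based, closed
intervals). BED and bedGraph files (0-based, half-open) and GFF3 (1-based)
are converted at the file boundary by the readers; nothing downstream ever
sees file-format coordinates.

## Island calling

Broad histone marks (H3K27me3, H3K9me2/3) form multi-kilobase domains
rather than punctate peaks, so calling follows the SICER design: fixed
windows, a per-window eligibility test, gap-tolerant assembly, and an
island-level significance test against a control library.

Given a tag library of size $T$ over a genome of $G$ bp, counted in
windows of $W$ bp (default 200):

1. **Window counting.** Each tag is assigned by its shifted 5' position
   (default shift 73 bp, half a nucleosome). Window $i$ covers
   $[(i-1)W+1,\ iW]$; the final window absorbs any partial remainder.
2. **Eligibility.** The background rate per window is
   $\lambda_{bg} = T W / (G \cdot f)$ with $f$ the effective genome
   fraction (default 1). A window with count $k$ is *eligible* when the
   Poisson upper tail $P(X \ge k)\le p_w$ (default $p_w = 0.2$);
   equivalently $k \ge k^\*$, the smallest count with that property.
3. **Assembly.** Runs of eligible windows separated by at most $G_{gap}$
   bp of ineligible windows (default 600 bp, a multiple of $W$) merge
   into one candidate island.
4. **Island test.** With treatment and control island totals $t$ and $c$
   and library sizes $T$ and $C$, the per-window null mean is
   $$\lambda_w = \max\!\left(\lambda_{bg},\ \frac{(c+1)\,T/C}{n}\right),$$
   where $n$ is the number of member windows. The pseudocount keeps
   $c = 0$ islands finite; the $\lambda_{bg}$ floor (the same guard as the
   local-lambda floor in MACS) prevents a downward-fluctuating control
   from manufacturing enrichment.
5. **FDR.** Island p-values are Benjamini-Hochberg adjusted; islands with
   $q \le$ `fdr` (default 0.01) are reported with their fold change
   $((t+1)/T)\,/\,((c+1)/C)$.

### The selection-adjusted null

The naive island test — Poisson($n\lambda_w$) on the total $t$ — is badly
anti-conservative, because member windows are *selected* for high counts:
every eligible window satisfies $X \ge k^\*$ by construction. In
background-only simulations the naive test calls islands in essentially
every replicate. chromstack instead conditions the null on the
eligibility mask: given the mask, window counts remain independent, so
the island total is a sum of independent *truncated* Poissons — eligible
windows truncated to $X \ge k^\*$, internal gap windows to $X < k^\*$.
The upper tail of this sum is computed by exact probability-mass
convolution. A normal-approximation screen handles the bulk of
candidates: an island whose total lies below 2 SD above the conditional
mean cannot approach any BH threshold, so its exact tail is not needed.

```{r island-demo}
gn <- cs_genome(c(chr1 = 3e5, chr2 = 3e5))
planted <- plant_islands(gn, n = 20, min_len = 600, max_len = 3000, seed = 7)
tl <- simulate_tags(gn, planted, fold = 8, library_size = 6e4, seed = 8)
called <- call_islands(tl$treatment, tl$control, gn,
                       island_params(w = 200, g = 600, fdr = 1e-2))
length(called)
mean(countOverlaps(planted, called) > 0)  # recall
```

## Annotation, chromatin states and methylation

`annotate_features()` marks a feature when any island of a mark overlaps
it by at least `min_overlap` bp (default 1); assignment is
non-exclusive. Intergenic space is derived as the complement of the
gene/TE union, so the three classes tile the genome.

States combine the activating marks (H3K4me2, H3K9_14Ac) with the
repressive marks (H3K9me2, H3K9me3, H3K27me3) per gene:

* **CS1** — at least one activating mark, no repressive mark;
* **CS2** — at least one repressive mark, no activating mark;
* **CS3** — both; otherwise **unmarked**.

Gene-body methylation (mC) is carried alongside as a parallel
stratifier, not as part of the state logic. A cytosine is called
methylated when covered by $\ge 3$ reads of which $\ge 20\%$ support
methylation; a feature is methylated when it contains at least
`min_sites` called cytosines. Expression uses
FPKM $= \text{count} / ((L/1000)(T_{RNA}/10^6))$, with groups compared by
five-number summaries and Mann-Whitney tests.

## Metagene profiles and dinucleotide preference

`metagene_profile()` averages a per-bp track over genes using fixed-width
flank bins (default 500 bp in 10 bins per side) and length-normalized
body bins (default 40): body bp $i$ of an $L$-bp gene contributes to the
bin containing its rescaled midpoint, $\lfloor((i-0.5)/L)\,n\rfloor + 1$.
Minus-strand genes are reversed so bin 1 is always 5'-most. Flank bp
beyond chromosome ends are missing data, not zeros. Tracks are in tags
per bp per million library tags, so profiles are comparable across
libraries. `occupancy_by_quantile()` stratifies genes into expression
quantiles (ties broken stably by gene ID) and profiles each stratum.

`dinucleotide_preference()` counts overlapping 2-mers with
`Biostrings::oligonucleotideFrequency()` inside versus outside a region
set; windows containing N are excluded from both numerator and
denominator. An interval of length $\ell$ contributes $\ell - 1$
windows.

## Positional clustering

`positional_matrix()` encodes each marked gene as a binary vector over
10 upstream, 10 body and 10 downstream bins (a bin is 1 when at least
one island bp overlaps it). `cluster_positional()` applies
complete-linkage hierarchical clustering (default Euclidean distance,
which on 0/1 rows is the square root of the Hamming distance), cuts at
`k` (default 6) and renumbers clusters by descending size. The procedure
is deterministic for a fixed matrix; the cluster archetypes (per-cluster
bin means) summarize where along the gene each group is marked.

## Differential analysis

`classify_changes()` performs exact set algebra per mark: gained, lost,
stable-marked, stable-unmarked, with percentages reported against
explicit denominators. `differential_binding()` tests each region's tag
counts $a, b$ with a two-sided binomial test of $b$ in $a+b$ trials at
$T_B/(T_A+T_B)$, and reports
$\log_2(((b+1)/T_B)/((a+1)/T_A))$, BH-adjusted. Expression changes are
$\log_2((\text{FPKM}_B+1)/(\text{FPKM}_A+1))$, and `correlate_diff()`
couples the two with a Pearson correlation and least-squares trend.

## The simulation model

The generator is first-class: every stage above is validated against it.
Design choices and their limits:

* **Genome.** Genes and TEs interleave along each chromosome with
  gamma-distributed spacers (mean 1.5 kb), lognormal lengths, and a
  random 50% GC sequence with GC-elevated 147-bp nucleosomal intervals —
  a caricature of a compact, gene-dense genome. No isochores, repeats, or
  mappability structure.
* **Chromatin.** Each gene draws a state; marks are drawn consistently
  with it (activating marks for CS1, repressive for CS2, both for CS3;
  TEs predominantly repressive). H3K27me3 islands follow one of six
  positional archetypes (downstream flank; body+downstream; body; whole
  locus; upstream; upstream+body) so positional clustering has a ground
  truth. Planted recovery islands keep a minimum separation larger than
  the assembly gap, so domains are resolvable as distinct islands.
* **Tags.** An inhomogeneous Poisson process: background rate outside
  islands, `fold` times that inside, calibrated so the expected library
  matches `library_size`; the control is uniform. No duplicates or
  mappability holes are modeled.
* **Expression and methylation.** True FPKM is lognormal with
  state-dependent location (CS1 high, CS3 intermediate, CS2 low); counts
  are Poisson. Methylated features draw per-site levels from Beta(8, 2),
  unmethylated from Beta(0.5, 12), with Poisson depth (mean 17).
* **Determinism.** Every generator takes an explicit seed derived from
  the master seed by fixed offsets, so components regenerate
  independently and whole datasets are byte-identical for a fixed seed.

```{r sim-demo}
cfg <- sim_config(seed = 11, n_chrom = 2, chrom_length = 3e5,
                  n_genes = 60, n_tes = 15, library_size = 5e4,
                  n_nucleosomes = 60)
ds <- simulate_dataset(cfg)
table(ds$truth$states)
```

The default scale (2 Mb, 300 genes, 60 TEs, 200k-tag libraries) is the
package's own choice of a size that exercises every code path in seconds
to a few minutes on one CPU; it is not a claim about any real genome.

## Numerical notes and limitations

* The truncated-Poisson convolution is exact up to FFT round-off;
  negative round-off mass is clamped at zero and the support is chosen so
  the discarded tail is below $10^{-14}$ per window.
* The normal screen returns a floor of 0.023 ($\approx P(Z>2)$) so
  screened p-values can never undercut exactly-computed significant ones.
* The island test treats the control-scaled mean as known apart from the
  floor; a fully Bayesian treatment of control noise is out of scope.
* Tag-level realism (duplicates, mappability, fragment-length variation,
  read-level sequence) is explicitly not modeled; the simulator validates
  the statistics, not read processing.

## Reproducing the headline numbers

`scripts/acceptance.R` runs the full battery against the installed
package and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
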