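---
title: "atacqc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{atacqc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific models implemented by `atacqc`,
the reasoning behind the numerical choices, and the known limitations
of the synthetic-data generator used to validate them.

## Coordinates

All interval data are held as `GenomicRanges::GRanges`, i.e. 1-based
closed intervals, the Bioconductor convention. BED, narrowPeak and
gene-model files use 0-based half-open coordinates; the conversion
happens in exactly one place (the readers and writers in the I/O layer),
so a BED fragment `chr1 1000 1200` becomes `GRanges("chr1",
IRanges(1001, 1200))` and round-trips byte for byte. Keeping a single
conversion boundary — rather than carrying a 0-based convention through
1-based containers — is the main design deviation from tools that work
on raw coordinates, and every worked example below is stated in both
systems where it matters.

## Cut sites

Tn5 inserts as a dimer and duplicates 9 bp of target sequence; the
centre of the insertion event is 4–5 bp inside each read end. The
standard correction shifts the forward-strand end by +4 bp and the
reverse-strand end by −5 bp. For a 0-based fragment $[s, e)$:

$$\text{cut}_+ = s + 4, \qquad \text{cut}_- = (e - 1) - 5.$$

Both cuts are emitted for every template (`tn5_shift()`); in 1-based
GRanges terms these are `start + 4` and `end − 5`. Cuts shifted past
the contig start are dropped with a warning and counted.

## Hotspots and replicate concordance

`concordant_hotspots()` retains a peak called on pooled replicates only
if at least `min_frac` (default 0.5, inclusive) of its bases are
covered by the merged peaks of **every** replicate. Coverage fractions
come from `overlap_fraction()`, which merges the subject set first so
overlapping replicate peaks never double-count a base.

## PRC and reference calibration

`calibrate_reference_peaks()` works per base: each input set is
self-merged, per-base presence counts are summed (on a common
per-contig width, so sets that end early contribute zeros), and bases
where the presence fraction clears the threshold are merged into
reference peaks; runs shorter than `min_width` (default 20 bp) are
discarded. Two modes match the two published calibrations: strictly
greater than 0.97 (the "open in >97% of samples" panel) and `≥ 1`
("common to all samples"). Working per base rather than per peak makes
the calibration robust to boundary jitter and peak fragmentation
between samples.

`prc()` is then simply

$$\mathrm{PRC} = 100 \cdot
  \frac{\#\{\text{reference peaks overlapped by} \ge 1\text{ bp of a hotspot}\}}
       {\#\{\text{reference peaks}\}}.$$

## TSS enrichment score

`tss_aggregate()` bins cut sites at 1-bp offsets in a ±2000 bp window
around every TSS, flipping the axis for minus-strand genes so positive
offsets are always downstream, and scales counts to 10 M tags. The
score is

$$S = \frac{\overline{c}_{[-50, 50]}}
           {\overline{c}_{[-2000,-1901] \cup [1900,1999]}},$$

the central mean over the mean of the two outermost 100-bp flanks. The
depth normalization cancels in the ratio; it is kept so the aggregate
profiles themselves are comparable across libraries. A score near 1
means no enrichment.

## Fragment-size periodicity

`fragment_size_profile()` histograms template lengths at 1-bp
resolution up to 1000 bp and reports a phasing score: the fraction of
spectral power (via `stats::fft`) of the mean-subtracted histogram at
periods of 190–200 bp, the nucleosome repeat. Intact chromatin shows
the mono/di/tri-nucleosome ladder and scores well above degraded
chromatin, which loses the ladder.

## PWM scanning at an exact p-value

`build_pwm()` converts counts to log2-odds with a background-weighted
pseudocount:

$$w_{b,j} = \log_2 \frac{(n_{b,j} + c \cdot \pi_b)/(N_j + c)}{\pi_b},$$

with pseudocount mass $c = 0.8$ and background $\pi$ (uniform by
default). `pwm_score_distribution()` rounds per-column scores to a
lattice of $10^{-3}$ bits and convolves the per-column distributions
exactly, so `score_threshold()` can return the smallest achievable
score whose background tail probability is at most `p` (default
$10^{-4}$). When `p` is below the probability of the single best word —
e.g. $4^{-6} \approx 2.4\times10^{-4}$ for a width-6 motif under a
uniform background — no threshold can satisfy it and the maximum
achievable score is returned. The $10^{-3}$-bit granularity bounds the
rounding error of a width-$W$ motif by $W \cdot 5\times10^{-4}$ bits,
negligible against typical column scores of order 1, while keeping the
DP table a few thousand entries wide. `scan_motifs()` scores both
strands (the reverse-strand score at a window is the forward score of
the reverse-complemented matrix) and skips windows containing non-ACGT
bases.

## Mappability

`mappability_mask()` is a brute-force uniqueness catalogue: a position
is usable if the k-mer starting there (default $k = 50$, a typical read
length) occurs exactly once across both strands of the genome.
Reverse-complement palindromes occur at least twice by construction and
are never unique. The exhaustive approach is intended for desk-scale
and synthetic genomes; for a real genome a precomputed track can be
supplied in the same list-of-logical-vectors layout.

## Hexamer bias model

Tn5 prefers particular local sequence contexts, and uncorrected
preference masquerades as footprint structure. `hexamer_model()`
tallies the 6-mer centred on each cut, strand-oriented: a plus-strand
cut at 1-based position $P$ reads the hexamer at $[P-3, P+2]$; a
minus-strand cut reads the reverse complement of $[P-2, P+3]$, so the
cut base occupies the same slot relative to the insertion's 5′ side on
either strand. Only cuts at uniquely mappable positions count (the
plus-strand read's k-mer starts at the cut; the minus-strand read's
k-mer starts at $P-k+1$). The model also tallies each hexamer's
abundance over usable positions on both strands, so the expected
relative cut rate at a position is its hexamer's cut share divided by
that abundance.

## Footprint profile and depth

`footprint_profile()` sums observed cuts and bias-expected rates at
strand-oriented offsets from $-25$ to motif width $+24$ around the
sites, both restricted to usable positions, scales the expected profile
to the observed total, converts both to a 100 M-tag depth, and forms

$$r(o) = \log_2 \frac{\mathrm{obs}(o) + \varepsilon}
                     {\mathrm{exp}(o) + \varepsilon},
  \qquad \varepsilon = 0.5.$$

The pseudocount $\varepsilon$ (on the raw-count scale, applied before
depth scaling) guards the logarithm at sparsely cut offsets without
biasing well-covered ones. A baseline — the mean of $r$ over the
outermost 40% of each flank (10 offsets per side at the default
25-bp flank) — is subtracted so a bias-only library is flat at zero
regardless of how open the region is, and the **footprint depth** is
the mean adjusted $r(o)$ over the motif offsets. A site bound with
protection factor $f$ has depth $\approx \log_2 f$.

## The synthetic generator

`simulation_spec()` + `make_genome()` + `simulate_cuts()` produce fully
controlled experiments. The per-position, per-strand cut intensity is a
product of independent factors:

$$\lambda_\pm(x) = h_\pm(x) \cdot
  \Big(1 + (E-1)\, e^{-d(x)^2 / 2\sigma^2}\Big) \cdot
  g_{\mathrm{open}}(x) \cdot g_{\mathrm{prot}}(x),$$

where $h$ is the planted hexamer preference at the would-be cut
(default uniform), $E$ the TSS enrichment factor with kernel width
$\sigma = 75$ bp and $d(x)$ the distance to the nearest TSS, and
$g_{\mathrm{open}}, g_{\mathrm{prot}}$ step factors over accessible
regions (default ×8) and protected intervals (the footprint, $f \le
1$). The mitochondrial contig receives a binomial share of templates
(default 5%) with hexamer preference only.

Two sampling modes serve different analyses:

- `paired = TRUE` draws each template's forward cut from
  $\lambda_+$, proposes the reverse cut at a nucleosomal-mixture
  distance (lengths $\mathcal{N}(75, 15)$, $\mathcal{N}(265, 25)$,
  $\mathcal{N}(455, 30)$ with weights 0.45/0.35/0.20), and accepts it
  in proportion to $\lambda_-$ there; the emitted fragments satisfy
  `tn5_shift(fragments)$cuts == cuts` exactly. The rejection step makes
  the marginal reverse-cut distribution only approximately
  $\lambda_-$ — partners are tied to their mates' positions — so
  paired mode is used for QC-level metrics, not for cut-level
  calibration.
- `paired = FALSE` draws $2n$ cut sites i.i.d. from
  $(\lambda_+, \lambda_-)$ with no fragments: the cleanest input for
  TSS-score, hexamer-recovery and footprint validations, where the
  closed-form expectations assume independent draws.

`simulate_peak_collections()` plants loci that appear, with ±20 bp
jitter, in exactly `round(f · n_sets)` of the sets, plus private peaks
kept at least 3 kb away, to exercise reference calibration with exact
truth.

## Validation design and known limitations

- **TSS recovery.** With planted enrichment the expected score has the
  closed form $\overline{m}_{[-50,50]} / \overline{m}_{\text{flanks}}$
  with $m(o) = 1 + (E-1)e^{-o^2/2\sigma^2}$; at $10^6$ cuts on 200 kb
  the simulation recovers it within ~1.5% (tolerance 5%).
- **Hexamer recovery.** At $10^6$ cuts over 4096 hexamers the mean
  count per hexamer is ~244, i.e. a per-hexamer Poisson error of ~6%,
  so a worst-case bound is not statistically attainable at this size.
  The validation asserts the **median** absolute relative error over
  observed hexamers ≤ 5%; an ideal multinomial draw of the same size
  floors at ~4.4%, and the implementation sits at that floor (~4.3–4.6%
  across seeds). The bias model must be built over the contigs that
  carry cuts: a cut-free contig contributes abundance (denominator)
  without tallies (numerator) and inflates the apparent error.
- **Footprint depth.** Depth validations use protected intervals placed
  uniformly at random rather than consensus-planted motifs. With
  consensus planting at desk scale the motif's hexamers occur almost
  exclusively inside protected sites, so a bias model estimated from
  the same cuts absorbs the footprint and no method could recover the
  depth — a circularity that a genome-scale analysis dilutes. With
  random placement the depletion is spread uniformly over hexamers and
  cancels in the rate normalization; a small residual (~+0.03 on a
  depth of −3) remains because protected sites still cover a few
  percent of the genome, within the ±0.1 validation tolerance. The
  null bound (|adjusted $\log_2$| ≤ 0.05 at every offset) is run at
  $2\times10^6$ cuts over 1500 sites, sized so the per-offset Poisson
  error (~0.012) puts the bound at more than 4 standard errors.
- **Published magnitudes.** Reference-peak counts and per-sample scores
  from published panels depend on versioned consortium downloads and
  raw sequencing data; they are out of scope here, and the validations
  are property- and simulation-based instead.
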