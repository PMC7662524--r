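---
title: "Methods: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`repsamotif` reconstructs, as reusable and tested code, the computational
workflow by which the DNA-binding specificity of a bacterial
transcription factor is determined from an in vitro iterative-selection
experiment and then dissected: selection-read analysis, palindromic
motif elicitation, genome-wide site mapping and annotation,
binding-kinetics quantification, and expression cross-validation. The
concrete system it is built around is TTHB099, a cAMP-receptor-protein
(CRP)-family regulator of the extreme thermophile *Thermus thermophilus*
HB8, which binds a 16-bp palindromic site as a homodimer. Because the
raw sequencing, sensorgram, and microarray data of such a study are not
redistributable, every stage is paired with a synthetic-data generator
with known ground truth; the measured rate constants and the mapped
site table are bundled as plain-text reference tables.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical decisions — in the spirit of a methods
section, not a tutorial.

## Selection simulation

`simulate_selection()` models restriction-endonuclease
protection/selection: in each round a cassette escapes cleavage with
probability

$$ p_\text{survive} = \theta + (1-\theta)\,(1-\varepsilon), $$

where $\varepsilon$ is the enzyme's cleavage efficiency and the
occupancy $\theta = [P] / ([P] + K_D(s))$ follows a per-cassette
dissociation constant

$$ K_D(s) = K_D^\text{ref} \cdot
   \exp\!\big(\lambda \cdot (S_\text{max} - S(s))\big), $$

with $S(s)$ the best log-odds site score over both strands,
$S_\text{max}$ the consensus score, and $\lambda$ the energy scale
(default 1 $k_BT$ per log~2~ unit — the simplest additive
log-odds-to-$\Delta\Delta G$ conversion consistent with PWM-driven
selection). Only the best site per cassette contributes; cooperative or
multi-site binding is not modelled. Survivors are resampled with
replacement to the configured pool size, i.e. uniform-multinomial PCR
with no amplification bias.

A configurable fraction of the initial pool is intrinsically resistant
to enzyme "A". This reproduces the qualitative artifact seen in such
selections: the contaminant sweeps the pool under enzyme A and collapses
within one or two rounds of switching to the less efficient enzyme "B"
(defaults $\varepsilon_A = 0.95$, $\varepsilon_B = 0.80$, resistant
fraction $10^{-3}$, round schedule A,A,A,A,B,B,B; protein 50.6 nM and
reference $K_D$ 2.214 nM, the measured study conditions).

Two scale choices matter. First, a real selection pool holds ~$10^{10}$
molecules; the simulator defaults to $10^4$. At that size subpopulations
seeded by a handful of founder molecules (the $10^{-3}$ resistant
fraction gives ten) behave as branching processes with visible drift, so
enrichment trajectories are reproducible only under a fixed seed, and
the monotone-enrichment property is asserted on the default pool size,
not on smaller ones. Second, a 16-mer cannot arise by chance in a
$10^4$-molecule random pool ($4^{-16}$), so the initial pool is seeded
with a small fraction (default 1%) of cassettes carrying one site drawn
from the generating motif model; those molecules are flagged and the
flag is the ground truth for the per-round motif-bearing fraction.
Late-round read pools used for motif-recovery experiments are generated
directly by `simulate_read_pool()` (default: 60% of cassettes carry a
planted site at uniform offset and strand), which matches the observed
composition of a successful selection without simulating the rounds.

The library architecture (18-bp fixed flanks around a randomized 24-bp
cassette) is configuration; the bundled flank sequences are synthetic
stand-ins, since the real primer sequences are not reproduced here.
Sequencing error, indels, and quality artifacts are deliberately out of
scope: reads are exact concatenations, so read preparation can be tested
as an inverse function.

## Read preparation

`extract_cassette()` locates both flanks by Hamming-distance matching
(no indels, default one substitution per flank) and accepts the
between-flank substring only at the exact cassette length; if the
forward orientation fails the reverse complement is tried, because the
cassette is double-stranded and sequencing orientation is arbitrary.
Deduplication defaults to exact string identity; a `strand_collapsed`
mode identifies a sequence with its reverse complement (keeping the
lexicographically smaller representative) for the same reason. The
pipeline deduplicates first and samples afterwards; the original
workflow's ordering is not documented, and dedup-then-sample makes the
sampled set's composition independent of PCR duplication depth.
Mean-quality filtering is available but off by default — read-quality
summaries were reported in the original workflow but not used as a
filter.

## Motif discovery

`discover_motif()` is a ZOOPS (zero-or-one occurrence per sequence)
expectation-maximization, the default model of MEME-style motif
elicitation, with OOPS behind a flag. The E-step computes, per
sequence, the posterior over site start positions on both strands (a
reverse-complemented copy of each sequence contributes placements, one
site indicator per sequence across both); the M-step re-estimates the
PWM from posterior-weighted base counts with a pseudocount of 0.25 per
base per column, and the site prior $\gamma$. The background is a
0-order model estimated from the input (floored at 0.01 per base so
degenerate input cannot produce zero background probabilities).

With `palindromic = TRUE` the matrix is averaged with its reverse
complement after every M-step. Because every motif column receives the
same posterior mass, probability averaging equals count averaging, so
this *is* the exact M-step under the reverse-complement symmetry
constraint — per-iteration averaging, rather than one final
symmetrization, keeps the E-step and the constraint consistent.

With pseudocounts the M-step maximizes a Dirichlet-penalized likelihood
(MAP-EM), so the quantity that is guaranteed non-decreasing — and that
the package tracks in `ll_trace`, asserts in its tests, and uses for
the stopping rule (gain < 1e-6, at most 200 iterations) — is the
penalized objective, not the raw likelihood, which can dip by ~1e-3
near convergence.

Each width is fit from 10 data-derived seed w-mers (probability 0.7 on
the seed base), each run for 4 iterations, the best continued to
convergence. The best width in 6–24 minimizes the E-value.

### E-value

The E-value is the number of possible motif placements times the tail
probability that `n_sites` random background sites jointly reach the
observed total log-likelihood ratio. The per-site score distribution
comes from the same quantized dynamic program used for scan p-values
(at a coarser 0.02-log~2~-unit step); the tail of its `n_sites`-fold
sum is an optimized exponential (Chernoff) bound computed in log space,
because the values of interest (10^-2000^ and below) underflow doubles.
This is an information-content-based approximation adequate for its two
uses — ranking candidate widths and confirming planted-versus-shuffled
separation; it is *not* the E-value machinery of any particular motif
suite, and published E-values are not reproduction targets. It is
deterministic, monotone decreasing in the observed total score,
linear in `n_sites` on the log scale at fixed per-site score, and
equals the placement count for a zero-information motif.

### Consensus notation

`consensus_string()` renders the mixed-case/IUPAC notation used in the
field's motif strings: a column writes an uppercase base at ≥ 0.75
top-base frequency; "(X/y)" when the top two bases together reach 0.75
and the runner-up at least 0.20 (lowercased when it is below 0.75 of
the top frequency); "N" below a 0.40 top frequency; otherwise the
minimal IUPAC code over bases ≥ 0.20. The thresholds are package
decisions — no published definition of the casing exists — chosen so
that the bundled degenerate motif model renders in the published
notation pattern, and all four are configurable.

The bundled generating model `tthb099_pwm()` encodes the published
degeneracy pattern with a deliberate detail: the two "N" spacer columns
are tilted slightly (0.31 vs 0.23) toward the consensus base, because a
learned matrix is never exactly uniform and an exact tie would make the
argmax consensus of a recovery run undefined.

## Genome scanning and annotation

`score_distribution()` quantizes each column's four log-odds scores to
integer multiples of a granularity (default 1/1000 log~2~ unit) and
convolves the per-column probability mass functions under the
background — the standard exact-p-value dynamic program. The
enumeration oracle in the test suite bounds the convolution error at
zero on the quantized grid; the granularity bounds the quantization
error itself at `width/2` thousandths of a log~2~ unit and is a
configuration knob. `scan_genome()` reports windows (both strands) with
$p < $ threshold (default $10^{-4}$; the stricter published cut of
$3.95\times10^{-5}$ is a parameter, not a constant), computes
Benjamini–Hochberg q-values over *all* tested windows, and — for a
palindromic matrix, whose two strands score identically at a locus —
merges the strand pair into one record keeping the plus-strand
representation, while still counting both strands as tests.

Coordinates are 1-based inclusive throughout (forced by the span
arithmetic of the published site table, e.g. 81,408–81,423 for a 16-bp
site); the BED writer converts to 0-based half-open exactly.

`annotate_hits()` assigns each hit to the nearest gene on each strand by
absolute TSS-relative location (within 1 kb), so a site in a
bidirectional intergenic region annotates both flanking genes. The
location convention is isolated in `tss_relative_loc()`: the signed
distance of the hit edge nearest the TSS, measured in the gene's
reading direction, negative upstream, with the upstream edge (≤ 0)
reported when the hit spans the TSS. The anchoring edge is not defined
in published Loc tables; nearest-edge is this package's choice and any
alternative needs to change one function. Promoter classification is
interval overlap against the gene's −35/−10/+1 elements with precedence
`overlapping_core` > `upstream_of_minus35` > `downstream_of_minus10`;
promoter elements are consumed as data (an external promoter
predictor's output transcribed to TSV), never computed. The proximal
flag marks the activator-typical window −200..+20 relative to the TSS;
candidate regulated genes additionally must head their operon ("1/n")
or be single transcriptional units ("S").

## Binding kinetics

`fit_global()` fits the 1:1 Langmuir model jointly across analyte
concentrations with shared $k_\text{on}$, $k_\text{off}$, $R_\max$ —
global fitting, because one rate pair per probe across a four-point
dilution series (17/50/150/450 nM) is what the reference measurements
report. Optimization is Levenberg–Marquardt in log-parameter space from
a deterministic 5×5 log-spaced start grid ($k_\text{on} \in
10^3..10^7$ M^-1^s^-1^, $k_\text{off} \in 10^{-5}..10^{-1}$ s^-1^); no
randomness enters the fit. $R^2$ is pooled ($1 - SS_\text{res}/
SS_\text{tot}$ over all points of all traces) rather than averaged per
curve — the published choice is unstated, and pooling matches the
single reported goodness-of-fit per probe. `kd` is stored as
`koff/kon` exactly, never refit. Mass-transport limitation, drift, and
reference-channel subtraction are out of scope: the reference model is
plainly 1:1.

A probe is declared `no_binding` when the maximal absolute response
stays below three times the residual-noise estimate (median over traces
of `sd(diff(response))/sqrt(2)`), reproducing the "no apparent
binding" dash of the reference tables; with many samples the maximum of
pure noise sits near 3.2–3.5 SD, so this rule flags truly flat or
deeply buried signals, not marginal ones. Simulator phase durations
default to 300 s association / 300 s dissociation at 1 s sampling —
plausible instrument settings, configurable, and not a published value.

## Differential expression

`differential_expression()` computes per-gene log~2~ fold-changes
(test minus control group means) with a two-sided Welch t-test and BH
adjustment, emulating a 3-vs-3 deficient-versus-wild-type microarray
comparison. This deviates from the reference analysis, which used a
moderated (empirical-Bayes) t-statistic: with $n = 3$ per group the
p-values differ slightly, so published expression p-values are not
reproduction targets — only recovery of planted effects on synthetic
data is, and the moderated-t implementation available in the
environment serves as an independent cross-check in the tests, never as
the implementation. Input is assumed log2-scale (a `log2_transform`
flag covers linear intensities). Zero-variance/equal-mean genes get
$p = 1$ by convention. `operon_summarize()` aggregates by operon
(member count, median logFC, direction, significant fraction);
`affected_gene_report()` partitions by |logFC| and adjusted-p cuts.

## Problem sizes and determinism

Default experiment sizes are chosen to keep the full test suite and the
acceptance script in the minutes range on one core while leaving the
statistical properties measurable: read pools of 1000 (the size of the
published motif-elicitation input), Monte-Carlo selection pools of
$10^4$, synthetic genomes of 20 kb, 150–200-gene expression matrices,
10–50 seed replicates per stochastic assertion. Every generator is a
pure function of (specification, seed); the pipeline manifest records
MD5 hashes of every stage file, and a rerun with the same configuration
is hash-identical.

## Known limitations

- The occupancy model is single-site, additive, and equilibrium; no
  cooperativity, no binding-site saturation across multiple sites per
  cassette, no kinetic protection model.
- The E-value is a bound, not a calibrated expectation; only its
  ordering is meaningful.
- Synthetic reads carry no sequencing error, so flank-matching
  tolerance is exercised by constructed mutations rather than an error
  model; recovery rates on real, noisier data will be lower.
- The annotation stage trusts its TSS/operon/promoter tables; it does
  not predict any of them.
- Expression simulation is i.i.d. Gaussian on the log scale with no
  probe effects, normalization artifacts, or correlation structure, so
  passing recovery tests demonstrates the statistics, not robustness to
  microarray preprocessing.
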