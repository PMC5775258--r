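---
title: "Methods: kinase substrate screening and nociceptor assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase substrate screening and nociceptor assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociscreen)
```

# The problem

Cdk5 is a proline-directed Ser/Thr kinase whose activity in sensory neurons
rises during inflammation and modulates nociception. Finding its substrates
among nociceptor proteins combines four largely independent computational
tasks: sequence-motif screening of candidate proteins, expression-based
restriction to the nociceptive neuron population, classification of
agonist-evoked calcium responses in cultured sensory neurons, and an
operant-behaviour aversion metric. This vignette documents how each is
modelled here, the defaults and their rationale, and what the synthetic-data
generators do and do not emulate.

# Motif screen

## Patterns

Two patterns are scanned over 1-based residue coordinates, both anchored on
the S/T phospho-acceptor at position *i*:

* **consensus**: `seq[i] ∈ {S,T}`, `seq[i+1] = P` (the obligate proline for
  a proline-directed kinase), `seq[i+3] ∈ {K,H,R}`;
* **T/SxxH**: `seq[i] ∈ {S,T}`, `seq[i+3] = H` — the tetrapeptide that
  stabilises the helix–turn–helix fold of ankyrin repeats.

The two overlap exactly when the consensus +3 residue is His; such sites are
reported once with class `both`. Overlapping matches are all reported and
never deduplicated. `X` residues match neither pattern and contribute zero
to any PSSM score. All coordinates exposed to the user are 1-based
inclusive; nothing internal leaks 0-based indices.

## Scoring

Kinase preference beyond the hard pattern is expressed as a
position-specific scoring matrix over offsets −4..+5 around the acceptor:
the score of a site is the sum of per-position weights of the observed
residues, with off-sequence offsets contributing 0. The matrix is an
**input** (TSV, offset × residue): empirically derived Cdk5 preference
matrices exist in the literature but their weights are not redistributable
here, so the package ships only a neutral all-zero default
(`uniform_pssm()`) and reads any user matrix with `read_pssm()`.

## Topology filtering

A cytoplasmic kinase cannot reach residues inside the membrane or outside
the cell, so sites whose acceptor falls in an annotated transmembrane or
extracellular segment are excluded. Sites at *unannotated* positions are
kept and labelled `unknown` rather than dropped: the biologically motivated
rule excludes only demonstrably inaccessible sites, and most proteins have
partial annotations at best. The filter is idempotent.

## Peptide windows

In vitro kinase assays use 10-mer peptide substrates. The window is
`acceptor−3 .. acceptor+6`, which places the acceptor at window position 4
and the obligate proline at position 5; this reproduces all six published
decapeptide substrates of mouse TRPA1 exactly (`trpa1_peptide_records()`).
Windows clipped at a sequence end are returned shorter and flagged.

## The synthetic TRPA1 stand-in

`synthetic_trpa1_record()` is a deterministic *synthetic* protein of the
real mouse TRPA1 length (1125 aa) whose only motif matches are the six
decapeptide windows planted with their acceptors at residues 101, 134, 242,
416, 449 and 485 — inside a cytoplasmic segment spanning the N-terminal
ankyrin-repeat region (1–720), with 721–960 marked transmembrane. It
validates scanner, topology and window logic against the known site
positions; its background is random sequence and supports no biological
conclusion about the flanks. Analyses of the true channel should load the
real sequence from a sequence database.

# Expression and coexpression

Positivity is `FPKM ≥ threshold` with threshold 5 by default; the
comparison is **inclusive**, a deliberate choice where convention is silent,
and the threshold is everywhere a parameter. Prevalence is the percentage of
positive cells; the conditional coexpression fraction
`coexpression_fraction(a, b)` is the percentage of `a`-positive cells also
positive for `b`, asymmetric by construction, and undefined (NA with a
warning) when no cell is `a`-positive.

The network edge rule is an explicit definition rather than a reconstruction
of any published figure: an undirected edge joins two genes when the
*smaller* of their two conditional fractions (scaled to \[0, 1\]) reaches
`edge_threshold` (default 0.5), and the edge weight is that minimum.
Requiring the minimum makes the rule symmetric and prevents a ubiquitous
gene from linking to everything merely by being common. The rule and its
threshold are configurable because co-positivity counts or correlations are
equally defensible choices.

FPKM normalisation itself is upstream of this package: matrices are
consumed as given, and missing values are rejected at ingestion rather than
imputed.

# Calcium imaging

The Fura-2 measurement chain is: ratio = F340/F380 per 2 s frame (any
uniform interval is accepted); relative response = ratio divided by the
mean of the **five** samples immediately preceding the first application,
making the pre-stimulus level exactly 1; amplitude fold = maximum of the
relative trace inside a stimulus window (application plus washout).
Conversion to absolute calcium uses the standard ratiometric relation
`[Ca2+] = Kd · β · (R − Rmin)/(Rmax − R)`; it is optional, provided for
calibrated rigs, and errors at `R ≥ Rmax` (dye saturation).

The responder cutoff is defined statistically: mean + 3 sample SD of the
peak folds of the non-responsive population, which evaluates to 1.15-fold
when that population has mean 1.00 and SD 0.05. Two entry points exist
because delimiting "the non-responsive population" is itself a choice:
`responder_threshold()` takes an explicitly supplied population, and
`derive_threshold()` takes all peaks, splits at a provisional cutoff
(default 1.15), applies the rule to the sub-cutoff mode and refines the
split once. Classification is inclusive (`fold ≥ cutoff`).

A strong low-dose response that has not decayed by the next application
makes the later amplitude uninterpretable. The flagging rule: the level just
before the later onset (mean of the preceding five samples) must have
fallen below `baseline + recovery_fraction × (low-dose peak − baseline)`;
`recovery_fraction = 0.5` is this package's operationalisation of "partial
recovery" and is configurable and recorded in run manifests. Flagged
windows get `NA` amplitude but the neuron may still be counted a responder
from the peak in its own window — an elevated plateau is evidence of
response, not its absence.

Population statistics use the **mouse** as the unit of analysis. Responder
counts per stimulus are normalised to the number of KCl responders of the
same mouse (KCl depolarisation defines the excitable population), and by
default the numerator is gated to KCl-responsive neurons so percentages
cannot exceed 100; the gate is a flag because the alternative reading
(ungated numerator) is also coherent. Mice with zero KCl responders yield
NA with a warning. Group comparisons (`group_compare`) wrap the classical
unpaired two-sided t-test (equal variances by default, matching standard
practice in this assay literature) and one-way ANOVA, applied to per-mouse
values only.

# Behaviour

Aversion is `100 × mean(licks under agonist) / mean(licks under water)` per
animal. Baseline is the mean over all water sessions by default (a last-k
option exists since habituation can drift early sessions); normalising per
animal *before* averaging across animals was chosen over pooling sessions
so that high-licking animals do not dominate the group mean. The default
concentration grid is 1, 10, 100, 1000 µM. Values above 100% are
meaningful: they indicate less aversion than baseline.

# Synthetic data

The generators produce every input format the pipeline reads, with truth
tables, under a fixed seed (identical seed ⇒ identical output, and the
caller's RNG stream is left untouched).

* **Proteomes**: uniform-random background over the 20 canonical residues,
  *scrubbed* of chance motif matches before planting, so the truth table is
  exact rather than probabilistic — the uniform background is documented as
  a modelling simplification (real proteomes have biased composition).
  Topology is three equal segments (cytoplasmic, transmembrane,
  extracellular) per protein.
* **Single-cell matrices**: per-gene Bernoulli positivity, log-normal FPKM
  above the threshold for positive cells and uniform sub-threshold values
  otherwise, optional dropout (zeroing positive measurements), and optional
  nested positivity pairs for exact 100% conditional fractions.
* **Traces**: a two-population mixture. Responder peak folds are
  `Normal(1.45, 0.08)` by default — inside the 1.3–1.6 range typical of
  low-dose agonist responses in this preparation — and non-responder peak
  folds are `Normal(1.00, 0.05)`, the population the 3-SD rule is
  calibrated on. Transients are double-exponential (rise τ 8 s, decay τ
  30 s): sampling interval and application duration mirror the assay (2 s,
  30 s) but the kinetics are generator parameters, not measured values. A
  configurable fraction responds to the terminal KCl pulse (default 1);
  desensitized responders simply do not decay after the low dose. Default
  schedule: low dose 60–90 s, high dose 150–180 s, KCl 240–270 s, 300 s
  total.
* **Lick sessions**: Poisson counts around a planted percent-of-baseline
  effect per genotype and concentration, five sessions per condition.

What passing tests on these fixtures shows: the implementation computes its
defined statistics correctly and recovers planted signal at realistic sizes.
What it does not show: robustness to real-data pathologies the generators
omit — motion artifacts and photobleaching in imaging, compositional bias
and batch structure in sequencing, habituation drift in behaviour.

# Numerical choices and problem sizes

Baseline normalisation requires ≥ 5 pre-stimulus samples and errors
otherwise; the responder-cutoff rule requires ≥ 2 values; degenerate
(zero-variance) groups propagate the standard `t.test`/`aov` behaviour.
Ties at thresholds always resolve inclusively (≥), in binarization and in
responder classification alike.

Test problem sizes were chosen as the smallest that make the statistical
assertions sharp: scanner/oracle equivalence over 1,000 random 150-mers;
responder-fraction recovery at 200 neurons × 20 seeds per planted fraction
(binomial 95% half-width ≈ 1.5 percentage points at p = 0.4); prevalence
recovery at 10,000 cells (±2 points); and the t-test's type-I error at
10,000 null replicates of 7 + 7 mice (Monte-Carlo SE ≈ 0.2 points).

# Known limitations

* The screen finds *candidate* sites; phosphorylation is a biochemical
  question the package does not model (four of the six TRPA1 candidate
  peptides act as substrates in vitro; two do not).
* No transmembrane-topology prediction: annotations are inputs.
* The synthetic TRPA1 stand-in shares only length and site positions with
  the real channel.
* Published group differences between genotypes depend on real animals and
  are represented here only as recovery properties on synthetic data.
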