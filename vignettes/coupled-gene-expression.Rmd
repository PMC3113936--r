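---
title: "Modeling coupled transcription and translation at sequence level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling coupled transcription and translation at sequence level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

txtlsim simulates prokaryotic expression of a single gene with transcription
resolved to the nucleotide and translation to the codon, coupled through the
nascent mRNA: ribosomes load as soon as the ribosome binding site (RBS)
emerges from under the RNA polymerase (RNAp) and can never pass the
transcription exposure front. This vignette describes the model, the design
choices behind the implementation, and what the shipped experiments do and
do not demonstrate.

```{r setup}
library(txtlsim)
```

## The reaction model

**Transcription.** A free RNAp binds the promoter as a bimolecular event
(propensity `k_eff / n_rnap * [free RNAp]`, default `k_init = 0.015` per
RNAp with 28 RNAp, i.e. a mean binding wait of ~2.4 s). Binding is followed
by the closed/open complex formation, a *delayed* event whose duration is
drawn from a normal distribution with mean 40 s and standard deviation 4 s,
re-sampled in the (practically impossible, ~10 sigma) event of a
non-positive draw. After promoter clearance (rate `k_m = 114 /s`) the
polymerase steps along the template one nucleotide at a time; each step is a
movement (rate `k_m`) followed by an activation (rate 114 /s, or 30 /s on
the first ten nucleotides, modeling slow promoter-proximal steps). Each
RNAp occupies `2 * 12 + 1 = 25` nucleotides and footprints exclude one
another, so polymerases queue and never overtake.

Competing with elongation at every activated position are: ubiquitous
pausing (`k_p = 0.55 /s`, mean dwell 3 s), arrest (`k_ar = 2.8e-4 /s`, mean
100 s), transcript editing (`k_ec = 8e-3 /s`, mean 5 s), premature
termination (`k_pre = 1.9e-4 /s`), pyrophosphorolysis (one nucleotide
backwards at `k_pyro = 0.75 /s`), and — at the final nucleotide — release
(`k_f = 2 /s`). A paused polymerase abutted by an activated trailing
polymerase can be pushed back into activity at rate `k_m` (collision
release), and an activated polymerase abutting a paused leader can itself be
collision-paused; arrests and editing are not released by collisions.
Sequence-specific pause and arrest sites are annotations on single
nucleotides: the first time a polymerase arrives there it triggers with the
site's probability and then dwells at rate `1 / mean_duration`.

**Pause, arrest and editing dwells are memoryless.** The mean dwells
(3 s, 100 s, 5 s) are implemented as exponential release channels at `1/tau`
rather than fixed delays. This is a deliberate design choice: collision
release must be able to interrupt a pause at any moment, which a fixed
delay cannot represent. The means match the quoted dwells exactly.

**Translation.** Each transcript is a run-time *compartment* with its own
reaction channels. Translation initiation (`k_trans_init = 0.33 /s`,
pseudo-first-order; the free-ribosome pool is tracked and must be positive)
requires the first `2 * 15 + 1 = 31` ribonucleotides (the RBS) to be
exposed, intact, and outside every bound ribosome's footprint. A binding
ribosome starts with its active site at the first codon boundary
(ribonucleotide 3), awaiting activation of codon 1. Elongation of one codon
is three translocation sub-steps (`k_tm = 1000 /s` each, one ribonucleotide
each) followed by a codon-specific activation: class rates
`k_transA = 35`, `k_transB = 8`, `k_transC = 4.5 /s`, with optional explicit
per-codon overrides. Competing events are back-translocation
(`k_bt = 1.5 /s`, one codon backwards; re-activating a codon never
double-counts the peptide bond), drop-off (`k_drop = 1.14e-4 /s` as a
continuous per-ribosome hazard), and trans-translation
(`k_tt = 5.2e-5 /s` per bound ribosome) which destroys the strand and
returns every ribosome to the pool — detaching the RNAp too if the strand
was still being transcribed. At the stop codon (the final codon of the
sequence; no release factors are modeled) completion fires at
`k_trans_f = 2 /s`, faster than initiation so no queue forms at the stop.
The finished peptide folds/activates at `k_fold = 2.4e-3 /s` and the active
protein degrades at `k_dec = 1.7e-3 /s`.

**mRNA degradation** is first-order per transcript (`k_dr = 0.011 /s`) and
gradual: the firing destroys the RBS region (no new initiations), bound
ribosomes complete their proteins, and the remainder of the strand is
removed when the last ribosome leaves. Degradation does not abort an RNAp
still transcribing the template; the strand is simply never again
translation-competent. Premature termination freezes the exposure front:
ribosomes already on board translate up to the front and stall, removable
only by drop-off or trans-translation, and the compartment is destroyed
when the last one leaves (immediately if none is bound). Pyrophosphorolysis
can retract the most recently exposed ribonucleotide, but the backward move
is blocked when a ribosome occupies it.

**The functional-mRNA observable** counts compartments that are
translation-competent: RBS exposed, not degradation-marked, not prematurely
terminated. This is the "mRNA level" used in all noise statistics, chosen
because the model's coupling of interest is through translation-competent
transcripts; a strand whose RBS is gone is invisible to ribosomes even
though its 3' remnant may persist.

## The simulation algorithm

The dynamics follow the delayed stochastic simulation algorithm: a direct
SSA over a dynamic set of propensity slots, plus a wait list for delayed
products (here, the open-complex completion). When the sampled exponential
waiting time would cross a queued release, the release is applied first and
the waiting time re-sampled. Simultaneous releases are handled
first-in-first-out for reproducibility.

Compartments and ribosomes register and deregister propensity slots at run
time; a Fenwick tree over the slots gives O(log n) selection and update,
and after an event only the entities whose gates could have changed (the
firing entity, its lattice neighbours, its compartment, the promoter and
the pools) are recomputed. The tree is rebuilt every 2^24 events to shed
floating-point drift. All randomness comes from R's RNG, so `set.seed()`
(or the `seed` arguments) makes any run bit-reproducible. A channel-slot
census is returned with every run: when a run ends with an empty reaction
vessel the census must equal the baseline (promoter + protein pools), which
the test suite asserts — the run-time creation and destruction of channels
leaks nothing.

An optional audit mode (`check_invariants = TRUE`) verifies at every sample
instant: disjoint RNAp footprints and no overtaking, disjoint ribosome
footprints, every ribosome at or behind its exposure front, RNAp and
ribosome conservation, and consistency of the mRNA observable.

## Tunable parameters that matter most

* `k_eff` (s^-1): effective transcription-initiation propensity at a full
  RNAp pool. This is the repression axis — the package never models
  repressor molecules; lowering `k_eff` *is* repression.
* `k_trans_init` (s^-1): translation initiation; the RBS-strength axis.
  Note the realized initiation rate saturates at roughly
  `1 / t_RBS` where `t_RBS` (~2 s at class-A speeds) is the time the
  previous ribosome needs to clear the RBS.
* `k_dr`, `k_dec` (s^-1): mRNA and protein turnover; they set the
  correlation times of the two noise observables, hence how long a
  simulation must run to estimate CV^2 well.
* Footprints `delta_rnap = 12`, `delta_rib = 15`: exclusion ranges; the RBS
  width and the collision geometry derive from them.

## Synthetic sequences

`generate_random_gene()` draws codons i.i.d. from a 61-codon sense-codon
frequency table (shipped default: standard E. coli K-12 usage) and ends
with a stop. `make_lacz_fixture()` builds a 3072-nt strand structurally
emulating the lacZ constructs used in ribosome-queuing experiments: 23
unevenly spread ATG codons shared across variants, and 24- or 48-codon
glutamate stretches forced to the slow class C at mid-gene. These are
structural emulations — the real lacZ and construct sequences, and their
exact insert coordinates, are not reproduced.

The codon-class map shipped with the package is a heuristic: classes A/B/C
assigned from codon-usage tertiles (frequent = fast), standing in for
directly measured per-codon rates. It is a plain TSV that users can
replace, and explicit per-codon rates (`specific_rates`) override classes
wherever supplied (the four codons known to have specific measured rates
default to none, since those values are not part of this package's
sources).

## The analysis statistics

* `cv2()` — variance over squared mean, the noise measure. In the scan
  protocol the replicate series are concatenated before computing CV^2
  (a per-replicate variant is trivial to compute from the same output;
  concatenation is the recorded protocol).
* `cross_correlation()` — the normalized discrete cross-correlation for m
  replicate pairs: per lag `tau`,
  `r(tau) = mean_i [ sum_t (x_t - m_x)(y_{t+tau} - m_y) / ((n - tau) s_x s_y) ]`
  with full-series means and *population* (1/n) standard deviations, which
  makes `r(x, x, 0) = 1` exactly. `max_correlation()` scans lags with ties
  broken toward the smaller lag.
* `interval_stats()` — consecutive-event intervals with mean, CV^2,
  skewness and Sarle's bimodality coefficient. A CV^2 well below 1 marks
  the Gaussian-like transcription-initiation intervals (open-complex
  dominated); CV^2 near 1 the exponential-like translation-initiation
  intervals.
* `burst_stats()` — proteins per compartment lifetime (burst sizes,
  including zeros) and intervals between first productions of consecutive
  compartments.
* `methionine_curve()` — pulse-labeling emulation: methionine-codon
  activations after the pulse by the labeled ribosome cohort, normalized by
  (methionines per protein) x (cohort size). By default the cohort is
  restricted to ribosomes that finish their protein, so the curve plateaus
  at exactly 1 and its shape reads out elongation speed; without that
  restriction, losses to drop-off and trans-translation depress the
  plateau.
* `compensate_degradation()` — sets `k_dr` and `k_dec` so mean mRNA and
  protein levels match shared targets across a scan. The analytic pass
  models the initiation cycle, premature-termination thinning, RBS
  occlusion (effective `k_tr`), and the trans-translation contribution to
  functional-mRNA death; an optional pilot-run loop corrects
  multiplicatively to within 5%.

## Study designs and problem sizes

The shipped experiment runners default to desk-scale designs chosen to
finish in minutes on one CPU while keeping every estimate honest. The
paper-scale protocol (100 replicates of 1e5 s after steady state) is
available behind `--paper-scale` in the CLI and by passing the
corresponding arguments.

* **Noise scan** (`run_noise_scan`): grids of `k_eff` in {0.01, 0.045, 0.2}
  and `k_tr` in {0.03, 0.1, 0.33} s^-1, 4 replicates of 15,000 s after a
  2,500 s burn-in, sampled every 2 s, with targets mean mRNA = 2 and mean
  protein = 30 (the protein target is deliberately modest so that the
  compensated `k_dec` keeps the protein correlation time well below the
  measuring window). The default burn-in covers at least five protein
  half-lives at the compensated decay rates across the default grid.
  The headline trends — mRNA noise falling with `k_eff`, protein noise
  falling with `k_eff` and rising with `k_tr`, the maximum mRNA-protein
  correlation rising with `k_tr` and falling with `k_eff` — are asserted on
  the marginal means of the grid (each trend read on a 3-point scan
  averaged over the other factor), which is the statistically stable
  readout of a stochastic 3 x 3 grid at this scale. Very low `k_eff`
  (< ~5e-3 at these targets) mixes too slowly for desk-scale CV^2
  estimates and is outside the default grid.
* **Pause-noise experiment** (`run_pause_experiment`): a single long-pause
  site at nucleotide 2900 (near the gene end, where ribosome pile-up
  maximizes the effect), his-like 70% trigger probability, mean dwells of
  100 s and 500 s versus an unannotated baseline, shared replicate seeds.
  The desk design sets `k_dec = 0.01 /s`: with a protein lifetime
  comparable to the pause durations, production stalls register as protein
  dips instead of being integrated away, so the *sign and ordering* of the
  noise increase is resolvable in minutes. The baseline-relative CV^2
  changes at the slower default turnover (the percent-level effects) are a
  paper-scale measurement — hours of compute — not a desk-scale one.
* **Methionine pulse** (`run_methionine_experiment`): pulse at 300 s,
  labeled cohort = initiations within the following 300 s, curves sampled
  every 10 s. Half-incorporation times order wild type < insert24 <
  insert48; the 24-versus-48 gap is only ~15 s on a ~200 s rise, so several
  replicates are needed before the ordering emerges from strand-level
  transcription noise (arrests and long pauses hit whole cohorts riding one
  transcript).

What passing these desk-scale suites shows is that the mechanisms and their
directions are implemented faithfully; it does not pin down the paper-scale
effect magnitudes, and none of the synthetic sequences reproduce real
genome sequence features (codon correlations, structured pause sites,
RNase-mediated decay pathways).

## Numerical and degenerate-input choices

* Open-complex delays: truncated at zero by re-sampling; with mean 40 and
  sd 4 truncation is a ~1e-23 event.
* The promoter-proximal slow-activation boundary uses the active-site
  position, 1-based inclusive (positions 1-10 slow).
* Simultaneous delayed releases: FIFO. Correlation ties: smaller lag.
* A gene must have at least two codons; its length must be a multiple of
  three; the final codon is the stop.
* Genes shorter than the 31-nt RBS can only initiate translation after
  transcription completes (the front then jumps to the full length).
* `cv2()` refuses a non-positive mean; `cross_correlation()` refuses
  zero-variance series; the scan drops zero-variance replicate pairs from
  the correlation (with a warning) rather than failing the whole grid.
* Event-type codes, counters and the channel census are returned with every
  run so ledgers (initiations = completions + drop-offs + rescues + still
  bound) can be audited from the outside.

## Known limitations

* No mechanical RNAp-ribosome coupling: the pioneering ribosome neither
  pushes nor rescues the polymerase (and a paused RNAp does not pause
  ribosomes other than by halting the front).
* No abortive initiation, supercoiling, endonucleolytic decay variants, or
  explicit tRNA/initiation/release factors; repression is an effective
  rate, not a molecule.
* One gene per simulation; no cell growth, division or dilution.
* The codon-class default is a usage-based heuristic, not measured rates.

## A worked example

```{r example, eval = FALSE}
gene <- make_lacz_fixture("wt")
sim <- simulate_expression(gene, kinetic_params(), t_end = 5000, seed = 1,
                           sample_interval = 2, kymograph_interval = 2)
glance(sim)
autoplot(sim)
plot_kymograph(sim, "rnap")

scan <- run_noise_scan(gene, replicates = 3, seed = 1)
autoplot(scan, metric = "cv2_protein")
```
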