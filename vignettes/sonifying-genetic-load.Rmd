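---
title: "Sonifying the realised genetic load of virtual crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sonifying the realised genetic load of virtual crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonicload)
```

## The load model

`sonicload` quantifies genetic load as sums of per-variant mutation-impact
scores (CADD-like, PHRED-scaled, dimensionless). Scores are inputs: the
package never rescales them, and computing them is out of its scope. The
load of an individual splits into two components. The **realised load** is
what reduces fitness now: a variant of score $s$ contributes $s$ when
homozygous, $h\,s$ when heterozygous with dominance coefficient
$h \in [0,1]$, and $s$ from a single copy at a hemizygous sex-linked site in
the heterogametic sex (the female, in birds). The **masked load**,
$(1-h)\,s$ per heterozygous variant, costs its carrier nothing but is the
reservoir that inbreeding converts into realised load. At $h = 0$ the two
components exactly partition the carried load — a property the test suite
checks on random populations.

The default $h = 0$ reflects the fully recessive worst case that drives
inbreeding depression; the coefficient is exposed everywhere because real
deleterious variants are rarely all fully recessive, but no single published
value fits all variants, so the package does not guess one.

Loads are aggregated per genome **scaffold**, the unit that later maps to
one melody note. Scaffold order is lexicographic by name, chosen for
stability across outputs rather than biological meaning, and enforced with
a byte-order (`radix`) sort so it cannot drift with the locale. Missing
genotypes contribute zero with a warning — resequencing data are sparse and
failing an entire profile over one uncalled site would be worse — but an
individual with no called genotype at all is an error.

## Virtual crosses

Mendelian segregation makes a parent of dosage $d$ transmit the deleterious
allele with probability $p = d/2$, independently across variants (linkage is
deliberately ignored: the method works at scaffold-sum level, where
within-scaffold covariance between two parents' transmissions does not move
the expectation). The expected realised contribution of a variant to an
offspring of parents $A$ and $B$ is

$$s\left(p_A p_B + h\,[p_A(1-p_B) + p_B(1-p_A)]\right),$$

which for selfing reduces to $s\,p^2$ at $h=0$. The expectation is the
primary output; a seeded per-gamete sampler (`sample_offspring()`) exists
for validation and teaching, and the tests show its Monte-Carlo means
converge to the expectation within three standard errors at $N = 10{,}000$.

"All possible crossings" means all **ordered** pairs including selfing:
$n$ founders give $n^2$ crosses, matching the 36-cross layout of the
deposited-style data tables (unordered pairs with selfing would give 21).
Expected profiles are symmetric in the parents, so the duplication is
harmless and keeps the table layout predictable. Selfing crosses are kept
because they illustrate extreme inbreeding vividly in the game.

Sex-linked variants are scored as autosomal by default (typical variant
tables carry no sex-chromosome annotation). An opt-in mode treats offspring
sex as a 50/50 mixture, scoring the heterogametic offspring hemizygously on
the homogametic parent's transmission probability; it requires both parent
sexes to be known and exactly one homogametic parent.

## The sonification transform

Each scaffold's load score is mapped to a MIDI pitch-bend value in two
steps: round to the nearest multiple of the **quantum** (default 5, ties
away from zero — deterministic and spreadsheet-familiar), then multiply by
the **scale** (default $-20$), yielding downward-only detuning that leaves
low loads audibly in tune. Values are clamped at the 14-bit signed floor
$-8192$; the MIDI standard's signed bend range is $[-8192, +8191]$ and the
mapping never produces positive values. With the conventional default bend
range, $-8192$ is two semitones flat.

One consequence of the round-then-scale order is worth documenting: a
maximum load score of 376 quantises to 375 and maps to $-7500$, whereas
scaling the unrounded maximum gives $-7520$. Quoted bend-range floors
derived from an unrounded maximum therefore sit 20 units below what the
production path emits; `load_to_pitchbend(x, quantum = 1)` reproduces the
unrounded mapping when that convention is wanted.

`detune_melody()` inserts one pitch-bend event immediately before each note
onset (the bend inherits the onset's tick delay; the onset follows at delta
zero), so the note sounds off-key but steady — a wrong *note*, not a bent
one. The first `skip_prefix` onsets (default 4) are left completely
untouched, giving listeners an in-tune reference; they receive no zero-value
bend either, the minimal-diff reading of an undetuned prefix. A melody with
fewer onsets than `skip_prefix + length(scores)` is an error naming both
counts — silently truncating a load profile would misrepresent the genome —
and so is polyphony, because pitch bend is channel-wide and would detune any
simultaneously sounding neighbour. No bend-range RPN setup is emitted by
default (General MIDI synthesisers default to ±2 semitones); `emit_rpn =
TRUE` prepends the explicit RPN 0 messages for strict synthesisers.

MIDI files are read and written by a purpose-built Standard MIDI File layer
(`read_melody()` / `write_melody()`): format 0, or format 1 with a single
note-bearing track whose sibling meta tracks are merged at absolute times.
Running status is expanded on read and the `note_on`-velocity-0 release
dialect is normalised to `note_off`, so onsets are exactly the `note_on`
rows; the writer emits velocity-0 releases as `note_on` 0, no running
status, and a fresh end-of-track meta. Round trips are lossless at the
event level, which the tests verify byte-up from hand-assembled files.

## The game and its evaluation

`rank_crosses()` orders candidate offspring by total expected realised load
(ascending; ties break lexicographically by cross id so the ranking is a
deterministic function of the data). Survey answers are tallied per option
with percentages to one decimal place, and the count of respondents who
named both the most and the least optimal offspring is tested against the
random-guessing null with an exact one-sided binomial test. For $k$
presented offspring a random ranking gets both extremes right with
probability $1/(k(k-1))$ — $1/6$ for three. The upper tail
$P(X \ge x)$ is computed through the binomial CDF in log space, so
survey-scale evidence does not underflow: for 62 double-correct answers out
of 98 the exact tail is $7.3\times10^{-25}$, agreeing with brute-force pmf
summation to full precision. Normal-approximation shortcuts can claim
considerably smaller bounds for the same data; the package reports the
exact value.

## What the synthetic data emulates — and what it does not

`generate_population()` stands in for a small sequenced founder cohort: 6
diploid individuals, 658 deleterious SNPs spread over 100 scaffolds (each
scaffold carries at least one SNP so every melody note has a scaffold),
deleterious-allele frequencies drawn from Beta(0.5, 2) — right-skewed, most
harmful alleles rare — and founder genotypes in Hardy–Weinberg proportions.
Impact scores are Gamma(shape 2, scale 20); the scale was fixed by a one-off
calibration so that the maximum expected per-scaffold offspring load across
all 36 crosses stays within the working range (0, 376] in at least 95% of
seeds (empirically all of 60 calibration seeds), with cross totals spanning
roughly 2,000–4,000 — the magnitude regime the sonification mapping was
designed for. These distributions are stand-ins chosen for plausibility,
not estimates from data: the generator has no linkage, no site-frequency
spectrum from demography, no relatedness among founders and no genotyping
error. Passing tests on this material therefore validate the *bookkeeping
and mapping*, not population-genetic realism. `check_load_range = TRUE`
re-derives all cross profiles and errors if the calibration ceiling is
exceeded, suggesting a parameter change.

`generate_melody()` is likewise a stand-in for a transcribed familiar
melody: a seeded random walk on an A-minor scale in straight eighth notes,
strictly monophonic on one channel, 104 onsets by default so that 100 notes
remain after the reference prefix. The detuning algorithm is
melody-agnostic by design — any monophonic single-channel SMF works.

`generate_responses()` models listeners who answer each question
independently with stated success probabilities, errors uniform over the
wrong options; colliding most/least picks (possible only through a wrong
answer) are resolved by resampling the wrong member within its wrong set,
which keeps the per-question correctness marginals exact while guaranteeing
distinct answers.

## Numerical and degenerate-input choices

Tie rounding at half-quantum is away from zero, fixed and undocumented in
the interface on purpose. Profile scores are plain doubles; totals equal
profile sums to numerical tolerance by construction. An empty score vector
detunes nothing and returns an event-identical track; an all-zero profile
inserts value-0 bends, audibly the identity. A variant-free population is
valid and produces empty load tables. Dosage 2 at a hemizygous site in a
heterogametic carrier is rejected at population construction and again at
scoring. The VCF importer maps ALT dosage to deleterious dosage only when
the deleterious allele is declared, and drops sites lacking the impact-score
INFO key with a warning.

## Problem sizes in the test suite

Property checks run at deliberately small scale: expectation-versus-
enumeration oracles on populations of at most 20 variants (tolerance
$10^{-12}$), Monte-Carlo convergence at $N = 10{,}000$ offspring within
three standard errors, generator calibration and the selfing-versus-outbred
contrast over 50 seeds of the full default population, and binomial
agreement with direct summation for all $n \le 30$. These sizes give the
properties real statistical teeth while keeping the whole suite fast.

## Known limitations

Kinship and pedigree-based management (inbreeding coefficients, founder
genome equivalents) are out of scope, as are multi-generation breeding
simulation, audio rendering to waveforms (use any DAW or GM synthesiser on
the written `.mid`), melody transcription, and the computation of the
impact scores themselves. Linkage is ignored throughout; per-scaffold
expectations are exact under that assumption, but variances (and any
statistic beyond the mean) are not. The survey layer analyses forced-choice
answers only, not free text.
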