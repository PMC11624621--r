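# sonicload

Genomics-informed captive breeding tries to pair founders so that their
offspring inherit as little *realised* genetic load as possible: harmful
recessive variants hurt fitness mainly when an offspring receives two copies
of the same allele, which happens most often when related parents share the
same deleterious variants. `sonicload` implements the full pipeline from
founder genotypes and per-variant mutation-impact scores (CADD-like weights)
to the expected realised load of virtual offspring — and then makes that
load *audible*, by detuning the notes of a familiar melody with MIDI
pitch-bend messages, one note per genome scaffold. It was designed around a
captive pink-pigeon founder set (six genome-sequenced birds, 658 deleterious
SNPs on the 100 largest scaffolds), but every dimension is a parameter.

It is aimed at conservation-genomics practitioners and science
communicators: the former get the load bookkeeping and mate-pair ranking,
the latter get a sonification game in which listeners pick the most and
least optimal offspring by ear, plus the machinery to score their answers.

## The model

For a variant with impact score *s*, dosage *d* of the deleterious allele
and dominance coefficient *h* (default 0, fully recessive):

* **realised load** contribution: *s* if *d* = 2, *h·s* if *d* = 1, and *s*
  for a single copy at a hemizygous (sex-linked) site in the heterogametic
  sex — the component that reduces fitness in the current generation;
* **masked load** contribution: (1 − *h*)·*s* if *d* = 1 — hidden in the
  carrier, convertible to realised load by inbreeding.

Virtual crosses assume Mendelian segregation: a parent with dosage *d*
transmits the allele with probability *p* = *d*/2, independently across
variants. The expected realised contribution of a variant to an offspring of
parents A and B is

&nbsp;&nbsp;&nbsp;&nbsp;*s* · ( p<sub>A</sub> p<sub>B</sub> + h ( p<sub>A</sub>(1 − p<sub>B</sub>) + p<sub>B</sub>(1 − p<sub>A</sub>) ) )

summed per scaffold (scaffolds ordered lexicographically by name) and over
scaffolds for the cross total. All ordered parent pairs are enumerated,
including selfing crosses (n founders → n² crosses) that illustrate extreme
inbreeding. The **shared load** of two parents — the sum of *s* over loci
where both carry the allele — predicts offspring homozygosity risk.

Sonification maps each scaffold's load to a downward pitch bend: scores are
rounded to the nearest multiple of 5 (so small loads stay in tune) and
multiplied by −20, clamped to the 14-bit floor −8192 (±2 semitones at the
default bend range). The bend is inserted immediately before each note
onset, after an undetuned 4-note reference prefix; a 104-note melody
therefore carries one detuned note per scaffold of a 100-scaffold profile.

Listener performance on "pick the most and the least optimal of k
offspring" is tested against the exact binomial null π = 1/(k(k−1)) (1/6
for three offspring), with the upper tail computed in log space.

## Worked example

```r
library(sonicload)
v <- read_variants(system.file("extdata", "example_variants.csv", package = "sonicload"))
g <- read_genotypes(system.file("extdata", "example_genotypes.csv", package = "sonicload"))
pop <- load_population(v, g)
pop
#> <load_population> 3 individuals, 5 variants on 2 scaffolds

res <- expected_offspring_profile(pop, "PP1", "PP2")
res
#> <cross_result> PP1xPP2 - expected realised load 2.75 over 2 scaffolds
res$profile
#> # A tibble: 2 x 2
#>   scaffold score
#>   <chr>    <dbl>
#> 1 scafA     1.75
#> 2 scafB     1

shared_load(pop, "PP1", "PP2")
#> [1] 11

head(as.data.frame(rank_crosses(cross_totals(cross_all(pop)))), 3)
#>   cross_id total rank
#> 1  PP2xPP3   0.0    1
#> 2  PP3xPP2   0.0    2
#> 3  PP1xPP3   1.5    3
```

The expected load of PP1×PP2 is 2.75: e.g. on `scafA`, variant `v1`
(score 5, PP1 homozygous, PP2 non-carrier) cannot become homozygous, while
`v2` (score 7, both heterozygous) is homozygous with probability 1/4,
contributing 1.75. The ranking says PP2×PP3 offspring carry the least
expected load — the pair a breeding programme (or a winning player) would
choose. `shared_load` flags PP1×PP2 as riskier: they share 11 points of
load at the same loci.

Sonifying is one call per cross:

```r
mel <- generate_melody(n_notes = 104, seed = 1)   # or read_melody("melody.mid")
load_to_pitchbend(c(2.4, 33.2, 100, 376))
#> [1]     0  -700 -2000 -7500
pop6 <- generate_population(seed = 1)             # six founders, 100 scaffolds
det <- detune_melody(mel, profile_scores(cross_all(pop6), "PP2xPP6"))
write_melody(det, "offspring_C.mid")              # play in any GM synth
```

and the survey layer reproduces published-style summaries:

```r
binomial_exact_upper(62, 98, pi0 = 1/6)
#> [1] 7.285095e-25
```

Command-line wrappers over the same functions live in `inst/cli/`
(`simulate.R`, `sonify.R`, `survey.R`); see each file's header for usage.

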