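---
title: "The senesim model: life-history evolution in an age-structured individual-based simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The senesim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

senesim simulates a population of individuals in discrete time. Each
individual carries an age (in simulation steps), a life phase (egg or
living), an infection status, and a heritable genome: two haplotypes of
bits. The environment carries a step counter, the number of consecutive
steps the population has spent above the carrying capacity, a predator
count, and a drift map recording which allele is currently beneficial at
each locus.

Each step executes a configurable sequence of processes (default order:
intrinsic mortality, abiotic mortality, infection, predation, starvation,
reproduction, aging, environmental drift). Within a process, every
individual's outcome depends only on the state at the start of that
process — a parallel update that removes order-of-individual artifacts —
while deaths are committed before the next process reads the state. The
one necessary exception is mate pairing, which consumes a shared pool:
each individual mates at most once per step.

Because mortality sources act sequentially on the survivors of earlier
sources, the order changes the *death structure* but not the total number
of deaths: a cohort of 1000 facing hazards 0.4 then 0.8 loses 400 + 480 =
880 individuals (observed rates 40% and 48%), and in the reverse order
800 + 80 (80% and 8%) — the same 880. `expected_sequential_mortality()`
computes this decomposition exactly, and the property suite checks
permutation invariance of the total.

## Genotype-to-phenotype map

The source text of the model family never fixes how bits become rates, so
the map here is a deliberate design choice. Every evolvable trait
(age-specific survival probability, age-specific reproduction probability,
optionally the germline mutation rate) owns one block of `bits_per_block`
bits per age class (one block if age-independent). For a block, the raw
score is the fraction of bits — across both haplotypes — whose value
matches the drift map's beneficial direction, and the trait value is
`lower + raw * (upper - lower)`. Consequences of this additive-linear
choice:

* every bit is a variant with a defined effect size,
  `(upper - lower) / (2 * bits_per_block)`, acting at a defined age class —
  which is exactly what the site-frequency-spectrum annotation reports;
* the map is monotone (making a bit match the beneficial direction never
  lowers the trait), so selection gradients are well behaved;
* with an initialization fraction `f`, expected trait values are age-flat
  at `lower + f * (upper - lower)` — a non-aging starting phenotype.

Ploidy is two haplotypes in both sexual and asexual populations; asexual
inheritance copies both haplotypes, so one genome representation serves
both modes. Mutation flips bits symmetrically by default (an asymmetry
ratio is available for deleterious-biased scenarios); it acts only on
offspring at conception — genomes are stable across life. Recombination
draws a Poisson number of crossovers, cut points uniform among inter-locus
boundaries; assortment transmits one recombined haplotype per parent.
Asexual reproduction bypasses recombination and assortment entirely: with
mutation off, offspring are bit-identical clones (heritability one).

## Mortality processes

* **Intrinsic**: a living individual of age `a` dies with probability
  `1 - survival(a)` from its own phenotype. This is the only mortality
  channel that is genetic and age-dependent, and it is the trait whose
  evolution the simulator is built to expose.
* **Abiotic**: periodic hazards `baseline + amplitude * waveform(...)`
  with flat, sinusoid, square, triangle or sawtooth waveforms (range
  scaled to `[0, 1]`; the sinusoid has its trough at the phase origin).
  The functional form — baseline plus scaled waveform — is this package's
  choice; only the periodic character is prescribed by the model family.
* **Infection**: an SIS process. Susceptibles are infected with
  probability `background + transmissibility * infected_fraction`;
  infected individuals die with the fatality rate, else recover with the
  recovery rate. A linear force of infection with recovery to the
  susceptible class is the least-assumption form consistent with the
  three published parameters.
* **Predation**: per-prey kill probability
  `vulnerability * (1 - exp(-predators / prey))` — a saturating response
  that keeps probabilities bounded — followed by a discrete logistic
  predator update capped by the prey count. Only the growth rate and
  vulnerability are prescribed; the functional response is ours.
* **Starvation**: engages when the living, non-egg population exceeds the
  carrying capacity `K`. *Instantaneous*: exactly the uniformly chosen
  excess dies, so the population never exceeds `K` after the process.
  *Gradual*: per-step survival decays as `(1 - m)^t` with the number `t`
  of consecutive steps spent above `K`. The optional age weighting is
  normalized to mean 1 over the exposed individuals, so the age-flat case
  reduces exactly to the stated law. Eggs neither die of starvation nor
  count toward `K`: of the two statements in the model family —
  equal resource consumption versus egg invulnerability — invulnerability
  was taken to dominate.

Every death is tagged with exactly one cause (`intrinsic`, `abiotic`,
`infection`, `predation`, `starvation`, `age_limit`); the per-step ledger
reconciles cause-tagged deaths against population decrements, and the
test suite asserts this conservation on every run it makes.

## Reproduction, eggs, and the age limit

Eligibility requires age in `[maturity, menopause)`; each eligible
individual attempts reproduction with probability equal to its fertility
phenotype (bounded at 0.5 per step by the default trait bounds).
Attempting individuals are paired by a uniformly random permutation; a
pair produces exactly one offspring; the germline mutation rate applied
to the offspring is that of the first-listed pair member (the mother of
record — an arbitrary but reproducible choice). Reproduction runs after
all mortality, so offspring never face hazards in their birth step, and
newborns are not aged in their birth step.

Under oviparity, offspring enter an egg pool, invulnerable to every
hazard. Eggs hatch either a fixed incubation after laying (an egg laid at
step `s` with incubation 0 is alive the step after laying) or — for
non-overlapping generations — all at once at the first step with zero
living adults. The carry-over policy ranks eggs by laying step
(`earliest`, `latest`, or `all`) and truncates at a cap; the `latest`
policy implements "preferentially carry over late-laid eggs" as strict
ranking, the strongest version of that selection rule.

Individuals reaching the last age class die with cause `age_limit`,
recorded at the final age class lived. Ages at or beyond `n_age_classes`
cannot occur.

## Determinism and random-number discipline

One master seed spawns a named L'Ecuyer-CMRG stream per stochastic
process (initialization, each mortality source, reproduction, drift).
Toggling one process therefore cannot perturb another's draws — the
property that makes A/B comparisons clean — and identical configuration
plus seed gives byte-identical ledgers and snapshots. Draws within a
process are made in the storage order of living individuals; the store
appends newborns and compacts by dropping dead slots while preserving
relative order, so a run resumed from a snapshot (which saves the
compacted order and all stream states) reproduces the uninterrupted run
exactly. Snapshots are RDS containers holding genomes, ages, phases,
infection statuses, the egg pool, environment counters, the drift map,
the RNG streams, the architecture and a hash of the evolutionary
conditions; loading one into an incompatible architecture is refused.

## Recorders and derived curves

Demography is aggregated over recording windows: deaths by cause and age
class, births by parental age, individuals entering each age class
(the exposure), and the age structure; population size is recorded each
step immediately after reproduction. The observed life table is a period
life table: `q(a)` divides all-cause deaths at age `a` by the number of
individuals that entered age `a` in the window (eggs excluded from all
denominators); survivorship is the cumulative product of `1 - q`; ages
with zero exposure are undefined (`NA`), not zero. Intrinsic curves are
computed from phenotypes alone: mean intrinsic mortality per age and its
cumulative-product survivorship — what a cohort would experience were
intrinsic mortality the only death source. Median lifespan is the median
age at death (for curves, the interpolated age at which survivorship
crosses 0.5, with the age cap as fallback since no lifespan can exceed
it); life expectancy is the sum of the survivorship values (one age class
= one step). Fertility phenotypes live on `[0, 0.5]` and are stored
unscaled; plots double them, following the field's display convention.

The site frequency spectrum reports, per locus, the fraction of
haplotypes carrying a 1, annotated with the trait, age class and signed
effect under the current drift map; fixed loci are excluded from the
binned spectrum by default (a toggle includes them).

## Study conditions used by the tests and the acceptance script

All problem sizes below are this package's desk-scale choices; the
reference experiments in the model family ran far longer (millions of
steps, 100 replicates) and these conditions are their property-preserving
reductions.

* **Emergent aging**: K = 500, 50 age classes, maturity 10, default
  traits (survival bounds `[0, 1]` initialized at 1; reproduction bounds
  `[0, 0.5]` initialized at 0.25; 8 bits per block; constant germline
  mutation rate `1e-3` per bit), 10,000 steps, 10 replicates. With a
  generation time near 10 steps this spans several hundred generations —
  past the point where age patterns become detectable. The check is
  directional: Spearman correlation of population-mean intrinsic
  mortality (positive) and fertility (negative) with adult age.
* **Neutral drift**: zero-effect architecture (survival bounds pinned at
  `[1, 1]`, 100 loci), constant census 200, fertility 1, mutation 0,
  recombination 20 (near-free, so loci are quasi-independent for the
  binned test), non-overlapping 20-step generations: each generation lays
  2000 eggs and instantaneous starvation culls the hatchlings uniformly
  back to 200. The comparison oracle is an independent haploid
  Wright-Fisher simulation at the variance-effective size given by
  Crow's formula `Ne = (4N - 2) / (Vk + 2)`, with `Vk` the
  offspring-number variance of hypergeometric culling (200 kept from
  2000 eggs in families of 20), i.e. `2Ne = 422`; the final model state
  is the generation-99 gamete pool, so the oracle runs 99 generations.
  Matching on the variance-effective size is the standard way to compare
  a structured reproduction scheme against idealized Wright-Fisher drift.
* **Delayed-reproduction selection**: two oviparous arms with
  non-overlapping generations, K = 1000, maturity 14, shared 3000-step
  burn-in under baseline (earliest-egg) conditions, then 1000 steps per
  arm; arm O carries over the latest-laid eggs. The wild-like extension
  re-runs each evolved snapshot for 150 steps with viviparity
  (overlapping generations) and gradual resource limitation, and compares
  observed survivorship over early/mid ages (0-25) across replicate
  pairs. "Indistinguishable" is an effect-size claim, so it is tested as
  equivalence (two one-sided tests) with a margin of 0.05 survivorship —
  the resolution below which two curves on a unit axis cannot be told
  apart — rather than as failure to reject a null, which would merely
  reward low replication.

## What the synthetic conditions do and do not show

The simulator generates all populations de novo; no empirical data enter.
Passing the checks above shows that the implementation has the intended
mathematical behavior — exact sequential-mortality bookkeeping, the
starvation law, drift consistent with the neutral expectation, and the
emergence of senescence from mutation-selection balance over age-specific
traits. It does not show that any particular biological population
behaves this way: the genome map is an abstraction (no molecular alphabet,
no dominance, no linkage map in physical units), mating is random with no
sexes or parental care, space is absent, and resource consumption is
uniform. Conclusions about real taxa require the user to argue that these
abstractions are adequate for their question.

## Numerical and degenerate-input choices

* Hazards are probabilities throughout; configuration constructors reject
  out-of-range values at load time, naming the offending key.
* An empty living set short-circuits each process; extinction terminates
  the run gracefully with the extinction step recorded.
* `starvation` resets its streak when the population is at or below `K`,
  and increments it before drawing mortality, so the first starving step
  uses `t = 1`.
* Crossover counts are capped at `L - 1` (the number of distinct cut
  points); drift flips are capped at the map length.
* With zero exposure at an age, observed rates are `NA` and survivorship
  propagates `NA` beyond that age rather than inventing zeros.
* Ties in egg ranking are broken by laying order (stable), keeping runs
  reproducible.

## Known limitations

Selection, pairing and culling all happen within one well-mixed
population: no spatial structure, no group selection. The mutation-rate
trait, when made evolvable, is age-independent by default (a single
block). Starvation counts only living individuals against the carrying
capacity, so an oviparous population can bank arbitrarily many eggs
unless a carry-over cap is set. Very small populations under high
mutation rates can collapse (mutational meltdown) — the experiment
harness reports extinction rather than masking it.
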