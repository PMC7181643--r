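---
title: "Modeling mutation accumulation and clonal expansion in nitrogen-starved quiescence"
author: "starveGASP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mutation accumulation and clonal expansion in nitrogen-starved quiescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starveGASP)
```

# The system

Fission yeast starved of nitrogen arrests reversibly in G0. Cells in this
state still accumulate mutations, but on a clock that ticks with *time*
rather than with replication, and with a distinctive spectrum: indels about
as frequent as single-nucleotide variants, deletions dominating insertions.
Over two to three months of starvation, cultures pass through three
viability phases (maintenance, rapid decline, stabilization), and mutants
of the stress- and mitogen-activated protein kinase (S/MAPK) cascades and
of downstream effectors come to dominate the survivors. The mechanism is a
growth advantage in stationary phase (GASP) fed by kin selection: dying
wild-type cells release traces of nitrogen; wild-type cells that sense
those traces commit to DNA replication they cannot complete and are killed
by their own checkpoint, releasing yet more nitrogen, while pathway mutants
either delay commitment until the pool suffices (SAPK-class alleles) or
survive the failed commitment (MAPK/sgf73-class alleles) and divide about
once every three days on the recycled nitrogen.

`starveGASP` implements this whole experimental design as a simulation plus
the matching inference stack. Everything below is reproducible from
exported functions; the problem sizes quoted are the package defaults used
throughout the test suite and `scripts/acceptance.R`.

# The mutation clock (`clockParams`, `sampleGrowthBurden`, `sampleQuiescenceBurden`, `realizeMutations`)

Two Poisson regimes:

* **Growth**: mean burden per genome after $g$ generations is
  $g \cdot \mu \cdot L$ with $\mu = 2\times10^{-10}$ mutations per
  nucleotide per generation and $L = 1.257\times10^7$ nt. Twenty-seven
  generations (the bound used to limit preexisting mutations) yield a mean
  of 0.068 mutations per genome.
* **Quiescence**: a homogeneous Poisson process in time with
  $\lambda_q = 0.6/90$ per genome per day, i.e. 0.6 mutations per genome
  after three months, with $e^{-0.6}\approx 0.55$ of genomes mutation-free.
  The literature describes accumulation as linear "starting on day 1"; we
  start the process at day 0, a discrepancy of at most one day's worth of
  rate ($\sim0.007$ mutations), which we accept for simplicity. Burdens in
  unrefreshed medium have been reported about two-fold higher; we do not
  assert that, but `lambdaQ` is a plain argument if you want it.

Mutation *identities* are drawn hierarchically: type from the
origin-specific spectrum, gene with probability equal to the catalog's
share of the genome (weighted by gene length within the catalog), position
uniformly except at hotspot sites, where homonucleotide runs multiply the
local indel rate (default 50x) and direct repeats the local duplication
rate (default 20x). Effect classes: indels are frameshifts unless their
size is a multiple of three; SNVs are missense/nonsense/silent with
probabilities 0.70/0.05/0.25. The default spectra
(quiescence: SNV 0.50, deletion 0.30, insertion 0.15, duplication 0.05;
growth: SNV 0.85, indels 0.15) satisfy the qualitative constraints -
quiescence indels roughly as frequent as SNVs, deletions over insertions -
but the exact values are assumptions, exposed as arguments.

Selection during quiescence is modeled by *rejection*: a quiescence-origin
event whose effect class is not tolerated by the hit gene (loss-of-function
in a SAPK gene other than win1) is discarded and redrawn. This keeps the
clock decoupled from the population dynamics; it is an approximation - in
reality the cell dies rather than the mutation being re-rolled - but the
distribution of *surviving* mutations is the same.

# The target catalog (`defaultCatalog`)

Nine genes: the SAPK module (win1, wis4, wis1, sty1), the MAPK module
(mkh1, pek1, pmk1) and the downstream targets sgf73 and tif452, with the
vacuolar transporter pmc1 available as a tenth, config-toggled entry
(`includePmc1 = TRUE`) because the published gene list can be read either
way; the package asserts neither reading. Gene lengths are
order-of-magnitude CDS sizes; they only set relative mutational target
weights and can be overridden from TSV. Hotspots: the 8-adenine run at
sgf73 position 896, the 7-adenine run at mkh1 position 640, and the 17-bp
and 13-bp direct-repeat duplication sites at win1 positions 1273 and 394.
Coordinates are 1-based within genes, strandless - the readout is
amplicon-level. The rate multipliers are not published; 50x/20x were chosen
so hotspot alleles recur across independent subcultures without dominating
the spectrum. When gene sequences are available as FASTA,
`addHotspotsFromFasta()` auto-registers runs of seven or more identical
bases.

# Culture dynamics (`stepPopulation` and the `run*` scenario functions)

Cells are tracked per genotype class in five states: `G0`, `engaged`
(committed to S phase), `dividing` (transient), `ghost` (replication-
engaged cells that died and lost their contents; never form colonies) and
`dead`. The nitrogen pool is one well-mixed concentration in mM
glutamate-equivalents. A step of `dt` days (default 0.5, matching
twice-daily feeding) applies, in order:

1. **Basal death** - binomial per class at a piecewise-constant rate,
   releasing $\rho$ per cell into the pool. The calibrated schedules are
   wild-type 0.002/day to day 20, 0.14/day to day 50, 0.006/day after
   (reproducing the three phases), and SAPK-mutant 0.01/day to day 3,
   0.165/day to day 30, 0.002/day after (reproducing the decline to ~1% of
   the inoculum); MAPK-class mutants use the wild-type schedule. These
   constants are data, not mechanism: they live in `PhenotypeParams`.
2. **Uptake** - Michaelis-Menten per cell
   ($v_{max} = 5\times10^{-9}$ mM mL/cell/day, $K_s = 5\times10^{-4}$ mM).
   Engaged cells switch to a high-affinity, higher-capacity importer (10x
   affinity, 3x capacity, active below 0.1 mM) whose imports go to biomass:
   cultures gain mass without gaining cell number, as observed. This
   futile assimilation is also what keeps released traces "shared by too
   many identical mutants" in a pure mutant culture.
3. **Engagement** - G0 cells of a class engage (rate 2/day) once the pool
   reaches the class's sensing threshold: 0.03 mM for wild-type (the
   measured value at $4\times10^6$ cells/mL), trace level
   ($10^{-5}$ mM) for S/MAPK mutants, whose hypomorphic signaling lowers
   the commitment threshold. sty1-class alleles respond only
   `entryDelay = 3` days after first perceiving the signal.
4. **Completion or abort** - an engaged cell attempts to complete its
   round at a rate calibrated (by the Euler-Lotka relation for the
   two-stage cycle) so the realized CFU doubling time in free expansion is
   the configured `doublingTime` of 3 days; when the pool covers one full
   replication budget (0.105 mM per $4\times10^6$ cells/mL, the midpoint
   of the measured 0.09-0.12 mM) for every demanding cell at >= 0.02 mM,
   attempts switch to a fast quiescence-exit rate instead. Completion is
   gated by the per-cell budget: checkpoint-proficient classes
   (`pDeathOnAbort > 0`, i.e. an intact MAPK module) complete only when
   the pool could have supported their whole engaged cohort, failed
   (ghost) cells included - the population-level quantity the bulk
   measurement captures - whereas checkpoint-deficient scavengers commit
   cell by cell, so a rare clone can divide on traces that a bulk
   population cannot use. Completing cells consume their budget and leave
   two G0 daughters; cells that cannot complete abort, becoming ghosts
   with probability `pDeathOnAbort` (0.9 for wild-type, 0 for mutants)
   and releasing $\rho$.

Nitrogen release per death, $\rho$, defaults to exactly one completion
budget ($0.105/4\times10^6$ mM mL): death recycles one division's worth.
Mass balance - `nitrogen + consumed = initial + released + added` - holds
to 1e-9 by construction and is asserted on every validity check. With
$\rho = 0$ no class can ever expand: recycling is necessary for GASP.
`consume = FALSE` switches off uptake, stoichiometric consumption *and*
release crediting, so ten unconsumed 20-uM pulses accumulate to exactly
200 uM.

`refreshEvery` models periodic medium replacement by discarding the
accumulated pool: recycling-driven expansion shrinks several-fold (the
trickle released between refreshes remains consumable). Because phase III
is carried by the calibrated death schedule rather than by recycling, a
refreshed-regime experiment should pair the toggle with its own death
schedule.

A deterministic mean-field mode (`deterministic = TRUE`) replaces binomial
draws by expectations; it agrees with the stochastic mode within
Monte-Carlo error for populations of $10^5$ cells and is used for
monotonicity checks (raising `pDeathOnAbort` never increases wild-type
survival).

Default study conditions: 10 mL cultures at $10^6$ cells/mL ($10^7$
cells), 90-day horizon; co-cultures contaminate wild-type with 0.1% marked
mutant at day 1; pulse feeding gives 20 uM twice daily for 3 days to
3-day-old quiescent cultures at $4\times10^6$ cells/mL.

## What the defaults reproduce

* wild-type: phase boundaries at days 20 and 50, terminal survival ~1.1%;
* sty1/win1-class singles: decline to a ~1.0% plateau; mkh1/sgf73-class
  singles track wild-type;
* co-cultures: the marked mutant dies with single-culture kinetics until
  the low-threshold engagement opens around days 22-25, then expands
  exponentially; a log-linear fit over days 30-60 returns a doubling time
  of 3.2-3.3 days (slightly above the intrinsic 3.0 because the tail of
  the window is already supply-limited), and the mutant exceeds both its
  inoculum and the wild-type count by day 60;
* pulse feeding: wild-type engages from day ~1.5, cannot complete, and
  loses about half its CFU by day 4 with a ghost fraction near 0.5 while
  its mass proxy rises; abort-protected mutants retain ~99% CFU;
  sty1-class mutants engage only after their 3-day delay;
* a single 0.2 mM addition is above the whole-population budget: every
  class exits quiescence and replicates with no net killing.

# The resequencing readout (`sampleColonies`, `simulateReads`, `callVariants`)

The targeted design: 1000 survivor colonies picked into pools of 100, the
target genes PCR-amplified in two independent batches, each sequenced to
5000x. Colonies are drawn multinomially from survivor clone frequencies;
each colony contributes equal cells, so the frequency denominator is the
colony count and one mutant colony among 1000 contributes exactly 0.1%
allele frequency - the detection floor (five expected alternate reads per
batch at 5000x). Amplicons, primers and the 420-bp tiling are abstracted
into a uniform-coverage assumption; alleles are symbolic
(`gene:position:type:size`).

Noise has two parts: sequencing errors (default $2\times10^{-4}$ per base,
split across the three alternative alleles, present in both batches) and
PCR amplification artifacts (default: about three spurious alleles per
batch), which are *batch-private by construction* - that is the entire
point of the duplicate design.

The caller requires, for one allele: depth >= 5000 in both batches (the
lower batch gates), at least 2 alternate reads in *both* batches
(concordance - this removes amplification artifacts), and a mean batch
frequency >= 0.1%. The reported frequency is the mean of the batch
frequencies. A strict mode (`perBatchFloor = TRUE`) instead demands the
floor in each batch separately; we do not use it by default because with
5-read expectations per batch it costs several points of sensitivity at
the floor. Under the defaults the measured operating characteristics are a
false-call rate below $10^{-4}$ per mutation-free site and >= 99% recall
for alleles carried by two or more colonies. The published workflow's
internal details are not available; this caller is a reconstruction from
the stated rules (0.1% floor, >= 5000x, duplicate batches to exclude
amplification errors) and is documented as such.

# The subculture split (`runSubcultureSplit`)

To separate preexisting from de novo mutations, a culture grown from a
single colony for <= 27 generations is starved for one day and dispatched
into six subcultures of $10^7$ cells. Growth-origin mutations follow a
Luria-Delbruck genealogy (a mutation in generation $g$ of $G$ leaves
$2^{G-g}$ carrier cells) and are multinomially partitioned at the split;
quiescence-origin mutations arise independently afterwards, Poisson over
the live-cell person-days implied by the wild-type survival curve.

Survivor frequencies come from a lineage-level branching sketch rather
than a per-clone integration of the full nutrient dynamics (which would
make hundred-replicate studies impractical): each founder cell survives to
the expansion onset (day 21, when the death-phase nitrogen release first
opens the mutant engagement gate in the dynamics model, plus the class's
entry delay) with probability $\exp(-\int d)$ under its phenotype's death
schedule, then its clone grows at the 3-day doubling time as a Yule
process, so clone sizes are geometric around $2^{(t-t_0)/3}$. Total
expansion is capped by the recycled budget (one birth per death). Only
viable, non-silent mutations that actually confer the expansion phenotype
found clones; that probability, `gaspEffectProb = 0.01`, is not a
published number - it is calibrated once so that the simulated mutant
fraction of survivors (mean ~45%, range ~15-65% per subculture) and the
count of detectable alleles (~15 per subculture) match the reported
ranges. Hotspot alleles are always expansion-competent (the recurrently
recovered hotspot mutations are, by construction of the evidence,
functional).

This sketch reproduces the observable structure of the experiment - no
calls above 0.1% at day 1, tens of percent mutant survivors at two months,
non-hotspot de novo alleles private to their subculture, hotspot alleles
recurring in several but usually not all six - while remaining fast enough
for power studies. What it does *not* model: clonal interference beyond
the shared budget cap, post-onset death of expanding clones, intra-clone
secondary mutations, and any coupling back into the nitrogen pool.

# Inference (`classifyOrigin`, `segmentPhases`, `fitExpansion`, `burdenStats`, `spectrumSummary`, `minDoublings`)

* **Origin classification**: an allele detected in >= 2 subcultures that is
  not a registered hotspot is `preexisting`; in exactly one, `de_novo`;
  any registered hotspot allele is `hotspot_ambiguous` (recurrence is
  explicable by independent origin). This is the minimal formalization of
  the sharing argument; on ground-truth splits at default conditions it is
  ~99% accurate, with the residual errors being preexisting singleton
  lineages that happen to expand in only one subculture - an
  identifiability limit, not a bug. A stricter likelihood mode
  (`mode = "likelihood"`) tests recurrence against an explicit
  independent-origin probability (a base rate times the hotspot
  multiplier) instead of the blanket hotspot exemption.
* **Phase segmentation**: continuous two-breakpoint piecewise-linear least
  squares on log10 CFU, exhaustive over the observation grid, so recovery
  is exact (to one grid step) on noiseless piecewise input; a fit that
  improves on a single line by less than 5% of its RSS is flagged
  degenerate.
* **Expansion fitting**: ordinary least squares on log2 CFU in a window
  (default days 30-60); the doubling time is the reciprocal slope, with
  declining series flagged rather than returned as negative doublings.
* **Burden statistics**: mean, zero fraction, variance/mean dispersion and
  a chi-square goodness-of-fit p against Poisson(mean) with tail bins
  pooled to expected counts >= 5 (reported raw - single-test context). The
  test has >0.9 power at n = 1000 against a 50:50 mix of zero and
  Poisson(2).
* **Spectrum summaries** tabulate mutation types and per-gene effect
  classes and audit the SAPK constraint: any loss-of-function allele in a
  non-win1 SAPK gene is flagged as a model violation.
* **Minimum doublings**: $\log_2(f_2 N_2 / f_1 N_1)$; for the reported
  clone moving from 9.6% to 43.5% of a stable population this is 2.18
  divisions.

# Numerical choices and limitations

Time step 0.5 days; binomial/multinomial (tau-leaping style) updates;
counts are absolute cells in the culture volume, so co-culture inocula of
$10^4$ cells carry realistic demographic noise. Seeds make every exported
stochastic function bit-reproducible without disturbing the caller's RNG;
`runScenario` derives independent per-stage substreams from one master
seed and writes a provenance manifest.

The model is well-mixed and nitrogen-only (glucose stays in excess in the
real cultures); there is no spatial structure, no mating, and no
nucleotide-resolution sequence (no substitution matrix, no real
annotation). Ghosts are terminal. Phase-III wild-type survival is imposed
through the calibrated death schedule - whether those survivors are
phenotypically adapted or rare mutants is left open, and both readings can
be expressed through the phenotype parameters. Passing tests show that the
pipeline reproduces the quantitative skeleton of the experimental design
under these idealizations, not that real sequencing data would behave
identically - in particular real amplicon noise is position- and
context-dependent in ways the two-component error model is not.
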