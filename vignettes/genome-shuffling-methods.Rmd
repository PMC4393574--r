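---
title: "Models and methods: simulating and deconstructing genome-shuffled populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and deconstructing genome-shuffled populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gshuffle)
```

## The problem

Genome shuffling (GS) evolves a yeast strain by recursive pool-wise
mating: a UV-mutagenized haploid population is screened on gradient
plates against an inhibitory substrate, survivors are mated en masse,
the diploids sporulated, and the cycle repeated. After several rounds a
tolerant strain is isolated and resequenced. The analytical question is
which of its mutations *cause* the tolerance. Pooled amplicon sequencing
of the archived populations answers it indirectly: the fraction of reads
carrying each mutation estimates its allele frequency per round, and
alleles that climb under repeated selection are the productive
candidates, while alleles that entered on the same founder genome as a
productive mutation but decay over rounds are hitchhikers being crossed
out.

`gshuffle` implements that analysis — frequency calling, false-positive
filtering, codon-level effect annotation, trajectory and co-origin
analysis, candidate ranking — together with a forward-time simulator of
the breeding protocol that supplies ground truth for every stage.

## The simulator

### State and fitness

A haploid genome is a 0/1 vector over the locus catalogue; a diploid
holds two such haplotypes. Fitness is additive over loci,

$$ w(g) = \sum_l s_l \, d_l(g) + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma^2), $$

where the dose $d_l$ is 0/1 for haploids and, for diploids, 1 for the
homozygous alternate, the dominance coefficient $h_l$ for heterozygotes
(default $h = 0.5$, additive) and 0 otherwise. Gradient-plate screening
is abstracted as truncation selection: rank by $w$, keep the top
`selection_fraction`, multinomially resample to the pool size. The
protocol gives no quantitative growth model ("more tolerant than the
reference" is the only criterion), so the truncation quantile (default
0.2) and the noise scale (default $\sigma = 1$) are free parameters of
this package, not measured quantities.

### Mutagenesis and the founder clone

UV mutagenesis adds alternate alleles at a Poisson($\lambda$) number of
catalogue loci per genome, drawn uniformly without replacement. Because a
catalogue locus is one specific base, the same site essentially never
recurs in two independent mutants; the default $\lambda = 0.05$ keeps
per-locus independent carriers at the ~1% level.

The sequenced population showed five mutations at virtually identical
~60% frequency in the UV pool, interpreted as a single founder clone
enriched by screening. The simulator reproduces this emergently:
`run_gs_rounds(..., founder_loci =)` implants the founder's alleles into
`founder_cells` genomes per mating type (default 60, the clone's
expansion during post-mutagenesis outgrowth) and then applies
`founder_boost` (default 5) rounds of the same truncation selection
before archiving the UV sample. With the default demonstration catalogue
this lands the founder at a mean UV frequency of 0.57 (SD ≈ 0.15 across
seeds). A single implanted cell would be more parsimonious, but the
early rounds are then a near-critical branching process whose outcome
varies over orders of magnitude; a small implanted count keeps dominance
a product of selection while bounding that variance.

### Breeding rounds

Each round runs selection on the haploid pool, random MATa × MATalpha
pairing without replacement (surplus of the majority type is discarded —
plate mating has no replacement mechanism), archiving of the post-mating
*diploid* pool as that round's sample, meiosis, and selection among the
spores to seed the next round. The diploid pool is the archive point
because the frozen populations of the original protocol are the mated,
screened pools from which diploid colonies were picked and genotyped;
zygosity analysis requires diploid samples.

Meiosis follows the Haldane model: crossovers form a Poisson process
along the genetic map with no interference, giving recombinant fraction
$r = (1 - e^{-2d})/2$ at distance $d$ Morgans. It is realised as the
equivalent Markov walk — the strand of origin at the first locus of a
chromosome is uniform, and switches across an inter-locus interval with
probability $r(d)$ — which is jointly distribution-identical to placing
the crossovers explicitly, and exact at the tracked loci. Each meiosis
emits two complementary gamete pairs, so 2:2 Mendelian segregation holds
exactly at every locus, and spores within a pair take opposite mating
types. With probability `selfing_probability` (default 0.1) a diploid's
four spores are tagged as a tetrad and the next mating pairs sister
spores preferentially — modelling incompletely segregated spores, which
is the hypothesised route to the homozygous mutations observed in the
final strain.

### Sequencing and isolates

`simulate_amplicon_counts` draws per-locus coverage from
Poisson(`mean_coverage`) and variant reads from
Binomial$(n,\ p(1-e) + (1-p)e/3)$: a read error substitutes one of the
three non-template bases uniformly, so only a third of errors on a
reference read produce the specific alternate allele. The default
coverage in the pipeline, $1.35 \times 10^5$ reads per locus, is the mean
coverage of the study being emulated. `simulate_isolates` draws colonies
with weight $\propto \exp(\beta\, w(g))$; $\beta = 0$ (uniform) is the
default because the picking bias of "colonies from the frontier of
growth" is unquantified.

### The demonstration catalogue

`demo_catalogue()` encodes the inferred architecture of the real
experiment: one strong driver (effect 1.0) and four passengers carried by
the same founder clone but located on four *other* chromosomes — the real
founder's five mutations sit on five different chromosomes, so they are
clone-linked, not map-linked — plus three moderately beneficial competitor
loci (0.6/0.5/0.4) that arise in other mutant clones, and two neutral
loci. The passengers carry a small fitness cost (−0.13 each). This is a
deliberate modelling choice: with strictly neutral passengers, truncation
selection necessarily *raises* alleles perfectly associated with the
fittest clone before linkage decay can act, and no parameterisation
reproduces the observed monotone passenger decay. The GS rationale itself
— combine beneficial mutations, cross out deleterious ones — treats
founder baggage as costly, and a −0.13 cost (about an eighth of the
driver benefit) suffices for recombination plus competition to purge the
passengers while the driver sweeps. Under the defaults, 94% of seeds
reproduce the rising-driver / falling-passenger pattern and 95% recover
the four passengers as one UV co-origin cluster (validated over 400
seeds). Costs beyond about −0.14 destabilise the simulation: the founder's
load lets an independent, passenger-free driver clone of a single mating
type sweep the boost phase and collapse mating.

## The frequency caller

Pooled frequency is the variant read fraction; the detection threshold
(default 1%, inclusive) mirrors the reporting threshold of the emulated
study. The clonal-sample false-positive filter applies the study's
calling rule: a variant is called iff the evolved sample shows it in
≥ 35% of reads with central base quality ≥ 40 and minimum flanking
quality ≥ 30, and the matched wild-type control shows it in < 10% of
reads; an evolved-passing variant with a control fraction ≥ 10% is
discarded as a false positive. All thresholds written "≥" in the source
protocol are implemented inclusively; the protocol's wording mixes "more
than 35%" and "≥35%", resolved here as inclusive. A control with fewer
than `control_min_coverage` reads (default 5) cannot veto a call; the
result is flagged `control_uninformative` rather than silently accepted,
because the protocol's coverage clause ("lowered to ≤5-fold") is
ambiguous between a floor and a ceiling.

Zygosity bands for clonal diploid samples — homozygous at ≥ 0.90 variant
fraction, heterozygous in [0.35, 0.90), ambiguous between detection and
0.35 — are package-chosen operating points; the original zygosity calls
came from read alignments and mixed Sanger traces without stated
cut-offs.

## Effect annotation

CDS coordinates are 1-based on the coding strand with the start codon at
positions 1–3 (the convention of the catalogue's `137C > A (P46Q)`
notation; the source does not state whether numbering includes the ATG,
and the standard convention is assumed). The affected codon is
`ceiling(position / 3)`; reference and mutated codons are translated with
the standard genetic code (Biostrings); a substitution is silent iff the
amino acid is unchanged. Real CDS sequences are not shipped — tests build
minimal synthetic CDS fixtures whose relevant codons match the catalogued
substitutions. SIFT scores are inputs (computing them is out of scope);
the phenotype rule is damaging iff score ≤ 0.05, inclusive.

The packaged catalogue (`inst/extdata/r57_catalogue.tsv`) holds the 21
point mutations of the sequenced strain, including the ambiguous
intergenic record 43 bp 3′ of BCS1, which carries no published ref/alt
nucleotides (stored as NA, allowed only for intergenic records) and is
excluded from gene-level counts, as in the source analysis.

## Trajectory analysis

Frequency matrices keep sub-threshold cells *absent* (NA), not zero,
because the emulated report omits sub-1% bars; trend arithmetic treats
them as 0 while preserving the not-detected flag. The trend rules
formalise narrative labels: with margin $m$ (default 0.02), a trajectory
is **rising** if the final frequency exceeds the first by more than $m$,
**falling** if below by more than $m$, **transient** if neither holds but
an interior round exceeds both endpoints by $m$, **stable** otherwise,
and **not-detected** if no round reaches the detection threshold. One
known tension is documented rather than hidden: the source narrative both
lists certain alleles as "gaining over evolution" and notes their
round-5 dip; an endpoint rule cannot satisfy both readings, and the
endpoint reading is used.

Co-origin clustering groups loci whose UV-pool frequencies are within
`cluster_tolerance` (default 0.03) by single linkage (in one dimension:
sort and split at gaps exceeding the tolerance), keeping clusters of ≥ 2
loci with mean frequency ≥ `cluster_min_frequency` (default 0.20). UV
frequencies alone are used because the co-origin argument in the source
rests solely on the UV pool.

Isolate allele frequency is $(2 n_{homo} + n_{het}) / 2N$.
Population-vs-isolate comparison reports per-locus absolute deviation and
the Spearman rank correlation (flagged undefined below two shared loci).
Ranking orders rising loci first, then transient/stable, then
falling/not-detected, breaking ties by final-round frequency then locus
id.

## Numerical and reproducibility choices

All randomness flows from a single integer seed (`set.seed` at the
entry points `run_gs_rounds` / `run_end_to_end`); identical configuration
plus seed reproduces every output byte-identically, and each report
bundle echoes its scientific configuration with an MD5 hash so a run can
be reproduced from its own artifacts. Selection ties are broken uniformly
at random (relevant when all effects and the noise SD are zero). Degenerate
inputs error early with named messages: zero-coverage loci, single-mating-
type pools, haploid input to sporulation, empty populations.

Test and acceptance problem sizes — pools of 300–1000 genomes, 5 rounds,
100 replicate simulations, $10^4$ meioses, $10^4$ random filter
configurations — were chosen so the full suite completes in well under a
minute of simulation time while leaving Monte-Carlo standard errors far
inside the asserted 3–5 SE bands.

## What the simulator does and does not show

The generator emulates the protocol's population-genetic skeleton:
founder-clone dominance, recursive selection/mating/meiosis, binomial
pooled sequencing, biased colony picking. Passing tests therefore show
that the analysis stack recovers the right signals *under that model*.
Real data differ in ways the model omits deliberately: genome-wide
mutational background beyond the catalogue, non-additive fitness
(epistasis), interference in crossover placement, UV mutational spectra,
realistic chromosome maps, PCR amplification bias between amplicons, and
base-level read errors with quality correlation. The quality scores
attached to simulated counts are draws from a configurable distribution,
not a read-level error model; they exercise the filter's gates, not its
error biology. Conclusions about real pools should lean on the caller's
binomial error envelope (which is model-independent) rather than on the
simulator's trajectories.
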