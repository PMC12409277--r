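---
title: "Methods: authenticating ancient biomolecules from bone-adhered sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: authenticating ancient biomolecules from bone-adhered sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedsift)
```

# The problem

Sediment clinging to excavated bone carries a degraded metagenomic
mixture — endogenous DNA of the buried individual, their gut and oral
microbiota, environmental animals, plants and soil microbes, and modern
contamination — alongside a parallel mixture of ancient peptides. None
of these signals can be taken at face value: k-mer classifiers
mis-assign conserved regions, close relatives cross-map, and modern DNA
mimics ancient taxa. `sedsift` implements the authentication layer that
separates genuine ancient signal from noise, and ships a simulator that
generates every input with known truth so each decision rule is
testable end to end.

# Models and procedures

## Terminal deamination

Post-mortem cytosine deamination is read as C→T at 5′ fragment ends
and, in double-stranded libraries, symmetrically as G→A at 3′ ends. The
simulator and the recovery fit both use a geometric decay:

$$\mathrm{rate}_i = f + (\delta_5 - f)\,\lambda^{\,i-1}$$

with terminal rate $\delta_5$, per-position decay $\lambda \in (0,1]$
and background floor $f$. Published damage profiles are empirical
curves with no canonical functional form; the geometric form is the
standard single-strand-overhang approximation, has three interpretable
parameters, and is recoverable from simulated data by weighted least
squares (`fitDamageModel()`), which is what makes the simulator's truth
checkable. Defaults $\delta_5 = 0.2$, $\lambda = 0.6$, $f = 0.01$ are
realistic magnitudes for temperate-climate archaeological material;
they are package choices, set once and not tuned against any test.

`misincorporationProfile()` counts, in read orientation, all 12
substitution types and the reference-base opportunities at the first 30
positions from each end. Reference bases are reconstructed from MD tags
when present, otherwise sliced from a supplied FASTA; both paths are
pinned to agree by test. Conventions follow standard damage-profiling
practice: positions inside insertions are skipped, deletions advance
the reference only, soft-clipped bases are excluded from position
indexing, and minus-strand records are reverse-complemented into read
orientation before counting.

`terminalDamage(profile, k)` is the opportunity-weighted mean over the
5′ C→T and 3′ G→A cells at positions 1..k (k = 3 and 5 are the
conventional summaries). The averaging is not standardised in the
literature; weighting by opportunity counts makes the summary a plain
binomial proportion, and the choice is pinned by a unit test. The
estimate is gated on read support: strictly more than 100 profiled
reads are required before the summary is considered interpretable.

## E-score screening of classification reports

For each taxon in a KrakenUniq-style report the default validation
statistic is

$$E = \frac{\text{unique k-mers} / \text{reads}}{\text{coverage}}$$

— the per-read unique k-mer yield normalised by the fraction of the
taxon's reference k-mers observed. Dispersed, non-clonal hits score
high; duplicated reads saturating one locus score low. The exact
algebra of the published score this emulates is not restated in the
source literature, so `eScore()` exposes the formula as a pluggable
strategy (`fun =`): swapping the algebra leaves every downstream filter
untouched, and the retention threshold (7) applies to whichever
strategy is active. Rows with zero reads or zero coverage are flagged
unevaluable and can never pass a filter silently.

Retention uses three inclusive thresholds (E ≥ 7, reads ≥ 10, relative
abundance ≥ 0.02 %). The screening literature prints both "above 7" and
"7 or above"; this package resolves the conflict as inclusive ≥ 7 and
pins the boundary by test. Candidate selection for competitive mapping
keeps genera with strictly more than three mitochondrial hits
(interpreted as classified read counts against mitochondrial reference
entries, summed per genus) and, within them, species passing the
E-score.

For joint abundance tables, `mergeReports()` keeps species with at
least 200 reads in some reference sample and at least 50 in the target,
then drops species below 0.02 % of the pooled dataset, then normalises
each sample by its retained library size. Whether the 200-read rule
means "in every reference" or "in at least one" is ambiguous in the
source; the any-reference reading is implemented (a species well
attested in one reference panel member is usable evidence), and the
boundary case "199 in all references" is pinned as dropped either way.

## Competitive assignment

Reads classified to a candidate taxon are mapped against all selected
close relatives, and each read goes to the reference with the smallest
edit distance (NM), ties broken by mapping quality, residual ties
discarded rather than randomly assigned — for authentication,
specificity beats yield. Winners below mapq 30 are rejected with their
own reason code, and the reason codes partition the read universe
exactly (assigned + tie + below_mapq + no_hit = total), which the
pipeline manifest checks on every run. Per-taxon summaries report
mapped reads, mean edit distance and breadth-agnostic mean coverage
(aligned bases / genome length).

## Sample-level inference

* **Ry sex**: $R_y = n_Y/(n_X+n_Y)$, called XX strictly below 0.016
  and XY strictly above 0.077, undetermined between; the decision is on
  the point estimate, with a normal-approximation CI reported for the
  user. The boundaries are binary-searchable to 1e-9 — the acceptance
  script recomputes them that way.
* **Coverage-ratio sex** (non-human animals): the ratio is oriented
  Y-over-X because the verbal rule it implements ("near 1 = male, near
  0 = female") is only self-consistent in that orientation — an XY
  individual has X and Y each at half the autosomal rate, an XX
  individual has Y near zero. The published description gives no
  numeric bands, so the defaults 0.25 / 0.75 are package choices.
* **Contamination**: at manually annotated diagnostic sites of the
  mitochondrial genome, the pooled minority / (majority + minority)
  allele-depth ratio, with an exact binomial CI. Site selection is an
  explicit input, not automated: the practice this follows chose sites
  by eye in a genome browser.
* **Individual count**: biallelic sites at ≥ 5× depth whose two alleles
  both exceed a 10 % minor-fraction floor count as heterozygous;
  transition pairs (C/T, G/A) are excluded as deamination artefacts;
  zero transversion-heterozygous sites is consistent with a single
  individual. The 10 % floor is a package choice (the source states no
  floor) that prevents single sequencing errors from producing false
  heterozygosity; it is pinned by test.
* **Consensus**: sites pass at depth ≥ 5 and GQ ≥ 20; heterozygous
  sites are recoded to the majority allele when minority:majority ≤ 1/9
  (inclusive — the boundary case 2:18 is emitted), all other failures
  are masked to N and tallied so masked + emitted = total.

When the input is a bare pileup with no caller-provided GQ, a
model-based stand-in is computed: the phred-scaled likelihood gap
between "the majority allele is the true haploid allele" and "the
minority allele is", under a symmetric 1 % per-read error rate.
Mixture (heterozygosity) evidence is deliberately left to the
allele-ratio rule rather than folded into this GQ, so the two filters
stay independent. This stand-in is clearly a model default, not a
reproduction of any caller's quality.

## Concordance statistics

Pseudohaploid calls draw one covering read base per panel site,
uniformly and seeded; bases matching neither panel allele are missing.
Imputation post-filters are inclusive at panel MAF ≥ 0.05 and GP ≥
0.98 (the source prints both "98 % and higher" and "> 0.98"; the
inclusive reading is implemented and the boundary pinned). Dosage hard
calls use the plink rule: nearest integer within 0.1, else missing.
Phenotype concordance counts markers with differing non-missing codes;
pairs with any missing call are excluded from numerator and denominator
by default (the published worked figure — 29 of 109 markers discordant,
≈ 73.4 % — is all-called, so the convention does not affect it; a flag
includes missing pairs as discordant for sensitivity analysis).
Transitions are not excluded from concordance by default; a
transversions-only mode is available. P0 is the raw mismatch fraction
over jointly called sites, flagged low-confidence below 100 sites;
kinship classification beyond the statistic is out of scope.

## Peptide discrimination

PSMs are aggregated per modification-stripped peptide and kept at
score ≤ 0.01 (lower is better) with ≥ 2 PSMs. Matching against the
species-tagged protein database is exact substring containment with I/L
equivalence on by default — the residues are isobaric and
indistinguishable by mass spectrometry. Matching does not enforce
tryptic termini: the module validates search-engine output rather than
re-running a search. A peptide is species-diagnostic when its matches
fall in exactly one species; for diagnostic peptides the residue
positions at which the other species' homolog (same gene tag, compared
co-linearly at the matched offset) differs are reported in peptide
coordinates. Protein-level evidence needs ≥ 2 unique peptides; coverage
is the union of matched residue intervals over protein length, and
≥ 5 % coverage earns the "partial protein" label. Blank-derived
peptides and contaminant-list matches are subtracted after identical
filtering.

# What the simulator emulates — and what it does not

`simulateMetagenome()` draws read counts from a multinomial over the
mixture abundances, fragment lengths from a clamped lognormal
(default log-mean log 55, log-sd 0.35, bounds 30–120 bp — the short
fragment regime of ancient libraries), uniform placements and strands,
position-decaying terminal damage applied only where the source base
permits (C at 5′ distances, G at 3′), uniform sequencing error, and an
undamaged contaminant admixture drawn from a designated source — the
core authentication premise that modern contaminants lack deamination.
Every read carries a lossless truth record (placement, damaged
positions, contaminant flag), and alignments are emitted with exact NM
and MD tags. All randomness flows from named sub-streams of one master
seed, so toggling one model (say, error) does not perturb the others,
and identical configurations produce byte-identical outputs.

The sex-read simulator distributes reads over chromosomes by length ×
copy number with an equal-length X and Y by default — a stylised layout
that makes the XY expectation exactly the "1 X : 1 Y at half-autosome
rate" signature the read-ratio classifier relies on. Real X and Y
differ in length and mapability; the classifier is threshold-based
either way, but simulated Ry magnitudes should not be read as realistic
for any genome build. Likewise the simulator does not model mapability
masks, reference bias, indel damage, single-stranded library
asymmetry, base-quality miscalibration, or classifier false assignment
— so passing tests demonstrate the correctness of the decision rules
given their inputs, not robustness to upstream artefacts of real data.

The k-mer report generator counts distinct (sequence, offset) k-mer
start positions covered by the truth reads, capped by the genome k-mer
count — a faithful small-scale surrogate for unique-k-mer counting that
preserves the property the E-score depends on (spread reads beat clonal
reads), without emulating k-mer collisions across genomes. The
protein-pair generator builds homologous two-species proteins that are
identical except at chosen diagnostic residues (backbones avoid I and L
so the diagnostic distinction survives I/L collapsing), which makes
"diagnostic" exactly decidable by exhaustive substring search.

# Numerical and interface choices

* All coordinates are 0-based half-open internally; FASTQ, SAM and
  report files are read and written per their standards (FASTQ via
  Biostrings; SAM read via Rsamtools through a temporary BAM; SAM
  written by a plain serializer since no installed package writes text
  SAM).
* "Quality below 20" is interpreted as mean read phred < 20 — the
  source does not say per-base vs mean; the mean is monotone, matches
  common screening practice, and is what the filter tests pin.
* The DUST statistic is fixed to the windowed overlapping-triplet form
  (window 64, step 32, tail window always included; score
  $100\sum_t c_t(c_t-1)/2 / ((w-3)(w-2)/2)$, read score = max over
  windows) so that "dust value 7" is reproducible without external
  tools. Reads above 7 are removed. Whether this scaling matches every
  external implementation exactly is unknowable from the description it
  follows; the formula here is pinned by an independent triplet-count
  oracle in the tests.
* Deduplication is exact-sequence (not alignment-coordinate) because it
  runs before alignment in the stage order; the representative is the
  highest-mean-quality copy, ties to first occurrence, so shuffling
  input changes representatives only, never the kept sequence set.
* Degenerate inputs are flagged, never NaN-propagated: zero-read taxon
  statistics report NA fields; zero-opportunity damage summaries warn
  and return NA; unevaluable E-score rows carry an explicit flag.
* `fitDamageModel()` fits by ported Gauss–Newton (`nls`, port
  algorithm) with box constraints and data-driven starting values;
  positions 1–10 carry essentially all the curvature at the default
  decay.

# Problem sizes

The test suite and acceptance checks run at deliberately desk-scale
sizes chosen to keep Monte-Carlo noise well inside the asserted
tolerances: damage recovery at 20,000 reads (position-1 standard error
≈ 0.006), assignment oracles at 200 reads × 3 references, contamination
recovery at 500 replicates of 50 sites × 100× depth (mean-bias standard
error ≈ 0.0002), sex classification over 100 seeds of 100,000 reads,
peptide soundness over 1,000 random two-species databases, and a full
pipeline run at 10,000 reads across 3 taxa. Headline results from the
original archaeological datasets (multi-million-read mapping tables,
specific coverages, published P0 values) depend on deposited sequencing
data and are not reproducible at these scales; what the package
verifies is every decision rule and statistic those results flow
through.

# Known limitations

* The E-score default is a literal algebraic reading of its verbal
  description; if the published form differs, the strategy seam is the
  supported path to swap it.
* Damage is modelled and recovered as geometric decay; strongly
  non-geometric empirical curves (e.g. UDG-treated libraries) will fit
  poorly.
* The coverage-ratio sex bands (0.25/0.75) and the heterozygosity
  minor-fraction floor (0.1) are package defaults where the source is
  silent; both are exposed as parameters.
* Human-read depletion ("discard any read with a reported alignment")
  and classifier behaviour itself are out of scope: reports are
  consumed, not produced.
* Imputation, PCA projection, kinship classification, phylogenetics
  and spectrum-level peptide search are consumed as upstream inputs
  where relevant and are not reimplemented.
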