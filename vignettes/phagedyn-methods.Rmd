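---
title: "Tracking active viral infections by read recruitment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking active viral infections by read recruitment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Most marine phages cannot be cultured, but an actively infecting phage
betrays itself in a cellular metatranscriptome: during the latent period
its genes are transcribed, so RNA reads from the cellular size fraction
recruit to its genome. `phagedyn` implements the analysis chain that
turns such recruitment into ecology: per-contig abundance that is robust
to conserved-region artifacts, persistence calls across a site-by-date
sampling grid, percent-identity spectra that reveal population structure
(microdiversity), marker-gene partitioning of photosystem-II (*psbA*)
expression into cyanobacterial and cyanophage origin with an
infected-fraction estimate, and co-occurrence host matching.  Because
the statistics are only testable against known truth, the package ships
a first-class synthetic community generator: host and phage populations
with controlled microdiversity, infection states that drive viral
transcript production, and complete ground truth for every read.

# Recruitment and the built-in aligner

Reads are recruited by a seed-and-extend local aligner implemented in
C++: exact 15-mer seeds against an index of the references, seeds
grouped by diagonal, and a full affine-gap Smith-Waterman over a
reference window around the seeded diagonals (match +1, mismatch -2, a
gap of length $L$ costs $5 + 2L$).  Percent identity is
$100\,m/c$ where $m$ is the number of identical columns and $c$ the
alignment columns including gaps.  Hits are retained when they are
strictly longer than the molecule's minimum (100 bp for metagenomes,
200 bp for metatranscriptomes) and at least 70% identity, the floor of
the recruitment-spectrum range.  With `best_hit_only` (default), each
read keeps its highest-scoring hit, ties broken by the
lexicographically smallest reference id.  References at or below
5 kbp are excluded before recruitment.

The aligner's contract is equivalence with an exhaustive
dynamic-programming oracle, and the test suite enforces it on 1000
random instances: hit/no-hit decisions must agree exactly and scores
must be equal.  One numerical subtlety: co-optimal local alignments
(equal score, different end trimming) are common, because a trailing
"mismatch + two matches" segment changes the score by exactly zero.
Identity is therefore compared on the *canonical* co-optimal alignment,
obtained by maximally extending both ends of a gapless alignment along
its diagonal with net-zero-score segments; two co-optimal gapless
alignments on the same diagonal then compare identically.  Instances
for the identity comparison are substitution-only, matching the
generator's divergence model; instances with indels additionally check
score equality.

External alignments can be substituted for the built-in aligner via
`import_alignments()` (SAM, or 12-column tabular).  SAM identities are
recomputed from CIGAR + `NM` with gap columns counted as non-matches;
coordinates are normalized to 0-based half-open internally, while all
written tables use 1-based inclusive coordinates (stated in their
headers).

# Trimmed coverage and persistence

Mean coverage is computed after excluding the `floor(0.25 * L)` deepest
positions of a contig ("top 25% of positions by depth", ties at the
cutoff resolved by position index).  The trim guards against short,
highly conserved regions — "islands" — that recruit non-specifically at
high identity and can dominate the plain mean; zero-depth positions
stay in the denominator, so the statistic remains coverage per position
of the whole contig.  `detect_islands()` makes the artifact visible:
sliding 500 bp windows (step 250) at five-fold or more the median
contig depth are merged into islands, and intervals longer than 10% of
the contig are rejected (an elevated whole contig is abundance, not an
island).  The median rather than the mean defines the background so the
islands themselves cannot mask their own detection.

A contig is *detected* in a metatranscriptome when its trimmed coverage
is at least 0.75x, *persistent* at a site when detected in at least 3
of 4 dates, *ephemeral* when detected at least once but fewer times,
and *absent* otherwise; the global call is persistent if any site is.
The detection threshold equals the persistence coverage threshold, so
persistent / ephemeral / absent partition the contig set.  For display,
abundances are normalized within each sample as
$h_i = \log_{10}(1 + c_i) / \log_{10}(1 + \max_j c_j)$ (the transform
base and pseudocount are parameters; the source analyses state only
"log-transformed").  Community comparisons use Bray-Curtis
dissimilarity ($1 - 2\sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)$,
defined as 0 with a warning for two all-zero profiles), and contigs are
clustered by average-linkage on Bray-Curtis distances of
log-transformed abundances, with columns pre-sorted by label so leaf
order is deterministic.

# Identity spectra and population structure

Recruitment is histogrammed into one-point identity bins over
[70, 100] (top bin closed), weighted by aligned bases so long hits
dominate, as in a recruitment plot.  Classification renders the
qualitative population-structure descriptions quantitatively; all
thresholds are config-exposed defaults of `spectrum_params()`:

* **clonal** — at least 50% of weight at 98-100% and at most 10% at
  90-97%: many nearly identical relatives, few moderately close ones
  (the typical signature of contigs assembled from the sample itself).
* **gapped** — two occupied regions (bins holding at least 1% of the
  weight) separated by at least 3 empty bins within [88, 98]: discrete
  clouds with a recruitment discontinuity.
* **continuum** — occupied bins spanning at least 10 consecutive points
  within [80, 98] with no internal gap of 2+ bins: a genomic continuum
  of relatives, the signature of high microdiversity.
* **sparse** — anything else.  Precedence is clonal > gapped >
  continuum.

# The synthetic community generator

Populations derive variants from a random ancestor by i.i.d.
substitution — no indels by default, which keeps coordinates stable for
coverage arithmetic (an indel option is deliberately absent rather than
untested).  Cloud models: `clonal` draws per-variant divergence
uniformly in [0, 0.02]; `continuum` uniformly in [0, 0.20] (the source
analyses describe the continuum only qualitatively, so the uniform
choice is a modeling convenience, stated once here); `two_cloud` draws
half the variants at up to 2% and half at 11-15%.  The two-cloud far
band deserves its justification: the defining observable of the
discrete-cloud structure is the recruitment discontinuity below ~95%
identity.  A 200-250 bp read from a variant at divergence $d$ has
binomially distributed identity with a spread of 1.7-2.1 points, plus a
slight upward shift from local-alignment end trimming.  At a far cloud
of 8-10% divergence those spreads fill the identity gap and the
realized spectrum is a continuum — the pattern the model is supposed to
produce never materializes.  Drawn at 11-15% divergence, the far cloud
recruits at 85-89% identity and the discontinuity survives read-level
noise (33/33 recovery in our simulations, versus 6/33 at 8-15%).
Conserved islands (intervals exempt from divergence) and marker genes
(replacement insertion, so genome length and island coordinates are
preserved) are likewise exempt in every variant.

Read simulation draws genome positions and strands uniformly, applies a
0.1% uniform substitution error (no quality model, no amplicon
simulation — out of scope), and is byte-reproducible under a seed; no
wall-clock seeding exists anywhere.  DNA reads follow population
abundances; RNA reads for a phage are drawn only when its linked host
is present and the infected fraction is positive, reflecting that
viral mRNA requires an ongoing infection.  Phages without a configured
host link (e.g. a heterophage background population) transcribe
ungated.

Marker-gene reads are generated so that the *expected* viral fraction
of marker transcripts is $\alpha I / (\alpha I + 1 - I)$ for infected
fraction $I$ and relative per-infected-cell expression $\alpha$ — the
closed form that also underlies the infected-fraction estimator, making
the estimator testable against truth.  The generator's defaults are the
study conditions: $\alpha = 1$ (equal per-cell *psbA* expression in
infected and uninfected cells, the stated assumption of the
infected-fraction argument), infected fraction 0.545 (the value implied
by a T4-like:cyanobacterial expression ratio of 1.2 under
$\alpha = 1$), a 95:5 T4-like:T7-like split of viral *psbA* transcripts
(the T7-like contribution is consistently minor), and a 15% cyanophage
share of Gp23 transcripts (the middle of the reported 10-20% range).

The curated marker-protein reference sets used in the original analyses
are not redistributable here, so `make_marker_refs()` generates fully
synthetic stand-ins: an ancestral protein diverged into group
consensuses (5% inter-group divergence by default) and then into
individual references (up to 2% within groups), with reverse-translated
nucleotide versions for genome embedding and read simulation.  They
reproduce the *structure* of a curated set (labelled groups, alignment,
group-level divergence), not the biology of real D1 or Gp23 sequences;
classification accuracies measured on them transfer to real sets only
to the extent that real inter-clade divergences are comparable or
larger.

# Marker partitioning and the infected fraction

The profile is an ungapped position-specific scoring matrix rather than
a full profile HMM: per-column log-odds
$\log_2 \frac{(n_{a,c} + 0.5)/(N + 10)}{1/20}$ with columns of more
than 50% gaps dropped.  Reads are translated in six frames, stop codons
break segments, and every segment of at least 10 codons is scanned
ungapped across all profile placements.  The acceptance threshold is
the empirical $(1 - \mathrm{FPR})$ quantile of best scores of random
nucleotide reads (default target FPR $10^{-3}$, 10000 null reads at the
configured read length) — an empirical stand-in for analytic E-values,
calibrated rather than derived.  Passing reads are assigned to the
group of their highest-identity reference at the placement columns
(ties: higher non-gap column coverage, then smallest reference id);
nearest-reference classification replaces phylogenetic placement
because the partition is inter-clade, where the two agree, and tree
building is out of scope.

Partition statistics over the cyanobacterial + cyanophage total:
per-group fractions, the T4-like fraction, the viral:host ratio
$r = n_{T4} / (n_{Syn} + n_{Pro})$ (the headline ratio; a variant
including T7-like is also reported), and the infected-fraction estimate
$\hat I = r / (r + \alpha)$, monotone in $r$ with $\hat I = 0.5$
exactly when $r = \alpha$.  $\alpha$ is an explicit parameter so the
equal-expression assumption is a visible knob, not a buried constant.
Note a small conservatism: because the T7-like share of viral
transcripts is excluded from $r$, $\hat I$ underestimates $I$ by about
one point at $I = 0.5$ under the default 95:5 split; the all-viral
ratio removes the bias.

# Host matching

An actively infecting phage must have host cells present at sampling
time, which is a *necessary* condition and therefore usable as a
filter: the consistency score of a candidate host ASV is the fraction
of phage-active samples (RNA trimmed coverage at or above 0.75x) in
which the ASV is present (relative abundance at or above 0.001).
Candidates are ranked by score; Pearson correlation between phage
coverage and ASV abundance only breaks ties — correlation between
environmental phage and host abundances is notoriously hard to
interpret, so it is never treated as evidence on its own.  Candidates
below a score of 1 carry an incompatibility flag listing the violating
samples.

# Problem sizes and what the tests show

The test suite and the acceptance script run entirely on synthetic
data at desk scale, chosen to exercise every statistic with comfortable
margins: persistence recovery over 50 seeded 3-site x 4-date
communities (2 kb contigs, ~720 reads each); spectrum recovery over 99
seeded populations (20 kb ancestors, 2100 reads of 200 bp each,
metagenome filters); 1000 aligner-oracle instances of up to 200 bp;
infected-fraction recovery at $I \in \{0.1, 0.3, 0.5, 0.7\}$ with
20000 marker reads for each of 50 seeds per level; and a 69-contig
study-scale run (8 kb contigs, 2000 reads per sample, 5000 marker
reads per metatranscriptome) in the acceptance script.  Passing these
tests shows the statistics are implemented correctly and recover
planted truth under the generator's assumptions — i.i.d. substitution
divergence, uniform read sampling, uniform sequencing error.  It does
not show robustness to properties real data have and the generator
does not: indels and rearrangements, GC- and coverage-bias, chimeric
reads, rRNA carryover, conserved genes shared across unrelated
genomes, or marker proteins whose clade structure differs from the
synthetic 5%-divergence groups.

# Known limitations

* The aligner is exact-seeded: relatives beyond ~20% divergence from
  any reference recruit poorly (seed hits become rare), compressing the
  left tail of identity spectra — the same limitation the recruitment
  literature notes for mapping-based methods, here softened by the 70%
  floor rather than removed.
* The PSSM scan is ungapped; reads with indels inside the marker
  segment lose score linearly and may drop below threshold.
* Persistence calls inherit the contig catalog's biases: a population
  that failed to assemble is invisible, and the marker-gene route is
  the designed complement for exactly that case.
* `import_alignments()` requires `NM` tags in SAM input; records
  without them are an error rather than a silent identity guess.
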