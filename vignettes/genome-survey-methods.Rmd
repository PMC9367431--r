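---
title: "Genome survey statistics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey statistics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsurvey)
```

A genome survey characterizes an unassembled genome from low-cost short
reads: its size, sequencing error rate, heterozygosity and repeat content
from the k-mer spectrum; its microsatellite (SSR) landscape and assembly
contiguity from a draft assembly; the gene content of its mitochondrial
genome; and its demographic history from PSMC output. This vignette
explains the models behind each estimator, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices that were genuinely open.

## The k-mer spectrum model

Every window of $k$ consecutive non-N bases in the reads contributes one
count to its *canonical* k-mer, the lexicographic minimum of the window and
its reverse complement. Odd $k$ is enforced so that no k-mer is its own
reverse complement. The histogram records, for each depth $d$, the number
of distinct canonical k-mers seen exactly $d$ times (*species*), and the
*volume* $d \cdot \mathrm{species}(d)$; the total volume $N_{kmer}$ equals
the number of counted windows exactly. The default $k = 19$ is the common
survey choice: large enough that almost all genomic 19-mers are unique in a
sub-gigabase genome, small enough that the $4^{19}$ key space and per-read
window count stay manageable.

For a genome of size $G$ sequenced to depth $c$ with reads of length $L$,
a single-copy k-mer is observed approximately
$\mathrm{Pois}(\lambda)$ times with $\lambda = c\,(L-k+1)/L$ (a read of
length $L$ contains $L-k+1$ windows). The spectrum then shows an error
spike at depth 1, a heterozygous component near $\lambda/2$, the main
homozygous mode near $\lambda$, and repeat components at multiples of
$\lambda$.

**Peak depth.** $C_{kmer}$ is the depth of the main mode. The error region
is excluded by finding the first local minimum of the window-3 moving
average of species counts and searching strictly beyond it. Because the top
of a Poisson-shaped mode is nearly flat, the raw argmax is fragile: species
counts in neighbouring bins differ by a fraction of a percent while
read-level coverage correlation (a read covers $L-k+1$ consecutive
windows) inflates the bin variance well beyond multinomial noise. The mode
is therefore refined to the rounded species-weighted mean depth within one
third of the mode on either side, which is stable across simulation seeds.
Argmax ties resolve toward the smaller depth.

**Genome size.** $G = N_{kmer} / C_{kmer}$. Depth-1 k-mers are treated as
the error case, giving $\mathrm{error\ rate} = \mathrm{volume}(1) /
N_{kmer}$ and the corrected size
$\mathrm{revised}\,G = G \times (1 - \mathrm{error\ rate})$, equal to
$(N_{kmer} - \mathrm{volume}(1)) / C_{kmer}$ exactly. Note the integer
granularity of $C_{kmer}$ bounds the attainable accuracy: at
$\lambda = 26.4$ (30x coverage, 150 bp reads, $k=19$) rounding to 26
biases $G$ by about +1.5%, which is inherent to the method, not a defect
of the fit.

**Error rate.** With per-base substitution rate $e$, a window is erroneous
with probability $1-(1-e)^k$; nearly all erroneous k-mers are singletons
(the chance that two errors collide on the same novel 19-mer is
negligible), so the depth-1 volume fraction estimates the erroneous-window
fraction, not $e$ itself. At $e = 0.001$ and $k = 19$ the expected value
is $1-(0.999)^{19} \approx 0.0188$.

**Heterozygosity.** A window covering a heterozygous site yields *two*
distinct k-mer species, one per haplotype, each sequenced at half depth;
windows covering no heterozygous site yield one species at full depth. The
species counts over depths $[C/4,\ 1.5C]$ are fit by least squares to
$A_1\,\mathrm{Pois}(d; m/2) + A_2\,\mathrm{Pois}(d; m)$, with non-negative
closed-form amplitudes and the coverage mean $m$ refined continuously
within 20% of the integer peak (the histogram mode locates coverage only
to one depth unit, and a half-unit offset in the means visibly biases the
amplitudes at low heterozygosity). The heterozygous *window* weight is
$\alpha = A_1/(A_1 + 2A_2)$ — the factor 2 converts species weight to
window weight, since each heterozygous window contributed two species —
and the per-base rate follows from the standard window-to-site transform
$\alpha = 1-(1-r)^k$, i.e. $r = 1-(1-\alpha)^{1/k}$. In simulation this
recovers $r$ within a few percent across $r \in [0.002, 0.01]$; the
accuracy contract of the package is this parameter-recovery test, not any
particular published estimate.

**Repeat ratio.** Repetitive sequence appears at multiples of $C_{kmer}$;
the estimate is the error-free volume fraction at depths
$\ge \mathrm{round}(1.5\,C_{kmer})$. The 1.5x threshold splits the
homozygous peak from the 2x repeat peak and is a documented heuristic:
about 1% of a Poisson homozygous peak leaks above it, and repeats at
fractional multiplicities below 1.5x are missed.

Counting is in-memory (a C++ hash map over 2-bit-packed k-mers) and sized
for desk-scale inputs of tens of megabases; depths above 10,000 accumulate
in a cap bin so pathological histograms stay bounded. Disk-based counting
of production-scale libraries is out of scope.

## Microsatellite mining

`find_ssrs()` reports maximal perfect tandem runs of motifs with period
2-6 at the standard thresholds — at least 6 copies for dinucleotides and 5
for periods 3-6, configurable. Partial trailing copies are excluded from
the repeat count and coordinates; any N breaks a run; motif phase is
preserved (AC and CA are distinct motifs, as census figures convention-
ally list them); motifs that are repetitions of a shorter unit are
classified at the shorter period, and mononucleotide runs are out of the
search scope entirely. Overlapping candidates of different periods resolve
to the longer span, ties to the smaller period, which prevents reporting
(AT)6 a second time as (ATAT)3. The scanner is validated against an
exhaustive brute-force enumerator on random sequences; the two agree
record-for-record.

`merge_compound()` merges consecutive SSRs separated by at most 100 bp
(the de facto standard interruption parameter; configurable) into compound
records, rendering interruptions in lowercase, e.g. `(AC)6tt(GA)5`. The
census (`summarize_ssrs()`) mirrors the standard summary table: totals,
SSR-bearing sequence counts, compound membership, density per Mb
(total SSRs divided by scanned megabases), and per-period and per-motif
percentage tables.

## Assembly metrics

N50/N90 use the convention "smallest length L such that sequences of
length at least L cover at least x% of the total", computed by descending
sort and cumulative sum and cross-checked against a brute-force oracle.
GC content is $(G+C)/(A+C+G+T)$, excluding ambiguous bases from the
denominator while still counting their length. Scaffolds split into
contigs at runs of one or more N — the simplest defensible reading, with
no minimum gap or contig length. The GC-depth table uses canonical k-mer
multiplicity as the depth proxy (no aligner is in scope): per
non-overlapping 500 bp window it reports GC% and the mean multiplicity of
the k-mers starting in the window, skipping windows that are more than
half N.

## Mitochondrial census

Annotations (6-column TSV or a minimal GenBank-style feature table) are
normalized to 1-based inclusive coordinates on the heavy strand; light-
strand features are marked L, and features crossing the origin of the
circular genome carry a wrap flag with the end recorded modulo the length.
CDS extraction honours both: wrapped features concatenate the two arcs and
light-strand features are reverse complemented. The start codon is the
first 3 nt; the stop codon is the trailing 1-3 nt after whole codons, so a
CDS of length 1 mod 3 ends in a bare T and 2 mod 3 in TA — incomplete
stops completed to TAA by polyadenylation, recorded rather than rejected.
AGA and AGG are treated as conventional stops alongside TAA/TAG, as is
standard under the vertebrate mitochondrial code (translation table 2,
the fixed default).

## PSMC scaling

The package parses the PSMC text dialect (RD/TR/RS round blocks, last
round selected) and applies the standard plot scaling:
$N_0 = \theta_0/(4 u s)$, $N_k = N_0 \lambda_k$, and
$\mathrm{years}_k = 2 N_0 t_k g$, with defaults $u = 2.5\times10^{-8}$
substitutions per site per generation, bin size $s = 100$ bp (the
consensus-input convention of the upstream tool, exposed as a parameter
since published analyses rarely state it) and generation time $g = 1$
year. $u$ is interpreted as per-site per-generation, the tool convention.
Bootstrap replicates are step-interpolated onto the union time grid
(piecewise-constant, inventing no new population-size levels; type-1
quantiles likewise) and summarized as the pointwise median with a
2.5%/97.5% band. The HMM/EM inference itself is out of scope — the
package implements the output contract and the plot mathematics.

## The synthetic-data generator

Every estimator ships with a parameter-recovery test against
`simulate_diploid_genome()` truth. The generator emulates:

* a diploid genome whose haplotype 2 differs from haplotype 1 by
  independent per-base substitutions at the target heterozygosity
  (default 0.47% per base, a typical diploid fish value);
* repeat content as exact duplications of `repeat_unit_length` blocks
  (default 500 bp), copied until the requested fraction of the genome
  (default 32.6%) is *covered by* duplicated sequence — source and copy
  both count, matching what a spectrum-based repeat ratio measures, and
  exact copies give the spectrum a clean 2x peak;
* uniform-coverage single-end reads (150 bp default) from both haplotypes
  and strands with i.i.d. substitution errors (default $10^{-3}$, a
  stand-in for an unreported library error profile) and constant
  placeholder qualities;
* planted SSR arrays wrapped in guard bases chosen so flanks can neither
  extend nor re-phase the run, at sites vetted to have no pre-existing
  tandem structure, so truth coordinates are exactly recoverable;
* a ~16.5 kb circular mitochondrial fixture in the canonical teleost
  layout (13 PCGs, 22 tRNAs, 2 rRNAs, 1 control region; ND6 plus eight
  tRNAs on the light strand; one GTG and one ATA start; seven
  conventional and six incomplete stops) with the control region spanning
  the origin;
* PSMC text generated from a known trajectory, so parse-and-scale is an
  exact algebraic round trip.

It does **not** emulate paired-end inserts, indels, base-quality error
profiles, GC-coverage bias, diverged or nested repeat families, or
real-organism base composition. Passing recovery tests therefore show the
estimators are correct *under their own model assumptions* — uniform
coverage, substitution-only errors, exact repeats — not that they match
any particular organism's published values, which depend on data the
package does not ship.

All simulations are seeded and byte-reproducible: the same parameters and
seed give identical FASTA/FASTQ output, and `run_survey()` re-runs are
byte-identical.

## Problem sizes and degenerate inputs

The test suite and acceptance script exercise 500 kb genomes at 30x
coverage with 150 bp reads (about 13 million 19-mer windows per run) —
large enough that binomial noise sits well inside every recovery
tolerance, small enough for interactive use. Degenerate inputs fail
loudly rather than silently: even k, monotone-decreasing spectra (no
post-error peak), peaks below the estimator minima (2 for genome size,
4 for heterozygosity), malformed histogram lines (reported with line
numbers), non-DNA characters in SSR input, out-of-range or duplicate
annotation features, CDS shorter than 6 nt, PSMC files without RS lines
or with non-increasing times, and empty length lists or trajectories all
raise errors.

## Known limitations

* Genome-size accuracy is bounded by the integer peak depth (about
  $\pm 1/(2 C_{kmer})$ relative); surveys at higher coverage suffer less.
* The heterozygosity mixture assumes two well-separated Poisson
  components; it will underestimate when coverage is so low that the
  components merge, and it ignores het k-mers inside repeats.
* The repeat threshold 1.5x misclassifies the Poisson tail (~1%) and
  misses diverged repeats, which do not stack k-mer depth.
* The SSR scanner is perfect-repeat only; imperfect/approximate models
  and primer design are out of scope.
* The GC-depth proxy saturates where k-mer multiplicity reflects
  repeat copy number rather than sequencing depth.
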