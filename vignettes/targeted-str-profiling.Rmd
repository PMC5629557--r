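---
title: "Targeted STR profiling by greedy seed extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted STR profiling by greedy seed extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strscan)
```

## The problem

Short tandem repeats (STRs) are loci of roughly 2–30 tandem copies of a
1–6 bp unit. Because their copy numbers are highly polymorphic, small
panels of STR loci (the autosomal CODIS panel, Y-chromosome Y-STR panels)
are the workhorse markers of forensic identity and kinship testing, and
expansions of some trinucleotide repeats are diagnostic of genetic disease.
Given whole-genome or amplicon sequencing reads, the task here is
*targeted*: for a user-defined panel of loci, find the reads that contain
each locus and report the repeat copy number each read supports, without
mapping reads to a reference genome first (mapping-based pipelines lose
exactly the reads whose repeat length differs most from the reference).

## The locus model

A locus is a pattern
$$P = s_L\,(s_1)_{c_1}\,t_1\,(s_2)_{c_2}\,t_2\,\cdots\,(s_n)_{c_n}\,s_R,$$
with repetitive units $s_i$ (1–6 bp) at reference copy numbers $c_i$,
spacers $t_i$ between consecutive runs ($t_n$ empty), and unique flanks
$s_L$, $s_R$. The distance between a read substring $Q$ and $P$ is the
minimum over partitions of $Q$ into flank/run/spacer segments, and over
per-unit copy numbers $m_i$ with $|m_i - c_i| \le \varepsilon$, of the
summed edit distances of each segment to its pattern component. An
occurrence is reported when this distance is at most $\delta$. Both flanks
must be reached: an alignment that never leaves the repeat run carries no
evidence of which locus (or which part of a long run) it saw.

All alignment here is unit-cost Levenshtein distance, restricted by a band
$\omega$ on the number of indels within any single component alignment —
within one unit copy or one flank, more than a few indels are better
explained as a copy-number change (which $\varepsilon$ handles) than as
alignment noise.

## The scan

1. **Index.** For every unit, the length-$k$ prefix of its infinite tandem
   repetition is a *seed* (`build_seed("ATCC", 18)` is
   `"ATCCATCCATCCATCCAT"` — the last copy is truncated when $k$ is not a
   multiple of the unit length). A read can enter a run at any phase of the
   unit, so every distinct rotation of each unit is seeded
   (`seed_phases()`), and all seeds go into an exact k-mer index
   (Biostrings `PDict`). Units whose maximum admissible run
   $(c_i+\varepsilon)\,|s_i|$ is shorter than $k$ can never be seeded and
   are skipped with a warning.
2. **Seed.** Every k-mer of the read (and of its reverse complement) is
   looked up exactly. A long error-free run produces many overlapping hits;
   per (pattern, unit, strand) run they are collapsed to one hit — the one
   covering the most whole unit copies, preferring a copy-boundary-aligned
   phase, then the leftmost (see *Numerical choices*).
3. **Extend.** If the seed starts or ends mid-copy, the partial copy is
   completed by gap-free, position-by-position comparison (a mismatch costs
   1). Then the 3′ end repeatedly applies the cheapest of three *fitting
   alignments* against the remaining read: (a) one more copy of the current
   unit (admissible while $m_i < c_i + \varepsilon$), (b) the spacer plus
   the next unit, (c) the right flank; the 5′ end does the mirror image
   toward $s_L$. Extension stops when both flanks are anchored or the
   running distance exceeds $\delta$. The per-step fit aligns the whole
   component against the best prefix (suffix) of the remaining read within
   the band — so the greedy total is always an upper bound on the exact
   partition distance, and equals it exactly on error-free reads.

Accepted calls are aggregated per locus: each supporting read contributes
its per-unit copy-number signature to one allele; a locus with two or more
distinct signatures is flagged *multi-allelic* (heterozygosity on
autosomes, or multi-copy marker families on chrY).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 18 | seed length (bases). A multiple of the common unit lengths 2, 3 and 6, long enough to be specific in a genome-scale read set, short enough to fit inside 100 bp-read runs. |
| `delta` | 4 | maximum total edit distance of an accepted occurrence. Occurrences are expected to differ from the pattern only by SNPs/sequencing errors, i.e. a small fraction of the locus. |
| `epsilon` | 30 | maximum per-unit deviation of observed from reference copies. Effectively unconstrained: observed forensic alleles can sit 10+ copies from the reference, so the default restricts nothing and real filtering is done by `delta` and the flanks. |
| `band` | 3 | maximum indels per component alignment. |
| `min_flank_anchor` | 8 | flank bases that must align at each end. Reads truncate flanks arbitrarily, so requiring the full flank would discard reads that end inside one; 8 exact-ish bases make a chance anchor unlikely ($4^{-8}$ per position) while keeping clipped reads callable. |
| `both_strands` | TRUE | scan the reverse complement too; shotgun reads sample both strands. |

## Numerical choices

* **Band semantics.** The indel budget is enforced as the diagonal band
  $|i-j| \le \omega$ of each component DP, which is exactly the set of
  alignments with at most $\omega$ unbalanced indels. Infeasible fits
  return an infinity sentinel so the per-step minimum skips them uniformly.
* **Fit tie-breaks.** Among equal-distance prefixes, the fit consumes the
  most read bases (prefers the full component length).
* **Step tie-breaks.** Among extension candidates, minimum distance wins;
  ties prefer the candidate consuming the most read bases, then the order
  copy → spacer+unit → flank. The progress preference matters only on
  corrupted boundaries: a unit copy can absorb an indel and tie the true
  flank step (e.g. fitting `TAT` against a flank starting `AT…` costs 1),
  and preferring the near-zero-progress copy then walks the alignment into
  the flank until the budget dies. On error-free reads the choice is
  provably irrelevant (see the generator's boundary screen below).
* **Seed collapse.** Within a run, all phases tie on whole copies whenever
  the run is long enough, and the flank's last base can extend a
  boundary-straddling phase one base into the flank; preferring the
  copy-boundary-aligned phase guarantees the gap-free completion stays
  inside the run on error-free reads.
* **Copy counts are integers.** Partial trailing copies are completed when
  cheap, otherwise discarded; reported alleles are whole-copy counts.
* **Coordinates.** Panel files use 1-based inclusive reference coordinates;
  all read coordinates in reports are also 1-based inclusive, the
  R/Bioconductor convention used throughout the implementation.
* **Degenerate inputs.** Reads shorter than $k$, non-ACGT characters
  (never match a seed), empty FASTA records, and loci whose flanks are
  shorter than `min_flank_anchor` (never accepted) are all handled without
  error.

## The simulator

`make_panel()` and `simulate_reads()` generate the study conditions used
by the tests and the acceptance script: 18-locus panels, units of 3–6 bp
(aperiodic, so seed phase is unambiguous), reference copies uniform in
8–30, 30 bp flanks, ~15% two-unit loci with 4–8 bp spacers; 10 reads per
locus of 1000 bp (Sanger-like regime) or 100 bp (short-read regime),
substitution errors i.i.d. per base, about half the reads
reverse-complemented, each read carrying one planted locus inside random
padding. These sizes keep every end-to-end check under a few minutes on
one CPU while still exercising every code path; they are the package's
default experimental frame, not a constraint of the method.

Two generator choices deserve emphasis:

* **Padding screen.** Padding is resampled until it contains no panel seed
  k-mer outside the planted locus, so false seeding in fixtures is
  impossible by construction and recall measurements are attributable to
  the scan itself.
* **Boundary screen.** Flanks and spacers are resampled until the unit-length
  window adjacent to each run differs from the unit in at least 2 positions
  (1 for single-base units). Real flanks almost always satisfy this; the
  screen guarantees it, making zero-error greedy choices strictly ordered.

What the simulator does **not** model: PCR stutter (the dominant artifact
of amplified forensic material), quality-score structure, coverage
variation, indel-rich platforms (an optional single-indel mode exists, off
by default so truth copy numbers stay exact), and paralogous genomic
sequence resembling a locus. Passing the synthetic checks therefore
demonstrates correctness of the machinery — seeding, fitting, extension,
aggregation — not field performance on amplified or low-quality data.

## Design decisions that were genuinely open

* **One seed phase or all?** All rotations are indexed; without them, reads
  entering a run mid-unit would need the run to be a full $k$ longer to be
  seeded. The index cost is a handful of extra k-mers per unit.
* **Both flanks or one?** Both are required. A single-flank rule would call
  reads that end inside the run, whose copy number is only a lower bound;
  whole-copy reporting would silently undercount.
* **Ties toward continuation vs progress.** See *Numerical choices*; the
  implementation prefers progress on ties because the continuation-first
  rule demonstrably loses calls and overcounts copies on noisy boundaries.
* **Copy-slack admissibility.** The per-step admissibility bound is
  $m_i < c_i + \varepsilon$, the reference copy number of the unit being
  extended, and accepted calls additionally verify
  $|m_i - c_i| \le \varepsilon$ for every unit.
* **A read supports one allele per marker.** Among multiple accepted
  interpretations of one read for one marker, the minimum-distance call
  (ties: most copies, then leftmost) is kept, matching how supporting-read
  counts are tabulated per allele.

## Limitations

* Greedy extension is locally optimal: the accepted distance can exceed the
  exact partition distance when an error sits exactly on a component
  boundary (a few percent of noisy instances in the acceptance checks;
  never below the exact distance).
* Seeding requires one exact k-mer in a run: a single substitution can
  de-seed a run shorter than about $k + |s_i|$ bases, which is the dominant
  loss mode at 0.5% noise for the shortest loci.
* Short reads recover few loci: a locus longer than the read can never
  satisfy the both-flank rule. This is inherent to targeted profiling, not
  a tuning artifact — longer reads (Sanger, long-amplicon) are the
  appropriate input.
* No diploid genotyping model: allele tables report raw supporting-read
  counts; stutter-aware statistical genotyping is out of scope.

## Reproducing the numbers

The `scripts/acceptance.R` script regenerates every quantity quoted in the
README from scratch — synthetic panel and reads, profiling, evaluation
against planted truth — under a single `--seed`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
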