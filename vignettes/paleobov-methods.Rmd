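---
title: "paleobov: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paleobov: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleobov)
```

## What the package models

`paleobov` re-implements, as one tested pipeline, the computational chain
used to take degraded (ancient) bovine sequencing reads to haplogroup
assignments, median-joining haplotype networks and diversity statistics:
read simulation with an explicit post-mortem damage model, mapping to a
circular mitochondrial reference, duplicate removal and alignment filtering,
threshold consensus calling, terminal-misincorporation profiling for
authentication, diagnostic-SNP mitochondrial haplogrouping, Y-marker typing,
and cohort summaries. A synthetic-data module generates every input with
known truth, so each stage is verifiable closed-loop without any external
download.

Domestic cattle mitochondrial lineages fall into taurine haplogroups — most
prominently T3 (prevalent in Europe) and T1 (prevalent in Africa), with
sub-clades such as T1a/T1b/T1d and the ancestral T123 node — while Y
chromosomes split into the taurine Y1/Y2 and indicine Y3 lineages. The
package's shipped mitochondrial panels realise that hierarchy; apart from
the two literature-derived T1b transitions at reference positions 7,542 and
16,022, the shipped panel coordinates are synthetic placeholders (clearly
non-biological), because published sub-clade definitions live in external
references rather than in printed tables. Panels are therefore plain
user-editable TSV config (`haplogroup, parent, position, ref, alt, class`),
and the generator and classifier consume the same file.

## The damage model

Reads are simulated with a Briggs-style two-rate deamination model:

* fragment lengths are log-normal, `meanlog = log(frag_mean)`,
  `sdlog = frag_sd` (defaults 70 b and 0.3); the empirical mean therefore
  converges to `exp(meanlog + sdlog^2/2)`, about 73 b, not to `frag_mean`;
* fragment start positions are uniform on the circle and strands are
  drawn uniformly; fragments longer than the genome are resampled;
* each terminus carries a single-stranded overhang whose length is
  geometric with parameter `overhang_p` (counting failures before the
  first success), so a read position `i` lies in the overhang with
  probability `(1 - overhang_p)^i`;
* cytosines deaminate with probability `delta_ss` inside the 5' overhang
  and `delta_ds` in the double-stranded core; the complementary strand's
  overhang produces the mirrored G→A excess at the 3' end;
* a uniform per-base sequencing error (`seq_error`) is applied last.

The closed-form terminal rate used as an oracle throughout the tests is

```
f_CT(i) = delta_ss (1-p)^i + delta_ds (1 - (1-p)^i)   (+ error term),
```

with `p = overhang_p`. Defaults (`overhang_p = 0.3`, `delta_ss = 0.4`,
`delta_ds = 0.02`, `seq_error = 0.001`, coverage 30×) are conventional
ancient-DNA magnitudes; damage signatures of real libraries are usually
reported only qualitatively, so these numbers are deliberately ordinary and
fully overridable. Every simulated change is recorded in a
truth table (read, position, from, to, mechanism), which the tests replay
against the reads to prove the bookkeeping exact.

What the generator does *not* emulate: contamination mixtures, library
index hopping, depurination context (which needs flanking genomic sequence),
base-quality variation (qualities are fixed), and paired-end geometry. A
green closed-loop suite therefore demonstrates internal consistency of the
chain, not robustness to every real-world artefact.

## Mapping and filtering

The mapper is a deliberately transparent seed-and-extend design: exact
k-mer seeds (default `k = 13`) on both strands against the doubled circular
sequence, diagonal voting, then a fitting alignment of the whole read inside
a ±16-base window around each candidate diagonal with scores match +1,
mismatch −1, gap −2. Coordinates are 1-based and inclusive and wrap across
the origin. The mapping quality proxy is `min(60, 4 × (best − second))`,
with 60 for a unique location — an explicit, documented replacement for
proprietary mapper scores, keeping the published filter threshold (≥ 30)
meaningful.

Filters retain alignments with mismatch fraction ≤ 5%, gap-column fraction
≤ 5% and mapping quality ≥ 30. The 5% caps are read as *inclusive* bounds
(≤), stated here and tested at the boundary. Filtering precedes duplicate
removal (the published order is unstated; this order is the conservative
choice because mapping-quality failures should never crowd out better
duplicates). Duplicates are alignments sharing (start, end, strand); the
highest-scoring one survives, ties broken by smallest read id. Only the
best location is reported per read: for a single-copy circular mitogenome,
secondary hits carry no extra information.

Damage profiling runs on the mapped-but-unfiltered alignments: the mismatch
cap clips precisely the most-damaged reads, and profiling after it would
bias terminal rates downward. The authenticity rule formalises the usual
qualitative damage-plot reading: verdict `authentic` requires both terminal
fractions (5' C→T and 3' G→A) ≥ 0.05 *and* a significant rank decay over
the first 5 positions (one-sided Spearman, p < 0.05); sparse profiles give
`indeterminate`, which is deliberately distinct from `not_authentic`. The
0.05/5 convention is this package's own, configurable formalisation.

## Consensus and haplogroup assignment

Consensus calling uses raw base counts: the winning allele is emitted when
it reaches 75% of the depth (inclusive — a tie at exactly the threshold is
a call) and depth ≥ 3; otherwise N. `min_depth = 3` is the package's proxy
for a mapper suite's opaque "highest quality" consensus setting. Deletions
compete as ordinary alleles; insertions must meet the same support rule
against the flanking position's depth.

Mitochondrial assignment walks the panel hierarchy: a clade matches when
every callable variant of its own and all ancestral panels is derived, each
panel being ≥ 80% callable; uncallable positions never count for or against
a panel (missing ≠ ancestral). The most-derived matching clade is assigned;
several maximal matches give `ambiguous`, none `unassigned`. The 0.8
completeness floor and the ≥ 4 callable markers required for Y assignment
are robustness floors for degraded consensi, both configurable.

Y typing reads five SNPs, one (AT)n microsatellite and one 2-base indel
across five intron regions and matches callable markers exactly against the
three haplogroup rows (Y1: C/(AT)×10/C/C/C/C/–, Y2: C/(AT)×10/C/A/C/C/GT,
Y3: T/(AT)×8/T/A/T/T/GT). The microsatellite is counted on the consensus as
the maximal uninterrupted run containing the anchor — adequate for a
haploid marker; stutter modelling is out of scope. Distinguishing an absent
indel from a failed call requires knowing the region's uninserted length,
so marker definitions carry `ref_len`. The published anchor table names the
two ZFY introns inconsistently (9/10 in headers, 4/5 in a footnote); the
neutral ids `zfy9`/`zfy10` follow the table headers.

## Median-joining networks

`minimum_spanning_network()` implements the Kruskal-style construction that
keeps *all* edges of a weight class connecting distinct components at the
moment the class is processed — the union of all minimum spanning trees.
`median_joining()` alternates MSN construction with median insertion:
candidate vectors are per-site majorities of triples (three-way splits fall
back to the lexicographically smallest sequence's state), generated by
default from triples connected through the current MSN, with an exhaustive
mode for testing; the novel vector whose insertion most reduces total
network length is added, until nothing helps. Inferred nodes of degree < 3
are pruned at the end. `epsilon` defaults to 0, the common default of
network software when nothing else is stated. All tie-breaks are
lexicographic, so results are deterministic under a fixed input order.
Columns containing a gap or N in any sequence are dropped before distance
computation (complete-column deletion), mirroring common practice.

On the canonical three-haplotype binary example (000, 110, 101) the
algorithm adds the single median 100 and reaches total length 3, which the
test suite verifies against an exhaustive Steiner-vector search; on tie-free
tree-like data the MSN weight equals an independent MST oracle (igraph).

## Diversity statistics

Haplotype diversity is Nei's unbiased gene diversity
`H = n (1 − Σ p_i²) / (n − 1)`, the estimator standard polymorphism
software reports. For the published
21-sequence control-region comparison, the 18-haplotype multiplicity
profile {3, 2, 1×16} is the unique partition of 21 into 18 parts whose H
rounds to the printed 0.981 (the alternatives give 0.971 and 0.986) — the
cohort generator therefore engineers exactly that D-loop structure, with
one shared trio, one shared pair, and unique deterministic control-region
variants for the other 16 specimens, while random private mutations are
kept outside the window. Published control-region comparisons rarely state
their exact coordinates; the last 700 bases of the circular reference are
used by convention, and the region is a required parameter for real data. Reports round H to 3 decimals and frequencies to 2 (matching
the usual table presentation); machine outputs keep full precision.

## Reproducibility and problem sizes

A single master seed drives everything; per-specimen seeds derive from it
by stable string hashing, so any cohort row can be regenerated in
isolation. Reruns with the same seed produce byte-identical machine outputs
(timestamps are simply never written).

Test problem sizes are chosen for tight closed loops at desk scale: the
haplotyping closed loop runs every shipped panel at 30× coverage on the
full 16,338 b reference over 3 seeds; the damaged-consensus recovery
property uses 40 replicates on a 2 kb reference; profile recovery uses a
deep (60×) single run, giving > 50,000 terminal columns. The end-to-end
cohort run (21 specimens, 30×, 16 kb) completes in about two minutes on a
single core.

## Known limitations

* The mapper is built for a short, single-copy circular reference; it has
  no mate-pair logic, indel realignment or base-quality recalibration.
* Damage profiling is empirical only; there is no Bayesian rescaling of
  base qualities.
* Microsatellite genotyping ignores stutter and per-read phasing.
* Likelihood-based phylogenetics is out of scope: alignments can be
  exported for external tree software, but no tree search is performed.
* The authenticity rule is a convention, not a calibrated classifier; its
  thresholds should be revisited for libraries with unusual preparation
  chemistry (e.g. single-stranded protocols that alter damage symmetry).
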