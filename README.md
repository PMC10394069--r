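# paleobov

Ancient-DNA analysis pipeline for bovine mitogenomes and Y markers, with a
fully closed-loop synthetic-data generator.

Archaeological cattle remains carry short, damaged DNA fragments whose
terminal cytosine deamination (C→T at 5' ends, the mirrored G→A at 3' ends)
both authenticates them and complicates their analysis. From such reads,
studies of cattle dispersal type each specimen's maternal lineage — the
taurine mitochondrial haplogroups T3 ("European"), T1 ("African") with
sub-clades T1a/T1b/T1d, and the ancestral T123 node — and, where preserved,
the paternal lineage (taurine Y1/Y2 versus indicine Y3) from five Y-intron
markers; cohorts are then summarised with median-joining haplotype networks
and control-region diversity statistics.

`paleobov` implements that entire chain as tested R code, for method
developers and for teaching: every stage can be exercised against simulated
cohorts with known truth, without downloading anything.

## What is implemented

* **Synthetic data** — circular reference generation; haplotypes carrying
  hierarchical diagnostic-SNP panels; read simulation under a Briggs-style
  two-rate deamination model (geometric single-strand overhangs, `delta_ss`
  vs `delta_ds`, log-normal fragment lengths, uniform sequencing error)
  with exact truth tables; cohort builders including a 21-specimen roster
  with an engineered 18-haplotype control-region structure.
* **Alignment** — seed-and-extend mapping to the doubled circular sequence
  (match +1 / mismatch −1 / gap −2, ±16 b window), mapping-quality proxy
  `min(60, 4·(best − second))`; filters (MQ ≥ 30, ≤ 5% mismatches,
  ≤ 5% gap columns, inclusive); duplicate removal on (start, end, strand);
  pileups over the circle.
* **Damage profiling** — strand-aware terminal C→T / G→A misincorporation
  profiles with stored numerators/denominators, and an explicit
  authenticity rule (terminal rate ≥ 0.05 at both ends plus significant
  decay over 5 positions).
* **Consensus** — the 75% raw-count threshold rule with a depth floor and
  N masking; deletions and insertions as competing alleles.
* **Haplotyping** — most-derived-clade mitochondrial assignment over panel
  hierarchies (uncallable ≠ ancestral; completeness floors), and Y typing
  from 5 SNPs + (AT)n microsatellite + 2-base indel against the Y1/Y2/Y3
  allele rows.
* **Networks** — minimum spanning networks keeping all tied edges
  (Kruskal over Hamming distances) and median-joining networks with
  majority median vectors, verified against exhaustive Steiner search.
* **Diversity** — Nei's unbiased haplotype diversity
  `H = n(1 − Σp²)/(n − 1)`, segregating sites, nucleotide diversity π, and
  haplogroup frequency tables with sub-clade rollup.
* **Orchestration** — `run_pipeline()` + YAML configs, deterministic under
  a single master seed, plus a thin CLI (`inst/cli/paleobov`).

## Worked example

```r
library(paleobov)

ref <- make_reference(16338, gc = 0.4, seed = 7)   # circular synthetic mitogenome
pan <- default_panels()                            # T123/T1/T3 hierarchy + sub-clades

hap <- make_haplotype(ref, pan, "T1b", n_private = 0, seed = 1)
sim <- simulate_reads(hap, damage_params(coverage = 30), seed = 2)
sim
#> <read_sim> 6694 reads, 30.2x mean depth, 6911 recorded changes

alns <- deduplicate(filter_alignments(map_reads(sim, ref)))
cons <- call_consensus(build_pileup(alns, ref))
cons
#> <consensus_seq> synthetic_mito: 16338 positions, 0.00% N, 0 deletions, 0 insertions

assign_mt_haplogroup(cons, ref, pan, specimen_id = "demo")
#> <mt_call> demo: T1b (assigned, completeness 1.00)

prof <- misincorporation_profile(map_reads(sim, ref))
prof
#> <misinc_profile> W=25  f_CT[1]=0.2772  f_GA[1]=0.2583  background CT=0.0203 GA=0.0209
authenticity_check(prof)$verdict
#> [1] "authentic"
```

The terminal C→T fraction matches the generator's closed form
`delta_ss·(1−p) + delta_ds·p ≈ 0.286` at the defaults, and decays into the
~2% double-stranded background — the classic ancient-DNA signature.

Cohort-level, the built-in 21-specimen roster (14 T3, 6 T1-family, 1 T123)
runs end to end with `run_pipeline(pipeline_config(outdir, seed = 42))` and
reports:

```
  label count  frequency frequency_report
1    T3    14 0.66666667             0.67
2    T1     6 0.28571429             0.29
3     T     1 0.04761905             0.05

<diversity_report> n=21  k=18  H=0.981  S=18  pi=0.00257  (700 sites used)
```

i.e. 18 control-region haplotypes among 21 specimens with haplotype
diversity 0.981, and every specimen's damage profile judged authentic.

The median-joining worked example:

```r
net <- median_joining(haplotype_table(c(s1 = "000", s2 = "110", s3 = "101")))
net
#> <haplotype_network> 4 nodes (1 inferred), 3 edges, total length 3
```

one inferred median (100) joins the three haplotypes at total length 3,
versus 4 for the best median-free tree.

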