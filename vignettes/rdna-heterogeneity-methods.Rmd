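---
title: "Methods: simulating and detecting intragenomic rDNA variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting intragenomic rDNA variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the models, algorithms and decision rules
implemented in `rdnavar`, in the order the pipeline applies them. The
code chunks are illustrative and not evaluated at build time; the same
computations are exercised by the test suite and by
`scripts/acceptance.R`.

## 1. Ground truth

### Reference unit

`make_reference_unit()` draws a random rDNA repeat unit as five tiled
regions — partial 18S, ITS1, 5.8S, ITS2, partial 28S — with configurable
lengths and GC content. The default lengths (1683 / 300 / 160 / 386 /
2165 bp) give a ~4.7 kb unit whose ITS1-5.8S-ITS2 aggregate ("ITS",
846 bp) is the cloned and amplified target.

### Haplotype models

`heterogeneity_model()` + `evolve_haplotypes()` generate repeat
haplotypes under three mechanisms of incomplete concerted evolution:

* `accumulated_mutation` — each haplotype independently accumulates
  substitutions at per-region rates (and optional single-base indels),
  modelling relaxed homogenization.
* `hybridization` — two diverged parental repeat clusters co-exist; half
  the haplotypes carry the parental substitution set plus private
  mutations.
* `foreign_element` — one haplotype carries an inserted foreign segment
  of configurable length.

Each haplotype is a copy class with an integer copy count (default: 8
total copies spread evenly, so every carried allele has population
frequency ≥ 1/8 — detectable by design). The generator returns the exact
truth table `true_variant_sites` (position, ref, alt, type, frequency);
indel alleles are left-aligned against the reference, deletions written
`"-"`, insertions `"+SEQ"` anchored to the preceding reference position.
`make_haplotypes_exact()` is the calibration variant that places an
*exact* number of substitution and indel sites at well-separated ITS
positions.

`assemble_genome()` embeds the tandem array (all copies, in copy-count
multiplicity) in a random unique background, and also produces the
*assembly*: background plus a single collapsed unit copy, mimicking how
assemblers collapse near-identical tandem repeats.

## 2. The three detection arms

* `sample_clones()` — PCR-cloning-Sanger: each clone is one repeat copy
  drawn with probability proportional to copy counts, then corrupted by
  a per-base substitution process error (default 5×10⁻⁴), which is what
  creates singleton artefact alleles.
* `simulate_amplicon_reads()` — `n_runs` independent amplicon runs over
  the target region; per-run realized depth jitters around the nominal
  depth; reads carry per-base substitution errors and random strand.
* `simulate_wgs_reads()` — uniform shotgun reads over the physical
  genome at a target coverage; the rDNA locus is covered at
  copy-number-fold higher depth than unique sequence, which is exactly
  the signal the copy-number estimator uses.

## 3. Alignment, pileup, calling

The alignment kernel is an affine-gap Needleman-Wunsch
(match 2, mismatch −3, gap open −5, gap extend −2) with deterministic
traceback, in C++. Read mapping is seed-and-extend: k-mer votes select a
diagonal and orientation, a gapless check accepts reads with at most one
mismatch (provably score-optimal under this scoring, since the minimum
gap cost exceeds the mismatch-vs-match delta), and the remainder fall
back to a banded semiglobal alignment around the seeded diagonal. Reads
below an identity floor (default 0.9) are unmapped.

`build_pileup()` accumulates per-position, per-strand counts of
A/C/G/T/deletion plus anchored insertion events. The final `end_trim`
bases of each aligned read (default 2) are excluded from the counts:
a read ending one base past a deletion has a score-optimal *gapless*
alignment whose terminal base shows a spurious substitution, and at
amplicon depth this recurrent indel-edge artefact would otherwise pass
every filter. End trimming is the pileup-level analog of local
realignment.

`call_variants()` emits one call per (position, allele) with at least
`min_alt_count` supporting reads and annotates:

* `QUAL = -10 log10 P[X ≥ alt_count]`, `X ~ Binomial(depth, base_error)`
  — the phred-scaled probability that sequencing error alone explains
  the allele;
* `QD = QUAL / depth`;
* `FS` — phred-scaled two-sided Fisher exact test of the
  (ref, alt) × (+, −) strand count table.

Hard filters (GATK-style, in cascade order): depth below
`max(200, 0.10 × mean depth of called sites)` → `fail_depth`;
`QD < 2.0` → `fail_qd`; `QUAL < 30.0` → `fail_qual`; `FS > 200.0` →
`fail_fs`; otherwise `pass`. Indels are left-aligned in homopolymers
before reporting. `detect_clone_variants()` is the cloning-arm caller:
clones are globally aligned to the region, assembled into a
reference-anchored clone alignment, and every non-reference column state
becomes a call with frequency = clones carrying it / clones sequenced.

## 4. Reconciliation

`compute_run_consistency()` compares amplicon runs per allele: present
in how many covering runs, mean frequency (zero-filled where covered
but not called), consistent or not.

`merge_methods()` builds one record per (position, allele) over all
methods. **Consensus rule:** an allele is a consensus variant when it is
*present* in at least two methods — presence is pre-filter: ≥ 1 clone,
called in ≥ 1 amplicon run at any filter status, or called in WGS at any
filter status. This is deliberate: at 10× genome coverage WGS calls
essentially always fail the depth filter, yet their mere presence is
independent corroboration, so a hard-filter-failed amplicon call seen in
clones and WGS is *rescued* into the consensus. When only one method has
data, the method's own rules decide (hard filters for read methods;
≥ 2 supporting clones for cloning). Singleton clone alleles with no
read-based support are never consensus.

`classify_conflicts()` assigns exactly one verdict per record, in
precedence order:

1. `reference_error` — the reference base has zero read support in every
   covering read-based method: the reference itself is wrong.
2. `consensus_variant` — per the merge rules (annotated
   `inadequate_clone_sampling` when the clone library missed it).
3. `clone_undersampling` — the available read methods agree but no
   sampled clone carries the allele.
4. Cloning-only alleles: `amplicon_edge` within the edge window
   (default 50 bp) of the amplicon 3′ end, where amplicon coverage
   decays; `cloning_artifact` for singletons; otherwise `ambiguous`.
5. `run_inconsistent` — amplicon runs disagree, WGS absent or negative.
6. `amplicon_false_call` — amplicon-only, contradicted by covering WGS.
7. `other`.

`correct_clone_alignment()` masks alignment columns whose only variation
is `cloning_artifact` alleles — the manual-exclusion step applied to
suspected PCR/cloning errors — and reports variant-site counts and
p-distance summaries before and after. Masking can move pairwise
p-distances in both directions (it removes mismatches but also shrinks
denominators).

## 5. Phylogenetic summaries

`p_distance_matrix()` computes proportion-of-differing-sites under
pairwise or complete gap deletion. `neighbor_joining()` is the Saitou-Nei
algorithm with the standard Q-criterion, deterministic smallest-index
tie-breaking and negative-branch clamping that transfers the deficit to
the sibling branch; on additive matrices it reproduces the generating
tree exactly (a test-suite property). `count_haplotypes()` collapses
identical clones over the (unmasked) alignment columns.

## 6. Copy number

`mapping_stats_from_reads()` maps each WGS read against (a) the rDNA
unit, indexed in doubled/tandem form so junction-spanning reads map
end-to-end, and (b) the collapsed assembly. Then

```
copies = (pct_reads_on_rdna × assembly_size) /
         (rdna_length × pct_reads_on_assembly)
```

Because the assembly collapses the array while reads come from the
physical genome, the expectation is `C(B + U)/(B + C·U)` (background
`B`, unit `U`, true copies `C`): biased low unless `B ≫ C·U`. The
acceptance tests verify ≤ 15% relative error at 7, 30 and 233 copies
with backgrounds chosen so the bias term stays inside that budget, and
the toy default configuration documents the visible bias honestly
(estimate ≈ 6.1 for 8 true copies at `B` = 100 kb).

## 7. Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the RNG
state of the caller; `run_pipeline()` derives all stage seeds from the
single config seed, so the entire result — including every written
artifact — is a pure function of the configuration. Default problem
sizes run in about 2 seconds per pipeline on one CPU; the full
acceptance battery (25 recovery seeds, 60 copy-number genomes up to
3.2 Mb, 100 calibration seeds) runs in minutes.
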