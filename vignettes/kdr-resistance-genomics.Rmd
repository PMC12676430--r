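---
title: "Methods: population genomics of kdr insecticide resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of kdr insecticide resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`kdrpopgen` implements the analyses used to characterise target-site and
metabolic insecticide resistance in *Anopheles gambiae* sensu lato cohorts:
diversity statistics in the voltage-gated sodium channel gene (*Vgsc*),
codon-level effect annotation and allele frequencies including the triallelic
402 locus, classification of individuals into kdr diplotype groups,
EM maximum-likelihood linkage disequilibrium from unphased genotypes,
median-joining haplotype networks, and copy-number-variation summaries for
detoxification gene families (CYP, COE, GST). Upstream steps — read alignment,
variant calling, phasing, sex calling, and CNV discovery from sequencing
depth — are out of scope: the package consumes a VCF, a metadata table, a gene
annotation table, and a table of per-sample per-gene modal copy numbers.

# The kdr panel model

The panel comprises three *Vgsc* loci in fixed order: codon 995 (reference
allele labelled L, alternates F and S), codon 402 (reference V; the two
mutant nucleotide changes g>t and g>c both encode leucine and are labelled L1
and L2), and codon 1527 (reference I, alternate T). A haplotype label is the
concatenation of one label per locus (FVI, LVI, LL1T, ...). Codon 995 is
modelled as a single triallelic site even though the F and S changes occupy
adjacent codon positions in the real gene; at the three-locus label level the
two representations are equivalent, and the single-site form keeps the panel
uniform. Published coordinates for these loci differ between sources and
numbering conventions (the community codon numbering 995 supersedes the
legacy 1014 numbering); the shipped defaults are a self-consistent set inside
the *Vgsc* span 2L:2358158–2431617 (402 at 2L:2391228, 995 at 2L:2422652,
1527 at 2L:2429617) and every coordinate is config-overridable via
`kdr_panel()`. Effect labels produced by `annotate_effects()` use the
supplied transcript's internal codon numbering; `apply_label_aliases()`
renders community names from an explicit alias map rather than hard-coding
either convention.

# Diplotype classification

Five named diplotype groups are recognised — FVI/FVI, FL1T/LVI, FL2T/LVI,
LL1T/LL1T and LL1T/LL2T — with every other haplotype pair (including all
S-carrying pairs and anything with a missing panel call) pooled as OD, "other
diplotypes". For phased input the unordered label pair is matched directly.
For unphased input all phase resolutions of the three-locus genotype are
enumerated; when more than one resolution exists the call is flagged
`ambiguous`, and when a named group is among the resolutions the *coupling
rule* assigns the group that places 995F, 402L and 1527T on the same
haplotype (so the triple heterozygote L/F, V/L1, I/T is reported FL1T/LVI
rather than the repulsion-phase FVI/LL1T). The flag preserves honesty about
phase uncertainty: unphased calls agree with phased calls whenever
`ambiguous = FALSE`, a property the test suite asserts on simulated cohorts.

# Diversity statistics

A site is segregating when at least two distinct non-missing alleles are
observed in the subset; the multiallelic fraction is the share of segregating
sites with more than two observed alleles. Per-site nucleotide diversity is
the mean pairwise difference over haplotype pairs divided by the region
length L; pairs missing at a site skip that site while the denominator stays
L (no per-pair renormalisation). Watterson's estimator is S/(a1·L) with a1
the harmonic number of n−1, and Tajima's D uses the classical constants with
S and the *total* mean pairwise difference. Choices for degenerate and
missing data:

* S = 0 reports D as undefined (`NA` with a flag), never 0.
* The constants use the region-wide modal haplotype count; per-site counts
  only affect the per-site heterozygosity terms.
* Multiallelic sites enter diversity through the full heterozygosity term
  (1 − Σ p²) and count once in S.
* Unphased genotypes use the unbiased allele-frequency form
  π = L⁻¹ Σ (n/(n−1))(1 − Σ p²) over the 2n observed alleles, which is
  algebraically identical to pairwise counting when no data are missing.

# EM linkage disequilibrium

For each pair of a 402 mutant allele (collapsed to focal-allele dosage, with
the other mutant pooled into "non-focal") and 1527T, haplotype frequencies
are estimated from the 3×3 unphased genotype table by the classic two-locus
EM under Hardy–Weinberg: only the double-heterozygote cell is
phase-ambiguous, split each E-step between coupling and repulsion in
proportion to the current frequency products; the M-step divides expected
haplotype counts by 2n. Initialisation is at linkage equilibrium
(f = product of allele frequencies), convergence is max |Δf| < 1e-10 within
1000 iterations, and the observed-data log-likelihood is recorded every
iteration (the tests assert it never decreases). r² = D²/(p_A q_A p_B q_B)
with D = f_AB − p_A p_B. Numerical conventions:

* A monomorphic locus leaves r² undefined; output tables render `NA` by
  default, with a switch (`zero_when_monomorphic`) to render 0 for fidelity
  with summary tables that print 0 where an allele is absent.
* Data consisting solely of double heterozygotes leave the likelihood flat
  between coupling and repulsion; the equilibrium start is then stationary at
  D = 0 and the result carries a `saddle` flag rather than pretending the
  phase is identified.
* Missing genotypes are removed pairwise per locus pair.
* A count-based phased estimator (`phased_r2()`) is provided as the
  independent oracle; the tests require the EM estimate to track it within
  0.05 on cohorts of 1000 diploids and the two converge as n grows.

# Median-joining networks

`median_joining()` follows the Bandelt construction: the minimum spanning
network keeps every link within ε of the minimal connection cost (ε defaults
to 0, the parsimonious network, matching common practice for *Vgsc*
haplotype reports); for every triplet in which two nodes share a linked
neighbour the majority-consensus median vector is added; the two steps
iterate to a fixed point; finally median vectors of degree ≤ 2 that lie on no
shortest path between sampled nodes are removed. Ties (median ties on
three-state columns, node ordering) resolve by lexicographic vector order, so
output is deterministic. Multi-state columns count any state change as
distance 1. On every instance with ≤ 4 sampled haplotypes over ≤ 6 binary
sites in the test battery, the network's spanning cost equals a brute-force
minimal Steiner-network search; the three-singleton instance {100, 010, 001}
recovers exactly the 000 median.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, with
ground truth retained for oracle tests:

* **Hardy–Weinberg pairing.** Each individual's two haplotype classes are
  drawn i.i.d. from the population's class frequencies — random union of
  gametes, no inbreeding parameter, matching the assumption built into the
  EM estimator.
* **Neutral background sites.** Derived-allele counts follow the standard
  neutral site-frequency spectrum (Pr(k) ∝ 1/k); sites are unlinked to the
  panel and to each other, and are private to their population (each
  population's segregating-site count is then the configured value, and
  populations are mutually diverged). Mean Tajima's D over 200 replicates at
  n = 20, S = 200 is required to sit in [−0.15, 0.15].
* **Class marker mutations.** Each haplotype class optionally carries k
  private marker sites (default cohort: k = 3) so that haplotype networks
  are non-degenerate. This is a modelling convenience, not a claim about
  within-class variation in real cohorts.
* **Copy numbers.** Per sample and gene: deletion with probability
  `del_freq` (uniform below baseline, 0 allowed — a complete deletion),
  amplification with probability `amp_freq` (baseline + 1 + geometric),
  otherwise baseline; baselines are 2 on autosomes and, on the X, 2 for
  females and 1 for males.

The default configuration (`inst/extdata/default_cohort.yaml`) holds eight
populations of 100 mosquitoes across the three ecological zones of the study
area: *An. gambiae* s.s. fixed for FVI, *An. arabiensis* mixing FVI and SVI,
and six *An. coluzzii* populations mixing LVI/FVI/LL1T with LL2T rare
(0.02–0.04). Under that mixture the L1 allele occurs only on T-bearing
haplotypes while T also rides the rare L2 class, which reproduces the
qualitative LD contrast the analysis is designed to detect: pooled
r²(402L(g>t), 1527T) ≈ 0.8 against r²(402L(g>c), 1527T) ≈ 0.05. Frequencies
of this kind — intermediate-frequency resistance classes — also produce the
positive Tajima's D the diversity stage reports.

What the generator does **not** emulate: linkage between background sites
(no recombination map or coalescent tree), selection, within-class haplotype
genealogy beyond the fixed markers, genotyping error, or missing data.
Passing tests therefore demonstrate correctness of the estimators under the
stated sampling models, not robustness to every property of field data.

# Pipeline determinism and problem sizes

`run_full_analysis()` executes the stages in dependency order, writes every
table with 6 significant digits, and records a manifest of MD5 checksums
keyed by the seed and a configuration hash; identical configuration and seed
give byte-identical manifests. The analysis scripts and acceptance checks use
the default cohort (800 samples, ~6,000 background sites, ~6,020 variants),
which runs end-to-end in about a minute on a single CPU; unit tests use
cohorts of 20–120 samples, LD oracle comparisons use 1,000–10,000 diploids,
and the Steiner brute force is restricted to ≤ 4 haplotypes × ≤ 6 sites,
where exhaustive search is exact and fast. These sizes were chosen to make
the statistical assertions sharp (binomial standard errors small relative to
the tested tolerances) while keeping the whole suite quick to run.

# Known limitations

* The PCA and clustering views operate on biallelic-collapsed dosages (one
  column per alternate allele); rare multiallelic genotype configurations are
  therefore represented by two correlated columns rather than a joint
  encoding.
* The unphased diplotype path resolves ambiguity by a fixed coupling rule;
  with phased input (the primary path) no such rule is needed.
* The LD estimator is the point-estimate EM; no bias correction or
  confidence intervals are computed.
* `cluster_map_order()` and `genotype_clustering()` use UPGMA throughout;
  alternative linkages are deliberately not exposed to keep outputs
  deterministic and comparable.
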