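---
title: "Simulating the neutral decay of codon adaptation"
author: "cubdecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the neutral decay of codon adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cubdecay` tests whether the codon adaptation of a gene — its bias toward the
translationally optimal codons of highly expressed genes — is consistent with
pure mutational decay from an ancestral state, or requires ongoing selection.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not establish.

## The mutation model

Chloroplast (and many other) mutation dynamics are strongly
*context-dependent*: the probability that a base mutates, and what it mutates
to, depends on its immediate 5' and 3' neighbours. The package represents
this as one 4x4 matrix per flanking context `N_N`. Because complementary
contexts describe the same double-stranded neighbourhood read from opposite
strands, the 16 contexts reduce to 10 canonical matrices (`A_A`, `A_T`,
`T_A`, `A_C`, `A_G`, `C_A`, `G_A`, `C_C`, `C_G`, `G_C`); `lookup_row()`
serves the other six by complementing the context, the current base and the
derived-base labels, which keeps a strand-specific analysis consistent.

Counts come from aligned *triplets* of noncoding sequence: two closely
related ingroup sequences and an outgroup. A column is scored only when both
flanking columns are identical and unambiguous in all three sequences —
otherwise the context itself is uncertain. Conserved ingroup sites increment
the diagonal of the ancestral base; ingroup differences are polarized by the
outgroup (the matching ingroup base is taken as ancestral); columns where all
three sequences differ are ignored. Working at very low divergence (about
0.5–1% on the ingroup branches) keeps multiple hits per site rare, so the
count ratios approximate relative instantaneous mutation probabilities, and
no multiple-hit correction is applied inside the model.

`fit_mutation_model()` converts counts to probabilities in two steps: each
row of each count matrix is divided by its row total (so diagonals are
non-zero and encode per-base "non-mutation" mass, i.e. rate variation), and
then a single global scalar rescales every off-diagonal entry so that the
fastest row across all matrices has off-diagonal sum `target_max_rate`
(default 1), diagonals absorbing the remainder. A single scalar is used
deliberately: it preserves relative rates both within rows and across
matrices, and it provably leaves every matrix's stationary vector unchanged
(the rescaled matrix is `I + c (P - I)`). The default of 1 minimizes
discarded self-mutation proposals in the simulator; any smaller value only
slows the simulation without changing its law.

Stationary compositions are obtained by repeated squaring of `P` until all
rows agree within `tol` (default 1e-10, at most 64 doublings); the common row
is the stationary vector, cross-checked in the test suite against a left
eigenvector computation at 1e-8. Non-ergodic matrices (possible when a
context has no observed substitutions from some base) raise an error from
`stationary_vector()` and are reported as undefined (`NA`) equilibrium
statistics by `summary()`, as are Ts:Tv and rate ratios with empty
denominators.

Model summaries report, per context: Ts:Tv among substitutions with G/C and
with A/T ancestral bases (classified by the *inferred ancestral* base; the
outgroup base is an equivalent choice at conserved-context sites, and the
package documents this as its convention), substitutions per site x 100, the
G/C-to-A/T per-site rate ratio, and the stationary composition as % G+C plus
skews. The skew conventions are `100 (C - G) / (C + G)` and
`100 (T - A) / (T + A)`; sign and denominator are package conventions chosen
for symmetry, since no standard exists.

Two other model kinds share the interface: `k2p_model()` builds the Kimura
two-parameter comparison model with a 3:1 transition:transversion ratio —
implemented as the transition receiving three times the mass of *each*
transversion (3/5 vs 1/5 of the row's off-diagonal mass), with equal rates
for all four bases — and `mutation_model()` wraps externally estimated
matrices (e.g. a previously published context model) after validating row
stochasticity.

## Codon adaptation

`fitness_table()` pools codon counts over reference genes and assigns, within
each synonymous family, `w(c) = (count + p) / (max family count + p)` with
pseudocount `p = 0.5`. The family maximum keeps `w = 1` exactly and
unobserved codons get a small positive value instead of zero, following the
usual practice for zero counts. Families are defined by amino acid (the
sixfold Leu/Ser/Arg families are kept whole), and Met, Trp and stop codons
are excluded from both estimation and scoring, the standard CAI convention;
families entirely absent from the references are omitted as unscorable.
`cai()` is the geometric mean of `w` over a gene's scorable codons.

Ambiguous ancestral reconstructions (IUPAC codes) are resolved site by site,
left to right, to the expansion base giving the codon with the highest or
lowest `w` (`resolve_ambiguities()`, modes `high`/`low`), bracketing the
ancestral adaptation. Stop-producing choices are disallowed; codons without a
table entry count as their family maximum (`w = 1`); ties break to the
alphabetically earlier base so results are deterministic. When an ambiguity
is amino-acid-changing the same `w` comparison is applied — the procedure
presumes mostly synonymous ambiguities, and this generalization is the
documented fallback.

## The decay simulator

Each round proposes and then selects:

1. a site is drawn uniformly over interior positions (positions 2..L-1;
   terminal bases have no two-sided context and are held fixed);
2. a derived base is drawn from the probability row of the site's *current*
   context — so context changes feed back as neighbours mutate — and a draw
   of the current base is discarded, implementing rate variation;
3. synonymous changes are accepted; stop-creating changes are always
   discarded; nonsynonymous changes are discarded in `syn_only` mode, and in
   `with_nonsyn` mode accepted with probability dN/dS provided the new
   residue appears at that site in a user-supplied amino-acid alignment
   (`acceptable_replacements()`). The per-gene dN/dS is supplied by the user
   (e.g. 0.029 for *psbA*, 0.101 for *psbD*, 0.074 for *rbcL*, 0.039 for
   *psaB* from published estimates).

CAI is recorded at accepted-mutation checkpoints (every `record_every = 5` of
`n_mutations = 500` by default, checkpoint 0 before any mutation), and
`simulate_decay()` aggregates mean and SD over `replicates = 1000`
independent replicates. Per-replicate seeds derive from the master seed by a
counter scheme (`(seed + 1000003 i) mod 2147483629`), so runs are
bit-reproducible and any single replicate can be regenerated. The start
codon gets no special protection — changes to it are nonsynonymous and follow
the normal rules. A proposal cap (default 1e7 per replicate) turns degenerate
inputs (ancestors with no synonymous moves) into an error instead of an
infinite loop. The inner loop is compiled (Rcpp) and draws from R's RNG, so
`set.seed()` governs everything.

## Divergence and the overlay

`k2p_distance()` implements the Kimura two-parameter estimator and its
large-sample variance from transition/transversion proportions, skipping
gap/ambiguity columns; `n` counts compared columns and the inferred mutation
count is `k * n`. The compared (ungapped) column count is used as the length
multiplier — the aligned or ancestor lengths are the documented alternatives,
identical in the no-indel case. K2P is appropriate here precisely because the
extant–ancestor divergences are small; at larger divergences the inferred
count under-corrects multiple hits at silent sites (a two-state synonymous
toggle saturates in a way no four-state model can see), so extant placements
drift left of the accepted-mutation axis. Comparisons should therefore be
read at modest divergence, which is also where the biology operates.

`mutation_range()` takes the minimum and maximum inferred count over the
(typically four) reconstructed ancestors, and `build_overlay()` classifies
each extant gene's CAI against the envelope spanned by the trajectories'
mean +/- 1 SD at the nearest checkpoint ("above", "within", "below";
positions beyond the simulated range are flagged `out_of_range` and
classified at the last checkpoint). The +/- 1 SD envelope is a package
convention — the original comparison of this kind was visual — and no
hypothesis test is attached, since extant genes share phylogenetic history
and are not independent.

## The synthetic-data generator

`generate_triplets()` draws a root from the model's stationary composition
averaged over contexts and evolves the outgroup and both ingroups on
independent branches with the same proposal kernel as the simulator
(`evolve_neutral()`), the number of substitutions drawn Poisson around the
requested expectation. Defaults (0.005 substitutions/site on ingroup
branches, 0.01 on the outgroup branch) mirror the sub-percent divergence
regime in which triplet scoring is meaningful. No indels are generated —
alignment is the identity — so gap handling in the scorer is tested by
separately injected gap columns; region-to-region rate heterogeneity and
real phylogenetic structure are likewise not emulated. Passing
parameter-recovery tests on these data therefore shows that counting,
merging, normalization and simulation are mutually consistent at known
truth; it does not validate alignment quality, annotation, or
rate-heterogeneity robustness on real genomes. `generate_coding()` draws
codons within each family with probability proportional to `w^beta`, giving
smooth control of ancestral adaptation from uniform (`beta = 0`) to maximal
(large `beta`). `example_context_model()` is a fixed, deterministic
10-matrix model with context-varying Ts:Tv (1–4), rates and G/C target bias
(0.55–1.55) — heterogeneity of the kind real chloroplast data display —
used as the known truth in recovery exercises.

## Validation scale and numerical choices

The test suite validates, among others: exact count conservation under
complement merging; stationary vectors against an independent eigenvector
oracle on 1000 random stochastic matrices (1e-8); recovery of the example
model from about 11.5 million scored synthetic sites (over 1e5 per context;
per-row substitution spectra checked at binomial resolution with a
family-wise threshold across the 120 comparisons, equilibrium G+C within 2
percentage points); protein preservation in 1000 of 1000 synonymous-only
replicates of a 353-codon gene; the terminal CAI of a long symmetric-kernel
run against an exact uniform-within-component enumeration oracle; and the
realized nonsynonymous acceptance rate against the configured dN/dS. These
problem sizes were chosen so that each statistical check has comfortable
power while the whole suite runs in minutes on one CPU.

Numerical conventions worth knowing: the >70 nt region filter is a strict
inequality on *ungapped* length (the aligned length is the documented
alternative); flanking context is read from adjacent alignment columns;
probability rows are renormalized exactly once at fit time and asserted
row-stochastic to 1e-12 afterwards; all tie-breaks are alphabetical; file
round-trips (counts, models, fitness tables, trajectories) are exact to the
serialized digits (counts are integers and round-trip bit-exactly).

## Interfaces and limitations

The package's interface is its functions — the workflow composes
`score_triplets()` + `merge_complements()` → `fit_mutation_model()` →
`simulate_decay()` → `build_overlay()` — plus plain-text serializations
(FASTA via Biostrings; TSV/JSON for matrices, fitness tables and
trajectories) and a minimal GenBank reader (`read_genbank()` /
`extract_intergenic()`, which reduces join/complement locations to their
enclosing span and takes regions on the forward strand; the model's
complementation machinery keeps counting strand-consistent). Multiple
sequence alignment, phylogeny inference, ML ancestral reconstruction and
dN/dS estimation are consumed as inputs, not performed. Wright–Fisher
selection on synonymous codons, indels and recombination are out of scope:
the simulator asks what happens in the *absence* of selection on codon
usage, which is exactly the null the analysis needs.
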