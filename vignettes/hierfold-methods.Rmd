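---
title: "Methods: hierarchical comparative prediction of joint RNA structures and interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical comparative prediction of joint RNA structures and interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`hierfold` predicts a *joint* secondary structure for two families of
homologous, interacting RNAs given two pre-computed multiple alignments
with matched taxa: the intra-molecular structure of each RNA plus the
inter-molecular helices that form the interaction. The biologically
interesting geometries — kissing hairpins, where loop residues of one
hairpin pair with loop residues of another — are pseudoknots with respect
to the union of intra- and inter-molecular pairs, and are therefore
inaccessible to a single nested dynamic program over the concatenated
sequences. The package takes the hierarchical route: first fix what is
reliable, then fold the remainder under constraints, and allow the two
rounds to cross each other.

Two probabilistic models are combined throughout.

**Evolutionary model.** A stochastic context-free grammar

    S -> LS | L      L -> s | dFd      F -> dFd | LS

defines a prior over consensus structures; column emissions come from
reversible substitution models on a phylogenetic tree (Felsenstein
pruning): a 4-state model for unpaired columns and a 16-state
dinucleotide model for paired columns, whose stationary distribution
concentrates on the six canonical (Watson–Crick and GU) pairs so that
compensatory double substitutions preserve pairing. Inside–outside over
the grammar yields, per column, the posterior probability of being
single-stranded and, per column pair, the base-pair reliability; by
construction these satisfy `P_ss(i) + sum_j P_bp(i,j) = 1`. All
probabilities are defined over *parse trees* (the grammar is ambiguous for
some structures), and the enumeration oracle used in the tests enumerates
parse trees accordingly.

The grammar probabilities and rate matrices are loaded from a bundled
plain-text asset (`inst/extdata/scfg_params_synthetic.txt`). The asset is
a synthetic stand-in constructed for this package — grammar production
probabilities at the magnitudes typical for structural-RNA grammars
trained on rRNA/tRNA, GTR-style rate matrices built from stationary
frequencies — and every operation takes the parameter set as an argument,
so a user can substitute their own file in the same format. Two
calibration choices matter:

* the single-nucleotide process is scaled to 1 expected substitution per
  unit branch length (branch lengths are in substitutions per site);
* the dinucleotide process is scaled to **2** per unit branch length
  (`pair_rate` in the asset), because a pair state covers two sites.
  With both processes on the per-site clock, conserved columns do not
  spuriously prefer the paired emission model simply because it runs
  slower.

**Thermodynamic model.** Per-sequence Boltzmann ensembles over nested
structures under a deliberately simplified nearest-neighbor energy
function: a 6×6 stacking table (pair strengths GC/CG 3, AU/UA 2, GU/UG 1
kcal/mol, `stack = -(s_outer + s_inner)/2 - 0.5`), affine hairpin
(`1.8 + 0.3·u`), interior/bulge (`1.0 + 0.3·u`) and multiloop
(`3.4 + 0.3·u + 0.4·branches`) penalties, `RT = 0.61633` kcal/mol
(310.15 K), no dangling ends, minimum hairpin loop 3 nt. The package's
contract is *a constrained thermodynamic ensemble whose probabilities are
exactly the Boltzmann sums its energy function defines* — verified
against exhaustive enumeration to 1e-9 — not kcal-level agreement with
any published parameter compilation. The inside/outside partition-function
kernel supports forced-unpaired positions, forced pairs, cofolding and an
isolated-pair filter.

**Cofolding semantics.** The concatenation `s1 & s2` carries a linker
that can never pair. Any loop *containing* the linker (no child helix
covering the cut point) is scored as an exterior-like region: no loop
penalty, no hairpin minimum — so a lone inter-molecular pair between the
chain ends is legal. A stacking step between pairs `(i,j)` and
`(i+1,j-1)` is only valid when both pairs agree on spanning the cut;
an outer pair spanning the cut above a side-local inner pair has the
backbone break inside its loop (the strands are not adjacent there), so
that arrangement is scored exterior-like instead. The isolated-pair
filter uses the same adjacency notion: two stacked neighbors form a helix
step only if they agree on spanning the cut. These conventions are
mirrored verbatim in the enumeration oracle, which is the authority the
DP is tested against.

## The two-step pipeline

**Step 1 — reliable partial structures.** Per part, combined
reliabilities `R(i,j) = P_ev(i,j) + (beta/n) Σ_s P_th(i,j,s)` are
thresholded on the normalized scale `R/(1+beta)`: since both components
are per-position sub-probabilities of nested-structure distributions, two
conflicting (crossing or position-sharing) pairs have normalized masses
summing to at most 1, so any cutoff `>= 0.5` yields a conflict-free
selection — this is the invariant the acceptance script measures. The
cutoff starts at `delta_start` (default 0.5, the smallest safe value) and
is raised in `delta_step` increments until the *ensemble probability* of
the selection passes the gate: `Pr_ev[E(sigma^p)] >= gamma` or the
per-row thermodynamic `Z_constrained/Z >= gamma`, aggregated over rows by
minimum (default; every sequence must tolerate the constraints) or mean.
An empty selection passes trivially with probability 1. Selected maximal
helices are then extended by the immediately inner, then outer pair while
the extended stem's average normalized reliability exceeds the cutoff and
the gate still passes; the gate is re-evaluated after every single added
pair (the conservative reading of per-stem extension), and candidates
that would collide or cross existing pairs are rejected.

**Step 2 — constrained joint scoring.** The `sigma^p` positions are
constrained single-stranded, which keeps every structure nested on the
*remaining* positions even when the true joint structure is pseudoknotted
— the crossings reappear when the layers are united. Each row is
cofolded under those constraints; the joint alignment (three prior-free
linker columns, single tree estimated from the concatenation by
neighbor-joining on Jukes–Cantor distances) is re-scored by the
constrained SCFG. Raw probabilities are rescaled by the product of the
two Step-1 ensemble probabilities, per model and (thermodynamically) per
row; the `sigma^p` pairs themselves are set to their fixed ensemble
probability, which avoids competition with the constrained-run
probabilities while weakening the strict independence assumption (the
variant that scores them 1 is available as `eq15 = TRUE`). Prior-free
linker columns emit probability 1, are constrained unpaired and
contribute no unpaired-production probability; they exist so the joint
SCFG run is not biased by an arbitrary linker composition.

**Final assembly.** A Nussinov-style maximum-expected-accuracy decoder
maximizes `Σ 2·R2_bp + Σ R2_ss` over nested structures with the
`sigma^p` positions forced unpaired and their pairs at weight 0, then the
`sigma^p` pairs are re-added unconditionally. Output pairs carry one of
three layers — constrained `[ ]`, new intra-molecular `( )`,
inter-molecular `< >` — each internally nested, with crossings only
between layers. The per-pair "accuracy credit" convention is 2 per pair
(its two columns) and 1 per unpaired position; only the ratio of pair to
single-stranded weight matters to the argmax, and `alpha` (default 0.2)
exposes it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.9 | demo-configuration reliability cutoff (normalized scale, must be ≥ 0.5) |
| `delta_start`, `delta_step` | 0.5, 0.05 | cutoff adaptation: start (clamped to ≥ 0.5) and increment |
| `gamma` | 0.1 | ensemble-probability gate for partial structures |
| `alpha` | 0.2 | weight of single-stranded reliabilities in the decoder |
| `beta` | 1.0 | weight of the thermodynamic vs the evolutionary part |
| `extend_stems` | TRUE | inner/outer extension of constrained stems |
| `no_isolated` | FALSE | remove lone pairs from the thermodynamic ensemble |
| `eq15` | FALSE | score constrained pairs 1 instead of their ensemble probability |
| `gamma_agg` | "min" | per-row aggregation of the thermodynamic gate |
| `evo` | TRUE | disable for single-sequence input |

The `delta`/`delta_start` pairing deserves a note: the adaptation is
specified as *raising the cutoff from the smallest safe value until the
ensemble is probable enough*, so selection defaults to `delta_start =
0.5`; `delta = 0.9` is the strict demonstration cutoff a user can pass as
`delta_start` to reproduce that behavior. Starting low and letting the
gamma gate prune improbable selections is what keeps the hierarchical
layer active on alignments whose thermodynamic part dilutes the combined
reliabilities.

## The synthetic generator

`synth_spec()`/`generate_pair()` emulate the signal the method is built
for: a root sequence pair evolved down a fixed 5-taxon tree (branch
lengths 0.06–0.18 substitutions/site), with two 4-bp planted stems per
60-nt part and one 6-bp inter-molecular site placed in the loops of the
first stem of each part (kissing-hairpin geometry). Planted pair columns
— intra-molecular *and* inter-molecular — co-evolve under the 16-state
model conditioned on canonical states, producing compensatory base
changes; background positions evolve independently under the 4-state
model; gaps can optionally be injected at background positions. The
generator returns the planted truth as a `joint_structure`, and the
end-to-end acceptance check asks that ≥ 80% of 20 seeded replicates
recover at least 4 of the 6 planted inter-molecular pairs.

What the generator does *not* emulate: alignment errors (rows are
generated aligned), indel evolution (gaps are injected, not evolved),
rate heterogeneity across sites, non-canonical or tertiary interactions,
and interaction sites in unstructured regions. Passing the recovery test
therefore demonstrates that the pipeline exploits clean compensatory
signal in well-aligned data; it does not bound performance on real
alignments, where alignment quality around unstructured binding sites is
the known weak point of comparative methods.

## Numerical choices

* SCFG inside–outside runs in log space with streamed log-sum-exp; the
  per-column posterior identity is checked to 1e-6 and then enforced
  exactly by recomputing the single-stranded posterior as the complement.
  Infeasible constraints return `-Inf` normalizers and are flagged rather
  than raised.
* The thermodynamic kernel runs in linear space (double precision
  comfortably covers the ~150-nt scale the tool targets) and raises an
  explicit overflow error otherwise. Probabilities are clipped of
  negative rounding residue below 1e-12.
* Matrix exponentials use the symmetrized eigendecomposition of the
  reversible rate matrices, with a scaling-and-squaring series fallback;
  `t = 0` returns the exact identity so that impossible observations give
  true zeros rather than rounding noise.
* Neighbor-joining branch lengths are clamped at 0; saturated
  Jukes–Cantor distances are an error naming the offending pair.
* The MEA decoder breaks ties deterministically (prefer unpaired, then
  the smallest left index), so identical configurations give
  byte-identical reports.
* Gaps and ambiguity codes are missing data in the evolutionary model
  (all-ones partial likelihoods); a leaf gapped in exactly one column of
  a pair is treated as missing in both — the symmetric convention. In
  the thermodynamic model `N` never pairs. Consensus pairs projected onto
  a row drop gap ends and non-canonical realizations; a row whose
  projection of the partial structure is impossible gets ensemble
  probability (and hence scale factor) 0 and is flagged, but still
  cofolds.
* Problem sizes in the test suite are chosen to keep brute-force oracles
  exact and fast: enumeration to total length 14 for thermodynamics,
  8 columns × 3 rows for parse-tree enumeration, length 14 for
  exhaustive MEA search, and 20 pipeline replicates at the generator's
  standard 60+60 condition.

## Known limitations

* The energy model is intentionally lite; absolute free energies are not
  comparable to Turner-parameter tools, only the ensemble *probabilities*
  under the stated model are meaningful.
* Constraining `sigma^p` single-stranded in Step 2 means intra-molecular
  helix extensions across the constrained pairs are scored as interior
  loops or hairpins of the surrogate ensemble; stem extension in Step 1
  mitigates but does not remove this bias.
* One tree is estimated from the concatenated alignment in Step 2; RNAs
  with genuinely different evolutionary histories violate this
  assumption.
* Iterating Step 2 to stack further pseudoknot layers is out of scope:
  combining the shrinking partial-structure probabilities across
  iterations into one scoring scheme is unresolved, so the package stops
  at one constrained round (three bracket layers).
* The summed inter-molecular reliability reported by
  `interaction_score()` is a convenience metric of this package, not part
  of the method's scoring scheme.
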