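---
title: "Quantifying genetic correlations in genotype-phenotype maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic correlations in genotype-phenotype maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A genotype-phenotype (GP) map assigns every string of length $L$ over a
$K$-letter alphabet to one phenotype. Mutational neighbourhoods in
biophysical GP maps are widely believed to be far from random: a genotype's
single-mutant neighbours are much more likely to share its phenotype, and
the composition of nearby neighbourhoods is correlated. `gpmapcorr`
quantifies these *genetic correlations* by comparing a map of interest to a
frequency-matched **random null map** that keeps the alphabet, genome
length, phenotype inventory and every redundancy $F_p$ fixed, while
scattering the genotypes of each phenotype uniformly over the Hamming
graph. Departures of any statistic from this null are, by construction,
correlations in how phenotypes are arranged.

The package provides three self-contained biophysical engines (HP lattice
protein folding, polyomino lattice self-assembly, and a toy maximum-pairing
RNA folder), synthetic map generators that serve as null and
positive-control conditions, and the statistics described below.

## Statistics

**Robustness.** The phenotype robustness $\rho_p$ is the fraction of the
$(K-1)L$ point-mutation neighbours that preserve the phenotype, averaged
over the neutral set $G_p$. In the random map $\rho_p = f_p$, the
phenotype's frequency, so $\rho_p \gg f_p$ diagnoses positive neutral
correlations. `robustness()` computes the exact average on complete maps in
one vectorised sweep over the $(K-1)L$ neighbour classes, or a sampled mean
with standard errors.

**n-robustness and the correlation length.** `n_robustness()` generalises
this to the exact Hamming-distance-$n$ shell of $\binom{L}{n}(K-1)^n$
mutants. In the null the curve is flat at $f_p$; in correlated maps it
decays, and the smallest radius at which it falls *strictly below* $f_p$ is
the neutral correlation length $n^\*$ (`NA` when no crossing occurs within
`n_max` — the strict inequality means noisy flat curves can report a
spurious small $n^\*$; the reported standard errors should be consulted).
Shells are enumerated exhaustively while `F_p * shell_size` stays below
`exact_bound` (default $2\times 10^6$) and sampled otherwise.

**Percolation thresholds and neutral components.** The random map has a
giant-component onset at $\delta = 1/((K-1)L)$ (on average one neutral
neighbour), a single-component onset at $\lambda = 1-(1/K)^{1/(K-1)}$, and
a neighbourhood sampling threshold $\gamma = 1/(F_p (K-1) L)$ below which a
phenotype is expected to be absent from a neutral set's 1-mutation
neighbourhood. `neutral_components()` decomposes a neutral set with
union-find (union by size, path halving, edges streamed position-major so
the result is deterministic); the test suite checks it against independent
breadth-first-search and igraph decompositions. Component analysis is
restricted to complete maps: a sampled oracle cannot certify connectivity.

**Phenotype mutation probabilities.** `phi_matrix()` computes
$\phi_{qp}$, the probability that a point mutation from a random member of
$G_p$ yields $q$; columns sum to one and $\phi_{pp}=\rho_p$ exactly on
complete maps. In the null $\phi_{qp} = f_q$ for $f_q > \gamma$;
`phi_spearman()` reports the rank correlation over that regime and flags
unreachable phenotypes ($\phi_{qp}=0$).

**Local over-representation.** `overrep_distribution()` measures the
conditional distribution $P(q,p,m)$ of the number of occurrences $m$ of $q$
in a neighbourhood, given at least one occurrence. The conditioning is
per neighbour *slot* (uniform genotype, uniform slot carrying $q$), which
makes the random map reproduce the binomial null
$P_1(m) = \binom{(K-1)L-1}{m-1} f_q^{m-1}(1-f_q)^{(K-1)L-m}$ exactly; on
complete maps the slot-weighted distribution is computed exactly rather
than sampled. $P_2$ substitutes $\phi_{qp}$ for $f_q$. The panel of focal
phenotypes defaults to the largest non-deleterious phenotypes other than
$q$ itself.

**Neighbourhood similarity.** For a neutral neighbour pair $(g,h)$ and a
non-neighbouring neutral control $g_2$, local neighbourhood phenotype
distributions are compared with the Bhattacharyya coefficient
$BC(x,y)=\sum_i \sqrt{x_i y_i}$, and the similarity ratio
$BC(g,h)/BC(g,g_2)$ is averaged over draws. The $K-2$ mutual neighbours of
$g$ and $h$ (the other variants at their differing locus) are removed from
both distributions, because they contribute trivially to similarity; no
slots are removed for the control pair. Two conventions for draws with a
zero coefficient are reported (`mean_ratio` over finite ratios, and
`mean_ratio_positive` over draws where both coefficients are positive),
and the deleterious phenotype is included as a category by default
(`include_del = FALSE` drops it). Note the ratio is a biased estimator at
finite neighbourhood size: conditioning on neutral adjacency guarantees one
shared category, the mutual-neighbour exclusion removes guaranteed-shared
mass, and the ratio of noisy coefficients carries Jensen curvature. These
effects are $O(1/((K-1)L))$ and vanish at the neighbourhood sizes of
realistic maps; on small test spaces the null check is therefore made at
each realisation's own sampling precision rather than on an
infinitely-averaged ensemble.

**Deleterious correlations.** `deleterious_correlation()` reports
$\phi_{\mathrm{del},p}/f_{\mathrm{del}}$ per folding/assembling phenotype
(below one when the deleterious phenotype is under-represented around
functional ones) and the self-ratio
$\rho_{\mathrm{del}}/f_{\mathrm{del}}$.

## Engines

**HP lattice.** Binary H/P chains on the square lattice with contact
energies $E_{HH}=-1$, $E_{HP}=E_{PP}=0$; a contact is a chain-non-adjacent,
lattice-adjacent residue pair. Folds are self-avoiding walks, enumerated
depth-first; compact mode restricts them to Hamiltonian paths of a
$W\times W$ grid. Fold identity is the equivalence class under translation
plus the 8-element dihedral group, with chain direction fixed (residue 1
distinguished) — the canonical id is the lexicographically minimal
coordinate string over symmetry images. Degeneracy is counted over
symmetry-distinct folds: a sequence maps to a fold only when it is the
*unique* energy minimum, and to the deleterious label otherwise. Whether
chain reversal should also be quotiented is a genuine convention choice;
with direction fixed, length-4 chains fall into five classes (straight,
two L-bends, zigzag, U-bend), of which only the U-bend supports a contact.
The complete map builder evaluates contact energies for all $2^L$
sequences in vectorised chunks; the full compact $5\times 5$ enumeration
is provided as a separate long-running script, and the default analyses
use the $3\times 3$ and $4\times 4$ compact maps, which exercise the same
code path at desk scale.

**Polyomino self-assembly.** A genotype of length $4N_t$ over interface
labels $0..N_c-1$ encodes square tiles (edges written clockwise from
north); labels interact in odd-even pairs ($1{\leftrightarrow}2$,
$3{\leftrightarrow}4$, $5{\leftrightarrow}6$ for $N_c=8$; 0 and 7 are
inert). Assembly seeds tile 1 at the origin and repeatedly draws a uniform
(frontier cell, tile, orientation) triple, accepting placements with at
least one interacting facing pair — non-interacting facing pairs are
tolerated (no steric veto), the minimal reading of bond-based acceptance.
After 50 consecutive rejected draws an exhaustive attachability scan
decides halting exactly, making termination deterministic rather than
probabilistic; structures exceeding `size_cap` (default $16 N_t$) are
declared unbounded. A genotype maps to a shape only when `n_repeats`
(default 20) independent assemblies — streams derived from (genotype,
repeat, master seed), so verdicts are reproducible and monotone in the
repeat count — produce the same canonical shape; otherwise it is the
undefined (deleterious) phenotype UND. Shape identity quotients rotations
only: oriented interfaces make mirror shapes physically distinct
(`reflections = TRUE` switches this). A worked subtlety: a tile with a
complementary pair on *adjacent* edges closes deterministically into a
$2\times 2$ windmill tetromer, while the same pair on *opposite* edges
polymerises without bound. The identity convention is a real sensitivity:
in sampled classifications of the full two-tile, eight-interface space the
rotations-only convention yields one extra phenotype relative to the
reflection quotient, because one deterministic octomer assembly comes in a
chiral mirror pair.

**Toy RNA.** A self-contained maximum-base-pairing folder: dynamic
programming over allowed pairs (AU, UA, GC, CG, GU, UG by default) with a
minimum hairpin loop of 3 unpaired bases and a deterministic traceback
(when pairing the interval's first position attains the optimum it is
paired with the smallest admissible partner; otherwise it is left
unpaired). The phenotype is the dot-bracket string; the deleterious label
is the fully unpaired structure. The traceback structure is taken as the
phenotype without a degeneracy test — a documented divergence from
thermodynamic folding, where co-optimal ground states would be flagged.
This engine exists so every statistic has a reproducible RNA-like map; it
does not claim to reproduce thermodynamic-package results, and the
optional `external` backend (an `RNAfold` executable on the PATH) is
best-effort only.

## Synthetic conditions

`generate_random_map()` realises the null itself: a seeded Fisher-Yates
permutation of the rank array sliced by cumulative redundancy, preserving
the spectrum exactly. Spectra are either explicit counts or log-uniform
frequencies over a stated number of decades (counts rounded with the total
repaired on the largest phenotype, so $\sum_p F_p = K^L$ holds exactly).

`generate_correlated_map()` provides positive controls with known
direction: `hamming_ball` grows each phenotype from a random seed genotype
by frontier accretion (with probability `strength`; uniform placement
otherwise), producing compact connected neutral sets with
$\rho_p \gg f_p$; small phenotypes are grown first so their clusters stay
intact and the large background absorbs the residue. `locus_block` orders
genotypes by a chosen set of determining loci and slices, so phenotype
identity is carried by a few positions — this is the control that makes
neutral neighbours' neighbourhoods measurably more similar (BC ratio above
one). Both preserve the spectrum exactly, and `strength = 0` degenerates
to the random map.

`build_wordgame_map()` builds the 4-letter word game over $26^4 = 456{,}976$
strings from any plain-text word list: "valid" versus "invalid" (the
deleterious role). The bundled demo list of 641 common four-letter words
(including the WORD-WORE-GORE-GONE-GENE chain) exists so the game is
testable offline; its frequency and robustness differ from a full Scrabble
dictionary, so tests assert the structural facts (100 neighbours per word,
connectivity of the demonstration path, $\rho \gg f$) rather than
dictionary-specific values.

## What the synthetic tests do and do not show

The generators emulate arrangement structure only — clustering and
locus-determination against a uniform null. They do not emulate the
biophysical constraint systems (base-pairing reciprocal sign epistasis,
chain parity, interface chirality) that fragment real neutral sets into
many components, nor realistic phenotype inventories whose frequencies
span ten orders of magnitude. Passing null-recovery and positive-control
tests therefore certifies that the statistics measure what they claim on
maps with known ground truth; conclusions about any particular biophysical
map still require running the engines themselves.

## Numerical choices

* Genotypes are ranked in mixed radix (position 1 most significant);
  ranks and space sizes are held as doubles, exact below $2^{53}$, so
  $8^{12}$-genotype spaces index correctly without 64-bit integers.
* Complete maps store one integer phenotype code per rank with a sidecar
  label table; sampled maps wrap a deterministic oracle behind a memo
  cache keyed by rank.
* All stochastic routines take an explicit seed and restore the caller's
  RNG state; derived stream seeds stay below $2^{31}$.
* Default problem sizes in the test suite ($K \le 4$, $L \le 10$ complete
  maps, 20-seed ensembles, a few hundred similarity draws) were chosen so
  every statistic can be checked against exhaustive enumeration; the
  engines scale to the $2^{25}$-genotype compact HP map via the chunked
  builder and the long-running regression script.
* Enumeration guards refuse non-compact HP beyond $L=20$, complete RNA
  maps beyond $L=12$ and complete polyomino spaces beyond $2^{20}$
  genotypes unless explicitly overridden, failing with a distinct guard
  condition class.

## Known limitations

* The neutral-walk sampler for rare phenotypes in oracle-backed spaces is
  approximately uniform; it over-visits high-robustness genotypes. Results
  derived from it carry that bias and are labelled as sampled.
* The similarity-ratio estimator's finite-size bias (above) makes
  cross-map comparisons meaningful only at matched $(K-1)L$.
* The polyomino UND verdict is a stochastic decision; it is reproducible
  under the seeded protocol and stable under doubling `n_repeats`, but a
  genotype whose assemblies disagree with probability far below
  $1/\texttt{n\_repeats}$ can be misclassified as deterministic.
* Indels, recombination, fitness assignment, thermodynamic ensembles and
  3-D lattices are out of scope throughout.
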