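# gpmapcorr

Genetic correlations in genotype-phenotype (GP) maps.

A GP map assigns each of the `K^L` strings over a `K`-letter alphabet to a
phenotype. In biophysical maps the arrangement of phenotypes over the
Hamming graph is far from random: a genotype's point-mutation neighbours
are much more likely to share its phenotype (*neutral correlations*), and
the composition of nearby mutational neighbourhoods is itself correlated
(*non-neutral correlations*). Both kinds of structure shape mutational
robustness, the existence of neutral networks, and the rate at which
evolution discovers novelty. This package is for researchers who want to
measure that structure quantitatively, by comparing any complete or
oracle-backed GP map against a **frequency-matched random null map** — same
alphabet size `K`, length `L`, phenotype inventory and redundancies `F_p`,
but with genotypes assigned uniformly at random.

## What it computes

For a phenotype `p` with neutral set `G_p` (size `F_p`, frequency
`f_p = F_p / K^L`):

* **Robustness** `rho_p = (1/F_p) * sum_{g in G_p} n_{p,g} / ((K-1)L)`,
  against the null value `rho_p = f_p`; generalised **n-robustness** over
  exact Hamming-distance-`n` shells, its map-level average against `1/N_P`,
  and the **neutral correlation length** `n*` (first radius where the curve
  drops below its null).
* **Percolation thresholds** of the null: giant-component onset
  `delta = 1/((K-1)L)`, single-component onset
  `lambda = 1 - (1/K)^(1/(K-1))`, sampling threshold
  `gamma = 1/(F_p (K-1) L)`; plus exact **neutral-component
  decompositions** (union-find) and per-phenotype percolation summaries.
* **Phenotype mutation probabilities** `phi_qp` (columns sum to one,
  `phi_pp = rho_p`), with Spearman comparison against `f_q` above `gamma`.
* **Local over-representation**: the conditional distribution of the number
  of occurrences `m` of a phenotype in a neighbourhood given at least one,
  against two binomial nulls (from `f_q` and from `phi_qp`).
* **Neighbourhood similarity** of neutral neighbours versus non-neighbour
  neutral pairs, via Bhattacharyya coefficients of local phenotype
  distributions (mutual neighbours removed).
* **Deleterious-phenotype correlations**: `phi_del,p / f_del` ratios and
  `rho_del / f_del`.

Three GP-map engines are included — the HP lattice protein model (compact
and non-compact), the polyomino lattice self-assembly model, and a toy
maximum-base-pairing RNA folder (with an optional external `RNAfold`
backend) — together with synthetic generators: frequency-matched random
maps, positively correlated positive-control maps (Hamming-ball and
locus-block clustering), and Maynard Smith's 4-letter word game built from
any plain-text word list.

## Worked example

```r
library(gpmapcorr)

# Maynard Smith's word game over 26^4 = 456,976 strings, with the bundled
# demo list of 641 common four-letter words
m  <- build_wordgame_map()
ws <- wordgame_summary(m)
ws$F_valid                      # 641
signif(ws$f_valid, 3)           # 0.0014   frequency of the "valid" phenotype
round(ws$rho_valid, 4)          # 0.0447   robustness: 32x the null value f_p
percolation_thresholds(26, 4)$delta    # 0.01  giant-component onset
ws$components$n_components      # 79      neutral components of the valid set
ws$components$largest           # 526     most words sit in one component
```

Even this small dictionary shows the hallmark of neutral correlations: a
valid word has a valid neighbour about 32 times more often than the random
expectation, and most valid words form a single mutationally connected
network even though `f_p` is well below the percolation threshold `delta`.

```r
# positive control with known ground truth: a Hamming-ball phenotype
spec <- spectrum_spec(2, 10, counts = c(ball = 56, del = 968))
mb   <- generate_correlated_map(spec, "hamming_ball", strength = 1, seed = 3)
robustness(mb)
#>   phenotype       rho      null
#> 1      ball 0.2892857 0.0546875
#> 2       del 0.9588843 0.9453125
n_robustness(mb, "ball", n_max = 10)$n_star   # 5: correlations reach radius 5
neutral_components(mb, "ball")$n_components   # 1: a connected neutral network
```

A command-line wrapper over the same functions lives in
`inst/scripts/gpmap-tools.R`
(`build-map {hp,polyomino,rna}`, `generate {random,correlated,wordgame}`,
`nullmap`, `stats {robustness,phi,components,delcorr}`), writing TSV tables
with JSON metadata sidecars.

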