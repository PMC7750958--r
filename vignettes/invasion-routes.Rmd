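---
title: "Reconstructing DNA-transposon invasion routes from internal-deletion fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing DNA-transposon invasion routes from internal-deletion fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(idroute)
```

## The problem

DNA transposons such as the *Drosophila melanogaster* P-element multiply by
cut-and-paste transposition: the element excises, reinserts elsewhere, and the
double-strand break left at the donor site is repaired from the sister
chromatid, which restores a copy there. When that gap repair is interrupted,
the restored copy lacks an internal segment — an internal deletion (ID),
defined by an ordered breakpoint pair on the 2,907-bp consensus. IDs are
nonautonomous (they need the transposase of full-length, FL, copies), they
arise at a high rate but *only while the element is active*, and their
breakpoints are essentially random, so identical IDs rarely arise twice.

These properties make IDs natural markers of invasion history. Each invaded
population accumulates its own set of IDs — its *ID fingerprint* — during the
brief window before the host silences the element. Migrants carry a sample of
FL and ID copies into a naive population, triggering a new invasion there that
amplifies the inherited IDs and adds new ones. Two consequences follow:

1. the fraction of ID copies increases along a chain of successively invaded
   populations (the first-invaded population retains the most FL copies), and
2. successively invaded populations share similar fingerprints, so a
   distance built from ID frequencies reflects the invasion path.

`idroute` implements both halves of this logic: a forward simulator that
produces invasions with IDs under the piRNA-cluster trap model, and the
analysis pipeline that turns fingerprint tables into distance matrices, trees,
and route reconstructions.

## The simulation model

`run_invasion()` performs an individual-based forward simulation of diploids
with `N` individuals per population and non-overlapping generations. Each
generation executes, in order: fitness-weighted formation of parent pairs,
gamete formation along the recombination map, transposition into the gametes
of active parents, zygote formation, bookkeeping of cluster insertions, and
(in stepping-stone runs) migration.

**Genome and clusters.** The default genome has five 1-Mb chromosomes at
4 cM/Mb with a 100-kb piRNA cluster at the distal end of each chromosome
(10% of the genome). Under the trap model, a TE is active in an individual
only if the individual carries at least one FL copy and *no* insertion — FL
or ID — inside any cluster; a single cluster insertion silences every copy in
that individual.

**Transposition and conversion.** In the germline of an active parent, the
number of new insertions per gamete is Poisson with mean `u` times the
gamete's copy number, and each event copies a template element to a uniform
unoccupied site (chromosomes weighted by length). The template is drawn with
per-copy weight `fl_id` for FL copies and `1 - fl_id` for ID copies, so the
default 0.5 makes every copy an equally likely template. The pasted copy is a
complete copy of its template. When the template is FL, interrupted gap repair
converts the *transposing element itself* into a fresh ID with probability
`c`: its two breakpoints are drawn as distinct uniform positions on the
consensus and ordered. We place the deletion at the donor side deliberately —
that is where gap repair happens mechanistically; the pasted element moved as
an intact unit. (At the level of expected ID counts the two placements are
nearly equivalent, since either way each event converts one copy with
probability `c`; we verified this empirically.) ID copies propagate their
breakpoints unchanged and never revert: a copy carries at most one deletion.

**Mating and migration.** Each offspring draws two parents independently with
probability proportional to fitness `max(0, 1 - x * n)` (uniform at the
default `x = 0`), excluding self-pairing. Migration copies `m` individuals
sampled without replacement from the most recently invaded population over
`m` random individuals of the next naive one, keeping both censuses at `N`;
the source is unchanged. This keeps the constant-`N` bookkeeping simple and
matches the usual stepping-stone convention.

**Invasion phases.** With the defaults (`u = 0.1`, 300 founder FL copies at
frequency `1/2N`), an invasion shows the familiar three phases: rapid spread,
a long "shotgun" phase in which segregating cluster insertions silence a
growing majority of individuals, and eventual inactivity. Silencing by
*segregating* insertions is slow: a shrinking minority of cluster-free
individuals keeps transposing for hundreds of generations, so the ID fraction
keeps creeping upward long after the copy number has visibly plateaued. We
therefore measure plateau quantities at a 3,000-generation horizon — the same
horizon at which stepping-stone runs are sampled — averaging the last 100
generations. Much later (beyond ~4,000 generations) drift starts to erode
segregating ID variants and the mean ID fraction slowly declines again; the
3,000-generation plateau is the regime the method is about.

```{r quick-run}
cfg <- sim_config(N = 200, n_fl = 60, conversion = 0.05,
                  chrom_len = rep(2e5, 5), cluster_len = 2e4,
                  generations = 150, u = 0.1)
inv <- run_single_invasion(cfg, seed = 1)
tail(inv$records, 3)
```

Key tunable parameters, with units and defaults:

| parameter | meaning | default |
|---|---|---|
| `u` | transposition rate per copy per generation | 0.1 |
| `conversion` (`c`) | ID conversion probability per transposing FL element | 0 |
| `x` | per-copy fitness cost | 0 (neutral) |
| `N` | diploid population size | 1000 |
| `fl_id` | per-copy mobilization weight of FL copies | 0.5 |
| `cluster_len` | piRNA cluster length per chromosome (bp) | 100,000 |
| `rr` | recombination rate (cM/Mb) | 4 |
| `n_fl` | founder FL copies in population 1 | 300 |
| `migration_m` / `migration_interval` | migrants per event / generations between events | 0 / 0 |

The plateau ID fraction is insensitive to `c` in its effect on TE abundance
(conversion swaps one copy class for another and adds one intact copy per
event either way) but strongly sensitive in its effect on the ID fraction
itself: about 3% of copies end up deleted at `c = 0.005` and about 25% at
`c = 0.05` under the default single-population conditions, measured at the
3,000-generation plateau. At low conversion rates this mean hides strong
replicate skew: so few distinct ID variants segregate that drift wipes out
*all* of them before the sampling horizon in roughly four out of ten runs,
while occasional runs end up with 10–20% deleted copies. Plateau estimates at
low `c` therefore need tens of replicates to be stable.

## From fingerprints to routes

The analysis side consumes DeviaTE-style fingerprint tables
(`sample_id, start, end, support, frequency`) and proceeds through:

1. **Support filter** — entries with fewer supporting reads than
   `min_support` are dropped (2 for high-coverage experimental data, 3 for
   natural pool-seq samples).
2. **Breakpoint clustering** (`cluster_breakpoints()`) — split-read
   alignments place indel gaps ambiguously, so IDs from different samples are
   merged into one allele when both breakpoints agree within 3 bp of a
   cluster representative. Representatives are chosen greedily in decreasing
   order of total read support, ties broken by the smaller `(start, end)`;
   an entry joins the first representative within tolerance, so chains do
   not merge transitively. Merged entries of one sample sum their
   frequencies.
3. **FL complement** — each ID and the FL element are treated as alleles of
   a single TE "locus"; the FL frequency is `1 - sum(f_i)`.
4. **Private-ID exclusion** (`drop_private_ids()`) — alleles seen in exactly
   one sample are noise for between-sample distances (each population makes
   many of its own); after dropping them the FL column is recomputed so each
   row remains a probability vector.
5. **FL reference** (`add_fl_reference()`) — an artificial sample of pure FL
   marks the putative origin of the invasion.
6. **Jost's D** (`jost_d_pair()`, `distance_matrix()`) — the two-deme
   frequency form `D = (H_T - H_S) / (1 - H_S) * 2`. Unlike Fst-type
   measures, D stays unbiased when one locus has very many alleles, which is
   exactly the regime of ID fingerprints. We use the plain frequency
   estimator, not the sample-size-corrected one: pooled read proportions do
   not carry genotype counts.
7. **Trees and embeddings** — BIONJ on the distance matrix (`bionj_tree()`,
   via ape), a bootstrap majority-rule consensus over resampled ID alleles
   (`bootstrap_consensus()`), and classical Torgerson MDS
   (`classical_mds()`).

```{r pipeline}
fp <- generate_fixture_fingerprints(n_pops = 6)
rec <- suppressWarnings(pipeline_reconstruct(fp, min_support = 3, bootstrap = 25))
rec$log
shared_splits(rec$tree, expected_invasion_tree(c("FL", paste0("pop", 1:6))))
```

**Bootstrapping IDs.** The consensus resamples allele *columns* with
replacement. A multiply-drawn allele counts once per draw, so row sums can
exceed one; rows are renormalized to stay on the simplex before distances are
recomputed. Splits retained need support strictly above 0.5 (edges at exactly
half are collapsed); retained splits above half are automatically pairwise
compatible, so the consensus is built directly from them. BIONJ branch
lengths may be negative; they are kept as computed because all tree
comparisons here are topological.

## Measuring route recovery

A reconstruction is scored by the number of nontrivial bipartitions (splits)
it shares with the expected route — the caterpillar tree
`FL, pop1, ..., popN` built by `expected_invasion_tree()`, whose splits are
exactly the prefixes of the invasion order. A fully resolved tree on `n` tips
has `n - 3` splits, so 8 is the ceiling for the standard 11-tip setup.

Per-split recovery is summarized with a binomial model with `n_max = n - 3`
trials and a flat Beta(1, 1) prior. The posterior is conjugate —
`Beta(1 + sum(k), 1 + T * n_max - sum(k))` — so `split_share_posterior()`
reports the exact posterior mean and central 95% interval in closed form; a
Monte-Carlo sampler would merely approximate the same distribution.

The null is what a random tree on the same tips would share.
`random_tree()` offers two generators, because "random tree" is ambiguous:

* `"recursive-split"` (default): recursively assign each label independently
  to one of two sides, redrawing empty sides — the splitting scheme of the
  classical `rtree`-style generators. It is *not* uniform over labeled
  topologies; on 11 tips its posterior-mean shared-split recovery against
  the caterpillar is ≈ 0.022.
* `"uniform-addition"`: stepwise insertion on a uniformly chosen edge,
  uniform over the `(2n - 5)!!` topologies; the closed-form expectation of
  shared splits with an 11-tip caterpillar is
  `sum((2a - 3)!!(2b - 3)!! / 17!!) ≈ 0.156` summed over the eight splits,
  i.e. recovery ≈ 0.0195.

Both sit near 2% — an order of magnitude below what reconstructed invasions
achieve — but the default matches the null most practitioners will have used.

```{r null, eval = FALSE}
cat11 <- expected_invasion_tree(c("FL", paste0("pop", 1:10)))
counts <- random_shared_splits(cat11, 10000)
split_share_posterior(counts, n_max = 8)
```

## The synthetic fingerprint generator

`generate_fixture_fingerprints()` emulates the *tabular shape and sharing
structure* of pool-seq fingerprints without running the simulator: shared IDs
originate in one deme of the chain and persist downstream with an
exponentially decaying frequency kernel plus gamma noise, private IDs are
added per deme, and the total ID fraction grows along the chain. It is a
stand-in for testing the pipeline's plumbing and order recovery, not a
mechanistic model: it has no drift, no linkage, no cluster trapping, and its
distances are close to one-dimensional (MDS on such fixtures legitimately
warns that only one positive eigenvalue exists). Tests that pass on fixtures
therefore certify the pipeline's bookkeeping, not the population genetics;
the simulator-driven tests cover the latter.

## Numerical choices and degenerate inputs

* Breakpoints are 1-based inclusive positions; the deleted interval is
  `[start, end]`, and `1 <= start < end <= consensus_len` always.
* piRNA clusters occupy the *last* `cluster_len` bp of each chromosome.
* Insertion-site collisions within a gamete are resolved by redrawing the
  site; at 5 Mb and tens of copies, collisions are vanishingly rare.
* Every conversion creates a fresh variant id even if its breakpoints
  coincide with an existing variant by chance; fingerprints merge variants
  by breakpoints, so homoplasy is representable in the simulation truth yet
  indistinguishable in the observed data — as in reality.
* `jost_d_pair()` clips to `[0, 1]` only against floating-point overshoot;
  for two demes `H_T >= H_S` holds by convexity, so no true clipping occurs.
  Two identical monomorphic samples give `D = 0`.
* Frequency-vector sums are validated to `1e-6`; fingerprint sums to
  `1 + 1e-9`.
* Populations with zero TE copies have no fingerprint; asking for one is an
  error rather than a silent empty sample.
* All randomness — simulator, bootstrap, permutation tests, random trees —
  flows through R's RNG, so `set.seed()` (or the `seed` arguments) makes
  every result bit-reproducible; replicate `r` of a multi-replicate run uses
  `seed + r - 1`.

Problem sizes used by the acceptance script, chosen to keep Monte-Carlo error
well below the comparison tolerances: 50 replicates for the two plateau
measurements (SE ≈ 1 percentage point), 10,000 random trees for the null
(posterior SD ≈ 0.0005), and 3 stepping-stone replicates for the private-ID
fraction.

## Limitations

* The trap model silences by *random* cluster insertion; insertion bias into
  clusters, maternal piRNA inheritance, and cluster-independent silencing
  are not modeled, and all would shorten the activity window.
* IDs are selectively neutral here; positive or negative selection on
  specific deletions (and any fitness cost `x` of copies) would distort both
  the ID fraction gradient and the fingerprint similarity.
* Migration is a strict 1D stepping stone with copy-based migration;
  arbitrary migration graphs are out of scope.
* Pool-seq noise is not simulated: simulator fingerprints are exact
  population counts, so read-support filtering matters only for external
  data and fixtures.
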