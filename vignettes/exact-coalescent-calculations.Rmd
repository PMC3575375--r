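---
title: "Exact coalescent calculations: models, recursion and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact coalescent calculations: models, recursion and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalexact)
```

## The models

`coalexact` works with the two classical mutation models of coalescent
theory in which exact likelihoods are tractable.

Under the **infinite-alleles model (IAM)** every mutation creates a
brand-new allele, and the data reduce to the multiset of allele counts
`n_1, ..., n_d` — the frequency spectrum. Its probability is the Ewens
sampling formula, implemented in `esf_probability()`.

Under the **infinite-sites model (ISM)** every mutation additionally hits
a brand-new site, so the data are a binary haplotype-by-site matrix with
a known ancestral state: 0 ancestral, 1 derived. The ISM is a refinement
of the IAM — `spectrum_of()` recovers the IAM view of ISM data by
forgetting the sites.

Both models sit on the standard neutral coalescent: a panmictic,
constant-size population, no recombination, no migration, no selection.
Time is measured in coalescent units; while `k` ancestral lineages
remain, the next coalescence is exponential with rate `k(k-1)/2`, and
mutations fall on each lineage as a Poisson process of rate `θ/2`, where
`θ` is the population-scaled mutation rate. All of `θ`'s appearances in
the package (recursion coefficients, Ewens formula, simulator) use this
one convention, which is what makes the exact recursion and the forward
simulator directly comparable.

## The gene tree statistic

ISM data that are consistent with the model form a **perfect
phylogeny**: the carrier sets of any two sites are disjoint or nested
(never "crossing"). The data can then be displayed as a rooted **gene
tree**: each site is a node, nested according to carrier sets, and each
haplotype is the allele sitting at the node whose root path carries
exactly its mutations, with its sample count as the node's
*multiplicity*. The tree is the sufficient statistic of ISM data and the
configuration object of the recursion.

Two compatibility tests are provided. `four_gamete_check()` examines
site pairs directly; in the rooted convention (ancestral state known) a
pair is incompatible when the gametes 01, 10 and 11 all occur, and in
the classic unrooted variant all four gametes are required.
`gusfield_check()` sorts columns as binary numbers and checks the
leftmost-one (L-value) consistency condition in time linear in the
matrix size. The two algorithms provably decide the same property; the
suite cross-checks them on large batches of random matrices, and when
data are incompatible the Gusfield path recovers the same first
violating column pair by direct re-check, so both report identical
witnesses.

Conventions worth stating explicitly:

* **All-zero columns** carry no mutation; they are dropped on input with
  a warning.
* **All-ones columns** are legal: a mutation on the stem above the whole
  sample, which becomes a node between the root and its single subtree.
* **Duplicate columns** (identical carriers) become a chain of nodes on
  one edge, kept in input column order. The recursion removes them
  sequentially either way, so probabilities do not depend on this
  conventional order.
* **Frequencies never affect compatibility** — only the distinct
  patterns matter.

## The probability recursion

For a configuration `T` with sample size `n` and allele multiplicities
`n_k`, the exact probability satisfies

```
n(n-1+θ) P(T) =   Σ_{k∈S0} n_k(n_k-1) P(C_k T)
                + θ Σ_{k∈S1} P(M_k T)
                + θ Σ_{k∈S2} (n_i+1) P(M_k T),        P(MRCA) = 1.
```

The three event classes partition what can happen one step back in time:

* **Coalescence** `C_k`: any allele with `n_k ≥ 2` loses one copy;
  coefficient `n_k(n_k-1)`.
* **Mutation of the first kind** (`S1`): a leaf mutation node with
  multiplicity 1 whose parent allele is absent; removing the mutation
  creates a new allele type. Coefficient `θ`.
* **Mutation of the second kind** (`S2`): the parent allele is present
  with multiplicity `n_i`; the lineage merges into that *merge allele*.
  Coefficient `θ(n_i+1)`.

`enumerate_events()` lists exactly these events with their coefficients
(`θ` kept symbolic as a recorded power), and `apply_event()` produces
the successor configuration. Every event lowers the **level** `n + m`
(lineages plus mutations) by exactly one, which makes the configuration
space a level-graded DAG: `build_recursion_graph()` discovers it
breadth-first from the data, de-duplicating by a canonical key, and
`exact_probability()` then solves the linear recursion bottom-up by
ascending level. The bottom-up evaluation avoids recursion-depth limits
on deep graphs and makes the per-level cache profile
(`profile_levels()`) a natural by-product. All configuration
probabilities lie in `(0, 1]`, with 1 attained only at the MRCA.

### Labelled configurations and shape automorphisms

The recursion sums over *alleles*, exactly as written above, so `P(T)`
is the probability of the **labelled** configuration — the configuration
of the data's actual sites. For most data this distinction is
invisible, but shapes with a nontrivial automorphism expose it: for two
lineages each carrying one private mutation, the recursion gives
`θ²/(1+θ)³`, while the probability that a simulated sample *looks like*
that unlabelled shape is half of it — the automorphism group of the
shape has order 2, and two labelled configurations map onto one
observable pattern. The package keeps the recursion exactly as stated
and documents the relation instead of inserting correction factors; the
test suite verifies the factor of 2 on this shape empirically. For the
same reason `mc_probability_estimate()`, which can only match simulated
samples by shape (simulated site labels are arbitrary), is compared to
the exact recursion on non-automorphic shapes, where the two notions
coincide. A related conventional freedom — the order of a
duplicate-column chain — is likewise invisible to the probability: both
chain orders are distinct labelled keys for the same data, and the
builder fixes input order as the convention.

Counting conventions: `count_configurations()` includes both the data
configuration and the MRCA, so counts from software with other
conventions may differ by up to 2. Genealogy counts
(`count_genealogies()`) are ordered event paths from the data to the
MRCA, each of length `n + m - 1`, computed by dynamic programming with
exact big-integer addition; the suite checks the DP against an
exhaustive depth-first path count on instances with at most 10⁴ paths.

## Numerical choices

* **Default arithmetic is double precision.** Desk-scale configurations
  (tens of alleles, ~10 mutations) produce probabilities far from
  underflow. An **exact-rational mode** is available for regression
  testing; it reduces numerator/denominator pairs by gcd at every step
  and aborts cleanly if either would exceed 2^53 (the exact-integer
  range of a double). `θ` is converted to a rational by continued
  fractions with a 10⁻¹² relative-accuracy requirement.
* **Determinism.** Event order is fixed (coalescences, first-kind, then
  second-kind removals, each sorted by the target's root-path labels);
  enumeration orders are (descending level, key-lexicographic); all
  sorts use radix order, so outputs are locale-independent and
  reproducible. The simulator uses R's Mersenne-Twister stream, seeded
  explicitly, and records the generator name in its output metadata.
* **Canonical keys** serialize a tree with children sorted by their
  recursive encoding, so equal keys mean identical configurations
  (labelled) or shape-isomorphic ones (unlabelled). Site labels may not
  contain the key's structural characters (braces, bar, parentheses,
  comma, whitespace), which the validators enforce.
* **Caps.** Graph discovery stops with a distinct *capped-run* error
  beyond a configurable configuration cap (default 10⁷), and genealogy
  enumeration accepts a path cap that truncates the stream with a
  capped-run warning — the batch analogue of cancelling a runaway job.
* **Degenerate inputs.** A zero-site matrix is the single ancestral
  haplotype (its file form is a lone `freq` header); the MRCA yields an
  empty event list, probability exactly 1 at any `θ`, and a one-node
  recursion graph.

## The simulator: what it emulates, and what it does not

`simulate_ism_sample()` is a faithful forward implementation of the
model the recursion assumes — neutral constant-size coalescent,
`Exp(k(k-1)/2)` epoch lengths, Poisson(`θ/2`) mutations per lineage,
every mutation a new site. It is therefore an *independent oracle*: its
output distribution must match the exact recursion, the Ewens formula
and the geometric pairwise-difference law `P(S=j) = θ^j/(1+θ)^{j+1}`
for `n = 2`, and the test suite checks all three.

Passing these checks says the two implementations agree *about the
model*; it says nothing about features of real data the model excludes:
recombination, migration, population-size change, selection, recurrent
or back mutation, missing data, and sequencing error are all outside
scope (the first two deliberately deferred). Real data that violate the
ISM typically fail the perfect-phylogeny check, which is the intended
diagnostic.

Default study conditions used by the tests: `θ = 1` (one expected
pairwise difference, a typical nuclear-locus value), sample sizes 2–6
for distributional checks, conservation fixtures drawn with `n ∈ {2,3,4}`
at `θ = 1` and kept when `n + m ≤ 8` (50 datasets), and 10⁵ Monte-Carlo
replicates, which give standard errors of a few 10⁻³ on the
probabilities being verified — tight enough for the 3–4 standard-error
agreement checks the test suite applies, without overnight runs. These sizes are the package's
choice of a representative desk-scale experiment, stated here so they
can be scaled up deliberately.

## Known limitations

* Genealogy counts explode combinatorially; enumeration is for
  intuition on small data, and even counting becomes slow before
  `n + m` reaches real-data sizes. The level profile exists precisely
  to study that growth.
* Exact-rational mode is for small configurations; it aborts (rather
  than silently losing precision) when intermediate rationals outgrow
  2^53.
* The probability is labelled-configuration probability; users comparing
  against simulation or other software on automorphic shapes must
  account for the automorphism factor as described above.
* Only perfect-phylogeny (homoplasy-free, complete, binary) data are
  accepted; there is no repair of imperfect phylogenies and no support
  for multi-state characters.
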