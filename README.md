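# coalexact

Exact calculations in coalescent theory for infinite-sites and
infinite-alleles data.

## What it does, and for whom

Population geneticists usually analyse sequence variation with summary
statistics or simulation-based approximations, because the probability of
a sample under a coalescent model rarely has a closed form. For two
classical mutation models, however, the probability of the observed data
can be computed *exactly*, and those exact values are the benchmark
against which approximate and importance-sampling methods are judged.
`coalexact` implements that exact machinery:

* **Perfect phylogeny.** Binary haplotype data under the infinite-sites
  model (ISM; every mutation hits a brand-new site) is consistent with a
  unique rooted *gene tree* of mutations — if it is consistent with any.
  The package tests compatibility with both Gusfield's linear-time
  algorithm and the (rooted or classic unrooted) four-gamete test, and
  builds the gene tree when it exists.

* **Exact sample probability.** For a gene tree `T` with sample size `n`,
  allele multiplicities `n_k` and population mutation rate `θ`, the
  probability solves the backward recursion

  ```
  n(n-1+θ) P(T) =   Σ_{k∈S0} n_k(n_k-1) P(C_k T)
                  + θ Σ_{k∈S1} P(M_k T)
                  + θ Σ_{k∈S2} (n_i+1) P(M_k T)
  ```

  with `P(MRCA) = 1`: `C_k` coalesces two copies of allele `k`; `M_k`
  removes a mutation, creating either a brand-new allele type (first
  kind, `S1`) or merging into an existing *merge allele* `i` (second
  kind, `S2`). The package discovers the full DAG of ancestral
  configurations reachable from the data, solves the recursion bottom-up
  (in doubles or in exact rational arithmetic), and reports the
  probability of the data and of every ancestral configuration.

* **Combinatorics of the recursion.** Total counts and full enumerations
  of ancestral configurations and genealogies (ordered event paths to the
  MRCA), and per-level profiles of the recursion graph — the quantities
  used in the literature to gauge the complexity of exact methods.

* **Infinite-alleles model.** Allele frequency spectra and their exact
  probability, the Ewens sampling formula.

* **An independent oracle.** A forward coalescent simulator under the ISM
  (exponential coalescence times, Poisson mutations at rate `θ/2` per
  lineage) that doubles as a Monte-Carlo check of the exact recursion.

## Worked example

The package ships a four-haplotype, four-site sample
(`inst/extdata/foursite.tsv`):

```r
library(coalexact)

tsv <- system.file("extdata", "foursite.tsv", package = "coalexact")
m <- read_incidence_matrix(tsv)
m
#> Incidence matrix: 4 haplotype(s), 4 site(s), n = 4
#> # A tibble: 4 × 5
#>      M1    M2    M3    M4  freq
#> 1     0     1     1     0     1
#> 2     1     1     1     0     1
#> 3     0     0     0     0     1
#> 4     0     0     0     1     1

gusfield_check(m)
#> Perfect phylogeny check (gusfield): compatible

t <- build_gene_tree(m)
t
#> Gene tree: n = 4, m = 4, level = 8
#> (((M1_1)M3_1)M2_0,M4_1)root_1;
```

The tree reads: the all-zero haplotype sits at the root (one copy); one
branch carries mutation `M4` (one copy); the other carries the shared
chain `M2→M3` (sites with identical carriers), with one allele at `M3`
and, nested inside it, the `M1`-bearing allele. The `_k` suffixes are
allele multiplicities.

```r
p <- exact_probability(t, theta = 1)
p
#> Exact ISM probability (theta = 1, float mode): 0.0004701967593
#>   17 ancestral configuration(s)

exact_probability(t, theta = 1, mode = "rational")$fraction
#> [1] "13/27648"

glance(p)
#> # A tibble: 1 × 7
#>   probability theta mode      n     m n_configurations n_edges
#> 1    0.000470     1 float     4     4               17      25

as.character(count_genealogies(t))
#> [1] "16"

profile_levels(t)
#> # A tibble: 8 × 2   (level 8 = the data ... level 1 = the MRCA)
#>   level count
#> 1     8     1
#> 2     7     2
#> 3     6     3
#> 4     5     3
#> 5     4     3
#> 6     3     3
#> 7     2     1
#> 8     1     1
```

So this sample has probability `13/27648 ≈ 4.7 × 10⁻⁴` at `θ = 1`, its
recursion graph contains 17 ancestral configurations connected by 25
events, and 16 distinct genealogies lead from the data to the MRCA.
`tidy(p)` returns the probability of every ancestral configuration;
`autoplot(profile_levels(t))` plots the level profile. Collapsing the
sites gives the infinite-alleles view of the same data:

```r
esf_probability(spectrum_of(m), theta = 1)   # Ewens sampling formula
#> [1] 0.04166667
```

A command-line interface wraps the same functions
(`system.file("cli", "coalescent", package = "coalexact")`):

```sh
coalescent phylo check foursite.tsv        # exit 0: compatible
coalescent phylo tree foursite.tsv         # newick to stdout
coalescent recursion prob foursite.tsv --theta 1 --exact
coalescent simulate --n 5 --theta 2 --seed 9
```

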