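# Shared fixtures and independent oracles, all built in code.

foursite_path <- function() {
  system.file("extdata", "foursite.tsv", package = "coalexact")
}

foursite_matrix <- function() {
  read_incidence_matrix(foursite_path())
}

# canonical small trees -----------------------------------------------------

tree_single <- function(n) gene_tree(mult = n)

# {ancestral x1, one-mutation allele x1}: n = 2, m = 1
tree_one_mut <- function() {
  gene_tree(mult = 1, children = list(mutation_node("a", 1)))
}

# {ancestral x1, allele with two chained mutations x1}: n = 2, m = 2
tree_chain2 <- function() {
  gene_tree(mult = 1, children = list(
    mutation_node("a", 0, list(mutation_node("b", 1)))))
}

# one private mutation on each of two lineages (automorphic shape)
tree_private2 <- function() {
  gene_tree(mult = 0, children = list(
    mutation_node("a", 1), mutation_node("b", 1)))
}

# random/simulated fixtures --------------------------------------------------

# random binary matrix collapsed into a valid incidence matrix (duplicate
# rows become counts; all-zero columns are silently dropped)
random_incidence <- function(n_rows, n_sites, p = 0.4) {
  x <- matrix(as.integer(runif(n_rows * n_sites) < p), n_rows, n_sites)
  cp <- coalexact:::collapse_patterns(x)
  kept <- suppressWarnings(
    coalexact:::drop_nonsegregating(cp$patterns, paste0("S", seq_len(n_sites))))
  pat <- kept$patterns
  freq <- cp$freq
  if (!ncol(pat) && nrow(pat) > 1) {
    freq <- sum(freq)
    pat <- pat[1, , drop = FALSE]
  }
  incidence_matrix(pat, freq, kept$site_labels)
}

# simulated dataset with bounded level n + m, by rejection
simulated_small <- function(seed, max_level = 8) {
  for (k in 0:200) {
    n <- 2 + (seed + k) %% 3
    m <- simulate_ism_sample(n, theta = 1, seed = seed * 1000 + k)
    if (sample_size(m) + length(site_labels(m)) <= max_level) return(m)
  }
  stop("rejection sampling failed")
}

# independent oracles --------------------------------------------------------

# exhaustive depth-first genealogy count, no memoization
dfs_genealogy_count <- function(t) {
  if (is_mrca(t)) return(1)
  ev <- enumerate_events(t)
  total <- 0
  for (r in seq_len(nrow(ev))) {
    total <- total +
      dfs_genealogy_count(apply_event(t, list(kind = ev$kind[r],
                                              path = ev$path[[r]])))
  }
  total
}

# direct per-pair gamete re-check used to validate reported witnesses
pair_violates <- function(m, pair, rooted = TRUE) {
  pat <- haplotype_patterns(m)
  x <- pat[, pair[1]]
  y <- pat[, pair[2]]
  g <- c(any(x == 0 & y == 0), any(x == 0 & y == 1),
         any(x == 1 & y == 0), any(x == 1 & y == 1))
  if (rooted) all(g[2:4]) else all(g)
}

# all integer partitions of n, as decreasing vectors
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (k in seq(min(n, max_part), 1)) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1]] <- c(k, rest)
    }
  }
  out
}

# expand a gene tree back into distinct haplotype rows (site-label sets
# with multiplicities) for reconstruction checks
tree_to_rows <- function(t) {
  rows <- list()
  visit <- function(node, labels) {
    if (node$mult > 0) {
      rows[[length(rows) + 1]] <<- list(sites = sort(labels), freq = node$mult)
    }
    for (ch in node$children) visit(ch, c(labels, ch$site))
  }
  visit(t, character())
  rows
}
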