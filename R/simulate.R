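#' Forward coalescent simulation under the infinite-sites model
#'
#' Simulates one sample of size `n`: a standard coalescent tree with
#' exponential waiting times (rate `k(k-1)/2` while `k` lineages
#' remain, coalescent time units), mutations laid down as a Poisson
#' process of rate `theta/2` per lineage per unit time, each mutation
#' creating a brand-new segregating site. The sample is returned
#' collapsed to distinct haplotypes with counts. Output is
#' deterministic given `seed` (Mersenne-Twister, recorded in the
#' result's `rng` attribute).
#'
#' @param n Sample size (>= 1).
#' @param theta Positive population mutation rate.
#' @param seed Optional integer seed; when `NULL` the current RNG
#'   stream is used.
#' @return An [incidence_matrix] with sites labelled `S1`, `S2`, ... in
#'   order of appearance. Every simulated matrix admits a perfect
#'   phylogeny by construction.
#' @examples
#' m <- simulate_ism_sample(5, theta = 1, seed = 42)
#' gusfield_check(m)$compatible
#' @export
simulate_ism_sample <- function(n, theta, seed = NULL) {
  check_sim_args(n, theta)
  run <- function() sim_leaf_sites(n, theta)
  sets <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  nsite <- max(c(0L, unlist(sets)))
  labels <- if (nsite) paste0("S", seq_len(nsite)) else character()
  x <- matrix(0L, nrow = n, ncol = nsite)
  for (i in seq_len(n)) x[i, sets[[i]]] <- 1L
  collapsed <- collapse_patterns(x)
  out <- incidence_matrix(collapsed$patterns, collapsed$freq, labels)
  attr(out, "rng") <- "Mersenne-Twister"
  out
}

check_sim_args <- function(n, theta) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort_domain("sample size n must be a positive integer")
  }
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0) {
    abort_domain("theta must be a single positive number")
  }
}

# Core simulator: returns, per leaf, the integer ids of the derived sites
# it carries. During the epoch with k lineages each lineage receives
# Poisson(theta * t / 2) new mutations shared by all its descendant
# leaves; then a uniformly chosen pair of lineages merges.
sim_leaf_sites <- function(n, theta) {
  sets <- vector("list", n)
  groups <- as.list(seq_len(n))
  nsite <- 0L
  k <- n
  while (k > 1L) {
    t <- rexp(1L, k * (k - 1L) / 2)
    nm <- rpois(k, theta * t / 2)
    for (i in which(nm > 0L)) {
      new_sites <- nsite + seq_len(nm[i])
      nsite <- nsite + nm[i]
      for (leaf in groups[[i]]) sets[[leaf]] <- c(sets[[leaf]], new_sites)
    }
    pr <- sample.int(k, 2L)
    a <- min(pr); b <- max(pr)
    groups[[a]] <- c(groups[[a]], groups[[b]])
    groups[[b]] <- NULL
    k <- k - 1L
  }
  sets
}

#' Simulate segregating-site counts
#'
#' Number of segregating sites in each of `reps` simulated samples.
#' For `n = 2` the exact law is geometric,
#' `P(S = j) = theta^j / (1 + theta)^(j+1)` — the pairwise-difference
#' distribution — which makes this a convenient distributional check of
#' the simulator.
#'
#' @inheritParams simulate_ism_sample
#' @param reps Number of replicate samples.
#' @return An integer vector of length `reps`.
#' @export
simulate_segregating_sites <- function(n, theta, reps, seed = NULL) {
  check_sim_args(n, theta)
  run <- function() {
    s <- integer(reps)
    for (k in seq(n, 2)) {
      t <- rexp(reps, k * (k - 1) / 2)
      s <- s + rpois(reps, theta * t * k / 2)
    }
    s
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Shape key of the gene tree of a simulated sample, computed directly
# from per-leaf site sets without materializing a gene_tree (site labels
# of simulated data are arbitrary, so matching is by unlabelled
# canonical key). Agrees with canonical_key(build_gene_tree(.),
# labelled = FALSE); the agreement is property-tested.
shape_key_of_sets <- function(sets) {
  pk <- vapply(sets, paste, "", collapse = ",")
  keep <- !duplicated(pk)
  freq <- tabulate(match(pk, pk[keep]), nbins = sum(keep))
  pats <- sets[keep]
  sites <- unique(unlist(pats))
  if (!length(sites)) return(paste0("{|", sum(freq), "}"))
  # carriers over distinct patterns; duplicate carriers form chains
  carr <- lapply(sites, function(s) {
    which(vapply(pats, function(p) any(p == s), NA))
  })
  ckey <- vapply(carr, paste, "", collapse = ",")
  keepg <- !duplicated(ckey)
  chain <- tabulate(match(ckey, ckey[keepg]), nbins = sum(keepg))
  gcarr <- carr[keepg]
  G <- length(gcarr)
  sizes <- lengths(gcarr)
  # deepest node containing each pattern gets its frequency
  gmult <- integer(G)
  root_mult <- 0L
  for (r in seq_along(pats)) {
    if (!length(pats[[r]])) { root_mult <- freq[r]; next }
    cand <- which(vapply(gcarr, function(cc) any(cc == r), NA))
    gmult[cand[which.min(sizes[cand])]] <- freq[r]
  }
  # parent = smallest strict carrier superset (0 = root)
  parent <- integer(G)
  for (g in seq_len(G)) {
    best <- 0L; bestsize <- Inf
    for (h in seq_len(G)) {
      if (sizes[h] > sizes[g] && sizes[h] < bestsize &&
          all(gcarr[[g]] %in% gcarr[[h]])) {
        best <- h; bestsize <- sizes[h]
      }
    }
    parent[g] <- best
  }
  enc <- function(g) {
    kids <- sort(vapply(which(parent == g), enc, ""), method = "radix")
    inner <- paste0("{m|", gmult[g],
                    if (length(kids)) paste0("(", paste0(kids, collapse = ","), ")"),
                    "}")
    for (i in seq_len(chain[g] - 1L)) inner <- paste0("{m|0(", inner, ")}")
    inner
  }
  top <- sort(vapply(which(parent == 0L), enc, ""), method = "radix")
  paste0("{|", root_mult, "(", paste0(top, collapse = ","), ")}")
}

#' Monte-Carlo estimate of a configuration probability
#'
#' Independent stochastic oracle for [exact_probability()]: simulates
#' `reps` samples of size `tree_n(t0)` and reports the fraction whose
#' gene tree matches `t0` up to a site-relabelling — i.e. equal
#' unlabelled canonical keys (shape-and-multiplicity isomorphism) —
#' with the binomial standard error. For shapes with a nontrivial
#' automorphism the labelled recursion probability exceeds this
#' unlabelled estimate by the automorphism order; comparisons should use
#' non-automorphic shapes.
#'
#' @param t0 A [gene_tree].
#' @param theta Positive population mutation rate.
#' @param reps Number of simulated samples.
#' @param seed Optional integer seed.
#' @return A one-row tibble with `estimate`, `se`, `matches`, `reps`.
#' @export
mc_probability_estimate <- function(t0, theta, reps, seed = NULL) {
  validate_gene_tree(t0)
  n <- tree_n(t0)
  check_sim_args(n, theta)
  target <- canonical_key(t0, labelled = FALSE)
  run <- function() {
    hits <- 0L
    for (r in seq_len(reps)) {
      if (shape_key_of_sets(sim_leaf_sites(n, theta)) == target) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  est <- hits / reps
  tibble(estimate = est, se = sqrt(est * (1 - est) / reps),
         matches = hits, reps = as.integer(reps))
}
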