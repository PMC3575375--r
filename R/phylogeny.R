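#' Perfect-phylogeny reports
#'
#' Result of a compatibility check on binary haplotype data: whether the
#' sites admit a perfect phylogeny (a rooted gene tree without
#' homoplasy), which algorithm decided, and — when incompatible — a
#' witness pair of site labels that violates the criterion.
#'
#' @param compatible Logical verdict.
#' @param witness `NULL`, or a character pair of violating site labels.
#' @param algorithm `"gusfield"` or `"four-gamete"`.
#' @return A list of class `phylogeny_report`.
#' @keywords internal
phylogeny_report <- function(compatible, witness, algorithm) {
  structure(list(compatible = compatible, witness = witness,
                 algorithm = algorithm),
            class = "phylogeny_report")
}

#' @export
print.phylogeny_report <- function(x, ...) {
  cat(sprintf("Perfect phylogeny check (%s): %s\n", x$algorithm,
              if (x$compatible) "compatible" else "INCOMPATIBLE"))
  if (!is.null(x$witness)) {
    cat(sprintf("  witness pair: %s, %s\n", x$witness[1], x$witness[2]))
  }
  invisible(x)
}

# Gametes exhibited by a pair of site columns over the distinct haplotypes.
# Frequencies are irrelevant: compatibility depends on patterns only.
pair_gametes <- function(x, y) {
  c(`00` = any(x == 0L & y == 0L), `01` = any(x == 0L & y == 1L),
    `10` = any(x == 1L & y == 0L), `11` = any(x == 1L & y == 1L))
}

# First violating pair in column order under the rooted (three-gamete) or
# unrooted (four-gamete) criterion; NULL when compatible.
first_violation <- function(pat, labels, rooted) {
  p <- ncol(pat)
  if (p < 2) return(NULL)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      g <- pair_gametes(pat[, i], pat[, j])
      bad <- if (rooted) all(g[c("01", "10", "11")]) else all(g)
      if (bad) return(c(labels[i], labels[j]))
    }
  }
  NULL
}

#' Four-gamete compatibility test
#'
#' Decides whether binary haplotype data admits a perfect phylogeny by
#' examining site pairs. In the rooted convention (the default; the
#' ancestral state 0 is known) a pair is incompatible when the three
#' gametes 01, 10 and 11 all occur among the haplotypes — equivalently,
#' the carrier sets of the two sites are neither disjoint nor nested.
#' With `rooted = FALSE` the classic unrooted test is applied: a pair is
#' incompatible only when all four gametes occur. Haplotype frequencies
#' play no role.
#'
#' @param m An [incidence_matrix].
#' @param rooted Use the rooted (three-gamete) criterion; default `TRUE`.
#' @return A [phylogeny_report]; the witness is the first violating pair
#'   in column order.
#' @export
four_gamete_check <- function(m, rooted = TRUE) {
  stopifnot(inherits(m, "incidence_matrix"))
  w <- first_violation(haplotype_patterns(m), site_labels(m), rooted)
  phylogeny_report(is.null(w), w, "four-gamete")
}

#' Gusfield's perfect-phylogeny test
#'
#' Linear-time test for a rooted perfect phylogeny: columns are sorted
#' as binary numbers (most significant bit first) in decreasing order,
#' then for each 1-entry the column index of the nearest 1 to its left
#' (the L-value) is computed; the data admits a perfect phylogeny iff
#' within every column all L-values agree. Gives the same verdict as
#' [four_gamete_check()] with `rooted = TRUE`; on failure the witness
#' pair is recovered by a direct pair check so that both algorithms
#' report identically.
#'
#' @param m An [incidence_matrix].
#' @return A [phylogeny_report].
#' @export
gusfield_check <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  pat <- haplotype_patterns(m)
  labels <- site_labels(m)
  p <- ncol(pat)
  if (p < 2) return(phylogeny_report(TRUE, NULL, "gusfield"))

  # sort columns as binary numbers, row 1 the most significant bit
  keys <- apply(pat, 2, paste, collapse = "")
  ord <- order(keys, decreasing = TRUE, method = "radix")
  M <- pat[, ord, drop = FALSE]

  ok <- TRUE
  r <- nrow(M)
  L <- matrix(0L, r, p)
  last <- integer(r)  # most recent column with a 1, per row
  for (j in seq_len(p)) {
    ones <- M[, j] == 1L
    if (any(ones)) {
      lv <- last[ones]
      if (length(unique(lv)) > 1L) { ok <- FALSE; break }
      L[ones, j] <- lv
      last[ones] <- j
    }
  }
  if (ok) return(phylogeny_report(TRUE, NULL, "gusfield"))
  w <- first_violation(pat, labels, rooted = TRUE)
  phylogeny_report(FALSE, w, "gusfield")
}

#' Build the gene tree of a perfect phylogeny
#'
#' Constructs the rooted mutation tree for compatible binary data: the
#' carrier sets of the sites form a laminar family, so each site becomes
#' a mutation node nested under the sites whose carriers contain its
#' own. Duplicate columns (identical carrier sets) become a chain of
#' nodes along one edge, kept in input column order. Each haplotype's
#' frequency becomes the multiplicity of the node whose root-path
#' mutation set equals the haplotype's 1-set; the root carries the
#' frequency of the all-zero haplotype (0 when absent). All-ones
#' columns are legal and appear as mutation nodes between the root and
#' its single subtree.
#'
#' @param m A compatible [incidence_matrix].
#' @return A [gene_tree] whose multiplicities sum to `sample_size(m)`.
#' @export
build_gene_tree <- function(m) {
  rep <- gusfield_check(m)
  if (!rep$compatible) {
    abort_phylogeny(sprintf(
      "data does not admit a perfect phylogeny (witness pair: %s, %s)",
      rep$witness[1], rep$witness[2]), witness = rep$witness)
  }
  pat <- haplotype_patterns(m)
  labels <- site_labels(m)
  freq <- haplotype_freq(m)
  sets <- lapply(seq_along(labels), function(j) which(pat[, j] == 1L))
  build_tree_from_carriers(labels, sets, pat, freq)
}

# Core laminar-insertion construction shared with the simulator's
# pattern-based matching. `labels`/`sets`: per-site carrier row sets;
# `pat`: distinct 0/1 patterns; `freq`: their counts.
build_tree_from_carriers <- function(labels, sets, pat, freq) {
  sizes <- lengths(sets)
  ord <- order(-sizes)  # stable: ties keep input column order
  # flat node store: 1 = root
  site <- c(NA_character_, labels[ord])
  carrier <- c(list(seq_len(nrow(pat))), sets[ord])
  children <- vector("list", length(site))
  parent <- rep(NA_integer_, length(site))
  for (k in seq_along(ord)) {
    id <- k + 1L
    cur <- 1L
    repeat {
      nxt <- 0L
      for (ch in children[[cur]]) {
        if (all(carrier[[id]] %in% carrier[[ch]])) { nxt <- ch; break }
      }
      if (nxt == 0L) break
      cur <- nxt
    }
    children[[cur]] <- c(children[[cur]], id)
    parent[id] <- cur
  }
  # multiplicities: haplotype's 1-set must equal some node's root path
  path_key <- character(length(site))
  path_key[1] <- ""
  # children were appended in sorted insertion order; compute keys by BFS
  order_ids <- 1L
  qi <- 1L
  while (qi <= length(order_ids)) {
    cur <- order_ids[qi]
    for (ch in children[[cur]]) {
      path_key[ch] <- paste(sort(c(strsplit(path_key[cur], "\x1f")[[1]],
                                   site[ch])), collapse = "\x1f")
      order_ids <- c(order_ids, ch)
    }
    qi <- qi + 1L
  }
  mult <- rep(0L, length(site))
  for (i in seq_len(nrow(pat))) {
    key <- paste(sort(labels[pat[i, ] == 1L]), collapse = "\x1f")
    id <- match(key, path_key)
    if (is.na(id)) abort_invariant("haplotype does not map onto the mutation tree")
    mult[id] <- freq[i]
  }
  assemble <- function(id) {
    ch <- lapply(children[[id]], assemble)
    if (id == 1L) {
      structure(list(site = NA_character_, mult = mult[1], children = ch),
                class = "gene_tree")
    } else {
      mutation_node(site[id], mult[id], ch)
    }
  }
  t <- assemble(1L)
  validate_gene_tree(t)
  t
}
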