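#' Rooted gene trees of mutations
#'
#' A gene tree is the compact statistic of an infinite-sites sample: a
#' rooted tree whose non-root nodes are mutations (one per segregating
#' site) and whose nodes carry allele multiplicities. The allele sitting
#' at a node is the haplotype carrying exactly the mutations on the path
#' from the root to that node; its multiplicity is the number of sampled
#' copies. The sum of multiplicities is the sample size `n`, the number
#' of mutation nodes is `m`, and `n + m` is the level of the
#' configuration in the backward recursion. The most recent common
#' ancestor (MRCA) is the configuration with `m = 0` and `n = 1`.
#'
#' `gene_tree()` builds a root node, `mutation_node()` a mutation node;
#' children are nested node lists.
#'
#' @param mult Non-negative integer multiplicity (number of sampled
#'   copies of the allele at this node).
#' @param children List of child nodes built with `mutation_node()`.
#' @param site Site label of the mutation (unique within a tree).
#'
#' @return A node list; the root node, of class `gene_tree`, represents
#'   the whole tree.
#'
#' @examples
#' # one ancestral copy plus one copy carrying a single mutation
#' t <- gene_tree(mult = 1, children = list(mutation_node("a", mult = 1)))
#' tree_n(t)      # 2 lineages
#' tree_m(t)      # 1 mutation
#' tree_level(t)  # 3
#' @export
gene_tree <- function(mult = 1L, children = list()) {
  t <- structure(list(site = NA_character_, mult = as.integer(mult),
                      children = children),
                 class = "gene_tree")
  validate_gene_tree(t)
  t
}

#' @rdname gene_tree
#' @export
mutation_node <- function(site, mult = 0L, children = list()) {
  list(site = as.character(site), mult = as.integer(mult), children = children)
}

#' Gene-tree accessors
#'
#' `tree_n()` is the sample size (sum of node multiplicities), `tree_m()`
#' the number of mutation nodes, `tree_level()` their sum (the level of
#' the configuration in the recursion graph), and `is_mrca()` tests for
#' the terminal single-lineage, zero-mutation configuration.
#'
#' @param t A [gene_tree].
#' @return An integer, or a logical for `is_mrca()`.
#' @export
tree_n <- function(t) {
  walk_sum(t, function(node) node$mult)
}

#' @rdname tree_n
#' @export
tree_m <- function(t) {
  walk_sum(t, function(node) 1L) - 1L
}

#' @rdname tree_n
#' @export
tree_level <- function(t) {
  tree_n(t) + tree_m(t)
}

#' @rdname tree_n
#' @export
is_mrca <- function(t) {
  length(t$children) == 0L && t$mult == 1L
}

walk_sum <- function(node, f) {
  f(node) + sum(vapply(node$children, walk_sum, 0L, f = f))
}

#' Validate gene-tree invariants
#'
#' Checks that multiplicities are non-negative integers, the sample size
#' is at least 1, every non-root leaf has multiplicity at least 1, every
#' zero-multiplicity mutation node has a child, and site labels are
#' unique.
#'
#' @param t A [gene_tree].
#' @return `t`, invisibly; aborts with an invariant error otherwise.
#' @export
validate_gene_tree <- function(t) {
  if (!inherits(t, "gene_tree")) abort_invariant("not a gene_tree object")
  sites <- character()
  check <- function(node, is_root) {
    if (!is.numeric(node$mult) || length(node$mult) != 1 || is.na(node$mult) ||
        node$mult < 0 || node$mult != as.integer(node$mult)) {
      abort_invariant("node multiplicity must be a non-negative integer")
    }
    if (!is_root) {
      if (is.na(node$site) || !nzchar(node$site)) {
        abort_invariant("mutation nodes must carry a non-empty site label")
      }
      if (grepl("[{}|(),\t ]", node$site)) {
        abort_invariant(sprintf(
          "site label '%s' contains a reserved character", node$site))
      }
      sites[[length(sites) + 1L]] <<- node$site
      if (node$mult == 0L && !length(node$children)) {
        abort_invariant(sprintf(
          "mutation node '%s' has multiplicity 0 and no children", node$site))
      }
    }
    for (ch in node$children) check(ch, FALSE)
  }
  check(t, TRUE)
  if (anyDuplicated(sites)) {
    abort_invariant(sprintf("duplicate site label '%s' in gene tree",
                            sites[duplicated(sites)][1]))
  }
  if (walk_sum(t, function(nd) nd$mult) < 1L) {
    abort_invariant("gene tree must carry at least one sampled lineage")
  }
  invisible(t)
}

#' Canonical key of a gene-tree configuration
#'
#' Encodes a configuration as text, invariant under reordering of
#' children (children are sorted by their recursive encoding). With
#' `labelled = TRUE` (the default) site labels are preserved, so equal
#' keys mean identical configurations of the actual data's sites; with
#' `labelled = FALSE` labels are erased and equal keys mean
#' shape-and-multiplicity isomorphism. Labelled keys identify
#' configurations throughout the recursion graph; shape keys are used
#' for matching simulated samples, whose site labels are arbitrary.
#'
#' @param t A [gene_tree].
#' @param labelled Keep site labels (`TRUE`) or erase them (`FALSE`).
#' @return A single string.
#' @export
canonical_key <- function(t, labelled = TRUE) {
  encode <- function(node, is_root) {
    kids <- vapply(node$children, encode, "", is_root = FALSE)
    kids <- sort(kids, method = "radix")
    name <- if (is_root) "" else if (labelled) node$site else "m"
    paste0("{", name, "|", node$mult,
           if (length(kids)) paste0("(", paste0(kids, collapse = ","), ")"),
           "}")
  }
  encode(t, TRUE)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("Gene tree: n = %d, m = %d, level = %d%s\n",
              tree_n(x), tree_m(x), tree_level(x),
              if (is_mrca(x)) " (MRCA)" else ""))
  cat(to_newick(x), "\n")
  invisible(x)
}

# --- backward events -------------------------------------------------------

# Internal traversal: one row per node, with its path (integer child indices
# from the root), its label, parent multiplicity, and a deterministic
# ordering key (the root-path label string).
node_table <- function(t) {
  acc <- list()
  visit <- function(node, path, labels, parent_mult) {
    acc[[length(acc) + 1L]] <<- list(
      site = if (is.null(node$site) || is.na(node$site)) "root" else node$site,
      mult = node$mult,
      n_children = length(node$children),
      parent_mult = parent_mult,
      path = path,
      order_key = paste(labels, collapse = "\x1f")
    )
    for (i in seq_along(node$children)) {
      ch <- node$children[[i]]
      visit(ch, c(path, i), c(labels, ch$site), node$mult)
    }
  }
  visit(t, integer(), character(), NA_integer_)
  acc
}

#' Enumerate backward events of a configuration
#'
#' Lists the events through which the probability recursion steps one
#' level down from a configuration: one coalescence per allele with
#' multiplicity at least 2 (coefficient `n_k (n_k - 1)`), and one
#' mutation removal per leaf mutation node with multiplicity 1. A
#' removal is of the first kind when the parent allele is absent
#' (multiplicity 0), so removal creates a new allele type (coefficient
#' `theta`); it is of the second kind when the parent allele is present,
#' so the lineage merges into that existing *merge allele* `i`
#' (coefficient `theta * (n_i + 1)`). `theta` is kept symbolic: the
#' tibble records the rational multiplier in `coef` and the power of
#' `theta` in `theta_power`.
#'
#' Events are ordered deterministically: coalescences, then first-kind,
#' then second-kind removals, each sorted by the target node's root-path
#' label sequence.
#'
#' @param t A [gene_tree]; the MRCA yields zero events.
#' @return A tibble with columns `kind`, `target`, `merge`, `coef`,
#'   `theta_power`, and list-columns `path`, `merge_path` addressing the
#'   nodes inside `t`.
#' @export
enumerate_events <- function(t) {
  validate_gene_tree(t)
  nodes <- node_table(t)
  rows <- list()
  for (nd in nodes) {
    if (nd$mult >= 2L) {
      rows[[length(rows) + 1L]] <- list(
        kind = "coalescence", target = nd$site, merge = NA_character_,
        coef = nd$mult * (nd$mult - 1), theta_power = 0L,
        path = nd$path, merge_path = NULL, ord = nd$order_key)
    }
    if (!is.na(nd$parent_mult) && nd$mult == 1L && nd$n_children == 0L) {
      if (nd$parent_mult == 0L) {
        rows[[length(rows) + 1L]] <- list(
          kind = "mutation_first", target = nd$site, merge = NA_character_,
          coef = 1, theta_power = 1L,
          path = nd$path, merge_path = NULL, ord = nd$order_key)
      } else {
        parent_path <- nd$path[-length(nd$path)]
        labs <- strsplit(nd$ord, "\x1f", fixed = TRUE)[[1]]
        parent_site <- if (length(labs) >= 2) labs[length(labs) - 1] else "root"
        rows[[length(rows) + 1L]] <- list(
          kind = "mutation_second", target = nd$site, merge = parent_site,
          coef = nd$parent_mult + 1, theta_power = 1L,
          path = nd$path, merge_path = parent_path, ord = nd$order_key)
      }
    }
  }
  if (!length(rows)) {
    return(tibble(kind = character(), target = character(),
                  merge = character(), coef = numeric(),
                  theta_power = integer(), path = list(),
                  merge_path = list()))
  }
  kind <- vapply(rows, `[[`, "", "kind")
  ord <- vapply(rows, `[[`, "", "ord")
  kind_rank <- match(kind, c("coalescence", "mutation_first", "mutation_second"))
  o <- order(kind_rank, ord, method = "radix")
  rows <- rows[o]
  tibble(
    kind = vapply(rows, `[[`, "", "kind"),
    target = vapply(rows, `[[`, "", "target"),
    merge = vapply(rows, `[[`, "", "merge"),
    coef = vapply(rows, `[[`, 0, "coef"),
    theta_power = vapply(rows, `[[`, 0L, "theta_power"),
    path = lapply(rows, `[[`, "path"),
    merge_path = lapply(rows, `[[`, "merge_path")
  )
}

node_at <- function(t, path) {
  node <- t
  for (i in path) {
    if (i > length(node$children)) abort_invariant("event path does not address a node")
    node <- node$children[[i]]
  }
  node
}

modify_at <- function(node, path, f) {
  if (!length(path)) return(f(node))
  node$children[[path[1]]] <- modify_at(node$children[[path[1]]], path[-1], f)
  node
}

#' Apply one backward event to a configuration
#'
#' Produces the successor configuration one level down: a coalescence
#' decrements the target allele's multiplicity; a first-kind removal
#' deletes the target mutation node and raises its parent's multiplicity
#' from 0 to 1; a second-kind removal deletes the target node and
#' increments the merge allele's multiplicity. The input tree is not
#' modified.
#'
#' @param t A [gene_tree].
#' @param event One row of [enumerate_events()] on `t` (a one-row tibble
#'   or a list with the same fields).
#' @return The successor [gene_tree], with `tree_level()` one less than
#'   the input's.
#' @export
apply_event <- function(t, event) {
  if (is.data.frame(event)) {
    if (nrow(event) != 1) abort_invariant("apply_event takes a single event")
    event <- list(kind = event$kind, path = event$path[[1]])
  }
  kind <- event$kind
  path <- event$path
  target <- node_at(t, path)
  if (kind == "coalescence") {
    if (target$mult < 2L) abort_invariant("coalescence requires multiplicity >= 2")
    out <- modify_at(t, path, function(nd) { nd$mult <- nd$mult - 1L; nd })
  } else if (kind %in% c("mutation_first", "mutation_second")) {
    if (!length(path)) abort_invariant("cannot remove a mutation from the root")
    if (target$mult != 1L || length(target$children)) {
      abort_invariant("mutation removal requires a leaf node with multiplicity 1")
    }
    parent_path <- path[-length(path)]
    idx <- path[length(path)]
    parent <- node_at(t, parent_path)
    first <- parent$mult == 0L
    if (first != (kind == "mutation_first")) {
      abort_invariant("event kind does not match the parent's multiplicity")
    }
    out <- modify_at(t, parent_path, function(nd) {
      nd$children[[idx]] <- NULL
      nd$mult <- nd$mult + 1L
      nd
    })
  } else {
    abort_invariant(sprintf("unknown event kind '%s'", kind))
  }
  class(out) <- "gene_tree"
  out
}
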