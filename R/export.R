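#' Newick export and import of gene trees
#'
#' `to_newick()` serializes a gene tree as a Newick string without
#' branch lengths. Each node is named by its site label (the root by
#' `root`) with the allele multiplicity appended as a `_k` suffix;
#' children are written in the deterministic order of their labelled
#' [canonical_key()], so trees differing only in child insertion order
#' serialize identically. `from_newick()` parses the same dialect back
#' into a [gene_tree].
#'
#' @param t A [gene_tree].
#' @param text A Newick string produced by `to_newick()`.
#' @return A single string, or a [gene_tree] for `from_newick()`.
#'
#' @examples
#' to_newick(gene_tree(mult = 3))  # "root_3;"
#' @export
to_newick <- function(t) {
  validate_gene_tree(t)
  nw <- function(node, is_root) {
    name <- paste0(if (is_root) "root" else node$site, "_", node$mult)
    if (!length(node$children)) return(name)
    keys <- vapply(node$children, function(ch) {
      canonical_key(structure(ch, class = "gene_tree"))
    }, "")
    kids <- vapply(node$children[order(keys, method = "radix")], nw, "",
                   is_root = FALSE)
    paste0("(", paste0(kids, collapse = ","), ")", name)
  }
  paste0(nw(t, TRUE), ";")
}

#' @rdname to_newick
#' @export
from_newick <- function(text) {
  s <- sub(";\\s*$", "", trimws(text))
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  read_name <- function() {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% c("(", ")", ",", ";"))) {
      pos <<- pos + 1L
    }
    substr(s, start, pos - 1L)
  }
  parse_node <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        abort_format("malformed Newick: expected ',' or ')'")
      }
    }
    name <- read_name()
    mm <- regmatches(name, regexec("^(.*)_([0-9]+)$", name))[[1]]
    if (length(mm) != 3) {
      abort_format(sprintf("node name '%s' lacks the '_multiplicity' suffix", name))
    }
    list(label = mm[2], mult = as.integer(mm[3]), children = children)
  }
  raw <- parse_node()
  if (pos <= n) abort_format("trailing characters after Newick tree")
  if (raw$label != "root") abort_format("outermost node must be named 'root'")
  as_node <- function(x) mutation_node(x$label, x$mult, lapply(x$children, as_node))
  t <- structure(list(site = NA_character_, mult = raw$mult,
                      children = lapply(raw$children, as_node)),
                 class = "gene_tree")
  validate_gene_tree(t)
  t
}

#' Graphviz DOT export
#'
#' Renders a gene tree or a recursion graph as a DOT digraph. For a
#' recursion graph there is one node per ancestral configuration,
#' labelled by its canonical key and level, and one edge per backward
#' event, labelled by the event kind and its coefficient (with `t`
#' standing for the population mutation rate theta).
#'
#' @param x A [gene_tree] or a `recursion_graph` from
#'   [build_recursion_graph()].
#' @param ... Unused.
#' @return A single DOT string.
#' @export
to_dot <- function(x, ...) UseMethod("to_dot")

dot_quote <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

#' @export
to_dot.gene_tree <- function(x, ...) {
  validate_gene_tree(x)
  nodes <- character()
  edges <- character()
  nid <- 0L
  visit <- function(node, is_root) {
    nid <<- nid + 1L
    id <- paste0("n", nid)
    name <- paste0(if (is_root) "root" else node$site, "_", node$mult)
    nodes[[length(nodes) + 1L]] <<- sprintf("  %s [label=%s];", id, dot_quote(name))
    for (ch in node$children) {
      cid <- visit(ch, FALSE)
      edges[[length(edges) + 1L]] <<- sprintf("  %s -> %s;", id, cid)
    }
    id
  }
  visit(x, TRUE)
  paste(c("digraph genetree {", nodes, edges, "}"), collapse = "\n")
}

event_edge_label <- function(kind, coef, theta_power) {
  short <- c(coalescence = "C", mutation_first = "M1", mutation_second = "M2")[kind]
  co <- ifelse(theta_power > 0,
               ifelse(coef == 1, "t", paste0(coef, "t")),
               as.character(coef))
  paste0(short, " x", co)
}

#' @export
to_dot.recursion_graph <- function(x, ...) {
  keys <- names(x$configurations)
  ids <- setNames(paste0("c", seq_along(keys)), keys)
  levels <- x$levels
  nodes <- vapply(keys, function(k) {
    sprintf("  %s [label=%s];", ids[[k]],
            dot_quote(paste0(k, "\\nlevel=", levels[[k]])))
  }, "")
  edges <- character()
  for (k in keys) {
    ev <- x$edges[[k]]
    if (is.null(ev) || !nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      edges[[length(edges) + 1L]] <- sprintf(
        "  %s -> %s [label=%s];", ids[[k]], ids[[ev$succ_key[i]]],
        dot_quote(event_edge_label(ev$kind[i], ev$coef[i], ev$theta_power[i])))
    }
  }
  paste(c("digraph recursion {", nodes, edges, "}"), collapse = "\n")
}
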