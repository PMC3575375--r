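#' Tidy the result of the exact recursion
#'
#' `tidy()` returns one row per ancestral configuration (key, level,
#' probability, and the exact fraction in rational mode); `glance()`
#' returns a one-row summary of the fit: the data probability, theta,
#' the sample size and mutation count, and the size of the recursion
#' graph.
#'
#' @param x An `ism_probability` from [exact_probability()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ism_probability <- function(x, ...) {
  x$configurations
}

#' @rdname tidy.ism_probability
#' @export
glance.ism_probability <- function(x, ...) {
  t0 <- x$graph$configurations[[x$graph$root_key]]
  tibble(
    probability = x$probability,
    theta = x$theta,
    mode = x$mode,
    n = tree_n(t0),
    m = tree_m(t0),
    n_configurations = length(x$graph$configurations),
    n_edges = sum(vapply(x$graph$edges, nrow, 0L))
  )
}

#' Tidy a recursion graph
#'
#' `tidy()` returns the edge list (one row per backward event with its
#' source and successor keys, kind and coefficient); `glance()` a
#' one-row summary (configuration, edge and level counts).
#'
#' @param x A `recursion_graph` from [build_recursion_graph()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.recursion_graph <- function(x, ...) {
  keys <- names(x$configurations)
  rows <- lapply(keys, function(k) {
    ev <- x$edges[[k]]
    if (is.null(ev) || !nrow(ev)) return(NULL)
    tibble(from = k, to = ev$succ_key, level = unname(x$levels[[k]]),
           kind = ev$kind, target = ev$target, merge = ev$merge,
           coef = ev$coef, theta_power = ev$theta_power)
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.recursion_graph
#' @export
glance.recursion_graph <- function(x, ...) {
  tibble(
    n_configurations = length(x$configurations),
    n_edges = sum(vapply(x$edges, nrow, 0L)),
    level_max = max(x$levels),
    level_min = min(x$levels)
  )
}

#' Plot a level profile
#'
#' Column chart of the number of distinct ancestral configurations at
#' each level of the recursion graph, the profile of the recursion
#' cache.
#'
#' @param object A `level_profile` from [profile_levels()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.level_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_reverse(breaks = object$level) +
    ggplot2::labs(
      x = "level (n + m)", y = "ancestral configurations",
      title = "Recursion graph level profile"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @export
plot.level_profile <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}

#' Plot a gene tree
#'
#' Draws the rooted mutation tree via its Newick serialization using
#' the ape package (listed in Suggests).
#'
#' @param x A [gene_tree].
#' @param ... Passed to `ape::plot.phylo()`.
#' @export
plot.gene_tree <- function(x, ...) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("plotting gene trees requires the 'ape' package")
  }
  ph <- ape::read.tree(text = to_newick(x))
  ape::plot.phylo(ph, show.node.label = TRUE, ...)
  invisible(x)
}
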