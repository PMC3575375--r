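#' Build the recursion graph of ancestral configurations
#'
#' Expands the data configuration backward in time into the
#' level-stratified DAG of all ancestral configurations reachable by
#' coalescence and mutation-removal events, down to the most recent
#' common ancestor. Discovery is breadth-first and configurations are
#' de-duplicated by their labelled [canonical_key()], so
#' identical-shape configurations of distinct sites are distinct nodes.
#' Every edge drops the level (`n + m`) by exactly 1, so the graph is
#' acyclic with the single terminal MRCA at level 1.
#'
#' Output processors can be attached: each processor is a list with
#' optional functions `on_configuration(key, tree, level)` and
#' `on_edge(from_key, to_key, event)`; every processor is invoked once
#' per discovered configuration (in discovery order) and once per edge
#' (in event order), mirroring a pluggable output/profiling pipeline.
#'
#' @param t0 A [gene_tree], the data configuration.
#' @param processors List of processor lists as described above.
#' @param cap Maximum number of configurations to discover; exceeding it
#'   raises a capped-run error (default `1e7`).
#' @return A list of class `recursion_graph` with fields
#'   `configurations` (named list, discovery order), `edges` (named list
#'   of event tibbles with a `succ_key` column), `levels` (named integer
#'   vector), `root_key` and `mrca_key`.
#' @export
build_recursion_graph <- function(t0, processors = list(), cap = 1e7) {
  validate_gene_tree(t0)
  fire <- function(hook, ...) {
    for (p in processors) if (is.function(p[[hook]])) p[[hook]](...)
  }
  configs <- new.env(parent = emptyenv())
  keys <- character()
  edges <- list()
  levels <- integer()

  root_key <- canonical_key(t0)
  assign(root_key, t0, envir = configs)
  keys <- c(keys, root_key)
  levels[root_key] <- tree_level(t0)
  fire("on_configuration", root_key, t0, levels[[root_key]])

  i <- 1L
  while (i <= length(keys)) {
    key <- keys[[i]]
    t <- get(key, envir = configs)
    ev <- enumerate_events(t)
    succ_key <- character(nrow(ev))
    if (nrow(ev)) {
      for (r in seq_len(nrow(ev))) {
        succ <- apply_event(t, list(kind = ev$kind[r], path = ev$path[[r]]))
        sk <- canonical_key(succ)
        succ_key[r] <- sk
        if (!exists(sk, envir = configs, inherits = FALSE)) {
          if (length(keys) + 1L > cap) {
            abort_capped(sprintf(
              "recursion graph exceeded the configuration cap (%d)", cap))
          }
          assign(sk, succ, envir = configs)
          keys <- c(keys, sk)
          levels[sk] <- tree_level(succ)
          fire("on_configuration", sk, succ, levels[[sk]])
        }
      }
    }
    ev$succ_key <- succ_key
    edges[[key]] <- ev
    if (nrow(ev)) {
      for (r in seq_len(nrow(ev))) {
        fire("on_edge", key, ev$succ_key[r], ev[r, ])
      }
    }
    i <- i + 1L
  }

  mrca_key <- keys[levels[keys] == 1L]
  if (length(mrca_key) != 1L) {
    abort_invariant("recursion graph must have exactly one terminal MRCA")
  }
  structure(list(
    configurations = setNames(lapply(keys, get, envir = configs), keys),
    edges = edges,
    levels = levels,
    root_key = root_key,
    mrca_key = mrca_key
  ), class = "recursion_graph")
}

#' @export
print.recursion_graph <- function(x, ...) {
  cat(sprintf(
    "Recursion graph: %d configuration(s), %d edge(s), levels %d..%d\n",
    length(x$configurations),
    sum(vapply(x$edges, nrow, 0L)),
    min(x$levels), max(x$levels)))
  invisible(x)
}

#' Exact sample probability under the infinite-sites model
#'
#' Solves the backward probability recursion for a gene-tree
#' configuration `T` with sample size `n` and allele multiplicities
#' `n_k`:
#'
#' \deqn{n(n-1+\theta)P(T) = \sum_{k \in S_0} n_k(n_k-1)P(C_kT)
#'   + \theta \sum_{k \in S_1} P(M_kT)
#'   + \theta \sum_{k \in S_2} (n_i+1)P(M_kT)}
#'
#' where `S0` are the alleles available for coalescence, `S1` the
#' mutations of the first kind (removal creates a new allele type), `S2`
#' those of the second kind (removal merges into the existing allele
#' `i`), and `theta` the population mutation rate. The initial condition
#' is `P(MRCA) = 1`. The sum runs over alleles exactly as written, so
#' the result is the probability of the labelled configuration. The
#' graph is discovered breadth-first and the system is solved bottom-up
#' by ascending level, which avoids deep recursion and yields the
#' probability of the data and of every ancestral configuration.
#'
#' @param t0 A [gene_tree], the data configuration.
#' @param theta Positive population mutation rate.
#' @param mode `"float"` (double precision, default) or `"rational"`
#'   (exact arithmetic; `theta` must be rational).
#' @param graph Optional pre-built [build_recursion_graph()] result for
#'   `t0`.
#' @param cap Configuration cap passed to the graph builder.
#' @return An object of class `ism_probability`: a list with
#'   `probability` (of `t0`), `theta`, `mode`, and `configurations`, a
#'   tibble with one row per ancestral configuration (`key`, `level`,
#'   `probability`, and in rational mode exact `num`/`den` columns plus
#'   a `fraction` string).
#'
#' @examples
#' t <- gene_tree(mult = 2)  # two lineages, no mutations
#' exact_probability(t, theta = 1)$probability  # 1/(1+theta) = 0.5
#' @export
exact_probability <- function(t0, theta, mode = c("float", "rational"),
                              graph = NULL, cap = 1e7) {
  mode <- arg_match(mode)
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0) {
    abort_domain("theta must be a single positive number")
  }
  g <- graph %||% build_recursion_graph(t0, cap = cap)
  keys <- names(g$configurations)
  ord <- keys[order(g$levels[keys], method = "radix")]  # ascending level

  if (mode == "float") {
    P <- setNames(numeric(length(keys)), keys)
    P[g$mrca_key] <- 1
    for (key in ord) {
      if (key == g$mrca_key) next
      ev <- g$edges[[key]]
      n <- tree_n(g$configurations[[key]])
      P[key] <- sum(ev$coef * theta^ev$theta_power * P[ev$succ_key]) /
        (n * (n - 1 + theta))
    }
    cfg <- tibble(key = keys, level = unname(g$levels[keys]),
                  probability = unname(P[keys]))
    prob <- unname(P[g$root_key])
    frac <- NULL
  } else {
    th <- as_rational(theta)
    P <- setNames(vector("list", length(keys)), keys)
    P[[g$mrca_key]] <- rat(1)
    for (key in ord) {
      if (key == g$mrca_key) next
      ev <- g$edges[[key]]
      n <- tree_n(g$configurations[[key]])
      acc <- rat(0)
      if (nrow(ev)) {
        for (r in seq_len(nrow(ev))) {
          term <- rat_mul(rat(ev$coef[r]), P[[ev$succ_key[r]]])
          if (ev$theta_power[r] > 0) term <- rat_mul(term, th)
          acc <- rat_add(acc, term)
        }
      }
      denom <- rat_mul(rat(n), rat_add(rat(n - 1), th))
      P[[key]] <- rat_div(acc, denom)
    }
    cfg <- tibble(
      key = keys, level = unname(g$levels[keys]),
      probability = vapply(P[keys], rat_num, 0),
      num = vapply(P[keys], function(r) unname(r[1]), 0),
      den = vapply(P[keys], function(r) unname(r[2]), 0),
      fraction = vapply(P[keys], rat_format, "")
    )
    prob <- rat_num(P[[g$root_key]])
    frac <- rat_format(P[[g$root_key]])
  }
  structure(list(probability = prob, fraction = frac, theta = theta,
                 mode = mode, configurations = cfg, graph = g),
            class = "ism_probability")
}

#' @export
print.ism_probability <- function(x, ...) {
  cat(sprintf("Exact ISM probability (theta = %g, %s mode): %.10g%s\n",
              x$theta, x$mode, x$probability,
              if (!is.null(x$fraction)) paste0(" = ", x$fraction) else ""))
  cat(sprintf("  %d ancestral configuration(s)\n", nrow(x$configurations)))
  invisible(x)
}

#' Count ancestral configurations
#'
#' Number of distinct labelled configurations in the recursion graph of
#' a data configuration, inclusive of the data configuration itself and
#' of the MRCA.
#'
#' @inheritParams build_recursion_graph
#' @param graph Optional pre-built graph.
#' @return An integer (double) count.
#' @export
count_configurations <- function(t0, graph = NULL, cap = 1e7) {
  g <- graph %||% build_recursion_graph(t0, cap = cap)
  length(g$configurations)
}

#' Count genealogies
#'
#' Number of distinct ordered event paths from the data configuration to
#' the MRCA, computed by dynamic programming over the recursion graph
#' (`count(MRCA) = 1`, `count(T)` = sum of successor counts) in exact
#' arbitrary-precision integer arithmetic.
#'
#' @inheritParams count_configurations
#' @return A `coalexact_bigint`; use `as.character()` for the exact
#'   decimal value or `as.numeric()` for a double (exact below 2^53).
#' @export
count_genealogies <- function(t0, graph = NULL, cap = 1e7) {
  g <- graph %||% build_recursion_graph(t0, cap = cap)
  keys <- names(g$configurations)
  ord <- keys[order(g$levels[keys], method = "radix")]
  counts <- setNames(vector("list", length(keys)), keys)
  counts[[g$mrca_key]] <- big_new(1)
  for (key in ord) {
    if (key == g$mrca_key) next
    ev <- g$edges[[key]]
    acc <- big_new(0)
    for (sk in ev$succ_key) acc <- big_add(acc, counts[[sk]])
    counts[[key]] <- acc
  }
  counts[[g$root_key]]
}

#' Enumerate ancestral configurations
#'
#' Yields every distinct ancestral configuration exactly once, ordered
#' by descending level and then lexicographically by labelled canonical
#' key.
#'
#' @inheritParams count_configurations
#' @return A tibble with columns `key`, `level` and a list-column `tree`
#'   of [gene_tree] objects.
#' @export
enumerate_configurations <- function(t0, graph = NULL, cap = 1e7) {
  g <- graph %||% build_recursion_graph(t0, cap = cap)
  keys <- names(g$configurations)
  o <- order(-g$levels[keys], keys, method = "radix")
  keys <- keys[o]
  tibble(key = keys, level = unname(g$levels[keys]),
         tree = unname(g$configurations[keys]))
}

#' Enumerate genealogies
#'
#' Emits every complete event path from the data configuration to the
#' MRCA by depth-first traversal in the deterministic event order of
#' [enumerate_events()], so the output order is event-lexicographic.
#' Each path has length `n + m - 1`. With a `cap`, emission stops after
#' `cap` paths and a capped-run warning is raised (the returned tibble
#' carries `attr(, "capped") = TRUE`).
#'
#' @param t0 A [gene_tree].
#' @param cap Optional maximum number of paths to emit.
#' @return A tibble with columns `path_id`, `length`, and a list-column
#'   `events` of per-path event tibbles (`kind`, `target`, `merge`).
#' @export
enumerate_genealogies <- function(t0, cap = NULL) {
  validate_gene_tree(t0)
  paths <- list()
  capped <- FALSE
  dfs <- function(t, prefix) {
    if (capped) return(invisible())
    if (is_mrca(t)) {
      if (!is.null(cap) && length(paths) >= cap) {
        capped <<- TRUE
        return(invisible())
      }
      paths[[length(paths) + 1L]] <<- prefix
      return(invisible())
    }
    ev <- enumerate_events(t)
    for (r in seq_len(nrow(ev))) {
      if (capped) break
      step <- list(kind = ev$kind[r], target = ev$target[r], merge = ev$merge[r])
      dfs(apply_event(t, list(kind = ev$kind[r], path = ev$path[[r]])),
          c(prefix, list(step)))
    }
    invisible()
  }
  dfs(t0, list())
  out <- tibble(
    path_id = seq_along(paths),
    length = vapply(paths, length, 0L),
    events = lapply(paths, function(p) {
      tibble(kind = vapply(p, `[[`, "", "kind"),
             target = vapply(p, `[[`, "", "target"),
             merge = vapply(p, `[[`, "", "merge"))
    })
  )
  if (capped) {
    attr(out, "capped") <- TRUE
    warn_capped(sprintf("genealogy enumeration stopped at the cap (%d paths)", cap))
  }
  out
}

#' Profile the recursion graph by level
#'
#' Counts the distinct ancestral configurations at each level of the
#' recursion graph. The counts are accumulated through a graph
#' processor as configurations are discovered, so a live consumer can
#' observe (e.g. plot) the profile during the computation via
#' `on_update`.
#'
#' @inheritParams count_configurations
#' @param on_update Optional callback `function(level, count)` invoked
#'   after each discovered configuration with the running count of its
#'   level.
#' @return A tibble of class `level_profile` with columns `level`
#'   (descending, the contiguous range `(n+m)..1`) and `count`; counts
#'   sum to [count_configurations()].
#' @export
profile_levels <- function(t0, graph = NULL, on_update = NULL, cap = 1e7) {
  counts <- new.env(parent = emptyenv())
  if (is.null(graph)) {
    proc <- list(on_configuration = function(key, tree, level) {
      lv <- as.character(level)
      cur <- (if (exists(lv, envir = counts, inherits = FALSE))
        get(lv, envir = counts) else 0L) + 1L
      assign(lv, cur, envir = counts)
      if (is.function(on_update)) on_update(level, cur)
    })
    graph <- build_recursion_graph(t0, processors = list(proc), cap = cap)
    tab <- unlist(as.list(counts))
    lv <- as.integer(names(tab))
  } else {
    tab <- table(graph$levels)
    lv <- as.integer(names(tab))
    tab <- as.integer(tab)
    names(tab) <- NULL
  }
  o <- order(lv, decreasing = TRUE)
  out <- tibble::new_tibble(
    list(level = lv[o], count = as.integer(tab[o])),
    nrow = length(lv), class = "level_profile")
  out
}
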