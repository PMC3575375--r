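test_that("graph expansion matches the hand-enumerated small cases", {
  g0 <- build_recursion_graph(tree_single(1))
  expect_equal(length(g0$configurations), 1L)
  expect_equal(sum(vapply(g0$edges, nrow, 0L)), 0L)

  # {ancestral x1, mutant x1}: a single chain of 3 configurations
  g <- build_recursion_graph(tree_one_mut())
  expect_equal(length(g$configurations), 3L)
  expect_equal(sum(vapply(g$edges, nrow, 0L)), 2L)
  expect_equal(sort(unname(g$levels)), c(1L, 2L, 3L))
})

test_that("the graph is level-graded with a single MRCA terminal", {
  for (t in list(tree_chain2(), tree_private2(),
                 build_gene_tree(foursite_matrix()))) {
    g <- build_recursion_graph(t)
    expect_equal(unname(g$levels[g$root_key]), tree_level(t))
    expect_equal(unname(g$levels[g$mrca_key]), 1L)
    for (key in names(g$configurations)) {
      ev <- g$edges[[key]]
      if (nrow(ev)) {
        expect_equal(unname(g$levels[ev$succ_key]),
                     rep(g$levels[[key]] - 1L, nrow(ev)))
      } else {
        expect_equal(key, g$mrca_key)
      }
    }
  }
})

test_that("processors fire once per configuration and once per edge", {
  n_cfg <- 0L
  n_edge <- 0L
  seen_levels <- integer()
  proc <- list(
    on_configuration = function(key, tree, level) {
      n_cfg <<- n_cfg + 1L
      seen_levels <<- c(seen_levels, level)
    },
    on_edge = function(from, to, event) n_edge <<- n_edge + 1L
  )
  t <- build_gene_tree(foursite_matrix())
  g <- build_recursion_graph(t, processors = list(proc))
  expect_equal(n_cfg, length(g$configurations))
  expect_equal(n_edge, sum(vapply(g$edges, nrow, 0L)))
  # BFS discovery: levels never increase
  expect_true(all(diff(seen_levels) <= 0))
})

test_that("exact probabilities reproduce the n = 2 closed forms", {
  for (theta in c(0.5, 1, 2)) {
    expect_equal(exact_probability(tree_single(2), theta)$probability,
                 1 / (1 + theta), tolerance = 1e-12)
    expect_equal(exact_probability(tree_one_mut(), theta)$probability,
                 theta / (1 + theta)^2, tolerance = 1e-12)
    expect_equal(exact_probability(tree_chain2(), theta)$probability,
                 theta^2 / (2 * (1 + theta)^3), tolerance = 1e-12)
  }
  # exact-rational mode gives the fractions themselves
  r <- exact_probability(tree_single(2), 1, mode = "rational")
  expect_identical(r$fraction, "1/2")
  r <- exact_probability(tree_one_mut(), 1, mode = "rational")
  expect_identical(r$fraction, "1/4")
  r <- exact_probability(tree_chain2(), 1, mode = "rational")
  expect_identical(r$fraction, "1/16")
  r <- exact_probability(tree_chain2(), 0.5, mode = "rational")
  expect_identical(r$fraction, "1/27")
})

test_that("the MRCA has probability exactly 1 at any theta", {
  for (theta in c(0.1, 1, 10)) {
    p <- exact_probability(tree_single(1), theta)
    expect_identical(p$probability, 1)
    r <- exact_probability(tree_single(1), theta, mode = "rational")
    expect_identical(r$fraction, "1")
  }
})

test_that("theta must be positive", {
  expect_error(exact_probability(tree_single(2), 0),
               class = "coalexact_domain_error")
  expect_error(exact_probability(tree_single(2), -1),
               class = "coalexact_domain_error")
})

test_that("all ancestral probabilities lie in (0, 1]", {
  for (seed in 1:10) {
    m <- simulated_small(seed)
    t <- build_gene_tree(m)
    p <- exact_probability(t, theta = 1.5)
    cfg <- tidy(p)
    expect_true(all(cfg$probability > 0))
    expect_true(all(cfg$probability <= 1))
    non_mrca <- cfg$probability[cfg$level > 1]
    expect_true(all(non_mrca < 1))
  }
})

test_that("float and rational modes agree to 1e-10 relative error", {
  trees <- list(tree_chain2(), tree_private2(),
                build_gene_tree(foursite_matrix()),
                build_gene_tree(simulated_small(4)))
  for (t in trees) {
    g <- build_recursion_graph(t)
    pf <- exact_probability(t, 0.75, graph = g)$probability
    pr <- exact_probability(t, 0.75, mode = "rational", graph = g)$probability
    expect_equal(pf, pr, tolerance = 1e-10)
  }
})

test_that("counts, enumerations and profiles are mutually consistent", {
  expect_equal(count_configurations(tree_single(1)), 1L)
  expect_equal(count_configurations(tree_one_mut()), 3L)
  expect_true(count_genealogies(tree_single(1)) == 1)
  expect_true(count_genealogies(tree_private2()) == 2)

  for (seed in 1:12) {
    t <- build_gene_tree(simulated_small(seed))
    g <- build_recursion_graph(t)
    nc <- count_configurations(t, graph = g)
    cfgs <- enumerate_configurations(t, graph = g)
    expect_equal(nrow(cfgs), nc)
    expect_false(anyDuplicated(cfgs$key) > 0)
    pr <- profile_levels(t, graph = g)
    expect_equal(sum(pr$count), nc)
    expect_equal(pr$level, seq(tree_level(t), 1L))
  }
})

test_that("configuration enumeration is ordered and keyed consistently", {
  t <- build_gene_tree(foursite_matrix())
  cfgs <- enumerate_configurations(t)
  expect_true(all(diff(cfgs$level) <= 0))
  # keys re-derive from the stored trees
  expect_identical(cfgs$key,
                   vapply(cfgs$tree, canonical_key, ""))
  expect_equal(cfgs$level, vapply(cfgs$tree, tree_level, 0L))
})

test_that("genealogy DP count equals the exhaustive DFS count", {
  expect_equal(as.numeric(count_genealogies(tree_chain2())),
               dfs_genealogy_count(tree_chain2()))
  t4 <- build_gene_tree(foursite_matrix())
  expect_equal(as.numeric(count_genealogies(t4)), dfs_genealogy_count(t4))
  for (seed in 1:10) {
    t <- build_gene_tree(simulated_small(seed))
    dp <- as.numeric(count_genealogies(t))
    if (dp <= 1e4) {
      expect_equal(dp, dfs_genealogy_count(t))
    }
  }
})

test_that("genealogy enumeration streams every path exactly once", {
  # MRCA: a single empty path
  ge <- enumerate_genealogies(tree_single(1))
  expect_equal(nrow(ge), 1L)
  expect_equal(ge$length, 0L)

  # two private mutations: two paths of length n + m - 1 = 3
  ge <- enumerate_genealogies(tree_private2())
  expect_equal(nrow(ge), 2L)
  expect_equal(ge$length, c(3L, 3L))
  first_steps <- vapply(ge$events, function(e) e$target[1], "")
  expect_equal(sort(first_steps), c("a", "b"))

  for (seed in 1:6) {
    t <- build_gene_tree(simulated_small(seed))
    total <- as.numeric(count_genealogies(t))
    if (total <= 500) {
      ge <- enumerate_genealogies(t)
      expect_equal(nrow(ge), total)
      expect_equal(ge$length, rep(tree_level(t) - 1L, nrow(ge)))
    }
  }
})

test_that("the genealogy cap stops emission with a capped-run signal", {
  t <- build_gene_tree(foursite_matrix())
  total <- as.numeric(count_genealogies(t))
  expect_gt(total, 3)
  expect_warning(ge <- enumerate_genealogies(t, cap = 3),
                 class = "coalexact_capped_run")
  expect_equal(nrow(ge), 3L)
  expect_true(attr(ge, "capped"))
})

test_that("the configuration cap converts runaway runs into clean errors", {
  expect_error(build_recursion_graph(build_gene_tree(foursite_matrix()), cap = 5),
               class = "coalexact_capped_error")
  expect_error(count_configurations(build_gene_tree(foursite_matrix()), cap = 5),
               class = "coalexact_capped_error")
})

test_that("level profiles stream through the processor callback", {
  updates <- list()
  pr <- profile_levels(tree_one_mut(), on_update = function(level, count) {
    updates[[length(updates) + 1]] <<- c(level, count)
  })
  expect_equal(length(updates), 3L)
  expect_equal(as.data.frame(pr),
               data.frame(level = c(3L, 2L, 1L), count = c(1L, 1L, 1L)))
  pr1 <- profile_levels(tree_single(1))
  expect_equal(as.data.frame(pr1), data.frame(level = 1L, count = 1L))
})

test_that("tidiers summarize probability objects and graphs", {
  t <- build_gene_tree(foursite_matrix())
  p <- exact_probability(t, 1)
  gl <- glance(p)
  expect_equal(gl$n, 4L)
  expect_equal(gl$m, 4L)
  expect_equal(gl$probability, p$probability)
  expect_equal(nrow(tidy(p)), gl$n_configurations)
  g <- build_recursion_graph(t)
  ed <- tidy(g)
  expect_equal(nrow(ed), glance(g)$n_edges)
  expect_true(all(ed$to %in% names(g$configurations)))
  pl <- autoplot(profile_levels(t, graph = g))
  expect_s3_class(pl, "ggplot")
})
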