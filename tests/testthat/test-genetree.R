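test_that("event enumeration matches the hand-derived small cases", {
  # single allele, n = 3: one coalescence, coefficient n_k(n_k-1) = 6
  ev <- enumerate_events(tree_single(3))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "coalescence")
  expect_equal(ev$coef, 6)
  expect_equal(ev$theta_power, 0L)

  # {ancestral x1, mutant x1}: one second-kind removal merging into the
  # root allele (n_i = 1), coefficient theta * (n_i + 1) = 2 theta
  ev <- enumerate_events(tree_one_mut())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "mutation_second")
  expect_equal(ev$target, "a")
  expect_equal(ev$merge, "root")
  expect_equal(ev$coef, 2)
  expect_equal(ev$theta_power, 1L)

  # two private mutations: two first-kind removals, coefficient theta each
  ev <- enumerate_events(tree_private2())
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$kind, rep("mutation_first", 2))
  expect_equal(sort(ev$target), c("a", "b"))
  expect_equal(ev$coef, c(1, 1))
  expect_equal(ev$theta_power, c(1L, 1L))

  # MRCA: no events, not an error
  expect_equal(nrow(enumerate_events(tree_single(1))), 0L)
})

test_that("events on the all-singleton four-site tree are all removals", {
  t <- build_gene_tree(foursite_matrix())
  ev <- enumerate_events(t)
  expect_false(any(ev$kind == "coalescence"))
  expect_gt(nrow(ev), 0L)
})

test_that("applying events steps the configuration down one level", {
  # coalescence on the two-lineage tree reaches the MRCA
  ev <- enumerate_events(tree_single(2))
  succ <- apply_event(tree_single(2), ev[1, ])
  expect_true(is_mrca(succ))

  # second-kind removal merges the mutant into the ancestral allele
  t <- tree_one_mut()
  succ <- apply_event(t, enumerate_events(t)[1, ])
  expect_equal(canonical_key(succ), canonical_key(tree_single(2)))
  expect_equal(tree_level(t), 3L)
  expect_equal(tree_level(succ), 2L)

  # first-kind removal turns the chained pair into the one-mutation tree
  t2 <- tree_chain2()
  succ2 <- apply_event(t2, enumerate_events(t2)[1, ])
  expect_equal(tree_m(succ2), 1L)
  expect_equal(tree_n(succ2), 2L)
})

test_that("every event drops the level by exactly 1 and conserves mass", {
  for (seed in 1:15) {
    t <- build_gene_tree(simulate_ism_sample(2 + seed %% 4, theta = 2,
                                             seed = 200 + seed))
    ev <- enumerate_events(t)
    for (r in seq_len(nrow(ev))) {
      succ <- apply_event(t, ev[r, ])
      validate_gene_tree(succ)
      expect_equal(tree_level(succ), tree_level(t) - 1L)
      if (ev$kind[r] == "coalescence") {
        expect_equal(tree_n(succ), tree_n(t) - 1L)
        expect_equal(tree_m(succ), tree_m(t))
      } else {
        expect_equal(tree_n(succ), tree_n(t))
        expect_equal(tree_m(succ), tree_m(t) - 1L)
      }
    }
  }
})

test_that("removal classification is exhaustive and exclusive", {
  for (seed in 1:15) {
    t <- build_gene_tree(simulate_ism_sample(2 + seed %% 4, theta = 2,
                                             seed = 300 + seed))
    ev <- enumerate_events(t)
    removable <- 0L
    count_leaves <- function(node, is_root) {
      if (!is_root && node$mult == 1L && !length(node$children)) {
        removable <<- removable + 1L
      }
      for (ch in node$children) count_leaves(ch, FALSE)
    }
    count_leaves(t, TRUE)
    expect_equal(sum(ev$kind %in% c("mutation_first", "mutation_second")),
                 removable)
  }
})

test_that("invalid event applications are rejected", {
  expect_error(apply_event(tree_single(1), list(kind = "coalescence",
                                                path = integer())),
               class = "coalexact_invariant_error")
  expect_error(apply_event(tree_one_mut(), list(kind = "mutation_first",
                                                path = 1L)),
               class = "coalexact_invariant_error")
})

test_that("canonical keys are invariant under child reordering", {
  ta <- gene_tree(mult = 1, children = list(
    mutation_node("x", 2), mutation_node("y", 1, list(mutation_node("z", 1)))))
  tb <- gene_tree(mult = 1, children = list(
    mutation_node("y", 1, list(mutation_node("z", 1))), mutation_node("x", 2)))
  expect_identical(canonical_key(ta), canonical_key(tb))
  expect_identical(canonical_key(ta, labelled = FALSE),
                   canonical_key(tb, labelled = FALSE))
})

test_that("shape keys erase labels, labelled keys keep them", {
  ta <- gene_tree(mult = 0, children = list(
    mutation_node("x", 2), mutation_node("y", 1)))
  tb <- gene_tree(mult = 0, children = list(
    mutation_node("y", 2), mutation_node("x", 1)))
  expect_false(identical(canonical_key(ta), canonical_key(tb)))
  expect_identical(canonical_key(ta, labelled = FALSE),
                   canonical_key(tb, labelled = FALSE))
  # multiplicities still distinguish shapes
  tc <- gene_tree(mult = 0, children = list(
    mutation_node("x", 1), mutation_node("y", 1, list(mutation_node("z", 1)))))
  expect_false(identical(canonical_key(ta, labelled = FALSE),
                         canonical_key(tc, labelled = FALSE)))
})

test_that("duplicate-column chains have order-invariant shape keys", {
  t1 <- gene_tree(mult = 1, children = list(
    mutation_node("p", 0, list(mutation_node("q", 1)))))
  t2 <- gene_tree(mult = 1, children = list(
    mutation_node("q", 0, list(mutation_node("p", 1)))))
  expect_identical(canonical_key(t1, labelled = FALSE),
                   canonical_key(t2, labelled = FALSE))
})

test_that("gene-tree invariants are enforced", {
  bad_leaf <- structure(
    list(site = NA_character_, mult = 1L,
         children = list(mutation_node("a", 0))),
    class = "gene_tree")
  expect_error(validate_gene_tree(bad_leaf),
               class = "coalexact_invariant_error")
  dup <- structure(
    list(site = NA_character_, mult = 1L,
         children = list(mutation_node("a", 1), mutation_node("a", 1))),
    class = "gene_tree")
  expect_error(validate_gene_tree(dup),
               class = "coalexact_invariant_error")
  empty <- structure(list(site = NA_character_, mult = 0L, children = list()),
                     class = "gene_tree")
  expect_error(validate_gene_tree(empty),
               class = "coalexact_invariant_error")
})
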