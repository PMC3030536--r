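test_that("parse_newick reads branch values on the requested scale", {
  tr <- parse_newick("((A:0.1,B:0.1):0.05,C:0.2);", "probability", N = 2)
  expect_equal(n_tips(tr), 3L)
  tips <- which(lengths(tr$children) == 0)
  expect_equal(tr$branch_p[tips[tr$label[tips] == "A"]], 0.1)
  expect_equal(tr$branch_p[tips[tr$label[tips] == "C"]], 0.2)

  z <- parse_newick("(A:0.0,B:0.0);", "probability", N = 4)
  expect_equal(unname(z$branch_p[-z$root]), c(0, 0))

  ln <- parse_newick("(A:0.25,B:0.25);", "length", N = 4, rate = 1)
  expect_equal(unname(ln$branch_p[-ln$root]),
               rep(branch_prob_from_length(0.25, 1, 4), 2))
  expect_equal(unname(ln$branch_len[-ln$root]), c(0.25, 0.25))
})

test_that("parse_newick rejects malformed or out-of-model input", {
  expect_error(parse_newick("((A:0.1,B:0.1)", "probability", N = 2), "parse")
  expect_error(parse_newick("((A,B):0.05,C:0.2);", "probability", N = 2),
               "numeric value")
  expect_error(parse_newick("(A:0.1,B:0.1,C:0.1);", "probability", N = 2),
               "binary")
  expect_error(parse_newick("(A:0.4,B:0.1);", "probability", N = 4),
               "substitution probability")
  expect_silent(parse_newick("(A:0.3,B:0.1);", "probability", N = 4,
                             allow_superstationary = TRUE))
  expect_error(parse_newick("(A:0.1,B:0.2);", "length", N = 2),
               "rate")
  expect_error(parse_newick("(A:0.1,A:0.2);", "probability", N = 2),
               "unique")
})

test_that("branch_prob_from_length follows the Jukes-Cantor curve", {
  expect_equal(branch_prob_from_length(0, 1, 4), 0)
  expect_equal(branch_prob_from_length(1e6, 1, 4), 0.25, tolerance = 1e-12)
  expect_equal(branch_prob_from_length(0.25, 1, 4), (1 / 4) * (1 - exp(-1)))
  expect_error(branch_prob_from_length(-0.1, 1, 4), "nonnegative")
  # conservation identity q = 1 - (N-1) p = 1/N + ((N-1)/N) exp(-N rate l)
  for (N in 2:5) {
    l <- runif(5, 0, 2)
    p <- branch_prob_from_length(l, 0.7, N)
    expect_equal(1 - (N - 1) * p, 1 / N + ((N - 1) / N) * exp(-N * 0.7 * l))
  }
})

test_that("compose_branch is the transition-matrix product", {
  expect_equal(compose_branch(0.13, 0, 4), 0.13)          # identity
  expect_equal(compose_branch(1 / 4, 0.13, 4), 1 / 4)     # absorbing
  expect_equal(compose_branch(0.1, 0.1, 2), 0.18)         # (1-2p)^2 = 0.64
  jc <- function(p, N) matrix(p, N, N) + diag(1 - N * p, N)
  set.seed(42)
  for (N in 2:5) {
    for (rep in 1:50) {
      p1 <- runif(1, 0, 1 / N); p2 <- runif(1, 0, 1 / N)
      expect_equal(compose_branch(p1, p2, N), (jc(p1, N) %*% jc(p2, N))[1, 2],
                   tolerance = 1e-14)
    }
  }
  # associativity and commutativity
  expect_equal(compose_branch(compose_branch(0.05, 0.1, 3), 0.2, 3),
               compose_branch(0.05, compose_branch(0.1, 0.2, 3), 3))
  expect_equal(compose_branch(0.05, 0.2, 3), compose_branch(0.2, 0.05, 3))
})

test_that("Newick round-trips preserve topology and branch values", {
  cherry <- parse_newick("(A:0.1,B:0.1);", "probability", N = 2)
  expect_equal(leaf_path_probs(parse_newick(write_newick(cherry), "probability", 2), 2),
               leaf_path_probs(cherry, 2))

  cb <- complete_binary_tree(3, 0.07, 2)
  cb2 <- parse_newick(write_newick(cb), "probability", N = 2)
  expect_equal(leaf_path_probs(cb2, 2), leaf_path_probs(cb, 2))
  expect_equal(tree_accuracy(cb2, 2)$UA, tree_accuracy(cb, 2)$UA,
               tolerance = 1e-12)

  set.seed(11)
  for (i in 1:100) {
    topo <- generate_yule(sample(4:12, 1))
    tr <- set_branch_probabilities(topo, runif(1, 0, 0.2), 2)
    tr$branch_p[-tr$root] <- runif(length(tr$parent) - 1, 0, 0.5)
    rt <- parse_newick(write_newick(tr), "probability", N = 2)
    expect_equal(leaf_path_probs(rt, 2), leaf_path_probs(tr, 2),
                 tolerance = 1e-10)
    expect_equal(tree_accuracy(rt, 2)$AA, tree_accuracy(tr, 2)$AA,
                 tolerance = 1e-10)
  }
})

test_that("restrict_to_leafset prunes, composes and collapses correctly", {
  t3 <- parse_newick("((A:0.1,B:0.1):0.05,C:0.2);", "probability", N = 2)

  full <- restrict_to_leafset(t3, c("A", "B", "C"))
  expect_equal(tree_accuracy(full, 2)$AA, tree_accuracy(t3, 2)$AA,
               tolerance = 1e-12)

  ac <- restrict_to_leafset(t3, c("A", "C"))
  pp <- leaf_path_probs(ac, 2)
  # A's path: 0.1 then 0.05 in series = matrix-product value 0.14
  expect_equal(unname(pp["A"]), compose_branch(0.1, 0.05, 2))
  expect_equal(unname(pp["A"]), 0.14)
  expect_equal(unname(pp["C"]), 0.2)

  onlyA <- restrict_to_leafset(parse_newick("(A:0.1,B:0.1);", "probability", 2), "A")
  expect_equal(n_tips(onlyA), 1L)
  acc <- tree_accuracy(onlyA, 2)
  expect_equal(acc$UA, 1 - 0.1)   # single branch: accuracy = q
  expect_equal(acc$AA, acc$UA)

  expect_error(restrict_to_leafset(t3, character(0)), "nonempty")
  expect_error(restrict_to_leafset(t3, c("A", "Z")), "unknown leaf")
})

test_that("restriction agrees with marginalizing pruned leaves", {
  # On small trees: accuracy of the induced tree (recurrence) equals the
  # joint-enumeration oracle run on the induced tree, and enumeration itself
  # marginalizes the full model, so the composed branches are consistent.
  set.seed(5)
  for (rep in 1:10) {
    N <- sample(2:3, 1)
    tr <- random_tree(sample(3:5, 1), N)
    tips <- tr$label[lengths(tr$children) == 0]
    keep <- sample(tips, sample(2:(length(tips) - 1), 1))
    sub <- restrict_to_leafset(tr, keep)
    rec <- tree_accuracy(sub, N)
    oracle <- exact_enumeration_accuracy(sub, N)
    expect_equal(rec$UA, oracle$UA, tolerance = 1e-10)
    expect_equal(rec$AA, oracle$AA, tolerance = 1e-10)
  }
})

test_that("leaf-state TSV reading validates its input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t1", "B\t3", "C\t2"), f)
  st <- read_leaf_states(f, N = 4)
  expect_equal(st, c(A = 1L, B = 3L, C = 2L))
  writeLines(c("A\t5", "B\t1"), f)
  expect_error(read_leaf_states(f, N = 4), "1..4")
})
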