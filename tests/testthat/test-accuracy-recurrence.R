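# Class index convention: (i, contains-true) -> 2i-1, (i, not) -> 2i.
ci <- function(i, c) if (c == 1) 2L * i - 1L else 2L * i

test_that("leaf class vector is a point mass on class (1,1)", {
  expect_equal(leaf_class_vector(2), c(1, 0, 0))
  v4 <- leaf_class_vector(4)
  expect_equal(length(v4), 7L)
  expect_equal(v4[1], 1)
  expect_equal(sum(v4), 1)
  expect_error(leaf_class_vector(1), ">= 2")
})

test_that("branch mixing matches direct conditioning on the child's state", {
  A <- leaf_class_vector(4)
  expect_equal(branch_mixing(A, 0, 4), A)                        # p = 0
  M <- branch_mixing(A, 0.1, 4)
  expect_equal(M[ci(1, 1)], 1 - 3 * 0.1)                          # stays: q
  expect_equal(M[ci(1, 0)], 3 * 0.1)                              # moved: 3p

  # p = 1/N: membership fully randomized, m(i,1) = (i/N) * size marginal
  set.seed(2)
  for (N in c(2, 4, 6)) {
    A <- runif(2 * N - 1); A <- A / sum(A)
    M <- branch_mixing(A, 1 / N, N)
    for (i in 1:N) {
      tot <- A[ci(i, 1)] + if (i < N) A[ci(i, 0)] else 0
      expect_equal(M[ci(i, 1)], (i / N) * tot, tolerance = 1e-12)
    }
  }

  # size marginal and total mass preserved for arbitrary p
  for (N in c(2, 3, 5)) {
    A <- runif(2 * N - 1); A <- A / sum(A)
    p <- runif(1, 0, 1 / N)
    M <- branch_mixing(A, p, N)
    expect_equal(sum(M), 1, tolerance = 1e-12)
    for (i in 1:(N - 1))
      expect_equal(M[ci(i, 1)] + M[ci(i, 0)], A[ci(i, 1)] + A[ci(i, 0)],
                   tolerance = 1e-12)
  }
  # up to 1/(N-1) is a valid transition matrix (needed for q < 1/N analyses);
  # beyond it is not
  expect_silent(branch_mixing(leaf_class_vector(2), 0.9, 2))
  expect_error(branch_mixing(leaf_class_vector(3), 0.9, 3), "probability")
})

test_that("combination kernel reproduces exhaustive set combinatorics", {
  K2 <- build_combination_kernel(2)
  expect_equal(K2[ci(1, 1), ci(1, 1), ], c(1, 0, 0))    # {1}*{1} = {1}

  K4 <- build_combination_kernel(4)
  # disjoint singletons, one containing the true state: union (2, 1)
  row <- K4[ci(1, 1), ci(1, 0), ]
  expect_equal(row[ci(2, 1)], 1)
  expect_equal(sum(row), 1)

  # (2,0) x (2,0) for N = 4 by brute force over the 3x3 pairs of 2-subsets
  # of {2,3,4}: intersect-else-union, then classify
  subsets20 <- list(c(2, 3), c(2, 4), c(3, 4))
  counts <- c(0, 0)   # to class (1,0) and (2,0)
  for (a in subsets20) for (b in subsets20) {
    i <- intersect(a, b)
    s <- if (length(i)) i else union(a, b)
    if (length(s) == 1) counts[1] <- counts[1] + 1
    if (length(s) == 2 && !(1 %in% s)) counts[2] <- counts[2] + 1
  }
  expect_equal(K4[ci(2, 0), ci(2, 0), ci(1, 0)], counts[1] / 9)  # 2/3
  expect_equal(K4[ci(2, 0), ci(2, 0), ci(2, 0)], counts[2] / 9)  # 1/3

  # rows are distributions; kernel symmetric in its two class arguments
  for (N in c(2, 3, 5, 25)) {
    K <- build_combination_kernel(N)
    d <- 2 * N - 1
    sums <- apply(K, c(1, 2), sum)
    expect_true(max(abs(sums - 1)) < 1e-12)
    Ka <- array(K, dim = c(d, d, d))
    expect_equal(Ka, aperm(Ka, c(2, 1, 3)))
  }
})

test_that("combine_children matches the exact cherry enumeration", {
  lv <- leaf_class_vector(2)
  expect_equal(combine_children(lv, lv), c(1, 0, 0))

  # N = 2 cherry, p = 0.1 both: enumerate the 4 leaf configurations exactly
  M <- branch_mixing(lv, 0.1, 2)
  expect_equal(M, c(0.9, 0.1, 0))
  AZ <- combine_children(M, M)
  p11 <- 0.9 * 0.9          # both leaves true state -> {1}
  p22 <- 0.1 * 0.1          # both flipped -> {2}
  p12 <- 2 * 0.9 * 0.1      # discordant -> {1,2}
  expect_equal(AZ, c(p11, p22, p12))

  MX <- branch_mixing(leaf_class_vector(3), 0.2, 3)
  MY <- branch_mixing(leaf_class_vector(3), 0.05, 3)
  expect_equal(combine_children(MX, MY), combine_children(MY, MX))
  expect_error(combine_children(MX, leaf_class_vector(4),
                                build_combination_kernel(3)), "dimension")
})

test_that("accuracies_from_classvector implements UA and AA", {
  lv <- leaf_class_vector(5)
  acc <- accuracies_from_classvector(lv, 5)
  expect_equal(acc$UA, 1); expect_equal(acc$AA, 1)

  acc2 <- accuracies_from_classvector(c(1 / 3, 1 / 3, 1 / 3), 2)
  expect_equal(acc2$UA, 1 / 3)
  expect_equal(acc2$AA, 1 / 3 + (1 / 2) * (1 / 3))

  A <- numeric(7); A[ci(1, 1)] <- 0.5; A[ci(2, 1)] <- 0.3; A[ci(4, 1)] <- 0.2
  acc3 <- accuracies_from_classvector(A, 4)
  expect_equal(acc3$UA, 0.5)
  expect_equal(acc3$AA, 0.5 + 0.3 / 2 + 0.2 / 4)

  expect_error(accuracies_from_classvector(c(0.5, 0.2, 0.2), 2), "normalized")
})

test_that("tree_accuracy handles degenerate and extreme regimes", {
  cherry <- parse_newick("(A:0.1,B:0.1);", "probability", N = 2)
  acc <- tree_accuracy(cherry)
  expect_equal(acc$UA, 0.81)
  expect_equal(acc$AA, 0.90)

  single <- restrict_to_leafset(cherry, "A")
  zero <- single; zero$branch_p[-zero$root] <- 0
  a1 <- tree_accuracy(zero, 2)
  expect_equal(a1$UA, 1); expect_equal(a1$AA, 1)

  # p = 0 everywhere: perfect reconstruction on any tree
  set.seed(3)
  t0 <- set_branch_probabilities(generate_yule(12), 0, 3)
  expect_equal(tree_accuracy(t0, 3)$UA, 1)

  # p = 1/N everywhere: leaves carry no signal, AA collapses to 1/N
  t1 <- set_branch_probabilities(generate_yule(12), 1 / 3, 3)
  expect_equal(tree_accuracy(t1, 3)$AA, 1 / 3, tolerance = 1e-12)

  # child order never matters
  tr <- random_tree(5, 3)
  sw <- tr; sw$children <- lapply(sw$children, rev)
  expect_equal(tree_accuracy(sw, 3)$UA, tree_accuracy(tr, 3)$UA,
               tolerance = 1e-14)

  expect_gte(tree_accuracy(tr, 3)$AA, tree_accuracy(tr, 3)$UA)
})

test_that("recurrence equals the enumeration oracle on small trees", {
  # the full battery runs in the acceptance suite; this is the rapid version
  set.seed(17)
  for (N in 2:3) {
    for (shape in tree_shapes(4)) {
      for (rep in 1:5) {
        txt <- shape_to_newick(shape, function() runif(1, 0, 1 / N))
        tr <- parse_newick(txt, "probability", N = N)
        a <- tree_accuracy(tr, N)
        b <- exact_enumeration_accuracy(tr, N)
        expect_equal(a$UA, b$UA, tolerance = 1e-10)
        expect_equal(a$AA, b$AA, tolerance = 1e-10)
      }
    }
  }
})

test_that("4-leaf complete binary tree matches the oracle to 1e-12", {
  cb <- complete_binary_tree(2, 0.05, 3)
  a <- tree_accuracy(cb, 3)
  b <- exact_enumeration_accuracy(cb, 3)
  expect_equal(a$UA, b$UA, tolerance = 1e-12)
  expect_equal(a$AA, b$AA, tolerance = 1e-12)
})
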