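## Specialized recurrences and asymptotics on extremal tree shapes:
## complete binary trees (level map, equilibrium threshold b), equal-branch
## caterpillars (comb step), Hennigian caterpillars (finite-n accuracy and
## the closed-form limiting UA), and the single-path baseline.

#' One level of the equal-branch complete binary tree
#'
#' Because both root subtrees of the complete binary tree with `2^n` leaves
#' are complete binary trees with `2^(n-1)` leaves, the whole per-tree
#' recurrence collapses to iterating one map: mix the current root vector
#' through a branch with probability `p` and combine it with itself. Iterating
#' `n` times from [leaf_class_vector()] yields the root vector of the
#' equal-branch complete binary tree with `2^n` leaves.
#'
#' @param A class vector of the level-(n-1) tree
#' @param p substitution probability on every branch
#' @param N number of states
#' @param kernel optional precomputed [build_combination_kernel()]
#' @return class vector of the level-n tree
#' @export
complete_binary_level_map <- function(A, p, N, kernel = NULL) {
  M <- branch_mixing(A, p, N)
  combine_children(M, M, kernel, N = N)
}

#' One step of the equal-branch comb recurrence
#'
#' The caterpillar with `n` leaves is a cherry of (leaf, caterpillar with
#' `n-1` leaves), so its root vector follows from the previous one by mixing
#' both through branches with probability `p` and combining:
#' `A_n = combine(mix(leaf, p), mix(A_{n-1}, p))`, with `A_1` the leaf vector.
#'
#' @param A_prev class vector of the comb with `n - 1` leaves
#' @inheritParams complete_binary_level_map
#' @return class vector of the comb with `n` leaves
#' @export
comb_step <- function(A_prev, p, N, kernel = NULL) {
  combine_children(branch_mixing(leaf_class_vector(N), p, N),
                   branch_mixing(A_prev, p, N), kernel, N = N)
}

#' Accuracy on the equal-branch comb with n leaves
#'
#' Iterates [comb_step()] `n - 1` times from the leaf vector.
#'
#' @param n number of leaves (>= 1)
#' @param p substitution probability on every branch
#' @param N number of states
#' @return a `fitch_accuracy`
#' @export
comb_accuracy <- function(n, p, N) {
  stopifnot(n >= 1)
  kernel <- build_combination_kernel(N)
  A <- leaf_class_vector(N)
  if (n > 1) for (k in 2:n) A <- comb_step(A, p, N, kernel)
  accuracies_from_classvector(A, N)
}

#' Accuracy on the Hennigian comb with n leaves
#'
#' Evaluates the bottom-up recurrence along the interior path of the
#' ultrametric caterpillar (see [hennigian_tree()] for the construction) in
#' O(n) kernel applications, without materializing the tree. Pendant branch
#' probabilities come from [branch_prob_from_length()].
#'
#' @param n number of leaves (>= 2)
#' @param l interior edge length
#' @param rate substitution rate
#' @param N number of states
#' @return a `fitch_accuracy`
#' @export
hennigian_accuracy <- function(n, l, rate, N) {
  stopifnot(n >= 2, l > 0, rate > 0)
  kernel <- build_combination_kernel(N)
  pl <- branch_prob_from_length(l, rate, N)
  leafv <- leaf_class_vector(N)
  Ml <- branch_mixing(leafv, pl, N)
  A <- combine_children(Ml, Ml, kernel)            # deepest cherry
  if (n > 2) for (k in (n - 2):1) {
    pend <- branch_prob_from_length((n - k) * l, rate, N)
    A <- combine_children(branch_mixing(leafv, pend, N),
                          branch_mixing(A, pl, N), kernel)
    A <- A / sum(A)   # strip O(eps) drift over thousands of steps
  }
  accuracies_from_classvector(A, N)
}

#' Limiting UA of the Fitch method on Hennigian combs
#'
#' As the number of leaves grows, AA on the ultrametric caterpillar always
#' degenerates to 1/N while UA converges to the closed form
#' \deqn{UA_\infty(N) = \frac{N^{N-2}}{\sum_{i=1}^{N} N^{N-i} (N-1)!/(N-i)!},}
#' independent of the interior edge length. Evaluated through the equivalent
#' stable product recurrence `t_1 = N`, `t_i = t_{i-1} (N-i+1)/N`,
#' `UA = 1 / sum_i t_i`, which avoids overflowing factorials at large N.
#'
#' @param N number of states (>= 2)
#' @return the limiting unambiguous accuracy
#' @examples
#' hennigian_limiting_ua(2)  # 1/3
#' @export
hennigian_limiting_ua <- function(N) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  t <- N; s <- t
  for (i in 2:N) { t <- t * (N - i + 1) / N; s <- s + t }
  1 / s
}

#' Accuracy of reconstructing from a single root-to-leaf path
#'
#' Using one leaf `k` branches below the root, the Fitch reconstruction is
#' that leaf's state, so UA = AA = the k-step conservation probability
#' `1/N + ((N-1)/N) (1 - N p)^k`.
#'
#' @param k number of branches on the path (>= 0)
#' @param p substitution probability per branch
#' @param N number of states
#' @return the path accuracy (UA = AA), vectorized over `k`
#' @export
path_accuracy <- function(k, p, N) {
  stopifnot(all(k >= 0))
  check_branch_domain(p, N)
  1 / N + ((N - 1) / N) * (1 - N * p)^k
}

#' Iterate the complete-binary level map to its limit
#'
#' Repeatedly applies [complete_binary_level_map()] from the leaf vector at
#' conservation probability `q` until the even and odd iteration subsequences
#' are stationary, or `max_iters` is reached. Stationarity is judged on the
#' two-step difference because for N = 2 the map can settle into a period-2
#' cycle (the limits of the even and odd subsequences then differ). The
#' vector is renormalized by its computed sum each step: the exact sum is 1,
#' but the map is quadratic, so unremoved roundoff in the sum would square
#' every iteration and overflow after ~60 steps.
#'
#' @param q common conservation probability, in `(0, 1]`
#' @param N number of states
#' @param max_iters iteration cap
#' @param tol two-step stationarity tolerance
#' @param kernel optional precomputed kernel
#' @return list with class vectors `even` and `odd` (consecutive iterates at
#'   termination), `UA`/`AA` (from `even`), `AA_odd`, and `iters`
#' @export
complete_binary_limit <- function(q, N, max_iters = 10000, tol = 1e-13,
                                  kernel = NULL) {
  stopifnot(q > 0, q <= 1)
  if (is.null(kernel)) kernel <- build_combination_kernel(N)
  p <- (1 - q) / (N - 1)
  A <- leaf_class_vector(N); Aprev <- A
  iters <- max_iters
  for (t in seq_len(max_iters)) {
    Anew <- complete_binary_level_map(A, p, N, kernel)
    Anew <- Anew / sum(Anew)
    if (max(abs(Anew - Aprev)) < tol) { Aprev <- A; A <- Anew; iters <- t; break }
    Aprev <- A; A <- Anew
  }
  even <- accuracies_from_classvector(A, N)
  odd <- accuracies_from_classvector(Aprev, N)
  list(even = A, odd = Aprev, UA = even$UA, AA = even$AA,
       UA_odd = odd$UA, AA_odd = odd$AA, iters = iters)
}

#' Equilibrium interval of the conservation probability
#'
#' On equal-branch complete binary trees there is an interval `[a, b]` of the
#' conservation probability `q` in which the limiting ambiguous accuracy
#' equals 1/N — no better than picking a state at random. `b` is located by
#' bisection on `q` in `(1/N, 1)`: a candidate is classified "equilibrium"
#' when both iteration subsequences of [complete_binary_limit()] end with
#' `|AA - 1/N| < detect_tol`. For N = 2 the lower endpoint `a` (= 1/8) is
#' located the same way as the boundary below which the even/odd subsequence
#' limits separate; for N >= 3 the divergence regime vanishes and `a = 0`
#' (verified by equilibrium classification at q = 0.01, 0.05, 0.1).
#'
#' @param N number of states
#' @param max_iters level-map iteration cap per candidate q
#' @param bisect_tol bisection stopping width on q
#' @param detect_tol tolerance on `|AA - 1/N|` for the equilibrium call
#' @return object of class `equilibrium_result`: list with `N`, `a`, `b`,
#'   `bisect_tol`, and `iters_at_b` (iterations used at the last candidate)
#' @examples
#' \donttest{estimate_threshold_b(2)$b  # ~ 0.875}
#' @export
estimate_threshold_b <- function(N, max_iters = 10000, bisect_tol = 1e-4,
                                 detect_tol = 1e-5) {
  stopifnot(N >= 2)
  kernel <- build_combination_kernel(N)
  is_equilibrium <- function(q) {
    r <- complete_binary_limit(q, N, max_iters, kernel = kernel)
    abs(r$AA - 1 / N) < detect_tol && abs(r$AA_odd - 1 / N) < detect_tol
  }
  lo <- 1 / N + 1e-6; hi <- 1 - 1e-6
  if (!is_equilibrium(lo) || is_equilibrium(hi))
    stop("bisection endpoints do not bracket the threshold b", call. = FALSE)
  last_iters <- NA_integer_
  while (hi - lo > bisect_tol) {
    mid <- (lo + hi) / 2
    r <- complete_binary_limit(mid, N, max_iters, kernel = kernel)
    last_iters <- r$iters
    if (abs(r$AA - 1 / N) < detect_tol && abs(r$AA_odd - 1 / N) < detect_tol)
      lo <- mid else hi <- mid
  }
  b <- (lo + hi) / 2
  if (N == 2) {
    diverges <- function(q) {
      r <- complete_binary_limit(q, N, max_iters, kernel = kernel)
      abs(r$AA - r$AA_odd) > detect_tol
    }
    alo <- 0.01; ahi <- 0.5
    if (!diverges(alo) || diverges(ahi))
      stop("bisection endpoints do not bracket the lower endpoint a", call. = FALSE)
    while (ahi - alo > bisect_tol) {
      amid <- (alo + ahi) / 2
      if (diverges(amid)) alo <- amid else ahi <- amid
    }
    a <- (alo + ahi) / 2
  } else {
    ok <- vapply(c(0.01, 0.05, 0.1), is_equilibrium, logical(1))
    if (!all(ok))
      warning("equilibrium classification failed near q = 0 for N = ", N)
    a <- 0
  }
  structure(list(N = as.integer(N), a = a, b = b, bisect_tol = bisect_tol,
                 detect_tol = detect_tol, iters_at_b = last_iters),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium interval of conservation probability (N = %d)\n", x$N))
  cat(sprintf("  [a, b] = [%.4f, %.4f]  (bisection width %.1e)\n",
              x$a, x$b, x$bisect_tol))
  cat("  inside: limiting AA = 1/N (random guessing); above b: AA > 1/N\n")
  invisible(x)
}

#' @export
tidy.equilibrium_result <- function(x, ...) {
  tibble::tibble(N = x$N, a = x$a, b = x$b,
                 bisect_tol = x$bisect_tol, detect_tol = x$detect_tol)
}
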