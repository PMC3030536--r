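## The 2N-1 class recurrence for Fitch reconstruction accuracy.
##
## Nonempty subsets B of the state set {1..N} are partitioned by
## (size |B|, whether B contains the true state 1):
##   class (i, 1) <-> index 2i-1   (i = 1..N)
##   class (i, 0) <-> index 2i     (i = 1..N-1; (N, 0) cannot occur)
## A class vector holds, conditional on the node's true state, the TOTAL
## probability that the reconstructed set lies in each class; it sums to 1.
## Because both the model and the Fitch rule are symmetric on states, the set
## is uniformly distributed within its class, which is what lets the pair
## (size, contains-true-state) carry all information through the recurrence.

class_index <- function(i, c) if (c == 1L) 2L * i - 1L else 2L * i

#' Class vector of a leaf
#'
#' A leaf reconstructs exactly its own (true) state, so all mass sits on
#' class (1, 1).
#'
#' @param N number of states (>= 2)
#' @return numeric vector of length `2N - 1`
#' @export
leaf_class_vector <- function(N) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  A <- numeric(2 * N - 1)
  A[1L] <- 1
  A
}

#' Push a class vector through a branch
#'
#' Converts a class vector conditioned on the child's true state into one
#' conditioned on the parent's true state, for a branch with substitution
#' probability `p` (conservation `q = 1 - (N-1) p`). Conditioning on the
#' child's true state: it equals the parent's with probability q; it is each
#' other state j with probability p, and by within-class uniformity a size-i
#' set containing j contains the parent state with probability (i-1)/(N-1),
#' a size-i set avoiding j with probability i/(N-1). Summing over the N-1
#' choices of j gives
#' \deqn{m(i,1) = q a(i,1) + p[(i-1) a(i,1) + i a(i,0)]}
#' \deqn{m(i,0) = q a(i,0) + p[(N-i) a(i,1) + (N-1-i) a(i,0)]}
#' The size marginal `m(i,1) + m(i,0) = a(i,1) + a(i,0)` is preserved.
#'
#' @param A_child class vector conditional on the child's true state
#' @param p branch substitution probability in `[0, 1/N]`
#' @param N number of states
#' @return class vector conditional on the parent's true state
#' @export
branch_mixing <- function(A_child, p, N) {
  stopifnot(length(A_child) == 2 * N - 1)
  ## p up to 1/(N-1) is a valid (super-stationary) transition matrix; the
  ## two-state equilibrium analysis needs q < 1/2, i.e. p > 1/2, so the
  ## strict Jukes-Cantor cap 1/N applies to tree input, not to mixing
  check_branch_domain(p, N, allow_superstationary = TRUE)
  q <- 1 - (N - 1) * p
  i <- seq_len(N)
  a1 <- A_child[2L * i - 1L]
  a0 <- c(A_child[2L * i[-N]], 0)        # a(i,0); (N,0) is structurally 0
  m1 <- q * a1 + p * ((i - 1) * a1 + i * a0)
  m0 <- q * a0 + p * ((N - i) * a1 + (N - 1 - i) * a0)
  M <- numeric(2 * N - 1)
  M[2L * i - 1L] <- m1
  M[2L * i[-N]] <- m0[-N]
  M
}

kernel_cache <- new.env(parent = emptyenv())

#' Combination kernel of the Fitch intersect-else-union rule
#'
#' For independent child sets `B_X` uniform on class `(i, c)` and `B_Y`
#' uniform on class `(j, c')` (both w.r.t. the parent's true state), the
#' parent set is `B_X` intersect `B_Y` if nonempty, else the union. With
#' `i' = i - c`, `j' = j - c'` the non-true-state part sizes, the overlap `m`
#' of the non-true parts is hypergeometric:
#' `P(m) = C(i',m) C(N-1-i', j'-m) / C(N-1, j')`, and the parent lands in
#' class `(m + c c', c c')` when `m + c c' >= 1`, else (empty intersection)
#' in the union class `(i + j, max(c, c'))`.
#'
#' Binomial coefficients up to `C(49, 24)` are exact integers in double
#' precision, so each entry is correct to one rounding; rows sum to 1.
#'
#' @param N number of states (2..50)
#' @return array `K` of dimension `(2N-1)^3`: `K[x, y, z]` is the probability
#'   that child classes `x`, `y` combine to parent class `z`; class
#'   `"combination_kernel"`
#' @export
build_combination_kernel <- function(N) {
  stopifnot(N >= 2, N <= 50)
  key <- as.character(N)
  if (!is.null(kernel_cache[[key]])) return(kernel_cache[[key]])
  d <- 2L * N - 1L
  K <- array(0, dim = c(d, d, d))
  for (x in seq_len(d)) {
    i <- (x + 1L) %/% 2L; ci <- x %% 2L
    for (y in seq_len(d)) {
      j <- (y + 1L) %/% 2L; cj <- y %% 2L
      ip <- i - ci; jp <- j - cj
      lo <- max(0L, ip + jp - (N - 1L)); hi <- min(ip, jp)
      denom <- choose(N - 1L, jp)
      for (m in lo:hi) {
        pm <- choose(ip, m) * choose(N - 1L - ip, jp - m) / denom
        isz <- m + ci * cj
        z <- if (isz >= 1L) class_index(isz, ci * cj)
             else class_index(i + j, max(ci, cj))
        K[x, y, z] <- K[x, y, z] + pm
      }
    }
  }
  K <- structure(K, class = "combination_kernel", N = N)
  kernel_cache[[key]] <- K
  K
}

#' Combine two parent-conditioned child class vectors
#'
#' Applies the combination kernel: the parent's class vector is the bilinear
#' form `A_Z[z] = sum_{x,y} M_X[x] M_Y[y] K[x,y,z]`. Symmetric in its two
#' vector arguments; preserves the total probability.
#'
#' @param M_X,M_Y class vectors conditioned on the parent's true state
#'   (outputs of [branch_mixing()])
#' @param kernel a `combination_kernel` from [build_combination_kernel()];
#'   built (or fetched from the per-N cache) when omitted
#' @param N number of states; inferred from `kernel` when given
#' @return the parent's class vector
#' @export
combine_children <- function(M_X, M_Y, kernel = NULL, N = NULL) {
  if (is.null(kernel)) {
    if (is.null(N)) N <- (length(M_X) + 1L) %/% 2L
    kernel <- build_combination_kernel(N)
  }
  d <- dim(kernel)[1L]
  if (length(M_X) != d || length(M_Y) != d)
    stop("class-vector length does not match kernel dimension", call. = FALSE)
  as.vector(crossprod(matrix(kernel, d * d, d), as.vector(outer(M_X, M_Y))))
}

#' Accuracies encoded in a root class vector
#'
#' `UA` is the probability of reconstructing exactly the singleton of the true
#' state, i.e. the mass of class (1, 1). `AA` adds, for every set containing
#' the true state, the `1/|B|` chance of drawing it:
#' `AA = sum_k A[(k,1)] / k`.
#'
#' @param A class vector (must sum to 1 within 1e-9)
#' @param N number of states
#' @return object of class `fitch_accuracy`: list with `UA`, `AA`, the root
#'   `class_vector`, and `N`
#' @export
accuracies_from_classvector <- function(A, N) {
  stopifnot(length(A) == 2 * N - 1)
  if (abs(sum(A) - 1) > 1e-9)
    stop("class vector is not normalized (sum = ", format(sum(A), digits = 12),
         ")", call. = FALSE)
  k <- seq_len(N)
  ua <- A[1L]
  aa <- sum(A[2L * k - 1L] / k)
  structure(list(UA = ua, AA = aa, class_vector = A, N = as.integer(N)),
            class = "fitch_accuracy")
}

#' Exact Fitch reconstruction accuracy at the root of a tree
#'
#' Post-order dynamic program over the 2N-1 classes: leaves start at
#' [leaf_class_vector()], each internal node combines its two children's
#' vectors after [branch_mixing()] through the branch into each child. A
#' single-child root (as produced by [restrict_to_leafset()]) contributes a
#' plain branch-mixing step; a bare single-leaf tree has UA = AA = 1.
#' Normalization of every intermediate vector is asserted (1e-9), not
#' repaired, so kernel or mixing defects surface immediately.
#'
#' @param tree a `fitch_tree` with branch probabilities set
#' @param N number of states (defaults to the tree's `N`)
#' @return a `fitch_accuracy` (UA, AA, root class vector)
#' @examples
#' cherry <- parse_newick("(A:0.1,B:0.1);", "probability", N = 2)
#' tree_accuracy(cherry)  # UA = 0.81, AA = 0.90
#' @export
tree_accuracy <- function(tree, N = tree$N) {
  stopifnot(inherits(tree, "fitch_tree"))
  if (anyNA(tree$branch_p[-tree$root]))
    stop("tree has branches without substitution probabilities", call. = FALSE)
  kernel <- build_combination_kernel(N)
  vec <- vector("list", length(tree$parent))
  for (u in postorder(tree)) {
    kids <- tree$children[[u]]
    A <- if (length(kids) == 0L) {
      leaf_class_vector(N)
    } else if (length(kids) == 1L) {
      branch_mixing(vec[[kids]], tree$branch_p[kids], N)
    } else {
      combine_children(branch_mixing(vec[[kids[1L]]], tree$branch_p[kids[1L]], N),
                       branch_mixing(vec[[kids[2L]]], tree$branch_p[kids[2L]], N),
                       kernel)
    }
    if (abs(sum(A) - 1) > 1e-9)
      stop("internal class vector lost normalization at node ", u, call. = FALSE)
    vec[[u]] <- A
    vec[kids] <- list(NULL)
  }
  accuracies_from_classvector(vec[[tree$root]], N)
}

#' @export
print.fitch_accuracy <- function(x, ...) {
  cat(sprintf("Fitch reconstruction accuracy (N = %d)\n  UA = %.10g\n  AA = %.10g\n",
              x$N, x$UA, x$AA))
  invisible(x)
}

#' @export
tidy.fitch_accuracy <- function(x, ...) {
  tibble::tibble(accuracy = c("UA", "AA"), estimate = c(x$UA, x$AA))
}

#' @export
glance.fitch_accuracy <- function(x, ...) {
  tibble::tibble(UA = x$UA, AA = x$AA, N = x$N)
}
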