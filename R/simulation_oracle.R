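## Ground truth and stochastic machinery: exact enumeration of the accuracy
## definitions on small trees, vectorized Monte-Carlo estimation, character
## evolution along a tree, and Yule (pure-birth) topology generation.

#' Simulate character evolution along a tree
#'
#' Draws one character: the root takes `root_state`, every other node copies
#' its parent's state with the branch's conservation probability
#' `q = 1 - (N-1) p` and otherwise moves to one of the `N - 1` other states
#' uniformly. Uses R's global RNG; `set.seed()` for reproducibility.
#'
#' @param tree a `fitch_tree` with branch probabilities set
#' @param N number of states
#' @param root_state true state at the root (default 1; by state symmetry the
#'   accuracies do not depend on it)
#' @return named integer vector of leaf states
#' @export
simulate_evolution <- function(tree, N = tree$N, root_state = 1L) {
  stopifnot(root_state >= 1L, root_state <= N)
  st <- simulate_states_matrix(tree, N, reps = 1L, root_state = root_state)
  tips <- tip_ids(tree)
  stats::setNames(st[tips, 1L], tree$label[tips])
}

## All-node state draws, vectorized over replicates: integer matrix
## (n_nodes x reps). A substitution moves by a uniform offset in 1..N-1
## (mod N), which is exactly uniform over the other states.
simulate_states_matrix <- function(tree, N, reps, root_state = 1L) {
  if (anyNA(tree$branch_p[-tree$root]))
    stop("tree has branches without substitution probabilities", call. = FALSE)
  n <- length(tree$parent)
  st <- matrix(0L, n, reps)
  ord <- rev(postorder(tree))              # parents before children
  st[tree$root, ] <- as.integer(root_state)
  for (u in ord) {
    if (u == tree$root) next
    ps <- st[tree$parent[u], ]
    move <- stats::runif(reps) < (N - 1) * tree$branch_p[u]
    off <- sample.int(N - 1L, reps, replace = TRUE)
    st[u, ] <- ifelse(move, ((ps - 1L + off) %% N) + 1L, ps)
  }
  st
}

popcount <- function(mask, N) {
  sz <- integer(length(mask))
  for (b in seq_len(N) - 1L)
    sz <- sz + as.integer(bitwAnd(mask, bitwShiftL(1L, b)) != 0L)
  sz
}

#' Exact accuracy by enumeration of all leaf configurations
#'
#' The definitions themselves, computed literally: every leaf-state
#' configuration D in `{1..N}^L` is enumerated jointly with (i) its
#' probability given root state 1, by matrix peeling with the per-branch
#' Jukes-Cantor transition matrices, and (ii) its deterministic Fitch root
#' set, by the intersect-else-union rule on bitmasks. Then
#' `UA = sum_D Pr[D|1] [S_r(D) = {1}]` and
#' `AA = sum_D Pr[D|1] [1 in S_r(D)] / |S_r(D)|`.
#' Completely independent of the class recurrence; serves as its oracle.
#'
#' @param tree a `fitch_tree` (at most `N^L <= 1e7` configurations)
#' @param N number of states (<= 30, bitmask representation)
#' @return a `fitch_accuracy`
#' @export
exact_enumeration_accuracy <- function(tree, N = tree$N) {
  stopifnot(inherits(tree, "fitch_tree"), N >= 2, N <= 30)
  L <- n_tips(tree)
  if (N^L > 1e7)
    stop("enumeration capacity exceeded: N^L = ", format(N^L), " > 1e7",
         call. = FALSE)
  if (L > 1L && anyNA(tree$branch_p[-tree$root]))
    stop("tree has branches without substitution probabilities", call. = FALSE)
  P_mat <- function(p) {
    q <- 1 - (N - 1) * p
    matrix(p, N, N) + diag(q - p, N)
  }
  lik <- vector("list", length(tree$parent))   # configs x N
  msk <- vector("list", length(tree$parent))   # configs (bitmask)
  through_branch <- function(u) lik[[u]] %*% t(P_mat(tree$branch_p[u]))
  for (u in postorder(tree)) {
    kids <- tree$children[[u]]
    if (length(kids) == 0L) {
      lik[[u]] <- diag(N)
      msk[[u]] <- bitwShiftL(1L, 0:(N - 1L))
    } else if (length(kids) == 1L) {
      lik[[u]] <- through_branch(kids)
      msk[[u]] <- msk[[kids]]
    } else {
      x <- kids[1L]; y <- kids[2L]
      Mx <- through_branch(x); My <- through_branch(y)
      cx <- nrow(Mx); cy <- nrow(My)
      ix <- rep(seq_len(cx), times = cy); iy <- rep(seq_len(cy), each = cx)
      lik[[u]] <- Mx[ix, , drop = FALSE] * My[iy, , drop = FALSE]
      I <- bitwAnd(msk[[x]][ix], msk[[y]][iy])
      msk[[u]] <- ifelse(I > 0L, I, bitwOr(msk[[x]][ix], msk[[y]][iy]))
    }
    lik[kids] <- list(NULL); msk[kids] <- list(NULL)
  }
  prob <- lik[[tree$root]][, 1L]
  if (abs(sum(prob) - 1) > 1e-9)
    stop("configuration probabilities do not sum to 1", call. = FALSE)
  mask <- msk[[tree$root]]
  sz <- popcount(mask, N)
  ua <- sum(prob[mask == 1L])
  aa <- sum(prob * (bitwAnd(mask, 1L) > 0L) / sz)
  structure(list(UA = ua, AA = aa, class_vector = NULL, N = as.integer(N)),
            class = "fitch_accuracy")
}

#' Monte-Carlo accuracy estimate
#'
#' Per replicate: simulate a character from root state 1, run the Fitch
#' leaf-to-root stage (vectorized on bitmasks), and record the UA indicator
#' `[S_r = {1}]` together with the analytic AA contribution
#' `[1 in S_r] / |S_r|` — the expectation of the uniform stage-two draw,
#' used instead of sampling it to cut variance without changing the mean.
#'
#' @param tree a `fitch_tree` with branch probabilities set
#' @param N number of states (<= 30)
#' @param reps number of replicates
#' @param seed optional integer seed (set locally when given)
#' @return object of class `fitch_mc`: list with `UA_hat`, `AA_hat`,
#'   `se_UA`, `se_AA`, `reps`, `N`
#' @export
estimate_accuracy_mc <- function(tree, N = tree$N, reps = 10000L, seed = NULL) {
  stopifnot(reps >= 1, N <= 30)
  if (!is.null(seed)) set.seed(seed)
  st <- simulate_states_matrix(tree, N, reps = reps, root_state = 1L)
  mask <- matrix(0L, length(tree$parent), reps)
  tips <- tip_ids(tree)
  mask[tips, ] <- bitwShiftL(1L, st[tips, , drop = FALSE] - 1L)
  for (u in postorder(tree)) {
    kids <- tree$children[[u]]
    if (length(kids) == 2L) {
      I <- bitwAnd(mask[kids[1L], ], mask[kids[2L], ])
      mask[u, ] <- ifelse(I > 0L, I, bitwOr(mask[kids[1L], ], mask[kids[2L], ]))
    } else if (length(kids) == 1L) mask[u, ] <- mask[kids, ]
  }
  rmask <- mask[tree$root, ]
  ua_i <- as.numeric(rmask == 1L)
  aa_i <- (bitwAnd(rmask, 1L) > 0L) / popcount(rmask, N)
  se <- function(v) if (reps > 1) stats::sd(v) / sqrt(reps) else 0
  structure(list(UA_hat = mean(ua_i), AA_hat = mean(aa_i),
                 se_UA = se(ua_i), se_AA = se(aa_i),
                 reps = as.integer(reps), N = as.integer(N)),
            class = "fitch_mc")
}

#' @export
print.fitch_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo Fitch accuracy (N = %d, %d replicates)\n", x$N, x$reps))
  cat(sprintf("  UA = %.6f (se %.2g)\n  AA = %.6f (se %.2g)\n",
              x$UA_hat, x$se_UA, x$AA_hat, x$se_AA))
  invisible(x)
}

#' @export
tidy.fitch_mc <- function(x, ...) {
  tibble::tibble(accuracy = c("UA", "AA"),
                 estimate = c(x$UA_hat, x$AA_hat),
                 std.error = c(x$se_UA, x$se_AA))
}

#' Yule (pure-birth) tree topology
#'
#' Starting from a two-leaf cherry, a uniformly chosen current leaf is split
#' into two leaves until `n_leaves` is reached — every extant lineage equally
#' likely to speciate. Branch probabilities are left unset (the experiments
#' assign one common conservation probability to every branch afterwards,
#' see [set_branch_probabilities()]). Uses R's global RNG.
#'
#' @param n_leaves number of leaves (>= 2)
#' @return a `fitch_tree` topology with `branch_p` unset (`NA`)
#' @export
generate_yule <- function(n_leaves) {
  stopifnot(n_leaves >= 2)
  nmax <- 2L * n_leaves - 1L
  children <- rep(list(integer(0)), nmax)
  parent <- integer(nmax)
  children[[1L]] <- c(2L, 3L); parent[2L] <- 1L; parent[3L] <- 1L
  leaves <- c(2L, 3L); nxt <- 4L
  while (length(leaves) < n_leaves) {
    k <- sample.int(length(leaves), 1L)
    u <- leaves[k]
    children[[u]] <- c(nxt, nxt + 1L)
    parent[nxt] <- u; parent[nxt + 1L] <- u
    leaves[k] <- nxt
    leaves <- c(leaves, nxt + 1L)
    nxt <- nxt + 2L
  }
  label <- rep(NA_character_, nmax)
  tipv <- which(lengths(children) == 0L)
  label[tipv] <- paste0("t", seq_along(tipv))
  new_fitch_tree(parent, children, rep(NA_real_, nmax), label,
                 N = NA_integer_, root = 1L)
}

#' Assign one substitution probability to every branch
#'
#' @param tree a `fitch_tree`
#' @param p substitution probability for every branch
#' @param N number of states (also stored on the tree)
#' @return the tree with `branch_p` set everywhere (root stays `NA`)
#' @export
set_branch_probabilities <- function(tree, p, N) {
  check_branch_domain(p, N)
  tree$branch_p <- rep(as.numeric(p), length(tree$parent))
  tree$branch_p[tree$root] <- NA_real_
  tree$N <- as.integer(N)
  tree
}

#' Accuracy sweep over Yule trees with a complete-binary reference
#'
#' Generates `n_trees` Yule topologies with `n_leaves` leaves, assigns every
#' branch the substitution probability `p = (1 - q)/(N - 1)` for each `q` in
#' `q_grid`, and computes exact accuracies with [tree_accuracy()]. The
#' equal-branch complete binary tree with the same (power-of-two) number of
#' leaves is evaluated at each `q` as the reference, via
#' [complete_binary_level_map()].
#'
#' @param n_trees number of Yule topologies
#' @param n_leaves leaves per tree (a power of two, for the reference)
#' @param q_grid conservation probabilities to sweep
#' @param N number of states
#' @param seed optional integer seed
#' @return a tibble of class `accuracy_sweep` with columns `tree`
#'   (`"yule_<i>"` or `"complete_binary"`), `q`, `UA`, `AA`
#' @export
yule_experiment <- function(n_trees, n_leaves, q_grid, N, seed = NULL) {
  stopifnot(n_trees >= 1, all(q_grid > 0 & q_grid <= 1))
  levels <- round(log2(n_leaves))
  if (2^levels != n_leaves)
    stop("n_leaves must be a power of two (complete-binary reference)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kernel <- build_combination_kernel(N)
  rows <- vector("list", n_trees + 1L)
  for (i in seq_len(n_trees)) {
    topo <- generate_yule(n_leaves)
    res <- vapply(q_grid, function(q) {
      tr <- set_branch_probabilities(topo, (1 - q) / (N - 1), N)
      a <- tree_accuracy(tr, N)
      c(a$UA, a$AA)
    }, numeric(2))
    rows[[i]] <- tibble::tibble(tree = sprintf("yule_%03d", i), q = q_grid,
                                UA = res[1L, ], AA = res[2L, ])
  }
  ref <- vapply(q_grid, function(q) {
    p <- (1 - q) / (N - 1)
    A <- leaf_class_vector(N)
    for (k in seq_len(levels)) A <- complete_binary_level_map(A, p, N, kernel)
    a <- accuracies_from_classvector(A / sum(A), N)
    c(a$UA, a$AA)
  }, numeric(2))
  rows[[n_trees + 1L]] <- tibble::tibble(tree = "complete_binary", q = q_grid,
                                         UA = ref[1L, ], AA = ref[2L, ])
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_sweep", class(out))
  attr(out, "N") <- as.integer(N)
  out
}

#' Accuracy-vs-q sweep on an extremal tree shape
#'
#' @param shape `"complete"` (equal-branch complete binary, `2^n` leaves),
#'   `"comb"` (equal-branch caterpillar with `n` leaves), or `"hennigian"`
#'   (ultrametric caterpillar; `q_grid` is then interpreted through the
#'   per-interior-edge conservation probability, converting each q to the
#'   interior edge length at rate 1)
#' @param N number of states
#' @param q_grid conservation probabilities (`> 1/N`)
#' @param n size parameter: levels for `"complete"`, leaves otherwise
#' @return a tibble of class `accuracy_sweep` (`tree`, `q`, `UA`, `AA`)
#' @export
extremal_sweep <- function(shape = c("complete", "comb", "hennigian"),
                           N, q_grid, n) {
  shape <- match.arg(shape)
  kernel <- build_combination_kernel(N)
  res <- vapply(q_grid, function(q) {
    p <- (1 - q) / (N - 1)
    a <- switch(shape,
      complete = {
        A <- leaf_class_vector(N)
        for (k in seq_len(n)) A <- complete_binary_level_map(A, p, N, kernel)
        accuracies_from_classvector(A / sum(A), N)
      },
      comb = comb_accuracy(n, p, N),
      hennigian = {
        ## q = 1/N + ((N-1)/N) exp(-N l)  =>  l at rate 1
        l <- -log((q - 1 / N) * N / (N - 1)) / N
        hennigian_accuracy(n, l, rate = 1, N = N)
      })
    c(a$UA, a$AA)
  }, numeric(2))
  out <- tibble::tibble(tree = shape, q = q_grid, UA = res[1L, ], AA = res[2L, ])
  class(out) <- c("accuracy_sweep", class(out))
  attr(out, "N") <- as.integer(N)
  out
}

#' @export
autoplot.accuracy_sweep <- function(object, ...) {
  long <- rbind(
    tibble::tibble(tree = object$tree, q = object$q,
                   accuracy = "UA", value = object$UA),
    tibble::tibble(tree = object$tree, q = object$q,
                   accuracy = "AA", value = object$AA))
  is_ref <- long$tree == "complete_binary"
  p <- ggplot2::ggplot(long[!is_ref, ],
                       ggplot2::aes(x = .data$q, y = .data$value,
                                    group = .data$tree)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey35") +
    ggplot2::facet_wrap(~accuracy) +
    ggplot2::labs(x = "conservation probability q",
                  y = "reconstruction accuracy",
                  title = sprintf("Fitch reconstruction accuracy (N = %d)",
                                  attr(object, "N"))) +
    ggplot2::theme_minimal()
  if (any(is_ref))
    p <- p + ggplot2::geom_line(data = long[is_ref, ], colour = "firebrick",
                                linetype = "dashed", linewidth = 0.8)
  N <- attr(object, "N")
  if (!is.null(N) && is.finite(N))
    p <- p + ggplot2::geom_hline(yintercept = 1 / N, linetype = "dotted")
  p
}

#' @importFrom ggplot2 .data
NULL
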