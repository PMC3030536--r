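# Shared fixtures: rooted-binary shape enumeration, random tree generation
# (as Newick text, so the parser is on the hot path), and small brute-force
# oracles that are deliberately independent of the package internals.

# All distinct rooted binary tree shapes with n leaves, as nested lists
# (leaf = NA). 1, 1, 2, 3 shapes for n = 2..5.
tree_shapes <- function(n) {
  if (n == 1) return(list(NA))
  out <- list()
  seen <- character(0)
  for (a in 1:(n %/% 2)) {
    for (left in tree_shapes(a)) for (right in tree_shapes(n - a)) {
      sh <- list(left, right)
      key <- paste(deparse(sh), collapse = "")
      if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1]] <- sh }
    }
  }
  out
}

# Instantiate a shape as Newick text with branch probabilities drawn by pgen().
shape_to_newick <- function(shape, pgen) {
  counter <- new.env(); counter$i <- 0
  rec <- function(s, top = FALSE) {
    if (!is.list(s)) {
      counter$i <- counter$i + 1
      lab <- paste0("t", counter$i)
      return(if (top) paste0("(", lab, ":", pgen(), ");")
             else paste0(lab, ":", pgen()))
    }
    inner <- paste0("(", rec(s[[1]]), ",", rec(s[[2]]), ")")
    if (top) paste0(inner, ";") else paste0(inner, ":", pgen())
  }
  rec(shape, top = TRUE)
}

random_tree <- function(n_leaves, N, pmax = 1 / N) {
  shapes <- tree_shapes(n_leaves)
  sh <- shapes[[sample.int(length(shapes), 1)]]
  txt <- shape_to_newick(sh, function() formatC(runif(1, 0, pmax), format = "g",
                                               digits = 12))
  parse_newick(txt, "probability", N = N)
}

# Brute-force parsimony: minimum number of substitutions over every internal
# labeling, by exhaustive enumeration. Independent of the Fitch recursion.
brute_parsimony <- function(tree, states, N) {
  tips <- which(lengths(tree$children) == 0)
  internals <- setdiff(seq_along(tree$parent), tips)
  lab <- integer(length(tree$parent))
  lab[tips] <- as.integer(states[tree$label[tips]])
  grid <- as.matrix(expand.grid(rep(list(1:N), length(internals))))
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab[internals] <- grid[g, ]
    best <- min(best, sum(lab[nonroot] != lab[tree$parent[nonroot]]))
  }
  best
}

# Number of substitutions implied by a full labeling (for stage-two checks).
labeling_changes <- function(tree, chosen) {
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  sum(chosen[nonroot] != chosen[tree$parent[nonroot]])
}

# Joint-enumeration accuracy oracle: sums over ALL full labelings (internal
# states x leaf states), using only transition-probability products and the
# Fitch set rule re-implemented locally on plain integer vectors. Slower and
# cruder than exact_enumeration_accuracy's peeling - that is the point.
joint_enumeration_accuracy <- function(tree, N) {
  tips <- which(lengths(tree$children) == 0)
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  fitch_sets <- function(leaf_states) {
    sets <- vector("list", length(tree$parent))
    for (u in order_children_first(tree)) {
      kids <- tree$children[[u]]
      sets[[u]] <- if (length(kids) == 0) leaf_states[match(u, tips)]
      else if (length(kids) == 1) sets[[kids]]
      else {
        i <- intersect(sets[[kids[1]]], sets[[kids[2]]])
        if (length(i)) i else union(sets[[kids[1]]], sets[[kids[2]]])
      }
    }
    sets[[tree$root]]
  }
  leaf_grid <- as.matrix(expand.grid(rep(list(1:N), length(tips))))
  free <- setdiff(seq_along(tree$parent), tree$root)
  ua <- 0; aa <- 0; total <- 0
  for (g in seq_len(nrow(leaf_grid))) {
    D <- leaf_grid[g, ]
    # Pr[D|1]: sum over internal labelings of the product of branch factors
    pr <- 0
    internals <- setdiff(free, tips)
    igrid <- if (length(internals))
      as.matrix(expand.grid(rep(list(1:N), length(internals))))
    else matrix(0, 1, 0)
    lab <- integer(length(tree$parent))
    lab[tree$root] <- 1L
    lab[tips] <- D
    for (h in seq_len(nrow(igrid))) {
      if (length(internals)) lab[internals] <- igrid[h, ]
      f <- 1
      for (u in nonroot) {
        p <- tree$branch_p[u]; q <- 1 - (N - 1) * p
        f <- f * if (lab[u] == lab[tree$parent[u]]) q else p
      }
      pr <- pr + f
    }
    S <- fitch_sets(D)
    total <- total + pr
    if (length(S) == 1 && S == 1) ua <- ua + pr
    if (1 %in% S) aa <- aa + pr / length(S)
  }
  stopifnot(abs(total - 1) < 1e-9)
  list(UA = ua, AA = aa)
}

# children-before-parents order without touching package internals
order_children_first <- function(tree) {
  out <- integer(0); stack <- tree$root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, tree$children[[u]])
  }
  rev(out)
}

# Compose branch probabilities leaf -> root per leaf (round-trip invariant).
leaf_path_probs <- function(tree, N) {
  tips <- which(lengths(tree$children) == 0)
  out <- vapply(tips, function(u) {
    p <- 0
    while (u != tree$root) { p <- compose_branch(p, tree$branch_p[u], N); u <- tree$parent[u] }
    p
  }, numeric(1))
  names(out) <- tree$label[tips]
  out[order(names(out))]
}
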