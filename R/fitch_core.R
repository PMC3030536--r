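## The Fitch method: deterministic leaf-to-root set stage, randomized
## root-to-leaf state-choice stage, and the parsimony score.

#' Fitch leaf-to-root stage
#'
#' Assigns each node u a state set S_u, post-order: a leaf gets the singleton
#' of its state; an internal node gets the intersection of its children's
#' sets if nonempty, else the union. The number of union events equals the
#' parsimony score of the character on the tree (Fitch's theorem).
#'
#' @param tree a `fitch_tree`
#' @param states named integer vector of leaf states (names = leaf labels,
#'   values in `1..N`), e.g. from [read_leaf_states()]
#' @param N number of states (defaults to the tree's `N`)
#' @return object of class `fitch_annotation`: list with `sets` (list of
#'   sorted integer vectors per node id), `chosen` (NULL until
#'   [fitch_top_down()]), `union_count`, `root`, `n_nodes`
#' @examples
#' tr <- parse_newick("((A:.1,B:.1):.1,(C:.1,D:.1):.1);", "probability", N = 2)
#' fitch_bottom_up(tr, c(A = 1, B = 2, C = 1, D = 1))
#' @export
fitch_bottom_up <- function(tree, states, N = tree$N) {
  stopifnot(inherits(tree, "fitch_tree"))
  tips <- tip_ids(tree)
  labs <- tree$label[tips]
  miss <- setdiff(labs, names(states))
  if (length(miss) > 0L)
    stop("no state for leaf/leaves: ", paste(miss, collapse = ", "), call. = FALSE)
  st <- as.integer(states[labs])
  if (any(st < 1L | st > N))
    stop("leaf states must lie in 1..", N, call. = FALSE)
  sets <- vector("list", length(tree$parent))
  union_count <- 0L
  for (u in postorder(tree)) {
    kids <- tree$children[[u]]
    sets[[u]] <- if (length(kids) == 0L) {
      st[match(u, tips)]
    } else if (length(kids) == 1L) {
      sets[[kids]]
    } else {
      i <- intersect(sets[[kids[1L]]], sets[[kids[2L]]])
      if (length(i) > 0L) sort(i) else {
        union_count <- union_count + 1L
        sort(union(sets[[kids[1L]]], sets[[kids[2L]]]))
      }
    }
  }
  structure(list(sets = sets, chosen = NULL, union_count = union_count,
                 root = tree$root, n_nodes = length(tree$parent)),
            class = "fitch_annotation")
}

#' Fitch root-to-leaf stage
#'
#' Resolves one state per node from the stage-one sets: the root state is
#' drawn uniformly from S_r; walking down, a child keeps its parent's state
#' whenever that state lies in the child's set, and otherwise draws uniformly
#' from its own set. Uses R's global RNG stream — call `set.seed()` first for
#' reproducibility. Every labeling so produced attains the parsimony score.
#'
#' @param annotation a `fitch_annotation` from [fitch_bottom_up()]
#' @param tree the same `fitch_tree` the annotation was computed on
#' @return the annotation with `chosen` filled (integer state per node)
#' @export
fitch_top_down <- function(annotation, tree) {
  stopifnot(inherits(annotation, "fitch_annotation"), inherits(tree, "fitch_tree"))
  if (annotation$n_nodes != length(tree$parent) || annotation$root != tree$root)
    stop("annotation does not match this tree", call. = FALSE)
  sets <- annotation$sets
  chosen <- integer(length(tree$parent))
  pick <- function(s) if (length(s) == 1L) s else s[sample.int(length(s), 1L)]
  for (u in rev(postorder(tree))) {        # preorder: parent before children
    chosen[u] <- if (u == tree$root) pick(sets[[u]])
    else if (chosen[tree$parent[u]] %in% sets[[u]]) chosen[tree$parent[u]]
    else pick(sets[[u]])
  }
  annotation$chosen <- chosen
  annotation
}

#' Parsimony score of a character on a tree
#'
#' The minimum number of substitutions over all internal labelings, equal to
#' the number of union events in the Fitch leaf-to-root stage.
#'
#' @inheritParams fitch_bottom_up
#' @return nonnegative integer
#' @export
parsimony_score <- function(tree, states, N = tree$N) {
  fitch_bottom_up(tree, states, N)$union_count
}

#' @export
print.fitch_annotation <- function(x, ...) {
  cat("Fitch annotation: ", x$n_nodes, " nodes, parsimony score ",
      x$union_count, "\n", sep = "")
  r <- x$sets[[x$root]]
  cat("  root set S_r = {", paste(r, collapse = ","), "}",
      if (!is.null(x$chosen)) paste0(", chosen root state ", x$chosen[x$root]),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fitch_annotation <- function(x, ...) {
  tibble::tibble(
    node = seq_len(x$n_nodes),
    set = vapply(x$sets, function(s) paste(s, collapse = ","), character(1)),
    set_size = lengths(x$sets),
    chosen = if (is.null(x$chosen)) NA_integer_ else x$chosen)
}

#' @export
glance.fitch_annotation <- function(x, ...) {
  tibble::tibble(parsimony_score = x$union_count,
                 root_set_size = length(x$sets[[x$root]]),
                 resolved = !is.null(x$chosen))
}
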