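## Rooted binary trees with per-branch Jukes-Cantor substitution probabilities.
##
## Internal representation ("fitch_tree"): flat parent/children arrays indexed
## by node id, with the substitution probability stored on the branch INTO each
## non-root node. Node ids follow the ape convention where possible (tips
## first), but nothing downstream relies on it; traversals use postorder().

new_fitch_tree <- function(parent, children, branch_p, label, N,
                           branch_len = NULL, root = which(parent == 0L)) {
  stopifnot(length(root) == 1L)
  structure(
    list(parent = as.integer(parent), children = children,
         branch_p = as.numeric(branch_p),
         branch_len = if (is.null(branch_len)) NULL else as.numeric(branch_len),
         label = as.character(label), root = as.integer(root),
         N = as.integer(N)),
    class = "fitch_tree")
}

#' Number of tips of a tree
#' @param tree a `fitch_tree`
#' @return integer count of leaves
#' @export
n_tips <- function(tree) sum(lengths(tree$children) == 0L)

tip_ids <- function(tree) which(lengths(tree$children) == 0L)

## Topological order with every child before its parent (iterative: reverse
## of a stack-based preorder), safe for caterpillars with thousands of nodes.
postorder <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n); stack <- integer(n)
  stack[1L] <- tree$root; sp <- 1L; k <- 0L
  while (sp > 0L) {
    u <- stack[sp]; sp <- sp - 1L
    k <- k + 1L; out[k] <- u
    for (v in tree$children[[u]]) { sp <- sp + 1L; stack[sp] <- v }
  }
  rev(out[seq_len(k)])
}

check_branch_domain <- function(p, N, allow_superstationary = FALSE) {
  hi <- if (allow_superstationary) 1 / (N - 1) else 1 / N
  bad <- !is.na(p) & (p < 0 | p > hi + 1e-12)
  if (any(bad))
    stop("branch substitution probability outside [0, ", signif(hi, 4),
         "] (N = ", N, "): ", paste(signif(p[bad], 6), collapse = ", "),
         if (!allow_superstationary)
           "; values in (1/N, 1/(N-1)] need allow_superstationary = TRUE",
         call. = FALSE)
  invisible(TRUE)
}

#' Substitution probability along a branch of given length
#'
#' Under the symmetric N-state Jukes-Cantor model with substitution rate
#' `rate`, the probability of ending in any one specific different state after
#' a branch of length `l` is `p = (1/N) (1 - exp(-N rate l))`; the
#' conservation probability is `q = 1 - (N-1) p = 1/N + ((N-1)/N) exp(-N rate l)`.
#'
#' @param l branch length(s), nonnegative
#' @param rate substitution rate per unit length, positive
#' @param N number of character states, >= 2
#' @return substitution probability in `[0, 1/N)`, vectorized over `l`
#' @examples
#' branch_prob_from_length(0.25, rate = 1, N = 4)  # (1/4)(1 - exp(-1))
#' @export
branch_prob_from_length <- function(l, rate, N) {
  stopifnot(N >= 2, rate > 0)
  if (any(l < 0)) stop("branch length must be nonnegative", call. = FALSE)
  (1 / N) * (1 - exp(-N * rate * l))
}

#' Serial composition of two Jukes-Cantor branches
#'
#' The substitution probability of two branches traversed in sequence,
#' i.e. the off-diagonal entry of the product of the two N x N transition
#' matrices. Satisfies `1 - N p_out = (1 - N p1)(1 - N p2)`; the operation is
#' associative and commutative with identity 0 and absorbing element 1/N.
#'
#' @param p1,p2 substitution probabilities in `[0, 1/N]`
#' @param N number of states
#' @return composed substitution probability
#' @export
compose_branch <- function(p1, p2, N) {
  check_branch_domain(c(p1, p2), N)
  (1 - (1 - N * p1) * (1 - N * p2)) / N
}

#' Parse a rooted binary Newick tree
#'
#' Reads a single Newick string whose branch values are interpreted either as
#' substitution probabilities directly, or as branch lengths converted through
#' [branch_prob_from_length()]. Non-binary trees are rejected: every internal
#' node must have exactly two children (a single-child root is tolerated only
#' for the degenerate one-tip tree).
#'
#' @param text Newick string (single tree, semicolon-terminated)
#' @param interpretation `"probability"` (store values as branch_p) or
#'   `"length"` (store as branch lengths; requires `rate`)
#' @param N number of character states (>= 2)
#' @param rate substitution rate, required when `interpretation = "length"`
#' @param allow_superstationary allow branch_p in `(1/N, 1/(N-1)]`, outside the
#'   Jukes-Cantor reachable range (guards against length/probability mix-ups)
#' @return a `fitch_tree`
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.1):0.05,C:0.2);", "probability", N = 2)
#' @export
parse_newick <- function(text, interpretation = c("probability", "length"),
                         N, rate = NULL, allow_superstationary = FALSE) {
  interpretation <- match.arg(interpretation)
  stopifnot(is.character(text), length(text) == 1L, N >= 2)
  if (interpretation == "length" && is.null(rate))
    stop("interpretation = \"length\" requires a substitution rate", call. = FALSE)
  phy <- withCallingHandlers(
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ", conditionMessage(e),
                                      call. = FALSE)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: unreadable input", call. = FALSE)
  if (is.null(phy$edge.length))
    stop("every branch must carry a numeric value", call. = FALSE)
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length)))
    stop("every branch must carry a numeric value", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("leaf names must be unique", call. = FALSE)
  from_phylo(phy, interpretation, N, rate, allow_superstationary)
}

from_phylo <- function(phy, interpretation, N, rate, allow_superstationary = FALSE) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  parent <- integer(nnode)
  children <- rep(list(integer(0)), nnode)
  val <- rep(NA_real_, nnode)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    parent[b] <- a
    children[[a]] <- c(children[[a]], b)
    val[b] <- phy$edge.length[e]
  }
  degs <- lengths(children)[(ntip + 1L):nnode]
  if (ntip >= 2L && any(degs != 2L))
    stop("tree must be strictly binary (every internal node with 2 children)",
         call. = FALSE)
  label <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  if (interpretation == "probability") {
    check_branch_domain(val, N, allow_superstationary)
    new_fitch_tree(parent, children, val, label, N)
  } else {
    v <- val; v[is.na(v)] <- 0            # root carries no branch
    p <- branch_prob_from_length(v, rate, N)
    p[is.na(val)] <- NA_real_
    new_fitch_tree(parent, children, p, label, N, branch_len = val)
  }
}

## Nested-list constructor used by shape builders and restriction.
## A node is list(label=, p=, len=, kids=list(...)); kids empty => leaf.
tree_from_nested <- function(root_spec, N) {
  parent <- integer(0); kids_idx <- list(); p <- numeric(0)
  len <- numeric(0); label <- character(0)
  any_len <- FALSE
  ## iterative DFS so caterpillar depth is not limited by the C stack
  n <- 0L
  add_node <- function(spec, par) {
    n <<- n + 1L; id <- n
    parent[id] <<- par
    kids_idx[[id]] <<- integer(0)
    p[id] <<- if (is.null(spec$p)) NA_real_ else spec$p
    len[id] <<- if (is.null(spec$len)) NA_real_ else { any_len <<- TRUE; spec$len }
    label[id] <<- if (is.null(spec$label)) NA_character_ else spec$label
    id
  }
  stack <- list(list(spec = root_spec, par = 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    id <- add_node(top$spec, top$par)
    if (top$par > 0L) kids_idx[[top$par]] <- c(kids_idx[[top$par]], id)
    ks <- top$spec$kids
    if (!is.null(ks)) for (k in rev(seq_along(ks)))
      stack[[length(stack) + 1L]] <- list(spec = ks[[k]], par = id)
  }
  new_fitch_tree(parent, kids_idx, p, label, N,
                 branch_len = if (any_len) len else NULL)
}

leaf_spec <- function(label, p, len = NULL) list(label = label, p = p, len = len)

#' Equal-branch complete binary tree
#'
#' The perfectly balanced rooted binary tree with `2^levels` leaves and the
#' same substitution probability `p` on every branch.
#'
#' @param levels number of levels (>= 1); the tree has `2^levels` leaves
#' @param p substitution probability on each branch
#' @param N number of states
#' @return a `fitch_tree` with tips labelled `t1..t(2^levels)`
#' @export
complete_binary_tree <- function(levels, p, N) {
  stopifnot(levels >= 1, N >= 2)
  check_branch_domain(p, N)
  cnt <- 0L
  rec <- function(depth, pp) {
    if (depth == 0L) { cnt <<- cnt + 1L; return(leaf_spec(paste0("t", cnt), pp)) }
    list(p = pp, kids = list(rec(depth - 1L, p), rec(depth - 1L, p)))
  }
  tree_from_nested(list(kids = list(rec(levels - 1L, p), rec(levels - 1L, p))), N)
}

#' Equal-branch comb-shaped tree (rooted caterpillar)
#'
#' The maximally unbalanced rooted binary tree: each internal node has one
#' leaf child, every branch carries the same substitution probability.
#' `t1` is the leaf nearest the root.
#'
#' @param n_leaves number of leaves (>= 2)
#' @param p substitution probability on every branch
#' @param N number of states
#' @return a `fitch_tree`
#' @export
comb_tree <- function(n_leaves, p, N) {
  stopifnot(n_leaves >= 2, N >= 2)
  check_branch_domain(p, N)
  ## build iteratively from the deepest cherry upwards
  spec <- list(p = p, kids = list(leaf_spec(paste0("t", n_leaves - 1L), p),
                                  leaf_spec(paste0("t", n_leaves), p)))
  if (n_leaves > 2L) for (k in (n_leaves - 2L):1L) {
    spec <- list(p = p, kids = list(leaf_spec(paste0("t", k), p), spec))
  }
  spec$p <- NULL
  tree_from_nested(spec, N)
}

#' Hennigian (ultrametric) comb-shaped tree
#'
#' A caterpillar in which every interior edge has length `l` and pendant edges
#' are stretched so that all leaves lie at the same depth `(n-1) l` from the
#' root: the leaf hanging off the k-th interior node gets pendant length
#' `(n-k) l`, and the deepest interior node carries two leaves of pendant
#' length `l`. Branch substitution probabilities follow
#' [branch_prob_from_length()].
#'
#' @param n_leaves number of leaves (>= 2)
#' @param l interior edge length, positive
#' @param rate substitution rate
#' @param N number of states
#' @return a `fitch_tree` (with branch lengths retained)
#' @export
hennigian_tree <- function(n_leaves, l, rate, N) {
  stopifnot(n_leaves >= 2, l > 0, rate > 0, N >= 2)
  pl <- function(len) branch_prob_from_length(len, rate, N)
  spec <- list(p = pl(l), len = l,
               kids = list(leaf_spec(paste0("t", n_leaves - 1L), pl(l), l),
                           leaf_spec(paste0("t", n_leaves), pl(l), l)))
  if (n_leaves > 2L) for (k in (n_leaves - 2L):1L) {
    pend <- (n_leaves - k) * l
    spec <- list(p = pl(l), len = l,
                 kids = list(leaf_spec(paste0("t", k), pl(pend), pend), spec))
  }
  spec$p <- NULL; spec$len <- NULL
  tree_from_nested(spec, N)
}

#' Convert a fitch_tree to an ape "phylo" object
#'
#' Edge lengths are taken from the stored branch lengths if present, otherwise
#' from the branch substitution probabilities.
#'
#' @param tree a `fitch_tree` with >= 2 tips
#' @param use x value to place on edges: `"auto"` (lengths if stored, else
#'   probabilities), `"probability"`, or `"length"`
#' @return an object of class `phylo`
#' @export
as_phylo <- function(tree, use = c("auto", "probability", "length")) {
  use <- match.arg(use)
  ntip <- n_tips(tree)
  if (ntip < 2L) stop("ape cannot represent a tree with fewer than 2 tips",
                      call. = FALSE)
  vals <- switch(use,
    auto = if (!is.null(tree$branch_len)) tree$branch_len else tree$branch_p,
    probability = tree$branch_p,
    length = {
      if (is.null(tree$branch_len)) stop("tree carries no branch lengths", call. = FALSE)
      tree$branch_len
    })
  tips <- tip_ids(tree)
  internals <- setdiff(seq_along(tree$parent), tips)
  ## ape numbering: tips 1..ntip, then root, then remaining internals
  internals <- c(tree$root, setdiff(internals, tree$root))
  newid <- integer(length(tree$parent))
  newid[tips] <- seq_len(ntip)
  newid[internals] <- ntip + seq_along(internals)
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  edge <- cbind(newid[tree$parent[nonroot]], newid[nonroot])
  ord <- order(edge[, 1L], edge[, 2L])
  phy <- structure(list(edge = edge[ord, , drop = FALSE],
                        edge.length = vals[nonroot][ord],
                        tip.label = tree$label[tips],
                        Nnode = length(internals)),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Serialize a tree to Newick
#'
#' Writes branch values to 12 significant digits so that
#' `parse_newick(write_newick(t))` reproduces `t` up to node numbering.
#'
#' @inheritParams as_phylo
#' @return a single Newick string
#' @export
write_newick <- function(tree, use = c("auto", "probability", "length")) {
  use <- match.arg(use)
  if (n_tips(tree) >= 2L)
    return(ape::write.tree(as_phylo(tree, use), digits = 12))
  ## degenerate single-tip tree (root with one pendant branch, or bare leaf)
  tid <- tip_ids(tree)
  if (tid == tree$root) return(paste0(tree$label[tid], ";"))
  vals <- if (use == "length" ||
              (use == "auto" && !is.null(tree$branch_len))) tree$branch_len
          else tree$branch_p
  paste0("(", tree$label[tid], ":", format(vals[tid], digits = 12), ");")
}

#' Restrict a tree to a subset of leaves
#'
#' Returns the tree induced on the leaf subset `keep`: pruned leaves are
#' removed, internal nodes left with a single child are suppressed and their
#' two incident branches merged with [compose_branch()] (branch lengths, when
#' stored, add). The original root is retained; if only one child subtree
#' survives, the chain below the root collapses into a single composed branch
#' hanging from the root.
#'
#' @param tree a `fitch_tree`
#' @param keep character vector of leaf names to retain (nonempty)
#' @return the induced `fitch_tree`
#' @export
restrict_to_leafset <- function(tree, keep) {
  if (length(keep) == 0L) stop("keep must be a nonempty set of leaf names", call. = FALSE)
  tips <- tip_ids(tree)
  labs <- tree$label[tips]
  unknown <- setdiff(keep, labs)
  if (length(unknown) > 0L)
    stop("unknown leaf name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keepset <- labs %in% keep
  has_len <- !is.null(tree$branch_len)
  ## postorder fold building nested specs bottom-up (iterative, no recursion)
  spec <- vector("list", length(tree$parent))
  for (u in postorder(tree)) {
    if (length(tree$children[[u]]) == 0L) {
      spec[u] <- list(if (tree$label[u] %in% keep)
        leaf_spec(tree$label[u], tree$branch_p[u],
                  if (has_len) tree$branch_len[u] else NULL))
    } else {
      ks <- Filter(Negate(is.null), lapply(tree$children[[u]], function(v) spec[[v]]))
      if (length(ks) == 0L) { spec[u] <- list(NULL) }
      else if (length(ks) == 1L) {
        ## suppress degree-2 node: compose the child's branch with u's branch
        ch <- ks[[1L]]
        if (u != tree$root) {
          ch$p <- compose_branch(ch$p, tree$branch_p[u], tree$N)
          if (has_len) ch$len <- ch$len + tree$branch_len[u]
        }
        spec[[u]] <- ch
      } else {
        spec[[u]] <- list(p = tree$branch_p[u],
                          len = if (has_len) tree$branch_len[u] else NULL,
                          kids = ks)
      }
    }
  }
  rs <- spec[[tree$root]]
  if (is.null(rs$kids)) {
    ## single surviving leaf: one branch root -> leaf
    rs <- list(kids = list(rs))
  } else if (u_root_has_branch <- !is.null(rs$p) && !is.na(rs$p)) {
    ## surviving subtree top kept its composed branch: hang it from the root
    rs <- list(kids = list(rs))
  } else {
    rs$p <- NULL; rs$len <- NULL
  }
  tree_from_nested(rs, tree$N)
}

#' Read a leaf-state assignment table
#'
#' Two-column TSV (leaf name, integer state in `1..N`), no header.
#'
#' @param file path to the TSV file
#' @param N number of states (validation bound)
#' @return named integer vector of states, names = leaf names
#' @export
read_leaf_states <- function(file, N) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         col.names = c("leaf", "state"),
                         colClasses = c("character", "integer"))
  if (any(d$state < 1L | d$state > N))
    stop("leaf states must be integers in 1..", N, call. = FALSE)
  if (anyDuplicated(d$leaf)) stop("duplicated leaf name in state table", call. = FALSE)
  stats::setNames(as.integer(d$state), d$leaf)
}

#' @export
print.fitch_tree <- function(x, ...) {
  nt <- n_tips(x)
  cat("Rooted binary tree (fitch_tree): ", nt, " tips, ",
      length(x$parent) - nt, " internal nodes, N = ", x$N, "\n", sep = "")
  pr <- x$branch_p[-x$root]
  if (length(pr) > 0L && !all(is.na(pr)))
    cat("branch substitution probabilities in [",
        signif(min(pr, na.rm = TRUE), 4), ", ",
        signif(max(pr, na.rm = TRUE), 4), "]\n", sep = "")
  invisible(x)
}
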