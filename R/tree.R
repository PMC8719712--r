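#' Build the 15-node binary decision tree
#'
#' Constructs the static structure of the three-level binary decision tree
#' used throughout the package: 7 internal nodes (ids 1--7, heap order) that
#' deliver motion evidence when queried, and 8 leaf nodes (ids 8--15), one of
#' which hides the target. Node \code{i}'s children are \code{2i} and
#' \code{2i + 1}; levels run 1 (root) to 3 for internal nodes and 4 for
#' leaves.
#'
#' The same structure serves both coordinate systems used in the package:
#' \emph{spatial} ids (left child = \code{2i}, right child = \code{2i + 1})
#' in which trials are simulated, and \emph{canonical} (target-relative) ids
#' in which the child in the true direction of motion always gets the odd
#' (higher) id, so the target is always node 15 and the path to it is
#' (1, 3, 7).
#'
#' @return An object of class \code{"query_tree"}: a list with elements
#'   \item{internal}{integer vector 1:7}
#'   \item{leaves}{integer vector 8:15}
#'   \item{level}{integer vector of length 15, level of each node}
#'   \item{children}{7 x 2 integer matrix, children of each internal node}
#'   \item{parent}{integer vector of length 15 (0 for the root)}
#'   \item{ancestors}{8 x 3 integer matrix; row \code{T - 7} holds the
#'     level-1..3 ancestors of leaf \code{T} (the error path)}
#' @seealso [tree_ancestors()], [tree_counterfactual()], [canonical_map()]
#' @export
#' @examples
#' tr <- build_tree()
#' tree_ancestors(tr, 15)        # 1 3 7
#' tree_counterfactual(tr, 11)   # 3 4 10
build_tree <- function() {
  level <- c(1L, 2L, 2L, 3L, 3L, 3L, 3L, rep(4L, 8))
  children <- cbind(2L * (1:7), 2L * (1:7) + 1L)
  parent <- c(0L, as.integer((2:15) %/% 2))
  anc <- t(vapply(8:15, function(T) c(1L, as.integer(T %/% 4), as.integer(T %/% 2)),
                  integer(3)))
  structure(list(internal = 1:7, leaves = 8:15, level = level,
                 children = children, parent = parent, ancestors = anc),
            class = "query_tree")
}

#' Error path of a leaf
#'
#' The three internal nodes connecting the root to leaf \code{leaf}
#' (levels 1, 2, 3), i.e. the error path for an error at that leaf.
#'
#' @param tree a [build_tree()] object
#' @param leaf leaf id in 8..15
#' @return integer vector of length 3
#' @export
tree_ancestors <- function(tree, leaf) {
  stopifnot(leaf %in% tree$leaves)
  tree$ancestors[leaf - 7L, ]
}

#' Counterfactual children of an error path
#'
#' For an error at \code{leaf}, each node on the error path has one child
#' that is itself off the path: the "counterfactual" branch that would have
#' been taken had the choice at that node been different. Querying one of
#' these after an error is an \emph{off-path} query.
#'
#' @inheritParams tree_ancestors
#' @return integer vector of length 3, ordered by the level (1..3) of the
#'   blamed ancestor; the last element is the sibling leaf of \code{leaf}.
#' @export
tree_counterfactual <- function(tree, leaf) {
  anc <- tree_ancestors(tree, leaf)
  on_path_child <- c(anc[2], anc[3], leaf)
  as.integer(bitwXor(on_path_child, 1L))
}

#' Canonical (target-relative) relabeling of the tree
#'
#' Maps spatial node ids to canonical ids under which the child in the true
#' direction of motion at every internal node receives the higher (odd) id.
#' Under this bijection the target leaf is always node 15 and the error path
#' to it is (1, 3, 7); analyses are carried out in these coordinates because
#' they align trials with different ground truths.
#'
#' @param directions integer/numeric vector of length 7; true direction at
#'   spatial internal nodes 1..7, coded -1 (left, child \code{2i}) or
#'   +1 (right, child \code{2i + 1}).
#' @return list with \code{to_canonical} (length-15 integer vector: canonical
#'   id of each spatial node) and \code{to_spatial} (its inverse permutation).
#' @export
#' @examples
#' m <- canonical_map(rep(1, 7))   # all rightward: identity
#' stopifnot(identical(m$to_canonical, 1:15))
canonical_map <- function(directions) {
  stopifnot(length(directions) == 7, all(directions %in% c(-1, 1)))
  canon <- integer(15)
  canon[1] <- 1L
  for (i in 1:7) {
    hi <- if (directions[i] > 0) 2L * i + 1L else 2L * i  # child in true direction
    lo <- bitwXor(hi, 1L)
    canon[hi] <- 2L * canon[i] + 1L
    canon[lo] <- 2L * canon[i]
  }
  list(to_canonical = canon, to_spatial = order(canon))
}

#' Number of latent problem states
#'
#' Each internal node can be in one of \code{n_coherence * 2} states
#' (coherence times direction), independently across the 7 internal nodes.
#'
#' @param n_coherence number of coherence levels (default 5)
#' @return the number of joint latent states (\code{10^7} for the default
#'   task)
#' @export
n_latent_states <- function(n_coherence = 5) {
  (n_coherence * 2)^7
}
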