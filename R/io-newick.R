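#' Read a rooted tree from a Newick file
#'
#' Single rooted tree, leaf-labeled; branch lengths are accepted and
#' ignored. Unnamed internal nodes are auto-named `node<k>` where `k` is
#' the node's position (among internal nodes) in a post-order traversal,
#' so names are deterministic for a given topology.
#'
#' @param path Newick file (one tree).
#' @return object of class `rooted_tree`; see [as_rooted_tree()].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path), collapse = "")
  parse_newick(txt)
}

#' Parse a rooted tree from a Newick string
#' @param text Newick string ending in `;`.
#' @rdname read_newick
#' @export
parse_newick <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, " ')')")
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick string")
  if (inherits(phy, "multiPhylo")) stop("expected a single tree, got several")
  as_rooted_tree(phy)
}

#' Convert an ape phylo object to the internal rooted-tree structure
#'
#' The internal structure is a plain list: `n_tips`, `n_nodes`, `parent`
#' (integer, `NA` at the root), `children` (list of integer vectors),
#' `labels` (all nodes; tips keep their labels, unnamed internal nodes get
#' post-order names), `root`, `postorder` (node ids, children before
#' parents), `is_tip`. Node ids follow ape numbering (tips `1..n`).
#' The conceptual stem edge above the root is named `"stem"` wherever edges
#' are reported.
#'
#' @param phy an `ape::phylo` object (rooted).
#' @return object of class `rooted_tree`.
#' @export
as_rooted_tree <- function(phy) {
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  n_tips <- length(phy$tip.label)
  n_nodes <- n_tips + phy$Nnode
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; c_ <- phy$edge[k, 2]
    parent[c_] <- p
    children[[p]] <- c(children[[p]], c_)
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  # iterative post-order traversal (children in edge order)
  post <- integer(0)
  stack <- list(list(node = root, visited = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$visited || length(children[[top$node]]) == 0L) {
      post <- c(post, top$node)
    } else {
      stack[[length(stack) + 1L]] <- list(node = top$node, visited = TRUE)
      for (ch in rev(children[[top$node]])) {
        stack[[length(stack) + 1L]] <- list(node = ch, visited = FALSE)
      }
    }
  }
  labels <- character(n_nodes)
  labels[seq_len(n_tips)] <- phy$tip.label
  existing <- phy$node.label
  internal_post <- post[post > n_tips]
  for (k in seq_along(internal_post)) {
    v <- internal_post[k]
    lab <- if (!is.null(existing)) existing[v - n_tips] else ""
    if (is.null(lab) || is.na(lab) || !nzchar(lab)) lab <- paste0("node", k)
    labels[v] <- lab
  }
  if (anyDuplicated(labels)) {
    stop("duplicate node labels after auto-naming: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(
    n_tips = n_tips, n_nodes = n_nodes, parent = parent,
    children = children, labels = labels, root = root,
    postorder = post, is_tip = seq_len(n_nodes) <= n_tips
  ), class = "rooted_tree")
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("<rooted_tree> ", x$n_tips, " tips, ", x$n_nodes - x$n_tips,
      " internal nodes\n", sep = "")
  cat("  tips: ", paste(utils::head(x$labels[x$is_tip], 8), collapse = ", "),
      if (x$n_tips > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# edge above node v, named by its child node's label
edge_name <- function(tree, v) {
  if (is.na(tree$parent[v])) "stem" else tree$labels[v]
}
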