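# Naive suffix-tree construction by repeated suffix insertion with edge
# compression. O(n^2) worst case, intended for texts up to ~1e5 bases; no
# online (Ukkonen) construction is attempted.

#' Suffix tree of a terminated DNA text
#'
#' Builds the compressed suffix tree of the terminated text by inserting each
#' suffix in turn and splitting edges on partial matches. Every internal node
#' has at least two children, no two sibling edges share a first character,
#' and the concatenated edge labels on the path to leaf `i` spell the suffix
#' starting at 0-based position `i`. The terminator `$` guarantees one leaf
#' per suffix (`n + 1` leaves in total).
#'
#' Nodes are stored as a flat list; node 1 is the root. Each node is a list
#' with `children` (named by first edge character, each entry
#' `list(from, to, id)` giving the 1-based label span in the terminated text
#' and the child node id) and `leaf` (0-based suffix start, or `NA` for
#' internal nodes).
#'
#' @param text An [indexed_text()] or a string coercible to one.
#' @return An object of class `suffix_tree` with elements `nodes` and `text`.
#' @examples
#' st <- build_suffix_tree("ACGTACAAAT")
#' length(st$nodes[[1]]$children) # 5 branches from the root: $, A, C, G, T
#' @seealso [suffix_tree_leaf_order()]
#' @export
build_suffix_tree <- function(text) {
  tx <- indexed_text(text)
  term <- .chars(tx$terminated)
  N <- length(term)
  nodes <- vector("list", 2L * N + 8L)
  n_nodes <- 1L
  nodes[[1L]] <- list(children = list(), leaf = NA_integer_)

  for (p in 0:(N - 1L)) {
    cur <- 1L
    i <- p # 0-based offset of the next unmatched suffix character
    repeat {
      c0 <- term[i + 1L]
      edge <- nodes[[cur]]$children[[c0]]
      if (is.null(edge)) {
        n_nodes <- n_nodes + 1L
        nodes[[n_nodes]] <- list(children = list(), leaf = p)
        nodes[[cur]]$children[[c0]] <- list(from = i + 1L, to = N, id = n_nodes)
        break
      }
      lab_len <- edge$to - edge$from + 1L
      j <- 0L
      while (j < lab_len && i + 1L + j <= N &&
             term[edge$from + j] == term[i + 1L + j]) {
        j <- j + 1L
      }
      if (j == lab_len) {
        cur <- edge$id
        i <- i + j
        next
      }
      # partial match: split the edge at offset j
      n_nodes <- n_nodes + 1L
      mid <- n_nodes
      nodes[[mid]] <- list(children = list(), leaf = NA_integer_)
      nodes[[mid]]$children[[term[edge$from + j]]] <-
        list(from = edge$from + j, to = edge$to, id = edge$id)
      n_nodes <- n_nodes + 1L
      nodes[[n_nodes]] <- list(children = list(), leaf = p)
      nodes[[mid]]$children[[term[i + 1L + j]]] <-
        list(from = i + 1L + j, to = N, id = n_nodes)
      nodes[[cur]]$children[[c0]] <-
        list(from = edge$from, to = edge$from + j - 1L, id = mid)
      break
    }
    if (n_nodes > length(nodes) - 4L) {
      nodes <- c(nodes, vector("list", length(nodes)))
    }
  }
  structure(list(nodes = nodes[seq_len(n_nodes)], text = tx),
            class = "suffix_tree")
}

#' @export
print.suffix_tree <- function(x, ...) {
  n_leaves <- sum(vapply(x$nodes, function(nd) !is.na(nd$leaf), logical(1)))
  cat("<suffix_tree> ", n_leaves, " leaves, ",
      length(x$nodes) - n_leaves, " internal node(s), root degree ",
      length(x$nodes[[1L]]$children), "\n", sep = "")
  invisible(x)
}

#' Depth-first leaf order of a suffix tree
#'
#' Visits children in `$ < A < C < G < T` order and collects the leaf labels
#' (0-based suffix starts). By construction this order equals the suffix
#' array of the same text, which the test-suite uses as a cross-structure
#' consistency check.
#'
#' @param tree A `suffix_tree` from [build_suffix_tree()].
#' @return Integer vector of 0-based suffix start positions, one per leaf.
#' @export
suffix_tree_leaf_order <- function(tree) {
  stopifnot(inherits(tree, "suffix_tree"))
  nodes <- tree$nodes
  out <- integer(0)
  visit <- function(id) {
    nd <- nodes[[id]]
    if (!is.na(nd$leaf)) {
      out[[length(out) + 1L]] <<- nd$leaf
      return(invisible(NULL))
    }
    for (c in ALPHABET) {
      e <- nd$children[[c]]
      if (!is.null(e)) {
        visit(e$id)
      }
    }
    invisible(NULL)
  }
  visit(1L)
  out
}
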