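# Sample distances from abundance profiles and neighbor-joining tree
# inference.

#' Pairwise sample distances from an abundance matrix
#'
#' Distances between sample columns over the shared repeat rows. Euclidean
#' (default) and Manhattan are the usual metrics; correlation distance
#' (`1 - Pearson r`) is offered because abundance profiles are
#' compositional-like.
#'
#' @param x An `abundance_matrix` in state `"log"` or
#'   `"quantile_normalized"`.
#' @param metric `"euclidean"`, `"manhattan"` or `"correlation"`.
#' @return A symmetric distance matrix with sample ids as dimnames.
#' @export
abundance_distance <- function(x, metric = c("euclidean", "manhattan", "correlation")) {
  metric <- match.arg(metric)
  assert_state(x, c("log", "quantile_normalized"), "abundance_distance()")
  v <- am_values(x)
  if (ncol(v) < 2L) abort("need at least 2 samples for distances")
  d <- switch(metric,
    euclidean = as.matrix(dist(t(v), method = "euclidean")),
    manhattan = as.matrix(dist(t(v), method = "manhattan")),
    correlation = 1 - cor(v)
  )
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' The Saitou--Nei agglomeration with the Studier--Keppler Q-criterion:
#' repeatedly join the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` (with `r` the row sums), assign
#' branch lengths `l(i) = d(i,j)/2 + (r(i) - r(j)) / (2(n-2))`, and reduce
#' the matrix with `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties are
#' broken by label order, so the tree is deterministic. Negative branch
#' lengths are clamped to zero with a warning reporting the clamped total.
#' For an additive distance matrix the output tree's path-length matrix
#' reproduces the input exactly.
#'
#' @param d Symmetric distance matrix with labels as dimnames (n >= 2), as
#'   from [abundance_distance()].
#' @return An unrooted `phylo` tree (ape format), basal trifurcation for
#'   n >= 3.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) abort("neighbor joining needs at least 2 taxa")
  stopifnot(!is.null(labels), isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
  # order taxa by label so that which.min tie-breaks lexicographically
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]
  clamped <- 0
  clamp <- function(x) {
    neg <- x < 0
    clamped <<- clamped + sum(-x[neg])
    x[neg] <- 0
    x
  }
  # active clusters are tracked by node id: tips 1..n, internals n+1, ...
  node_of <- seq_len(n)
  next_node <- n + 1L
  edges <- list() # (parent, child, length)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    idx <- which.min(q)
    i <- (idx - 1L) %% m + 1L
    j <- (idx - 1L) %/% m + 1L
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] / 2 + (r[j] - r[i]) / (2 * (m - 2)))
    u <- next_node
    next_node <- next_node + 1L
    edges[[length(edges) + 1L]] <- c(u, node_of[i], li)
    edges[[length(edges) + 1L]] <- c(u, node_of[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node_of <- c(node_of[keep], u)
    rn <- c(rownames(d)[seq_along(keep)], paste0("__u", u))
    rownames(d) <- colnames(d) <- rn
  }
  root <- next_node
  if (nrow(d) == 2L) {
    l <- clamp(d[1, 2] / 2)
    edges[[length(edges) + 1L]] <- c(root, node_of[1], l)
    edges[[length(edges) + 1L]] <- c(root, node_of[2], l)
  } else {
    l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    edges[[length(edges) + 1L]] <- c(root, node_of[1], l1)
    edges[[length(edges) + 1L]] <- c(root, node_of[2], l2)
    edges[[length(edges) + 1L]] <- c(root, node_of[3], l3)
  }
  if (clamped > 1e-12) {
    warn(sprintf("clamped %.6g of negative branch length to zero", clamped))
  }
  em <- do.call(rbind, edges)
  # renumber internals in preorder from the basal (root) node: ape expects
  # tips 1..n and internals n+1..2n-2 with the root first
  kids <- split(seq_len(nrow(em)), em[, 1L])
  new_id <- integer(next_node)
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  edge_out <- matrix(0L, nrow(em), 2L)
  edge_len <- numeric(nrow(em))
  pos <- 0L
  visit <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      child <- em[e, 2L]
      pos <<- pos + 1L
      row <- pos
      edge_len[row] <<- em[e, 3L]
      if (child <= n) {
        edge_out[row, ] <<- c(new_id[node], as.integer(child))
      } else {
        par <- new_id[node]
        visit_child <- child
        edge_out[row, 1L] <<- par
        # child id assigned during its visit
        visit(visit_child)
        edge_out[row, 2L] <<- new_id[visit_child]
      }
    }
  }
  visit(root)
  tr <- structure(
    list(
      edge = edge_out, edge.length = edge_len,
      tip.label = labels, Nnode = counter - n
    ),
    class = "phylo"
  )
  attr(tr, "clamped") <- clamped
  tr
}

nj_quote <- function(labels) {
  bad <- grepl("[][ \t(),:;']", labels)
  ifelse(bad, paste0("'", gsub("'", "''", labels), "'"), labels)
}

#' Serialize a tree as Newick
#'
#' Writes a `phylo` tree (with branch lengths) as a Newick string; labels
#' containing spaces or Newick metacharacters are single-quoted. Round
#' trips through [ape::read.tree()].
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when given the string is also written
#'   there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 12L) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  labels <- nj_quote(tree$tip.label)
  rec <- function(node) {
    if (node <= n_tip) return(labels[node])
    rows <- children[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2L]
      len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NA_real_
      paste0(rec(child), if (!is.na(len)) paste0(":", fmt(len)) else "")
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- if (n_tip == 1L) {
    paste0(labels[1L], ";")
  } else {
    paste0(rec(root), ";")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Tree path-length (cophenetic) matrix
#'
#' Sum of branch lengths along the path between every pair of leaves; for
#' an additive input distance matrix NJ reproduces it exactly.
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix over tip labels.
#' @export
tree_path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}
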