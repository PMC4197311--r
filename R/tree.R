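#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic behavior: at each step the
#' pair minimizing the Q-criterion is joined (ties broken by the smaller
#' index pair in the current node order), branch lengths follow the standard
#' NJ formulas, and a negative branch length is clamped to 0 with the
#' deficit transferred to its sister branch (so the pair still spans the
#' joining distance). The result is an unrooted tree whose root node has
#' degree 3.
#'
#' @param d symmetric numeric matrix with zero diagonal and taxa labels as
#'   dimnames (or a `dist` object), at least 3 taxa
#' @return an [ape::phylo] tree with branch lengths
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("`d` must be a square matrix")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))

  # build with placeholder tip names, then restore the user labels, so
  # metacharacters never reach the Newick parser
  nodes <- paste0("t", seq_len(nrow(d)))
  D <- d
  while (length(nodes) > 3) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j) with i < j in current order
    best <- c(NA, NA); best_q <- Inf
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      if (Q[i, j] < best_q) { best_q <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { li <- 0; lj <- D[i, j] }
    else if (lj < 0) { lj <- 0; li <- D[i, j] }
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], format_bl(li),
                      nodes[j], format_bl(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], merged)
    D <- D2
  }
  l1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nodes[1], format_bl(l1), nodes[2], format_bl(l2),
                    nodes[3], format_bl(l3))
  tree <- ape::read.tree(text = newick)
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

format_bl <- function(x) formatC(x, format = "g", digits = 15)

# quote labels containing Newick metacharacters or whitespace ('' escapes
# an embedded quote, per the Newick standard)
newick_label <- function(lab) {
  if (grepl("[][(){}:;,'\" \t]", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Write a tree in Newick format
#'
#' Labels containing Newick metacharacters or whitespace are single-quoted
#' per the Newick rules (ape's serializer would instead substitute them).
#'
#' @param tree an [ape::phylo] object
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  labels <- tree$tip.label
  safe <- paste0("qtip", seq_along(labels), "qe")
  tree$tip.label <- safe
  s <- ape::write.tree(tree)
  for (i in seq_along(labels))
    s <- sub(safe[i], newick_label(labels[i]), s, fixed = TRUE)
  writeLines(s, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Handles single-quoted labels (which [ape::read.tree()] keeps verbatim,
#' quotes included) by unquoting them after parsing.
#'
#' @param path path to a Newick file
#' @return an [ape::phylo] object
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  unquote <- function(lab) {
    quoted <- grepl("^'.*'$", lab)
    lab[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[quoted]))
    lab
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}

#' Do the members of each group form a connected subtree?
#'
#' Checks, for every group in the assignment, whether its tips are
#' monophyletic in the unrooted tree (i.e. some edge separates exactly that
#' tip set from the rest). Used to verify that individuals cluster by their
#' population of origin.
#'
#' @param tree an [ape::phylo] object
#' @param assignment named character vector (tip label -> group)
#' @return named logical vector, one entry per group
#' @export
groups_monophyletic <- function(tree, assignment) {
  groups <- unique(assignment)
  res <- stats::setNames(logical(length(groups)), groups)
  for (grp in groups) {
    tips <- names(assignment)[assignment == grp]
    others <- setdiff(tree$tip.label, tips)
    if (length(others) == 0) { res[grp] <- TRUE; next }
    # root at an outside tip, then test the clade
    rooted <- ape::root(tree, outgroup = others[1], resolve.root = TRUE)
    res[grp] <- ape::is.monophyletic(rooted, tips)
  }
  res
}
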