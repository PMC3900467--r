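#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair of clusters
#' minimizing the Q-criterion
#' `Q(i,j) = (n - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`
#' is joined, branch lengths to the new node follow the standard
#' rate-corrected formulas, the matrix is reduced, and the final three
#' clusters are resolved with the three-point closed form.  The result is an
#' unrooted tree (the last join creates one internal node of degree three).
#'
#' Determinism: exact ties in Q are broken by the lowest (row, column) index
#' pair in the current label order, so identical input yields an identical
#' Newick string.  Negative branch lengths, which NJ can produce on
#' non-additive input, are retained by default; `clamp_negative = TRUE`
#' sets them to zero and transfers the deficit to the sibling branch.
#'
#' @param D a [dist_matrix()] (or plain labeled symmetric matrix) with at
#'   least 3 labels and finite entries.
#' @param clamp_negative replace negative branch lengths by zero, adding the
#'   deficit to the adjacent sibling branch.  Default `FALSE`.
#' @return an unrooted `phylo` tree (class from the \pkg{ape} package) whose
#'   tip labels are exactly the matrix labels.
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  m <- unclass(D)
  if (!is.matrix(m) || nrow(m) < 3L) stop("need at least 3 labels")
  if (any(!is.finite(m))) stop("non-finite distance entries")
  labels <- rownames(m)
  # each active cluster is a Newick fragment (leaf label or subtree string)
  frags <- vapply(labels, quote_newick_label, "")
  while (nrow(m) > 3L) {
    n <- nrow(m)
    r <- rowSums(m)
    q <- (n - 2) * m - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    hits <- which(q == qmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    bi <- m[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- m[i, j] - bi
    if (clamp_negative) {
      if (bi < 0) { bj <- bj + bi; bi <- 0 }
      if (bj < 0) { bi <- bi + bj; bj <- 0 }
    }
    frag <- sprintf("(%s:%s,%s:%s)", frags[i], format_branch(bi),
                    frags[j], format_branch(bj))
    dnew <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frags <- c(frags[keep], frag)
    rownames(m2) <- colnames(m2) <- seq_len(n - 1L)  # positional labels
    m <- m2
  }
  # final three-cluster join: three-point closed form
  b1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  b2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  b3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  if (clamp_negative) { b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0) }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frags[1], format_branch(b1),
                    frags[2], format_branch(b2),
                    frags[3], format_branch(b3))
  ape::read.tree(text = newick)
}

# 15 significant digits: round-trips the lengths well beyond the 12-digit
# interchange guarantee without decimal noise
format_branch <- function(x) sprintf("%.15g", x)

quote_newick_label <- function(lab) {
  if (grepl("[ \t(),:;'\\[\\]]", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Serialize a tree to Newick text
#'
#' Unquoted labels (quoted only when they contain Newick metacharacters),
#' decimal branch lengths, trailing semicolon.  `read_newick` /
#' `write_newick` round-trips preserve topology and branch lengths to at
#' least 12 significant digits.
#'
#' @param tree a `phylo` tree.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse Newick text into a tree
#'
#' @param text a Newick string, or `NULL` if `path` is given.
#' @param path optional file to read instead of `text`.
#' @return a `phylo` tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  if (!nzchar(gsub("\\s", "", text))) stop("empty Newick input")
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    stop("malformed Newick: unbalanced parentheses (", open, " '(' vs ",
         close, " ')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   warning = function(w) stop("malformed Newick: ",
                                              conditionMessage(w)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  tree
}

#' Patristic (leaf-to-leaf path length) distance matrix of a tree
#'
#' Each entry is the sum of branch lengths along the unique path between two
#' leaves.  With `normalize = TRUE` the matrix is divided by its maximum
#' entry, putting distances on the 0–1 scale conventionally used for
#' sequence-based target trees.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param normalize divide by the maximum entry.  Default `FALSE`.
#' @return a [dist_matrix()] over the tree's tip labels.
#' @export
patristic_matrix <- function(tree, normalize = FALSE) {
  m <- cophenetic(tree)
  m <- m[tree$tip.label, tree$tip.label]
  if (normalize && max(m) > 0) m <- m / max(m)
  dist_matrix(m, metric = if (normalize) "patristic_normalized" else "patristic")
}
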