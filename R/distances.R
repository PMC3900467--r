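#' Construct a labeled distance matrix
#'
#' @param values square numeric matrix with matching row/column names,
#'   symmetric with a zero diagonal and finite entries.
#' @param metric name of the metric that produced it.
#' @return a `dist_matrix` object (the matrix plus a `metric` attribute).
#' @export
dist_matrix <- function(values, metric = "unknown") {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("'values' must be a square matrix")
  if (is.null(rownames(values))) stop("'values' must be labeled")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column labels differ")
  if (any(!is.finite(values))) stop("non-finite distance entries")
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal is not zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("distance matrix: %d targets, metric '%s', range [%g, %g]\n",
              nrow(x), attr(x, "metric"), min(x), max(x)))
  invisible(x)
}

#' Normalized Manhattan distance between enrichment profiles
#'
#' Sum of absolute coordinate differences divided by the number of
#' vocabulary dimensions, so panels with different vocabulary sizes are
#' comparable.
#'
#' @param p,q enrichment vectors on the same feature vocabulary.
#' @return a single non-negative number.
#' @export
manhattan_enrichment_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles live on different vocabularies (lengths differ)")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("profiles live on different vocabularies (feature ids differ)")
  sum(abs(p - q)) / length(p)
}

#' Tanimoto distance between binary bioactivity fingerprints
#'
#' With `c` shared set bits and `n_a`, `n_b` set bits in each fingerprint,
#' the Tanimoto coefficient is `T = c / (n_a + n_b - c)` and the distance is
#' `D = 1 - T`.  Two all-zero fingerprints are defined as identical
#' (distance 0) with a warning; in-pipeline this never occurs because
#' zero-active targets are excluded upstream.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return a number in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b)) stop("bitstrings have different lengths")
  a <- as.logical(a); b <- as.logical(b)
  cc <- sum(a & b); na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both bitstrings empty; Tanimoto distance defined as 0")
    return(0)
  }
  1 - cc / (na + nb - cc)
}

#' Hamming distance between binary bioactivity fingerprints
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @param normalize divide by the fingerprint length (default `FALSE`:
#'   raw disagreement count).
#' @return non-negative number (an integer count unless normalized).
#' @export
hamming_distance <- function(a, b, normalize = FALSE) {
  if (length(a) != length(b)) stop("bitstrings have different lengths")
  d <- sum(as.logical(a) != as.logical(b))
  if (normalize) d / length(a) else d
}

#' Build a pairwise distance matrix
#'
#' Applies a metric once per unordered pair of rows.  Convenience wrappers
#' [enrichment_distance_matrix()] and [bioactivity_distance_matrix()] use
#' vectorized equivalents for the package's standard metrics.
#'
#' @param items matrix with `>= 2` labeled rows (one item per row).
#' @param metric function of two row vectors returning a number.
#' @param name metric name recorded in the result.
#' @return a [dist_matrix()].
#' @export
build_distance_matrix <- function(items, metric, name = "custom") {
  if (nrow(items) < 2L) stop("need at least 2 items")
  n <- nrow(items)
  labels <- rownames(items)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- tryCatch(metric(items[i, ], items[j, ]),
                  error = function(e) stop("metric failed on pair (",
                                           labels[i], ", ", labels[j], "): ",
                                           conditionMessage(e)))
    d[i, j] <- d[j, i] <- v
  }
  dist_matrix(d, metric = name)
}

#' Distance matrix between enrichment profiles
#'
#' Normalized Manhattan distance ([manhattan_enrichment_distance()]) between
#' every pair of target profiles.
#'
#' @param profiles an [enrichment_profiles()] matrix.
#' @return a [dist_matrix()] with metric `"manhattan_enrichment"`.
#' @export
enrichment_distance_matrix <- function(profiles) {
  d <- as.matrix(dist(unclass(profiles), method = "manhattan")) / ncol(profiles)
  dist_matrix(d, metric = "manhattan_enrichment")
}

#' Distance matrix between binary bioactivity fingerprints
#'
#' Each target's fingerprint is its row of activity calls (one bit per
#' compound instance).
#'
#' @param calls an `activity_calls` matrix from [binarize()].
#' @param metric `"tanimoto"` (default) or `"hamming"`.
#' @param normalize for `"hamming"` only: divide counts by the number of
#'   instances.
#' @return a [dist_matrix()].
#' @export
bioactivity_distance_matrix <- function(calls, metric = c("tanimoto", "hamming"),
                                        normalize = FALSE) {
  metric <- match.arg(metric)
  m <- unclass(calls) * 1
  if (metric == "tanimoto") {
    cc <- tcrossprod(m)
    n <- rowSums(m)
    denom <- outer(n, n, "+") - cc
    if (any(denom == 0 & upper.tri(denom)))
      warning("target pair(s) with two empty fingerprints; distance set to 0")
    d <- ifelse(denom == 0, 0, 1 - cc / denom)
    diag(d) <- 0
    return(dist_matrix(d, metric = "tanimoto"))
  }
  both <- tcrossprod(m)
  neither <- tcrossprod(1 - m)
  d <- ncol(m) - both - neither
  if (normalize) d <- d / ncol(m)
  dist_matrix(d, metric = if (normalize) "hamming_normalized" else "hamming")
}

#' Write / read a labeled distance matrix as TSV
#'
#' Full-precision square layout: header row of labels, first column of
#' labels.
#'
#' @param d a [dist_matrix()].
#' @param path file path.
#' @return `write_distance_matrix`: `path` invisibly;
#'   `read_distance_matrix`: a [dist_matrix()].
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(target = rownames(d), format_full(unclass(d)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("target", colnames(d))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param metric metric name to record on read.
#' @export
read_distance_matrix <- function(path, metric = "unknown") {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  dist_matrix(m, metric = metric)
}

#' Write / read PHYLIP square distance format
#'
#' The classic interchange format of distance-based tree programs: a first
#' line with the number of taxa, then one line per taxon with its (possibly
#' truncated to 10 characters, here kept full-length) name and the full row
#' of distances.
#'
#' @param d a [dist_matrix()].
#' @param path file path.
#' @return `write_phylip_distance`: `path` invisibly;
#'   `read_phylip_distance`: a [dist_matrix()].
#' @export
write_phylip_distance <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i], sprintf("%.10f", unclass(d)[i, ])),
                     collapse = "  "), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_distance
#' @param metric metric name to record on read.
#' @export
read_phylip_distance <- function(path, metric = "unknown") {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  rows <- strsplit(trimws(lines[1L + seq_len(n)]), "[ \t]+")
  labels <- vapply(rows, `[`, "", 1L)
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(m) <- list(labels, labels)
  dist_matrix(m, metric = metric)
}
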