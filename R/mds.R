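#' Stress-minimizing multidimensional scaling by majorization (SMACOF)
#'
#' Embeds the targets of a distance matrix into `dims` dimensions by
#' iterative majorization of the raw stress
#' `sigma(X) = sum_{i<j} (d_ij(X) - delta_ij)^2`
#' (Guttman transform), starting from seeded Gaussian coordinates.  The
#' majorization guarantee makes the stress trace non-increasing.  The
#' reported trace and final value use the normalized stress
#' `sqrt(sum (d_hat - d)^2 / sum d^2)` over unordered pairs, a monotone
#' transform of raw stress for fixed input.  Iteration stops when the
#' per-step change in normalized stress drops below `min_stress_change` or
#' after `max_steps` steps.
#'
#' In this package the conventional input is the Hamming distance matrix on
#' binary bioactivity fingerprints ([bioactivity_distance_matrix()] with
#' `metric = "hamming"`); any distance matrix is accepted.
#'
#' @param D a [dist_matrix()] with at least 3 labels (an all-zero matrix is
#'   handled as the degenerate case: all points at the origin, stress 0).
#' @param dims embedding dimension, default 2.
#' @param min_stress_change convergence tolerance on the normalized stress,
#'   default 0.00005.
#' @param max_steps iteration cap, default 5000.
#' @param seed integer seed for the Gaussian initialization (required unless
#'   `init` is given).
#' @param init optional explicit starting coordinate matrix (rows = targets)
#'   overriding the random start.
#' @return an `mds_embedding` list: `coordinates` (labeled matrix),
#'   `stress_trace`, `final_stress`, `converged`, `n_steps`, `seed`.
#' @export
mds_embed <- function(D, dims = 2, min_stress_change = 0.00005,
                      max_steps = 5000, seed = NULL, init = NULL) {
  m <- unclass(D)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 labels")
  labels <- rownames(m)
  denom <- sum(m[upper.tri(m)]^2)
  if (denom == 0) {
    x <- matrix(0, n, dims, dimnames = list(labels, NULL))
    return(structure(list(coordinates = x, stress_trace = 0,
                          final_stress = 0, converged = TRUE, n_steps = 0L,
                          seed = seed), class = "mds_embedding"))
  }
  if (is.null(init)) {
    if (is.null(seed)) stop("a seed is required for the random initialization")
    rng <- local({ set.seed(seed); matrix(rnorm(n * dims), n, dims) })
    x <- rng
  } else {
    if (!is.matrix(init) || nrow(init) != n || ncol(init) != dims)
      stop("'init' must be a ", n, " x ", dims, " matrix")
    x <- unname(init)
  }
  normalized_stress <- function(x) {
    dhat <- as.matrix(dist(x))
    sqrt(sum((dhat[upper.tri(dhat)] - m[upper.tri(m)])^2) / denom)
  }
  trace <- normalized_stress(x)
  converged <- FALSE
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    dhat <- as.matrix(dist(x))
    ratio <- ifelse(dhat > 0, m / dhat, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n                       # Guttman transform
    s <- normalized_stress(x)
    trace <- c(trace, s)
    if (abs(trace[length(trace) - 1L] - s) < min_stress_change) {
      converged <- TRUE
      break
    }
  }
  rownames(x) <- labels
  structure(list(coordinates = x, stress_trace = trace,
                 final_stress = trace[length(trace)], converged = converged,
                 n_steps = step, seed = seed), class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf(
    "MDS embedding: %d targets in %d dims; normalized stress %.4f after %d steps (%s)\n",
    nrow(x$coordinates), ncol(x$coordinates), x$final_stress, x$n_steps,
    if (x$converged) "converged" else "step limit"))
  invisible(x)
}

#' Write embedding coordinates (with optional class labels) as TSV
#'
#' @param embedding an [mds_embed()] result.
#' @param path output path.
#' @param classes optional named character vector of class labels per target
#'   (e.g. outlier group 1 / group 2 / non-outlier); missing targets get
#'   `"non-outlier"`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, classes = NULL) {
  co <- embedding$coordinates
  df <- data.frame(target = rownames(co), co, stringsAsFactors = FALSE)
  colnames(df) <- c("target", paste0("dim", seq_len(ncol(co))))
  cls <- rep("non-outlier", nrow(df))
  if (!is.null(classes)) {
    hit <- df$target %in% names(classes)
    cls[hit] <- classes[df$target[hit]]
  }
  df$class <- cls
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
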