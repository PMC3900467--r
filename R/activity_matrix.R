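#' Construct a bioactivity matrix
#'
#' A bioactivity matrix holds percent-inhibition values (relative to native
#' target activity) for a full-matrix screen: one row per target, one column
#' per compound *instance*, where an instance is a compound screened at one
#' concentration.  The same compound at two concentrations yields two
#' instances, which downstream analyses deliberately count as distinct
#' compounds so that features of strong inhibitors (active at both
#' concentrations) are weighted twice.
#'
#' Instance labels follow the `"<compound_id>@<concentration>"` convention;
#' compound ids may therefore not contain `"@"`.
#'
#' @param values numeric matrix, targets in rows and instances in columns;
#'   must carry row and column names.  Raw assay values outside \[0, 100\]
#'   are accepted (assay noise) with a warning.
#' @return an object of class `bioactivity_matrix`: the numeric matrix with
#'   an `instances` attribute (data frame with columns `label`,
#'   `compound_id`, `concentration`).
#' @seealso [read_activity_matrix()], [binarize()], [panel_summary()]
#' @export
bioactivity_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have target row names and instance column names")
  if (anyNA(values))
    stop("bioactivity matrix must be complete: found missing cells")
  if (anyDuplicated(rownames(values)))
    stop("duplicate target ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate instance labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  inst <- parse_instance_labels(colnames(values))
  if (any(values < 0 | values > 100))
    warning("percent-inhibition values outside [0, 100] present; ",
            "retained as-is (assay noise)")
  structure(values, instances = inst,
            class = c("bioactivity_matrix", "matrix", "array"))
}

#' @export
print.bioactivity_matrix <- function(x, ...) {
  cat(sprintf("bioactivity matrix: %d targets x %d compound instances\n",
              nrow(x), ncol(x)))
  inst <- attr(x, "instances")
  cat(sprintf("  %d distinct compounds at concentrations {%s}\n",
              length(unique(inst$compound_id)),
              paste(sort(unique(inst$concentration)), collapse = ", ")))
  invisible(x)
}

# "<id>@<conc>" -> data.frame(label, compound_id, concentration)
parse_instance_labels <- function(labels) {
  parts <- strsplit(labels, "@", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("unparseable instance label(s) (expected '<compound>@<conc>'): ",
         paste(labels[bad], collapse = ", "))
  conc <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(conc) || any(conc <= 0))
    stop("instance label(s) with non-positive or non-numeric concentration: ",
         paste(labels[is.na(conc) | conc <= 0], collapse = ", "))
  data.frame(label = labels,
             compound_id = vapply(parts, `[`, "", 1L),
             concentration = conc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a bioactivity matrix from a delimited text file
#'
#' Expects a labeled full matrix: one header row of instance labels
#' (`"<compound>@<conc>"`) and one header column of target ids, or the
#' transposed layout with `orientation = "instances"`.  The field separator
#' is taken from the file extension (`.csv` means comma, anything else tab)
#' unless given explicitly.
#'
#' @param path file path (UTF-8 text).
#' @param orientation `"targets"` if rows are targets (default) or
#'   `"instances"` if rows are compound instances.
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @return a [bioactivity_matrix()].  Axis order is file order.
#' @export
read_activity_matrix <- function(path, orientation = c("targets", "instances"),
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("expected a header column plus at least one data column")
  row_labels <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  if (anyDuplicated(row_labels))
    stop("duplicate row label(s) in ", path, ": ",
         paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "))
  m <- as.matrix(body)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)
    stop("non-numeric cell(s), e.g. row '", row_labels[bad[1, 1]],
         "' column '", colnames(body)[bad[1, 2]], "'")
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing cell at row '", row_labels[bad[1, 1]], "' column '",
         colnames(body)[bad[1, 2]], "'")
  }
  rownames(m) <- row_labels
  if (orientation == "instances") m <- t(m)
  bioactivity_matrix(m)
}

#' Write a bioactivity matrix to a delimited text file
#'
#' Inverse of [read_activity_matrix()]; round-trips finite decimal values
#' losslessly (values are rendered with full double precision).
#'
#' @param mat a [bioactivity_matrix()].
#' @param path output path; `.csv` extension selects comma separation.
#' @param sep field separator; `NULL` infers from the extension.
#' @return `path`, invisibly.
#' @export
write_activity_matrix <- function(mat, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(target = rownames(mat),
                   format_full(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("target", colnames(mat))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# full-precision decimal rendering (17 significant digits round-trips doubles)
format_full <- function(m) {
  out <- apply(m, 2L, function(col) sprintf("%.17g", col))
  out <- array(out, dim(m), dimnames(m))
  out
}

#' Binarize percent-inhibition values into activity calls
#'
#' A compound instance is called active on a target when it inhibits the
#' target's activity by at least `threshold` percent at the screened
#' concentration (boundary inclusive: a value exactly at the threshold is
#' active).
#'
#' @param mat a [bioactivity_matrix()] (or plain numeric matrix with
#'   instance-style column labels).
#' @param threshold activity threshold in percent inhibition; default 50.
#' @return an `activity_calls` object: logical matrix with the same axes,
#'   plus `threshold` and `instances` attributes.
#' @export
binarize <- function(mat, threshold = 50) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  if (!inherits(mat, "bioactivity_matrix")) mat <- bioactivity_matrix(mat)
  calls <- unclass(mat) >= threshold
  structure(calls, threshold = threshold, instances = attr(mat, "instances"),
            class = c("activity_calls", "matrix", "array"))
}

#' @export
print.activity_calls <- function(x, ...) {
  cat(sprintf(
    "activity calls: %d targets x %d instances, threshold %g%%, %.1f%% active\n",
    nrow(x), ncol(x), attr(x, "threshold"), 100 * mean(x)))
  invisible(x)
}

# internal: keep a subset of target rows, preserving attributes
subset_targets <- function(x, keep) {
  stopifnot(all(keep %in% rownames(x)))
  out <- unclass(x)[keep, , drop = FALSE]
  attrs <- attributes(x)
  for (a in setdiff(names(attrs), c("dim", "dimnames")))
    attr(out, a) <- attrs[[a]]
  class(out) <- class(x)
  out
}

#' Summary statistics of a screened panel
#'
#' Computes the descriptive statistics used to characterise a panel before
#' classification: the fraction of active cells, the fraction of cells in
#' the ambiguous mid-band of percent inhibition, per-instance promiscuity
#' (how many targets each compound instance inhibits), per-target inhibitor
#' counts, and the instances flagged as pan-inhibitors because their
#' promiscuity count exceeds the panel mean by more than three population
#' standard deviations.
#'
#' @param mat a [bioactivity_matrix()].
#' @param calls the matching [binarize()] result; recomputed at 50% when
#'   omitted.
#' @param midband numeric length-2: the half-open mid-band interval
#'   `[lo, hi)` of raw percent inhibition, default `c(40, 60)`.
#' @return a `panel_summary` list with elements `fraction_active`,
#'   `fraction_midband`, `instance_counts`, `target_counts`,
#'   `promiscuous_instances`, `promiscuity_cutoff`, `n_targets`,
#'   `n_instances`.
#' @export
panel_summary <- function(mat, calls = binarize(mat), midband = c(40, 60)) {
  if (!identical(dimnames(mat), dimnames(calls)))
    stop("matrix and calls do not share axes")
  instance_counts <- colSums(calls)
  target_counts <- rowSums(calls)
  mu <- mean(instance_counts)
  sd_pop <- sqrt(mean((instance_counts - mu)^2))
  cutoff <- mu + 3 * sd_pop
  structure(list(
    fraction_active = mean(calls),
    fraction_midband = mean(unclass(mat) >= midband[1] & unclass(mat) < midband[2]),
    instance_counts = instance_counts,
    target_counts = target_counts,
    promiscuous_instances = names(instance_counts)[instance_counts > cutoff],
    promiscuity_cutoff = cutoff,
    n_targets = nrow(mat),
    n_instances = ncol(mat)
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel: %d targets x %d instances\n", x$n_targets, x$n_instances))
  cat(sprintf("  active cells: %.1f%%;  mid-band cells: %.1f%%\n",
              100 * x$fraction_active, 100 * x$fraction_midband))
  cat(sprintf("  mean promiscuity %.1f targets/instance; %d instance(s) above mu+3sd (%.1f)\n",
              mean(x$instance_counts), length(x$promiscuous_instances),
              x$promiscuity_cutoff))
  invisible(x)
}
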