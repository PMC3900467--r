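#' Laplacian-corrected feature enrichment ratio
#'
#' For one substructure feature on one target, `f_a` counts the active
#' compound instances whose compound contains the feature and `f_i` the
#' inactive instances.  The enrichment is the plain ratio `f_a / f_i`; when
#' either count is zero the Laplacian-corrected form `(f_a + 1) / (f_i + 2)`
#' is used instead, so the value is always finite and positive (a feature
#' absent from both sets scores 1/2).  Set `always_correct = TRUE` to apply
#' the corrected form everywhere (sensitivity-analysis variant).
#'
#' Values are exact ratios of small integers; equality comparisons against
#' hand counts are exact.
#'
#' @param f_a,f_i non-negative integer count vectors (recycled together).
#' @param always_correct apply the add-one/add-two correction to every pair,
#'   not only to zero counts.  Default `FALSE`.
#' @return numeric vector of enrichment values, all `> 0`.
#' @export
feature_enrichment <- function(f_a, f_i, always_correct = FALSE) {
  if (any(f_a < 0) || any(f_i < 0)) stop("counts must be non-negative")
  if (any(f_a != floor(f_a)) || any(f_i != floor(f_i)))
    stop("counts must be integers")
  if (always_correct) return((f_a + 1) / (f_i + 2))
  ifelse(f_a > 0 & f_i > 0, f_a / f_i, (f_a + 1) / (f_i + 2))
}

# internal: instances x vocabulary presence matrix from calls + feature table
instance_feature_matrix <- function(calls, table, vocab) {
  inst <- attr(calls, "instances")
  missing <- setdiff(unique(inst$compound_id), names(table))
  if (length(missing))
    stop("compound(s) missing from feature table: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(unique(unlist(table, use.names = FALSE)), vocab)
  if (length(extra))
    stop("feature table contains features outside the vocabulary: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  m <- matrix(FALSE, length(names(table)), length(vocab),
              dimnames = list(names(table), vocab))
  for (cid in names(table)) m[cid, table[[cid]]] <- TRUE
  m[inst$compound_id, , drop = FALSE]
}

#' Bioactivity-based fingerprint enrichment profile of one target
#'
#' Splits the panel's compound instances into the target's active and
#' inactive sets (instances of the same compound at different concentrations
#' count separately, so features of strong inhibitors are counted twice) and
#' scores every vocabulary feature with [feature_enrichment()].
#'
#' @param target_id target to profile.
#' @param calls an `activity_calls` matrix from [binarize()].
#' @param table a [feature_table()] covering every compound in the panel.
#' @param vocab feature vocabulary from [build_vocabulary()]; defaults to the
#'   table's own vocabulary.
#' @param always_correct see [feature_enrichment()].
#' @return named numeric vector of enrichment values over `vocab`, with
#'   attributes `target_id`, `f_a`, `f_i`.
#' @export
build_profile <- function(target_id, calls, table, vocab = build_vocabulary(table),
                          always_correct = FALSE) {
  if (!target_id %in% rownames(calls)) stop("unknown target: ", target_id)
  im <- instance_feature_matrix(calls, table, vocab)
  active <- unclass(calls)[target_id, ]
  f_a <- colSums(im[active, , drop = FALSE])
  f_i <- colSums(im[!active, , drop = FALSE])
  e <- feature_enrichment(f_a, f_i, always_correct = always_correct)
  structure(setNames(e, vocab), target_id = target_id, f_a = f_a, f_i = f_i)
}

#' Enrichment profiles for every target of a panel
#'
#' @inheritParams build_profile
#' @return an `enrichment_profiles` numeric matrix, targets in rows and
#'   vocabulary features in columns, with a `vocabulary` attribute.
#' @export
enrichment_profiles <- function(calls, table, vocab = build_vocabulary(table),
                                always_correct = FALSE) {
  im <- instance_feature_matrix(calls, table, vocab)
  cm <- unclass(calls)
  storage.mode(im) <- "double"
  f_a <- cm %*% im                     # targets x features active counts
  f_i <- (!cm) %*% im
  e <- feature_enrichment(as.vector(f_a), as.vector(f_i),
                          always_correct = always_correct)
  profiles <- matrix(e, nrow(cm), ncol(im),
                     dimnames = list(rownames(cm), colnames(im)))
  structure(profiles, vocabulary = vocab,
            class = c("enrichment_profiles", "matrix", "array"))
}

#' @export
print.enrichment_profiles <- function(x, ...) {
  cat(sprintf("enrichment profiles: %d targets x %d features\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Write enrichment profiles as a labeled TSV
#'
#' @param profiles an [enrichment_profiles()] matrix.
#' @param path output path; values are rendered with full precision so the
#'   exact rational values survive the round trip.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(target = rownames(profiles), format_full(unclass(profiles)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("target", colnames(profiles))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
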