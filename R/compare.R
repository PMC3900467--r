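#' Map each inhibitor instance to the targets it inhibits
#'
#' @param calls an `activity_calls` matrix.
#' @param by `"instance"` (default): one set per compound instance;
#'   `"compound"`: a compound's set is the union over its concentrations.
#' @return named list: inhibitor id -> character vector of inhibited targets
#'   (empty sets dropped).
#' @export
inhibitor_target_sets <- function(calls, by = c("instance", "compound")) {
  by <- match.arg(by)
  m <- unclass(calls)
  sets <- apply(m, 2L, function(col) rownames(m)[col], simplify = FALSE)
  if (by == "compound") {
    cid <- attr(calls, "instances")$compound_id
    sets <- lapply(split(sets, cid), function(s) sort(unique(unlist(s))))
  }
  sets[lengths(sets) > 0L]
}

#' Sequence-versus-bioactivity distance cross-tabulation
#'
#' For every inhibitor and every unordered pair of targets it inhibits, one
#' scatter row pairs the sequence-based distance with the bioactivity-based
#' distance of that pair.  The reported fraction is the share of rows whose
#' sequence distance falls in `seq_window` while the bioactivity distance
#' falls in `bio_window` (both windows closed) — i.e. pairs that look
#' distant by sequence but close by bioactivity.  Pairs involving a target
#' absent from either matrix are skipped with a warning.  Duplicate pairs
#' contributed by different inhibitors are kept by default (`dedup = TRUE`
#' collapses them).
#'
#' @param seqD,bioD [dist_matrix()] objects (typically the normalized
#'   patristic matrix of a sequence tree and a bioactivity distance matrix).
#' @param sets an [inhibitor_target_sets()] mapping.
#' @param seq_window,bio_window closed numeric intervals, defaults
#'   `c(0.6, 0.8)` and `c(0, 0.4)`.
#' @param dedup drop duplicate (target, target) rows across inhibitors.
#' @return list with `fraction`, `rows` (data frame: `inhibitor`, `target1`,
#'   `target2`, `seq_distance`, `bio_distance`, `in_window`), `n_skipped`.
#' @export
cross_density <- function(seqD, bioD, sets, seq_window = c(0.6, 0.8),
                          bio_window = c(0, 0.4), dedup = FALSE) {
  if (!length(intersect(rownames(seqD), rownames(bioD))))
    stop("distance matrices share no target labels")
  rows <- list(); skipped <- 0L
  for (inh in names(sets)) {
    targets <- unique(sets[[inh]])
    if (length(targets) < 2L) next
    prs <- combn(sort(targets), 2L)
    for (k in seq_len(ncol(prs))) {
      t1 <- prs[1, k]; t2 <- prs[2, k]
      if (!all(c(t1, t2) %in% rownames(seqD)) ||
          !all(c(t1, t2) %in% rownames(bioD))) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        inhibitor = inh, target1 = t1, target2 = t2,
        seq_distance = unclass(seqD)[t1, t2],
        bio_distance = unclass(bioD)[t1, t2], stringsAsFactors = FALSE)
    }
  }
  if (skipped) warning(skipped, " pair(s) skipped: target absent from a matrix")
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(inhibitor = character(), target1 = character(),
               target2 = character(), seq_distance = numeric(),
               bio_distance = numeric(), stringsAsFactors = FALSE)
  if (dedup && nrow(df))
    df <- df[!duplicated(df[, c("target1", "target2")]), , drop = FALSE]
  if (nrow(df)) {
    df$in_window <- df$seq_distance >= seq_window[1] &
      df$seq_distance <= seq_window[2] &
      df$bio_distance >= bio_window[1] & df$bio_distance <= bio_window[2]
  } else df$in_window <- logical()
  list(fraction = if (nrow(df)) mean(df$in_window) else NA_real_,
       rows = df, n_skipped = skipped)
}

#' Read a target-to-gatekeeper annotation table
#'
#' Two tab-separated columns: target id, one-letter gatekeeper residue code
#' (20 amino-acid letters plus `X` for unknown).  A `target`-headed first
#' line is skipped.
#'
#' @param path input TSV path.
#' @return named character vector (target -> residue).
#' @export
read_gatekeeper_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("target", "residue"))
  if (nrow(df) && df$target[1] == "target") df <- df[-1L, , drop = FALSE]
  gk <- setNames(toupper(df$residue), df$target)
  bad <- !gk %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  if (any(bad))
    stop("invalid residue code(s): ",
         paste(unique(gk[bad]), collapse = ", "))
  gk
}

#' Gatekeeper-residue identity across bioactivity distance bins
#'
#' Bins every unordered pair of annotated targets by bioactivity distance
#' into half-open bins `[k w, (k+1) w)` and reports, per bin, the fraction
#' of pairs whose two targets carry the same gatekeeper residue.  Two head/
#' tail summaries are returned: the unweighted mean over the bins covering
#' `[0, 0.5)`, and both the mean over the 5 highest non-empty bins and the
#' mean over all bins beyond 0.5.  Empty bins are reported as `NA`, not 0.
#'
#' @param bioD a [dist_matrix()].
#' @param gk named character vector from [read_gatekeeper_table()];
#'   unannotated targets are skipped with a warning.  Residue `X` pairs are
#'   never counted as identical.
#' @param bin_width bin width, default 0.1.
#' @return list with `bins` (data frame: `bin_lo`, `bin_hi`, `n_pairs`,
#'   `n_same`, `fraction_same`), `head_average`, `tail_average_top5`,
#'   `tail_average_above_05`.
#' @export
gatekeeper_bins <- function(bioD, gk, bin_width = 0.1) {
  annotated <- intersect(rownames(bioD), names(gk))
  dropped <- setdiff(rownames(bioD), annotated)
  if (length(dropped))
    warning(length(dropped), " unannotated target(s) skipped")
  if (length(annotated) < 2L) stop("need at least 2 annotated targets")
  m <- unclass(bioD)[annotated, annotated]
  prs <- combn(annotated, 2L)
  d <- m[cbind(prs[1, ], prs[2, ])]
  same <- gk[prs[1, ]] == gk[prs[2, ]] & gk[prs[1, ]] != "X"
  bin <- floor(d / bin_width)
  nbins <- max(bin) + 1L
  bins <- data.frame(bin_lo = (seq_len(nbins) - 1L) * bin_width,
                     bin_hi = seq_len(nbins) * bin_width)
  bins$n_pairs <- vapply(seq_len(nbins) - 1L, function(b) sum(bin == b), 0)
  bins$n_same <- vapply(seq_len(nbins) - 1L, function(b) sum(same[bin == b]), 0)
  bins$fraction_same <- ifelse(bins$n_pairs > 0, bins$n_same / bins$n_pairs,
                               NA_real_)
  head_bins <- bins$bin_lo < 0.5
  nonempty <- which(bins$n_pairs > 0)
  top5 <- utils::tail(nonempty, 5L)
  above <- bins$bin_lo >= 0.5 & bins$n_pairs > 0
  list(bins = bins,
       head_average = mean(bins$fraction_same[head_bins], na.rm = TRUE),
       tail_average_top5 = mean(bins$fraction_same[top5]),
       tail_average_above_05 = if (any(above))
         mean(bins$fraction_same[above]) else NA_real_)
}
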