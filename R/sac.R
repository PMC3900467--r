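#' Shared-activity statistics of a panel
#'
#' For every unordered pair of targets, counts the compound instances active
#' on both (instances of the same compound at different concentrations count
#' separately).  Per target it also reports the total number of active
#' instances, `shared_total` — how many of its active instances are active
#' on at least one other target (each instance counted once however many
#' partners it has) — and `mean_partners`, the average number of *other*
#' targets its active instances are shared with.
#'
#' These statistics drive the data-density exclusion filter: targets whose
#' actives are barely shared cannot be placed reliably in bioactivity space.
#'
#' @param calls an `activity_calls` matrix from [binarize()].
#' @return a `shared_activity_stats` list with `pair_counts` (symmetric
#'   integer matrix), `total_active`, `shared_total`, `mean_partners`
#'   (named vectors).
#' @export
shared_activity_stats <- function(calls) {
  m <- unclass(calls) * 1
  pair <- tcrossprod(m)            # instances active on both targets
  diag(pair) <- 0
  col_act <- colSums(m)            # targets inhibited per instance
  total <- rowSums(m)
  shared_total <- vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ] == 1 & col_act >= 2), numeric(1))
  mean_partners <- vapply(seq_len(nrow(m)), function(i) {
    act <- m[i, ] == 1
    if (!any(act)) 0 else mean(col_act[act] - 1)
  }, numeric(1))
  structure(list(
    pair_counts = pair,
    total_active = setNames(total, rownames(m)),
    shared_total = setNames(shared_total, rownames(m)),
    mean_partners = setNames(mean_partners, rownames(m))
  ), class = "shared_activity_stats")
}

#' @export
print.shared_activity_stats <- function(x, ...) {
  cat(sprintf(
    "shared-activity stats: %d targets; shared_total median %g (range %g-%g)\n",
    length(x$total_active), stats::median(x$shared_total),
    min(x$shared_total), max(x$shared_total)))
  invisible(x)
}

#' Raw shared-active-compound percentage for one target pair
#'
#' The number of compound instances active on both targets, as a percentage
#' of a normalizing total that depends on `mode`: the common target's active
#' count (`"common"`), the variable target's active count (`"variable"`), or
#' the size of the union of the two active sets (`"both"`; with
#' `both_denominator = "sum"` the sum of the two totals is used instead).
#'
#' @param common,variable target ids of the pair (common = the fixed target
#'   of the series, variable = the partner).
#' @param stats a [shared_activity_stats()] object.
#' @param mode normalization mode, `"variable"` (default), `"common"` or
#'   `"both"`.
#' @param both_denominator for `mode = "both"`: `"union"` (default) or
#'   `"sum"`.
#' @return percentage in `[0, 100]`, or `NA` with a warning when the
#'   denominator is zero (the point is excluded from series).
#' @export
sac_raw_percentage <- function(common, variable, stats,
                               mode = c("variable", "common", "both"),
                               both_denominator = c("union", "sum")) {
  mode <- match.arg(mode)
  both_denominator <- match.arg(both_denominator)
  shared <- stats$pair_counts[common, variable]
  denom <- switch(mode,
    common = stats$total_active[[common]],
    variable = stats$total_active[[variable]],
    both = {
      u <- stats$total_active[[common]] + stats$total_active[[variable]]
      if (both_denominator == "union") u - shared else u
    })
  if (denom == 0) {
    warning("zero denominator for pair (", common, ", ", variable,
            ") under mode '", mode, "'; point excluded")
    return(NA_real_)
  }
  100 * shared / denom
}

#' Build the raw SAC series of one common target
#'
#' Compares the common target pairwise against every other target in the
#' panel: one point per partner with a defined percentage, pairing the raw
#' shared-active-compound percentage with the bioactivity distance read from
#' `D`.
#'
#' @param common target id; must have at least one active instance
#'   (zero-active targets are excluded from series construction).
#' @param stats a [shared_activity_stats()] object.
#' @param D a [dist_matrix()] over the same targets.
#' @inheritParams sac_raw_percentage
#' @return a `sac_series` data frame with columns `variable`, `shared`,
#'   `raw_percentage`, `raw_distance` and attributes `common`, `mode`,
#'   `scaled = FALSE`.
#' @export
build_sac_series <- function(common, stats, D,
                             mode = c("variable", "common", "both"),
                             both_denominator = c("union", "sum")) {
  mode <- match.arg(mode)
  both_denominator <- match.arg(both_denominator)
  if (!common %in% names(stats$total_active)) stop("unknown target: ", common)
  if (stats$total_active[[common]] == 0)
    stop("target '", common, "' has no active instances; no SAC series defined")
  others <- setdiff(rownames(D), common)
  others <- intersect(others, names(stats$total_active))
  pct <- vapply(others, function(v)
    suppressWarnings(sac_raw_percentage(common, v, stats, mode,
                                        both_denominator)), numeric(1))
  dropped <- others[is.na(pct)]
  if (length(dropped))
    warning(length(dropped), " point(s) with zero denominator excluded from ",
            "series of '", common, "'")
  keep <- !is.na(pct)
  out <- data.frame(variable = others[keep],
                    shared = stats$pair_counts[common, others[keep]],
                    raw_percentage = pct[keep],
                    raw_distance = unclass(D)[common, others[keep]],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, common = common, mode = mode, scaled = FALSE,
            class = c("sac_series", "data.frame"))
}

#' Rescale a SAC series to the conventional axes
#'
#' Multiplicative per-series rescaling: distances are scaled so their mean
#' is exactly 0.5 and percentages so their mean is exactly 50 (the rescaled
#' percentage is the SAC score).  Because the rescaling is multiplicative
#' rather than an additive shift, a point whose raw percentage is five times
#' its series mean maps to a SAC score of 250 — scores above 200 are
#' attainable, as observed for close target pairs in dense panels.
#' Re-applying the scaling to an already-scaled series is the identity.
#'
#' @param series a `sac_series` from [build_sac_series()].
#' @return the series with added columns `sac_score`, `scaled_distance` and
#'   attribute `scaled = TRUE`.
#' @export
scale_series <- function(series) {
  if (nrow(series) == 0L) stop("empty series cannot be scaled")
  mp <- mean(series$raw_percentage)
  md <- mean(series$raw_distance)
  if (mp <= 0) stop("series of '", attr(series, "common"),
                    "': mean raw percentage is zero; cannot rescale")
  if (md <= 0) stop("series of '", attr(series, "common"),
                    "': mean raw distance is zero; cannot rescale")
  series$sac_score <- series$raw_percentage * (50 / mp)
  series$scaled_distance <- series$raw_distance * (0.5 / md)
  attr(series, "scaled") <- TRUE
  series
}

#' Classify a SAC series as neighborhood-consistent or outlier
#'
#' Fits an ordinary least-squares second-degree polynomial
#' `sac_score = a x^2 + b x + c` through the scaled series (x = scaled
#' distance) and evaluates the slope `2 a x + b` at x = 0.40 and x = 0.67.
#' The series exhibits *neighborhood behavior* — nearby targets share
#' relatively more active compounds — exactly when both slopes are negative
#' and the fit's R-squared exceeds 0.2; otherwise the common target is an
#' outlier.  Series with fewer than 3 points or degenerate x values cannot
#' be fitted and are classified outlier with a reason flag.
#'
#' @param series a scaled `sac_series` (see [scale_series()]).
#' @return an `outlier_call`: one-row data frame with columns `target`,
#'   `n_points`, `a`, `b`, `c`, `slope_040`, `slope_067`, `r_squared`,
#'   `verdict` (`"neighborhood"` or `"outlier"`), `reason`.
#' @export
classify_series <- function(series) {
  target <- attr(series, "common")
  if (!isTRUE(attr(series, "scaled")))
    stop("series must be scaled before classification (see scale_series)")
  fail <- function(reason) data.frame(
    target = target, n_points = nrow(series), a = NA_real_, b = NA_real_,
    c = NA_real_, slope_040 = NA_real_, slope_067 = NA_real_,
    r_squared = NA_real_, verdict = "outlier", reason = reason,
    stringsAsFactors = FALSE)
  if (nrow(series) < 3L) return(fail("fewer than 3 points"))
  x <- series$scaled_distance; y <- series$sac_score
  if (length(unique(x)) < 3L) return(fail("degenerate x values"))
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)                      # (Intercept), x, x^2
  a <- cf[[3L]]; b <- cf[[2L]]; cc <- cf[[1L]]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  s40 <- 2 * a * 0.40 + b
  s67 <- 2 * a * 0.67 + b
  verdict <- if (s40 < 0 && s67 < 0 && r2 > 0.2) "neighborhood" else "outlier"
  data.frame(target = target, n_points = nrow(series), a = a, b = b, c = cc,
             slope_040 = s40, slope_067 = s67, r_squared = r2,
             verdict = verdict, reason = "", stringsAsFactors = FALSE)
}

#' Data-density exclusion filter
#'
#' Excludes targets whose `shared_total` (active instances shared with at
#' least one other target) is at or below the threshold.  The default of 16
#' corresponds to roughly 10% of the maximum shared-activity count in a
#' dense kinase panel.  The filter is a single pass over statistics computed
#' on the unfiltered panel; it is not iterated.
#'
#' @param stats a [shared_activity_stats()] object.
#' @param threshold exclusion threshold (count); excluded iff
#'   `shared_total <= threshold`.  Default 16.
#' @return list with character vectors `kept` and `excluded`.
#' @export
exclusion_filter <- function(stats, threshold = 16) {
  excluded <- names(stats$shared_total)[stats$shared_total <= threshold]
  list(kept = setdiff(names(stats$shared_total), excluded),
       excluded = excluded)
}

#' Run the SAC-score outlier analysis over a panel
#'
#' For every eligible target (at least one active instance; optionally
#' surviving the [exclusion_filter()] at `threshold`), builds the raw SAC
#' series against the given distance matrix, rescales it, and classifies it.
#' Series that cannot be rescaled (all-zero shared percentages or zero mean
#' distance, e.g. a target whose actives are disjoint from every other
#' target) are classified outlier directly.
#'
#' @param calls an `activity_calls` matrix.
#' @param D a [dist_matrix()] over the same targets.
#' @param mode SAC normalization mode (see [sac_raw_percentage()]).
#' @param threshold optional exclusion threshold; `NULL` (default) disables
#'   the data-density filter.
#' @inheritParams sac_raw_percentage
#' @return a `sac_analysis` list: `calls_table` (one [classify_series()] row
#'   per analyzed target), `neighborhood_fraction`, `outliers`,
#'   `zero_active` (targets without actives, never given a series),
#'   `excluded` (by the density filter), `mode`, `metric`, `n_series`.
#' @export
run_sac_analysis <- function(calls, D, mode = c("variable", "common", "both"),
                             threshold = NULL,
                             both_denominator = c("union", "sum")) {
  mode <- match.arg(mode)
  both_denominator <- match.arg(both_denominator)
  if (!identical(sort(rownames(calls)), sort(rownames(D))))
    stop("calls and distance matrix cover different targets")
  stats_full <- shared_activity_stats(calls)
  excluded <- character()
  if (!is.null(threshold)) {
    flt <- exclusion_filter(stats_full, threshold)
    excluded <- flt$excluded
    calls <- subset_targets(calls, flt$kept)
    D <- dist_matrix(unclass(D)[flt$kept, flt$kept, drop = FALSE],
                     metric = attr(D, "metric"))
  }
  stats <- shared_activity_stats(calls)
  zero_active <- names(stats$total_active)[stats$total_active == 0]
  eligible <- setdiff(rownames(calls), zero_active)
  rows <- lapply(eligible, function(tg) {
    series <- suppressWarnings(
      build_sac_series(tg, stats, D, mode, both_denominator))
    scaled <- tryCatch(scale_series(series), error = function(e) NULL)
    if (is.null(scaled)) {
      out <- classify_series(structure(series[0, ], common = tg, mode = mode,
                                       scaled = TRUE,
                                       class = c("sac_series", "data.frame")))
      out$n_points <- nrow(series)
      out$reason <- "series could not be rescaled (zero mean)"
      return(out)
    }
    classify_series(scaled)
  })
  tab <- do.call(rbind, rows)
  structure(list(
    calls_table = tab,
    neighborhood_fraction = if (is.null(tab) || nrow(tab) == 0) NA_real_
                            else mean(tab$verdict == "neighborhood"),
    outliers = if (is.null(tab)) character() else
      tab$target[tab$verdict == "outlier"],
    zero_active = zero_active,
    excluded = excluded,
    mode = mode, metric = attr(D, "metric"),
    n_series = if (is.null(tab)) 0L else nrow(tab)
  ), class = "sac_analysis")
}

#' @export
print.sac_analysis <- function(x, ...) {
  cat(sprintf(
    "SAC analysis (%s normalization, %s distances): %d series\n",
    x$mode, x$metric, x$n_series))
  cat(sprintf("  neighborhood behavior: %.1f%%;  outliers: %d;  excluded: %d;  zero-active: %d\n",
              100 * x$neighborhood_fraction, length(x$outliers),
              length(x$excluded), length(x$zero_active)))
  invisible(x)
}

#' Write the per-target SAC classification table as TSV
#'
#' @param analysis a `sac_analysis` from [run_sac_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sac_table <- function(analysis, path) {
  write.table(analysis$calls_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
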