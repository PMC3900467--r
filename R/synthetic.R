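#' Configuration for the synthetic bioactivity panel generator
#'
#' The generator emulates the statistical structure of a dense kinase
#' inhibitor percent-inhibition screen: clusters of targets inhibited by
#' cluster-matched chemotypes, a small set of pan-inhibitors active almost
#' everywhere, a handful of sparsely-shared targets whose actives are
#' thinned below the data-density exclusion threshold, one completely
#' inactive target, every compound screened at a low and a high
#' concentration with low-concentration actives nested inside
#' high-concentration actives, and a small fraction of ambiguous mid-band
#' percent-inhibition values.
#'
#' @param n_clusters number of target clusters (>= 2), default 6.
#' @param targets_per_cluster targets per cluster, default 8.
#' @param n_compounds total compounds including pan-inhibitors, default 150.
#' @param concentrations screening concentrations in µM, low then high,
#'   default `c(1, 10)`.
#' @param chemotype_features_per_cluster features in each cluster's
#'   chemotype signature: a single size shared by all clusters, or a
#'   length-2 range spread linearly across clusters (unequal chemotype
#'   complexity, which keeps the inter-cluster distance distribution
#'   right-skewed as in real panels).  Default `c(12, 60)`.
#' @param background_features_per_compound random background features per
#'   compound, default 20.
#' @param n_background_features size of the background feature pool,
#'   default 1500.
#' @param signature_overlap number of signature features each cluster shares
#'   with the next (cross-reactive chemotypes), default 0.
#' @param p_within baseline probability that a cluster-matched compound is
#'   active on a cluster target at the high concentration, default 0.8.
#' @param sensitivity_range per-target uniform range of the multiplier
#'   applied to `p_within` (capped at probability 1), default `c(0.35, 1.25)`;
#'   models the spread between selective and sensitive targets so that
#'   per-target inhibitor counts span a realistic range instead of being
#'   homogeneous.
#' @param promiscuity_range per-target uniform range of the multiplier
#'   applied to `p_background`, default `c(0.5, 6)`; models promiscuous
#'   targets that respond well beyond their own chemotype.
#' @param p_low_given_high conditional probability that a high-concentration
#'   active is also active at the low concentration, default 0.6.
#' @param p_background off-cluster activity probability (high
#'   concentration), default 0.02.
#' @param n_pan_inhibitors number of pan-inhibitor compounds, default 2.
#' @param pan_activity_prob pan-inhibitor activity probability (high
#'   concentration), default 0.95.
#' @param n_sparse_targets targets with planted low shared activity,
#'   default 3.
#' @param sparse_max_actives cap on a sparse target's active instances;
#'   must be <= 16 so the planted targets fall below the exclusion
#'   threshold, default 10.
#' @param include_zero_active_target add one target never inhibited,
#'   default `TRUE`.
#' @param active_value_range percent-inhibition range for active cells,
#'   default `c(60, 100)`.
#' @param inactive_value_range range for inactive cells, default `c(0, 40)`.
#' @param midband_prob probability that a cell's value is drawn from the
#'   ambiguous mid-band (`[50, 60)` for actives, `[40, 50)` for inactives),
#'   default 0.02.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_clusters = 6, targets_per_cluster = 8,
                             n_compounds = 150, concentrations = c(1, 10),
                             chemotype_features_per_cluster = c(12, 60),
                             background_features_per_compound = 20,
                             n_background_features = 1500,
                             signature_overlap = 0,
                             p_within = 0.8, p_low_given_high = 0.6,
                             p_background = 0.02,
                             sensitivity_range = c(0.35, 1.25),
                             promiscuity_range = c(0.5, 6),
                             n_pan_inhibitors = 2, pan_activity_prob = 0.95,
                             n_sparse_targets = 3, sparse_max_actives = 10,
                             include_zero_active_target = TRUE,
                             active_value_range = c(60, 100),
                             inactive_value_range = c(0, 40),
                             midband_prob = 0.02, seed = 1) {
  cfg <- as.list(environment())
  probs <- c(p_within, p_low_given_high, p_background, pan_activity_prob,
             midband_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_clusters < 2) stop("need at least 2 clusters")
  if (length(concentrations) != 2L || any(concentrations <= 0) ||
      concentrations[1] >= concentrations[2])
    stop("'concentrations' must be two increasing positive values")
  if (any(sensitivity_range <= 0) || any(promiscuity_range <= 0) ||
      sensitivity_range[1] > sensitivity_range[2] ||
      promiscuity_range[1] > promiscuity_range[2])
    stop("sensitivity/promiscuity ranges must be positive and increasing")
  if (sparse_max_actives > 16)
    stop("infeasible config: sparse targets capped at more than 16 actives ",
         "cannot fall below the exclusion threshold")
  if (n_pan_inhibitors >= n_compounds)
    stop("infeasible config: no non-pan compounds left")
  if (active_value_range[1] < 50 || active_value_range[2] > 120 ||
      inactive_value_range[1] < -20 || inactive_value_range[2] > 50)
    stop("value ranges outside plausible assay bounds")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic bioactivity panel with ground truth
#'
#' See [synthetic_config()] for the generative model.  Cluster chemotype
#' signatures are disjoint feature blocks (optionally overlapping adjacent
#' clusters); a compound's feature set is its cluster signature plus random
#' background features; pan-inhibitors carry background features only.
#' Activity is Bernoulli per (compound, target) at the high concentration,
#' with the low-concentration active set nested inside it, so the same
#' compound active at both concentrations contributes its features twice —
#' strong inhibitors are emphasized.  Sparse targets are thinned
#' compound-wise until at most `sparse_max_actives` active instances remain.
#' Output is fully deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_panel` list: `matrix` ([bioactivity_matrix()]),
#'   `features` ([feature_table()]), `truth` (cluster labels, sparse
#'   targets, zero-active target, pan-inhibitors), `config`.
#' @export
generate_panel <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n_pan <- cfg$n_pan_inhibitors
  n_reg <- cfg$n_compounds - n_pan
  compounds <- sprintf("CPD%03d", seq_len(cfg$n_compounds))
  pan_compounds <- if (n_pan > 0) utils::tail(compounds, n_pan) else character()
  reg_compounds <- setdiff(compounds, pan_compounds)
  compound_cluster <- setNames(rep(seq_len(cfg$n_clusters), length.out = n_reg),
                               reg_compounds)

  # cluster signatures: consecutive feature blocks of (possibly unequal)
  # size, optionally overlapping adjacent clusters
  spc <- cfg$chemotype_features_per_cluster
  sig_sizes <- if (length(spc) == 1L) rep(round(spc), cfg$n_clusters)
               else round(seq(spc[1], spc[2], length.out = cfg$n_clusters))
  if (any(sig_sizes <= cfg$signature_overlap))
    stop("infeasible config: signature_overlap >= smallest signature size")
  offsets <- cumsum(c(0, utils::head(sig_sizes - cfg$signature_overlap, -1L)))
  all_sig <- sprintf("SIG%04d", seq_len(offsets[cfg$n_clusters] +
                                          sig_sizes[cfg$n_clusters]))
  signatures <- lapply(seq_len(cfg$n_clusters), function(k)
    all_sig[offsets[k] + seq_len(sig_sizes[k])])
  bg_pool <- sprintf("BGF%04d", seq_len(cfg$n_background_features))

  feats <- lapply(compounds, function(cid) {
    bg <- sample(bg_pool, cfg$background_features_per_compound)
    if (cid %in% pan_compounds) bg
    else c(signatures[[compound_cluster[[cid]]]], bg)
  })
  table <- feature_table(setNames(feats, compounds))

  # targets
  cluster_targets <- unlist(lapply(seq_len(cfg$n_clusters), function(k)
    sprintf("T%02d_%02d", k, seq_len(cfg$targets_per_cluster))))
  target_cluster <- setNames(rep(seq_len(cfg$n_clusters),
                                 each = cfg$targets_per_cluster),
                             cluster_targets)
  sparse_targets <- if (cfg$n_sparse_targets > 0)
    sprintf("SPT%02d", seq_len(cfg$n_sparse_targets)) else character()
  sparse_cluster <- setNames(rep(NA_integer_,
                                 length(sparse_targets)),
                             sparse_targets)
  zero_target <- if (cfg$include_zero_active_target) "ZAT01" else character()
  targets <- c(cluster_targets, sparse_targets, zero_target)
  target_cluster <- c(target_cluster, sparse_cluster,
                      setNames(rep(NA_integer_, length(zero_target)), zero_target))

  conc <- cfg$concentrations
  instances <- as.vector(t(outer(compounds, conc, paste, sep = "@")))
  inst_compound <- rep(compounds, each = 2L)
  inst_high <- rep(c(FALSE, TRUE), times = cfg$n_compounds)

  n_t <- length(targets); n_c <- cfg$n_compounds
  # per-target sensitivity (scales on-chemotype response) and promiscuity
  # (scales off-chemotype response): selective vs promiscuous targets
  real_targets <- c(cluster_targets, sparse_targets)
  sens <- setNames(runif(length(real_targets), cfg$sensitivity_range[1],
                         cfg$sensitivity_range[2]), real_targets)
  prom <- setNames(runif(length(real_targets), cfg$promiscuity_range[1],
                         cfg$promiscuity_range[2]), real_targets)
  # high-concentration activity per (target, compound), then nested low.
  # Sparse targets have no matched chemotype in the library: their few
  # actives come from pan-inhibitors and scattered background hits, so the
  # activities they do have are shared with many other targets.
  p_high <- matrix(0, n_t, n_c, dimnames = list(targets, compounds))
  for (tg in real_targets) {
    bg_p <- min(1, cfg$p_background * prom[[tg]])
    if (tg %in% sparse_targets) {
      p_high[tg, reg_compounds] <- bg_p
    } else {
      k <- target_cluster[[tg]]
      matched <- compound_cluster[reg_compounds] == k
      p_high[tg, reg_compounds[matched]] <- min(1, cfg$p_within * sens[[tg]])
      p_high[tg, reg_compounds[!matched]] <- bg_p
    }
  }
  if (n_pan > 0) p_high[, pan_compounds] <- cfg$pan_activity_prob
  if (length(zero_target)) p_high[zero_target, ] <- 0
  high <- matrix(runif(n_t * n_c) < p_high, n_t, n_c,
                 dimnames = list(targets, compounds))
  # potency follows sensitivity: sensitive targets keep more of their
  # high-concentration actives at the low concentration
  p_low <- matrix(cfg$p_low_given_high, n_t, n_c)
  for (tg in real_targets)
    p_low[match(tg, targets), ] <- min(1, cfg$p_low_given_high * sens[[tg]])
  low <- high & matrix(runif(n_t * n_c) < p_low, n_t, n_c)

  # thin sparse targets compound-wise so instance actives <= cap
  for (tg in sparse_targets) {
    act <- which(high[tg, ])
    if (!length(act)) next
    ord <- sample(act)
    n_inst <- cumsum(1L + low[tg, ord])
    keep <- ord[n_inst <= cfg$sparse_max_actives]
    drop <- setdiff(act, keep)
    high[tg, drop] <- FALSE
    low[tg, drop] <- FALSE
  }

  calls <- matrix(FALSE, n_t, length(instances),
                  dimnames = list(targets, instances))
  calls[, inst_high] <- high[, inst_compound[inst_high]]
  calls[, !inst_high] <- low[, inst_compound[!inst_high]]

  # percent-inhibition values consistent with the planted calls
  nv <- length(calls)
  mid <- matrix(runif(nv) < cfg$midband_prob, n_t, length(instances))
  vals <- matrix(0, n_t, length(instances), dimnames = dimnames(calls))
  a <- calls & !mid
  vals[a] <- runif(sum(a), cfg$active_value_range[1], cfg$active_value_range[2])
  a <- calls & mid
  vals[a] <- runif(sum(a), 50, 60)
  a <- !calls & !mid
  vals[a] <- runif(sum(a), cfg$inactive_value_range[1],
                   min(cfg$inactive_value_range[2], 50) - 1e-9)
  a <- !calls & mid
  vals[a] <- runif(sum(a), 40, 50 - 1e-9)

  truth <- list(cluster = target_cluster,
                sensitivity = sens, promiscuity = prom,
                sparse_targets = sparse_targets,
                zero_active_target = if (length(zero_target)) zero_target else NULL,
                pan_inhibitors = pan_compounds)
  structure(list(matrix = bioactivity_matrix(vals), features = table,
                 truth = truth, config = cfg),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "synthetic panel: %d targets (%d clusters, %d sparse, %s zero-active) x %d instances\n",
    nrow(x$matrix), x$config$n_clusters, length(x$truth$sparse_targets),
    if (is.null(x$truth$zero_active_target)) "no" else "one",
    ncol(x$matrix)))
  invisible(x)
}

#' Write a synthetic panel as pipeline-ready fixture files
#'
#' Emits `activity.tsv` (the percent-inhibition matrix in the layout
#' [read_activity_matrix()] expects), `features.tsv` (long-format table for
#' [read_feature_table()]) and `truth.json` (ground-truth labels) into a
#' directory.
#'
#' @param panel a [generate_panel()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixtures <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(activity = file.path(dir, "activity.tsv"),
             features = file.path(dir, "features.tsv"),
             truth = file.path(dir, "truth.json"))
  write_activity_matrix(panel$matrix, paths[["activity"]])
  write_feature_table(panel$features, paths[["features"]])
  jsonlite::write_json(panel$truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
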