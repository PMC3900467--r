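#' Configuration for the two-stage panel analysis
#'
#' Collects the inputs and tunables of [run_full()].  Inputs may be given
#' either in memory (`matrix` + `features`, e.g. from [generate_panel()]) or
#' as file paths (`matrix_path`, `features_path`), plus an optional sequence
#' tree (Newick) and gatekeeper annotation table for the cross-panel
#' comparisons.
#'
#' @param matrix a [bioactivity_matrix()], or `NULL` if `matrix_path` given.
#' @param features a [feature_table()], or `NULL` if `features_path` given.
#' @param matrix_path,features_path input file paths (see
#'   [read_activity_matrix()], [read_feature_table()]).
#' @param sequence_tree_path optional Newick file of a sequence-based tree.
#' @param gatekeeper_path optional gatekeeper annotation TSV.
#' @param threshold activity threshold in percent, default 50.
#' @param sac_mode SAC normalization mode, default `"variable"`.
#' @param exclusion_threshold data-density exclusion threshold, default 16.
#' @param mds_min_stress_change,mds_max_steps MDS stopping conditions,
#'   defaults 0.00005 and 5000.
#' @param seed integer seed for the stochastic stages (MDS start), required.
#' @param outdir optional output directory for artifacts; `NULL` keeps
#'   everything in memory.
#' @return a `run_config` list.
#' @export
run_config <- function(matrix = NULL, features = NULL, matrix_path = NULL,
                       features_path = NULL, sequence_tree_path = NULL,
                       gatekeeper_path = NULL, threshold = 50,
                       sac_mode = c("variable", "common", "both"),
                       exclusion_threshold = 16,
                       mds_min_stress_change = 0.00005, mds_max_steps = 5000,
                       seed = NULL, outdir = NULL) {
  sac_mode <- match.arg(sac_mode)
  if (is.null(matrix) && is.null(matrix_path))
    stop("either 'matrix' or 'matrix_path' is required")
  if (is.null(features) && is.null(features_path))
    stop("either 'features' or 'features_path' is required")
  if (threshold < 0) stop("'threshold' must be non-negative")
  if (is.null(seed)) stop("'seed' is required for reproducibility")
  for (p in c(matrix_path, features_path, sequence_tree_path, gatekeeper_path))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  structure(as.list(environment())[c(
    "matrix", "features", "matrix_path", "features_path",
    "sequence_tree_path", "gatekeeper_path", "threshold", "sac_mode",
    "exclusion_threshold", "mds_min_stress_change", "mds_max_steps",
    "seed", "outdir")], class = "run_config")
}

# one analysis stage: profiles -> distances -> trees -> SAC (both metrics) -> MDS
run_stage <- function(mat, table, config, stage_name, artifact = identity) {
  calls <- binarize(mat, config$threshold)
  profiles <- enrichment_profiles(calls, table)
  d_enr <- enrichment_distance_matrix(profiles)
  d_tan <- bioactivity_distance_matrix(calls, "tanimoto")
  d_ham <- bioactivity_distance_matrix(calls, "hamming")
  tree_enr <- neighbor_joining(d_enr)
  tree_tan <- neighbor_joining(d_tan)
  sac_enr <- run_sac_analysis(calls, d_enr, mode = config$sac_mode)
  sac_tan <- run_sac_analysis(calls, d_tan, mode = config$sac_mode)
  mds <- mds_embed(d_ham, min_stress_change = config$mds_min_stress_change,
                   max_steps = config$mds_max_steps, seed = config$seed)
  list(name = stage_name, calls = calls, summary = panel_summary(mat, calls),
       profiles = profiles, d_enr = d_enr, d_tan = d_tan, d_ham = d_ham,
       tree_enr = tree_enr, tree_tan = tree_tan,
       sac_enr = sac_enr, sac_tan = sac_tan, mds = mds)
}

#' Run the full two-stage bioactivity-classification pipeline
#'
#' Stage 1 analyzes the full panel: activity binarization, enrichment
#' profiles, both distance matrices (normalized Manhattan on enrichment
#' profiles; Tanimoto on bioactivity fingerprints), neighbor-joining trees,
#' SAC-score classification under both metrics (outlier group 1 =
#' enrichment-metric outliers, group 2 = Tanimoto-metric outliers), and the
#' Hamming-distance MDS diagnostic.  Stage 2 removes targets failing the
#' data-density criterion (`shared_total <= exclusion_threshold`, computed
#' once on the full panel) and rebuilds everything — profiles, vocabulary
#' usage, distances, trees, SAC — from the kept panel.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list with the panel summary, per-stage
#'   neighborhood fractions and outlier groups (and their intersection),
#'   the excluded-target list, MDS stress values, all parameters, and — when
#'   `config$outdir` is set — the paths of the written artifacts (Newick
#'   trees, distance/profile/SAC TSVs, embedding TSV, JSON report).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mat <- if (!is.null(config$matrix)) config$matrix
         else read_activity_matrix(config$matrix_path)
  inst <- attr(mat, "instances")
  table <- if (!is.null(config$features)) config$features
           else read_feature_table(config$features_path,
                                   compounds = unique(inst$compound_id))
  with_stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e)))

  s1 <- with_stage("stage1", run_stage(mat, table, config, "stage1"))

  stats_full <- shared_activity_stats(s1$calls)
  flt <- exclusion_filter(stats_full, config$exclusion_threshold)
  mat2 <- subset_targets(mat, flt$kept)
  s2 <- with_stage("stage2", run_stage(mat2, table, config, "stage2"))

  group1 <- s1$sac_enr$outliers
  group2 <- s1$sac_tan$outliers
  report <- list(
    parameters = config[c("threshold", "sac_mode", "exclusion_threshold",
                          "mds_min_stress_change", "mds_max_steps", "seed")],
    panel = list(n_targets = nrow(mat), n_instances = ncol(mat),
                 fraction_active = s1$summary$fraction_active,
                 fraction_midband = s1$summary$fraction_midband,
                 promiscuous_instances = s1$summary$promiscuous_instances),
    stage1 = list(
      n_series = s1$sac_enr$n_series,
      neighborhood_fraction_enrichment = s1$sac_enr$neighborhood_fraction,
      neighborhood_fraction_tanimoto = s1$sac_tan$neighborhood_fraction,
      outlier_group1 = group1, outlier_group2 = group2,
      outlier_intersection = intersect(group1, group2),
      zero_active = s1$sac_enr$zero_active,
      mds_stress = s1$mds$final_stress),
    excluded = flt$excluded,
    stage2 = list(
      n_targets = length(flt$kept),
      n_series = s2$sac_enr$n_series,
      neighborhood_fraction_enrichment = s2$sac_enr$neighborhood_fraction,
      neighborhood_fraction_tanimoto = s2$sac_tan$neighborhood_fraction,
      outlier_group1 = s2$sac_enr$outliers,
      outlier_group2 = s2$sac_tan$outliers,
      mds_stress = s2$mds$final_stress))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    art <- character()
    emit <- function(name, writer) {
      p <- file.path(config$outdir, name)
      writer(p)
      art[[name]] <<- p
    }
    for (st in list(s1, s2)) {
      pre <- st$name
      emit(paste0(pre, "_tree_enrichment.nwk"),
           function(p) write_newick(st$tree_enr, p))
      emit(paste0(pre, "_tree_tanimoto.nwk"),
           function(p) write_newick(st$tree_tan, p))
      emit(paste0(pre, "_dist_enrichment.tsv"),
           function(p) write_distance_matrix(st$d_enr, p))
      emit(paste0(pre, "_dist_tanimoto.tsv"),
           function(p) write_distance_matrix(st$d_tan, p))
      emit(paste0(pre, "_profiles.tsv"),
           function(p) write_profiles(st$profiles, p))
      emit(paste0(pre, "_sac_enrichment.tsv"),
           function(p) write_sac_table(st$sac_enr, p))
      emit(paste0(pre, "_sac_tanimoto.tsv"),
           function(p) write_sac_table(st$sac_tan, p))
      classes <- c(setNames(rep("outlier-group-1", length(st$sac_enr$outliers)),
                            st$sac_enr$outliers),
                   setNames(rep("outlier-group-2", length(st$sac_tan$outliers)),
                            st$sac_tan$outliers))
      emit(paste0(pre, "_mds.tsv"),
           function(p) write_embedding(st$mds, p, classes = classes))
    }
    emit("report.json", function(p)
      jsonlite::write_json(report, p, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA))
    report$artifacts <- art
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("two-stage panel analysis: %d targets, %d instances, %.1f%% active\n",
              x$panel$n_targets, x$panel$n_instances,
              100 * x$panel$fraction_active))
  cat(sprintf("  stage 1: neighborhood %.0f%% (enrichment) / %.0f%% (Tanimoto); %d + %d outliers, %d shared\n",
              100 * x$stage1$neighborhood_fraction_enrichment,
              100 * x$stage1$neighborhood_fraction_tanimoto,
              length(x$stage1$outlier_group1), length(x$stage1$outlier_group2),
              length(x$stage1$outlier_intersection)))
  cat(sprintf("  excluded (density filter): %d\n", length(x$excluded)))
  cat(sprintf("  stage 2: neighborhood %.0f%% (enrichment) on %d targets\n",
              100 * x$stage2$neighborhood_fraction_enrichment,
              x$stage2$n_targets))
  invisible(x)
}
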