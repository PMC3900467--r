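#' Construct a compound feature table
#'
#' A feature table maps each compound id to its *set* of substructure
#' feature ids (presence/absence; a feature occurring several times within
#' one molecule is still counted once per compound).  Feature ids are opaque
#' strings — canonical circular-environment identifiers when computed from
#' structures, or arbitrary ids from a precomputed table.
#'
#' @param x named list of character vectors (compound id -> feature ids);
#'   duplicates within a compound collapse.
#' @return a `feature_table` object (named list of sorted character vectors).
#' @export
feature_table <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop("'x' must be a named list of character vectors")
  if (anyDuplicated(names(x)))
    stop("duplicate compound ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(grepl("@", names(x), fixed = TRUE)))
    stop("compound ids may not contain '@' (reserved for instance labels)")
  out <- lapply(x, function(f) sort(unique(as.character(f))))
  structure(out, class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("feature table: %d compounds, %d distinct features (set sizes %d-%d)\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))
              , if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Read a long-format compound/feature table
#'
#' Two tab-separated columns, `compound_id` then `feature_id`, one row per
#' (compound, feature) occurrence; duplicate rows collapse under set
#' semantics.  A header line is detected and skipped when its first field is
#' literally `compound_id`.
#'
#' @param path input TSV path.
#' @param compounds optional character vector of compound ids that must have
#'   an entry; compounds with no rows get an empty feature set.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, compounds = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty feature table file: ", path)
    df <- data.frame(compound_id = character(), feature_id = character())
  } else {
    df <- read.delim(text = lines, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE,
                     col.names = c("compound_id", "feature_id"))
    if (nrow(df) && df$compound_id[1] == "compound_id") df <- df[-1L, , drop = FALSE]
  }
  sets <- split(df$feature_id, factor(df$compound_id, levels = unique(df$compound_id)))
  if (!is.null(compounds)) {
    missing <- setdiff(compounds, names(sets))
    sets[missing] <- list(character())
    sets <- sets[compounds]
  }
  feature_table(sets)
}

#' Write a feature table in long format
#'
#' @param table a [feature_table()].
#' @param path output TSV path (columns `compound_id`, `feature_id`, with
#'   header).  Compounds with empty feature sets contribute no rows.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(
    compound_id = rep(names(table), lengths(table)),
    feature_id = unlist(table, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Build the feature vocabulary of a panel
#'
#' The vocabulary is the lexicographically ordered union of all feature sets
#' in the table; every enrichment profile lives on this common axis, and the
#' normalized Manhattan distance divides by its size.
#'
#' @param table a [feature_table()].
#' @return character vector of distinct feature ids, sorted; class
#'   `feature_vocabulary`.
#' @export
build_vocabulary <- function(table) {
  vocab <- sort(unique(unlist(table, use.names = FALSE)))
  structure(as.character(vocab), class = "feature_vocabulary")
}

#' Extract circular substructure features from SMILES
#'
#' Computes extended-connectivity (Morgan) circular atom environments up to
#' `diameter/2` bonds of radius for each compound, through the RDKit
#' cheminformatics toolkit invoked as an external `python` backend.  Feature
#' ids are the backend's canonical environment identifiers, stable across
#' runs for identical input.  The default diameter of 4 bonds corresponds to
#' the ECFP_4 descriptor conventional in ligand-based target comparison.
#'
#' Tests and the synthetic pipeline use abstract feature tables, so the
#' chemistry backend is only required when real structures are featurized.
#'
#' @param smiles named character vector: `compound_id = SMILES`, or a path
#'   to a file with `SMILES<TAB>compound_id` records (one per line).
#' @param diameter even non-negative integer, default 4.
#' @param on_error `"stop"` (default) fails listing all unparseable records;
#'   `"skip"` drops them with a warning.
#' @param python python executable with RDKit importable, default `"python"`.
#' @return a [feature_table()].
#' @export
extract_features <- function(smiles, diameter = 4, on_error = c("stop", "skip"),
                             python = "python") {
  on_error <- match.arg(on_error)
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter < 0 ||
      diameter %% 2 != 0)
    stop("'diameter' must be a non-negative even integer")
  if (length(smiles) == 1L && is.null(names(smiles)) && file.exists(smiles)) {
    rec <- read.delim(smiles, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("smiles", "compound_id"))
    smiles <- setNames(rec$smiles, rec$compound_id)
  }
  if (is.null(names(smiles)) || any(names(smiles) == ""))
    stop("'smiles' must be a named vector (compound_id = SMILES)")
  script <- system.file("python", "ecfp_features.py", package = "bioactree",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".tsv"); on.exit(unlink(infile), add = TRUE)
  writeLines(paste(names(smiles), smiles, sep = "\t"), infile)
  out <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(infile),
                      as.character(as.integer(diameter / 2))),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("feature extraction backend failed:\n", paste(out, collapse = "\n"))
  bad <- sub("^ERROR\t", "", out[startsWith(out, "ERROR\t")])
  if (length(bad)) {
    msg <- paste("unparseable SMILES for compound(s):", paste(bad, collapse = ", "))
    if (on_error == "stop") stop(msg) else warning(msg)
  }
  rows <- strsplit(out[startsWith(out, "FEAT\t")], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, "", 2L)
  sets <- lapply(rows, function(r) r[-(1:2)][nzchar(r[-(1:2)])])
  keep <- setdiff(names(smiles), bad)
  tab <- setNames(sets[match(keep, ids)], keep)
  feature_table(tab)
}
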