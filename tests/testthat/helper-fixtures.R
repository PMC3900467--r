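# Shared fixture builders: everything is generated in code at test time.

# small labeled percent-inhibition matrix; rows targets, cols instances
toy_matrix <- function(values, targets, instances) {
  m <- matrix(values, nrow = length(targets), byrow = TRUE,
              dimnames = list(targets, instances))
  bioactivity_matrix(m)
}

# activity calls straight from a logical matrix (bypassing percent values)
toy_calls <- function(logical_values, targets, instances, threshold = 50) {
  m <- matrix(logical_values, nrow = length(targets), byrow = TRUE,
              dimnames = list(targets, instances))
  structure(m, threshold = threshold,
            instances = bioactree:::parse_instance_labels(instances),
            class = c("activity_calls", "matrix", "array"))
}

# random activity calls for property tests
random_calls <- function(n_targets, n_instances, p = 0.3) {
  instances <- paste0("c", seq_len(ceiling(n_instances / 2)))
  instances <- as.vector(outer(instances, c(1, 10), paste, sep = "@"))[seq_len(n_instances)]
  toy_calls(stats::runif(n_targets * n_instances) < p,
            sprintf("K%02d", seq_len(n_targets)), instances)
}

# a raw (unscaled) SAC series from explicit coordinates
make_series <- function(pct, dist, common = "K1") {
  structure(data.frame(variable = sprintf("V%03d", seq_along(pct)),
                       shared = NA_integer_, raw_percentage = pct,
                       raw_distance = dist, stringsAsFactors = FALSE),
            common = common, mode = "variable", scaled = FALSE,
            class = c("sac_series", "data.frame"))
}

# random binary tree with uniform branch lengths, as an ape phylo
random_branch_tree <- function(n_leaves, min_bl = 0.1, max_bl = 2) {
  tr <- ape::rtree(n_leaves, rooted = FALSE, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  tr
}

# bare numeric values of a distance matrix (class and metric stripped)
dm_values <- function(d) {
  x <- unclass(d)
  attr(x, "metric") <- NULL
  x
}
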