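test_that("shared-activity statistics count concentration instances separately", {
  # K1 active on c1@1 and c1@10, K2 only on c1@10: one shared instance
  calls <- toy_calls(c(TRUE, TRUE,
                       FALSE, TRUE), c("K1", "K2"), c("c1@1", "c1@10"))
  st <- shared_activity_stats(calls)
  expect_identical(st$pair_counts["K1", "K2"], 1)
  expect_identical(st$shared_total[["K1"]], 1)
  expect_identical(st$total_active[["K1"]], 2)
  expect_identical(st$mean_partners[["K1"]], 0.5)
})

test_that("a zero-active target has all shared statistics at zero", {
  calls <- toy_calls(c(TRUE, TRUE,
                       FALSE, FALSE), c("K1", "K0"), c("c1@1", "c2@1"))
  st <- shared_activity_stats(calls)
  expect_identical(st$total_active[["K0"]], 0)
  expect_identical(st$shared_total[["K0"]], 0)
  expect_identical(st$mean_partners[["K0"]], 0)
})

test_that("pairwise shared counts match exhaustive set intersection", {
  set.seed(51)
  for (rep in 1:5) {
    calls <- random_calls(3, 12, p = 0.4)
    st <- shared_activity_stats(calls)
    m <- unclass(calls)
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      expect_equal(st$pair_counts[i, j],
                   sum(colnames(m)[m[i, ]] %in% colnames(m)[m[j, ]]))
    }
    for (i in 1:3) {
      others <- m[-i, , drop = FALSE]
      expect_equal(st$shared_total[[i]],
                   sum(m[i, ] & colSums(others) > 0))
    }
  }
})

test_that("the SAC percentage honors all three normalization modes", {
  # common actives {c1,c2,c3}; variable actives {c2,c3,c4,c5}
  calls <- toy_calls(c(TRUE, TRUE, TRUE, FALSE, FALSE,
                       FALSE, TRUE, TRUE, TRUE, TRUE),
                     c("KC", "KV"), paste0("c", 1:5, "@1"))
  st <- shared_activity_stats(calls)
  expect_equal(sac_raw_percentage("KC", "KV", st, "common"), 100 * 2 / 3)
  expect_equal(sac_raw_percentage("KC", "KV", st, "variable"), 50)
  expect_equal(sac_raw_percentage("KC", "KV", st, "both"), 40)  # union of 5
  expect_equal(sac_raw_percentage("KC", "KV", st, "both",
                                  both_denominator = "sum"), 100 * 2 / 7)
  # identical active sets: 100% in every mode
  calls2 <- toy_calls(c(TRUE, TRUE, TRUE, TRUE), c("K1", "K2"),
                      c("c1@1", "c2@1"))
  st2 <- shared_activity_stats(calls2)
  for (mode in c("common", "variable", "both"))
    expect_equal(sac_raw_percentage("K1", "K2", st2, mode), 100)
  # disjoint active sets: 0% in every mode
  calls3 <- toy_calls(c(TRUE, FALSE, FALSE, TRUE), c("K1", "K2"),
                      c("c1@1", "c2@1"))
  st3 <- shared_activity_stats(calls3)
  for (mode in c("common", "variable", "both"))
    expect_equal(sac_raw_percentage("K1", "K2", st3, mode), 0)
})

test_that("series cover every eligible partner with symmetric distances", {
  set.seed(52)
  calls <- random_calls(5, 16, p = 0.5)
  st <- shared_activity_stats(calls)
  d <- bioactivity_distance_matrix(calls, "tanimoto")
  s <- build_sac_series("K01", st, d, mode = "variable")
  expect_identical(nrow(s), 4L)
  # brute-force reconstruction
  for (r in seq_len(nrow(s))) {
    v <- s$variable[r]
    expect_equal(s$raw_percentage[r],
                 100 * st$pair_counts["K01", v] / st$total_active[[v]])
    expect_equal(s$raw_distance[r], unclass(d)["K01", v])
    expect_equal(s$raw_distance[r], unclass(d)[v, "K01"])
  }
  # zero-active common target is refused
  calls0 <- calls; calls0[2, ] <- FALSE
  st0 <- shared_activity_stats(calls0)
  expect_error(build_sac_series("K02", st0, d), "no active")
})

test_that("zero-denominator partners drop out of series with a warning", {
  calls <- toy_calls(c(TRUE, TRUE,
                       TRUE, FALSE,
                       FALSE, FALSE), c("K1", "K2", "K0"),
                     c("c1@1", "c2@1"))
  st <- shared_activity_stats(calls)
  d <- dist_matrix(matrix(c(0, .2, .4, .2, 0, .3, .4, .3, 0), 3,
                          dimnames = list(c("K1", "K2", "K0"),
                                          c("K1", "K2", "K0"))))
  expect_warning(s <- build_sac_series("K1", st, d, mode = "variable"),
                 "zero denominator")
  expect_identical(s$variable, "K2")
})

test_that("per-series rescaling fixes the means at 0.5 and 50 exactly", {
  s <- make_series(pct = c(20, 40, 60), dist = c(0.2, 0.4, 0.6))
  sc <- scale_series(s)
  expect_equal(sc$sac_score, c(25, 50, 75))
  expect_equal(sc$scaled_distance, c(0.25, 0.5, 0.75))
  # a raw percentage 5x its series mean scores 250 after scaling
  sc2 <- scale_series(make_series(pct = c(100, 25, 0, 0, 0, 0, 0, 15, 0, 60),
                                  dist = seq(0.1, 1, by = 0.1)))
  expect_equal(sc2$sac_score[1], 250)   # 100 is 5x the series mean of 20
  expect_gt(max(sc2$sac_score), 200)
  # scaling an already-scaled series is the identity
  resc <- scale_series(structure(
    data.frame(variable = sc$variable, shared = sc$shared,
               raw_percentage = sc$sac_score, raw_distance = sc$scaled_distance),
    common = "K1", mode = "variable", scaled = FALSE,
    class = c("sac_series", "data.frame")))
  expect_equal(resc$sac_score, sc$sac_score)
  expect_error(scale_series(make_series(c(0, 0), c(.1, .2))), "percentage")
  expect_error(scale_series(make_series(c(10, 20), c(0, 0))), "distance")
})

test_that("rescaled means hit their targets within 1e-9 on random series", {
  set.seed(53)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    sc <- scale_series(make_series(runif(n, 1, 100), runif(n, 0.01, 2)))
    expect_lt(abs(mean(sc$scaled_distance) - 0.5), 1e-9)
    expect_lt(abs(mean(sc$sac_score) - 50), 1e-9)
  }
})

test_that("the quadratic rule classifies exact trends correctly", {
  x <- seq(0, 1.9, length.out = 30)
  down <- scale_series(make_series(100 - 50 * x, x))
  # scale first, then impose exact linearity on the scaled axes via raw ones:
  # use a series already centered at the target means so scaling is identity
  call <- classify_series(down)
  expect_identical(call$verdict, "neighborhood")
  expect_lt(call$slope_040, 0)
  expect_lt(call$slope_067, 0)
  expect_gt(call$r_squared, 0.99)

  flat <- structure(data.frame(variable = paste0("v", 1:10), shared = NA,
                               raw_percentage = rep(50, 10),
                               raw_distance = seq(0.1, 1, by = 0.1)),
                    common = "K1", mode = "variable", scaled = FALSE,
                    class = c("sac_series", "data.frame"))
  expect_identical(classify_series(scale_series(flat))$verdict, "outlier")
})

test_that("degenerate series are outliers with a reason", {
  tiny <- scale_series(make_series(c(10, 20), c(0.1, 0.2)))
  call <- classify_series(tiny)
  expect_identical(call$verdict, "outlier")
  expect_match(call$reason, "fewer")
  same_x <- scale_series(make_series(c(10, 20, 30), c(0.3, 0.3, 0.3)))
  expect_match(classify_series(same_x)$reason, "degenerate")
  expect_error(classify_series(make_series(c(1, 2, 3), c(1, 2, 3))), "scaled")
})

test_that("verdicts are invariant under common positive rescaling of raw axes", {
  set.seed(54)
  for (rep in 1:10) {
    n <- 30
    pct <- runif(n, 5, 95); dst <- runif(n, 0.05, 1.5)
    v1 <- classify_series(scale_series(make_series(pct, dst)))$verdict
    v2 <- classify_series(scale_series(make_series(pct * 7.3, dst * 0.21)))$verdict
    expect_identical(v1, v2)
  }
})

test_that("pure-noise series fail the R-squared gate almost always", {
  set.seed(55)
  hits <- vapply(1:100, function(i) {
    s <- scale_series(make_series(runif(200, 0, 100), runif(200, 0.05, 1.9)))
    classify_series(s)$verdict == "outlier"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the exclusion filter applies the <= threshold boundary", {
  st <- list(shared_total = c(K1 = 16, K2 = 17, K3 = 0, K4 = 100))
  flt <- exclusion_filter(st, threshold = 16)
  expect_setequal(flt$excluded, c("K1", "K3"))
  expect_setequal(flt$kept, c("K2", "K4"))
  # threshold 0 keeps everything sharing at least one activity
  flt0 <- exclusion_filter(st, threshold = 0)
  expect_identical(flt0$excluded, "K3")
  # monotone: the kept set shrinks as the threshold grows
  kept_sizes <- vapply(c(0, 5, 16, 17, 99, 100),
                       function(th) length(exclusion_filter(st, th)$kept), 0L)
  expect_true(all(diff(kept_sizes) <= 0))
})

test_that("the panel-level analysis excludes zero-active targets from series", {
  set.seed(56)
  calls <- random_calls(6, 20, p = 0.5)
  calls[4, ] <- FALSE                     # one never-inhibited target
  d <- bioactivity_distance_matrix(calls, "tanimoto")
  res <- suppressWarnings(run_sac_analysis(calls, d, mode = "variable"))
  expect_identical(res$zero_active, "K04")
  expect_identical(res$n_series, 5L)      # 6-target panel, one zero-active
  expect_false("K04" %in% res$calls_table$target)
})

test_that("a target with actives disjoint from all others is an outlier", {
  set.seed(57)
  calls <- random_calls(5, 24, p = 0.5)
  calls[5, ] <- FALSE
  calls[1:4, 21:24] <- FALSE
  calls[5, 21:24] <- TRUE                 # K05 active only where others are not
  d <- bioactivity_distance_matrix(calls, "tanimoto")
  res <- suppressWarnings(run_sac_analysis(calls, d, mode = "variable"))
  row <- res$calls_table[res$calls_table$target == "K05", ]
  expect_identical(row$verdict, "outlier")
  expect_match(row$reason, "rescaled")
})

test_that("variable normalization finds at least as many neighborhoods as common", {
  p <- generate_panel(synthetic_config(seed = 5, n_clusters = 4,
                                       targets_per_cluster = 5,
                                       n_compounds = 80))
  calls <- binarize(p$matrix)
  prof <- enrichment_profiles(calls, p$features)
  d <- enrichment_distance_matrix(prof)
  fv <- suppressWarnings(run_sac_analysis(calls, d, "variable"))$neighborhood_fraction
  fc <- suppressWarnings(run_sac_analysis(calls, d, "common"))$neighborhood_fraction
  expect_gte(fv, fc)
})
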