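test_that("normalized Manhattan distance matches hand sums", {
  p <- c(a = 0.5, b = 2, c = 1, d = 0.5)
  q <- c(a = 0.5, b = 1, c = 1, d = 0.5)
  expect_identical(manhattan_enrichment_distance(p, q), 0.25)
  expect_identical(manhattan_enrichment_distance(p, p), 0)
  expect_error(manhattan_enrichment_distance(p, q[1:3]), "vocabular")
  expect_error(manhattan_enrichment_distance(p, setNames(q, letters[2:5])),
               "vocabular")
})

test_that("Tanimoto distance follows D = 1 - c/(na + nb - c)", {
  a <- c(1, 1, 1, 0) == 1
  b <- c(0, 1, 1, 0) == 1
  expect_equal(tanimoto_distance(a, b), 1 / 3)
  expect_identical(tanimoto_distance(a, a), 0)
  expect_identical(tanimoto_distance(c(TRUE, TRUE, FALSE, FALSE),
                                     c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_warning(d0 <- tanimoto_distance(c(FALSE, FALSE), c(FALSE, FALSE)),
                 "empty")
  expect_identical(d0, 0)
  expect_error(tanimoto_distance(a, b[1:3]), "length")
})

test_that("Hamming distance counts disagreements, optionally normalized", {
  expect_identical(hamming_distance(c(1, 0, 1, 0) == 1, c(0, 1, 0, 1) == 1), 4L)
  expect_identical(hamming_distance(c(TRUE, TRUE), c(TRUE, TRUE)), 0L)
  expect_identical(hamming_distance(c(TRUE, FALSE), c(TRUE, TRUE),
                                    normalize = TRUE), 0.5)
})

test_that("metrics satisfy symmetry, identity, bounds and triangle inequality", {
  set.seed(31)
  n_bits <- 24
  for (rep in 1:60) {
    x <- runif(n_bits) < 0.4; y <- runif(n_bits) < 0.4; z <- runif(n_bits) < 0.4
    dt <- tanimoto_distance(x, y)
    expect_gte(dt, 0); expect_lte(dt, 1)
    expect_identical(dt, tanimoto_distance(y, x))
    expect_lte(hamming_distance(x, y), n_bits)
    expect_lte(hamming_distance(x, z),
               hamming_distance(x, y) + hamming_distance(y, z))
    p <- runif(6); q <- runif(6); r <- runif(6)
    expect_equal(manhattan_enrichment_distance(p, q),
                 manhattan_enrichment_distance(q, p))
    expect_lte(manhattan_enrichment_distance(p, r),
               manhattan_enrichment_distance(p, q) +
                 manhattan_enrichment_distance(q, r) + 1e-12)
  }
})

test_that("pairwise matrix construction matches a brute-force loop", {
  set.seed(32)
  items <- matrix(runif(5 * 8), 5, 8, dimnames = list(paste0("t", 1:5), NULL))
  d <- build_distance_matrix(items, manhattan_enrichment_distance,
                             name = "manhattan_enrichment")
  for (i in 1:5) for (j in 1:5)
    expect_equal(unclass(d)[i, j],
                 manhattan_enrichment_distance(items[i, ], items[j, ]))
  expect_identical(unclass(d), t(unclass(d)))
  expect_identical(attr(d, "metric"), "manhattan_enrichment")

  same <- matrix(rep(items[1, ], 3), 3, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), NULL))
  expect_true(all(unclass(build_distance_matrix(
    same, manhattan_enrichment_distance)) == 0))
})

test_that("vectorized distance matrices agree with the per-pair metrics", {
  set.seed(33)
  calls <- random_calls(7, 14)
  dt <- bioactivity_distance_matrix(calls, "tanimoto")
  dh <- bioactivity_distance_matrix(calls, "hamming")
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(unclass(dt)[i, j],
                 tanimoto_distance(unclass(calls)[i, ], unclass(calls)[j, ]))
    expect_equal(unclass(dh)[i, j],
                 hamming_distance(unclass(calls)[i, ], unclass(calls)[j, ]))
  }
  cids <- unique(attr(calls, "instances")$compound_id)
  tab <- feature_table(setNames(
    lapply(cids, function(i) sample(paste0("f", 1:15), 5)), cids))
  prof <- enrichment_profiles(calls, tab)
  de <- enrichment_distance_matrix(prof)
  expect_equal(unclass(de)[2, 5],
               manhattan_enrichment_distance(prof[2, ], prof[5, ]))
})

test_that("distance matrices survive TSV and PHYLIP round-trips", {
  set.seed(34)
  calls <- random_calls(5, 10)
  d <- bioactivity_distance_matrix(calls, "tanimoto")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, tsv)
  expect_identical(unclass(read_distance_matrix(tsv, "tanimoto")), unclass(d))
  phy <- withr::local_tempfile(fileext = ".dist")
  write_phylip_distance(d, phy)
  back <- read_phylip_distance(phy, metric = "tanimoto")
  expect_equal(unclass(back), unclass(d), tolerance = 1e-9)
  expect_identical(rownames(back), rownames(d))
})

test_that("invalid distance matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(dist_matrix(m), "symmetric")
  m2 <- matrix(c(1, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(dist_matrix(m2), "diagonal")
  m3 <- matrix(c(0, Inf, Inf, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(dist_matrix(m3), "finite")
})
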