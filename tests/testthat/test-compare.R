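sq <- function(values, labels)
  dist_matrix(matrix(values, length(labels), byrow = TRUE,
                     dimnames = list(labels, labels)))

test_that("cross-density counts inhibitor-linked pairs inside the windows", {
  seqD <- sq(c(0, .7, .7, 0), c("A", "B"))
  bioD <- sq(c(0, .2, .2, 0), c("A", "B"))
  res <- cross_density(seqD, bioD, list(inh1 = c("A", "B")))
  expect_equal(res$fraction, 1)
  expect_identical(nrow(res$rows), 1L)

  # an inhibitor hitting 3 targets contributes C(3,2) = 3 pairs
  labs <- c("A", "B", "C")
  seq3 <- sq(c(0, .7, .1, .7, 0, .9, .1, .9, 0), labs)
  bio3 <- sq(c(0, .2, .5, .2, 0, .2, .5, .2, 0), labs)
  res3 <- cross_density(seq3, bio3, list(inh = labs))
  expect_identical(nrow(res3$rows), 3L)
  # only (A,B) has seq in [0.6,0.8] and bio in [0,0.4]
  expect_equal(res3$fraction, 1 / 3)
})

test_that("cross-density skips pairs missing from a matrix and can dedup", {
  seqD <- sq(c(0, .7, .7, 0), c("A", "B"))
  bioD <- sq(c(0, .2, .2, 0), c("A", "B"))
  expect_warning(
    res <- cross_density(seqD, bioD, list(i1 = c("A", "B", "Z"))), "skipped")
  expect_identical(res$n_skipped, 2L)
  expect_identical(nrow(res$rows), 1L)

  dup <- cross_density(seqD, bioD, list(i1 = c("A", "B"), i2 = c("A", "B")))
  expect_identical(nrow(dup$rows), 2L)
  dd <- cross_density(seqD, bioD, list(i1 = c("A", "B"), i2 = c("A", "B")),
                      dedup = TRUE)
  expect_identical(nrow(dd$rows), 1L)
})

test_that("cross-density matches brute-force enumeration on random fixtures", {
  set.seed(61)
  labs <- paste0("T", 1:8)
  co <- matrix(runif(16), 8)
  seqD <- dist_matrix(`dimnames<-`(as.matrix(dist(co)) / 4, list(labs, labs)))
  bioD <- dist_matrix(`dimnames<-`(as.matrix(dist(co[, 2:1])) / 4, list(labs, labs)))
  sets <- list(i1 = sample(labs, 4), i2 = sample(labs, 3), i3 = sample(labs, 2))
  res <- cross_density(seqD, bioD, sets, seq_window = c(0.1, 0.5),
                       bio_window = c(0, 0.3))
  n_exp <- sum(vapply(sets, function(s) choose(length(s), 2), 0))
  expect_identical(nrow(res$rows), as.integer(n_exp))
  manual <- 0; total <- 0
  for (s in sets) for (i in seq_along(s)) for (j in seq_along(s)) if (i < j) {
    total <- total + 1
    sd <- unclass(seqD)[s[i], s[j]]; bd <- unclass(bioD)[s[i], s[j]]
    if (sd >= 0.1 && sd <= 0.5 && bd >= 0 && bd <= 0.3) manual <- manual + 1
  }
  expect_equal(res$fraction, manual / total)
})

test_that("target sets can be derived per instance or per compound", {
  calls <- toy_calls(c(TRUE, FALSE, TRUE,
                       TRUE, FALSE, FALSE),
                     c("K1", "K2"), c("c1@1", "c1@10", "c2@1"))
  by_inst <- inhibitor_target_sets(calls)
  expect_identical(by_inst[["c1@1"]], c("K1", "K2"))
  expect_false("c1@10" %in% names(by_inst))   # empty sets dropped
  by_cpd <- inhibitor_target_sets(calls, by = "compound")
  expect_identical(by_cpd[["c1"]], c("K1", "K2"))
  expect_identical(by_cpd[["c2"]], "K1")
})

test_that("gatekeeper bins report per-bin identity fractions", {
  labs <- c("A", "B")
  bioD <- sq(c(0, .05, .05, 0), labs)
  gk <- c(A = "T", B = "T")
  res <- gatekeeper_bins(bioD, gk)
  expect_equal(res$bins$fraction_same[1], 1)
  expect_identical(res$bins$n_pairs[1], 1)

  # same-residue pairs only at low distance, different only at high
  labs4 <- c("A", "B", "C", "D")
  m <- matrix(0.8, 4, 4, dimnames = list(labs4, labs4))
  m["A", "B"] <- m["B", "A"] <- 0.1
  m["C", "D"] <- m["D", "C"] <- 0.75
  diag(m) <- 0
  gk4 <- c(A = "T", B = "T", C = "M", D = "F")
  res4 <- gatekeeper_bins(dist_matrix(m), gk4)
  expect_equal(res4$head_average, 1)            # only bin [0.1,0.2) occupied
  expect_equal(res4$tail_average_above_05, 0)
  # only 3 bins are non-empty, so the "top 5" summary spans all of them
  expect_equal(res4$tail_average_top5, mean(c(1, 0, 0)))
})

test_that("unknown residues never count as identical and X is tolerated", {
  labs <- c("A", "B")
  bioD <- sq(c(0, .05, .05, 0), labs)
  res <- gatekeeper_bins(bioD, c(A = "X", B = "X"))
  expect_equal(res$bins$fraction_same[1], 0)
})

test_that("bins conserve pair counts and match brute-force counting", {
  set.seed(62)
  labs <- paste0("T", 1:10)
  co <- matrix(runif(20), 10)
  bioD <- dist_matrix(`dimnames<-`(as.matrix(dist(co)), list(labs, labs)))
  gk <- setNames(sample(c("T", "M", "F"), 10, replace = TRUE), labs)
  res <- gatekeeper_bins(bioD, gk, bin_width = 0.1)
  expect_identical(sum(res$bins$n_pairs), choose(10, 2))
  for (r in seq_len(nrow(res$bins))) {
    lo <- res$bins$bin_lo[r]; hi <- res$bins$bin_hi[r]
    cnt <- same <- 0
    for (i in 1:9) for (j in (i + 1):10) {
      d <- unclass(bioD)[i, j]
      if (d >= lo && d < hi) {
        cnt <- cnt + 1
        if (gk[i] == gk[j]) same <- same + 1
      }
    }
    expect_equal(res$bins$n_pairs[r], cnt)
    expect_equal(res$bins$n_same[r], same)
  }
})

test_that("gatekeeper tables read and validate residue codes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target\tresidue", "K1\tT", "K2\tm"), path)
  gk <- read_gatekeeper_table(path)
  expect_identical(gk, c(K1 = "T", K2 = "M"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("K1\tZZ", bad)
  expect_error(read_gatekeeper_table(bad), "invalid residue")
})

test_that("unannotated targets are skipped with a warning", {
  labs <- c("A", "B", "C")
  bioD <- sq(c(0, .1, .2, .1, 0, .3, .2, .3, 0), labs)
  expect_warning(res <- gatekeeper_bins(bioD, c(A = "T", B = "T")), "skipped")
  expect_identical(sum(res$bins$n_pairs), 1)
})
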