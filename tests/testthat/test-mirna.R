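mk_counts <- function() {
  cnt <- matrix(c(50L, 150L, 10L, 20L,
                  150L, 150L, 90L, 80L), nrow = 2, byrow = TRUE,
                dimnames = list(c("miR-A", "miR-B"),
                                c("g1s1", "g1s2", "g2s1", "g2s2")))
  mirna_counts(cnt, c("g1", "g1", "g2", "g2"))
}

test_that("pooled relative abundance matches arithmetic and sums to 100", {
  mc <- mk_counts()
  ab <- relative_abundance(mc, "g1")
  expect_equal(unname(ab["miR-A"]), 100 * 200 / 500)
  expect_equal(sum(ab), 100, tolerance = 1e-9)

  single <- mirna_counts(matrix(5L, 1, 1, dimnames = list("miR-X", "s1")), "g")
  expect_equal(unname(relative_abundance(single, "g")), 100)
  expect_error(relative_abundance(mc, "nope"), "no samples")
})

test_that("per-sample mode averages fractions and differs from pooling under uneven libraries", {
  mc <- mk_counts()
  ps <- relative_abundance(mc, "g1", mode = "per_sample")
  expect_equal(unname(ps["miR-A"]), 100 * mean(c(50 / 200, 150 / 300)))
  expect_equal(sum(ps), 100, tolerance = 1e-9)
})

test_that("abundance is invariant to uniform library scaling but not per-sample scaling", {
  mc <- mk_counts()
  scaled <- mirna_counts(mc$counts * 3L, as.character(mc$groups))
  expect_equal(relative_abundance(scaled, "g1"), relative_abundance(mc, "g1"))
  uneven <- mc$counts
  uneven[, 1] <- uneven[, 1] * 10L
  mc2 <- mirna_counts(uneven, as.character(mc$groups))
  expect_false(isTRUE(all.equal(relative_abundance(mc2, "g1"),
                                relative_abundance(mc, "g1"))))
})

test_that("count_expressed matches a brute-force row scan", {
  set.seed(51)
  cnt <- matrix(stats::rpois(200, 0.4), 20,
                dimnames = list(sprintf("m%02d", 1:20), sprintf("s%d", 1:10)))
  storage.mode(cnt) <- "integer"
  mc <- mirna_counts(cnt, rep(c("a", "b"), each = 5))
  for (thr in c(1L, 2L, 5L)) {
    brute <- sum(vapply(seq_len(nrow(cnt)),
                        function(i) any(cnt[i, ] >= thr), TRUE))
    expect_equal(count_expressed(mc, thr), brute)
  }
  zero <- mirna_counts(matrix(0L, 3, 2,
                              dimnames = list(letters[1:3], c("s1", "s2"))),
                       c("a", "a"))
  expect_equal(count_expressed(zero), 0L)
  expect_equal(count_expressed(mk_counts()), 2L)
})

test_that("volcano classification partitions a DE table exhaustively", {
  expect_equal(as.character(classify_volcano(4.37, 2.43e-18)), "sig_and_large")
  expect_equal(as.character(classify_volcano(0.2, 0.5)), "neither")
  expect_equal(as.character(classify_volcano(0.5, 0.01)), "sig_only")
  expect_equal(as.character(classify_volcano(-1.5, 0.5)), "large_only")
  # boundary: thresholds are strict
  expect_equal(as.character(classify_volcano(1.0, 0.05)), "neither")

  set.seed(52)
  n <- 300
  cls <- classify_volcano(stats::rnorm(n, 0, 2), stats::runif(n))
  expect_equal(sum(table(cls)), n)
  expect_false(anyNA(cls))
})

test_that("top_regulated reproduces published top-table ordering", {
  down_tbl <- data.frame(
    feature_id = c("hsa-miR-127-3p", "hsa-miR-143-3p", "hsa-let-7c-5p",
                   "hsa-miR-99a-5p", "hsa-miR-10a-5p", "hsa-miR-141-3p"),
    log2fc = c(-1.91, -2.81, -3.09, -3.57, 4.37, 4.67),
    padj = c(1.41e-08, 6.61e-09, 2.11e-04, 1.16e-03, 2.43e-18, 1.31e-15),
    stringsAsFactors = FALSE)
  shuffled <- down_tbl[c(4, 1, 6, 2, 5, 3), ]
  top_down <- top_regulated(shuffled, "down", 10)
  expect_equal(top_down$feature_id[1], "hsa-miR-143-3p")
  expect_equal(top_down$feature_id,
               c("hsa-miR-143-3p", "hsa-miR-127-3p", "hsa-let-7c-5p",
                 "hsa-miR-99a-5p"))
  top_up <- top_regulated(shuffled, "up", 10)
  expect_equal(top_up$feature_id[1], "hsa-miR-10a-5p")

  empty <- down_tbl[0, ]
  expect_equal(nrow(top_regulated(empty, "up", 5)), 0L)
})

test_that("top_regulated breaks p ties by |log2fc| then id and truncates at n", {
  tbl <- data.frame(feature_id = c("b", "a", "c"),
                    log2fc = c(2, 3, 2),
                    padj = c(1e-4, 1e-4, 1e-4), stringsAsFactors = FALSE)
  expect_equal(top_regulated(tbl, "up", 3)$feature_id, c("a", "b", "c"))
  expect_equal(nrow(top_regulated(tbl, "up", 2)), 2L)
})
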