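test_that("expression simulation is reproducible and validates its arguments", {
  a <- simulate_expression(n_genes = 500, n_per_class = 5,
                           classes = c("A", "B"), n_sets = 20,
                           set_size = c(5, 8), n_planted = 3, seed = 81)
  b <- simulate_expression(n_genes = 500, n_per_class = 5,
                           classes = c("A", "B"), n_sets = 20,
                           set_size = c(5, 8), n_planted = 3, seed = 81)
  expect_identical(a, b)
  expect_equal(dim(a$expression), c(500L, 10L))
  expect_length(a$sets, 20L)
  expect_equal(a$annotation$class_label, rep(c("A", "B"), each = 5))
  # pathways are disjoint by construction
  all_members <- unlist(a$sets)
  expect_false(anyDuplicated(all_members) > 0)
  expect_error(simulate_expression(n_genes = 500, n_sets = 20,
                                   set_size = c(5, 8), seed = 1,
                                   planted = list(classA = "NOPE",
                                                  classB = "PW001",
                                                  classC = "PW002")),
               "absent")
  expect_error(simulate_expression(n_genes = 500), "seed")
})

test_that("planted pathways score higher PAS in their active class", {
  sim <- simulate_expression(n_genes = 800, n_per_class = 8,
                             classes = c("A", "B"), n_sets = 30,
                             set_size = c(6, 10), n_planted = 3,
                             effect = 2, noise_sd = 0.2, seed = 7)
  pas <- unclass(pas_matrix(sim$expression, sim$sets, K = 200))
  cls <- sim$annotation$class_label
  for (target in c("A", "B")) {
    for (p in sim$planted[[target]]) {
      expect_gt(mean(pas[p, cls == target]), mean(pas[p, cls != target]))
    }
  }
})

test_that("null simulation shows no systematic class difference in pathway PAS", {
  # effect 0: per-pathway class difference should sit within Monte-Carlo noise
  set.seed(90)
  diffs <- replicate(30, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_expression(n_genes = 300, n_per_class = 6,
                               classes = c("A", "B"), n_sets = 10,
                               set_size = c(5, 8), n_planted = 2,
                               effect = 0, seed = seed)
    pas <- unclass(pas_matrix(sim$expression, sim$sets, K = 100))
    cls <- sim$annotation$class_label
    mean(pas[1, cls == "A"]) - mean(pas[1, cls == "B"])
  })
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("miRNA count simulation honours composition and library sizes", {
  conc <- list(OCCC = c("hsa-miR-10a-5p" = 215, other = 785) * 2,
               Eoma = c("hsa-miR-143-3p" = 145, other = 855) * 2)
  mc <- simulate_mirna_counts(conc, n_per_group = 10,
                              library_size = 1e6, seed = 82)
  expect_s3_class(mc, "mirna_counts")
  expect_equal(unname(colSums(mc$counts)), rep(1e6, 20))
  ab <- relative_abundance(mc, "OCCC")
  expect_lt(abs(ab[["hsa-miR-10a-5p"]] - 21.5), 1)

  single <- simulate_mirna_counts(list(g = c(only = 5)), n_per_group = 2,
                                  library_size = 1000, seed = 1)
  expect_equal(unname(relative_abundance(single, "g")[["only"]]), 100)

  m1 <- simulate_mirna_counts(conc, n_per_group = 3, library_size = 1e4,
                              seed = 9)
  m2 <- simulate_mirna_counts(conc, n_per_group = 3, library_size = 1e4,
                              seed = 9)
  expect_identical(m1$counts, m2$counts)
  expect_error(simulate_mirna_counts(list(g = c(a = -1)), 2, 10, seed = 1),
               "positive")
})

test_that("simulated target lists have the designed consensus", {
  lists <- simulate_target_lists(c("BDNF", "RORA"), extras_per_source = 3,
                                 seed = 83)
  expect_length(lists, 3L)
  down <- unique(unlist(lapply(lists, `[[`, "genes")))
  res <- consensus_targets(down, lists)
  expect_equal(res$consensus, c("BDNF", "RORA"))
  expect_equal(unname(res$counts["union"]), 2L + 9L)

  same <- simulate_target_lists(c("A1", "B2"), extras_per_source = 0, seed = 1)
  expect_equal(same[[1]]$genes, same[[2]]$genes)

  set.seed(84)
  for (rep in 1:5) {
    cons <- sprintf("C%d", seq_len(sample(2:5, 1)))
    k <- sample(0:4, 1)
    lst <- simulate_target_lists(cons, extras_per_source = k, seed = rep)
    gsets <- lapply(lst, `[[`, "genes")
    expect_setequal(Reduce(intersect, gsets), cons)
    extras <- lapply(gsets, setdiff, cons)
    if (k > 0) expect_length(Reduce(intersect, extras), 0L)
  }
})

test_that("generators leave the global random state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_expression(n_genes = 200, n_per_class = 3,
                                classes = c("A", "B"), n_sets = 5,
                                set_size = c(4, 6), n_planted = 1, seed = 5))
  invisible(simulate_mirna_counts(list(g = c(a = 1, b = 2)), 2, 100, seed = 5))
  expect_identical(.Random.seed, before)
})
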