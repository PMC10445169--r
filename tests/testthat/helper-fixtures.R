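# Small fixtures built in code, shared across test files.

# independent brute-force PAS: per-gene loop over an explicit decreasing sort,
# no shared code with pas_matrix()
pas_oracle <- function(x, sets, K) {
  out <- matrix(0, length(sets), ncol(x),
                dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    vals <- x[, j]
    ord <- names(sort(vals, decreasing = TRUE))
    # stable tie-break: among equal values, ascending gene id
    ord <- ord[order(-vals[ord], ord, method = "radix")]
    rank_of <- setNames(seq_along(ord), ord)
    for (s in seq_along(sets)) {
      total <- 0
      for (g in sets[[s]]) {
        ig <- rank_of[g]
        if (!is.na(ig) && ig < K) total <- total + (K - ig)
      }
      out[s, j] <- total / (length(sets[[s]]) * K)
    }
  }
  out
}

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  x <- matrix(round(stats::rexp(n_genes * n_samples, 1 / 50), 3),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  x
}

random_sets <- function(genes, n_sets, seed, min_size = 2, max_size = 8) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(min_size:max_size, 1))
  })
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  sets
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# exhaustive two-sided Fisher p for a 2x2 table: enumerate all tables with the
# observed margins and sum probabilities <= the observed table's
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(k) stats::dhyper(k, c1, n - c1, r1), 0)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements form the category
  mean(hits >= k)
}
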