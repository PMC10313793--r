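test_that("log-normalization matches the closed form and preserves zeros", {
  m <- toy_counts(matrix(c(100, 9900, 0, 7), 2, 2))
  nm <- normalize_counts(m, scale_factor = 1e4)
  # count 100 in a column totalling 10,000 at scale 10,000 -> ln(101)
  expect_equal(nm[1, 1], log(101), tolerance = 1e-12)
  expect_equal(nm[1, 2], 0)
  # single nonzero gene in a column -> ln(10001) whatever the count
  expect_equal(nm[2, 2], log(10001), tolerance = 1e-12)

  zero_col <- toy_counts(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(normalize_counts(zero_col), "c02")
})

test_that("normalization is a monotone transform within each column", {
  set.seed(1)
  m <- toy_counts(matrix(rpois(50 * 10, 2), 50, 10))
  stopifnot(all(colSums(m) > 0))
  nm <- normalize_counts(m)
  for (j in seq_len(ncol(m))) {
    expect_equal(order(m[, j], seq_len(nrow(m))),
                 order(nm[, j], seq_len(nrow(m))))
  }
})

test_that("positivity is count > 0 and classifies the toy four cells", {
  m <- toy_counts(rbind(IL26 = c(1, 1, 0, 0), IL17A = c(1, 0, 1, 0)),
                  genes = c("IL26", "IL17A"))
  calls <- call_positive(m, c("IL26", "IL17A"))
  expect_type(calls, "logical")
  expect_equal(sum(calls["IL26", ] & calls["IL17A", ]), 1)  # double+
  expect_equal(sum(calls["IL26", ] & !calls["IL17A", ]), 1) # IL26 only
  expect_equal(sum(!calls["IL26", ] & calls["IL17A", ]), 1) # IL17A only
  expect_equal(sum(!calls["IL26", ] & !calls["IL17A", ]), 1)
  expect_error(call_positive(m, "IFNG"), "IFNG")
})

test_that("positivity is monotone in counts", {
  set.seed(2)
  m <- toy_counts(matrix(rpois(20 * 6, 1), 20, 6))
  before <- call_positive(m, rownames(m))
  bumped <- m
  idx <- cbind(sample(20, 10, TRUE), sample(6, 10, TRUE))
  bumped[idx] <- bumped[idx] + 1
  after <- call_positive(bumped, rownames(m))
  expect_true(all(after >= before))
})

test_that("variance-inflated genes rank on top of variable-gene selection", {
  set.seed(3)
  n_cells <- 200
  # background genes span a range of means so the mean-variance trend is
  # well determined; 5 genes at mean 5 get strongly inflated variance
  lam <- rep(seq(1, 20, length.out = 19), length.out = 95)
  base <- rbind(
    matrix(rpois(95 * n_cells, rep(lam, n_cells)), 95, n_cells),
    matrix(rpois(5 * n_cells, 10) * rbinom(5 * n_cells, 1, 0.5), 5,
           n_cells)
  )
  hot <- 96:100
  m <- toy_counts(base)
  nm <- normalize_counts(m)
  top5 <- select_variable_genes(nm, 5)
  expect_setequal(top5, rownames(m)[hot])
})

test_that("variable-gene ties break lexicographically and degenerate cases rank by variance", {
  # all genes share one distribution: lexicographic order decides
  m <- toy_counts(matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4))
  # every row identical
  nm <- normalize_counts(m)
  sel <- select_variable_genes(nm, 3)
  expect_equal(sel, sort(rownames(m))[1:3])

  # constant genes never beat varying genes (equal column totals keep
  # the constant genes constant after normalization)
  m2 <- toy_counts(rbind(A = c(5, 5, 5, 5), B = c(1, 9, 2, 8),
                         C = c(9, 1, 8, 2), D = c(5, 5, 5, 5)),
                   genes = c("A", "B", "C", "D"))
  nm2 <- normalize_counts(m2)
  expect_setequal(select_variable_genes(nm2, 2), c("B", "C"))
  expect_error(select_variable_genes(nm2, 0), "positive")
  expect_error(select_variable_genes(nm2, 10), "exceeds")
})

test_that("PCA embedding preserves geometry of low-rank data", {
  set.seed(4)
  n <- 40
  f <- cbind(rnorm(n), rnorm(n))
  load <- matrix(rnorm(2 * 10), 2, 10)
  x <- f %*% load # rank-2, observations x genes
  nm <- t(x)
  dimnames(nm) <- list(sprintf("G%02d", 1:10), sprintf("c%02d", 1:n))
  emb <- embed_pca(nm, rownames(nm), d = 2)
  # rank-2 data: 2 components reproduce all pairwise distances of the
  # scaled data (oracle: full-space distances)
  xs <- scale(t(nm))
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(xs)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # and match prcomp scores up to the fixed sign rule
  pr <- prcomp(t(nm), center = TRUE, scale. = TRUE)
  expect_equal(abs(unname(emb)), abs(unname(pr$x[, 1:2])), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA embedding is deterministic and observation-order invariant", {
  set.seed(5)
  nm <- toy_counts(matrix(rnorm(20 * 30, 5), 20, 30))
  emb1 <- embed_pca(nm, rownames(nm), d = 4)
  perm <- sample(ncol(nm))
  emb2 <- embed_pca(nm[, perm], rownames(nm), d = 4)
  expect_equal(emb1[colnames(nm), ], emb2[colnames(nm), ], tolerance = 1e-8)
  # duplicated observations map to identical embedding rows
  nm3 <- cbind(nm, dup = nm[, 1])
  colnames(nm3) <- c(colnames(nm), "dup")
  emb3 <- embed_pca(nm3, rownames(nm3), d = 3)
  expect_equal(unname(emb3["dup", ]), unname(emb3[colnames(nm)[1], ]),
               tolerance = 1e-8)
  # zero-variance genes are dropped, not fatal, unless too few remain
  nm4 <- rbind(nm, const = rep(1, ncol(nm)))
  rownames(nm4) <- c(rownames(nm), "const")
  expect_message(embed_pca(nm4, rownames(nm4), d = 4), "zero-variance")
  expect_error(suppressMessages(embed_pca(nm4, c("const", rownames(nm)[1]),
                                          d = 2)), "non-degenerate")
})
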