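test_that("relative abundance normalises rows and flags empty samples", {
  prof <- matrix(c(8L, 2L, 0L, 0L), 2L, 2L, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("t1", "t2")))
  rel <- relative_abundance(prof)
  expect_equal(rel["A", ], c(t1 = 0.8, t2 = 0.2))
  expect_equal(unname(rel["B", ]), c(0, 0))          # not NaN-filled
  expect_identical(attr(rel, "empty_samples"), "B")

  with_seed(81L, {
    for (i in 1:20) {
      p <- random_profile(4L, 7L)
      r <- relative_abundance(p)
      expect_equal(unname(rowSums(r)[rowSums(p) > 0])
, rep(1, sum(rowSums(p) > 0)))
    }
  })
})

test_that("rare-taxon grouping pools below 1% and preserves totals", {
  rel <- matrix(c(0.695, 0.30, 0.005,
                  0.69, 0.30, 0.01), 2L, 3L, byrow = TRUE,
                dimnames = list(c("A", "B"), c("big", "mid", "tiny")))
  # tiny averages 0.75% -> pooled
  g <- group_rare(rel)
  expect_true("rare" %in% colnames(g))
  expect_false("tiny" %in% colnames(g))
  expect_equal(rowSums(g), rowSums(rel))

  # a taxon at exactly 1% mean stays separate
  rel2 <- matrix(c(0.69, 0.30, 0.01,
                   0.69, 0.30, 0.01), 2L, 3L, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("big", "mid", "edge")))
  expect_true("edge" %in% colnames(group_rare(rel2)))

  with_seed(82L, {
    for (i in 1:10) {
      p <- relative_abundance(random_profile(5L, 12L, lambda = 3))
      expect_equal(rowSums(group_rare(p, 0.05)), rowSums(p))
    }
  })
})

test_that("rarefaction depth picks the smallest marker-bearing library", {
  expect_equal(choose_depth(c(1.1e6, 2e6, 3e6), c(TRUE, TRUE, TRUE)), 1.1e6)
  expect_equal(choose_depth(c(100, 5000), c(FALSE, TRUE)), 5000)
  expect_equal(choose_depth(c(1200, 5000, 800), c(TRUE, TRUE, FALSE)), 1200)
  expect_error(choose_depth(c(10, 20), c(FALSE, FALSE)), "no library")
})

test_that("rarefaction draws without replacement to exact depth", {
  prof <- random_profile(3L, 6L, lambda = 40, seed = 83L)
  full <- rarefy(prof, min(rowSums(prof)), seed = 1L)
  expect_true(all(rowSums(full) == min(rowSums(prof))))
  same <- suppressWarnings(rarefy(prof, depth = rowSums(prof)[1L], seed = 1L))
  # the largest-total rows survive; the full-draw row equals its counts
  expect_identical(same["P01", ], prof["P01", ])

  expect_error(rarefy(prof, 0), "positive")
  expect_warning(rarefy(prof, max(rowSums(prof))), "excluded")

  # determinism
  expect_identical(rarefy(prof, 50, seed = 9L), rarefy(prof, 50, seed = 9L))
})

test_that("rarefied counts match hypergeometric expectations", {
  counts <- c(a = 30L, b = 10L, c = 60L)
  prof <- structure(matrix(counts, 1L, 3L,
                           dimnames = list("S", names(counts))),
                    class = c("taxon_profile", "matrix"))
  depth <- 40L
  n_seeds <- 1000L
  draws <- vapply(seq_len(n_seeds), function(s) {
    rarefy(prof, depth, seed = s)[1L, ]
  }, numeric(3))
  N <- sum(counts)
  for (i in seq_along(counts)) {
    expectation <- depth * counts[i] / N
    v <- depth * (counts[i] / N) * (1 - counts[i] / N) * (N - depth) / (N - 1)
    se <- sqrt(v / n_seeds)
    expect_lt(abs(mean(draws[i, ]) - expectation), 3 * se)
  }
})

test_that("rarefaction and relative abundance commute in expectation", {
  prof <- random_profile(1L, 5L, lambda = 50, seed = 84L)
  rel_full <- relative_abundance(prof)
  mean_rel <- rowMeans(vapply(1:400, function(s) {
    relative_abundance(rarefy(prof, 30L, seed = s))[1L, ]
  }, numeric(5)))
  expect_equal(unname(mean_rel), unname(rel_full[1L, ]), tolerance = 0.02)
})

test_that("pairwise Pearson correlations handle perfect, null and bad pairs", {
  x <- data.frame(x = seq_len(500))
  y <- data.frame(y = 2 * seq_len(500) + 1)
  expect_equal(pearson_matrix(x, y)$r, 1)

  with_seed(85L, {
    indep <- data.frame(y = stats::rnorm(500))
  })
  expect_lt(abs(pearson_matrix(x, indep)$r), 0.1)

  expect_warning(
    out <- pearson_matrix(data.frame(a = c(1, 2, NA, NA)),
                          data.frame(b = c(1, NA, 2, NA))),
    "fewer than 3")
  expect_identical(nrow(out), 0L)
  expect_warning(pearson_matrix(data.frame(a = rep(1, 5)),
                                data.frame(b = 1:5)), "constant")

  # closed-form agreement on a fixed fixture
  a <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  b <- c(0.7, 2.9, 2.1, 5.0, 3.3)
  r_closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_matrix(data.frame(a), data.frame(b))$r, r_closed,
               tolerance = 1e-12)
})

test_that("between-table regression reports r and R-squared", {
  a <- relative_abundance(random_profile(4L, 10L, lambda = 20, seed = 86L))
  expect_equal(regress_between_tables(a, a)$r_squared, 1)

  # noisy copy: R^2 approximately signal / (signal + noise)
  with_seed(87L, {
    means_a <- colMeans(a)
    noise_sd <- stats::sd(means_a) / 2
    b <- a + matrix(stats::rnorm(length(a), 0, noise_sd), nrow(a))
    fit <- regress_between_tables(a, b)
    snr <- stats::var(means_a) /
      (stats::var(means_a) + noise_sd^2 / nrow(a))
    expect_lt(abs(fit$r_squared - snr), 0.25)
    expect_equal(fit$r_squared, fit$r^2)
  })

  # independent tables stay near zero
  ind1 <- relative_abundance(random_profile(4L, 30L, lambda = 20, seed = 88L))
  ind2 <- relative_abundance(random_profile(4L, 30L, lambda = 20, seed = 89L))
  expect_lt(regress_between_tables(ind1, ind2)$r_squared, 0.2)

  expect_error(
    regress_between_tables(a[, 1:2, drop = FALSE], a[, 1:2, drop = FALSE]),
    "3 shared")
})
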