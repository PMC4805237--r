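test_that("the index matches an independent t-quantile inversion", {
  a <- list(n = 30, mean = 0, sd = 1)
  D <- d_index(a, a)
  expected <- -(t_quantile_inverted(0.75, 29) + t_quantile_inverted(0.99, 29))
  expect_equal(D, expected, tolerance = 1e-8)
  expect_equal(D, -3.145, tolerance = 1e-3)

  # degenerate point masses: only the mean gap remains
  expect_equal(d_index(list(n = 5, mean = 1, sd = 0),
                       list(n = 5, mean = 3, sd = 0)), 2)

  expect_error(d_index(list(n = 1, mean = 0, sd = 0), a), ">= 2")
  expect_error(d_index(a, a, p_focal = 0.4), "quantile")
  expect_error(d_index(a, a, p_reference = 1), "quantile")
})

test_that("the index is monotone in the group statistics", {
  ref <- list(n = 25, mean = 0, sd = 1)
  base <- list(n = 25, mean = 4, sd = 1)
  d0 <- d_index(base, ref)
  # strictly decreasing in each sd
  expect_lt(d_index(list(n = 25, mean = 4, sd = 1.5), ref), d0)
  expect_lt(d_index(base, list(n = 25, mean = 0, sd = 1.5)), d0)
  # strictly increasing in the absolute mean difference
  expect_gt(d_index(list(n = 25, mean = 5, sd = 1), ref), d0)
  expect_equal(d_index(list(n = 25, mean = -4, sd = 1), ref), d0)
})

test_that("t quantiles approach the normal limit at huge df", {
  big <- list(n = 1e6 + 1, mean = 0, sd = 1)
  D <- d_index(big, big)
  expect_equal(D, -(0.6745 + 2.3263), tolerance = 1e-3)
})

test_that("asymmetry comes from which sd receives which multiplier", {
  f <- list(n = 20, mean = 0, sd = 0.5)
  r <- list(n = 20, mean = 3, sd = 2)
  expect_false(isTRUE(all.equal(d_index(f, r), d_index(r, f))))
  # the wide sd hurts most as the reference, where it takes the outer
  # 99% multiplier; with the wide group focal the index is higher
  expect_gt(d_index(r, f), d_index(f, r))
})

test_that("the pairwise matrix flags and reciprocity behave as specified", {
  g2 <- data.frame(taxon = c("a", "b"), n = 30, mean = 0, sd = 1)
  dm2 <- d_matrix(g2)
  expect_false(any(dm2$diagnosable, na.rm = TRUE))
  expect_true(all(is.na(diag(dm2$D))))

  # one far-outlying mean: reciprocally diagnosable from both others
  g3 <- data.frame(taxon = c("a", "b", "out"), n = 30,
                   mean = c(0, 0.5, 10), sd = 1)
  dm3 <- d_matrix(g3)
  expect_true(dm3$reciprocal["out", "a"] && dm3$reciprocal["out", "b"])
  expect_false(dm3$reciprocal["a", "b"])
  # directional flags agree with direct index arithmetic
  expect_equal(dm3$D["out", "a"],
               d_index(g3[3, ], g3[1, ]))
  rep3 <- reciprocal_report(dm3)
  expect_setequal(rep3$per_taxon$out, c("a", "b"))
  expect_equal(rep3$fully_diagnosable, "out")
  expect_true(rep3$any_fully_diagnosable)

  expect_error(d_matrix(data.frame(taxon = c("a", "a"), n = 5, mean = 0,
                                   sd = 1)), "duplicate")
})

test_that("reciprocity is symmetric for arbitrary group configurations", {
  set.seed(14)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    g <- data.frame(taxon = paste0("t", 1:k),
                    n = sample(5:40, k, replace = TRUE),
                    mean = rnorm(k, sd = 3),
                    sd = runif(k, 0.2, 2))
    dm <- d_matrix(g)
    expect_equal(unname(dm$reciprocal), unname(t(dm$reciprocal)))
    # orientation swap transposes the index matrix
    dmT <- d_matrix(g, orientation = "cols_focal")
    expect_equal(dmT$D, t(dm$D), ignore_attr = TRUE)
  }
})

test_that("a positive index implies the 75% rule holds empirically", {
  set.seed(15)
  mu <- 4; n <- 2e5
  f <- list(n = 1e6 + 1, mean = mu, sd = 1)
  r <- list(n = 1e6 + 1, mean = 0, sd = 1)
  expect_gte(d_index(f, r), 0)
  # fraction of focal draws beyond the reference's 99% bound
  bound <- qnorm(0.99)
  frac <- mean(rnorm(n, mu, 1) > bound)
  expect_gte(frac, 0.75 - 0.01)

  # identical normals: both directions reject diagnosability
  same <- list(n = 1e6 + 1, mean = 0, sd = 1)
  expect_lt(d_index(same, same), 0)
  frac0 <- mean(abs(rnorm(n)) > bound)
  expect_lt(frac0, 0.75)
})

test_that("the empirical range rule counts exactly and is directional", {
  x <- c(0, 0, 1, 1, 4, 4, 5, 5)
  ref <- c(2, 3)
  res <- empirical_75(x, ref)
  expect_equal(res$fraction_outside, 1)
  expect_true(res$diagnosable)
  rev <- empirical_75(ref, x)
  expect_equal(rev$fraction_outside, 0)
  expect_false(rev$diagnosable)

  same <- empirical_75(x, x)
  expect_equal(same$fraction_outside, 0)
  expect_false(same$diagnosable)

  expect_error(empirical_75(numeric(0), ref), "non-empty")

  # counts are exact integers before any rounding
  res2 <- empirical_75(c(0, 0, 0, 5, 5, 5, 5), c(1, 4))
  expect_equal(res2$n_outside, 7L)
  expect_equal(res2$fraction_outside, 1)
})

test_that("the empirical matrix mirrors pairwise rule applications", {
  scores <- c(0, 0, 1, 5, 5, 4, 1, 4)
  labels <- c("pale", "pale", "pale", "dark", "dark", "dark", "mid", "mid")
  em <- empirical_75_matrix(scores, labels,
                            levels = c("pale", "mid", "dark"))
  expect_equal(em$D["pale", "dark"],
               empirical_75(c(0, 0, 1), c(5, 5, 4))$fraction_outside)
  # overlapping ranges block the rule in both directions for pale vs mid
  expect_equal(em$D["pale", "mid"], 2 / 3)
  expect_equal(em$D["mid", "pale"], 1 / 2)
  expect_false(em$reciprocal["pale", "mid"])
  # fully separated ranges are reciprocally diagnosable
  expect_true(em$reciprocal["pale", "dark"])
  rep_ <- reciprocal_report(em)
  expect_true("dark" %in% rep_$per_taxon$pale)
  expect_false("mid" %in% rep_$per_taxon$pale)
})

test_that("identical groups yield an empty reciprocal report", {
  g <- data.frame(taxon = c("a", "b", "c"), n = 20, mean = 1, sd = 0.5)
  rep_ <- reciprocal_report(d_matrix(g))
  expect_true(all(lengths(rep_$per_taxon) == 0))
  expect_false(rep_$any_fully_diagnosable)
  expect_equal(rep_$n_reciprocal_pairs, 0)
})
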