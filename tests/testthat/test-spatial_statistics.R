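test_that("first NND matches hand computations and the brute-force oracle", {
  two <- tibble::tibble(x = c(0, 50), y = 0)
  expect_equal(first_nnd(two)$nnd, c(50, 50))

  coll <- tibble::tibble(x = c(0, 3, 7), y = 0)
  expect_equal(first_nnd(coll)$nnd, c(3, 3, 4))

  expect_error(first_nnd(two[1, ]), "fewer than 2")

  rnd <- withr::with_seed(21, tibble::tibble(x = runif(500, 0, 1000),
                                             y = runif(500, 0, 1000)))
  expect_equal(first_nnd(rnd)$nnd,
               oracle_nn1(rnd, rnd, exclude_self = TRUE))

  # 3D distances honored when asked for
  three <- tibble::tibble(x = c(0, 0, 100), y = 0, z = c(0, 40, 0))
  expect_equal(first_nnd(three, use_z = TRUE)$nnd, c(40, 40, 100))
  expect_equal(first_nnd(three, use_z = FALSE)$nnd, c(0, 0, 100))
})

test_that("cross NND is asymmetric and permutation-invariant", {
  q <- tibble::tibble(x = 0, y = 0)
  r <- tibble::tibble(x = c(3, 10), y = c(4, 0))
  expect_equal(cross_nnd(q, r)$nnd, 5)           # 3-4-5 triangle
  expect_equal(cross_nnd(r, q)$nnd, c(5, 10))    # reversed arguments

  same <- tibble::tibble(x = c(1, 2, 3), y = 1)
  expect_equal(cross_nnd(same, same)$nnd, c(0, 0, 0))  # no self-exclusion

  expect_error(cross_nnd(q, r[0, ]), "empty")

  a <- withr::with_seed(22, tibble::tibble(x = runif(200, 0, 500),
                                           y = runif(200, 0, 500)))
  b <- withr::with_seed(23, tibble::tibble(x = runif(300, 0, 500),
                                           y = runif(300, 0, 500)))
  base <- cross_nnd(a, b)$nnd
  perm_a <- withr::with_seed(24, sample.int(nrow(a)))
  perm_b <- withr::with_seed(25, sample.int(nrow(b)))
  shuffled <- cross_nnd(a[perm_a, ], b[perm_b, ])$nnd
  expect_equal(shuffled, base[perm_a])
  expect_equal(cross_nnd(a, b)$nnd, oracle_nn1(a, b))
})

test_that("density estimation converts counts to per-square-micrometre", {
  roi <- roi_rect(0, 1e4, 0, 1e4)  # 10 x 10 um
  pts <- withr::with_seed(26, tibble::tibble(x = runif(100, 0, 1e4),
                                             y = runif(100, 0, 1e4)))
  expect_equal(estimate_density(pts, roi), 1.0)

  roi2 <- roi_rect(0, 7.3e3, 0, 4.1e3)
  pts2 <- withr::with_seed(27, tibble::tibble(x = runif(357, 0, 7.3e3),
                                              y = runif(357, 0, 4.1e3)))
  expect_equal(estimate_density(pts2, roi2), 357 / 29.93, tolerance = 1e-10)

  expect_warning(d0 <- estimate_density(pts[0, ], roi), "density is 0")
  expect_equal(d0, 0)
})

test_that("CSR ensembles have the right region, density and uniformity", {
  csr <- simulate_csr(1, n_molecules = 100, seed = 31)
  expect_equal(unname(attr(csr, "region")), 1e4)  # 10 um side
  expect_equal(nrow(csr), 100)
  expect_identical(csr, simulate_csr(1, n_molecules = 100, seed = 31))
  expect_error(simulate_csr(-1, 100, 1), "density")

  # chi-square uniformity over a 10 x 10 grid of sub-squares
  big <- simulate_csr(10, n_molecules = 1e4, seed = 32)
  side <- attr(big, "region")[["side"]]
  cell <- interaction(pmin(floor(big$x / side * 10), 9),
                      pmin(floor(big$y / side * 10), 9))
  counts <- as.vector(table(cell))
  chi2 <- sum((counts - 100)^2 / 100)
  expect_lt(chi2, qchisq(0.99, df = 99))
})

test_that("normalized histograms integrate to one over the range", {
  h1 <- nnd_histogram(c(11, 12, 13), bin_size = 5, norm_range = c(0, 200))
  expect_equal(h1$density[h1$bin_left == 10], 1 / 5)
  expect_equal(sum(h1$density * 5), 1)

  h2 <- nnd_histogram(c(2, 7, 12), bin_size = 5, norm_range = c(0, 200))
  expect_equal(h2$density[1:3], rep(1 / 15, 3))
  expect_equal(nrow(h2), 40)

  # distances outside the range drop out of the normalization
  h3 <- nnd_histogram(c(2, 7, 500), bin_size = 5, norm_range = c(0, 200))
  expect_equal(sum(h3$density * 5), 1)
  expect_equal(attr(h3, "n_in_range"), 2)

  expect_error(nnd_histogram(numeric(0)), "zero distances")
  expect_error(nnd_histogram(c(300, 400), norm_range = c(0, 200)), "normalization range")

  rnd <- withr::with_seed(33, runif(5000, 0, 180))
  h4 <- nnd_histogram(rnd)
  expect_equal(sum(h4$density * attr(h4, "bin_size")), 1)
})

test_that("delta area follows its arithmetic definition and stays in [0, 1]", {
  base <- nnd_histogram(withr::with_seed(34, runif(4000, 0, 200)))
  expect_equal(delta_area(base, base)$delta_area, 0)

  # one 5-nm bin exceeding by 0.008 per nm -> 0.04
  h_exp <- base
  h_csr <- base
  h_exp$density <- rep(1 / 200, 40)
  h_csr$density <- rep(1 / 200, 40)
  h_exp$density[3] <- h_exp$density[3] + 0.008
  h_exp$density[-3] <- h_exp$density[-3] - 0.008 * 5 / (39 * 5)
  da <- delta_area(h_exp, h_csr)
  expect_equal(da$delta_area, 0.04)

  mismatched <- nnd_histogram(runif(100, 0, 100), bin_size = 10)
  expect_error(delta_area(base, mismatched), "identical bin")

  # [0, 1] bound over random unit-density pairs
  for (s in 35:39) {
    a <- nnd_histogram(withr::with_seed(s, runif(500, 0, 250)))
    b <- nnd_histogram(withr::with_seed(s + 10, rlnorm(500, log(40), 0.8)))
    v <- delta_area(a, b)$delta_area
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("per-condition aggregation uses mean and population SD", {
  h <- nnd_histogram(c(11, 12, 13), bin_size = 5, norm_range = c(0, 20))
  single <- aggregate_histograms(list(h))
  expect_equal(single$mean_density, h$density)
  expect_equal(single$sd_density, rep(0, nrow(h)))
  expect_equal(aggregate_histograms(list(h, h))$sd_density, rep(0, nrow(h)))

  h1 <- h
  h2 <- h
  h1$density <- c(0.1, 0, 0, 0)
  h2$density <- c(0.3, 0, 0, 0)
  agg <- aggregate_histograms(list(h1, h2))
  expect_equal(agg$mean_density[1], 0.2)
  expect_equal(agg$sd_density[1], 0.1)  # population SD, not sample SD
})

test_that("one-way ANOVA across conditions matches hand computation", {
  same <- tibble::tibble(condition = rep(c("a", "b"), each = 2),
                         delta_area = c(0.1, 0.2, 0.1, 0.2))
  fit0 <- compare_conditions(same)
  expect_equal(glance(fit0)$statistic, 0)
  expect_equal(glance(fit0)$p_value, 1)
  expect_equal(glance(fit0)$stars, "n.s.")

  worked <- tibble::tibble(condition = rep(c("a", "b"), each = 2),
                           delta_area = c(0, 1, 2, 3))
  fit1 <- compare_conditions(worked)
  g <- glance(fit1)
  expect_equal(g$statistic, 8)
  expect_equal(g$p_value, pf(8, 1, 2, lower.tail = FALSE))
  expect_equal(g$p_value, 0.10557, tolerance = 1e-4)

  td <- tidy(fit1)
  expect_equal(td$mean, c(0.5, 2.5))
  expect_equal(td$sd, c(0.5, 0.5))  # population SD

  expect_error(compare_conditions(same[1:2, ]), "at least 2 conditions")
  expect_error(compare_conditions(same[1:3, ]), "at least 2 values")
})
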