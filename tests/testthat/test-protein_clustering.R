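test_that("local maxima: single site, well-separated sites, oracle equivalence", {
  one <- make_site_locs(tibble::tibble(x = 100, y = 100), n_per_site = 20,
                        sigma = 1, seed = 1)
  expect_equal(nrow(detect_local_maxima(one, radius = 10, min_locs = 10)), 1)

  two <- make_site_locs(tibble::tibble(x = c(0, 100), y = 0), n_per_site = 15,
                        sigma = 1, seed = 2)
  expect_equal(nrow(detect_local_maxima(two, radius = 10, min_locs = 10)), 2)

  # mixed scene vs exhaustive neighbor-count oracle
  mixed <- withr::with_seed(3, dplyr::bind_rows(
    make_site_locs(tibble::tibble(x = runif(6, 0, 300), y = runif(6, 0, 300)),
                   n_per_site = 25, sigma = 2, seed = 4),
    tibble::tibble(channel = "receptor", frame = 1:50,
                   x = runif(50, 0, 300), y = runif(50, 0, 300),
                   photons = 5000, lpx = 2, lpy = 2, site = NA)
  ))
  got <- detect_local_maxima(mixed, radius = 10, min_locs = 10)
  expect_equal(got$record, oracle_local_maxima(mixed, 10, 10))

  expect_equal(nrow(detect_local_maxima(mixed[0, ], radius = 10, min_locs = 10)), 0)
})

test_that("cluster assignment matches the nearest-maximum oracle and tie rule", {
  sites <- tibble::tibble(x = c(0, 30), y = 0)
  locs <- make_site_locs(sites, n_per_site = 15, sigma = 1.5, seed = 5)
  maxima <- detect_local_maxima(locs, radius = 10, min_locs = 10)
  got <- assign_clusters(locs, maxima, radius = 10)
  expect_equal(got$cluster_id, oracle_assign(locs, maxima, 10))

  # equidistant point goes to the lower cluster id
  maxima2 <- tibble::tibble(record = 1:2, x = c(0, 10), y = 0, n_neighbors = 1L)
  pt <- tibble::tibble(x = 5, y = 0, lpx = 1, lpy = 1)
  expect_equal(assign_clusters(pt, maxima2, radius = 10)$cluster_id, 1L)

  # localizations near no maximum stay unassigned
  far <- tibble::tibble(x = 500, y = 500, lpx = 1, lpy = 1)
  expect_true(is.na(assign_clusters(far, maxima2, radius = 10)$cluster_id))
})

test_that("weighted centers use squared-inverse-precision weights", {
  single <- tibble::tibble(x = 3, y = 4, lpx = 2, lpy = 2)
  expect_equal(weighted_center(single)$x, 3)
  expect_equal(weighted_center(single)$n_locs, 1)

  # equal precisions reduce to the arithmetic mean (machine precision)
  eq <- tibble::tibble(x = c(1, 2, 7), y = c(0, 3, 9), lpx = 1.7, lpy = 1.7)
  wc <- weighted_center(eq)
  expect_equal(wc$x, mean(eq$x))
  expect_equal(wc$y, mean(eq$y))

  # worked example: weights [1, 1, 0.25] -> 15/2.25
  m <- tibble::tibble(x = c(0, 10, 20), y = 0, lpx = c(1, 1, 2), lpy = 1)
  expect_equal(weighted_center(m)$x, 15 / 2.25)

  # random members vs direct arithmetic oracle
  rnd <- withr::with_seed(6, tibble::tibble(
    x = rnorm(40, 50, 2), y = rnorm(40, 80, 2),
    lpx = rlnorm(40, log(2), 0.3), lpy = rlnorm(40, log(2), 0.3)
  ))
  ora <- oracle_weighted_center(rnd)
  wc2 <- weighted_center(rnd)
  expect_equal(wc2$x, ora[["x"]])
  expect_equal(wc2$y, ora[["y"]])

  expect_error(weighted_center(m[0, ]), "at least one")
})

test_that("cluster_channel recovers isolated sites and honors min_locs", {
  sites <- withr::with_seed(7, tibble::tibble(
    x = rep(seq(0, 900, by = 100), 5),
    y = rep(seq(0, 400, by = 100), each = 10)
  ))
  locs <- make_site_locs(sites, n_per_site = 20, sigma = 2, seed = 8)
  pos <- cluster_channel(locs, radius = 10, min_locs = 10)
  expect_equal(nrow(pos), 50)
  expect_identical(pos$cluster_id, seq_len(50))
  expect_true(all(pos$n_locs >= 10))

  expect_equal(nrow(cluster_channel(locs, radius = 10, min_locs = 25)), 0)

  # recovered center within 3 standard errors of the truth
  one <- make_site_locs(tibble::tibble(x = 500, y = 500), n_per_site = 100,
                        sigma = 2, seed = 9)
  p1 <- cluster_channel(one, radius = 10, min_locs = 10)
  se <- 2 / sqrt(100)
  expect_lt(abs(p1$x - 500), 3 * se)
  expect_lt(abs(p1$y - 500), 3 * se)
})

test_that("clustering is translation-equivariant", {
  sites <- withr::with_seed(10, tibble::tibble(x = runif(8, 0, 400),
                                               y = runif(8, 0, 400)))
  locs <- make_site_locs(sites, n_per_site = 20, sigma = 2, seed = 11)
  base <- cluster_channel(locs, radius = 10, min_locs = 10)
  shifted <- dplyr::mutate(locs, x = x + 123.4, y = y - 56.7)
  moved <- cluster_channel(shifted, radius = 10, min_locs = 10)
  expect_equal(moved$x, base$x + 123.4)
  expect_equal(moved$y, base$y - 56.7)
  expect_equal(moved$n_locs, base$n_locs)
})

test_that("weighted-center error shrinks as sigma over sqrt(n)", {
  sigma <- 2
  rmse_at <- function(n) {
    errs <- vapply(1:40, function(r) {
      locs <- make_site_locs(tibble::tibble(x = 0, y = 0), n_per_site = n,
                             sigma = sigma, seed = 100 + r)
      wc <- weighted_center(locs)
      sqrt(wc$x^2 + wc$y^2)
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r10 <- rmse_at(10)
  r100 <- rmse_at(100)
  r1000 <- rmse_at(1000)
  expect_gt(r10, r100)
  expect_gt(r100, r1000)
  # 2D RMSE should track sigma * sqrt(2 / n) within a factor of 2
  for (pair in list(c(10, r10), c(100, r100), c(1000, r1000))) {
    expected <- sigma * sqrt(2 / pair[1])
    expect_gt(pair[2], expected / 2)
    expect_lt(pair[2], expected * 2)
  }
})
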