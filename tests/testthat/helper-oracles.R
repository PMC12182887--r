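# Independent brute-force oracles. These deliberately avoid the package's
# grid index and tidy plumbing: plain O(n^2) loops and direct arithmetic.

oracle_nn1 <- function(query, reference, use_z = FALSE, exclude_self = FALSE) {
  vapply(seq_len(nrow(query)), function(i) {
    dx <- reference$x - query$x[i]
    dy <- reference$y - query$y[i]
    dz <- if (use_z) reference$z - query$z[i] else 0
    d <- sqrt(dx^2 + dy^2 + dz^2)
    if (exclude_self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

oracle_count_within <- function(locs, radius) {
  n <- nrow(locs)
  vapply(seq_len(n), function(i) {
    sum(sqrt((locs$x - locs$x[i])^2 + (locs$y - locs$y[i])^2) <= radius)
  }, integer(1))
}

# same two-scale rule as the package, written longhand: counts and
# suppression at radius/2, ties to the lower record index
oracle_local_maxima <- function(locs, radius, min_locs) {
  scale <- radius / 2
  n <- nrow(locs)
  cnt <- oracle_count_within(locs, scale)
  keep <- integer(0)
  for (i in seq_len(n)) {
    if (cnt[i] < min_locs) next
    d <- sqrt((locs$x - locs$x[i])^2 + (locs$y - locs$y[i])^2)
    nb <- setdiff(which(d <= scale), i)
    if (all(cnt[nb] < cnt[i] | (cnt[nb] == cnt[i] & nb > i))) {
      keep <- c(keep, i)
    }
  }
  keep
}

oracle_assign <- function(locs, maxima, radius) {
  vapply(seq_len(nrow(locs)), function(i) {
    d <- sqrt((maxima$x - locs$x[i])^2 + (maxima$y - locs$y[i])^2)
    ok <- which(d <= radius)
    if (length(ok) == 0) return(NA_integer_)
    ok[which.min(d[ok])]  # which.min takes the first, i.e. lowest id, on ties
  }, integer(1))
}

oracle_weighted_center <- function(members) {
  wx <- 1 / members$lpx^2
  wy <- 1 / members$lpy^2
  c(x = sum(wx * members$x) / sum(wx), y = sum(wy * members$y) / sum(wy))
}

# even-odd ray casting; only meaningful for points not on the boundary
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py) &
      px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# quick localization table around given true site coordinates
make_site_locs <- function(sites, n_per_site = 20, sigma = 1, seed = 1,
                           channel = "receptor") {
  withr::with_seed(seed, {
    idx <- rep(seq_len(nrow(sites)), each = n_per_site)
    n <- length(idx)
    tibble::tibble(
      channel = channel,
      frame = seq_len(n),
      x = sites$x[idx] + rnorm(n, 0, sigma),
      y = sites$y[idx] + rnorm(n, 0, sigma),
      photons = 5000,
      lpx = sigma, lpy = sigma,
      site = idx
    )
  })
}
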