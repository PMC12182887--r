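#' First nearest-neighbor distances
#'
#' For every protein position, the Euclidean distance to its nearest
#' *other* position in the same set (self excluded). Duplicated
#' coordinates are legal and yield zero distances.
#'
#' @param positions Tibble of positions with `x`, `y` (and optionally
#'   `z`) in nm.
#' @param use_z Use 3D distances? Default `FALSE` (lateral analysis).
#' @return `positions` with columns `nnd` (nm) and `nn_id` (row index of
#'   the neighbor) added.
#' @export
first_nnd <- function(positions, use_z = FALSE) {
  check_positions(positions)
  if (nrow(positions) < 2) {
    abort("first NND is undefined for fewer than 2 positions")
  }
  use_z <- isTRUE(use_z) && has_z(positions)
  z <- zero_or(positions, "z")
  res <- cpp_nn1(positions$x, positions$y, z,
                 positions$x, positions$y, z,
                 use_z, TRUE)
  positions$nnd <- res$dist
  positions$nn_id <- res$index
  positions
}

#' Cross nearest-neighbor distances
#'
#' For every position in `query`, the distance to the nearest position in
#' `reference` (a different channel, so there is no self-exclusion). The
#' measure is asymmetric: `cross_nnd(a, b)` generally differs from
#' `cross_nnd(b, a)`.
#'
#' @param query,reference Position tibbles with `x`, `y` (and `z`) in nm.
#' @inheritParams first_nnd
#' @return `query` with columns `nnd` and `nn_id` (row in `reference`)
#'   added.
#' @export
cross_nnd <- function(query, reference, use_z = FALSE) {
  check_positions(query, "query")
  check_positions(reference, "reference")
  if (nrow(reference) == 0) abort("reference set is empty")
  use_z <- isTRUE(use_z) && has_z(query) && has_z(reference)
  res <- cpp_nn1(query$x, query$y, zero_or(query, "z"),
                 reference$x, reference$y, zero_or(reference, "z"),
                 use_z, FALSE)
  query$nnd <- res$dist
  query$nn_id <- res$index
  query
}

#' Protein density inside an ROI
#'
#' Count of positions inside (or on the boundary of) the ROI divided by
#' the ROI area, in molecules per square micrometre. This measured density
#' parameterizes the CSR null.
#'
#' @param positions Position tibble.
#' @param roi A `paint_roi`.
#' @return Density in um^-2 (a bare number).
#' @export
estimate_density <- function(positions, roi) {
  check_positions(positions)
  stopifnot(inherits(roi, "paint_roi"))
  n <- if (nrow(positions) == 0) 0L else nrow(filter_roi(positions, roi))
  if (n == 0) warn("no positions inside the ROI; density is 0")
  n / (roi$area / 1e6)
}

#' Simulate a complete-spatial-randomness (CSR) ensemble
#'
#' Places `n_molecules` points uniformly and independently in a square
#' whose side is chosen so the point density equals `density`; this is the
#' null model of no molecular clustering. The default ensemble size of
#' five million molecules makes the null NND curve essentially noise-free.
#'
#' @param density Target density in um^-2.
#' @param n_molecules Number of simulated molecules (default 5e6).
#' @param seed Integer seed; the ensemble is reproducible from it.
#' @return Tibble of `x`, `y` (nm) with attributes `region` (side length
#'   nm), `density`, and `seed`.
#' @export
simulate_csr <- function(density, n_molecules = 5e6, seed = 1) {
  if (!is.numeric(density) || density <= 0) abort("density must be > 0")
  stopifnot(n_molecules >= 2)
  side <- sqrt(n_molecules / density) * 1e3  # nm
  out <- withr::with_seed(seed, tibble::tibble(
    x = runif(n_molecules, 0, side),
    y = runif(n_molecules, 0, side)
  ))
  attr(out, "region") <- c(side = side)
  attr(out, "density") <- density
  attr(out, "seed") <- seed
  out
}

#' Normalized nearest-neighbor distance histogram
#'
#' Bins NND values into `bin_size`-wide bins aligned to zero and
#' normalizes the heights to a probability density over
#' `norm_range`: the sum of `density * bin_size` over the range is 1.
#' Distances outside the range are excluded from the normalization, so
#' histograms of different conditions and of their CSR nulls are directly
#' comparable and the delta-area statistic is bounded by 1. Bins are
#' right-open, `[a, a + bin_size)`.
#'
#' @param nnd Numeric vector of distances (nm) or a tibble with an `nnd`
#'   column as returned by [first_nnd()]/[cross_nnd()].
#' @param bin_size Bin width in nm (default 5).
#' @param norm_range Two-element numeric range over which to bin and
#'   normalize, default `c(0, 200)` nm. `NULL` extends the range to cover
#'   the largest distance.
#' @return A tibble of class `nnd_histogram` with columns `bin_left`,
#'   `bin_mid`, `bin_right`, `count`, `density` and attributes `bin_size`,
#'   `norm_range`, `n_query`, `n_in_range`.
#' @export
nnd_histogram <- function(nnd, bin_size = 5, norm_range = c(0, 200)) {
  if (is.data.frame(nnd)) {
    if (!"nnd" %in% names(nnd)) abort("data frame input must have an `nnd` column")
    nnd <- nnd$nnd
  }
  stopifnot(is.numeric(nnd), bin_size > 0)
  if (length(nnd) == 0) abort("cannot build a histogram from zero distances")
  if (is.null(norm_range)) {
    norm_range <- c(0, ceiling(max(nnd) / bin_size) * bin_size)
    if (norm_range[2] == 0) norm_range[2] <- bin_size
  }
  stopifnot(length(norm_range) == 2, norm_range[2] > norm_range[1],
            norm_range[1] >= 0)
  edges <- seq(floor(norm_range[1] / bin_size) * bin_size,
               ceiling(norm_range[2] / bin_size) * bin_size,
               by = bin_size)
  in_range <- nnd >= edges[1] & nnd < edges[length(edges)]
  n_in <- sum(in_range)
  if (n_in == 0) abort("no distances fall inside the normalization range")
  counts <- tabulate(pmin(floor((nnd[in_range] - edges[1]) / bin_size), length(edges) - 2L) + 1L,
                     nbins = length(edges) - 1L)
  out <- tibble::tibble(
    bin_left = edges[-length(edges)],
    bin_mid = edges[-length(edges)] + bin_size / 2,
    bin_right = edges[-1],
    count = counts,
    density = counts / (n_in * bin_size)
  )
  class(out) <- c("nnd_histogram", class(out))
  attr(out, "bin_size") <- bin_size
  attr(out, "norm_range") <- c(edges[1], edges[length(edges)])
  attr(out, "n_query") <- length(nnd)
  attr(out, "n_in_range") <- n_in
  out
}

#' Modal bin center of a histogram
#'
#' The center of the highest-density bin; ties go to the shortest
#' distance. Used to summarize spacings (dimer separation, label offsets).
#'
#' @param hist An `nnd_histogram` (or any tibble with `bin_mid` and
#'   `density`).
#' @return The modal bin center in nm.
#' @export
modal_bin_center <- function(hist) {
  stopifnot(all(c("bin_mid", "density") %in% names(hist)))
  hist$bin_mid[which.max(hist$density)]
}

check_same_binning <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$bin_left, b$bin_left)) ||
      !isTRUE(all.equal(a$bin_right, b$bin_right))) {
    abort("histograms must share identical bin edges and bin size")
  }
  invisible(TRUE)
}

#' Delta-area clustering statistic
#'
#' Quantifies the excess of short nearest-neighbor distances over the CSR
#' expectation: per bin within `range`, the positive part of
#' (experimental density - CSR density), summed and multiplied by the bin
#' size. Equivalently, the area of the experimental NND histogram lying
#' above the CSR curve over 0-200 nm. Because both histograms are unit
#' densities over the range, the statistic lies in `[0, 1]`; 0 means
#' CSR-like, larger values mean more clustering / co-localization.
#'
#' @param experimental,csr `nnd_histogram` objects on identical bins.
#' @param range Evaluation range in nm, default `c(0, 200)`.
#' @param label Optional condition label carried into summaries.
#' @return An object of class `delta_area`: see [tidy()] for the per-bin
#'   differences and [glance()] for the scalar.
#' @export
delta_area <- function(experimental, csr, range = c(0, 200), label = NULL) {
  check_same_binning(experimental, csr)
  bin_size <- attr(experimental, "bin_size") %||% (experimental$bin_right[1] - experimental$bin_left[1])
  keep <- experimental$bin_left >= range[1] & experimental$bin_right <= range[2]
  diffs <- tibble::tibble(
    bin_mid = experimental$bin_mid[keep],
    density_experimental = experimental$density[keep],
    density_csr = csr$density[keep],
    difference = experimental$density[keep] - csr$density[keep],
    positive_part = pmax(0, experimental$density[keep] - csr$density[keep])
  )
  structure(list(
    delta_area = sum(diffs$positive_part) * bin_size,
    differences = diffs,
    bin_size = bin_size,
    range = range,
    label = label
  ), class = "delta_area")
}

#' @export
print.delta_area <- function(x, ...) {
  cat(sprintf("<delta_area>%s %.4f (bin %g nm over [%g, %g] nm)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label, ":"),
              x$delta_area, x$bin_size, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
tidy.delta_area <- function(x, ...) x$differences

#' @export
glance.delta_area <- function(x, ...) {
  tibble::tibble(delta_area = x$delta_area, bin_size = x$bin_size,
                 range_min = x$range[1], range_max = x$range[2],
                 label = x$label %||% NA_character_)
}

#' Aggregate per-cell histograms for one condition
#'
#' Per-bin arithmetic mean and population standard deviation of the
#' normalized densities across cells, the summary drawn as a solid mean
#' curve with a standard-deviation band.
#'
#' @param histograms List of `nnd_histogram` objects on identical bins.
#' @return Tibble: `bin_left`, `bin_mid`, `bin_right`, `mean_density`,
#'   `sd_density`, `n_cells`.
#' @export
aggregate_histograms <- function(histograms) {
  stopifnot(is.list(histograms), length(histograms) >= 1)
  ref <- histograms[[1]]
  purrr::walk(histograms, check_same_binning, b = ref)
  dens <- vapply(histograms, function(h) h$density, numeric(nrow(ref)))
  dens <- matrix(dens, nrow = nrow(ref))
  tibble::tibble(
    bin_left = ref$bin_left,
    bin_mid = ref$bin_mid,
    bin_right = ref$bin_right,
    mean_density = rowMeans(dens),
    sd_density = apply(dens, 1, pop_sd),
    n_cells = length(histograms)
  )
}

#' Compare delta areas across conditions by one-way ANOVA
#'
#' Tests whether the mean per-cell delta area differs between treatment
#' conditions with the classical one-way (fixed-effects, equal-variance)
#' ANOVA; the F statistic is referred to its upper tail. Per-condition
#' summaries report mean and population standard deviation. Significance
#' stars: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else `n.s.`.
#'
#' @param data Data frame with one row per cell.
#' @param value Column of per-cell delta areas (tidy-eval), default
#'   `delta_area`.
#' @param group Column of condition labels, default `condition`.
#' @return Object of class `condition_anova`; `tidy()` gives per-condition
#'   mean/sd/n, `glance()` the F statistic, degrees of freedom, p-value
#'   and star label.
#' @export
compare_conditions <- function(data, value = delta_area, group = condition) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- tibble::tibble(
    value = rlang::eval_tidy(value, data),
    group = as.character(rlang::eval_tidy(group, data))
  )
  counts <- dplyr::count(df, .data$group)
  if (nrow(counts) < 2) abort("need at least 2 conditions")
  if (any(counts$n < 2)) abort("every condition needs at least 2 values")
  fit <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  summaries <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = pop_sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(condition = "group")
  p <- unname(fit$p.value)
  structure(list(
    statistic = unname(fit$statistic),
    df1 = unname(fit$parameter[1]),
    df2 = unname(fit$parameter[2]),
    p_value = p,
    stars = p_stars(p),
    summaries = summaries
  ), class = "condition_anova")
}

#' @export
print.condition_anova <- function(x, ...) {
  cat(sprintf("<condition_anova> F(%g, %g) = %.4g, p = %.4g (%s)\n",
              x$df1, x$df2, x$statistic, x$p_value, x$stars))
  print(x$summaries)
  invisible(x)
}

#' @export
tidy.condition_anova <- function(x, ...) x$summaries

#' @export
glance.condition_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value, stars = x$stars)
}
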