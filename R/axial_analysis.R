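#' Axial (z) profile of a channel
#'
#' Histograms the z coordinates of the protein positions inside an ROI
#' and locates the layer peak by a least-squares single-Gaussian fit to
#' the bin counts (amplitude, center, width). If the fit does not
#' converge the modal bin center is used instead (`method = "modal"`).
#' Two such profiles from different channels give the membrane's axial
#' layer separation via [peak_separation()].
#'
#' @param positions Position tibble carrying `z` (nm).
#' @param roi Optional `paint_roi`; default uses all positions.
#' @param bin_size z bin width in nm, default 5.
#' @param channel Optional label; defaults to the `channel` column value.
#' @return Object of class `axial_profile` with the histogram, the fitted
#'   peak (nm), the fitted Gaussian sigma (nm), and the fit method.
#' @export
axial_profile <- function(positions, roi = NULL, bin_size = 5, channel = NULL) {
  check_positions(positions)
  if (!"z" %in% names(positions)) abort("axial_profile() needs 3D positions (a z column)")
  if (!is.null(roi)) positions <- filter_roi(positions, roi)
  if (nrow(positions) < 10) {
    abort("fewer than 10 positions in the ROI: axial fit would be unreliable")
  }
  if (is.null(channel) && "channel" %in% names(positions)) {
    channel <- as.character(positions$channel[1])
  }
  z <- positions$z
  if (diff(range(z)) == 0) {
    # delta layer: the peak is the (single) value itself
    left <- floor(z[1] / bin_size) * bin_size
    hist <- tibble::tibble(bin_left = left, bin_mid = left + bin_size / 2,
                           bin_right = left + bin_size, count = length(z))
    return(structure(list(channel = channel %||% NA_character_,
                          histogram = hist, peak = z[1], width = 0,
                          n = length(z), bin_size = bin_size,
                          method = "modal"),
                     class = "axial_profile"))
  }
  edges <- seq(floor(min(z) / bin_size) * bin_size,
               ceiling(max(z) / bin_size) * bin_size + bin_size,
               by = bin_size)
  counts <- tabulate(pmin(floor((z - edges[1]) / bin_size), length(edges) - 2L) + 1L,
                     nbins = length(edges) - 1L)
  hist <- tibble::tibble(
    bin_left = edges[-length(edges)],
    bin_mid = edges[-length(edges)] + bin_size / 2,
    bin_right = edges[-1],
    count = counts
  )
  # moment-based starting values keep the fit stable for unimodal layers
  mu0 <- sum(hist$bin_mid * counts) / sum(counts)
  s0 <- sqrt(sum((hist$bin_mid - mu0)^2 * counts) / sum(counts))
  s0 <- max(s0, bin_size / 2)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      count ~ a * exp(-(bin_mid - mu)^2 / (2 * s^2)),
      data = hist,
      start = list(a = max(counts), mu = mu0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- coef(m)
    if (cf[["mu"]] < min(z) || cf[["mu"]] > max(z)) stop("peak outside data range")
    list(peak = unname(cf[["mu"]]), width = abs(unname(cf[["s"]])), method = "gaussian")
  }, error = function(e) {
    list(peak = hist$bin_mid[which.max(counts)], width = s0, method = "modal")
  })
  structure(list(
    channel = channel %||% NA_character_,
    histogram = hist,
    peak = fit$peak,
    width = fit$width,
    n = nrow(positions),
    bin_size = bin_size,
    method = fit$method
  ), class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("<axial_profile> channel %s: peak %.2f nm (sigma %.2f nm, %s fit, n = %d)\n",
              x$channel, x$peak, x$width, x$method, x$n))
  invisible(x)
}

#' @export
tidy.axial_profile <- function(x, ...) x$histogram

#' @export
glance.axial_profile <- function(x, ...) {
  tibble::tibble(channel = x$channel, peak = x$peak, width = x$width,
                 n = x$n, method = x$method)
}

#' Peak-to-peak axial separation of two channels
#'
#' Absolute difference of the fitted axial peaks of two profiles from the
#' same region, e.g. an intracellularly-labeled receptor layer versus an
#' extracellularly-bound ligand layer; for an intact membrane this
#' measures the label-to-label membrane thickness.
#'
#' @param a,b `axial_profile` objects.
#' @return Separation in nm.
#' @export
peak_separation <- function(a, b) {
  stopifnot(inherits(a, "axial_profile"), inherits(b, "axial_profile"))
  abs(a$peak - b$peak)
}

#' Per-region NND series for internalization staging
#'
#' Computes the first-NND distribution (3D distances) of each labeled
#' region — e.g. hand-drawn membrane, clustered-membrane and vesicle
#' regions — on shared bins, together with each region's modal bin
#' center. As receptor-ligand complexes progress from membrane clusters
#' into vesicles, the modal NND shifts to shorter distances.
#'
#' @param positions Position tibble with a region label column.
#' @param region Tidy-eval column holding the region labels, default
#'   `region`.
#' @param bin_size Bin width in nm, default 5.
#' @param norm_range Shared binning/normalization range, default
#'   `c(0, 200)` nm.
#' @param use_z Use 3D distances, default `TRUE`.
#' @return Object of class `region_nnd_series`; `tidy()` returns the long
#'   histogram table, `glance()` one row per region with its modal bin
#'   center and query count. Regions keep their input order.
#' @export
region_nnd_series <- function(positions, region = region, bin_size = 5,
                              norm_range = c(0, 200), use_z = TRUE) {
  region <- rlang::enquo(region)
  labels <- as.character(rlang::eval_tidy(region, positions))
  stopifnot(length(labels) == nrow(positions))
  order <- unique(labels)
  pieces <- purrr::map(order, function(lab) {
    sub <- positions[labels == lab, , drop = FALSE]
    withd <- first_nnd(sub, use_z = use_z)
    hist <- nnd_histogram(withd$nnd, bin_size = bin_size, norm_range = norm_range)
    list(label = lab, hist = hist, n = nrow(sub),
         mode = modal_bin_center(hist))
  })
  histograms <- purrr::map_dfr(pieces, function(p) {
    dplyr::mutate(tibble::as_tibble(p$hist), region = p$label, .before = 1)
  })
  modes <- purrr::map_dfr(pieces, function(p) {
    tibble::tibble(region = p$label, modal_bin_center = p$mode, n = p$n)
  })
  structure(list(histograms = histograms, modes = modes,
                 bin_size = bin_size, norm_range = norm_range),
            class = "region_nnd_series")
}

#' @export
print.region_nnd_series <- function(x, ...) {
  cat("<region_nnd_series>\n")
  print(x$modes)
  invisible(x)
}

#' @export
tidy.region_nnd_series <- function(x, ...) x$histograms

#' @export
glance.region_nnd_series <- function(x, ...) x$modes
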