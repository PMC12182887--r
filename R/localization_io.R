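#' Read a localization table
#'
#' Reads a per-channel localization table produced by upstream
#' single-molecule localization software (drift-corrected and
#' channel-aligned) from a CSV file with the conventional SMLM column
#' names `frame, x, y, z, photons, lpx, lpy, lpz`. `z`/`lpz` are optional
#' but must be present together; all other columns are required.
#'
#' Coordinates and precisions are returned in nanometres. If the file
#' stores lateral coordinates in camera pixels, pass `pixel_size` (nm per
#' pixel, e.g. 130 for a typical EMCCD setup) and `x`, `y`, `lpx`, `lpy`
#' are converted; `z`/`lpz` are assumed to be in nm already, as axial
#' calibrations usually emit nm. Rows whose coordinates are non-finite or
#' whose precisions are non-finite or non-positive are rejected with a
#' warning stating the count; the count is also stored in the
#' `n_rejected` attribute.
#'
#' @param path Path to a CSV localization table.
#' @param pixel_size Optional nm-per-pixel conversion factor. Supply it if
#'   and only if the lateral coordinates are in camera pixels.
#' @param channel Channel label. Defaults to the file name without
#'   extension; ignored if the file has a `channel` column.
#' @return A tibble with columns `channel, frame, x, y, photons, lpx, lpy`
#'   and, for 3D tables, `z, lpz`; units nm.
#' @export
read_localizations <- function(path, pixel_size = NULL, channel = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # read as text and convert with base R's strtod so doubles round-trip
  # bit-exactly (fast float parsers can be a ulp off)
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  numeric_cols <- intersect(c("frame", "x", "y", "z", "photons",
                              "lpx", "lpy", "lpz"), names(tbl))
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::all_of(numeric_cols), as.numeric))
  required <- c("frame", "x", "y", "photons", "lpx", "lpy")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("localization table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (xor("z" %in% names(tbl), "lpz" %in% names(tbl))) {
    abort("3D tables must carry both `z` and `lpz`")
  }
  if (!"channel" %in% names(tbl)) {
    tbl$channel <- channel %||% tools::file_path_sans_ext(basename(path))
  }
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), pixel_size > 0)
    tbl <- dplyr::mutate(tbl, dplyr::across(c("x", "y", "lpx", "lpy"),
                                            ~ .x * pixel_size))
  }
  validate_localizations(tbl)
}

#' Validate a localization table
#'
#' Checks the table invariants (finite coordinates, positive precisions,
#' all-2D or all-3D) and drops invalid rows, warning with the rejected
#' count. Called by [read_localizations()]; exported so in-memory tables
#' (e.g. simulated ones) can be checked the same way.
#'
#' @param tbl A localization tibble.
#' @return The validated tibble, with attribute `n_rejected`.
#' @export
validate_localizations <- function(tbl) {
  is3d <- "z" %in% names(tbl)
  if (is3d) {
    z_na <- is.na(tbl$z) | is.na(tbl$lpz)
    if (any(z_na) && !all(z_na)) {
      abort("mixed 2D/3D rows: some rows carry z and others do not")
    }
    if (all(z_na)) {
      tbl$z <- NULL
      tbl$lpz <- NULL
      is3d <- FALSE
    }
  }
  ok <- is.finite(tbl$x) & is.finite(tbl$y) &
    is.finite(tbl$lpx) & tbl$lpx > 0 &
    is.finite(tbl$lpy) & tbl$lpy > 0
  if (is3d) ok <- ok & is.finite(tbl$z) & is.finite(tbl$lpz) & tbl$lpz > 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(sprintf("rejected %d localization(s) with non-finite coordinates or invalid precisions",
                 n_rejected))
    tbl <- tbl[ok, , drop = FALSE]
  }
  out <- tibble::as_tibble(tbl)
  if ("frame" %in% names(out) && is.double(out$frame) &&
      all(out$frame == trunc(out$frame))) {
    out$frame <- as.integer(out$frame)
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a localization table
#'
#' Writes the CSV counterpart of [read_localizations()]; numeric columns
#' are written at full double precision so a write/read round trip
#' reproduces the table exactly.
#'
#' @param tbl Localization tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(tbl, path) {
  # 17 significant digits guarantee a bit-exact double round trip
  out <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.double),
                                          ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Region of interest polygons
#'
#' A region of interest (ROI) is a simple (non-self-intersecting) polygon
#' in nm over which densities are measured and CSR nulls are simulated.
#' `roi_polygon()` builds one from vertex coordinates, `roi_rect()` from a
#' bounding box, and `read_roi()`/`write_roi()` exchange the JSON
#' representation (a list of `[x, y]` vertices in nm).
#'
#' @param x,y Polygon vertex coordinates in nm (ordered, unclosed).
#' @return An object of class `paint_roi`: a list with `vertices` (tibble
#'   of x, y) and `area` (nm^2, by the shoelace formula).
#' @export
roi_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  # drop an explicitly closed final vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1L
  }
  if (n < 3) abort("ROI polygon needs at least 3 distinct vertices")
  if (polygon_self_intersects(x, y)) {
    abort("ROI polygon must be simple (non-self-intersecting)")
  }
  area <- shoelace_area(x, y)
  if (area <= 0) abort("ROI polygon has zero area")
  structure(list(vertices = tibble::tibble(x = x, y = y), area = area),
            class = "paint_roi")
}

#' @rdname roi_polygon
#' @param xmin,xmax,ymin,ymax Rectangle bounds in nm.
#' @export
roi_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  roi_polygon(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' @rdname roi_polygon
#' @param path JSON file holding a list of `[x, y]` vertices in nm.
#' @export
read_roi <- function(path) {
  v <- jsonlite::fromJSON(path)
  if (is.list(v)) v <- do.call(rbind, v)
  if (!is.matrix(v) || ncol(v) != 2) {
    abort("ROI JSON must be a list of [x, y] vertex pairs")
  }
  roi_polygon(v[, 1], v[, 2])
}

#' @rdname roi_polygon
#' @param roi A `paint_roi` object.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "paint_roi"))
  m <- cbind(roi$vertices$x, roi$vertices$y)
  jsonlite::write_json(m, path, digits = NA)
  invisible(path)
}

#' @export
print.paint_roi <- function(x, ...) {
  cat(sprintf("<paint_roi> %d vertices, area %.4g um^2\n",
              nrow(x$vertices), x$area / 1e6))
  invisible(x)
}

# signed shoelace area, returned as absolute value (nm^2)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# O(n^2) proper-crossing test between non-adjacent edges; ROI polygons are
# small so this is never a bottleneck
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n <= 3) return(FALSE)
  seg <- cbind(x, y, x[c(2:n, 1)], y[c(2:n, 1)])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      d1 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Restrict a table to a region of interest
#'
#' Keeps the rows whose `(x, y)` lies inside or on the boundary of the ROI
#' polygon. Works on localization tables and protein position tables
#' alike. Idempotent; an empty result is permitted but warned about.
#'
#' @param tbl A tibble with `x` and `y` columns in nm.
#' @param roi A `paint_roi` object.
#' @return The filtered tibble.
#' @export
filter_roi <- function(tbl, roi) {
  check_positions(tbl, "tbl")
  stopifnot(inherits(roi, "paint_roi"))
  if (nrow(tbl) == 0) return(tbl)
  inside <- pracma::inpolygon(tbl$x, tbl$y,
                              roi$vertices$x, roi$vertices$y,
                              boundary = TRUE)
  out <- tbl[inside, , drop = FALSE]
  if (nrow(out) == 0) warn("no records fall inside the ROI")
  out
}
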