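#' Pipeline run configuration
#'
#' Bundles the analysis parameters shared by [run_condition()] and
#' [run_report()]. Defaults are the package's standard settings: 10 nm
#' clustering radius with at least 10 localizations per protein, 5 nm
#' histogram bins evaluated over 0-200 nm, and a CSR null of five million
#' simulated molecules per measured density.
#'
#' @param radius Clustering radius, nm.
#' @param min_locs Minimum localizations per protein position.
#' @param bin_size Histogram bin width, nm.
#' @param delta_range Range over which histograms are normalized and the
#'   delta area is evaluated, nm.
#' @param csr_n Number of molecules per simulated CSR null.
#' @param use_z Use 3D distances for clustering and NND.
#' @param seed Root seed; every stochastic step derives its own child
#'   seed from it, so a rerun with the same config is identical.
#' @param receptor_channel,ligand_channel Channel labels identifying the
#'   receptor and ligand tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(radius = 10, min_locs = 10, bin_size = 5,
                            delta_range = c(0, 200), csr_n = 5e6,
                            use_z = FALSE, seed = 1,
                            receptor_channel = "receptor",
                            ligand_channel = "ligand") {
  stopifnot(radius > 0, min_locs >= 1, bin_size > 0,
            length(delta_range) == 2, delta_range[2] > delta_range[1],
            csr_n >= 2)
  structure(list(radius = radius, min_locs = min_locs, bin_size = bin_size,
                 delta_range = delta_range, csr_n = csr_n, use_z = use_z,
                 seed = as.integer(seed),
                 receptor_channel = receptor_channel,
                 ligand_channel = ligand_channel),
            class = "pipeline_config")
}

# The three NND analyses run per cell
condition_analyses <- c("receptor_receptor", "ligand_receptor_cross", "ligand_ligand")

analyse_cell <- function(cell_locs, config, cell_id, cell_index) {
  rec_locs <- cell_locs[cell_locs$channel == config$receptor_channel, , drop = FALSE]
  lig_locs <- cell_locs[cell_locs$channel == config$ligand_channel, , drop = FALSE]
  rec <- cluster_channel(rec_locs, config$radius, config$min_locs, config$use_z)
  lig <- cluster_channel(lig_locs, config$radius, config$min_locs, config$use_z)
  if (nrow(rec) < 2 || nrow(lig) < 2) {
    abort(sprintf("cell %s: fewer than 2 protein positions in a channel", cell_id))
  }
  roi <- roi_rect(min(cell_locs$x), max(cell_locs$x),
                  min(cell_locs$y), max(cell_locs$y))
  rho_rec <- estimate_density(rec, roi)
  rho_lig <- estimate_density(lig, roi)

  csr_of <- function(rho, step) {
    simulate_csr(rho, config$csr_n, child_seed(config$seed, cell_index * 10L + step))
  }
  csr_rec <- csr_of(rho_rec, 1L)
  csr_lig <- csr_of(rho_lig, 2L)
  # cross-NND null: both channels randomized independently at their
  # measured densities, laid over a common region
  csr_lig_q <- csr_of(rho_lig, 3L)

  hist_of <- function(d) nnd_histogram(d, config$bin_size, config$delta_range)
  # the cross null needs both ensembles in the same coordinate frame; the
  # query ensemble is rescaled to the reference region
  side_ref <- attr(csr_rec, "region")[["side"]]
  side_q <- attr(csr_lig_q, "region")[["side"]]
  csr_cross_query <- dplyr::mutate(csr_lig_q,
                                   x = .data$x / side_q * side_ref,
                                   y = .data$y / side_q * side_ref)
  n_keep <- min(nrow(csr_cross_query), round(rho_lig * (side_ref / 1e3)^2))
  csr_cross_query <- csr_cross_query[seq_len(max(2, n_keep)), , drop = FALSE]

  exp_h <- list(
    receptor_receptor = hist_of(first_nnd(rec, config$use_z)$nnd),
    ligand_receptor_cross = hist_of(cross_nnd(lig, rec, config$use_z)$nnd),
    ligand_ligand = hist_of(first_nnd(lig, config$use_z)$nnd)
  )
  csr_h <- list(
    receptor_receptor = hist_of(first_nnd(csr_rec)$nnd),
    ligand_receptor_cross = hist_of(cross_nnd(csr_cross_query, csr_rec)$nnd),
    ligand_ligand = hist_of(first_nnd(csr_lig)$nnd)
  )
  deltas <- purrr::map_dbl(condition_analyses,
                           ~ delta_area(exp_h[[.x]], csr_h[[.x]], config$delta_range)$delta_area)
  list(
    delta_areas = tibble::tibble(
      cell = cell_id, analysis = condition_analyses, delta_area = deltas,
      n_query = purrr::map_int(condition_analyses,
                               ~ attr(exp_h[[.x]], "n_query")),
      density_receptor = rho_rec, density_ligand = rho_lig
    ),
    histograms = purrr::map_dfr(condition_analyses, function(a) {
      dplyr::bind_rows(
        dplyr::mutate(tibble::as_tibble(exp_h[[a]]), curve = "experimental"),
        dplyr::mutate(tibble::as_tibble(csr_h[[a]]), curve = "csr")
      ) |>
        dplyr::mutate(cell = cell_id, analysis = a, .before = 1)
    }),
    exp_h = exp_h, csr_h = csr_h
  )
}

#' Run the three NND analyses for one condition
#'
#' For every cell of a condition: cluster the receptor and ligand
#' channels into protein positions, measure both densities over the
#' cell's bounding-box ROI, simulate matching CSR nulls, and compute the
#' receptor-receptor first-NND, ligand-to-receptor cross-NND and
#' ligand-ligand first-NND histograms with their delta areas. Cells where
#' clustering fails are skipped with a message and the run continues.
#'
#' @param locs Localization tibble with columns `cell`, `channel`, `x`,
#'   `y`, `lpx`, `lpy` (and `z`, `lpz`).
#' @param config A [pipeline_config()].
#' @param condition Condition label for reports.
#' @return Object of class `condition_result`; `tidy()` returns the
#'   per-cell delta-area table, `glance()` per-analysis mean and
#'   population-sd summaries.
#' @export
run_condition <- function(locs, config = pipeline_config(), condition = "condition") {
  stopifnot(inherits(config, "pipeline_config"))
  if (!"cell" %in% names(locs)) locs$cell <- "cell_1"
  cells <- unique(locs$cell)
  results <- list()
  skipped <- character()
  for (i in seq_along(cells)) {
    res <- tryCatch(
      analyse_cell(locs[locs$cell == cells[i], , drop = FALSE], config,
                   as.character(cells[i]), i),
      error = function(e) {
        inform(sprintf("skipping cell %s: %s", cells[i], conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) results[[length(results) + 1]] <- res
    else skipped <- c(skipped, as.character(cells[i]))
  }
  if (length(results) == 0) abort("no cell could be analysed")
  delta_areas <- purrr::map_dfr(results, "delta_areas") |>
    dplyr::mutate(condition = condition, .before = 1)
  histograms <- purrr::map_dfr(results, "histograms") |>
    dplyr::mutate(condition = condition, .before = 1)
  curves <- purrr::map_dfr(condition_analyses, function(a) {
    exp_agg <- aggregate_histograms(purrr::map(results, ~ .x$exp_h[[a]]))
    csr_agg <- aggregate_histograms(purrr::map(results, ~ .x$csr_h[[a]]))
    dplyr::bind_rows(
      dplyr::mutate(exp_agg, curve = "experimental"),
      dplyr::mutate(csr_agg, curve = "csr")
    ) |>
      dplyr::mutate(condition = condition, analysis = a, .before = 1)
  })
  structure(list(condition = condition, delta_areas = delta_areas,
                 histograms = histograms, curves = curves,
                 skipped = skipped, config = config),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %s: %d cell(s), %d skipped\n",
              x$condition, length(unique(x$delta_areas$cell)), length(x$skipped)))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.condition_result <- function(x, ...) x$delta_areas

#' @export
glance.condition_result <- function(x, ...) {
  x$delta_areas |>
    dplyr::group_by(.data$condition, .data$analysis) |>
    dplyr::summarise(mean_delta_area = mean(.data$delta_area),
                     sd_delta_area = pop_sd(.data$delta_area),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Multi-condition report
#'
#' Combines the per-condition results, tests each NND analysis across
#' conditions by one-way ANOVA, and (optionally) writes the machine-
#' readable report bundle: `delta_areas.csv`, `curves.csv`, `anova.csv`,
#' `summary.json` and `run.log` (all seeds and parameters). Reruns with
#' the same inputs produce byte-identical files.
#'
#' @param conditions List of `condition_result` objects (at least 2 for
#'   the ANOVA).
#' @param output_dir Optional directory to write the bundle into.
#' @return Object of class `analysis_report`; `tidy()` returns the
#'   combined per-cell delta-area table, `glance()` the per-analysis
#'   ANOVA table with star labels.
#' @export
run_report <- function(conditions, output_dir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            all(purrr::map_lgl(conditions, inherits, "condition_result")))
  delta_areas <- purrr::map_dfr(conditions, "delta_areas")
  curves <- purrr::map_dfr(conditions, "curves")
  summaries <- purrr::map_dfr(conditions, glance)
  anova_tbl <- NULL
  if (length(conditions) >= 2) {
    anova_tbl <- purrr::map_dfr(condition_analyses, function(a) {
      sub <- delta_areas[delta_areas$analysis == a, , drop = FALSE]
      fit <- compare_conditions(sub, value = delta_area, group = condition)
      dplyr::mutate(glance(fit), analysis = a, .before = 1)
    })
  }
  report <- structure(list(delta_areas = delta_areas, curves = curves,
                           summaries = summaries, anova = anova_tbl,
                           config = conditions[[1]]$config),
                      class = "analysis_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(delta_areas, file.path(output_dir, "delta_areas.csv"))
    readr::write_csv(curves, file.path(output_dir, "curves.csv"))
    if (!is.null(anova_tbl)) {
      readr::write_csv(anova_tbl, file.path(output_dir, "anova.csv"))
    }
    jsonlite::write_json(
      list(summaries = summaries, anova = anova_tbl),
      file.path(output_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    cfg <- report$config
    log_lines <- c(
      "paintnnd run log",
      sprintf("seed: %d", cfg$seed),
      sprintf("clustering: radius = %g nm, min_locs = %g", cfg$radius, cfg$min_locs),
      sprintf("histogram: bin_size = %g nm, delta_range = [%g, %g] nm",
              cfg$bin_size, cfg$delta_range[1], cfg$delta_range[2]),
      sprintf("csr: n_molecules = %g", cfg$csr_n),
      sprintf("use_z: %s", cfg$use_z),
      sprintf("conditions: %s",
              paste(purrr::map_chr(conditions, "condition"), collapse = ", "))
    )
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$summaries)
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

#' @export
tidy.analysis_report <- function(x, ...) x$delta_areas

#' @export
glance.analysis_report <- function(x, ...) {
  x$anova %||% abort("report has a single condition; no ANOVA was run")
}
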