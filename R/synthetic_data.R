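#' Ground-truth scene parameters
#'
#' Parameter record for [generate_scene()]. Defaults mirror the receptor
#' system the package targets: ligand pairs on a receptor dimer sit 11 nm
#' apart, oligomer clusters span 200-500 nm, the ligand layer lies 25 nm
#' above the receptor label layer, the ligand label sits about 17 nm
#' laterally from the receptor label, and the labeling efficiency is about
#' 40%. Receptor surface density is an order-of-magnitude choice (cells'
#' true densities vary widely and are not a measured input here).
#'
#' @param receptor_density Receptors per um^2 (default 20).
#' @param area_um2 Membrane patch area in um^2 (square patch, default 100).
#' @param fractions Named fractions of receptors in each group kind
#'   (`monomer`, `dimer`, `cluster`, `vesicle`); must sum to 1.
#' @param dimer_separation Exact partner spacing within a dimer, nm
#'   (default 11).
#' @param cluster_diameter Two-element range of oligomer cluster
#'   diameters, nm (default `c(200, 500)`).
#' @param cluster_mean_size Mean receptors per cluster (default 20).
#' @param vesicle_diameter Vesicle outer diameter, nm (default 150).
#' @param vesicle_mean_size Mean receptors per vesicle (default 40).
#' @param vesicle_depth Depth of vesicle centers below the membrane, nm
#'   (default 200).
#' @param ligand_offset_xy Lateral displacement of a bound ligand's label
#'   from its receptor's label, nm (default 17); drawn at a uniform random
#'   orientation per ligand.
#' @param axial_offset Ligand z minus receptor z for membrane-bound
#'   pairs, nm (default 25).
#' @param ligand_occupancy Probability that a receptor carries a bound
#'   ligand (default 1).
#' @param labeling_efficiency Probability that a molecule carries a
#'   detectable label (default 0.4).
#' @return A named list of class `scene_params`.
#' @export
scene_params <- function(receptor_density = 20,
                         area_um2 = 100,
                         fractions = c(monomer = 1, dimer = 0, cluster = 0, vesicle = 0),
                         dimer_separation = 11,
                         cluster_diameter = c(200, 500),
                         cluster_mean_size = 20,
                         vesicle_diameter = 150,
                         vesicle_mean_size = 40,
                         vesicle_depth = 200,
                         ligand_offset_xy = 17,
                         axial_offset = 25,
                         ligand_occupancy = 1,
                         labeling_efficiency = 0.4) {
  kinds <- c("monomer", "dimer", "cluster", "vesicle")
  fr <- setNames(rep(0, 4), kinds)
  fr[names(fractions)] <- fractions
  if (abs(sum(fr) - 1) > 1e-8) abort("group-kind fractions must sum to 1")
  if (any(fr < 0)) abort("group-kind fractions must be non-negative")
  stopifnot(receptor_density > 0, area_um2 > 0,
            dimer_separation >= 0, all(cluster_diameter >= 0),
            cluster_diameter[2] >= cluster_diameter[1],
            ligand_offset_xy >= 0, axial_offset >= 0,
            ligand_occupancy >= 0, ligand_occupancy <= 1,
            labeling_efficiency >= 0, labeling_efficiency <= 1,
            vesicle_diameter > 0, vesicle_depth >= 0)
  structure(list(
    receptor_density = receptor_density, area_um2 = area_um2,
    fractions = fr, dimer_separation = dimer_separation,
    cluster_diameter = cluster_diameter, cluster_mean_size = cluster_mean_size,
    vesicle_diameter = vesicle_diameter, vesicle_mean_size = vesicle_mean_size,
    vesicle_depth = vesicle_depth,
    ligand_offset_xy = ligand_offset_xy, axial_offset = axial_offset,
    ligand_occupancy = ligand_occupancy,
    labeling_efficiency = labeling_efficiency
  ), class = "scene_params")
}

#' Generate a ground-truth membrane scene
#'
#' Places receptor molecules on a square membrane patch according to the
#' configured group-kind fractions, attaches bound ligands, and marks
#' labeled molecules:
#'
#' * monomers: uniform positions at z = 0;
#' * dimers: uniformly placed pairs, partners exactly
#'   `dimer_separation` apart at a uniform random orientation;
#' * clusters: disc-uniform groups with diameter uniform in
#'   `cluster_diameter`;
#' * vesicles: groups on the outer surface of a sphere buried
#'   `vesicle_depth` below the membrane, with bound ligands on an inner
#'   shell (`axial_offset` closer to the center), i.e. pointing into the
#'   vesicle lumen;
#' * each receptor carries a bound ligand with probability
#'   `ligand_occupancy`; membrane-bound ligands sit `ligand_offset_xy`
#'   laterally (uniform random direction) and `axial_offset` above their
#'   receptor;
#' * every molecule is labeled with probability `labeling_efficiency`.
#'
#' @param params A [scene_params()] record.
#' @param seed Integer seed; scenes are bit-reproducible from
#'   `(params, seed)`.
#' @return A tibble of class `paint_scene` with one row per molecule:
#'   `molecule_id, species (receptor|ligand), group_id, group_kind, x, y,
#'   z, labeled`; attributes `params`, `region` (side nm), `seed`.
#' @export
generate_scene <- function(params, seed = 1) {
  stopifnot(inherits(params, "scene_params"))
  side <- sqrt(params$area_um2) * 1e3  # nm
  n_total <- round(params$receptor_density * params$area_um2)
  fr <- params$fractions
  n_dimer <- round(fr[["dimer"]] * n_total / 2) * 2
  n_cluster <- round(fr[["cluster"]] * n_total)
  n_vesicle <- round(fr[["vesicle"]] * n_total)
  n_monomer <- max(0L, n_total - n_dimer - n_cluster - n_vesicle)

  mols <- withr::with_seed(seed, {
    rec <- list()
    gid <- 0L

    if (n_monomer > 0) {
      gid_seq <- gid + seq_len(n_monomer)
      rec$monomer <- tibble::tibble(
        x = runif(n_monomer, 0, side), y = runif(n_monomer, 0, side),
        z = 0, group_id = gid_seq, group_kind = "monomer"
      )
      gid <- gid + n_monomer
    }

    if (n_dimer > 0) {
      np <- n_dimer / 2
      cx <- runif(np, 0, side)
      cy <- runif(np, 0, side)
      th <- runif(np, 0, 2 * pi)
      hx <- cos(th) * params$dimer_separation / 2
      hy <- sin(th) * params$dimer_separation / 2
      rec$dimer <- tibble::tibble(
        x = c(cx - hx, cx + hx), y = c(cy - hy, cy + hy),
        z = 0, group_id = gid + rep(seq_len(np), 2), group_kind = "dimer"
      )
      gid <- gid + np
    }

    if (n_cluster > 0) {
      ng <- max(1L, round(n_cluster / params$cluster_mean_size))
      sizes <- diff(round(seq(0, n_cluster, length.out = ng + 1)))
      sizes <- sizes[sizes > 0]
      ng <- length(sizes)
      cx <- runif(ng, 0, side)
      cy <- runif(ng, 0, side)
      diam <- runif(ng, params$cluster_diameter[1], params$cluster_diameter[2])
      member_g <- rep(seq_len(ng), sizes)
      r <- (diam[member_g] / 2) * sqrt(runif(n_cluster))
      phi <- runif(n_cluster, 0, 2 * pi)
      rec$cluster <- tibble::tibble(
        x = cx[member_g] + r * cos(phi), y = cy[member_g] + r * sin(phi),
        z = 0, group_id = gid + member_g, group_kind = "cluster"
      )
      gid <- gid + ng
    }

    if (n_vesicle > 0) {
      ng <- max(1L, round(n_vesicle / params$vesicle_mean_size))
      sizes <- diff(round(seq(0, n_vesicle, length.out = ng + 1)))
      sizes <- sizes[sizes > 0]
      ng <- length(sizes)
      cx <- runif(ng, 0, side)
      cy <- runif(ng, 0, side)
      cz <- rep(-params$vesicle_depth, ng)
      member_g <- rep(seq_len(ng), sizes)
      # uniform directions on the sphere
      u <- runif(n_vesicle, -1, 1)
      phi <- runif(n_vesicle, 0, 2 * pi)
      s <- sqrt(1 - u^2)
      r_out <- params$vesicle_diameter / 2
      rec$vesicle <- tibble::tibble(
        x = cx[member_g] + r_out * s * cos(phi),
        y = cy[member_g] + r_out * s * sin(phi),
        z = cz[member_g] + r_out * u,
        group_id = gid + member_g, group_kind = "vesicle",
        dir_x = s * cos(phi), dir_y = s * sin(phi), dir_z = u,
        center_x = cx[member_g], center_y = cy[member_g], center_z = cz[member_g]
      )
      gid <- gid + ng
    }

    receptors <- dplyr::bind_rows(rec)
    receptors$species <- "receptor"

    # bound ligands
    occupied <- rbinom(nrow(receptors), 1, params$ligand_occupancy) == 1
    lig <- receptors[occupied, , drop = FALSE]
    if (nrow(lig) > 0) {
      ves <- lig$group_kind == "vesicle"
      ang <- runif(nrow(lig), 0, 2 * pi)
      lx <- lig$x + params$ligand_offset_xy * cos(ang)
      ly <- lig$y + params$ligand_offset_xy * sin(ang)
      lz <- lig$z + params$axial_offset
      if (any(ves)) {
        # inner shell: same direction from the vesicle center, smaller radius
        r_in <- max(1, params$vesicle_diameter / 2 - params$axial_offset)
        lx[ves] <- lig$center_x[ves] + r_in * lig$dir_x[ves]
        ly[ves] <- lig$center_y[ves] + r_in * lig$dir_y[ves]
        lz[ves] <- lig$center_z[ves] + r_in * lig$dir_z[ves]
      }
      lig$x <- lx
      lig$y <- ly
      lig$z <- lz
      lig$species <- "ligand"
    }

    all <- dplyr::bind_rows(receptors, lig)
    all <- dplyr::select(all, -dplyr::any_of(c("dir_x", "dir_y", "dir_z",
                                               "center_x", "center_y", "center_z")))
    all$labeled <- rbinom(nrow(all), 1, params$labeling_efficiency) == 1
    all$molecule_id <- seq_len(nrow(all))
    dplyr::relocate(all, "molecule_id", "species", "group_id", "group_kind",
                    "x", "y", "z", "labeled")
  })

  out <- tibble::as_tibble(mols)
  class(out) <- c("paint_scene", class(out))
  attr(out, "params") <- params
  attr(out, "region") <- c(side = side)
  attr(out, "seed") <- seed
  out
}

#' Acquisition model for the localization forward simulation
#'
#' Abstracts DNA-PAINT imaging into (i) a Poisson number of localization
#' events per labeled site and (ii) per-event Gaussian localization
#' scatter. By default the per-event precision is drawn from a lognormal
#' (median 2 nm lateral, 5 nm axial, log-sd 0.3) to mimic photon-count
#' variation between events; fixed precisions can be requested instead.
#' Blinking kinetics are not modeled — they are integrated out into the
#' event count.
#'
#' @param mean_events Poisson mean localization events per labeled site
#'   (default 50).
#' @param sigma_xy,sigma_z Fixed lateral/axial precisions in nm; `NULL`
#'   (default) draws per-event precisions from the lognormal model.
#' @param median_sigma_xy,median_sigma_z Medians of the lognormal
#'   precision model, nm.
#' @param sdlog Log-scale sd of the lognormal precision model.
#' @param frames Number of camera frames events are spread over.
#' @return A list of class `acquisition_model`.
#' @export
acquisition_model <- function(mean_events = 50, sigma_xy = NULL, sigma_z = NULL,
                              median_sigma_xy = 2, median_sigma_z = 5,
                              sdlog = 0.3, frames = 40000) {
  stopifnot(mean_events > 0, frames >= 1,
            is.null(sigma_xy) || sigma_xy >= 0,
            is.null(sigma_z) || sigma_z >= 0)
  structure(list(mean_events = mean_events, sigma_xy = sigma_xy,
                 sigma_z = sigma_z, median_sigma_xy = median_sigma_xy,
                 median_sigma_z = median_sigma_z, sdlog = sdlog,
                 frames = frames),
            class = "acquisition_model")
}

#' Simulate localization tables from a ground-truth scene
#'
#' The forward model: every labeled molecule produces
#' `K ~ Poisson(mean_events)` localization events; each event is the true
#' position plus independent Gaussian noise per axis with the drawn (or
#' fixed) per-event precision, which is recorded in `lpx`/`lpy`/`lpz`
#' exactly as used. Frames are assigned uniformly at random. The
#' ground-truth molecule id is carried in `truth_id` so recovery can be
#' scored in tests.
#'
#' @param scene A `paint_scene`.
#' @param acq An [acquisition_model()].
#' @param seed Integer seed.
#' @return One localization tibble covering both species, with `channel`
#'   equal to the species name; split by channel for per-channel
#'   processing. Empty (with a warning) if the scene has no labeled
#'   molecules.
#' @export
simulate_localizations <- function(scene, acq = acquisition_model(), seed = 1) {
  stopifnot(inherits(scene, "paint_scene"), inherits(acq, "acquisition_model"))
  labeled <- scene[scene$labeled, , drop = FALSE]
  if (nrow(labeled) == 0) {
    warn("scene has no labeled molecules; returning an empty table")
    return(tibble::tibble(channel = character(), frame = integer(),
                          x = double(), y = double(), z = double(),
                          photons = double(), lpx = double(), lpy = double(),
                          lpz = double(), truth_id = integer()))
  }
  withr::with_seed(seed, {
    k <- rpois(nrow(labeled), acq$mean_events)
    src <- labeled[rep.int(seq_len(nrow(labeled)), k), , drop = FALSE]
    n <- nrow(src)
    sxy <- if (is.null(acq$sigma_xy)) {
      rlnorm(n, log(acq$median_sigma_xy), acq$sdlog)
    } else {
      rep(acq$sigma_xy, n)
    }
    sz <- if (is.null(acq$sigma_z)) {
      rlnorm(n, log(acq$median_sigma_z), acq$sdlog)
    } else {
      rep(acq$sigma_z, n)
    }
    tibble::tibble(
      channel = src$species,
      frame = sample.int(acq$frames, n, replace = TRUE),
      x = src$x + rnorm(n, 0, sxy),
      y = src$y + rnorm(n, 0, sxy),
      z = src$z + rnorm(n, 0, sz),
      photons = round(rlnorm(n, log(5000), 0.4)),
      lpx = sxy, lpy = sxy, lpz = sz,
      truth_id = src$molecule_id
    )
  })
}

#' Ground-truth summaries of a scene
#'
#' Computes, straight from the true molecule coordinates, the quantities
#' the analysis pipeline later estimates: per-species densities, true
#' first-NND distances (all molecules and the labeled subset separately),
#' and group-kind composition. Used to score the pipeline against truth.
#'
#' @param scene A `paint_scene`.
#' @param use_z Use 3D distances for the true NNDs, default `FALSE`.
#' @return A list of class `scene_report`: `densities` (tibble),
#'   `group_fractions` (tibble), `nnd` (named list of numeric vectors,
#'   keys like `receptor_all`, `ligand_labeled`).
#' @export
scene_oracle_report <- function(scene, use_z = FALSE) {
  stopifnot(inherits(scene, "paint_scene"))
  side <- attr(scene, "region")[["side"]]
  area_um2 <- (side / 1e3)^2
  densities <- scene |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n = dplyr::n(), n_labeled = sum(.data$labeled),
                     .groups = "drop") |>
    dplyr::mutate(density_um2 = .data$n / area_um2,
                  density_labeled_um2 = .data$n_labeled / area_um2)
  fractions <- scene |>
    dplyr::filter(.data$species == "receptor") |>
    dplyr::count(.data$group_kind) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  nnd <- list()
  for (sp in unique(scene$species)) {
    sub <- scene[scene$species == sp, , drop = FALSE]
    if (nrow(sub) >= 2) {
      nnd[[paste0(sp, "_all")]] <- first_nnd(sub, use_z = use_z)$nnd
    }
    lab <- sub[sub$labeled, , drop = FALSE]
    if (nrow(lab) >= 2) {
      nnd[[paste0(sp, "_labeled")]] <- first_nnd(lab, use_z = use_z)$nnd
    }
  }
  structure(list(densities = densities, group_fractions = fractions,
                 nnd = nnd, area_um2 = area_um2),
            class = "scene_report")
}

#' @export
print.scene_report <- function(x, ...) {
  cat("<scene_report>\n")
  print(x$densities)
  print(x$group_fractions)
  invisible(x)
}
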