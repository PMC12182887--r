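test_that("dimer scenes place exact pairs and bound ligands", {
  p <- scene_params(receptor_density = 10, area_um2 = 100,
                    fractions = c(monomer = 0, dimer = 1, cluster = 0, vesicle = 0),
                    ligand_occupancy = 1, labeling_efficiency = 1)
  sc <- generate_scene(p, seed = 1)
  rec <- sc[sc$species == "receptor", ]
  expect_equal(nrow(rec), 1000)
  expect_equal(length(unique(rec$group_id)), 500)
  pair_d <- rec |>
    dplyr::group_by(group_id) |>
    dplyr::summarise(d = sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(pair_d$d, rep(11, 500), tolerance = 1e-12)

  # membrane-bound ligands sit at the configured lateral and axial offsets
  lig <- sc[sc$species == "ligand", ]
  expect_equal(nrow(lig), 1000)
  joined <- dplyr::inner_join(rec, lig, by = "group_id", suffix = c("_r", "_l"),
                              relationship = "many-to-many")
  # each ligand's own receptor is exactly 17 nm away laterally (the
  # partner receptor sits at some other distance)
  derr <- joined |>
    dplyr::mutate(d = sqrt((x_r - x_l)^2 + (y_r - y_l)^2)) |>
    dplyr::group_by(molecule_id_l) |>
    dplyr::summarise(err = min(abs(d - 17)))
  expect_equal(derr$err, rep(0, 1000), tolerance = 1e-9)
  expect_equal(unique(lig$z), 25)
})

test_that("labeling efficiency behaves binomially", {
  p0 <- scene_params(receptor_density = 20, area_um2 = 50,
                     labeling_efficiency = 0)
  expect_equal(sum(generate_scene(p0, seed = 2)$labeled), 0)

  p40 <- scene_params(receptor_density = 100, area_um2 = 100,
                      ligand_occupancy = 0, labeling_efficiency = 0.4)
  sc <- generate_scene(p40, seed = 3)
  expect_equal(nrow(sc), 10000)
  expect_lt(abs(sum(sc$labeled) - 4000), 3 * sqrt(10000 * 0.4 * 0.6))
})

test_that("scene parameter validation", {
  expect_error(scene_params(fractions = c(monomer = 0.5, dimer = 0.2)), "sum to 1")
  expect_error(scene_params(receptor_density = -1))
  expect_error(scene_params(labeling_efficiency = 1.2))
})

test_that("cluster and vesicle geometry respect configured dimensions", {
  p <- scene_params(receptor_density = 40, area_um2 = 100,
                    fractions = c(monomer = 0, dimer = 0, cluster = 0.5, vesicle = 0.5),
                    labeling_efficiency = 1)
  sc <- generate_scene(p, seed = 4)
  rec <- sc[sc$species == "receptor", ]

  spread <- rec[rec$group_kind == "cluster", ] |>
    dplyr::group_by(group_id) |>
    dplyr::summarise(ext = max(stats::dist(cbind(x, y))))
  expect_true(all(spread$ext <= 500))  # pairwise spread <= largest diameter

  # vesicle receptors on a 75-nm sphere, ligands 25 nm further in
  ves_r <- sc[sc$species == "receptor" & sc$group_kind == "vesicle", ] |>
    dplyr::group_by(group_id) |>
    dplyr::summarise(cx = mean(x), cy = mean(y), cz = mean(z))
  rad <- sc[sc$group_kind == "vesicle", ] |>
    dplyr::inner_join(ves_r, by = "group_id") |>
    dplyr::mutate(r = sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2))
  # empirical centers wobble; radii should concentrate near 75 (receptor)
  # and 50 (ligand)
  med <- rad |>
    dplyr::group_by(species) |>
    dplyr::summarise(r = stats::median(r))
  expect_equal(med$r[med$species == "receptor"], 75, tolerance = 0.15)
  expect_equal(med$r[med$species == "ligand"], 50, tolerance = 0.25)
})

test_that("localization forward model has the stated event and noise laws", {
  one <- scene_params(receptor_density = 1, area_um2 = 1,
                      ligand_occupancy = 0, labeling_efficiency = 1)
  sc1 <- generate_scene(one, seed = 5)
  expect_equal(nrow(sc1), 1)

  # 10,000 replicate events at sigma = 2: empirical SD inside [1.94, 2.06]
  locs <- simulate_localizations(
    sc1, acquisition_model(mean_events = 10000, sigma_xy = 2, sigma_z = 5),
    seed = 6)
  expect_gt(sd(locs$x), 1.94)
  expect_lt(sd(locs$x), 2.06)
  expect_equal(unique(locs$lpx), 2)

  # sigma = 0 limit pins localizations to the true position
  exact <- simulate_localizations(
    sc1, acquisition_model(mean_events = 100, sigma_xy = 0, sigma_z = 0),
    seed = 7)
  expect_equal(unique(exact$x), sc1$x)
  expect_equal(unique(exact$z), sc1$z)

  # Poisson event counts: mean over 1,000 sites within the CLT bound
  many <- scene_params(receptor_density = 10, area_um2 = 100,
                       ligand_occupancy = 0, labeling_efficiency = 1)
  scm <- generate_scene(many, seed = 8)
  lm_ <- simulate_localizations(scm, acquisition_model(mean_events = 20, sigma_xy = 2),
                                seed = 9)
  per_site <- table(factor(lm_$truth_id, levels = scm$molecule_id))
  expect_lt(abs(mean(per_site) - 20), 3 * sqrt(20 / 1000))

  # determinism and the empty-scene warning
  expect_identical(lm_, simulate_localizations(scm, acquisition_model(mean_events = 20, sigma_xy = 2), seed = 9))
  none <- generate_scene(scene_params(labeling_efficiency = 0), seed = 10)
  expect_warning(empty <- simulate_localizations(none, seed = 11), "no labeled")
  expect_equal(nrow(empty), 0)
})

test_that("scene oracle report recovers truth directly", {
  p <- scene_params(receptor_density = 10, area_um2 = 100,
                    fractions = c(monomer = 0, dimer = 1, cluster = 0, vesicle = 0),
                    ligand_occupancy = 0, labeling_efficiency = 1)
  rep_d <- scene_oracle_report(generate_scene(p, seed = 12))
  # each receptor's partner sits at exactly 11 nm, so no NND can exceed it;
  # a different dimer occasionally wanders closer
  expect_true(all(rep_d$nnd$receptor_all <= 11 + 1e-9))
  expect_gt(mean(abs(rep_d$nnd$receptor_all - 11) < 1e-9), 0.98)
  expect_equal(rep_d$densities$density_um2[rep_d$densities$species == "receptor"], 10)
  expect_equal(rep_d$group_fractions$fraction, 1)

  # all-monomer true positions follow the closed-form CSR NND law
  mono <- scene_params(receptor_density = 10, area_um2 = 400,
                       ligand_occupancy = 0, labeling_efficiency = 1)
  scm <- generate_scene(mono, seed = 13)
  rp <- scene_oracle_report(scm)
  side <- attr(scm, "region")[["side"]]
  interior <- scm$x > 200 & scm$x < side - 200 & scm$y > 200 & scm$y < side - 200
  d_int <- rp$nnd$receptor_all[interior]
  rho <- nrow(scm) / side^2  # per nm^2
  ks <- suppressWarnings(
    stats::ks.test(d_int, function(r) 1 - exp(-pi * rho * r^2)))
  expect_gt(ks$p.value, 0.01)
})
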