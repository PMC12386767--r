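test_that("a null library carries no effects in either modality", {
  lib <- build_kinome_library(720, seed = 1)
  expect_equal(nrow(lib), 720)
  expect_true(all(lib$loc_effect == 0))
  expect_true(all(lib$rep_effect == 1))
  expect_true(all(lib$loc_class == "null" & lib$rep_class == "null"))
  expect_false(anyDuplicated(lib$gene_id) > 0)
})

test_that("full overlap spikes the same genes in both modalities", {
  lib <- build_kinome_library(720, n_loc_inhibitors = 20,
                              n_rep_inhibitors = 20,
                              overlap_fraction = 1, seed = 3)
  loc <- lib$gene_id[lib$loc_class == "inhibitor"]
  rep_ <- lib$gene_id[lib$rep_class == "inhibitor"]
  expect_setequal(loc, rep_)
  expect_length(loc, 20)
  # zero overlap gives disjoint sets
  lib0 <- build_kinome_library(720, n_loc_inhibitors = 20,
                               n_rep_inhibitors = 20,
                               overlap_fraction = 0, seed = 3)
  expect_length(intersect(lib0$gene_id[lib0$loc_class == "inhibitor"],
                          lib0$gene_id[lib0$rep_class == "inhibitor"]), 0)
})

test_that("hit assignment is deterministic and respects the effect size", {
  lib1 <- build_kinome_library(100, n_loc_inhibitors = 10,
                               effect_magnitude = 3, seed = 1)
  lib2 <- build_kinome_library(100, n_loc_inhibitors = 10,
                               effect_magnitude = 3, seed = 1)
  expect_identical(lib1, lib2)
  expect_equal(sum(lib1$loc_effect == 3), 10)
  lib3 <- build_kinome_library(100, n_loc_inhibitors = 10,
                               effect_magnitude = 3, seed = 2)
  expect_false(identical(lib1$loc_class, lib3$loc_class))
})

test_that("inconsistent library configurations are rejected by name", {
  expect_error(build_kinome_library(10, n_loc_inhibitors = 8,
                                    n_loc_activators = 5),
               "n_loc_activators|n_loc_inhibitors")
  expect_error(build_kinome_library(10, effect_magnitude = 0),
               "effect_magnitude")
  expect_error(build_kinome_library(10, fold_magnitude = -1),
               "fold_magnitude")
  expect_error(build_kinome_library(10, overlap_fraction = 2),
               "overlap_fraction")
})

test_that("the kinome-scale layout uses >= 3 plates and exact content counts", {
  lib <- build_kinome_library(720)
  lay <- layout_plates(lib, 384, c(siCTL = 72, siMARK4 = 16), seed = 1)
  expect_gte(length(unique(lay$plate_id)), 3)
  counts <- table(lay$content)
  expect_equal(unname(counts[["siCTL"]]), 72)
  expect_equal(unname(counts[["siMARK4"]]), 16)
  lib_wells <- lay$content[!(lay$content %in% c("siCTL", "siMARK4"))]
  expect_equal(sort(lib_wells), sort(lib$gene_id))  # each gene exactly once
  # deterministic for a fixed seed, different for another
  expect_identical(lay, layout_plates(lib, 384, c(siCTL = 72, siMARK4 = 16),
                                      seed = 1))
  expect_false(identical(lay$well,
                         layout_plates(lib, 384,
                                       c(siCTL = 72, siMARK4 = 16),
                                       seed = 2)$well))
})

test_that("per-plate control schemes place the scheme on every plate", {
  lib <- build_kinome_library(720)
  lay <- layout_plates(lib, 96, c(siCTL = 8, siYAP = 4), per_plate = TRUE,
                       seed = 1)
  per_plate <- table(lay$plate_id, lay$content)
  expect_true(all(per_plate[, "siCTL"] == 8))
  expect_true(all(per_plate[, "siYAP"] == 4))
  expect_equal(length(unique(lay$plate_id)), ceiling(720 / (96 - 12)))
})

test_that("degenerate layouts behave: controls only, no controls, overflow", {
  lay <- layout_plates(character(0), 96, c(siCTL = 8, siYAP = 4))
  expect_equal(nrow(lay), 12)
  expect_equal(length(unique(lay$plate_id)), 1)

  lay2 <- layout_plates(sprintf("g%02d", 1:10), 96, c())
  expect_equal(nrow(lay2), 10)
  expect_equal(sort(lay2$content), sprintf("g%02d", 1:10))

  expect_error(layout_plates(sprintf("g%02d", 1:10), 96,
                             c(siCTL = 96), per_plate = TRUE),
               "capacity")
})

test_that("well addresses are valid for the plate format", {
  a384 <- well_addresses(384)
  expect_length(a384, 384)
  expect_true(all(grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", a384)))
  a96 <- well_addresses(96)
  expect_length(a96, 96)
  expect_true(all(grepl("^[A-H](0[1-9]|1[0-2])$", a96)))
  lay <- layout_plates(character(0), 96, c(siCTL = 8))
  expect_true(all(lay$well %in% a96))
})

test_that("noiseless null localization wells sit exactly at baseline", {
  lib <- build_kinome_library(10)
  lay <- layout_plates(lib, 96, c(siCTL = 4), seed = 1)
  w <- simulate_localization_wells(lay, lib, baseline_pct_cytoplasmic = 15,
                                   mark4_effect = 0,
                                   noise = noise_model(well_sd = 0),
                                   n_replicates = 1)
  expect_true(all(w$metric == 15))
})

test_that("localization record count is occupied wells x replicates", {
  lib <- build_kinome_library(720)
  lay <- layout_plates(lib, 384, c(siCTL = 72, siMARK4 = 16), seed = 1)
  w <- simulate_localization_wells(lay, lib, noise = noise_model(seed = 2),
                                   n_replicates = 2)
  expect_equal(nrow(w), 2 * (720 + 72 + 16))
  expect_error(simulate_localization_wells(lay[0, ], lib), "empty")
})

test_that("metrics are clamped to the percent scale", {
  lib <- build_kinome_library(0)
  lay <- controls_layout(c(siCTL = 8, siMARK4 = 8))
  w <- simulate_localization_wells(lay, lib, baseline_pct_cytoplasmic = 99,
                                   mark4_effect = 10,
                                   noise = noise_model(well_sd = 1, seed = 1),
                                   n_replicates = 1)
  expect_true(all(w$metric <= 100 & w$metric >= 0))
  expect_true(any(w$metric == 100))  # positive controls pushed to the bound
})

test_that("strong siMARK4 effects separate completely from siCTL", {
  lib <- build_kinome_library(0)
  lay <- controls_layout()
  separated <- vapply(seq_len(200), function(s) {
    w <- simulate_localization_wells(lay, lib, mark4_effect = 6,
                                     noise = noise_model(well_sd = 1,
                                                         seed = s),
                                     n_replicates = 1)
    min(w$metric[w$content == "siMARK4"]) > max(w$metric[w$content == "siCTL"])
  }, logical(1))
  expect_gt(mean(separated), 0.99)
})

test_that("localization simulation is seed-deterministic", {
  lib <- build_kinome_library(50, n_loc_inhibitors = 5, seed = 1)
  lay <- layout_plates(lib, 96, c(siCTL = 8), seed = 1)
  n <- noise_model(seed = 11)
  expect_identical(simulate_localization_wells(lay, lib, noise = n),
                   simulate_localization_wells(lay, lib, noise = n))
})

test_that("the plate effect cancels in the firefly/beta-gal ratio", {
  lib <- build_kinome_library(150)  # spans two 96-well plates
  lay <- layout_plates(lib, 96, c(siCTL = 8, siYAP = 4), per_plate = TRUE,
                       seed = 1)
  w <- simulate_reporter_wells(lay, lib,
                               noise = noise_model(well_sd = 0,
                                                   plate_effect_sd = 0.5,
                                                   seed = 2))
  norm <- w$firefly / w$bgal
  lib_norm <- norm[!(w$content %in% c("siCTL", "siYAP"))]
  expect_equal(max(lib_norm) - min(lib_norm), 0)  # identical across plates
  # but raw firefly differs across plates (the plate effect is real)
  expect_gt(diff(range(tapply(w$firefly, w$plate_id, mean))), 0)
})

test_that("siYAP wells carry exactly yap_fold of the siCTL signal (noiseless)", {
  lib <- build_kinome_library(10)
  lay <- layout_plates(lib, 96, c(siCTL = 4, siYAP = 4), seed = 1)
  w <- simulate_reporter_wells(lay, lib, yap_fold = 0.2,
                               noise = noise_model(well_sd = 0,
                                                   plate_effect_sd = 0,
                                                   seed = 1))
  norm <- w$firefly / w$bgal
  expect_equal(mean(norm[w$content == "siYAP"]) /
                 mean(norm[w$content == "siCTL"]), 0.2)
  expect_error(simulate_reporter_wells(lay, lib, yap_fold = 0), "yap_fold")
})

test_that("a spiked gene's fold over plate median equals its rep_effect (noiseless)", {
  # 11 library wells: odd count, 10 nulls -> the plate median is a null well
  lib <- build_kinome_library(11, n_rep_inhibitors = 1, fold_magnitude = 0.4,
                              seed = 5)
  lay <- layout_plates(lib, 96, c(siCTL = 4), seed = 1)
  w <- simulate_reporter_wells(lay, lib,
                               noise = noise_model(well_sd = 0,
                                                   plate_effect_sd = 0.3,
                                                   seed = 2))
  f <- fold_over_plate_median(normalize_reporter(w))
  spiked <- lib$gene_id[lib$rep_class == "inhibitor"]
  expect_equal(f$fold[f$content == spiked], 0.4)
})

test_that("an empty field renders to pure background with empty ground truth", {
  img <- render_well_image(NULL, shape = c(32, 32),
                           noise = noise_model(image_background = 100))
  expect_true(all(img$dapi == 100) && all(img$fitc == 100))
  expect_equal(nrow(img$ground_truth), 0)
})

test_that("a single rendered cell has the constructed FITC ratio at the nuclear boundary", {
  one <- data.frame(row = 32, col = 32, nucleus_radius = 8,
                    cytoplasm_radius = 14, fitc_nuc = 1000, fitc_cyt = 400,
                    dapi_nuc = 3000)
  img <- render_well_image(one, shape = c(64, 64))
  expect_equal(img$ground_truth$true_ratio, 0.4)
  expect_equal(max(img$dapi), 3000)
  expect_setequal(unique(as.vector(img$fitc)), c(0, 400, 1000))
})

test_that("rendering is bit-identical under a fixed seed, noise included", {
  cells <- random_cell_field(25, seed = 2)
  nm <- noise_model(image_background = 150, image_noise_sd = 25, seed = 9)
  expect_identical(render_well_image(cells, noise = nm),
                   render_well_image(cells, noise = nm))
})

test_that("overlapping nuclei produce a recorded warning, not an error", {
  two <- data.frame(row = c(50, 50), col = c(50, 56), nucleus_radius = 6,
                    cytoplasm_radius = 11, fitc_nuc = 1000, fitc_cyt = 400,
                    dapi_nuc = 3000)
  img <- render_well_image(two, shape = c(100, 100))
  expect_gt(length(img$warnings), 0)
  expect_match(img$warnings[1], "overlap")
})

test_that("cells outside the image or with inverted radii are rejected", {
  bad <- data.frame(row = 5, col = 5, nucleus_radius = 6,
                    cytoplasm_radius = 11, fitc_nuc = 1, fitc_cyt = 1,
                    dapi_nuc = 1)
  expect_error(render_well_image(bad, shape = c(64, 64)), "fit inside")
  bad2 <- transform(bad, row = 32, col = 32, cytoplasm_radius = 4)
  expect_error(render_well_image(bad2, shape = c(64, 64)), "radius")
})

test_that("image pairs round-trip through 16-bit TIFF files losslessly", {
  cells <- random_cell_field(5, shape = c(96, 96), seed = 3)
  img <- render_well_image(cells, shape = c(96, 96),
                           noise = noise_model(image_background = 80,
                                               image_noise_sd = 10, seed = 4))
  dir <- tempfile()
  paths <- write_image_pair(img, dir, "P01", "A01")
  expect_true(all(file.exists(paths)))
  back <- read_image_pair(paths[1], paths[2])
  expect_identical(back$dapi, img$dapi)
  expect_identical(back$fitc, img$fitc)
})
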