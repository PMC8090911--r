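# Generator: determinism, ground-truth fidelity, plate/time-course/organoid
# structure.

test_that("render_cell_field is deterministic and handles the empty field", {
  a <- render_cell_field(field_spec(seed = 7))
  b <- render_cell_field(field_spec(seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$truth$puncta, b$truth$puncta)
  c <- render_cell_field(field_spec(seed = 8))
  expect_false(identical(a$image, c$image))

  e <- render_cell_field(field_spec(n_cells = 0, seed = 1))
  expect_equal(nrow(e$truth$nuclei), 0)
  expect_equal(nrow(e$truth$puncta), 0)
  # blank noisy channels: no structure above background + 6 sd
  expect_lt(max(e$image$channels$nucleus), 100 + 6 * 20)
  expect_gt(stats::sd(e$image$channels$marker), 10)
})

test_that("full perinuclear bias puts every punctum inside the band", {
  spec <- field_spec(perinuclear_bias = 1, n_cells = 6,
                     puncta_per_cell_range = c(15, 20), seed = 5)
  f <- render_cell_field(spec)
  tr <- f$truth
  expect_true(all(tr$puncta$radial_class == "perinuclear"))
  # direct distance computation against the generator's own band definition
  d <- sqrt((tr$puncta$row - tr$nuclei$row[tr$puncta$cell])^2 +
              (tr$puncta$col - tr$nuclei$col[tr$puncta$cell])^2) -
    tr$nuclei$radius[tr$puncta$cell]
  expect_true(all(d >= 0 & d <= spec$band_px))
})

test_that("radial-class fractions track the bias within binomial error", {
  for (bias in c(0.2, 0.7)) {
    f <- render_cell_field(field_spec(perinuclear_bias = bias, n_cells = 10,
                                      puncta_per_cell_range = c(15, 25),
                                      seed = round(100 * bias)))
    n <- nrow(f$truth$puncta)
    phat <- mean(f$truth$puncta$radial_class == "perinuclear")
    expect_lt(abs(phat - bias), 3.5 * sqrt(bias * (1 - bias) / n))
  }
})

test_that("every ground-truth punctum is bright above background at its center", {
  f <- render_cell_field(field_spec(seed = 11))
  img <- f$image$channels$marker
  spec <- f$truth$spec
  pix <- cbind(pmin(pmax(round(f$truth$puncta$row), 1), nrow(img)),
               pmin(pmax(round(f$truth$puncta$col), 1), ncol(img)))
  expect_true(all(img[pix] > spec$background + 3 * spec$noise_sd))
})

test_that("overcrowded specs fail with a density message", {
  expect_error(render_cell_field(field_spec(n_cells = 80, seed = 1)),
               "non-overlapping")
})

test_that("simulate_plate does the bookkeeping and validates the role map", {
  roles <- data.frame(well = c("A1", "A2", "A3", "B1", "B2", "B3"),
                      role = c("negative_control", "negative_control",
                               "positive_control", "positive_control",
                               "compound", "compound"),
                      compound = c(NA, NA, NA, NA, "drugX", "drugY"))
  ps <- plate_spec(roles, n_rows = 2, n_cols = 3, fields_per_well = 1,
                   field = field_spec(n_cells = 3), seed = 2)
  sim <- simulate_plate(ps)
  expect_length(sim$wells, 6)
  expect_equal(vapply(sim$wells, function(w) w$role, character(1)),
               setNames(roles$role, roles$well))
  expect_equal(sim$wells$B2$compound, "drugX")
  expect_equal(sim$wells$A1$bias, 0.1)
  expect_equal(sim$wells$B1$bias, 0.9)
  expect_length(sim$wells$A1$fields, 1)
  # per-well fields differ (independent substreams)
  expect_false(identical(sim$wells$A1$fields[[1]]$image,
                         sim$wells$A2$fields[[1]]$image))
  # effect map drives compound bias
  ps2 <- plate_spec(roles, n_rows = 2, n_cols = 3,
                    effect_map = c(drugX = 0.85), fields_per_well = 1,
                    field = field_spec(n_cells = 3), seed = 2)
  sim2 <- simulate_plate(ps2)
  expect_equal(sim2$wells$B2$bias, 0.85)
  expect_equal(sim2$wells$B3$bias, 0.1)

  expect_error(plate_spec(roles[-1, ], n_rows = 2, n_cols = 3),
               "cover all")
  roles_bad <- roles; roles_bad$role[1:2] <- "compound"
  expect_error(plate_spec(roles_bad, n_rows = 2, n_cols = 3),
               "control role")
})

test_that("screen_layout fills the plate with the requested well mix", {
  lay <- screen_layout(64, 4, 4, n_cols = 9)
  expect_equal(nrow(lay), 72)
  expect_equal(sum(lay$role == "compound"), 64)
  expect_equal(sum(is.na(lay$compound)), 8)
  expect_error(screen_layout(60, 4, 4, n_cols = 9), "exactly")
})

test_that("time-course profiles are monotone and drive the ground truth", {
  tps <- seq(0, 24, 4)
  for (cls in c("early_LMP", "late_LMP")) {
    sp <- timecourse_spec(tps, class = cls, seed = 3)
    expect_true(all(diff(puncta_rate(sp, tps)) >= 0))
    expect_true(all(puncta_rate(sp, tps) >= 0))
  }
  flat <- timecourse_spec(tps, class = "none", seed = 3)
  expect_true(all(puncta_rate(flat, tps) == flat$baseline_rate))

  # early class: mean truth puncta count at 12 h exceeds the 0 h count
  sp <- timecourse_spec(c(0, 12), class = "early_LMP",
                        field = field_spec(n_cells = 8), seed = 4)
  tc <- simulate_timecourse(sp)
  cnt <- vapply(tc, function(x) nrow(x$truth$puncta), numeric(1))
  expect_gt(cnt[2], cnt[1])

  expect_error(timecourse_spec(numeric(0)), "empty")
})

test_that("death ramp reaches the specified endpoint within binomial error", {
  # pool several seeds at the final timepoint: dead fraction ~ 0.5
  dead <- n <- 0
  for (s in 1:6) {
    sp <- timecourse_spec(c(0, 12, 24), class = "none",
                          death_end_frac = 0.5,
                          field = field_spec(n_cells = 10), seed = s)
    tc <- simulate_timecourse(sp)
    fl <- tc[[3]]$truth$nuclei$dead
    dead <- dead + sum(fl); n <- n + length(fl)
  }
  expect_lt(abs(dead / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("dead cells are rendered shrunken and bright", {
  f <- render_cell_field(field_spec(dead_fraction = 1, n_cells = 5,
                                    seed = 6))
  expect_true(all(f$truth$nuclei$dead))
  expect_equal(f$truth$nuclei$radius_rendered,
               f$truth$nuclei$radius * 0.5)
  # peak intensity doubled relative to the live level
  expect_gt(max(f$image$channels$nucleus), 1.8 * 3000)
})

test_that("organoid pairs respect growth factor, protrusions and contrast", {
  # identity growth
  op1 <- render_organoid_pair(organoid_spec(growth_factor = 1, seed = 2))
  expect_equal(op1$truth$area_d1_px, op1$truth$area_d3_px)
  # doubling within 2 % rasterization tolerance
  op2 <- render_organoid_pair(organoid_spec(growth_factor = 2, seed = 2))
  expect_lt(abs(op2$truth$area_d3_px / op2$truth$area_d1_px - 2), 0.02 * 2)
  # organoid darker than background in the rendered image
  img <- op2$image_d1$channels$tl
  expect_lt(mean(img[op2$truth$mask_d1]), mean(img[!op2$truth$mask_d1]))
  # five protrusions -> five connected extensions beyond the core disk
  op3 <- render_organoid_pair(organoid_spec(growth_factor = 1.2,
                                            n_protrusions = 5, seed = 2))
  core_rad <- sqrt(1.2 * 3500 / pi)
  H <- nrow(op3$truth$mask_d3)
  d <- sqrt((row(op3$truth$mask_d3) - (H + 1) / 2)^2 +
              (col(op3$truth$mask_d3) - (H + 1) / 2)^2)
  ext <- op3$truth$mask_d3 & d > core_rad + 1.5
  expect_equal(max(perilyso:::label_components(ext)), 5)
  # protrusions absent at day 1
  expect_equal(sum(op3$truth$mask_d1 & d > core_rad + 1.5), 0)
  expect_error(organoid_spec(area_d1_px = 1e6), "larger than the image")
  expect_error(organoid_spec(growth_factor = -1), ">= 0")
  expect_error(organoid_spec(organoid_level = 4000), "darker")
})

test_that("flux fields quench GFP on red puncta and keep the truth labels", {
  ff <- render_flux_field(field_spec(n_cells = 5, seed = 12),
                          red_fraction = 0.5)
  expect_setequal(names(ff$image$channels), c("nucleus", "gfp", "rfp"))
  tr <- ff$truth$puncta
  expect_true(all(tr$flux_class %in% c("red", "yellow")))
  pix <- cbind(pmin(pmax(round(tr$row), 1), 192),
               pmin(pmax(round(tr$col), 1), 192))
  g <- ff$image$channels$gfp[pix]; r <- ff$image$channels$rfp[pix]
  expect_true(all(g[tr$flux_class == "red"] < 0.5 * r[tr$flux_class == "red"]))
})

test_that("io round-trips: tiff channels, truth sidecar and yaml spec", {
  tmp <- withr::local_tempdir()
  f <- render_cell_field(field_spec(n_cells = 3, seed = 3))
  paths <- write_field_tiff(f$image, file.path(tmp, "w1_f1"))
  expect_true(all(file.exists(file.path(tmp, c("w1_f1_nucleus.tif",
                                               "w1_f1_marker.tif")))))
  back <- read_tiff_matrix(file.path(tmp, "w1_f1_marker.tif"))
  expect_equal(dim(back), c(192, 192))
  expect_lt(max(abs(back - f$image$channels$marker)), 1)  # 16-bit rounding
  df <- write_ground_truth_csv(f$truth, file.path(tmp, "truth.csv"),
                               well = "w1", field = 1)
  re <- utils::read.csv(file.path(tmp, "truth.csv"))
  expect_equal(nrow(re), nrow(f$truth$nuclei) + nrow(f$truth$puncta))
  expect_true(all(re$x >= 0 & re$y >= 0))
  write_spec_yaml(field_spec(seed = 3), file.path(tmp, "spec.yaml"))
  y <- yaml::read_yaml(file.path(tmp, "spec.yaml"))
  expect_equal(y$seed, 3)
  expect_equal(y$spec_class, "field_spec")
})
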