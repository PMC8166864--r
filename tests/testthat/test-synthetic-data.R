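test_that("phantom rendering is a pure function of (params, optics, seed)", {
  optics <- default_optics()
  p <- demo_params()
  g1 <- render_grain(p, optics, seed = 42)
  g2 <- render_grain(p, optics, seed = 42)
  expect_identical(g1$voxels, g2$voxels)
  g3 <- render_grain(p, optics, seed = 43)
  expect_false(identical(g1$voxels, g3$voxels))
})

test_that("rendered grains are dark discs with visible pores on the rim", {
  optics <- default_optics()
  # angularity and texture off so the rim ring sits at a known radius
  p <- grain_phantom_params("membranacea", 11, 7, 0.5, 0, 0, focal_z_um = 17.1)
  g <- render_grain(p, optics, seed = 3)
  sl <- g$voxels[, , attr(g, "sharpest_slice")]
  ctr <- attr(g, "centre")
  R <- 11 / 2 / optics$pixel_size_um
  pore_r <- max(2, 0.8 / optics$pixel_size_um)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ring <- sl[cbind(round(ctr[1] + (R - 0.6 * pore_r) * cos(th)),
                   round(ctr[2] + (R - 0.6 * pore_r) * sin(th)))]
  dark <- ring < 0.22
  runs <- sum(diff(c(dark, dark[1])) == 1)
  expect_equal(runs, 7)    # one dark run per pore
  expect_lt(min(ring), 0.2)
  expect_gt(mean(sl[1, ]), 0.9)   # bright background at the crop edge
})

test_that("pore-adjacent rim thickening scales with annulus strength", {
  optics <- default_optics()
  rim_area <- vapply(c(0, 0.5, 1), function(a) {
    p <- grain_phantom_params("urtica", 16, 3, a, 0, 0, focal_z_um = 17.1)
    g <- render_grain(p, optics, seed = 9)
    sum(g$voxels[, , attr(g, "sharpest_slice")] < 0.45)
  }, numeric(1))
  expect_true(all(diff(rim_area) > 0))
})

test_that("phantom parameter validation rejects impossible grains", {
  expect_error(grain_phantom_params("urtica", -1, 3, 0.5, 0, 0, 17), "diameter")
  expect_error(grain_phantom_params("urtica", 15, 0, 0.5, 0, 0, 17), "n_pores")
  expect_error(grain_phantom_params("weed", 15, 3, 0.5, 0, 0, 17), "class")
  tiny <- grain_phantom_params("urtica", 13, 3, 0.5, 0, 0, 17)
  coarse <- scene_config(c(50, 50), pixel_size_um = 5)
  expect_error(render_grain(tiny, coarse), "4 px")
})

test_that("class presets encode the documented morphological contrasts", {
  withr::with_seed(7, {
    draws <- lapply(pollen_classes(), function(cl)
      replicate(120, unclass(sample_grain_params(cl)), simplify = FALSE))
    names(draws) <- pollen_classes()
  })
  stat <- function(cl, f) mean(vapply(draws[[cl]], f, numeric(1)))
  pores <- vapply(pollen_classes(), stat, numeric(1),
                  f = function(p) p$n_pores)
  expect_gt(pores[["membranacea"]], pores[["urtica"]])
  expect_gt(pores[["membranacea"]], pores[["parietaria"]])
  expect_true(all(vapply(draws$membranacea,
                         function(p) p$n_pores >= 6, logical(1))))
  expect_gt(stat("urtica", function(p) p$annulus_strength),
            stat("parietaria", function(p) p$annulus_strength))
  expect_lt(stat("membranacea", function(p) p$diameter_um),
            stat("urtica", function(p) p$diameter_um))
  expect_gt(stat("parietaria", function(p) p$texture_amplitude),
            stat("urtica", function(p) p$texture_amplitude))
})

test_that("a phantom's footprint matches its nominal diameter within 1 px", {
  optics <- default_optics()
  for (spec in list(c(10, 1), c(12, 2), c(16, 3), c(19, 4))) {
    cl <- switch(spec[2] %% 3 + 1, "urtica", "parietaria", "membranacea")
    pr <- class_presets()[[cl]]
    d <- min(max(spec[1], pr$diameter_range[1]), pr$diameter_range[2])
    p <- grain_phantom_params(cl, d, 4, 0.5, 0.1, pr$angularity$mean,
                              focal_z_um = 17.1)
    g <- render_grain(p, optics, seed = spec[2])
    sl <- g$voxels[, , attr(g, "sharpest_slice")]
    # mid-level threshold marks the geometric footprint of the dark grain
    m <- binarize(sl, method = "fixed", fixed_threshold = 0.6)
    expect_lt(abs(2 * sqrt(sum(m) / pi) - d / optics$pixel_size_um), 1)
  }
})

test_that("an empty noiseless scene is uniform background", {
  sc <- scene_config(c(40, 40), noise_sd = 0, background_level = 0.85,
                     n_slices = 3, seed = 1)
  out <- render_scene(sc)
  expect_true(all(out$stack$voxels == 0.85))
  expect_equal(nrow(out$ground_truth), 0)
})

test_that("scene ground truth flags overlap and border contact", {
  p1 <- demo_params(diameter_um = 14)
  p2 <- demo_params("parietaria", diameter_um = 12, annulus = 0.2)
  # centres 60 px apart: footprints (radius ~44 + 38 px) overlap
  sc <- scene_config(c(300, 300), grains = list(
    list(params = p1, centre = c(120, 120)),
    list(params = p2, centre = c(120, 180)),
    list(params = demo_params(diameter_um = 13), centre = c(230, 40))),
    seed = 5)
  gt <- render_scene(sc)$ground_truth
  expect_equal(gt$overlap, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(gt), 3)

  sc_b <- scene_config(c(200, 200), grains = list(
    list(params = p2, centre = c(15, 100))), seed = 5)
  expect_true(render_scene(sc_b)$ground_truth$touches_border)
  expect_error(scene_config(c(200, 200), grains = list(
    list(params = p2, centre = c(300, 100)))), "bounds")
})

test_that("a centred grain yields one clean ground-truth record", {
  out <- render_scene(single_grain_scene(demo_params(), seed = 2))
  gt <- out$ground_truth
  expect_equal(nrow(gt), 1)
  expect_false(gt$overlap)
  expect_false(gt$touches_border)
  expect_equal(gt$class_label, "urtica")
})

test_that("scene seed controls noise but not geometry", {
  p <- demo_params()
  mk <- function(seed) {
    side <- 180
    scene_config(c(side, side),
                 grains = list(list(params = p, centre = c(90, 90))),
                 noise_sd = 0.02, seed = seed)
  }
  o1 <- render_scene(mk(1)); o1b <- render_scene(mk(1)); o2 <- render_scene(mk(2))
  expect_identical(o1$stack$voxels, o1b$stack$voxels)
  expect_false(identical(o1$stack$voxels, o2$stack$voxels))
  expect_identical(o1$ground_truth, o2$ground_truth)
})

test_that("generate_dataset writes a reproducible labelled library", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generate_dataset(d1, n_per_class = 2, seed = 31)
  r2 <- generate_dataset(d2, n_per_class = 2, seed = 31)
  expect_equal(nrow(r1$manifest), 6)
  expect_equal(as.integer(table(r1$manifest$label)), rep(2L, 3))
  expect_equal(r1$manifest$label, r2$manifest$label)
  expect_equal(basename(r1$manifest$path), basename(r2$manifest$path))
  s1 <- read_stack(r1$manifest$path[1])
  s2 <- read_stack(r2$manifest$path[1])
  expect_identical(s1$voxels, s2$voxels)
  expect_equal(s1$pixel_size_um, 0.16)
  expect_equal(dim(s1$voxels)[3], 20)
  gt <- read.csv(file.path(d1, "ground_truth.csv"))
  expect_equal(nrow(gt), 6)
})

test_that("scene configs round trip through YAML", {
  sc <- single_grain_scene(demo_params(), seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(sc, path)
  sc2 <- read_scene_config(path)
  expect_equal(sc2$image_shape_px, sc$image_shape_px)
  expect_equal(sc2$seed, sc$seed)
  expect_equal(sc2$grains[[1]]$params$diameter_um,
               sc$grains[[1]]$params$diameter_um)
  expect_identical(render_scene(sc2)$stack$voxels,
                   render_scene(sc)$stack$voxels)
})
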