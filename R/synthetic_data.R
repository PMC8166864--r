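#' Class presets for Urticaceae pollen phantoms
#'
#' Parameter distributions encoding the morphological contrasts that separate
#' the three monitored classes in brightfield stacks: Urtica grains are the
#' largest (13-20 um) with 3-4 pores, a pronounced annulus (exine thickening
#' around each pore) and a slightly angular outline; Parietaria grains are
#' somewhat smaller (11-16 um) with a weak annulus but coarser surface
#' ornamentation; Urtica membranacea grains are small (10-12 um) with six or
#' more pores and the most angular outline. Only the direction of these
#' contrasts is established morphology; the magnitudes are package choices,
#' picked so each contrast is visible at typical 100x sampling (~0.16 um/px).
#'
#' @return Named list of per-class preset lists with fields `diameter_range`
#'   (um), `pore_range` (count), `annulus` (mean, sd, range), `texture`
#'   (mean, sd), `angularity` (mean, sd).
#' @export
class_presets <- function() {
  list(
    urtica = list(diameter_range = c(13, 20), pore_range = c(3L, 4L),
                  annulus = list(mean = 0.80, sd = 0.06, range = c(0.60, 0.95)),
                  texture = list(mean = 0.06, sd = 0.02),
                  angularity = list(mean = 0.15, sd = 0.04)),
    parietaria = list(diameter_range = c(11, 16), pore_range = c(3L, 4L),
                      annulus = list(mean = 0.25, sd = 0.06, range = c(0.05, 0.40)),
                      texture = list(mean = 0.20, sd = 0.04),
                      angularity = list(mean = 0.06, sd = 0.02)),
    membranacea = list(diameter_range = c(10, 12), pore_range = c(6L, 8L),
                       annulus = list(mean = 0.55, sd = 0.06, range = c(0.35, 0.75)),
                       texture = list(mean = 0.08, sd = 0.02),
                       angularity = list(mean = 0.30, sd = 0.05))
  )
}

#' @export
pollen_classes <- function() c("urtica", "parietaria", "membranacea")

#' Phantom parameters for a single pollen grain
#'
#' @param class_label one of `"urtica"`, `"parietaria"`, `"membranacea"`.
#' @param diameter_um grain diameter in micrometres (> 0).
#' @param n_pores number of pores (>= 1).
#' @param annulus_strength pore-adjacent rim thickening, in `[0, 1]`; 0 means
#'   a flat rim with no thickening near pores.
#' @param texture_amplitude amplitude of the multiplicative high-frequency
#'   surface ornamentation (>= 0).
#' @param outline_angularity amplitude of the radial perturbation of the
#'   grain outline, in `[0, 1]`; 0 is a perfect disc.
#' @param focal_z_um depth of the grain's sharpest focal plane, measured from
#'   slice 1 (z = 0).
#' @return An object of class `grain_phantom_params`.
#' @export
grain_phantom_params <- function(class_label, diameter_um, n_pores,
                                 annulus_strength, texture_amplitude,
                                 outline_angularity, focal_z_um) {
  .assert(class_label %in% pollen_classes(), "unknown class label: %s",
          as.character(class_label)[1])
  .assert(is.numeric(diameter_um) && diameter_um > 0,
          "diameter_um must be positive")
  .assert(n_pores >= 1, "n_pores must be >= 1")
  .assert(annulus_strength >= 0 && annulus_strength <= 1,
          "annulus_strength must be in [0, 1]")
  .assert(texture_amplitude >= 0, "texture_amplitude must be >= 0")
  .assert(outline_angularity >= 0 && outline_angularity <= 1,
          "outline_angularity must be in [0, 1]")
  structure(list(class_label = class_label,
                 diameter_um = as.numeric(diameter_um),
                 n_pores = as.integer(n_pores),
                 annulus_strength = as.numeric(annulus_strength),
                 texture_amplitude = as.numeric(texture_amplitude),
                 outline_angularity = as.numeric(outline_angularity),
                 focal_z_um = as.numeric(focal_z_um)),
            class = "grain_phantom_params")
}

#' Draw phantom parameters from a class preset
#'
#' @param class_label class name.
#' @param presets preset list from [class_presets()].
#' @param focal_z_range range (um) the sharpest plane is drawn from.
#' @param plant_effect optional per-plant random effect, a list with numeric
#'   `diameter`, `annulus`, `texture` shifts (see [sample_plant_effects()]).
#' @return A [grain_phantom_params()] drawn from the preset distributions
#'   (uses the current RNG state).
#' @export
sample_grain_params <- function(class_label, presets = class_presets(),
                                focal_z_range = c(12, 22),
                                plant_effect = NULL) {
  p <- presets[[class_label]]
  .assert(!is.null(p), "no preset for class %s", class_label)
  eff <- plant_effect %||% list(diameter = 0, annulus = 0, texture = 0)
  clamp <- function(x, r) min(max(x, r[1]), r[2])
  d <- clamp(runif(1, p$diameter_range[1], p$diameter_range[2]) + eff$diameter,
             p$diameter_range)
  ann <- clamp(rnorm(1, p$annulus$mean + eff$annulus, p$annulus$sd),
               p$annulus$range)
  tex <- max(0, rnorm(1, p$texture$mean + eff$texture, p$texture$sd))
  ang <- clamp(rnorm(1, p$angularity$mean, p$angularity$sd), c(0, 1))
  grain_phantom_params(class_label, diameter_um = d,
                       n_pores = sample(seq(p$pore_range[1], p$pore_range[2]), 1),
                       annulus_strength = ann, texture_amplitude = tex,
                       outline_angularity = ang,
                       focal_z_um = runif(1, focal_z_range[1], focal_z_range[2]))
}

#' Per-plant random effects
#'
#' Grains sampled from the same plant share small shifts in mean diameter,
#' annulus prominence and ornamentation, emulating the within-species
#' variability between individual source plants.
#'
#' @param n_plants number of plants.
#' @return List of `n_plants` effect lists (uses the current RNG state).
#' @export
sample_plant_effects <- function(n_plants) {
  lapply(seq_len(n_plants), function(i) {
    list(diameter = rnorm(1, 0, 0.4),
         annulus = rnorm(1, 0, 0.03),
         texture = rnorm(1, 0, 0.015))
  })
}

#' Scene configuration for the synthetic renderer
#'
#' @param image_shape_px `c(rows, cols)` of the rendered frame.
#' @param grains list of entries `list(params = <grain_phantom_params>,
#'   centre = c(row, col))`; centres must lie inside the frame.
#' @param pixel_size_um pixel pitch (default 0.16 um/px, plausible for a 100x
#'   oil objective; configurable everywhere).
#' @param n_slices number of focal slices (default 20).
#' @param z_step_um focal step (default 1.8 um).
#' @param debris_density debris particles per 1000 um^2.
#' @param noise_sd additive Gaussian detector noise sd (intensity units).
#' @param background_level background intensity in `[0, 1]`.
#' @param seed integer; fully determines the rendered stack.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_shape_px, grains = list(),
                         pixel_size_um = 0.16, n_slices = 20L,
                         z_step_um = 1.8, debris_density = 0,
                         noise_sd = 0.01, background_level = 0.85,
                         seed = 1L) {
  .assert(length(image_shape_px) == 2L && all(image_shape_px >= 8),
          "image_shape_px must be c(rows, cols)")
  for (g in grains) {
    .assert(inherits(g$params, "grain_phantom_params"),
            "each grain entry needs $params of class grain_phantom_params")
    .assert(length(g$centre) == 2L &&
              all(g$centre >= 1) && g$centre[1] <= image_shape_px[1] &&
              g$centre[2] <= image_shape_px[2],
            "grain centre %s outside image bounds",
            paste(round(g$centre), collapse = ","))
  }
  structure(list(image_shape_px = as.integer(image_shape_px),
                 grains = grains,
                 pixel_size_um = pixel_size_um, n_slices = as.integer(n_slices),
                 z_step_um = z_step_um, debris_density = debris_density,
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# run code with a private, restored RNG stream
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}

# optics defaults of the defocus model sigma(z) = sigma0 + rate * |z - focal_z|
defocus_sigma0_px <- 0.5
defocus_rate_px_per_um <- 0.35

# intensity constants of the phantom, relative to a background of 1.0
phantom_levels <- list(interior = 0.62, rim = 0.30, pore = 0.12)

# radial boundary R(theta) of a grain, in px: disc perturbed by low-order
# harmonics with amplitude proportional to outline_angularity
grain_boundary <- function(theta, radius_px, angularity, phases) {
  harm <- c(3, 4, 5, 6)
  w <- c(0.45, 0.30, 0.15, 0.10) * 0.16 # total relative amplitude at angularity 1
  pert <- 0
  for (i in seq_along(harm)) pert <- pert + w[i] * cos(harm[i] * theta + phases[i])
  radius_px * (1 + angularity * pert)
}

#' Render one pollen grain phantom as a small Z-stack
#'
#' The grain is modelled as a dark-rimmed disc on a bright background: the
#' rim (exine wall) is darkest, the interior moderately dark with
#' multiplicative ornamentation texture, and `n_pores` darker pore spots sit
#' on the rim. Rim thickness widens near each pore in proportion to
#' `annulus_strength`. Each slice is the sharp grain blurred with a Gaussian
#' of width `sigma(z) = sigma0 + rate * |z - focal_z_um|`, emulating defocus.
#'
#' @param params a [grain_phantom_params()].
#' @param optics a [scene_config()] supplying `pixel_size_um`, `n_slices`,
#'   `z_step_um` (grain list is ignored).
#' @param seed optional integer; when given, rendering is a pure function of
#'   `(params, optics, seed)`.
#' @return A [zstack()] with attributes `mask` (the sharp in-focus grain
#'   footprint), `centre` (row, col of the grain centre within the crop) and
#'   `sharpest_slice`.
#' @export
render_grain <- function(params, optics, seed = NULL) {
  .assert(inherits(params, "grain_phantom_params"), "params must be grain_phantom_params")
  radius_px <- params$diameter_um / 2 / optics$pixel_size_um
  .assert(2 * radius_px >= 4, "grain spans < 4 px at this pixel size")
  if (!is.null(seed)) return(with_rng(seed, render_grain(params, optics)))

  zs <- (seq_len(optics$n_slices) - 1) * optics$z_step_um
  sigmas <- defocus_sigma0_px + defocus_rate_px_per_um * abs(zs - params$focal_z_um)
  pad <- ceiling(2 * max(sigmas)) + 4
  half <- ceiling(radius_px * (1 + 0.2 * params$outline_angularity)) + pad
  n <- 2L * as.integer(half) + 1L
  ctr <- half + 1

  rr <- matrix(seq_len(n) - ctr, n, n)
  cc <- t(rr)
  rho <- sqrt(rr^2 + cc^2)
  theta <- atan2(cc, rr)

  phases <- runif(4, 0, 2 * pi)
  rb <- grain_boundary(theta, radius_px, params$outline_angularity, phases)
  inside <- rho <= rb

  # rim width: base thickness plus pore-adjacent (annulus) widening
  t0 <- max(1.5, 0.06 * radius_px)
  spacing <- 2 * pi / params$n_pores
  pore_theta <- (seq_len(params$n_pores) - 1) * spacing +
    runif(params$n_pores, -0.25, 0.25) * spacing
  sigma_a <- 0.35 # angular width of the annulus bump, radians
  ann <- matrix(0, n, n)
  for (tp in pore_theta) {
    dang <- abs(((theta - tp + pi) %% (2 * pi)) - pi)
    ann <- ann + exp(-dang^2 / (2 * sigma_a^2))
  }
  rim_w <- t0 * (1 + 2.5 * params$annulus_strength * ann)
  rim <- inside & (rho >= rb - rim_w)

  img <- matrix(1, n, n)
  img[inside] <- phantom_levels$interior
  img[rim] <- phantom_levels$rim

  # pores: dark spots centred just inside the boundary
  pore_r <- max(2, 0.8 / optics$pixel_size_um)
  for (tp in pore_theta) {
    rb_p <- grain_boundary(tp, radius_px, params$outline_angularity, phases)
    pr <- ctr + (rb_p - 0.6 * pore_r) * cos(tp)
    pc <- ctr + (rb_p - 0.6 * pore_r) * sin(tp)
    img[(rr - (pr - ctr))^2 + (cc - (pc - ctr))^2 <= pore_r^2] <- phantom_levels$pore
  }

  if (params$texture_amplitude > 0) {
    tex <- matrix(rnorm(n * n), n, n)
    tex <- EBImage::gblur(tex, sigma = 1.2, boundary = "replicate")
    tex <- tex / max(sd(tex), 1e-12)
    img[inside] <- pmin(pmax(img[inside] * (1 + params$texture_amplitude * tex[inside]), 0.02), 1)
  }

  vox <- array(0, dim = c(n, n, optics$n_slices))
  for (s in seq_len(optics$n_slices)) {
    vox[, , s] <- EBImage::gblur(img, sigma = max(sigmas[s], 0.3),
                                 boundary = "replicate")
  }
  out <- zstack(pmin(pmax(vox, 0), 1), pixel_size_um = optics$pixel_size_um,
                z_step_um = optics$z_step_um)
  attr(out, "mask") <- inside
  attr(out, "centre") <- c(ctr, ctr)
  attr(out, "sharpest_slice") <- which.min(abs(zs - params$focal_z_um))
  out
}

# irregular dark debris blob rendered like a grain but smaller and asymmetric
render_debris <- function(optics, focal_z_um, radius_um, level) {
  fake <- grain_phantom_params("urtica", diameter_um = max(2 * radius_um, 1.5),
                               n_pores = 1L, annulus_strength = 0,
                               texture_amplitude = 0,
                               outline_angularity = 0, focal_z_um = focal_z_um)
  radius_px <- radius_um / optics$pixel_size_um
  zs <- (seq_len(optics$n_slices) - 1) * optics$z_step_um
  sigmas <- defocus_sigma0_px + defocus_rate_px_per_um * abs(zs - focal_z_um)
  pad <- ceiling(2 * max(sigmas)) + 3
  half <- ceiling(radius_px * 1.5) + pad
  n <- 2L * as.integer(half) + 1L
  ctr <- half + 1
  rr <- matrix(seq_len(n) - ctr, n, n); cc <- t(rr)
  rho <- sqrt(rr^2 + cc^2); theta <- atan2(cc, rr)
  # strongly perturbed outline -> angular polygon-like blob
  rb <- grain_boundary(theta, radius_px, 1, runif(4, 0, 2 * pi)) *
    (1 + 0.3 * cos(2 * theta + runif(1, 0, 2 * pi)))
  img <- matrix(1, n, n)
  img[rho <= rb] <- level
  vox <- array(0, dim = c(n, n, optics$n_slices))
  for (s in seq_len(optics$n_slices))
    vox[, , s] <- EBImage::gblur(img, sigma = max(sigmas[s], 0.3),
                                 boundary = "replicate")
  list(vox = pmin(pmax(vox, 0), 1), centre = c(ctr, ctr))
}

# composite a rendered sub-stack (background 1.0) into a canvas by pixelwise
# minimum, centred at (row, col); returns the modified canvas
composite_min <- function(canvas, sub, centre, scale = 1) {
  d <- dim(sub); H <- dim(canvas)[1]; W <- dim(canvas)[2]
  ctr <- attr(sub, "ctr") %||% c((d[1] + 1) / 2, (d[2] + 1) / 2)
  r0 <- round(centre[1]) - (ctr[1] - 1); c0 <- round(centre[2]) - (ctr[2] - 1)
  rs <- max(1, r0):min(H, r0 + d[1] - 1)
  cs <- max(1, c0):min(W, c0 + d[2] - 1)
  if (length(rs) == 0 || length(cs) == 0) return(canvas)
  srs <- rs - r0 + 1; scs <- cs - c0 + 1
  canvas[rs, cs, ] <- pmin(canvas[rs, cs, , drop = FALSE],
                           sub[srs, scs, , drop = FALSE] * scale)
  canvas
}

place_mask <- function(H, W, mask, centre) {
  d <- dim(mask)
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  r0 <- round(centre[1]) - (ctr[1] - 1); c0 <- round(centre[2]) - (ctr[2] - 1)
  out <- matrix(FALSE, H, W)
  rs <- max(1, r0):min(H, r0 + d[1] - 1)
  cs <- max(1, c0):min(W, c0 + d[2] - 1)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- mask[rs - r0 + 1, cs - c0 + 1]
  out
}

#' Render a full synthetic scene with ground truth
#'
#' Composites every configured grain into a calibrated Z-stack (pixelwise
#' minimum, so grains and debris may legally overlap), adds debris blobs at
#' random depths and additive Gaussian detector noise, and returns a ground
#' truth table flagging grains whose footprints overlap or touch
#' (< 1 background px separation) and grains whose disc crosses the frame
#' edge. The `seed` in the config fully determines the output.
#'
#' @param config a [scene_config()].
#' @return `list(stack = <zstack>, ground_truth = <data.frame>)`; the ground
#'   truth has one row per configured grain with columns `grain`,
#'   `centre_row`, `centre_col`, `diameter_um`, `class_label`, `overlap`,
#'   `touches_border`.
#' @export
render_scene <- function(config) {
  .assert(inherits(config, "scene_config"), "config must be a scene_config")
  with_rng(config$seed, {
    H <- config$image_shape_px[1]; W <- config$image_shape_px[2]
    canvas <- array(1, dim = c(H, W, config$n_slices))
    masks <- vector("list", length(config$grains))
    for (i in seq_along(config$grains)) {
      g <- config$grains[[i]]
      sub <- render_grain(g$params, config)
      attr(sub$voxels, "ctr") <- attr(sub, "centre")
      canvas <- composite_min(canvas, sub$voxels, g$centre)
      masks[[i]] <- place_mask(H, W, attr(sub, "mask"), g$centre)
    }
    area_um2 <- H * W * config$pixel_size_um^2
    n_debris <- round(config$debris_density * area_um2 / 1000)
    if (n_debris > 0) {
      zmax <- (config$n_slices - 1) * config$z_step_um
      for (i in seq_len(n_debris)) {
        deb <- render_debris(config,
                             focal_z_um = runif(1, 0, zmax),
                             radius_um = runif(1, 0.8, 2.5),
                             level = runif(1, 0.3, 0.6))
        attr(deb$vox, "ctr") <- deb$centre
        canvas <- composite_min(canvas, deb$vox,
                                c(runif(1, 1, H), runif(1, 1, W)))
      }
    }
    canvas <- canvas * config$background_level
    if (config$noise_sd > 0)
      canvas <- canvas + array(rnorm(length(canvas), 0, config$noise_sd),
                               dim = dim(canvas))
    canvas <- pmin(pmax(canvas, 0), 1)

    gt <- ground_truth_table(config, masks, H, W)
    list(stack = zstack(canvas, pixel_size_um = config$pixel_size_um,
                        z_step_um = config$z_step_um),
         ground_truth = gt)
  })
}

ground_truth_table <- function(config, masks, H, W) {
  k <- length(config$grains)
  overlap <- logical(k); border <- logical(k)
  if (k > 0) {
    kern <- EBImage::makeBrush(3, "box")
    dil <- lapply(masks, function(m)
      EBImage::dilate(EBImage::Image(m * 1), kern) > 0)
    for (i in seq_len(k)) {
      m <- masks[[i]]
      border[i] <- any(m[1, ]) || any(m[H, ]) || any(m[, 1]) || any(m[, W])
      for (j in seq_len(k)) if (j != i && any(dil[[i]] & masks[[j]]))
        overlap[i] <- TRUE
    }
    # a grain whose mask was clipped by the frame also touches the border
    full_area <- vapply(seq_len(k), function(i) {
      r <- config$grains[[i]]$params$diameter_um / 2 / config$pixel_size_um
      pi * r^2
    }, numeric(1))
    clipped <- vapply(masks, sum, numeric(1)) < 0.98 * full_area
    border <- border | clipped
  }
  data.frame(
    grain = seq_len(k),
    centre_row = vapply(config$grains, function(g) g$centre[1], numeric(1)),
    centre_col = vapply(config$grains, function(g) g$centre[2], numeric(1)),
    diameter_um = vapply(config$grains, function(g) g$params$diameter_um, numeric(1)),
    class_label = vapply(config$grains, function(g) g$params$class_label, character(1)),
    overlap = overlap, touches_border = border,
    stringsAsFactors = FALSE
  )
}

#' Generate a labelled synthetic reference library
#'
#' Renders `n_per_class` single-grain Z-stacks per class, each grain drawn
#' from its class preset with a per-plant random effect, and writes the
#' stacks as multi-page TIFFs plus a manifest CSV (`path,label,sample_id`)
#' and a ground-truth CSV. Regeneration with the same seed reproduces the
#' manifest and pixel data exactly.
#'
#' @param out_dir output directory (created if missing).
#' @param n_per_class stacks per class (>= 1).
#' @param classes class labels to generate.
#' @param presets per-class parameter distributions ([class_presets()]).
#' @param seed integer master seed.
#' @param pixel_size_um,n_slices,z_step_um,noise_sd,background_level optics,
#'   as in [scene_config()].
#' @param n_plants named vector: plants sampled per class (grains are
#'   attributed to plants round-robin; images from one plant share a small
#'   parameter shift).
#' @return Invisibly, `list(manifest, ground_truth)`; both are also written
#'   to `manifest.csv` and `ground_truth.csv` in `out_dir`.
#' @export
generate_dataset <- function(out_dir, n_per_class, classes = pollen_classes(),
                             presets = class_presets(), seed = 1L,
                             pixel_size_um = 0.16, n_slices = 20L,
                             z_step_um = 1.8, noise_sd = 0.01,
                             background_level = 0.85,
                             n_plants = c(urtica = 8L, parietaria = 8L,
                                          membranacea = 5L)) {
  .assert(n_per_class >= 1, "n_per_class must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); gt <- list(); idx <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    np <- unname(if (cl %in% names(n_plants)) n_plants[[cl]] else 4L)
    effects <- with_rng(derive_seed(seed, ci), sample_plant_effects(np))
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      plant <- ((i - 1L) %% np) + 1L
      sseed <- derive_seed(seed, ci * 100000L + i)
      scn <- with_rng(sseed, {
        params <- sample_grain_params(cl, presets, plant_effect = effects[[plant]])
        side <- 2L * as.integer(ceiling(params$diameter_um / 2 / pixel_size_um)) + 80L
        scene_config(c(side, side),
                     grains = list(list(params = params,
                                        centre = c((side + 1) / 2, (side + 1) / 2))),
                     pixel_size_um = pixel_size_um, n_slices = n_slices,
                     z_step_um = z_step_um, noise_sd = noise_sd,
                     background_level = background_level,
                     seed = derive_seed(sseed, 7L))
      })
      sc <- render_scene(scn)
      fn <- file.path(out_dir, sprintf("%s_%04d.tif", cl, i))
      write_stack(sc$stack, fn)
      manifest[[idx]] <- data.frame(path = fn, label = cl,
                                    sample_id = sprintf("%s_plant%02d", cl, plant),
                                    stringsAsFactors = FALSE)
      g <- sc$ground_truth
      g$path <- fn
      gt[[idx]] <- g
    }
  }
  manifest <- do.call(rbind, manifest)
  gt <- do.call(rbind, gt)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, ground_truth = gt))
}

#' Write / read a scene configuration as YAML
#'
#' @param config a [scene_config()].
#' @param path YAML path.
#' @return `path` invisibly (write); a [scene_config()] (read).
#' @export
write_scene_config <- function(config, path) {
  x <- unclass(config)
  x$grains <- lapply(config$grains, function(g)
    list(params = unclass(g$params), centre = as.numeric(g$centre)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  x <- yaml::read_yaml(path)
  grains <- lapply(x$grains, function(g)
    list(params = do.call(grain_phantom_params, g$params),
         centre = as.numeric(g$centre)))
  scene_config(image_shape_px = unlist(x$image_shape_px), grains = grains,
               pixel_size_um = x$pixel_size_um, n_slices = x$n_slices,
               z_step_um = x$z_step_um, debris_density = x$debris_density,
               noise_sd = x$noise_sd, background_level = x$background_level,
               seed = x$seed)
}
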