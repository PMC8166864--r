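# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately written as plain per-pixel loops so they share no code with
# the implementation they check.

default_optics <- function(seed = 1L, shape = c(200L, 200L)) {
  scene_config(shape, seed = seed)
}

demo_params <- function(class_label = "urtica", diameter_um = 16,
                        n_pores = 3L, annulus = 0.8, texture = 0.06,
                        angularity = 0.15, focal_z_um = 17.1) {
  grain_phantom_params(class_label, diameter_um, n_pores, annulus, texture,
                       angularity, focal_z_um)
}

# single centred grain in a frame just big enough
single_grain_scene <- function(params, seed = 1L, pad_px = 80L,
                               noise_sd = 0.01) {
  side <- 2L * as.integer(ceiling(params$diameter_um / 2 / 0.16)) + pad_px
  scene_config(c(side, side),
               grains = list(list(params = params,
                                  centre = c((side + 1) / 2, (side + 1) / 2))),
               noise_sd = noise_sd, seed = seed)
}

# wrap a bare array as a grain_stack covering the whole crop
bare_grain_stack <- function(vox, pixel_size_um = 0.16, margin_px = 0L) {
  d <- dim(vox)
  region <- structure(list(id = 1L,
                           mask = matrix(TRUE, d[1], d[2]),
                           bbox = c(1L, 1L, d[1] + 1L, d[2] + 1L),
                           centroid = c((d[1] + 1) / 2, (d[2] + 1) / 2),
                           area_um2 = d[1] * d[2] * pixel_size_um^2,
                           equivalent_diameter_um = 2 * sqrt(d[1] * d[2] / pi) * pixel_size_um,
                           perimeter_um = 2 * (d[1] + d[2]) * pixel_size_um,
                           circularity = pi / 4,
                           perimeter_estimator = "chain-code (1, sqrt(2))"),
                      class = "grain_region")
  structure(list(voxels = vox, region = region, offset = c(1L, 1L),
                 mask = matrix(TRUE, d[1], d[2]),
                 margin_px = as.integer(margin_px),
                 pixel_size_um = pixel_size_um, z_step_um = 1.8,
                 kept_slices = seq_len(d[3])),
            class = "grain_stack")
}

# ---- brute-force oracles -------------------------------------------------

bf_min_projection <- function(v) {
  out <- matrix(0, dim(v)[1], dim(v)[2])
  for (r in seq_len(dim(v)[1])) for (c in seq_len(dim(v)[2])) {
    m <- Inf
    for (s in seq_len(dim(v)[3])) if (v[r, c, s] < m) m <- v[r, c, s]
    out[r, c] <- m
  }
  out
}

bf_sd_projection <- function(v) {
  n <- dim(v)[3]
  out <- matrix(0, dim(v)[1], dim(v)[2])
  for (r in seq_len(dim(v)[1])) for (c in seq_len(dim(v)[2])) {
    x <- numeric(n)
    for (s in seq_len(n)) x[s] <- v[r, c, s]
    mu <- sum(x) / n
    out[r, c] <- sqrt(sum((x - mu)^2) / (n - 1))
  }
  out
}

# replicate-boundary lookup
.clamp_px <- function(v, r, c, s) {
  r <- min(max(r, 1), dim(v)[1]); c <- min(max(c, 1), dim(v)[2])
  v[r, c, s]
}

# Sobel gradient energy, box-averaged over a w x w window, per pixel;
# argmax slice index per pixel (ties to the earlier slice)
bf_edof_index <- function(v, w) {
  H <- dim(v)[1]; W <- dim(v)[2]; n <- dim(v)[3]
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  score <- array(0, dim = c(H, W, n))
  for (s in seq_len(n)) {
    g2 <- matrix(0, H, W)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      gx <- 0; gy <- 0
      for (dr in -1:1) for (dc in -1:1) {
        px <- .clamp_px(v, r + dr, c + dc, s)
        gx <- gx + kx[dr + 2, dc + 2] * px
        gy <- gy + kx[dc + 2, dr + 2] * px
      }
      g2[r, c] <- gx^2 + gy^2
    }
    h <- (w - 1) / 2
    for (r in seq_len(H)) for (c in seq_len(W)) {
      acc <- 0
      for (dr in -h:h) for (dc in -h:h) {
        rr <- min(max(r + dr, 1), H); cc <- min(max(c + dc, 1), W)
        acc <- acc + g2[rr, cc]
      }
      score[r, c, s] <- acc / w^2
    }
  }
  idx <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    best <- -Inf; bi <- 1L
    for (s in seq_len(n)) if (score[r, c, s] > best) {
      best <- score[r, c, s]; bi <- s
    }
    idx[r, c] <- bi
  }
  idx
}

# metrics by looping over every (true, predicted) pair
bf_metrics <- function(cm) {
  K <- nrow(cm)
  pairs <- list()
  for (i in seq_len(K)) for (j in seq_len(K))
    if (cm[i, j] > 0) pairs[[length(pairs) + 1L]] <-
      cbind(rep(i, cm[i, j]), rep(j, cm[i, j]))
  pr <- do.call(rbind, pairs)
  total <- nrow(pr)
  res <- data.frame(precision = numeric(K), recall = numeric(K),
                    f1 = numeric(K), support = numeric(K))
  for (k in seq_len(K)) {
    tp <- sum(pr[, 1] == k & pr[, 2] == k)
    fp <- sum(pr[, 1] != k & pr[, 2] == k)
    fn <- sum(pr[, 1] == k & pr[, 2] != k)
    res$precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    res$recall[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    res$f1[k] <- if (res$precision[k] + res$recall[k] > 0)
      2 * res$precision[k] * res$recall[k] / (res$precision[k] + res$recall[k]) else 0
    res$support[k] <- sum(pr[, 1] == k)
  }
  list(per_class = res,
       ccr = sum(pr[, 1] == pr[, 2]) / total,
       weighted = c(precision = sum(res$support / total * res$precision),
                    recall = sum(res$support / total * res$recall),
                    f1 = sum(res$support / total * res$f1)))
}

random_confusion <- function(K = 3L, lambda = 8) {
  repeat {
    cm <- matrix(rpois(K * K, lambda), K, K)
    if (all(rowSums(cm) > 0)) return(cm)
  }
}

n_components <- function(mask) {
  max(EBImage::bwlabel(EBImage::Image(mask * 1)))
}
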