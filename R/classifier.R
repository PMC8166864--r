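#' Training configuration
#'
#' @param architecture one of `"tiny_test"`, `"light_v1"`, `"light_v2"`,
#'   `"deep_baseline"`. All four are compact convolutional networks built by
#'   this package's own engine: `deep_baseline` is the deepest (stacked
#'   3x3 convolution blocks and three fully connected layers), the `light_*`
#'   variants are faster alternatives, and `tiny_test` is a small network
#'   sized for desk-scale runs and CI. None of them is a published
#'   large-scale backbone.
#' @param mode `"scratch"` (random initialization from `seed`) or
#'   `"pretrained"` (backbone weights supplied externally via
#'   `weights_path`; an absent file is an error, never a silent fallback).
#' @param k_folds 5 (80/20 split per fold) or 10 (90/10).
#' @param epochs training epochs per fold (default 30).
#' @param l2_weight L2 regularization strength.
#' @param dropout_rate dropout probability on fully connected inputs, in
#'   `[0, 1)`.
#' @param learning_rate,batch_size Adam step size and minibatch size. The
#'   optimizer, learning rate and batch size are this package's defaults,
#'   not values taken from any reference workflow.
#' @param seed integer; determines initialization, fold assignment, shuffling,
#'   dropout and augmentation draws.
#' @param weights_path path to an RDS weight list for `mode = "pretrained"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(architecture = "tiny_test",
                         mode = c("scratch", "pretrained"),
                         k_folds = 5L, epochs = 30L, l2_weight = 1e-4,
                         dropout_rate = 0.25, learning_rate = 1e-3,
                         batch_size = 16L, seed = 1L, weights_path = NULL) {
  .assert(architecture %in% names(architecture_specs()),
          "unknown architecture: %s", architecture)
  mode <- match.arg(mode)
  .assert(k_folds %in% c(5L, 10L), "k_folds must be 5 or 10")
  .assert(epochs >= 1, "epochs must be >= 1")
  .assert(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must be in [0, 1)")
  structure(list(architecture = architecture, mode = mode,
                 k_folds = as.integer(k_folds), epochs = as.integer(epochs),
                 l2_weight = l2_weight, dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), weights_path = weights_path),
            class = "train_config")
}

#' Augmentation configuration
#'
#' Only transformations that do not alter grain morphology are offered:
#' random horizontal/vertical flips and a single multiplicative brightness
#' factor drawn uniformly from `brightness_range` (applied to all channels,
#' then clipped to `[0, 1]`). No rotation, zoom, shear or translation.
#'
#' @param brightness_range `c(low, high)` with `0 < low <= 1 <= high`;
#'   default `c(0.1, 2)`.
#' @param horizontal_flip,vertical_flip enable the random flips.
#' @param seed optional integer for [augment()].
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(brightness_range = c(0.1, 2),
                           horizontal_flip = TRUE, vertical_flip = TRUE,
                           seed = NULL) {
  .assert(length(brightness_range) == 2L && brightness_range[1] > 0 &&
            brightness_range[1] <= 1 && brightness_range[2] >= 1,
          "brightness_range must satisfy 0 < low <= 1 <= high")
  structure(list(brightness_range = as.numeric(brightness_range),
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip), seed = seed),
            class = "augment_config")
}

# layer codes understood by the C++ engine:
# 1 avgpool(size) | 2 conv(filters, kernel) | 3 maxpool(size) | 4 fc(units)
architecture_specs <- function(n_classes = 3L) {
  L <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  list(
    tiny_test = L(1, 3, 0,  2, 8, 5,  3, 2, 0,  2, 16, 3,  3, 2, 0,
                  2, 32, 3,  3, 3, 0,  4, 32, 0,  4, n_classes, 0),
    light_v1 = L(1, 4, 0,  2, 16, 3,  3, 2, 0,  2, 32, 3,  3, 2, 0,
                 2, 32, 3,  3, 2, 0,  4, 64, 0,  4, n_classes, 0),
    light_v2 = L(1, 4, 0,  2, 12, 3,  3, 2, 0,  2, 24, 3,  3, 2, 0,
                 2, 48, 3,  3, 2, 0,  2, 48, 3,  4, 64, 0,  4, n_classes, 0),
    deep_baseline = L(1, 2, 0,  2, 16, 3,  2, 16, 3,  3, 2, 0,
                      2, 32, 3,  2, 32, 3,  3, 2, 0,  2, 64, 3,  3, 2, 0,
                      4, 128, 0,  4, 64, 0,  4, n_classes, 0)
  )
}

conv_layer_names <- function(spec) {
  paste0("conv", seq_len(sum(spec[, 1] == 2)))
}

#' Build a classifier model
#'
#' @param config a [train_config()].
#' @param input_shape `c(rows, cols, channels)` of the framed inputs.
#' @param classes class labels of the softmax head (order fixes the score
#'   column order).
#' @return An object of class `pollen_model` holding the architecture spec
#'   and (initial or loaded) weights. In `"scratch"` mode two builds with the
#'   same seed have identical parameters; `"pretrained"` mode loads the
#'   externally supplied weight list at `config$weights_path` and errors if
#'   it is missing or mismatched.
#' @export
build_model <- function(config, input_shape = c(276L, 276L, 3L),
                        classes = pollen_classes()) {
  .assert(inherits(config, "train_config"), "config must be a train_config")
  spec <- architecture_specs(length(classes))[[config$architecture]]
  storage.mode(spec) <- "integer"
  if (config$mode == "pretrained") {
    .assert(!is.null(config$weights_path) && file.exists(config$weights_path),
            paste("pretrained mode requires externally supplied backbone",
                  "weights (config$weights_path); none found. Use mode =",
                  "'scratch' explicitly if that is intended."))
    weights <- readRDS(config$weights_path)
    check <- cnn_init_cpp(spec, input_shape[1], input_shape[2],
                          input_shape[3], 0L)
    .assert(length(weights) == length(check),
            "weight file does not match the %s architecture",
            config$architecture)
    for (i in seq_along(weights))
      .assert(identical(dim(weights[[i]]$W), dim(check[[i]]$W)),
              "weight matrix %d has the wrong shape for %s", i,
              config$architecture)
  } else {
    weights <- cnn_init_cpp(spec, input_shape[1], input_shape[2],
                            input_shape[3], config$seed)
  }
  structure(list(config = config, spec = spec,
                 input_shape = as.integer(input_shape),
                 classes = classes, weights = weights,
                 trained = FALSE, loss = NULL),
            class = "pollen_model")
}

#' @export
print.pollen_model <- function(x, ...) {
  cat(sprintf("<pollen_model> %s (%s), %d conv layer(s), classes: %s, %s\n",
              x$config$architecture, x$config$mode, sum(x$spec[, 1] == 2),
              paste(x$classes, collapse = "/"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# coerce a list of framed_image (or an array) to H x W x 3 x N
frames_to_array <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 4L) return(frames)
  if (inherits(frames, "framed_image")) frames <- list(frames)
  .assert(length(frames) > 0, "no frames")
  px <- lapply(frames, function(f) {
    if (inherits(f, "framed_image")) f$pixels else f
  })
  d <- dim(px[[1]])
  array(unlist(px), dim = c(d, length(px)))
}

#' Train a model on framed images
#'
#' Online augmentation: each image is re-augmented (flips, brightness) every
#' time it is visited, so no epoch sees the same pixel data twice.
#'
#' @param model an untrained (or trained) [build_model()] result.
#' @param frames list of [framed_image()]s or an `H x W x 3 x N` array.
#' @param labels factor or character vector of true classes, length N.
#' @param aug augmentation settings ([augment_config()]), or `NULL` to train
#'   on the raw frames.
#' @param seed optional integer overriding `model$config$seed` for this run.
#' @return The model with updated weights, `trained = TRUE` and the per-epoch
#'   mean training loss in `$loss`.
#' @export
train_model <- function(model, frames, labels, aug = augment_config(),
                        seed = NULL) {
  .assert(inherits(model, "pollen_model"), "model must be a pollen_model")
  X <- frames_to_array(frames)
  y <- as.integer(factor(as.character(labels), levels = model$classes))
  .assert(!anyNA(y), "labels outside the model's class set")
  .assert(dim(X)[4] == length(y), "frames and labels differ in length")
  cfg <- model$config
  fit <- cnn_train_cpp(X, y, model$spec, model$weights,
                       epochs = cfg$epochs, batch = cfg$batch_size,
                       lr = cfg$learning_rate, l2 = cfg$l2_weight,
                       dropout = cfg$dropout_rate,
                       hflip = !is.null(aug) && aug$horizontal_flip,
                       vflip = !is.null(aug) && aug$vertical_flip,
                       blo = if (is.null(aug)) 1 else aug$brightness_range[1],
                       bhi = if (is.null(aug)) 1 else aug$brightness_range[2],
                       seed = seed %||% cfg$seed,
                       augment_on = !is.null(aug))
  model$weights <- fit$weights
  model$loss <- as.numeric(fit$loss)
  model$trained <- TRUE
  model
}

#' Class scores for framed images
#'
#' @param object a [pollen_model].
#' @param frames list of [framed_image()]s or an `H x W x 3 x N` array.
#' @param ... unused.
#' @return `N x K` matrix of softmax scores (rows sum to 1), columns named
#'   by class.
#' @export
predict.pollen_model <- function(object, frames, ...) {
  X <- frames_to_array(frames)
  p <- cnn_predict_cpp(X, object$spec, object$weights)
  colnames(p) <- object$classes
  p
}

#' Augment one framed image
#'
#' Random horizontal/vertical flips plus one multiplicative brightness
#' factor drawn uniformly from the configured range, applied to all three
#' channels and clipped to `[0, 1]`. Shape and pixel scale are unchanged;
#' no rotation, zoom, shear or translation is ever applied, since size and
#' shape are class features.
#'
#' @param image a [framed_image()].
#' @param config an [augment_config()].
#' @param seed optional integer making the draw reproducible (defaults to
#'   `config$seed`; `NULL` uses the current RNG state).
#' @return The augmented [framed_image()].
#' @export
augment <- function(image, config = augment_config(), seed = NULL) {
  .assert(inherits(image, "framed_image"), "image must be a framed_image")
  seed <- seed %||% config$seed
  do_it <- function() {
    px <- image$pixels
    if (config$horizontal_flip && runif(1) < 0.5) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (config$vertical_flip && runif(1) < 0.5) px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    f <- runif(1, config$brightness_range[1], config$brightness_range[2])
    px <- pmin(pmax(px * f, 0), 1)
    out <- image
    out$pixels <- px
    attr(out, "brightness_factor") <- f
    out
  }
  if (is.null(seed)) do_it() else with_rng(seed, do_it())
}

#' Confusion matrix from true and predicted labels
#'
#' @param true,predicted vectors of class labels.
#' @param classes label set fixing row/column order (rows = true class,
#'   columns = predicted class).
#' @return `K x K` integer matrix of counts.
#' @export
confusion_matrix <- function(true, predicted, classes = pollen_classes()) {
  t_f <- factor(as.character(true), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  .assert(!anyNA(t_f) && !anyNA(p_f), "labels outside the declared class set")
  as.matrix(table(true = t_f, predicted = p_f))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN per class, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and the correct classification rate
#' `CCR = (TP+TN)/(TP+TN+FP+FN)` (the trace over the total, identical for
#' every class). Averages are weighted by class support (row sums); for a
#' complete confusion matrix the weighted recall equals the CCR. Division by
#' zero yields 0, with attribute `zero_division = TRUE` and a warning.
#'
#' @param cm square count matrix, rows = true class, columns = predicted.
#' @return An object of class `pollen_metrics`: list with `per_class` (data
#'   frame), `weighted` (precision, recall, f1), `ccr`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  .assert(nrow(cm) == ncol(cm) && all(cm >= 0), "cm must be a square count matrix")
  total <- sum(cm)
  .assert(total > 0, "all-zero confusion matrix")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  zdiv <- FALSE
  safe_div <- function(a, b) {
    out <- ifelse(b > 0, a / ifelse(b > 0, b, 1), 0)
    if (any(b == 0)) zdiv <<- TRUE
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  w <- support / total
  out <- structure(list(
    per_class = data.frame(class = classes, support = support,
                           TP = tp, FP = fp, FN = fn, TN = tn,
                           precision = precision, recall = recall, f1 = f1,
                           row.names = NULL),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    ccr = sum(tp) / total), class = "pollen_metrics")
  attr(out, "zero_division") <- zdiv
  if (zdiv) warning("zero denominator in metrics; affected values set to 0",
                    call. = FALSE)
  out
}

#' @export
print.pollen_metrics <- function(x, ...) {
  cat(sprintf("<pollen_metrics> CCR %.4f | weighted P %.4f R %.4f F1 %.4f\n",
              x$ccr, x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  print(x$per_class, digits = 4)
  invisible(x)
}

# stratified fold assignment; groups images sharing sample_id into the same
# fold when grouping is on and the class has at least k groups
make_folds <- function(labels, k, seed, sample_id = NULL,
                       group_by_sample = TRUE) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_rng(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      .assert(length(idx) >= k, "class %s has fewer than %d images", cl, k)
      groups <- if (!is.null(sample_id) && group_by_sample)
        as.character(sample_id[idx]) else as.character(idx)
      ug <- unique(groups)
      if (length(ug) < k && !is.null(sample_id) && group_by_sample) {
        warning(sprintf("class %s has %d sample group(s) < %d folds; using plain stratification for it",
                        cl, length(ug), k), call. = FALSE)
        groups <- as.character(idx)
        ug <- unique(groups)
      }
      ug <- sample(ug)
      # greedy bin packing: biggest group to the currently smallest fold
      sizes <- vapply(ug, function(g) sum(groups == g), numeric(1))
      ug <- ug[order(sizes, decreasing = TRUE)]
      load <- numeric(k)
      gf <- setNames(integer(length(ug)), ug)
      for (g in ug) {
        f <- which.min(load)
        gf[g] <- f
        load[f] <- load[f] + sum(groups == g)
      }
      fold[idx] <- gf[groups]
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into `k_folds` stratified folds (each image is
#' validated exactly once; with 5 folds each fold trains on 80% and
#' validates on 20%, with 10 folds 90/10). When `sample_id` is given, images
#' from the same plant or sample are kept in the same fold so grains from
#' one source never appear on both sides of a split; `group_by_sample =
#' FALSE` restores plain stratification. Augmentation is applied to training
#' portions only; validation images are scored unmodified.
#'
#' @param frames list of [framed_image()]s or `H x W x 3 x N` array.
#' @param labels true class per frame.
#' @param train_cfg a [train_config()].
#' @param aug an [augment_config()] or `NULL`.
#' @param classes class set (fixes confusion-matrix order).
#' @param sample_id optional per-frame plant/sample identifiers.
#' @param group_by_sample keep identical `sample_id`s in one fold.
#' @param trainer optional function `(X_train, y_train, fold_seed)` returning
#'   a prediction function `(X) -> score matrix`; defaults to training the
#'   configured network. Intended for stubs and alternative engines.
#' @return List with `folds` (per fold: `confusion`, `metrics`, validation
#'   indices), `pooled` (metrics of the summed confusion matrix), `averaged`
#'   (mean of per-fold CCRs and weighted metrics), `confusion` (summed
#'   matrix) and `fold_assignment`.
#' @export
crossvalidate <- function(frames, labels, train_cfg = train_config(),
                          aug = augment_config(), classes = pollen_classes(),
                          sample_id = NULL, group_by_sample = TRUE,
                          trainer = NULL) {
  X <- frames_to_array(frames)
  labels <- as.character(labels)
  N <- dim(X)[4]
  .assert(length(labels) == N, "frames and labels differ in length")
  k <- train_cfg$k_folds
  fold <- make_folds(labels, k, train_cfg$seed, sample_id, group_by_sample)
  trainer <- trainer %||% function(Xtr, ytr, fold_seed) {
    cfg <- train_cfg
    cfg$seed <- fold_seed
    m <- build_model(cfg, input_shape = dim(Xtr)[1:3], classes = classes)
    m <- train_model(m, Xtr, ytr, aug = aug, seed = fold_seed)
    function(Xv) predict(m, Xv)
  }
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); va <- which(fold == f)
    pred_fn <- trainer(X[, , , tr, drop = FALSE], labels[tr],
                       derive_seed(train_cfg$seed, f))
    scores <- pred_fn(X[, , , va, drop = FALSE])
    pred <- classes[max.col(scores, ties.method = "first")]
    cmf <- confusion_matrix(labels[va], pred, classes)
    folds[[f]] <- list(confusion = cmf, metrics = compute_metrics(cmf),
                       validation = va)
  }
  va_all <- sort(unlist(lapply(folds, `[[`, "validation")))
  .assert(identical(va_all, seq_len(N)), "folds do not partition the dataset")
  cm_sum <- Reduce(`+`, lapply(folds, `[[`, "confusion"))
  avg <- list(
    ccr = mean(vapply(folds, function(x) x$metrics$ccr, numeric(1))),
    weighted = rowMeans(vapply(folds, function(x) x$metrics$weighted,
                               numeric(3))))
  list(folds = folds, pooled = compute_metrics(cm_sum), averaged = avg,
       confusion = cm_sum, fold_assignment = fold)
}

#' Open-set prediction with an identity threshold
#'
#' Each image is assigned its top-scoring class when the top softmax score
#' reaches the identity threshold, and `"unknown"` otherwise (open-set
#' rejection). A threshold of 0 never rejects; a threshold above 1 always
#' rejects.
#'
#' @param model a trained [pollen_model], or a precomputed `N x K` score
#'   matrix with class column names.
#' @param frames frames to score (ignored when `model` is a score matrix).
#' @param threshold identity threshold on the top score (default 0.60).
#' @return Data frame with one row per image: per-class `score_*` columns,
#'   `top_label`, `top_score`, `assigned`, `threshold`.
#' @export
predict_with_threshold <- function(model, frames = NULL, threshold = 0.60) {
  scores <- if (is.matrix(model)) model else predict(model, frames)
  .assert(!is.null(colnames(scores)), "score matrix needs class column names")
  classes <- colnames(scores)
  top <- max.col(scores, ties.method = "first")
  top_score <- scores[cbind(seq_len(nrow(scores)), top)]
  out <- as.data.frame(scores)
  names(out) <- paste0("score_", classes)
  out$top_label <- classes[top]
  out$top_score <- top_score
  out$assigned <- ifelse(top_score >= threshold, classes[top], "unknown")
  out$threshold <- threshold
  out
}

#' Aggregate open-set predictions into a per-sample monitoring report
#'
#' For each sample (e.g. one Hirst-tape slide) and each threshold, reports
#' the grain count and the percentage assigned to each class and to
#' `"unknown"`, rounded to one decimal as in routine monitoring tables, plus
#' the unweighted mean of the per-sample unknown percentages per threshold.
#'
#' @param scores `N x K` score matrix (class column names) or a trained
#'   model plus `frames`.
#' @param sample per-grain sample identifiers (length N).
#' @param thresholds identity thresholds to report (default 0.60 and 0.70).
#' @param date optional per-grain collection dates (one value per sample).
#' @return An object of class `test_case_report`: list with `report` (data
#'   frame: sample, date, threshold, n, one `pct_*` column per class,
#'   `pct_unknown`) and `mean_unknown` (named by threshold).
#' @export
summarize_test_cases <- function(scores, sample, thresholds = c(0.60, 0.70),
                                 date = NULL) {
  .assert(is.matrix(scores) && !is.null(colnames(scores)),
          "scores must be a matrix with class column names")
  .assert(nrow(scores) == length(sample), "scores and sample differ in length")
  .assert(length(sample) >= 1, "empty sample group")
  classes <- colnames(scores)
  samples <- unique(as.character(sample))
  rows <- list()
  for (thr in thresholds) {
    pred <- predict_with_threshold(scores, threshold = thr)
    for (sm in samples) {
      sel <- as.character(sample) == sm
      n <- sum(sel)
      .assert(n > 0, "empty sample group: %s", sm)
      pct <- vapply(c(classes, "unknown"), function(cl)
        round(100 * sum(pred$assigned[sel] == cl) / n, 1), numeric(1))
      row <- data.frame(sample = sm,
                        date = if (is.null(date)) NA_character_ else
                          as.character(date[sel][1]),
                        threshold = thr, n = n, stringsAsFactors = FALSE)
      for (cl in classes) row[[paste0("pct_", cl)]] <- pct[[cl]]
      row$pct_unknown <- pct[["unknown"]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  mean_unknown <- vapply(thresholds, function(thr)
    round(mean(report$pct_unknown[report$threshold == thr]), 1), numeric(1))
  names(mean_unknown) <- format(thresholds)
  structure(list(report = report, mean_unknown = mean_unknown),
            class = "test_case_report")
}

#' @export
print.test_case_report <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat("mean % unknown per threshold:\n")
  print(x$mean_unknown)
  invisible(x)
}

#' Export feature maps of a convolutional layer
#'
#' Runs one frame through the network and returns the per-filter activation
#' images of the selected convolutional layer, min-max scaled to `[0, 1]`
#' for display (white = high activation). Earlier layers respond to coarse
#' structure such as the grain outline; deeper layers to finer features such
#' as pores and the annulus.
#'
#' @param model a trained [pollen_model].
#' @param frame one [framed_image()].
#' @param layer convolutional layer selector: index (1 = first conv layer)
#'   or name `"conv<i>"`.
#' @return Named list of 2-D activation matrices, one per filter.
#' @export
export_feature_maps <- function(model, frame, layer = 1L) {
  .assert(inherits(model, "pollen_model"), "model must be a pollen_model")
  nm <- conv_layer_names(model$spec)
  if (is.character(layer)) {
    .assert(layer %in% nm, "unknown layer '%s'; available: %s", layer,
            paste(nm, collapse = ", "))
    layer <- match(layer, nm)
  }
  .assert(layer >= 1 && layer <= length(nm),
          "unknown layer %d; the network has %d conv layers", layer, length(nm))
  px <- if (inherits(frame, "framed_image")) frame$pixels else frame
  maps <- cnn_activations_cpp(px, model$spec, model$weights, as.integer(layer))
  maps <- lapply(maps, function(m) {
    rng <- range(m)
    if (diff(rng) < 1e-12) m * 0 else (m - rng[1]) / diff(rng)
  })
  names(maps) <- sprintf("%s_filter%02d", nm[layer], seq_along(maps))
  maps
}

#' Load a framed-image dataset from a manifest
#'
#' @param manifest manifest data frame or CSV path (columns `path`, `label`,
#'   `sample_id`) listing framed images written by [write_framed_image()].
#' @return List with `frames` (`H x W x 3 x N` array), `labels`,
#'   `sample_id`, `paths`.
#' @export
load_framed_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  frames <- lapply(manifest$path, read_framed_image)
  list(frames = frames_to_array(frames), labels = manifest$label,
       sample_id = manifest$sample_id, paths = manifest$path)
}
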