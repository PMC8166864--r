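test_that("metrics match hand computations on known confusion matrices", {
  cm <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- compute_metrics(cm)
  expect_equal(m$per_class$precision[1], 8 / 11)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$ccr, 0.75)
  expect_equal(m$per_class$TP, c(8, 7))
  expect_equal(m$per_class$FP, c(3, 2))
  expect_equal(m$per_class$FN, c(2, 3))
  expect_equal(m$per_class$TN, c(7, 8))

  diagm <- diag(c(5, 9, 4))
  md <- compute_metrics(diagm)
  expect_equal(md$ccr, 1)
  expect_true(all(md$per_class$precision == 1))
  expect_true(all(md$per_class$recall == 1))
  expect_equal(unname(md$weighted), c(1, 1, 1))
})

test_that("metrics agree with brute-force counting on random matrices", {
  withr::with_seed(51, {
    for (i in 1:100) {
      cm <- random_confusion(K = sample(2:4, 1))
      m <- compute_metrics(cm)
      bf <- bf_metrics(cm)
      expect_equal(m$per_class$precision, bf$per_class$precision)
      expect_equal(m$per_class$recall, bf$per_class$recall)
      expect_equal(m$per_class$f1, bf$per_class$f1)
      expect_equal(m$ccr, bf$ccr)
      expect_equal(m$weighted, bf$weighted)
      # identity: support-weighted recall equals the CCR
      expect_equal(unname(m$weighted["recall"]), m$ccr)
    }
  })
})

test_that("zero denominators yield 0 with a logged flag", {
  cm <- matrix(c(5, 0, 3, 0), 2, 2, byrow = TRUE)   # nothing predicted as 2
  expect_warning(m <- compute_metrics(cm), "zero")
  expect_equal(m$per_class$precision[2], 0)
  expect_true(attr(m, "zero_division"))
  expect_error(compute_metrics(matrix(0, 2, 2)), "all-zero")
})

test_that("the identity threshold gates open-set assignment", {
  sc <- rbind(c(0.55, 0.30, 0.15),
              c(0.85, 0.10, 0.05),
              c(0.20, 0.20, 0.60))
  colnames(sc) <- pollen_classes()
  p60 <- predict_with_threshold(sc, threshold = 0.60)
  expect_equal(p60$assigned, c("unknown", "urtica", "membranacea"))
  expect_equal(p60$top_label, c("urtica", "urtica", "membranacea"))
  expect_equal(p60$top_score, c(0.55, 0.85, 0.60))
  expect_true(all(predict_with_threshold(sc, threshold = 0)$assigned !=
                    "unknown"))
  expect_true(all(predict_with_threshold(sc, threshold = 1.01)$assigned ==
                    "unknown"))
  # invariant: assigned equals top label iff top score reaches the threshold
  withr::with_seed(52, {
    r <- matrix(runif(60), 20, 3); r <- r / rowSums(r)
    colnames(r) <- pollen_classes()
    pr <- predict_with_threshold(r, threshold = 0.5)
    expect_equal(pr$assigned == pr$top_label, pr$top_score >= 0.5)
  })
})

test_that("unknown rate is non-decreasing in the threshold", {
  withr::with_seed(53, {
    r <- matrix(runif(300), 100, 3); r <- r / rowSums(r)
    colnames(r) <- pollen_classes()
  })
  unk <- vapply(c(0.4, 0.5, 0.6, 0.7, 0.8), function(thr)
    mean(predict_with_threshold(r, threshold = thr)$assigned == "unknown"),
    numeric(1))
  expect_true(all(diff(unk) >= 0))
})

test_that("per-sample aggregation reproduces the monitoring-table arithmetic", {
  tc <- aerobio_test_cases()
  rep <- summarize_test_cases(tc$scores, tc$sample, thresholds = c(0.6, 0.7),
                              date = tc$date)
  r60 <- rep$report[rep$report$threshold == 0.6, ]
  r60 <- r60[match(c("Leiden_NL", "Lleida_SP", "Vielha_SP"), r60$sample), ]
  expect_equal(r60$n, c(112, 63, 26))
  expect_equal(r60$pct_urtica, c(85.7, 14.3, 69.2))
  expect_equal(r60$pct_parietaria, c(4.5, 81.0, 19.2))
  expect_equal(r60$pct_membranacea, c(0, 0, 0))
  expect_equal(r60$pct_unknown, c(9.8, 4.8, 11.5))
  r70 <- rep$report[rep$report$threshold == 0.7, ]
  r70 <- r70[match(c("Leiden_NL", "Lleida_SP", "Vielha_SP"), r70$sample), ]
  expect_equal(r70$pct_unknown, c(13.4, 7.9, 19.2))
  expect_equal(unname(rep$mean_unknown), c(8.7, 13.5))
})

test_that("single-sample degenerate aggregation behaves", {
  sc <- matrix(c(0.9, 0.05, 0.05), 4, 3, byrow = TRUE)
  colnames(sc) <- pollen_classes()
  rep <- summarize_test_cases(sc, rep("s1", 4), thresholds = 0)
  expect_equal(rep$report$pct_urtica, 100)
  expect_equal(rep$report$pct_unknown, 0)
  expect_error(summarize_test_cases(sc, character(0)), "length")
})

test_that("augmentation preserves shape and morphology transforms only", {
  px <- array(round(runif(276 * 276 * 3) * 1000) / 1000, dim = c(276, 276, 3))
  img <- framed_image(px, pixel_size_um = 0.16)
  # identity configuration
  id <- augment(img, augment_config(brightness_range = c(1, 1),
                                    horizontal_flip = FALSE,
                                    vertical_flip = FALSE), seed = 1)
  expect_identical(id$pixels, px)
  # flipping twice with the same seed undoes itself (brightness fixed at 1)
  cfg <- augment_config(brightness_range = c(1, 1), vertical_flip = FALSE)
  once <- augment(img, cfg, seed = 7)
  twice <- augment(once, cfg, seed = 7)
  expect_identical(twice$pixels, px)
  # brightness direction: darkening factors reduce the mean, brightening
  # factors (with clipping) never reduce it
  for (s in 1:15) {
    a <- augment(img, augment_config(horizontal_flip = FALSE,
                                     vertical_flip = FALSE), seed = s)
    f <- attr(a, "brightness_factor")
    if (f < 1) expect_lt(mean(a$pixels), mean(px))
    if (f > 1) expect_gte(mean(a$pixels), mean(px))
    expect_true(all(a$pixels >= 0 & a$pixels <= 1))
    expect_equal(dim(a$pixels), dim(px))
  }
  expect_error(augment_config(brightness_range = c(0, 2)), "brightness")
  expect_error(augment_config(brightness_range = c(0.5, 0.9)), "brightness")
})

test_that("scratch initialization is seed-deterministic", {
  m1 <- build_model(train_config(seed = 5))
  m2 <- build_model(train_config(seed = 5))
  m3 <- build_model(train_config(seed = 6))
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("model scores are softmax distributions and fast to compute", {
  m <- build_model(train_config(seed = 2))
  withr::with_seed(60, X <- array(runif(276 * 276 * 3 * 4),
                                  dim = c(276, 276, 3, 4)))
  t0 <- Sys.time()
  p <- predict(m, X)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 4)
  expect_equal(dim(p), c(4, 3))
  expect_equal(colnames(p), pollen_classes())
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("pretrained mode demands externally supplied weights", {
  expect_error(build_model(train_config(mode = "pretrained")), "weights")
  expect_error(build_model(train_config(mode = "pretrained",
                                        weights_path = "no/such/file.rds")),
               "weights")
  # a valid external weight file loads and is used verbatim
  w <- build_model(train_config(seed = 9))$weights
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(w, path)
  m <- build_model(train_config(mode = "pretrained", weights_path = path))
  expect_identical(m$weights, w)
  # shape mismatch is rejected
  w2 <- w; w2[[1]]$W <- w2[[1]]$W[, 1:2]
  saveRDS(w2, path)
  expect_error(build_model(train_config(mode = "pretrained",
                                        weights_path = path)), "shape")
})

test_that("all four architectures build and declare their conv layers", {
  for (arch in c("tiny_test", "light_v1", "light_v2", "deep_baseline")) {
    m <- build_model(train_config(architecture = arch, seed = 1))
    expect_s3_class(m, "pollen_model")
    expect_gte(sum(m$spec[, 1] == 2), 3)
  }
  expect_error(train_config(architecture = "vgg19"), "unknown")
})

test_that("training reduces the loss on a learnable toy problem", {
  withr::with_seed(61, {
    X <- array(0, dim = c(276, 276, 3, 12))
    for (i in 1:12) {
      base <- matrix(runif(276 * 276, 0, 0.2), 276, 276)
      if (i %% 3 == 0) base[100:170, 100:170] <- 0.9
      if (i %% 3 == 1) base[30:60, 30:60] <- 0.9
      for (k in 1:3) X[, , k, i] <- base
    }
  })
  y <- c("membranacea", "urtica", "parietaria")[(1:12) %% 3 + 1]
  m <- build_model(train_config(epochs = 10, batch_size = 4, seed = 3))
  mt <- train_model(m, X, y, aug = NULL)
  expect_true(mt$trained)
  expect_lt(mt$loss[10], mt$loss[1])
  expect_equal(length(mt$loss), 10)
  # training is reproducible from the seed
  mt2 <- train_model(m, X, y, aug = NULL)
  expect_identical(mt$weights, mt2$weights)
})

test_that("cross-validation partitions the data into stratified folds", {
  withr::with_seed(62, X <- array(runif(8 * 8 * 3 * 90),
                                  dim = c(8, 8, 3, 90)))
  y <- rep(pollen_classes(), each = 30)
  stub <- function(Xtr, ytr, fold_seed) {
    function(Xv) {
      p <- matrix(0, dim(Xv)[4], 3, dimnames = list(NULL, pollen_classes()))
      p[, 1] <- 1
      p
    }
  }
  cv <- suppressWarnings(crossvalidate(X, y, train_config(k_folds = 5, seed = 11),
                                       trainer = stub))
  # every image validated exactly once, 6 per class per fold
  expect_equal(sort(unlist(lapply(cv$folds, `[[`, "validation"))), 1:90)
  for (f in cv$folds) {
    expect_equal(unname(rowSums(f$confusion)), rep(6L, 3))
    expect_equal(length(f$validation), 18)
  }
  # constant-prediction stub on a balanced set scores CCR = 1/3
  expect_equal(cv$pooled$ccr, 1 / 3)
  expect_equal(cv$averaged$ccr, 1 / 3)
  # fold assignment reproducible from the seed
  cv2 <- suppressWarnings(crossvalidate(X, y, train_config(k_folds = 5, seed = 11),
                                        trainer = stub))
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  few <- c(1:5, 31:35, 61:63)            # only 3 membranacea images
  expect_error(crossvalidate(X[, , , few], y[few],
                             train_config(k_folds = 5), trainer = stub),
               "fewer than")
})

test_that("images sharing a sample identifier stay in one fold", {
  withr::with_seed(63, X <- array(runif(8 * 8 * 3 * 90),
                                  dim = c(8, 8, 3, 90)))
  y <- rep(pollen_classes(), each = 30)
  sid <- paste0(y, "_p", rep(rep(1:10, each = 3), 3))
  stub <- function(Xtr, ytr, fold_seed) {
    function(Xv) {
      p <- matrix(1 / 3, dim(Xv)[4], 3, dimnames = list(NULL, pollen_classes()))
      p
    }
  }
  cv <- suppressWarnings(crossvalidate(X, y, train_config(k_folds = 5, seed = 3),
                                       sample_id = sid, trainer = stub))
  for (g in unique(sid))
    expect_equal(length(unique(cv$fold_assignment[sid == g])), 1)
  # with fewer groups than folds the class falls back to plain stratification
  sid2 <- paste0(y, "_p", rep(rep(1:2, each = 15), 3))
  w <- character(0)
  withCallingHandlers(
    crossvalidate(X, y, train_config(k_folds = 5, seed = 3),
                  sample_id = sid2, trainer = stub),
    warning = function(cnd) {
      w <<- c(w, conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("plain stratification", w)))
})

test_that("feature maps expose per-filter activations at layer resolution", {
  m <- build_model(train_config(seed = 4))
  px <- array(0, dim = c(276, 276, 3))
  frame <- framed_image(px, pixel_size_um = 0.16)
  maps1 <- export_feature_maps(m, frame, layer = 1)
  maps2 <- export_feature_maps(m, frame, layer = "conv2")
  expect_length(maps1, 8)                      # filter count of conv1
  expect_length(maps2, 16)
  # an all-zero input activates only biases: constant per filter, scaled to 0
  expect_true(all(vapply(maps1, function(x) max(x) - min(x), numeric(1)) == 0))
  # earlier layers keep higher spatial resolution
  expect_gt(nrow(maps1[[1]]), nrow(maps2[[1]]))
  expect_error(export_feature_maps(m, frame, layer = "conv9"), "unknown")
  expect_error(export_feature_maps(m, frame, layer = 12), "unknown")
})
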