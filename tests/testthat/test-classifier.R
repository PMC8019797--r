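test_that("training requires both classes and is deterministic in the seed", {
  fx <- fixture_model()
  ph <- fx$phantom
  one_class <- generate_dataset(ph, 5, seed = 2)
  keep <- one_class$entries$label == "high"
  solo <- labeled_frame_set(frames = one_class$frames[keep],
                           labels = one_class$entries$label[keep])
  expect_error(train_quality_model(solo, ph$reference),
               class = "sonoqc_training_error")

  ds <- generate_dataset(ph, 25, seed = 31)
  parts <- split_frame_set(ds, 0.8, seed = 31)
  m1 <- train_quality_model(parts$train, ph$reference, seed = 31)
  m2 <- train_quality_model(parts$train, ph$reference, seed = 31)
  preds <- function(m) vapply(seq_len(nrow(parts$test$entries)), function(i)
    classify(m, parts$test$frames[[i]], ph$reference)$v_svm, integer(1))
  expect_identical(preds(m1), preds(m2))
})

test_that("training standardization yields mean 0 / variance 1 features", {
  fx <- fixture_model()
  ph <- fx$phantom; m <- fx$model
  ds <- generate_dataset(ph, 60, seed = 42)  # the training set of the fixture
  feats <- t(vapply(seq_len(nrow(ds$entries)), function(i) {
    fv <- extract_features(ds$frames[[i]], ph$reference, m$feature_config)
    c(fv$compression, fv$noise)
  }, numeric(2)))
  std <- sweep(sweep(feats, 2, m$center), 2, m$scale, "/")
  expect_equal(unname(colMeans(std)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(std, 2, var)), c(1, 1), tolerance = 1e-9)
})

test_that("the contact gate takes precedence over any SVM", {
  fx <- fixture_model()
  ph <- fx$phantom
  # models trained on different regimes/seeds all defer to the gate
  for (s in c(3, 9, 27)) {
    ds <- generate_dataset(ph, 15, seed = s)
    m <- train_quality_model(ds, ph$reference, seed = s,
                             kernel = if (s %% 2) "radial" else "linear",
                             cost = s)
    res <- classify(m, ph$reference, ph$reference)
    expect_identical(res$v_svm, 0L)
    for (ncseed in 1:5) {
      nc <- render_no_contact(ph, seed = 500 + ncseed)
      expect_identical(classify(m, nc, ph$reference)$v_svm, 0L)
    }
    # blank frame: degenerate correlation => gate => low quality
    expect_identical(classify(m, matrix(0, 64, 64), ph$reference)$v_svm, 0L)
  }
})

test_that("in-band frames classify high and off-band frames low", {
  fx <- fixture_model()
  m <- fx$model; ph <- fx$phantom
  mid <- render_contact(ph, 6.5, seed = 101)       # middle of quality band
  over <- render_contact(ph, 19, seed = 102)       # over-compressed
  expect_identical(classify(m, mid, ph$reference)$v_svm, 1L)
  expect_identical(classify(m, over, ph$reference)$v_svm, 0L)
  expect_identical(predict(m, mid, ph$reference), 1L)
})

test_that("evaluation tallies a coherent confusion matrix", {
  fx <- fixture_model()
  ph <- fx$phantom; m <- fx$model
  ds <- generate_dataset(ph, 20, seed = 77)
  ev <- evaluate_quality_model(m, ds, ph$reference)
  expect_equal(sum(ev$confusion), nrow(ds$entries))
  expect_equal(ev$accuracy,
               (ev$confusion["TP"] + ev$confusion["TN"]) / sum(ev$confusion),
               ignore_attr = TRUE)
  expect_gte(ev$accuracy, 0.9)  # same generator distribution as training

  # a test set of only no-contact frames labeled low is perfectly classified
  # by the gate alone
  nc <- lapply(1:10, function(s) render_no_contact(ph, seed = 900 + s))
  names(nc) <- sprintf("nc_%02d", 1:10)
  nc_set <- labeled_frame_set(frames = nc, labels = rep("low", 10))
  expect_equal(evaluate_quality_model(m, nc_set, ph$reference)$accuracy, 1.0)

  empty <- labeled_frame_set(frames = list(), labels = character(0))
  expect_error(evaluate_quality_model(m, empty, ph$reference),
               class = "sonoqc_label_error")
})

test_that("classification accuracy degrades to chance as class separation vanishes", {
  acc_at_contrast <- function(contrast, seed) {
    ph <- virtual_phantom(phantom_config(response_contrast = contrast,
                                         seed = seed))
    sampler <- sonoqc:::in_contact_force_sampler(ph$config)
    ds <- generate_dataset(ph, 50, force_sampler = sampler, seed = seed)
    parts <- split_frame_set(ds, 0.8, seed = seed)
    m <- train_quality_model(parts$train, ph$reference, seed = seed)
    evaluate_quality_model(m, parts$test, ph$reference)$accuracy
  }
  seeds <- 1:5
  acc <- vapply(c(1, 0.25, 0), function(ct)
    mean(vapply(seeds, function(s) acc_at_contrast(ct, s), numeric(1))),
    numeric(1))
  expect_gte(acc[1], 0.9)
  expect_true(all(diff(acc) <= 0.05))       # non-increasing in expectation
  expect_lt(acc[3], 0.65)                   # chance-level at zero separation
})

test_that("model persistence round-trips bit-identical predictions", {
  fx <- fixture_model()
  ph <- fx$phantom; m <- fx$model
  p <- withr::local_tempfile(fileext = ".rds")
  save_quality_model(m, p)
  m2 <- load_quality_model(p)
  frames <- lapply(1:50, function(s)
    render_contact(ph, local_seed(s, runif(1, 0, 20)), seed = s))
  v1 <- vapply(frames, function(f) classify(m, f, ph$reference)$v_svm, integer(1))
  v2 <- vapply(frames, function(f) classify(m2, f, ph$reference)$v_svm, integer(1))
  expect_identical(v1, v2)

  expect_error(load_quality_model("no/such/model.rds"), class = "sonoqc_io_error")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "sonoqc-quality-model-0", svm = NULL), bad)
  expect_error(load_quality_model(bad), class = "sonoqc_version_error")
})

test_that("seeded splits are disjoint, exhaustive and reproducible", {
  fx <- fixture_model()
  ds <- generate_dataset(fx$phantom, 25, seed = 13)
  p1 <- split_frame_set(ds, 0.8, seed = 4)
  p2 <- split_frame_set(ds, 0.8, seed = 4)
  expect_identical(p1$train$entries, p2$train$entries)
  expect_identical(nrow(p1$train$entries), 40L)
  expect_identical(nrow(p1$test$entries), 10L)
  expect_length(intersect(p1$train$entries$frame_id, p1$test$entries$frame_id), 0)
  expect_setequal(c(p1$train$entries$frame_id, p1$test$entries$frame_id),
                  ds$entries$frame_id)
})
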