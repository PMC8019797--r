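#' Labeled frame sets
#'
#' A labeled frame set holds the entries of a training/test collection: frame
#' ids, file paths (possibly `NA` for in-memory sets), subjective labels
#' (`"high"` or `"low"` quality) and optionally the frames themselves.
#'
#' @param frames named list of frame matrices, or `NULL` if frames live on
#'   disk.
#' @param labels character vector of `"high"`/`"low"` labels.
#' @param ids unique frame ids; defaults to the names of `frames`.
#' @param paths file paths (`NA` allowed when frames are in memory).
#' @param forces optional per-frame applied forces (N), recorded by the
#'   synthetic generator.
#' @return list of class `labeled_frame_set` with an `entries` data.frame and
#'   a `frames` list.
#' @export
labeled_frame_set <- function(frames = NULL, labels, ids = names(frames),
                              paths = NA_character_, forces = NULL) {
  if (!all(labels %in% c("high", "low")))
    stop_sonoqc("labels must be 'high' or 'low'", "sonoqc_label_error")
  n <- length(labels)
  if (is.null(ids)) ids <- sprintf("frame_%05d", seq_len(n))
  if (anyDuplicated(ids))
    stop_sonoqc("frame ids must be unique", "sonoqc_label_error")
  entries <- data.frame(frame_id = ids, path = rep_len(paths, n),
                        label = labels, stringsAsFactors = FALSE)
  if (!is.null(forces)) entries$force <- unname(forces)
  structure(list(entries = entries, frames = frames),
            class = "labeled_frame_set")
}

#' Read a labeled frame set from a CSV manifest
#'
#' The manifest must have columns `frame_id`, `path`, `label`. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param manifest path to the CSV manifest.
#' @param load_frames read the frames into memory (default TRUE).
#' @return a [labeled_frame_set()].
#' @export
read_frame_set <- function(manifest, load_frames = TRUE) {
  if (!file.exists(manifest))
    stop_sonoqc(sprintf("manifest not found: %s", manifest), "sonoqc_io_error")
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("frame_id", "path", "label")
  if (!all(need %in% names(df)))
    stop_sonoqc("manifest must have columns frame_id, path, label",
                "sonoqc_label_error")
  paths <- ifelse(file.exists(df$path), df$path,
                  file.path(dirname(manifest), df$path))
  frames <- NULL
  if (load_frames) {
    frames <- lapply(paths, function(p) {
      if (!file.exists(p))
        stop_sonoqc(sprintf("frame file not found: %s", p), "sonoqc_io_error")
      read_frame(p)
    })
    names(frames) <- df$frame_id
  }
  labeled_frame_set(frames = frames, labels = df$label, ids = df$frame_id,
                    paths = paths, forces = df$force)
}

#' @exportS3Method
print.labeled_frame_set <- function(x, ...) {
  tab <- table(x$entries$label)
  cat(sprintf("labeled frame set: %d frames (%s)\n", nrow(x$entries),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Fetch frame i of a set, reading from disk if not held in memory.
get_frame <- function(set, i) {
  if (!is.null(set$frames)) return(set$frames[[i]])
  p <- set$entries$path[i]
  if (is.na(p))
    stop_sonoqc("frame neither in memory nor on disk", "sonoqc_io_error")
  read_frame(p)
}

#' Seeded uniform train/test split
#'
#' @param set a [labeled_frame_set()].
#' @param train_frac fraction assigned to training (default 0.8, mirroring an
#'   800/200 protocol on 1,000 frames).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both labeled frame sets.
#' @export
split_frame_set <- function(set, train_frac = 0.8, seed = 1L) {
  n <- nrow(set$entries)
  n_train <- round(train_frac * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  subset_set <- function(keep) {
    labeled_frame_set(frames = if (!is.null(set$frames)) set$frames[keep],
                      labels = set$entries$label[keep],
                      ids = set$entries$frame_id[keep],
                      paths = set$entries$path[keep],
                      forces = set$entries$force[keep])
  }
  list(train = subset_set(sort(idx)),
       test = subset_set(sort(setdiff(seq_len(n), idx))))
}

features_matrix <- function(set, reference, config) {
  n <- nrow(set$entries)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("compression", "noise")))
  gate <- integer(n); nosig <- logical(n); corr <- numeric(n)
  for (i in seq_len(n)) {
    fv <- extract_features(get_frame(set, i), reference, config)
    out[i, ] <- c(fv$compression, fv$noise)
    gate[i] <- fv$contact; nosig[i] <- fv$no_signal
    corr[i] <- ifelse(is.na(fv$correlation_raw), NA_real_, fv$correlation_raw)
  }
  list(x = out, gate = gate, no_signal = nosig, correlation = corr)
}

MODEL_FORMAT_VERSION <- "sonoqc-quality-model-1"

#' Train the gated quality classifier
#'
#' Extracts the compression and noise features `(f_c, f_n)` for every training
#' frame (the correlation feature is not an input: it acts only as the contact
#' gate at prediction time), standardizes them to zero mean and unit variance,
#' and fits a binary support-vector machine with balanced class weights.
#' Deterministic for a fixed seed.
#'
#' @param train_set a [labeled_frame_set()] containing both classes.
#' @param reference no-contact reference frame.
#' @param config a [feature_config()].
#' @param seed integer seed recorded in the training metadata.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM regularization constant (default 1).
#' @param gamma RBF kernel width; default `1/2` (one over the feature
#'   dimension).
#' @return object of class `quality_model`.
#' @export
train_quality_model <- function(train_set, reference,
                                config = feature_config(), seed = 1L,
                                kernel = c("radial", "linear"),
                                cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  labs <- train_set$entries$label
  if (length(unique(labs)) < 2L)
    stop_sonoqc("training set must contain both quality classes",
                "sonoqc_training_error")
  fm <- features_matrix(train_set, reference, config)
  center <- colMeans(fm$x)
  scale_ <- apply(fm$x, 2, sd)
  if (any(!is.finite(center)) || any(!is.finite(scale_)) || any(scale_ == 0))
    stop_sonoqc("degenerate training features: zero or non-finite variance",
                "sonoqc_training_error")
  xs <- sweep(sweep(fm$x, 2, center), 2, scale_, "/")
  y <- factor(labs, levels = c("low", "high"))
  cw <- length(y) / (2 * table(y))  # balanced: inverse class frequency
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  fit <- with_seed(seed,
    e1071::svm(x = xs, y = y, kernel = kernel, cost = cost, gamma = gamma,
               scale = FALSE, class.weights = cw))
  structure(list(version = MODEL_FORMAT_VERSION,
                 svm = fit,
                 center = center, scale = scale_,
                 feature_config = config,
                 metadata = list(seed = seed, kernel = kernel, cost = cost,
                                 gamma = gamma,
                                 n_train = length(y),
                                 class_counts = as.list(table(y)),
                                 trained_at = format(Sys.time(), tz = "UTC"))),
            class = "quality_model")
}

#' Classify a frame with the gated SVM
#'
#' The contact gate takes precedence: a frame whose correlation with the
#' no-contact reference reaches the gate threshold (or whose correlation is
#' undefined) is judged low quality (`v_svm = 0`) without consulting the SVM,
#' as is a frame with no supra-threshold signal. Otherwise the verdict is the
#' SVM prediction on the standardized `(f_c, f_n)`. `v_svm = 1` means high
#' quality.
#'
#' @param model a trained [train_quality_model()] object.
#' @param frame,reference frame matrices of identical shape.
#' @return list with `v_svm` (integer 0/1) and `features` (the
#'   `us_features`).
#' @export
classify <- function(model, frame, reference) {
  if (!inherits(model, "quality_model") || is.null(model$svm))
    stop_sonoqc("model is not a trained quality_model", "sonoqc_state_error")
  fv <- extract_features(frame, reference, model$feature_config)
  if (fv$contact == 1L || fv$no_signal)
    return(list(v_svm = 0L, features = fv))
  xs <- (c(fv$compression, fv$noise) - model$center) / model$scale
  xs <- matrix(xs, 1, dimnames = list(NULL, c("compression", "noise")))
  pred <- predict(model$svm, xs)
  list(v_svm = as.integer(pred == "high"), features = fv)
}

#' @describeIn train_quality_model predict method; returns the binary verdict
#'   (`v_svm`) for one frame.
#' @param object a `quality_model`.
#' @param frame,reference frame matrices.
#' @param ... unused.
#' @export
predict.quality_model <- function(object, frame, reference, ...) {
  classify(object, frame, reference)$v_svm
}

#' Evaluate a quality model on a labeled test set
#'
#' Applies [classify()] (gate included) to every frame and tallies the
#' confusion matrix against the subjective labels (`"high"` is the positive
#' class).
#'
#' @param model a trained `quality_model`.
#' @param test_set a non-empty [labeled_frame_set()].
#' @param reference no-contact reference frame.
#' @return list of class `quality_eval` with `accuracy`, `confusion` (TP, TN,
#'   FP, FN) and per-class `precision`/`recall`.
#' @export
evaluate_quality_model <- function(model, test_set, reference) {
  n <- nrow(test_set$entries)
  if (n == 0L) stop_sonoqc("empty test set", "sonoqc_label_error")
  truth <- as.integer(test_set$entries$label == "high")
  pred <- integer(n)
  for (i in seq_len(n))
    pred[i] <- classify(model, get_frame(test_set, i), reference)$v_svm
  tp <- sum(pred == 1L & truth == 1L); tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
  prec <- c(high = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
            low = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  rec <- c(high = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           low = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  structure(list(accuracy = (tp + tn) / n,
                 confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 precision = prec, recall = rec, n = n),
            class = "quality_eval")
}

#' @exportS3Method
print.quality_eval <- function(x, ...) {
  cat(sprintf("quality classifier evaluation on %d frames\n", x$n))
  cat(sprintf("  accuracy: %.3f\n", x$accuracy))
  cat(sprintf("  confusion: TP %d, TN %d, FP %d, FN %d\n",
              x$confusion["TP"], x$confusion["TN"], x$confusion["FP"],
              x$confusion["FN"]))
  cat(sprintf("  precision (high/low): %.3f / %.3f; recall: %.3f / %.3f\n",
              x$precision["high"], x$precision["low"],
              x$recall["high"], x$recall["low"]))
  invisible(x)
}

#' @exportS3Method
print.quality_model <- function(x, ...) {
  md <- x$metadata
  cat("gated SVM ultrasound quality model\n")
  cat(sprintf("  kernel %s (cost %.3g, gamma %.3g), trained on %d frames (seed %d)\n",
              md$kernel, md$cost, md$gamma, md$n_train, md$seed))
  cat(sprintf("  gate: correlation >= %.2f vs no-contact reference => low quality\n",
              x$feature_config$t_corr))
  cat(sprintf("  support vectors: %d\n", nrow(x$svm$SV)))
  invisible(x)
}

#' @exportS3Method
summary.quality_model <- function(object, ...) {
  print(object)
  cat(sprintf("  feature standardization: f_c %.4f +/- %.4f, f_n %.4f +/- %.4f\n",
              object$center[1], object$scale[1], object$center[2],
              object$scale[2]))
  cat(sprintf("  class counts: low %d, high %d\n",
              object$metadata$class_counts$low,
              object$metadata$class_counts$high))
  invisible(object)
}

#' Persist and reload a quality model
#'
#' The model is written as a single serialized archive carrying an explicit
#' format-version field; loading checks the version and yields bit-identical
#' predictions.
#'
#' @param model a `quality_model`.
#' @param path file path.
#' @return `save_quality_model` returns `path` invisibly; `load_quality_model`
#'   returns the model.
#' @export
save_quality_model <- function(model, path) {
  if (!inherits(model, "quality_model"))
    stop_sonoqc("not a quality_model", "sonoqc_state_error")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_quality_model
#' @export
load_quality_model <- function(path) {
  if (!file.exists(path))
    stop_sonoqc(sprintf("model file not found: %s", path), "sonoqc_io_error")
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_sonoqc(sprintf("corrupt model file: %s", path), "sonoqc_io_error"))
  if (!is.list(obj) || is.null(obj$version) ||
      !identical(obj$version, MODEL_FORMAT_VERSION))
    stop_sonoqc(sprintf("model format version mismatch (expected %s)",
                        MODEL_FORMAT_VERSION), "sonoqc_version_error")
  obj
}
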