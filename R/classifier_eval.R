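# Random-forest training and prediction, rank-based AUC and the
# confusion-matrix metrics used to evaluate the classifier.

#' Train the random-forest coding-potential classifier
#'
#' Applies the Pearson correlation screen to the training table, fits a
#' random forest on the retained features (lncRNA is the positive class),
#' and snapshots everything needed for reproducible prediction: retained
#' feature names, encoding table, wavelet parameters, CDS-score mode and
#' seed. Training is deterministic for a fixed seed.
#'
#' @param features Feature data.frame from [extract_features()] (with or
#'   without its `label` column).
#' @param labels Class labels (`lncRNA`/`pcRNA`), one per row; defaults to
#'   the table's `label` column.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param cor_threshold Correlation-screen threshold (default 0.8).
#' @param seed Integer RNG seed (default 7).
#' @param table,params,cds_mode Preprocessing snapshots recorded in the
#'   bundle (must describe how `features` was produced).
#' @return Object of class `lnc_model`: the forest plus its preprocessing
#'   state. Serialize with [save_model()] / [load_model()].
#' @export
lnc_train <- function(features, labels = features$label, ntree = 500L,
                      mtry = NULL, cor_threshold = 0.8, seed = 7L,
                      table = encoding_table(), params = morse_params(),
                      cds_mode = "surrogate") {
  if (is.null(labels)) stop("labels required (lncRNA/pcRNA)")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("training labels must contain both classes")
  }
  if (!all(labels %in% c("lncRNA", "pcRNA"))) {
    stop("labels must be lncRNA or pcRNA")
  }
  x <- features[, intersect(colnames(features), feature_names_canonical()),
                drop = FALSE]
  if (nrow(x) != length(labels)) stop("one label per feature row required")
  retained <- correlation_filter(x, threshold = cor_threshold)
  x <- as.matrix(x[, retained, drop = FALSE])
  storage.mode(x) <- "double"
  y <- factor(labels, levels = c("pcRNA", "lncRNA"))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                       mtry = mtry)
  structure(list(forest = forest,
                 feature_names = as.character(retained),
                 encoding_table = c(table),
                 encoding_table_name = attr(table, "table_name"),
                 wavelet_params = unclass(params),
                 cds_mode = cds_mode,
                 cor_threshold = cor_threshold,
                 seed = as.integer(seed),
                 schema_version = "1"),
            class = "lnc_model")
}

#' @export
print.lnc_model <- function(x, ...) {
  cat("lncwave random-forest model (schema", x$schema_version, ")\n")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  trees: %d; encoding: %s; CDS mode: %s; seed: %d\n",
              x$forest$ntree, x$encoding_table_name, x$cds_mode, x$seed))
  invisible(x)
}

.check_model_schema <- function(model, features, cds_mode = NULL) {
  missing_cols <- setdiff(model$feature_names, colnames(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s) required by the model: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(cds_mode) && !identical(cds_mode, model$cds_mode)) {
    stop("cds_mode mismatch: model was trained with '", model$cds_mode,
         "', prediction requested '", cds_mode, "'")
  }
  invisible(TRUE)
}

#' Predict coding potential with a trained model
#'
#' @param model An `lnc_model` from [lnc_train()].
#' @param features Feature data.frame covering the model's retained columns.
#' @param threshold Probability threshold for calling lncRNA (default 0.5);
#'   a row is labelled lncRNA iff its probability is >= threshold.
#' @return data.frame with `seq_id` (when present), `prob_lncRNA`, `label`.
#' @export
lnc_predict <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "lnc_model"))
  .check_model_schema(model, features)
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  prob <- stats::predict(model$forest, newdata = x, type = "prob")[, "lncRNA"]
  out <- data.frame(prob_lncRNA = unname(prob),
                    label = ifelse(prob >= threshold, "lncRNA", "pcRNA"),
                    stringsAsFactors = FALSE)
  if ("seq_id" %in% colnames(features)) {
    out <- cbind(seq_id = features$seq_id, out)
  }
  rownames(out) <- NULL
  out
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' \deqn{AUC = \frac{\sum_{+} rank_i - \tfrac{1}{2}M(1+M)}{M\,N}} with
#' ascending midranks of the scores, M positives and N negatives. Equivalent
#' to all-pairs counting with half credit for score ties.
#'
#' @param labels Logical or lncRNA/pcRNA vector; lncRNA (or TRUE) positive.
#' @param scores Numeric scores, higher = more lncRNA-like.
#' @return AUC in [0, 1]; NaN with a warning when one class is absent.
#' @export
rank_auc <- function(labels, scores) {
  pos <- .as_positive(labels)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) {
    warning("AUC undefined: one class absent")
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - 0.5 * m * (1 + m)) / (m * n)
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "lncRNA")
  as.logical(labels)
}

#' Confusion-matrix metrics and AUC
#'
#' Thresholds the scores (score >= threshold calls lncRNA, the positive
#' class) and reports the standard metrics: accuracy
#' ACC = (TP+TN)/(TP+TN+FP+FN), sensitivity SEN = TP/(TP+FN), specificity
#' SPE = TN/(TN+FP), Matthews correlation coefficient
#' MCC = (TP.TN - FP.FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and the
#' rank-based AUC of [rank_auc()].
#'
#' @param labels True classes (lncRNA/pcRNA, or logical with TRUE = lncRNA).
#' @param scores Numeric scores (probability of lncRNA).
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `acc`, `sen`, `spe`, `mcc`,
#'   `auc`. `mcc`/`auc` are NaN (with a warning) when a class or a margin is
#'   degenerate.
#' @export
lnc_evaluate <- function(labels, scores, threshold = 0.5) {
  pos <- .as_positive(labels)
  pred <- scores >= threshold
  tp <- sum(pos & pred); fn <- sum(pos & !pred)
  tn <- sum(!pos & !pred); fp <- sum(!pos & pred)
  metrics_from_confusion(tp = tp, fp = fp, tn = tn, fn = fn,
                         auc = rank_auc(pos, scores))
}

#' Metrics from explicit confusion counts
#' @param tp,fp,tn,fn Confusion counts.
#' @param auc Optional AUC to carry through (default NA).
#' @return Same structure as [lnc_evaluate()].
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn, auc = NA_real_) {
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  sen <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spe <- if (tn + fp > 0) tn / (tn + fp) else NaN
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else {
    warning("MCC undefined for degenerate confusion matrix")
    NaN
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       acc = acc, sen = sen, spe = spe, mcc = mcc, auc = auc)
}

#' Seeded k-fold cross-validation of the full classifier
#'
#' Splits the rows into k stratified folds, trains on k-1 and scores the
#' held-out fold, so every row receives exactly one out-of-fold probability;
#' metrics are computed over the pooled out-of-fold scores.
#'
#' @param features Feature data.frame with labels (column or argument).
#' @param labels Class labels; defaults to `features$label`.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for fold assignment and training (default 7).
#' @param ... Passed to [lnc_train()].
#' @return List: `metrics` (as [lnc_evaluate()]), `scores` (out-of-fold
#'   probabilities, input order), `folds` (fold id per row).
#' @export
lnc_cv <- function(features, labels = features$label, k = 5L, seed = 7L,
                   ...) {
  labels <- as.character(labels)
  n <- nrow(features)
  stopifnot(length(labels) == n, k >= 2L)
  set.seed(seed)
  folds <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- lnc_train(features[!test, , drop = FALSE],
                       labels = labels[!test], seed = seed + f, ...)
    scores[test] <- lnc_predict(model, features[test, , drop = FALSE]
                                )$prob_lncRNA
  }
  list(metrics = lnc_evaluate(labels, scores), scores = scores,
       folds = folds)
}

#' Save / load a trained model bundle
#'
#' The bundle is written with R's native serialization; [load_model()]
#' restores an identical predictor.
#'
#' @param model An `lnc_model`.
#' @param path File path.
#' @return `path` / the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lnc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "lnc_model")) stop("not an lncwave model file")
  model
}
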