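# Assembly of the 15-column feature table (8 classic + 7 wavelet) and the
# Pearson correlation screen applied before classification.

#' Canonical feature order
#'
#' The fixed column order of the 15-feature table: the eight classic
#' features followed by the seven wavelet features.
#' @return Character vector of length 15.
#' @export
feature_names_canonical <- function() {
  c("seq_len", "GC_content", "Stop_std", "Orf_fullness", "CDS_Score",
    "CDS_percent", "PI", "Fickett_Score",
    "Count", "LenMean", "LenVar", "MidMean", "30Count", "30PwMean",
    "30LenCount")
}

#' Extract the full 15-feature table from transcripts
#'
#' Runs every transcript through the whole feature pipeline: numeric
#' encoding, Morse CWT, column-sum profile, above-mean segmentation, the
#' seven wavelet features, and the eight classic features. Transcripts on
#' which any feature fails (e.g. shorter than 3 bases) are skipped with a
#' warning naming the reason; the result is deterministic for a fixed
#' configuration.
#'
#' @param seqs Named character vector of canonical sequences (see
#'   [read_fasta()]).
#' @param table Encoding table (see [encoding_table()]).
#' @param params Wavelet parameters (see [morse_params()]).
#' @param labels Optional named character vector of class labels
#'   (lncRNA/pcRNA); defaults to the `labels` attribute of `seqs` if set.
#' @param cds_mode,stop_count_mode,variance_mode,third_rule Feature options;
#'   see [cds_score()], [stop_codon_std()], [wavelet_features()].
#' @return A data.frame with `seq_id` first, the 15 feature columns in
#'   canonical order, and a `label` column when labels are available.
#' @export
extract_features <- function(seqs, table = encoding_table(),
                             params = morse_params(), labels = NULL,
                             cds_mode = "surrogate",
                             stop_count_mode = "substring",
                             variance_mode = "population",
                             third_rule = "top_rank") {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (is.null(labels)) labels <- attr(seqs, "labels")
  rows <- vector("list", length(seqs))
  failed <- character(0)
  for (i in seq_along(seqs)) {
    res <- tryCatch({
      wf <- wavelet_features(
        segments_above_mean(scws_profile(morse_cwt(
          encode_signal(seqs[[i]], table), params))),
        variance_mode = variance_mode, third_rule = third_rule)
      cf <- classic_features(seqs[[i]], cds_mode = cds_mode,
                             stop_count_mode = stop_count_mode)
      c(cf, wf)
    }, error = function(e) {
      failed <<- c(failed, paste0(names(seqs)[i], ": ",
                                  conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[i]] <- res
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (length(failed)) {
    warning(length(failed), " transcript(s) skipped: ",
            paste(utils::head(failed, 3L), collapse = "; "))
  }
  if (!any(keep)) stop("no transcript yielded a feature row")
  mat <- do.call(rbind, rows[keep])
  out <- data.frame(seq_id = names(seqs)[keep],
                    as.data.frame(mat, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("seq_id", feature_names_canonical())]
  if (!is.null(labels)) {
    out$label <- unname(labels[out$seq_id])
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen over feature columns
#'
#' Computes all pairwise Pearson correlations and greedily scans pairs in
#' canonical column order, dropping the later-ordered member of every pair
#' with `|r|` above the threshold. Zero-variance columns (undefined r) are
#' treated as uncorrelated and logged. The surviving set is idempotent under
#' re-filtering and is frozen into a trained model: prediction-time data is
#' never re-screened.
#'
#' @param features Feature data.frame from [extract_features()] (the
#'   `seq_id`/`label` columns are ignored) or a numeric matrix.
#' @param threshold Drop threshold on `|r|` (default 0.8).
#' @return Character vector of retained feature names, in input column
#'   order, with the correlation matrix attached as attribute `cor`.
#' @export
correlation_filter <- function(features, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  x <- features
  if (is.data.frame(x)) {
    x <- x[, setdiff(colnames(x), c("seq_id", "label")), drop = FALSE]
    x <- as.matrix(x)
  }
  if (nrow(x) < 2L) stop("need at least 2 rows to estimate correlations")
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    message("zero-variance column(s) treated as uncorrelated: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  }
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  nm <- colnames(x)
  keep <- rep(TRUE, length(nm))
  for (i in seq_along(nm)) {
    if (!keep[i]) next
    for (j in seq_along(nm)) {
      if (j <= i || !keep[j]) next
      if (abs(cm[i, j]) > threshold) keep[j] <- FALSE
    }
  }
  structure(nm[keep], cor = cm)
}

#' Write / read a feature table as TSV
#'
#' Lossless round trip of the table produced by [extract_features()]:
#' header row, `seq_id` first, optional `label` last.
#'
#' @param features Feature data.frame.
#' @param path File path.
#' @return `path` / the data.frame.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
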