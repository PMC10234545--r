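#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file of DNA or RNA transcripts and
#' returns canonical DNA sequences. Headers are parsed up to the first
#' whitespace as the sequence identifier; an optional `|lncRNA` / `|pcRNA`
#' suffix on the identifier is recognised as an embedded class label.
#'
#' @param path Path to a FASTA file.
#' @param n_policy How to treat IUPAC ambiguity codes: `"drop"` removes them,
#'   `"random_seeded"` replaces each by a base drawn reproducibly from its
#'   IUPAC expansion, `"error"` rejects the record. See
#'   [canonicalize_sequence()].
#' @param seed Integer seed used only when `n_policy = "random_seeded"`.
#' @param warn_short Warn for transcripts shorter than 200 bp (below the
#'   conventional lncRNA length floor). They are kept.
#' @return A named character vector of canonical sequences (A/C/G/T). If any
#'   header carries a `|lncRNA` or `|pcRNA` suffix the vector has a
#'   `labels` attribute (named character vector) and the suffix is stripped
#'   from the identifier.
#' @export
read_fasta <- function(path, n_policy = c("drop", "random_seeded", "error"),
                       seed = 1L, warn_short = TRUE) {
  n_policy <- match.arg(n_policy)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  raw <- as.character(set)
  empty <- !nzchar(raw)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ", ids[which(empty)[1L]])
  }
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty identifier at position ",
         which(!nzchar(ids))[1L])
  }

  labels <- rep(NA_character_, length(ids))
  tagged <- grepl("\\|(lncRNA|pcRNA)$", ids)
  labels[tagged] <- sub("^.*\\|", "", ids[tagged])
  ids[tagged] <- sub("\\|(lncRNA|pcRNA)$", "", ids[tagged])
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[anyDuplicated(ids)])
  }

  seqs <- vapply(seq_along(raw), function(i) {
    tryCatch(
      canonicalize_sequence(raw[[i]], n_policy = n_policy,
                            seed = seed + i - 1L),
      error = function(e) stop("record '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }, character(1))
  names(seqs) <- ids
  if (warn_short && any(nchar(seqs) < 200L)) {
    warning(sum(nchar(seqs) < 200L),
            " transcript(s) shorter than 200 bp (kept)")
  }
  if (any(tagged)) {
    names(labels) <- ids
    attr(seqs, "labels") <- labels
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in columns (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

# IUPAC ambiguity expansions over the DNA alphabet (ambiguous codes only).
.iupac_ambiguous <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Canonicalize a raw nucleotide string
#'
#' Uppercases, maps U to T, and resolves IUPAC ambiguity codes according to
#' `n_policy`. The number of positions altered by the ambiguity policy is
#' recorded in the `altered` attribute.
#'
#' @param x A single raw sequence string (DNA or RNA alphabet).
#' @param n_policy `"drop"` (remove ambiguous bases, the default),
#'   `"random_seeded"` (replace each by a seeded draw from its IUPAC
#'   expansion, preserving length), or `"error"`.
#' @param seed Seed for `"random_seeded"`.
#' @return Canonical string over A/C/G/T with attribute `altered` (integer
#'   count of dropped or replaced positions).
#' @export
canonicalize_sequence <- function(x, n_policy = c("drop", "random_seeded",
                                                  "error"), seed = 1L) {
  n_policy <- match.arg(n_policy)
  stopifnot(is.character(x), length(x) == 1L)
  up <- chartr("u", "U", toupper(x))
  up <- chartr("U", "T", up)
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    stop("empty sequence")
  }
  ok <- chars %in% c("A", "C", "G", "T")
  amb <- chars %in% names(.iupac_ambiguous)
  bad <- !ok & !amb
  if (any(bad)) {
    stop("invalid character '", chars[which(bad)[1L]], "' at position ",
         which(bad)[1L])
  }
  altered <- sum(amb)
  if (altered > 0L) {
    if (n_policy == "error") {
      stop("ambiguous base '", chars[which(amb)[1L]], "' at position ",
           which(amb)[1L])
    } else if (n_policy == "drop") {
      chars <- chars[!amb]
      if (length(chars) == 0L) stop("empty sequence after dropping ambiguous bases")
    } else {
      idx <- which(amb)
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      set.seed(seed)
      chars[idx] <- vapply(chars[idx], function(code) {
        opts <- .iupac_ambiguous[[code]]
        opts[sample.int(length(opts), 1L)]
      }, character(1))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
  }
  out <- paste(chars, collapse = "")
  attr(out, "altered") <- altered
  out
}

#' Read class labels from a two-column TSV
#'
#' Accepts `seq_id<TAB>label` lines, with or without a header row. Labels
#' must be `lncRNA` or `pcRNA`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping seq_id to label.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label TSV must have two columns (seq_id, label)")
  # tolerate a header row
  if (tolower(tab[1, 2]) %in% c("label", "class")) tab <- tab[-1, , drop = FALSE]
  lab <- tab[[2]]
  bad <- !lab %in% c("lncRNA", "pcRNA")
  if (any(bad)) {
    stop("unknown label '", lab[which(bad)[1L]], "' (expected lncRNA/pcRNA)")
  }
  if (anyDuplicated(tab[[1]])) stop("duplicate seq_id in label file")
  stats::setNames(lab, tab[[1]])
}

#' Write labels as a two-column TSV
#' @param labels Named character vector (seq_id -> label).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(seq_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
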