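# The eight classic coding-potential features: composition, stop-codon
# statistics, ORF structure, a CDS score, peptide isoelectric point and the
# Fickett TESTCODE statistic.

.lnc_cache <- new.env(parent = emptyenv())

.load_fickett_tables <- function() {
  if (!is.null(.lnc_cache$fickett)) return(.lnc_cache$fickett)
  path <- system.file("extdata", "fickett_tables.tsv", package = "lncwave",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split_kind <- function(kind) {
    sub <- tab[tab$kind == kind, ]
    lapply(split(sub, sub$base), function(d) {
      d <- d[order(-ifelse(is.na(d$para), 0, d$para)), ]
      list(para = d$para, prob = d$prob)
    })
  }
  weights <- function(kind) {
    sub <- tab[tab$kind == kind, ]
    stats::setNames(sub$prob, sub$base)
  }
  .lnc_cache$fickett <- list(
    position = split_kind("position"),
    content = split_kind("content"),
    w_position = weights("weight_position"),
    w_content = weights("weight_content"))
  .lnc_cache$fickett
}

.load_pka <- function() {
  if (!is.null(.lnc_cache$pka)) return(.lnc_cache$pka)
  path <- system.file("extdata", "pka_emboss.tsv", package = "lncwave",
                      mustWork = TRUE)
  .lnc_cache$pka <- utils::read.delim(path, stringsAsFactors = FALSE)
  .lnc_cache$pka
}

#' GC content of a transcript
#' @param seq Canonical A/C/G/T string.
#' @return Percentage in [0, 100].
#' @export
gc_content <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Standard deviation of stop-codon counts
#'
#' Counts TAA, TAG and TGA as (possibly overlapping) substrings at every
#' position of the transcript, irrespective of reading frame, and returns
#' the population standard deviation of the three counts. With
#' `mode = "per_frame_sum"` the triplets are counted only at in-frame codon
#' positions, summed over the three forward frames (equivalent positions,
#' different bookkeeping for runs like TAATAA).
#'
#' @param seq Canonical A/C/G/T string.
#' @param mode `"substring"` (default) or `"per_frame_sum"`.
#' @return Nonnegative real.
#' @export
stop_codon_std <- function(seq, mode = c("substring", "per_frame_sum")) {
  mode <- match.arg(mode)
  n <- nchar(seq)
  counts <- c(TAA = 0, TAG = 0, TGA = 0)
  if (n >= 3L) {
    tri <- substring(seq, 1:(n - 2), 3:n)
    if (mode == "per_frame_sum") {
      # every position 1..n-2 is in-frame for exactly one forward frame,
      # so the per-frame sum equals the substring count; kept as a distinct
      # mode for clarity of contract
      tri <- tri
    }
    tc <- table(tri[tri %in% names(counts)])
    counts[names(tc)] <- as.numeric(tc)
  }
  sqrt(mean((counts - mean(counts))^2))
}

# codon -> amino acid, standard genetic code (stop = "*")
.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Find the longest open reading frame
#'
#' Scans the three forward frames for ATG-initiated runs terminated by an
#' in-frame stop (TAA/TAG/TGA). A run that reaches the end of the transcript
#' without a stop is kept as an incomplete candidate (`has_stop = FALSE`).
#' The longest candidate by nucleotide span wins; ties go to the earliest
#' start.
#'
#' @param seq Canonical A/C/G/T string.
#' @return `NULL` when no ATG exists, otherwise a list with `start` (0-based
#'   inclusive), `end` (0-based exclusive, including the stop codon when
#'   present), `frame` (0/1/2), `has_start`, `has_stop`, `peptide`
#'   (amino-acid string, stop excluded).
#' @export
find_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 1L) next
    starts <- frame + 3 * (seq_len(n_codons) - 1) + 1
    codons <- substring(seq, starts, starts + 2)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    # first stop at or after each ATG
    nxt <- if (length(stops)) {
      stops[findInterval(atg - 1L, stops) + 1L]
    } else rep(NA_integer_, length(atg))
    for (i in seq_along(atg)) {
      a <- atg[i]
      s <- nxt[i]
      has_stop <- !is.na(s)
      end_codon <- if (has_stop) s else n_codons
      span <- 3 * (end_codon - a + 1)
      start0 <- frame + 3 * (a - 1)
      cand <- list(start = start0, end = start0 + span, frame = frame,
                   has_start = TRUE, has_stop = has_stop)
      if (is.null(best) || span > (best$end - best$start) ||
          (span == (best$end - best$start) && start0 < best$start)) {
        pep_codons <- codons[a:(end_codon - has_stop)]
        cand$peptide <- paste(.translate_codons(pep_codons), collapse = "")
        best <- cand
      }
    }
  }
  best
}

#' ORF integrity code
#'
#' 1.0 for a complete ORF (start and stop), 0.5 when only one of the two is
#' present, 0.0 when no ORF was found.
#'
#' @param orf Result of [find_longest_orf()] (or `NULL`).
#' @return 0, 0.5 or 1.
#' @export
orf_fullness <- function(orf) {
  if (is.null(orf)) return(0)
  (isTRUE(orf$has_start) + isTRUE(orf$has_stop)) / 2
}

#' Fraction of the transcript covered by the longest ORF
#' @param seq Canonical A/C/G/T string.
#' @param orf Result of [find_longest_orf()] on `seq`.
#' @return Percentage in [0, 100]; 0 when no ORF.
#' @export
cds_percent <- function(seq, orf) {
  if (is.null(orf)) return(0)
  100 * (orf$end - orf$start) / nchar(seq)
}

#' CDS score of the longest ORF
#'
#' A deterministic, self-contained score of coding-sequence quality:
#' ORF span in bases, plus 50 for a start codon, plus 50 for a stop codon,
#' plus 25 when the start context matches the Kozak consensus (purine at
#' position -3 and G at position +4 around the ATG); in-frame internal stops
#' would subtract 10 each but are zero by construction of the ORF search.
#' Alternatively, `mode = "txcdspredict"` shells out to an installed UCSC
#' `txCdsPredict` binary and parses the score column of its output; scores
#' from the two modes are not on the same scale, so trained models record
#' which mode produced their features.
#'
#' @param seq Canonical A/C/G/T string.
#' @param orf Result of [find_longest_orf()] on `seq`.
#' @param mode `"surrogate"` (default) or `"txcdspredict"`.
#' @return Nonnegative real; 0 when no ORF.
#' @export
cds_score <- function(seq, orf, mode = c("surrogate", "txcdspredict")) {
  mode <- match.arg(mode)
  if (mode == "txcdspredict") {
    return(.cds_score_external(seq))
  }
  if (is.null(orf)) return(0)
  span <- orf$end - orf$start
  kozak <- 0
  if (orf$has_start) {
    up <- orf$start - 3L   # 0-based index of position -3
    dn <- orf$start + 3L   # 0-based index of position +4
    if (up >= 0L && dn < nchar(seq)) {
      m3 <- substr(seq, up + 1L, up + 1L)
      p4 <- substr(seq, dn + 1L, dn + 1L)
      if (m3 %in% c("A", "G") && p4 == "G") kozak <- 25
    }
  }
  span + 50 * isTRUE(orf$has_start) + 50 * isTRUE(orf$has_stop) + kozak
}

.cds_score_external <- function(seq) {
  bin <- Sys.which("txCdsPredict")
  if (!nzchar(bin)) {
    stop("txCdsPredict binary not found on PATH; use mode = 'surrogate'")
  }
  fa <- tempfile(fileext = ".fa")
  out <- tempfile(fileext = ".cds")
  on.exit(unlink(c(fa, out)), add = TRUE)
  write_fasta(c(query = seq), fa)
  status <- system2(bin, c(fa, out), stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out)) stop("txCdsPredict failed")
  tab <- utils::read.delim(out, header = FALSE)
  if (nrow(tab) == 0L) return(0)
  as.numeric(tab[1, 5])
}

#' Theoretical isoelectric point of a peptide
#'
#' pH at which the peptide's net charge is zero under the
#' Henderson-Hasselbalch model, with one positive group per N-terminus, H, K
#' and R, and one negative group per C-terminus, D, E, C and Y. pKa values
#' follow the EMBOSS convention and ship as an editable table. The root is
#' found by bisection on [0, 14] to a tolerance of 1e-3 pH units.
#'
#' @param peptide Amino-acid string over the 20 standard residues. The empty
#'   string returns the sentinel 0.
#' @return pH in [0, 14].
#' @export
isoelectric_point <- function(peptide) {
  if (is.null(peptide) || !nzchar(peptide)) return(0)
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  known <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(res %in% known)) {
    stop("unknown residue '", res[which(!res %in% known)[1L]], "'")
  }
  pka <- .load_pka()
  counts <- c(Nterm = 1, Cterm = 1, table(res)[c("C", "D", "E", "H", "K",
                                                 "R", "Y")])
  names(counts) <- c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y")
  counts[is.na(counts)] <- 0
  net_charge <- function(ph) {
    q <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      if (counts[[g]] == 0) next
      if (pka$charge[i] == "positive") {
        q <- q + counts[[g]] / (1 + 10^(ph - pka$pka[i]))
      } else {
        q <- q - counts[[g]] / (1 + 10^(pka$pka[i] - ph))
      }
    }
    q
  }
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1L]]
}

#' Fickett TESTCODE statistic
#'
#' For each base, a position parameter (the maximum of its three
#' codon-position counts divided by the minimum plus one; 3-periodic
#' asymmetry) and a content parameter (its overall frequency) are converted
#' to coding probabilities through the published TESTCODE lookup tables
#' (shipped as a plain-text data file with explicit bin edges, CPAT
#' convention) and combined with the published weights.
#'
#' @param seq Canonical A/C/G/T string of length >= 3.
#' @return The weighted probability sum (higher = more coding-like).
#' @export
fickett_score <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than 3 bases")
  tabs <- .load_fickett_tables()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    pos_counts <- vapply(0:2, function(p) sum(chars == base & phase == p),
                         numeric(1))
    pos_value <- max(pos_counts) / (min(pos_counts) + 1)
    content <- sum(chars == base) / n
    pt <- tabs$position[[base]]
    ct <- tabs$content[[base]]
    score <- score +
      .fickett_lookup(pos_value, pt$para, pt$prob) * tabs$w_position[[base]] +
      .fickett_lookup(content, ct$para, ct$prob) * tabs$w_content[[base]]
  }
  score
}

#' The eight classic features of one transcript
#'
#' @param seq Canonical A/C/G/T string (length >= 3).
#' @param cds_mode Passed to [cds_score()].
#' @param stop_count_mode Passed to [stop_codon_std()].
#' @return Named numeric vector: `seq_len`, `GC_content`, `Stop_std`,
#'   `Orf_fullness`, `CDS_Score`, `CDS_percent`, `PI`, `Fickett_Score`.
#'   All finite; ORF-derived features fall back to 0 when no ORF exists.
#' @export
classic_features <- function(seq, cds_mode = "surrogate",
                             stop_count_mode = "substring") {
  orf <- find_longest_orf(seq)
  c(seq_len = nchar(seq),
    GC_content = gc_content(seq),
    Stop_std = stop_codon_std(seq, mode = stop_count_mode),
    Orf_fullness = orf_fullness(orf),
    CDS_Score = cds_score(seq, orf, mode = cds_mode),
    CDS_percent = cds_percent(seq, orf),
    PI = isoelectric_point(if (is.null(orf)) "" else orf$peptide),
    Fickett_Score = fickett_score(seq))
}
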