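# Seeded simulator of two separable transcript classes: coding-like
# transcripts with a planted, codon-biased ORF and noncoding-like,
# GC-matched transcripts with suppressed ORFs. Used by the test suite and
# the worked examples so no external dataset is needed.

.sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

# A fixed skewed codon-usage table: one "preferred" codon per amino acid
# gets 6x the weight of its synonyms, emulating the codon-usage bias of real
# coding sequences (a 3-periodic composition signal).
.codon_weights <- function(strength) {
  stopifnot(strength >= 0, strength <= 1)
  codons <- .sense_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  w <- rep(1, length(codons))
  names(w) <- codons
  for (a in unique(aa)) {
    syn <- codons[aa == a]
    w[syn[1L]] <- 6   # first codon alphabetically is the preferred one
  }
  skew <- w / sum(w)
  unif <- rep(1 / length(codons), length(codons))
  p <- strength * skew + (1 - strength) * unif
  stats::setNames(p, codons)
}

.codon_gc_fraction <- function(weights) {
  gc_per <- vapply(names(weights), function(cdn) {
    ch <- strsplit(cdn, "")[[1]]
    sum(ch %in% c("G", "C")) / 3
  }, numeric(1))
  sum(weights * gc_per)
}

.sample_iid <- function(n, gc) {
  gc <- min(max(gc, 0.05), 0.95)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulation settings for the two-class transcript generator
#'
#' @param n_per_class Transcripts per class (default 500).
#' @param length_range Min/max transcript length in bp (default 250-3000;
#'   minimum 206 so a planted ORF plus UTRs always fits).
#' @param gc_target Target mean GC fraction of both classes (default 0.5).
#' @param orf_fraction Fraction of a coding-like transcript covered by the
#'   planted ORF (default 0.6).
#' @param codon_bias_strength Blend between the skewed codon-usage table and
#'   uniform codon usage, in [0, 1] (default 0.8).
#' @param stop_interval Maximum spacing, in bp, between seeded stop codons
#'   per frame in noncoding-like transcripts (default 90, capping chance
#'   ORFs near the 30-codon floor).
#' @param seed Integer RNG seed (default 7).
#' @return List of validated settings.
#' @export
synth_config <- function(n_per_class = 500L, length_range = c(250L, 3000L),
                         gc_target = 0.5, orf_fraction = 0.6,
                         codon_bias_strength = 0.8, stop_interval = 90L,
                         seed = 7L) {
  stopifnot(n_per_class >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            gc_target > 0, gc_target < 1,
            orf_fraction > 0, orf_fraction < 1,
            codon_bias_strength >= 0, codon_bias_strength <= 1,
            stop_interval >= 9L)
  if (length_range[1] < 206L) {
    stop("minimum transcript length must be >= 206 bp")
  }
  list(n_per_class = as.integer(n_per_class),
       length_range = as.integer(length_range),
       gc_target = gc_target, orf_fraction = orf_fraction,
       codon_bias_strength = codon_bias_strength,
       stop_interval = as.integer(stop_interval),
       seed = as.integer(seed))
}

#' Generate coding-like transcripts (planted ORF, biased codons)
#'
#' Each transcript is a random 5' UTR, an ATG, codon-biased sense codons
#' (internal stops excluded by construction), a stop codon, and a random
#' 3' UTR. An in-frame stop is written at the end of the 5' UTR so the
#' planted ORF is not extended by a chance upstream start. UTR composition
#' compensates the codon GC so the transcript-wide expectation hits
#' `gc_target`.
#'
#' @param config From [synth_config()].
#' @return Named character vector of sequences labelled `pcRNA` via the
#'   `labels` attribute; names are `pc_0001`-style identifiers.
#' @export
generate_coding_like <- function(config = synth_config()) {
  set.seed(config$seed)
  weights <- .codon_weights(config$codon_bias_strength)
  codon_gc <- .codon_gc_fraction(weights)
  n <- config$n_per_class
  out <- character(n)
  for (i in seq_len(n)) {
    L <- sample(config$length_range[1]:config$length_range[2], 1L)
    orf_nt <- min(3L * ceiling(config$orf_fraction * L / 3), L - 6L)
    orf_nt <- max(orf_nt, 9L)
    utr_total <- L - orf_nt
    utr5 <- sample(0:utr_total, 1L)
    utr3 <- utr_total - utr5
    utr_gc <- if (utr_total > 0) {
      (config$gc_target * L - orf_nt * codon_gc) / utr_total
    } else config$gc_target
    n_internal <- orf_nt / 3L - 2L
    body <- paste(sample(names(weights), n_internal, replace = TRUE,
                         prob = weights), collapse = "")
    stop_cdn <- sample(c("TAA", "TAG", "TGA"), 1L)
    u5 <- if (utr5 > 0) .sample_iid(utr5, utr_gc) else ""
    if (utr5 >= 3L) {
      substr(u5, utr5 - 2L, utr5) <- "TAA"  # block upstream in-frame starts
    }
    u3 <- if (utr3 > 0) .sample_iid(utr3, utr_gc) else ""
    out[i] <- paste0(u5, "ATG", body, stop_cdn, u3)
  }
  names(out) <- sprintf("pc_%04d", seq_len(n))
  attr(out, "labels") <- stats::setNames(rep("pcRNA", n), names(out))
  out
}

#' Generate noncoding-like transcripts (GC-matched, ORF-suppressed)
#'
#' Bases are sampled i.i.d. at a composition chosen so that, after stop
#' codons are written every `stop_interval` bp in each of the three forward
#' frames (suppressing long chance ORFs), the expected GC equals
#' `gc_target` - i.e. the class is GC-matched to the coding-like class and
#' separation cannot come from composition alone.
#'
#' @param config From [synth_config()].
#' @return Named character vector labelled `lncRNA` via the `labels`
#'   attribute; names are `lnc_0001`-style identifiers.
#' @export
generate_noncoding_like <- function(config = synth_config()) {
  set.seed(config$seed + 1000003L)
  n <- config$n_per_class
  step <- config$stop_interval
  out <- character(n)
  for (i in seq_len(n)) {
    L <- sample(config$length_range[1]:config$length_range[2], 1L)
    # stop positions (0-based codon starts): per frame f a lattice of
    # positions congruent to f mod 3, spaced `stride` <= stop_interval,
    # staggered across frames so the planted codons never overlap
    stride <- 3L * (step %/% 3L)
    third <- stride %/% 3L
    offsets <- vapply(0:2, function(f) {
      o <- f * third
      as.integer(o + ((f - o) %% 3L))  # nudge into frame f
    }, integer(1))
    starts <- sort(unique(unlist(lapply(offsets, function(o) {
      if (o > L - 3L) return(integer(0))
      seq.int(o, L - 3L, by = stride)
    }))))
    f_planted <- 3 * length(starts) / L
    gc_iid <- (config$gc_target - f_planted * (2 / 9)) / (1 - f_planted)
    s <- .sample_iid(L, gc_iid)
    stops <- sample(c("TAA", "TAG", "TGA"), length(starts), replace = TRUE)
    for (j in seq_along(starts)) {
      substr(s, starts[j] + 1L, starts[j] + 3L) <- stops[j]
    }
    out[i] <- s
  }
  names(out) <- sprintf("lnc_%04d", seq_len(n))
  attr(out, "labels") <- stats::setNames(rep("lncRNA", n), names(out))
  out
}

#' Generate the full two-class synthetic dataset
#'
#' @param config From [synth_config()].
#' @return Named character vector of `2 * n_per_class` sequences
#'   (noncoding-like first) with a `labels` attribute.
#' @export
simulate_transcripts <- function(config = synth_config()) {
  lnc <- generate_noncoding_like(config)
  pc <- generate_coding_like(config)
  seqs <- c(lnc, pc)
  attr(seqs, "labels") <- c(attr(lnc, "labels"), attr(pc, "labels"))
  seqs
}
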