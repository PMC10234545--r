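# Independent reference implementations (oracles) used to check the package
# against brute force. These deliberately avoid the code paths they verify.

# position-by-position scan for above-mean runs
oracle_segments <- function(power) {
  mu <- mean(power)
  segs <- list()
  start <- NA
  for (i in seq_along(power)) {
    if (power[i] > mu && is.na(start)) start <- i
    if ((power[i] <= mu || i == length(power)) && !is.na(start)) {
      end <- if (power[i] > mu) i else i - 1
      segs[[length(segs) + 1]] <- c(start - 1, end)  # 0-based incl, excl
      start <- NA
    }
  }
  if (length(segs) == 0) {
    return(data.frame(p_start = integer(0), p_end = integer(0)))
  }
  m <- do.call(rbind, segs)
  data.frame(p_start = m[, 1], p_end = m[, 2])
}

# Morse CWT by explicit DFT sums and direct circular convolution in the
# time domain (no stats::fft anywhere).
oracle_cwt <- function(signal, params) {
  n <- length(signal)
  x <- signal - mean(signal)
  m <- 2^ceiling(log2(max(2 * n, 4)))
  left <- (m - n) %/% 2
  t <- (1 - left):(m - left)
  m0 <- (t - 1) %% (2 * n)
  idx <- ifelse(m0 < n, m0 + 1, 2 * n - m0)
  xp <- x[idx]
  k <- 0:(m - 1)
  omega <- ifelse(k <= m / 2, 2 * pi * k / m, 0)
  scales <- seq_len(params$n_layers_total) * params$omega_p / (2 * pi)
  # h_j[t] = (1/m) sum_k conj(Psi_k) exp(2 pi i k t / m), explicit sum
  tt <- 0:(m - 1)
  E <- exp(2i * pi * outer(tt, k) / m)   # m x m
  out <- matrix(0 + 0i, params$n_layers_total, n)
  for (j in seq_along(scales)) {
    hat <- morse_wavelet_hat(scales[j] * omega, params)
    h <- as.vector(E %*% Conj(hat)) / m
    y <- complex(real = numeric(m), imaginary = numeric(m))
    for (pos in 0:(m - 1)) {
      y[pos + 1] <- sum(xp * h[((pos - (0:(m - 1))) %% m) + 1])
    }
    out[j, ] <- y[(left + 1):(left + n)]
  }
  out
}

# exhaustive enumeration of ATG-initiated, in-frame, (stop-terminated or
# terminal) runs; returns the longest by span, earliest start on ties
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  best <- NULL
  for (start in seq_len(max(n - 2, 0))) {
    if (paste(chars[start:(start + 2)], collapse = "") != "ATG") next
    pos <- start
    has_stop <- FALSE
    end <- NA
    while (pos + 2 <= n) {
      cdn <- paste(chars[pos:(pos + 2)], collapse = "")
      if (pos > start && cdn %in% c("TAA", "TAG", "TGA")) {
        has_stop <- TRUE
        end <- pos + 2
        break
      }
      end <- pos + 2
      pos <- pos + 3
    }
    span <- end - start + 1
    if (is.null(best) || span > best$span) {
      best <- list(start = start - 1, end = start - 1 + span, span = span,
                   has_stop = has_stop)
    }
  }
  best
}

# all-pairs Mann-Whitney AUC with half credit for ties
oracle_auc_pairs <- function(pos, scores) {
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# fine-grid sign-change search for the isoelectric point
oracle_pi_grid <- function(peptide, step = 1e-4) {
  pka <- utils::read.delim(system.file("extdata", "pka_emboss.tsv",
                                       package = "lncwave"))
  res <- strsplit(peptide, "")[[1]]
  counts <- c(Nterm = 1, Cterm = 1,
              C = sum(res == "C"), D = sum(res == "D"), E = sum(res == "E"),
              H = sum(res == "H"), K = sum(res == "K"), R = sum(res == "R"),
              Y = sum(res == "Y"))
  charge <- function(ph) {
    q <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      if (counts[[g]] == 0) next
      q <- q + if (pka$charge[i] == "positive") {
        counts[[g]] / (1 + 10^(ph - pka$pka[i]))
      } else {
        -counts[[g]] / (1 + 10^(pka$pka[i] - ph))
      }
    }
    q
  }
  grid <- seq(0, 14, by = step)
  qs <- vapply(grid, charge, numeric(1))
  i <- which(qs[-length(qs)] > 0 & qs[-1] <= 0)[1]
  (grid[i] + grid[i + 1]) / 2
}

# independent Fickett lookup from the shipped table file
oracle_fickett <- function(seq) {
  tab <- utils::read.delim(system.file("extdata", "fickett_tables.tsv",
                                       package = "lncwave"))
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  total <- 0
  for (base in c("A", "C", "G", "T")) {
    cnt <- c(sum(chars[seq(1, n, 3)] == base),
             sum(chars[seq(2, n, 3)] == base),
             if (n >= 3) sum(chars[seq(3, n, 3)] == base) else 0)
    pv <- max(cnt) / (min(cnt) + 1)
    cv <- sum(chars == base) / n
    look <- function(kind, value) {
      d <- tab[tab$kind == kind & tab$base == base, ]
      d <- d[order(-d$para), ]
      d$prob[which(value >= d$para)[1]]
    }
    wpos <- tab$prob[tab$kind == "weight_position" & tab$base == base]
    wcon <- tab$prob[tab$kind == "weight_content" & tab$base == base]
    total <- total + look("position", pv) * wpos + look("content", cv) * wcon
  }
  total
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
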