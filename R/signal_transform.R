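# Numeric encoding of transcripts and the generalized Morse continuous
# wavelet transform that produces the per-transcript scalogram.

.encoding_tables <- list(
  # Acid-dissociation (pKa) constants of the free nucleobases: the most
  # acidic/basic ring nitrogen of each base (adenine N1, cytosine N3,
  # guanine N1, thymine N3). A crude proxy for the local protonation /
  # charge behaviour of the chain.
  pk_default = c(A = 3.5, C = 4.2, G = 9.2, T = 9.7),
  # Electron-ion interaction potential (EIIP) of each nucleotide.
  eiip = c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
)

#' Nucleotide-to-amplitude encoding tables
#'
#' Returns the named amplitude table used to turn a transcript into a
#' numeric signal. Two tables ship with the package: `"pk_default"`
#' (nucleobase pKa values, the default) and `"eiip"` (electron-ion
#' interaction potentials). A custom table may be supplied as a named
#' numeric vector with entries for A, C, G and T; the downstream wavelet
#' features are invariant to affine changes of the table up to an overall
#' power scale, so the choice mainly matters for reproducibility and is
#' recorded in trained models.
#'
#' @param table Name of a shipped table, or a named numeric vector over
#'   A/C/G/T.
#' @return Named numeric vector with attributes `table_name`.
#' @export
encoding_table <- function(table = "pk_default") {
  if (is.character(table) && length(table) == 1L) {
    if (!table %in% names(.encoding_tables)) {
      stop("unknown encoding table '", table, "'; shipped tables: ",
           paste(names(.encoding_tables), collapse = ", "))
    }
    out <- .encoding_tables[[table]]
    attr(out, "table_name") <- table
    return(out)
  }
  stopifnot(is.numeric(table))
  if (!all(c("A", "C", "G", "T") %in% names(table))) {
    stop("encoding table must name all of A, C, G, T")
  }
  out <- table[c("A", "C", "G", "T")]
  if (any(!is.finite(out))) stop("encoding table amplitudes must be finite")
  if (length(unique(out)) < 2L) {
    stop("encoding table must contain at least two distinct amplitudes")
  }
  attr(out, "table_name") <- "custom"
  out
}

#' Encode a canonical sequence as a numeric signal
#'
#' @param seq A canonical A/C/G/T string.
#' @param table An encoding table (see [encoding_table()]).
#' @return Numeric vector, one amplitude per base.
#' @export
encode_signal <- function(seq, table = encoding_table()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  vals <- unname(table[chars])
  if (anyNA(vals)) {
    stop("residue '", chars[which(is.na(vals))[1L]],
         "' absent from encoding table")
  }
  vals
}

#' Generalized Morse wavelet parameters
#'
#' The analytic generalized Morse wavelet has frequency response
#' \deqn{\varphi(\beta,\gamma;\omega) = U(\omega)\, a_{\beta,\gamma}\,
#'   \omega^{\beta} e^{-\omega^{\gamma}}}
#' with unit step \eqn{U}. Its peak (carrier) angular frequency is
#' \eqn{\omega_p = (\beta/\gamma)^{1/\gamma}}. The normalization constant
#' \eqn{a_{\beta,\gamma}} is chosen so the frequency-domain peak value is 2
#' (the usual analytic-wavelet convention); any positive constant cancels in
#' the above-mean segmentation downstream.
#'
#' Layer j (1-based) is assigned the scale \eqn{s_j = j\,\omega_p/(2\pi)},
#' so that layer j responds maximally to periodicities of j bases: the layer
#' index reads directly as a base-length footprint.
#'
#' @param beta Positive shape parameter (default 20).
#' @param gamma Positive shape parameter (default 3).
#' @param n_layers_total Number of scalogram layers computed (default 35).
#' @param n_layers_sum Number of layers collapsed into the column-sum
#'   profile (default 20).
#' @param padding Boundary handling: `"reflect"` (reflection padding to the
#'   next power of two, default) or `"circular"` (periodic).
#' @return Object of class `morse_params`.
#' @export
morse_params <- function(beta = 20, gamma = 3, n_layers_total = 35L,
                         n_layers_sum = 20L,
                         padding = c("reflect", "circular")) {
  padding <- match.arg(padding)
  stopifnot(beta > 0, gamma > 0,
            n_layers_sum >= 1L, n_layers_sum <= n_layers_total)
  omega_p <- (beta / gamma)^(1 / gamma)
  norm_constant <- 2 / (omega_p^beta * exp(-omega_p^gamma))
  structure(list(beta = beta, gamma = gamma,
                 n_layers_total = as.integer(n_layers_total),
                 n_layers_sum = as.integer(n_layers_sum),
                 padding = padding,
                 omega_p = omega_p,
                 norm_constant = norm_constant),
            class = "morse_params")
}

#' @export
print.morse_params <- function(x, ...) {
  cat(sprintf(
    "Generalized Morse wavelet: beta=%g gamma=%g (peak omega %.4f)\n",
    x$beta, x$gamma, x$omega_p))
  cat(sprintf("  layers: %d total, %d summed; padding: %s\n",
              x$n_layers_total, x$n_layers_sum, x$padding))
  invisible(x)
}

#' Morse wavelet frequency response
#'
#' Evaluates \eqn{\varphi(\beta,\gamma;\omega)} (see [morse_params()]).
#' Zero for \eqn{\omega \le 0}; the maximum over \eqn{\omega > 0} sits at
#' \eqn{\omega_p = (\beta/\gamma)^{1/\gamma}} and equals the normalization
#' peak value 2.
#'
#' @param omega Angular frequency (vectorized).
#' @param params A `morse_params` object.
#' @return Real amplitudes, same length as `omega`.
#' @export
morse_wavelet_hat <- function(omega, params = morse_params()) {
  out <- numeric(length(omega))
  pos <- omega > 0
  w <- omega[pos]
  # evaluate in log space: omega^beta overflows for large beta
  out[pos] <- params$norm_constant *
    exp(params$beta * log(w) - w^params$gamma)
  out
}

# scale of each layer: layer j covers a footprint of ~j bases
.layer_scales <- function(params) {
  seq_len(params$n_layers_total) * params$omega_p / (2 * pi)
}

.next_pow2 <- function(n) 2^ceiling(log2(n))

# Reflection-pad x to length m (m >= length(x)), centered. Positions outside
# 1..n fold back by half-sample symmetric extension (period 2n).
.reflect_pad <- function(x, m) {
  n <- length(x)
  extra <- m - n
  left <- extra %/% 2
  t <- (1 - left):(m - left)
  m0 <- (t - 1) %% (2 * n)
  idx <- ifelse(m0 < n, m0 + 1, 2 * n - m0)
  list(values = x[idx], offset = left)
}

#' Continuous wavelet transform of a numeric signal (Morse wavelet)
#'
#' Computes the analytic Morse CWT layer by layer in the frequency domain:
#' the zero-meaned, padded signal's spectrum is multiplied by the conjugate
#' wavelet response at each layer's scale and inverse-transformed. L1 scale
#' normalization (response evaluated at \eqn{s\omega} with peak value held
#' constant) keeps peak magnitudes comparable across layers. Padding is
#' trimmed so the output width equals the input length.
#'
#' @param signal Numeric vector of length >= 2 (see [encode_signal()]).
#' @param params A `morse_params` object.
#' @return Object of class `lnc_scalogram`: list with `coeffs` (complex
#'   matrix, layers x positions), `layer_scales`, and `params`.
#' @export
morse_cwt <- function(signal, params = morse_params()) {
  stopifnot(is.numeric(signal))
  n <- length(signal)
  if (n < 2L) stop("signal must have length >= 2")
  x <- signal - mean(signal)
  if (params$padding == "reflect") {
    m <- .next_pow2(max(2L * n, 4L))
    pad <- .reflect_pad(x, m)
    xp <- pad$values
    offset <- pad$offset
  } else {
    m <- n
    xp <- x
    offset <- 0L
  }
  spec <- stats::fft(xp)
  # DFT bin k (0-based) carries angular frequency 2*pi*k/m for k < m/2;
  # bins at and above Nyquist map to omega <= 0 where the analytic wavelet
  # response vanishes.
  k <- 0:(m - 1)
  omega <- ifelse(k <= m / 2, 2 * pi * k / m, 0)
  scales <- .layer_scales(params)
  coeffs <- matrix(0 + 0i, nrow = params$n_layers_total, ncol = n)
  for (j in seq_along(scales)) {
    hat <- morse_wavelet_hat(scales[j] * omega, params)
    row <- stats::fft(spec * Conj(hat), inverse = TRUE) / m
    coeffs[j, ] <- row[(offset + 1):(offset + n)]
  }
  structure(list(coeffs = coeffs, layer_scales = scales, params = params),
            class = "lnc_scalogram")
}

#' @export
print.lnc_scalogram <- function(x, ...) {
  cat(sprintf("Morse scalogram: %d layers x %d positions\n",
              nrow(x$coeffs), ncol(x$coeffs)))
  invisible(x)
}

#' Write a scalogram magnitude matrix as TSV (layers x positions)
#' @param scalogram An `lnc_scalogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalogram <- function(scalogram, path) {
  utils::write.table(Mod(scalogram$coeffs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
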