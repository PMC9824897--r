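# Periodized discrete wavelet transform with the Daubechies-4 (8-tap)
# filter pair. Only the multi-level analysis (coefficients) is needed here;
# sub-band energies feed the wavelet features.

# db4 decomposition filters (orthonormal, standard values)
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)

dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) {        # pad odd lengths by repeating the last sample
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(DB4_DEC_LO)
  half <- n %/% 2L
  # periodized convolution: out[k] = sum_m h[m] * x[(2k + L/2 - m) mod n]
  idx <- outer(2L * (seq_len(half) - 1L) + L %/% 2L, seq_len(L) - 1L, "-") %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(approx = drop(xm %*% DB4_DEC_LO), detail = drop(xm %*% DB4_DEC_HI))
}

#' Multi-level periodized db4 wavelet decomposition
#'
#' Pyramid analysis with periodic boundary handling; odd intermediate
#' lengths are padded by repeating the last sample. Returns the level-`level`
#' approximation sub-band followed by the detail sub-bands from coarsest to
#' finest, matching the layout of a conventional multi-level DWT.
#'
#' @param x Numeric sample sequence.
#' @param level Decomposition depth (>= 1); `length(x)` must be at least
#'   `2^level`.
#' @return Named list of coefficient vectors: `a<level>`, `d<level>`, ...,
#'   `d1`.
#' @export
dwt_db4 <- function(x, level = 5L) {
  level <- as.integer(level)
  if (level < 1L) stop("level must be at least 1")
  if (length(x) < 2^level) stop("signal too short for the requested level")
  details <- vector("list", level)
  cur <- as.numeric(x)
  for (l in seq_len(level)) {
    st <- dwt_step(cur)
    details[[l]] <- st$detail
    cur <- st$approx
  }
  out <- c(list(cur), rev(details))
  names(out) <- c(paste0("a", level), paste0("d", rev(seq_len(level))))
  out
}
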