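# Internal helpers shared across modules.

# FFT-based 2-D "same" convolution of matrix a with kernel k (odd sides).
# Zero-padded boundary; numerically equal to the direct double loop to ~1e-12.
conv2_same <- function(a, k) {
  na <- nrow(a); ma <- ncol(a)
  nk <- nrow(k); mk <- ncol(k)
  nr <- na + nk - 1L; nc <- ma + mk - 1L
  pa <- matrix(0, nr, nc); pa[1:na, 1:ma] <- a
  pk <- matrix(0, nr, nc); pk[1:nk, 1:mk] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / (nr * nc)
  r0 <- (nk - 1L) %/% 2L
  c0 <- (mk - 1L) %/% 2L
  full[(r0 + 1L):(r0 + na), (c0 + 1L):(c0 + ma), drop = FALSE]
}

# Circular ("wrap") convolution on the torus; kernel centred.
conv2_wrap <- function(a, k) {
  na <- nrow(a); ma <- ncol(a)
  nk <- nrow(k); mk <- ncol(k)
  pk <- matrix(0, na, ma)
  ri <- ((seq_len(nk) - 1L - (nk - 1L) %/% 2L) %% na) + 1L
  ci <- ((seq_len(mk) - 1L - (mk - 1L) %/% 2L) %% ma) + 1L
  for (u in seq_len(nk)) for (v in seq_len(mk)) {
    pk[ri[u], ci[v]] <- pk[ri[u], ci[v]] + k[u, v]
  }
  Re(stats::fft(stats::fft(a) * stats::fft(pk), inverse = TRUE)) / (na * ma)
}

# Stable 32-bit FNV-1a hash of a character string; returns integer in [0, 2^31).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

# Per-stage child seed derived from a master seed by stable hashing.
child_seed <- function(master_seed, stage) {
  as.integer((as.numeric(master_seed) * 48271 + fnv1a32(stage)) %% 2147483647)
}

month_label <- function(dates) format(as.Date(dates), "%Y-%m")

# Decimal-year time of a "YYYY-MM" month label (month start).
month_to_time <- function(month) {
  y <- as.integer(substr(month, 1, 4))
  m <- as.integer(substr(month, 6, 7))
  y + (m - 1) / 12
}

`%||%` <- function(a, b) if (is.null(a)) b else a
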