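# Independent oracles, deliberately written as direct summations / loops,
# not sharing code with the package's vectorized FFT paths.

# direct-summation DFT with the package's unitary convention:
# S_k = sum_t x_t exp(-2 pi i k t / T) / sqrt(T), signed bin k
dft_direct <- function(x) {
  n <- length(x)
  ks <- 0:(n - 1)
  ks[ks >= ceiling(n / 2)] <- ks[ks >= ceiling(n / 2)] - n
  vapply(ks, function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)) / sqrt(n),
    complex(1))
}

dft_freqs <- function(n, dt) {
  ks <- 0:(n - 1)
  ks[ks >= ceiling(n / 2)] <- ks[ks >= ceiling(n / 2)] - n
  ks / (n * dt)
}

# Eq.-style periodicity by direct DFT: paired-power peak search in band,
# single +/- bin-pair numerator, all-bin denominator
periodicity_direct <- function(x, dt, band = c(0.7, 3.0)) {
  s <- dft_direct(x)
  f <- dft_freqs(length(x), dt)
  pw <- Mod(s)^2
  pos <- which(f > 0 & f >= band[1] & f <= band[2])
  paired <- vapply(pos, function(i) {
    j <- which(abs(f + f[i]) < 1e-9)
    pw[i] + sum(pw[j])
  }, numeric(1))
  best <- pos[which.max(paired)]
  sqrt(paired[which.max(paired)] / sum(pw))
}

# brick-wall high-pass written independently (explicit bin loop)
highpass_direct <- function(x, cutoff, dt) {
  n <- length(x)
  s <- stats::fft(x)
  f <- dft_freqs(n, dt)
  for (i in seq_len(n)) if (abs(f[i]) < cutoff) s[i] <- 0i
  stats::fft(s, inverse = TRUE) / n
}

# per-voxel loop Pearson on complex samples, after filtering each voxel
pearson_loop_map <- function(slice_data, ref, va_mask, cutoff, dt,
                             mode = "modulus") {
  d <- dim(slice_data)
  out <- matrix(NA_real_, d[2], d[3])
  y <- as.complex(ref)
  yc <- y - mean(y)
  for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (va_mask[r, c] != 1L) next
    x <- highpass_direct(slice_data[, r, c], cutoff, dt)
    xc <- x - mean(x)
    den <- sqrt(sum(Mod(xc)^2) * sum(Mod(yc)^2))
    if (den == 0) { out[r, c] <- 0; next }
    rho <- sum(xc * Conj(yc)) / den
    out[r, c] <- if (mode == "modulus") Mod(rho) else Re(rho)
  }
  out
}

# Welch t and one-tailed p straight from stats::t.test (independent of the
# package's hand-coded formula)
welch_oracle <- function(a, b, direction) {
  alt <- if (direction == "greater") "greater" else "less"
  tt <- stats::t.test(a, b, alternative = alt, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

# Anderson-Darling A^2 by a naive per-term loop
ad_oracle <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + (2 * i - 1) *
      (log(stats::pnorm(z[i])) + log(1 - stats::pnorm(z[n + 1 - i])))
  }
  -n - acc / n
}
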