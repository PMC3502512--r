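# internal helpers shared across modules

# Positive-frequency bin centres for an nfft-point transform at rate fs.
# Bin j (1..nfft/2) sits at j*fs/nfft; the DC bin is never part of a spectrum.
bin_frequencies <- function(sampling_rate, nfft) {
  j <- seq_len(nfft %/% 2)
  j * sampling_rate / nfft
}

# Indices (into the positive-frequency grid) whose centres fall in [f_lo, f_hi].
band_bin_indices <- function(freqs, f_lo, f_hi) {
  which(freqs >= f_lo & freqs <= f_hi)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
# `seed` is forced before the caller's RNG state is captured, so a seed
# expression that itself draws from the RNG (e.g. sample.int) is not undone
# by the restore.
with_local_seed <- function(seed, code) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (kept within 32-bit integer range).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- rlang::hash(key)
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
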