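# Shared fixtures: small in-code datasets and training configurations.

# A tiny two-channel dataset with a hand-built structure, for I/O round-trips.
tiny_dataset <- function() {
  mts_dataset(list(
    mts_instance("a1", list(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1)), 0),
    mts_instance("a2", list(c(2, 2, 1, 3, 2), c(0, 1, 0, 1, 0)), 1),
    mts_instance("a3", list(sin(1:5), cos(1:5)), 0)
  ), name = "tiny")
}

# Separable wafer-like fixture at a reduced scale.
separable_dataset <- function(n = 60, m = 3, seed = 7) {
  generate_synthetic(synth_config(
    n_instances = n, m = m, length_range = c(104L, 198L), seed = seed))
}

# Quick training configuration for unit tests.
quick_config <- function(seed = 1L, max_epochs = 15L, patience = 4L) {
  train_config(max_epochs = max_epochs, patience = patience, seed = seed)
}

# Brute-force MTF oracle: same quantile-bin rule, transition counting and
# field lookup written as plain loops, independent of the package's
# vectorized path.
mtf_oracle <- function(x, b) {
  edges <- unname(quantile(x, probs = seq_len(b - 1) / b, names = FALSE))
  bins <- integer(length(x))
  for (i in seq_along(x)) {
    bin <- 1L
    for (e in edges) if (x[i] > e) bin <- bin + 1L
    bins[i] <- bin
  }
  counts <- matrix(0, b, b)
  for (i in seq_len(length(x) - 1))
    counts[bins[i], bins[i + 1]] <- counts[bins[i], bins[i + 1]] + 1
  W <- matrix(0, b, b)
  for (i in seq_len(b)) {
    tot <- sum(counts[i, ])
    if (tot > 0) W[i, ] <- counts[i, ] / tot
  }
  M <- matrix(0, length(x), length(x))
  for (i in seq_along(x)) for (j in seq_along(x))
    M[i, j] <- W[bins[i], bins[j]]
  M
}

# Brute-force PAA oracle: element k of the input belongs to output segment
# ceiling(k * N / T); average within segments.
paa_oracle <- function(x, N) {
  Tn <- length(x)
  seg <- ceiling(seq_len(Tn) * N / Tn)
  as.numeric(tapply(x, seg, mean))
}
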