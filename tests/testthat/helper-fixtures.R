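# Small in-code fixtures shared across tests.

# patch set of P random standardized patches (population convention over
# the pooled pixels of each channel)
random_patch_set <- function(P = 30, side = 40, K = 2, n_samples = 3,
                             seed = 1) {
  set.seed(seed)
  x <- array(rnorm(P * side * side * K), c(P, side, side, K))
  for (k in seq_len(K)) {
    v <- x[, , , k]
    x[, , , k] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  patch_set(x, sample_ids = rep(sprintf("s%d", seq_len(n_samples)),
                                length.out = P),
            anchors = cbind(rep(0L, P), rep(0L, P)),
            tissue_fraction = rep(1, P))
}

# patches drawn from a few distinct "texture" classes (block patterns)
textured_patch_set <- function(P = 60, side = 40, K = 2, n_samples = 3,
                               n_classes = 3, seed = 1) {
  set.seed(seed)
  cls <- rep(seq_len(n_classes), length.out = P)
  x <- array(0, c(P, side, side, K))
  half <- side / 2
  for (i in seq_len(P)) {
    base <- array(rnorm(side * side * K, sd = 0.3), c(side, side, K))
    if (cls[i] == 1) base[seq_len(half), , 1] <- base[seq_len(half), , 1] + 2
    if (cls[i] == 2) base[, seq_len(half), 1] <- base[, seq_len(half), 1] - 2
    if (cls[i] == 3) base[, , 2] <- base[, , 2] + 2 * sin(seq_len(side) / 3)
    x[i, , , ] <- base
  }
  ps <- patch_set(x, sample_ids = rep(sprintf("s%d", seq_len(n_samples)),
                                      length.out = P),
                  anchors = cbind(rep(0L, P), rep(0L, P)),
                  tissue_fraction = rep(1, P))
  attr(ps, "class_labels") <- cls
  ps
}

tiny_metadata <- function(sample_ids, phenotype = NULL, donors = NULL) {
  s <- sort(unique(sample_ids))
  if (is.null(donors)) donors <- s
  if (is.null(phenotype)) phenotype <- rep_len(c(0, 1), length(s))
  sample_metadata(data.frame(sample_id = s, donor_id = donors,
                             phenotype = phenotype))
}

# small random MAT with optional planted signal columns
random_mat <- function(N = 10, P = 40, E = 2, seed = 1, signal_cols = NULL,
                       y = NULL, effect = 1) {
  set.seed(seed)
  Q <- array(abs(rnorm(N * P * E)) + 0.05, c(N, P, E))
  if (!is.null(signal_cols))
    for (e in seq_len(E))
      Q[, signal_cols, e] <- Q[, signal_cols, e] + effect * y
  for (e in seq_len(E)) Q[, , e] <- Q[, , e] / rowSums(Q[, , e])
  structure(list(Q = Q, samples = sprintf("s%02d", seq_len(N)),
                 s = 1, projected = FALSE), class = "vima_mat")
}

# deterministic tiny cvae config for fast tests
tiny_cvae_config <- function(...) {
  args <- list(latent_dim = 3, epochs = 2, kl_warmup_epochs = 2,
               batch_size = 32, widths = c(2, 3, 4), conv_widths = c(3, 4),
               extend = FALSE)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cvae_config, args)
}
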