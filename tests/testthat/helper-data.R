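# Shared in-code fixtures.  Everything is generated at test time; nothing
# binary is stored on disk.

# Small simulated dataset reused across test files (computed once).
.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    cfg <- simulation_config(n_chains = 10, length_mean = 90,
                             length_sd = 20, seed = 424242)
    .fixture_env$ds <- simulate_dataset(cfg)
  }
  .fixture_env$ds
}

tiny_features <- function(window = 5L) {
  key <- paste0("feat", window)
  if (is.null(.fixture_env[[key]])) {
    ds <- tiny_dataset()
    .fixture_env[[key]] <- featurize_dataset(ds$proteins, ds$pssms,
                                             ds$structurals, window = window)
  }
  .fixture_env[[key]]
}

# A trained model on the tiny dataset (computed once; several tests reuse it).
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    feat <- tiny_features()
    keep <- feat$meta$label != "U"
    .fixture_env$model <- train_predictor(feat$x[keep, , drop = FALSE],
                                          feat$meta$label[keep],
                                          hyper_params(window = 5L),
                                          seed = 99)
  }
  .fixture_env$model
}

# Hand-written 3-residue PSI-BLAST-style ASCII PSSM fixture.
write_tiny_pssm <- function(path, scores = NULL, letters = c("M", "K", "V")) {
  if (is.null(scores))
    scores <- matrix(rep(c(1, -2, 0, 3), 15), nrow = 3, ncol = 20)
  lines <- c("",
             "Last position-specific scoring matrix computed, weighted ...",
             paste0("      ", paste(sprintf("%3s",
               c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")), collapse = " ")),
             vapply(seq_len(nrow(scores)), function(i)
               paste0(sprintf("%5d %s ", i, letters[i]),
                      paste(sprintf("%3d", scores[i, ]), collapse = " ")),
               ""),
             "", "                      K         Lambda", "")
  writeLines(lines, path)
  path
}

# Brute-force window oracle: per-row slice-and-concatenate with explicit
# zero padding, independent of the vectorized implementation.
window_oracle <- function(blocks, w) {
  L <- nrow(blocks); h <- (w - 1) / 2
  t(vapply(seq_len(L), function(t) {
    unlist(lapply((t - h):(t + h), function(p) {
      if (p < 1 || p > L) numeric(ncol(blocks)) else blocks[p, ]
    }))
  }, numeric(w * ncol(blocks))))
}

# Exhaustive pairwise-ranking AUC oracle: fraction of (disorder, order)
# pairs ranked correctly, ties counting one half.
auc_oracle <- function(truth, prob) {
  dp <- prob[truth == "D"]; op <- prob[truth == "O"]
  s <- 0
  for (d in dp) for (o in op)
    s <- s + (d > o) + 0.5 * (d == o)
  s / (length(dp) * length(op))
}

random_confusion <- function() {
  list(TP = sample(1:500, 1), TN = sample(1:500, 1),
       FP = sample(0:500, 1), FN = sample(0:500, 1))
}
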