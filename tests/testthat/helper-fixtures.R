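# Shared fixture builders; all randomness is seeded per call.

random_pssm <- function(L, seed, id = sprintf("p%03d", seed)) {
  generate_synthetic_pssm(L, base_mean = 0, noise_sd = 3, seed = seed, id = id)
}

# Brute-force LAG: enumerate each group's positions explicitly and average.
# Independent of make_partition/lag_transform internals.
brute_lag <- function(scores) {
  L <- nrow(scores)
  out <- numeric(0)
  for (g in 1:20) {
    lo <- floor((g - 1) * L / 20) + 1
    hi <- floor(g * L / 20)
    seg <- scores[lo:hi, , drop = FALSE]
    out <- c(out, apply(seg, 2, mean))
  }
  as.numeric(out)
}

# Pairwise Mann-Whitney AUC oracle (ties count one half).
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == -1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small Gaussian two-class feature set for classifier tests.
gaussian_data <- function(n_pos, n_neg, d, sep, seed) {
  withr::with_seed(seed, {
    mu <- rep(sep / sqrt(d), d)
    X <- rbind(
      matrix(rnorm(n_pos * d), n_pos, d) + rep(mu, each = n_pos),
      matrix(rnorm(n_neg * d), n_neg, d)
    )
    list(X = X, y = c(rep(1, n_pos), rep(-1, n_neg)))
  })
}

# A tiny hand-written PSI-BLAST ASCII PSSM fixture with known scores.
write_fixture_pssm_text <- function(path, break_row = NA) {
  res <- pssm_residues()
  hdr <- paste0("      ", paste(sprintf("%3s", rep(res, 2)), collapse = ""))
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    hdr
  )
  set.seed(99)
  sc <- matrix(sample(-8:11, 5 * 20, replace = TRUE), 5, 20)
  seqs <- c("M", "K", "L", "A", "V")
  for (i in 1:5) {
    row <- paste0(sprintf("%5d %s ", i, seqs[i]),
                  paste(sprintf("%4d", sc[i, ]), collapse = ""),
                  paste(sprintf("%4d", rep(0, 20)), collapse = ""),
                  "  0.36 0.09")
    if (!is.na(break_row) && i == break_row) {
      row <- sub("^(\\s*\\d+ \\w \\s*-?\\d+)", "\\1 oops", row)
    }
    lines <- c(lines, row)
  }
  lines <- c(lines, "", "                      K         Lambda")
  writeLines(lines, path)
  list(scores = sc, sequence = seqs)
}
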