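# Independent reference implementations used as oracles. These deliberately
# share no code with the package: brute-force SASA uses randomly sampled
# sphere directions and all-against-all neighbour checks.

# Monte Carlo Shrake-Rupley reference: n_points random directions per atom,
# no binning, no early exit.
brute_force_sasa <- function(xyz, radii, probe = 1.4, n_points = 1e5,
                             seed = 42) {
  set.seed(seed)
  n <- nrow(xyz)
  rexp <- radii + probe
  vapply(seq_len(n), function(i) {
    v <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * rexp[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & (d2 >= rexp[j]^2)
    }
    mean(exposed) * 4 * pi * rexp[i]^2
  }, double(1))
}

# hand-formula Welch statistic, Welch-Satterthwaite df, two-sided p
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# simple two-atom model builder for SASA tests
pair_model <- function(distance, element = "C") {
  make_sphere_fixture("pair", distance = distance, element = element)
}

# write a small FASTA file and return its path
write_fasta_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
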