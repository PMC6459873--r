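options(hdxstat.log_level = "none")

# Small deterministic protein and peptide map used across unit tests.
toy_protein <- function() {
  protein_context(paste0(
    "MSTAVKELGH", "QWERTYIPAS", "DFGHKLMNVC", "WYTREWQASD"), name = "toy")
}

toy_peptides <- function(protein = toy_protein()) {
  df <- data.frame(start = c(1, 5, 11, 21), end = c(10, 20, 20, 32))
  df$sequence <- substring(protein$sequence, df$start, df$end)
  peptide_records(df, protein)
}

# Exhaustive Poisson-binomial oracle: enumerate all 2^N outcomes.
pb_enumerate <- function(probs) {
  n <- length(probs)
  dist <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[seq_len(n)])
    p <- prod(ifelse(bits == 1, probs, 1 - probs))
    dist[sum(bits) + 1] <- dist[sum(bits) + 1] + p
  }
  dist
}

# Fixed-point oracle for depletion binding: iterate free-ligand balance.
occupancy_fixed_point <- function(l_total, kd, r_total, tol = 1e-12) {
  b <- 0
  for (i in 1:10000) {
    b_new <- r_total * (l_total - b) / (kd + (l_total - b))
    if (abs(b_new - b) < tol) break
    b <- b_new
  }
  b / r_total
}

# Minimal in-memory uptake table written to a temp CSV.
write_toy_uptake_csv <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
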