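# Small fixture networks built in code.

# Linear chain of n residues, neighbouring exchange time `tau`.
chain_tau <- function(n, tau = 1, labels = paste0("A", seq_len(n))) {
  tm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) tm[i, i + 1] <- tm[i + 1, i] <- tau
  tau_matrix(tm, labels = labels)
}

# Exactly block-diagonal network: unit exchange time inside each block,
# no exchange between blocks.
block_diag_tau <- function(sizes, tau = 1) {
  n <- sum(sizes)
  b <- rep(seq_along(sizes), sizes)
  tm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (b[i] == b[j]) tm[i, j] <- tm[j, i] <- tau
    }
  }
  tau_matrix(tm, labels = paste0("A", seq_len(n)))
}

# Fully connected random symmetric network.
random_tau <- function(n, seed, rate_range = c(0.2, 2)) {
  set.seed(seed)
  tm <- matrix(NA_real_, n, n)
  m <- n * (n - 1) / 2
  tm[upper.tri(tm)] <- 1 / runif(m, rate_range[1], rate_range[2])
  tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
  tau_matrix(tm, labels = paste0("R", seq_len(n)))
}

# Hand-built generator (possibly asymmetric) for committor tests.
make_generator <- function(Lm, labels = paste0("R", seq_len(nrow(Lm)))) {
  diag(Lm) <- 0
  diag(Lm) <- -rowSums(Lm)
  dimnames(Lm) <- list(labels, labels)
  structure(list(labels = labels, L = Lm, unit = "1/arb"),
            class = "generator_matrix")
}

# Net-flux divergence at intermediate residues.
net_divergence <- function(f_net, iA, iB) {
  iC <- setdiff(seq_len(nrow(f_net)), c(iA, iB))
  rowSums(f_net[iC, , drop = FALSE]) - colSums(f_net[, iC, drop = FALSE])
}

# The 3-residue worked chain: A - M - B with unit exchange times.
worked_chain <- function() {
  tau <- chain_tau(3, labels = c("A1", "M2", "B3"))
  build_generator(tau)
}
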