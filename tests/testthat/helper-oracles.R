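# Independent oracles and small fixture builders shared across tests.

# Independent complex-arithmetic evaluation of the four-block circuit:
# written directly from the circuit topology, element by element, without
# going through pair_impedance().
oracle_pair_magnitude <- function(circuit, f) {
  blk <- function(b) b$Rs + b$Rp / (1 + 1i * 2 * pi * f * b$Rp * b$Cp)
  za <- blk(circuit$z1)
  zb <- blk(circuit$z2)
  zc <- blk(circuit$z3)
  zd <- blk(circuit$z4)
  par <- 1 / (1 / zb + 1 / zc)
  Mod(za + par + zd)
}

random_block <- function() {
  z_block(Rs = runif(1, 100, 1000), Rp = runif(1, 100, 10000),
          Cp = runif(1, 1e-9, 100e-9))
}

random_circuit <- function() {
  pair_circuit(random_block(), random_block(), random_block(), random_block())
}

fixture_circuit <- function() {
  pair_circuit(z1 = z_block(300, 2000, 20e-9),
               z2 = z_block(400, 2000, 20e-9),
               z3 = z_block(1000, 10000, 5e-9),
               z4 = z_block(320, 2200, 18e-9))
}

# Brute-force ROC: explicit loops over every candidate threshold; EER by the
# same bracketing/interpolation definition, AUC by the Wilcoxon pairwise
# statistic (equals the trapezoid over the score-sweep ROC).
oracle_roc <- function(genuine, impostor) {
  th <- c(-Inf, sort(unique(c(genuine, impostor))), Inf)
  far <- numeric(length(th))
  frr <- numeric(length(th))
  for (i in seq_along(th)) {
    far[i] <- sum(impostor >= th[i]) / length(impostor)
    frr[i] <- sum(genuine < th[i]) / length(genuine)
  }
  i <- which(frr >= far)[1]
  d1 <- far[i - 1] - frr[i - 1]
  d2 <- far[i] - frr[i]
  lam <- if (d1 == d2) 0 else d1 / (d1 - d2)
  eer <- far[i - 1] + lam * (far[i] - far[i - 1])
  gt <- eq <- 0
  for (g in genuine) {
    gt <- gt + sum(g > impostor)
    eq <- eq + sum(g == impostor)
  }
  auc <- (gt + eq / 2) / (length(genuine) * length(impostor))
  list(eer_pct = 100 * eer, auc = auc)
}

# a small record matrix (10 pairs x n_freq) with all-positive magnitudes
toy_record <- function(n_freq = 25, seed = 42) {
  set.seed(seed)
  fp <- finger_pairs()
  m <- matrix(exp(rnorm(nrow(fp) * n_freq, log(500), 0.3)),
              nrow(fp), n_freq,
              dimnames = list(fp$label, NULL))
  m
}

small_dataset <- function(...) {
  args <- list(n_subjects = 4, n_sessions = 3, n_repeats = 3, seed = 7)
  args[names(list(...))] <- list(...)
  do.call(generate_dataset, args)
}
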