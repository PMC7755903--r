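# Independent oracles used by the tests (kept deliberately naive).

# Exhaustive isotopologue enumeration for a small molecular formula:
# loops over every heavy-isotope count combination and accumulates
# probability by total integer mass offset.  Independent of the package's
# convolution machinery.
enumerate_envelope <- function(nC, nH, nN, nO, nS = 0) {
  pC <- c(0.9893, 0.0107)
  pH <- c(0.999885, 0.000115)
  pN <- c(0.99636, 0.00364)
  pO <- c(0.99757, 0.00038, 0.00205)
  pS <- c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  acc <- numeric(nC + nH + nN + 2 * nO + 4 * nS + 1)
  for (c13 in 0:nC) for (h2 in 0:nH) for (n15 in 0:nN) {
    for (o17 in 0:nO) for (o18 in 0:(nO - o17)) {
      s_states <- if (nS > 0) {
        as.matrix(expand.grid(s33 = 0:nS, s34 = 0:nS, s36 = 0:nS))
      } else matrix(0, 1, 3)
      for (r in seq_len(nrow(s_states))) {
        s33 <- s_states[r, 1]; s34 <- s_states[r, 2]; s36 <- s_states[r, 3]
        if (s33 + s34 + s36 > nS) next
        off <- c13 + h2 + n15 + o17 + 2 * o18 + s33 + 2 * s34 + 4 * s36
        pr <- dbinom(c13, nC, pC[2]) * dbinom(h2, nH, pH[2]) *
          dbinom(n15, nN, pN[2]) *
          dmultinom(c(nO - o17 - o18, o17, o18), prob = pO) *
          (if (nS > 0) dmultinom(c(nS - s33 - s34 - s36, s33, s34, s36),
                                 prob = pS[c(1, 2, 3, 5)]) else 1)
        acc[off + 1] <- acc[off + 1] + pr
      }
    }
  }
  acc
}

# Random rigid motion of an n x 3 coordinate matrix (proper rotation).
rigid_motion <- function(X, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- rnorm(3, sd = 10)
  sweep(X %*% R, 2, t_vec, "+")
}

# Apply a rigid motion to every atom of a structure model.
transform_model <- function(model, seed = 1) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz2 <- rigid_motion(xyz, seed)
  model$atoms$x <- xyz2[, 1]
  model$atoms$y <- xyz2[, 2]
  model$atoms$z <- xyz2[, 3]
  model
}
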