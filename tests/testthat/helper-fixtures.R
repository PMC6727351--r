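# Fixture builders shared across test files.  All randomness is seeded by the
# caller so tests stay deterministic.

# Noiseless separable instance: K cell types, each with `m_per` exclusive
# markers (value `hi` in the own type, `lo` elsewhere), proportions drawn on
# the simplex.  Returns the pieces needed to check recovery.
make_separable <- function(k = 4, m_per = 15, n = 30, hi = 10, lo = 0.1,
                           seed = 1) {
  set.seed(seed)
  m <- k * m_per
  w <- matrix(lo, m, k)
  for (j in seq_len(k)) w[((j - 1) * m_per + 1):(j * m_per), j] <- hi
  g <- matrix(rgamma(k * n, 1), k, n)
  h <- sweep(g, 2, colSums(g), "/")
  y <- w %*% h
  rownames(y) <- rownames(w) <- paste0("g", seq_len(m))
  colnames(w) <- rownames(h) <- paste0("C", seq_len(k))
  colnames(y) <- colnames(h) <- paste0("s", seq_len(n))
  list(y = y, w = w, h = h)
}

# Independent simplex-constrained least-squares oracle (quadratic program
# solved by pracma); used to cross-check the package's active-set solver.
simplex_ls_oracle <- function(w, y) {
  k <- ncol(w)
  pracma::lsqlincon(w, as.vector(y), Aeq = matrix(1, 1, k), beq = 1,
                    lb = rep(0, k))
}

# Build a minimal "crosscell_diff" object from explicit p-value / estimate
# matrices, for testing marker selection in isolation.
fake_diff <- function(p_mat, est_mat = NULL) {
  if (is.null(est_mat)) est_mat <- matrix(1, nrow(p_mat), ncol(p_mat),
                                          dimnames = dimnames(p_mat))
  structure(list(estimate = est_mat, se = est_mat * 0 + 1,
                 statistic = est_mat, p_value = p_mat, fit = NULL),
            class = "crosscell_diff")
}
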