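# Independent brute-force oracles: direct, scalar-loop evaluation of the
# displayed definitions of Abar, H, S, GC, DTF^2 and PDC for fixed
# coefficient sets.  Deliberately naive (no vectorization, explicit
# elementwise sums) so they share no code path with the package.

oracle_abar <- function(A_list, f, fs) {
  n <- nrow(A_list[[1]])
  Ab <- matrix(0i, n, n)
  w <- 2 * pi * f / fs
  for (i in 1:n) for (j in 1:n) {
    s <- if (i == j) 1 + 0i else 0 + 0i
    for (k in seq_along(A_list)) {
      s <- s - A_list[[k]][i, j] * exp(-1i * k * w)
    }
    Ab[i, j] <- s
  }
  Ab
}

oracle_H <- function(A_list, f, fs) solve(oracle_abar(A_list, f, fs))

oracle_S <- function(A_list, C, f, fs) {
  H <- oracle_H(A_list, f, fs)
  H %*% C %*% Conj(t(H))
}

# Geweke pairwise spectral GC from the full model: source s, target t.
oracle_gc_pair <- function(A_list, C, f, fs, s, t) {
  H <- oracle_H(A_list, f, fs)
  S <- oracle_S(A_list, C, f, fs)
  gamma <- C[s, s] - C[t, s]^2 / C[t, t]
  Stt <- Re(S[t, t])
  denom <- Stt - gamma * Mod(H[t, s])^2
  max(0, log(Stt / denom))
}

oracle_dtf2_pair <- function(A_list, f, fs, s, t) {
  H <- oracle_H(A_list, f, fs)
  num <- Mod(H[t, s])^2
  den <- 0
  for (m in seq_len(nrow(H))) den <- den + Mod(H[t, m])^2
  num / den
}

oracle_pdc_pair <- function(A_list, f, fs, s, t) {
  Ab <- oracle_abar(A_list, f, fs)
  den <- 0
  for (i in seq_len(nrow(Ab))) den <- den + Mod(Ab[i, s])^2
  Mod(Ab[t, s]) / sqrt(den)
}

# Fixed 2- and 3-channel coefficient sets used by the oracle-equivalence
# tests.  fix2 has a non-diagonal residual covariance to exercise the
# instantaneous-correlation handling in GC; fix3 is the 1 -> 2 -> 3 chain.
fix2_model <- function() {
  A1 <- matrix(c(0.5, 0.4, 0, 0.3), 2, 2)       # A1[2,1] = 0.4: 1 -> 2
  A2 <- matrix(c(-0.2, 0.1, 0, 0.2), 2, 2)
  C <- matrix(c(1, 0.2, 0.2, 1.5), 2, 2)
  list(A_list = list(A1, A2), C = C, fs = 250)
}

fix3_chain_model <- function() {
  A1 <- diag(c(0.5, 0.4, 0.3))
  A1[2, 1] <- 0.4                               # 1 -> 2
  A1[3, 2] <- 0.35                              # 2 -> 3
  list(A_list = list(A1), C = diag(3), fs = 250)
}

# Wrap a plain coefficient list as the package's model container.
as_mvar <- function(fix, labels = NULL) {
  n <- nrow(fix$A_list[[1]])
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  A <- array(0, dim = c(n, n, length(fix$A_list)),
             dimnames = list(labels, labels, NULL))
  for (k in seq_along(fix$A_list)) A[, , k] <- fix$A_list[[k]]
  C <- fix$C
  dimnames(C) <- list(labels, labels)
  mvarconn:::new_mvar_model(length(fix$A_list), A, C, fix$fs,
                            NA_integer_, labels, stable = TRUE)
}
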