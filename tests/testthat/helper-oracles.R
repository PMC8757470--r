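# Brute-force second-quantization oracles, independent of the package's
# Slater-Condon / phase machinery.  Determinants are bit-mask pairs; spin
# orbitals 1..n alpha then n+1..2n beta; kets are ordered products of
# creation operators in ascending spin-orbital order.

orc_occ_test <- function(am, bm, q, n) {
  if (q <= n) bitwAnd(am, as.integer(2^(q - 1))) != 0
  else bitwAnd(bm, as.integer(2^(q - n - 1))) != 0
}

orc_occ_before <- function(am, bm, q, n) {
  occ <- c(which(bitwAnd(rep(am, n), 2^(0:(n - 1))) != 0),
           which(bitwAnd(rep(bm, n), 2^(0:(n - 1))) != 0) + n)
  sum(occ < q)
}

orc_ann <- function(am, bm, q, n) {
  if (!orc_occ_test(am, bm, q, n)) return(NULL)
  s <- (-1)^orc_occ_before(am, bm, q, n)
  if (q <= n) am <- am - as.integer(2^(q - 1)) else bm <- bm - as.integer(2^(q - n - 1))
  list(am = am, bm = bm, s = s)
}

orc_cre <- function(am, bm, q, n) {
  if (orc_occ_test(am, bm, q, n)) return(NULL)
  s <- (-1)^orc_occ_before(am, bm, q, n)
  if (q <= n) am <- am + as.integer(2^(q - 1)) else bm <- bm + as.integer(2^(q - n - 1))
  list(am = am, bm = bm, s = s)
}

# full Hamiltonian matrix over a basis by operator algebra:
# H = sum h_pq a+_p a_q (spin-summed) + 1/2 sum (pq|rs) a+_p a+_r a_s a_q
oracle_hamiltonian <- function(basis, ints) {
  n <- basis$n_orb
  nso <- 2L * n
  nb <- length(basis$alpha)
  keyix <- new.env(parent = emptyenv())
  for (i in seq_len(nb))
    assign(as.character(basis$alpha[i] * 65536 + basis$beta[i]), i, keyix)
  H <- matrix(0, nb, nb)
  hso <- function(p, q) {
    if ((p <= n) != (q <= n)) return(0)
    ints$h[ifelse(p > n, p - n, p), ifelse(q > n, q - n, q)]
  }
  gso <- function(p, q, r, s) {
    if ((p <= n) != (q <= n) || (r <= n) != (s <= n)) return(0)
    o <- function(x) ifelse(x > n, x - n, x)
    ints$g[o(p), o(q), o(r), o(s)]
  }
  for (i in seq_len(nb)) {
    am0 <- as.integer(basis$alpha[i]); bm0 <- as.integer(basis$beta[i])
    H[i, i] <- H[i, i] + ints$core_energy
    for (q in 1:nso) {
      s1 <- orc_ann(am0, bm0, q, n); if (is.null(s1)) next
      for (p in 1:nso) {
        hpq <- hso(p, q)
        if (hpq != 0) {
          c1 <- orc_cre(s1$am, s1$bm, p, n)
          if (!is.null(c1)) {
            j <- get0(as.character(c1$am * 65536 + c1$bm), keyix)
            if (!is.null(j)) H[j, i] <- H[j, i] + hpq * s1$s * c1$s
          }
        }
      }
      for (s in 1:nso) {
        s2 <- orc_ann(s1$am, s1$bm, s, n); if (is.null(s2)) next
        for (r in 1:nso) {
          c2 <- orc_cre(s2$am, s2$bm, r, n); if (is.null(c2)) next
          for (p in 1:nso) {
            gv <- gso(p, q, r, s)
            if (gv == 0) next
            c1 <- orc_cre(c2$am, c2$bm, p, n); if (is.null(c1)) next
            j <- get0(as.character(c1$am * 65536 + c1$bm), keyix)
            if (!is.null(j))
              H[j, i] <- H[j, i] + 0.5 * gv * s1$s * s2$s * c2$s * c1$s
          }
        }
      }
    }
  }
  H
}

# S^2 matrix over a basis by operator application:
# S^2 = Sz(Sz+1) + S- S+,  S+ = sum_p a+_pa a_pb
oracle_s2_matrix <- function(basis) {
  n <- basis$n_orb
  nb <- length(basis$alpha)
  keyix <- new.env(parent = emptyenv())
  for (i in seq_len(nb))
    assign(as.character(basis$alpha[i] * 65536 + basis$beta[i]), i, keyix)
  S2 <- matrix(0, nb, nb)
  pc <- function(m) sum(bitwAnd(rep(as.integer(m), 16), 2^(0:15)) != 0)
  for (i in seq_len(nb)) {
    am0 <- as.integer(basis$alpha[i]); bm0 <- as.integer(basis$beta[i])
    ms <- (pc(am0) - pc(bm0)) / 2
    S2[i, i] <- S2[i, i] + ms * (ms + 1)
    # S- S+ applied as operators
    for (p in 1:n) {
      a1 <- orc_ann(am0, bm0, p + n, n); if (is.null(a1)) next
      c1 <- orc_cre(a1$am, a1$bm, p, n); if (is.null(c1)) next
      for (q in 1:n) {
        a2 <- orc_ann(c1$am, c1$bm, q, n); if (is.null(a2)) next
        c2 <- orc_cre(a2$am, a2$bm, q + n, n); if (is.null(c2)) next
        j <- get0(as.character(c2$am * 65536 + c2$bm), keyix)
        if (!is.null(j))
          S2[j, i] <- S2[j, i] + a1$s * c1$s * a2$s * c2$s
      }
    }
  }
  S2
}

# unconstrained (CAS) supergroup table over a single space
cas_table <- function(n_orb, nelec) {
  p <- gas_partition(n_orb)
  build_supergroup_table(p, gas_local(0, 2 * n_orb), nelec)
}
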