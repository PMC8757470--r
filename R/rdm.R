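# Reduced density matrices.
#
# Spin-resolved storage: gamma^alpha, gamma^beta (n x n) and three 2-RDM
# blocks in chemists' pair ordering,
#   Gaa[p,q,r,s] = <a+_pa a+_ra a_sa a_qa>,  Gbb likewise for beta,
#   Gab[p,q,r,s] = <a+_pa a+_rb a_sb a_qa>,
# so that E = E_core + sum h*gamma + 1/2 sum (pq|rs) Gamma.  Exact RDMs are
# contracted from an eigenvector; stochastic RDMs accumulate diagonal
# contributions from walker populations and off-diagonal contributions from
# spawn events reweighted by 1/p_gen.

rdm_acc_new <- function(n) {
  e <- new.env(parent = emptyenv())
  e$n <- n
  e$ga <- matrix(0, n, n); e$gb <- matrix(0, n, n)
  e$Gaa <- array(0, rep(n, 4)); e$Gbb <- array(0, rep(n, 4))
  e$Gab <- array(0, rep(n, 4))
  e$norm <- 0
  e$iters <- 0L
  e
}

# scatter-add with duplicate indices
acc_add <- function(arr, idx, val) {
  agg <- rowsum(val, group = idx)
  pos <- as.numeric(rownames(agg))
  arr[pos] <- arr[pos] + agg[, 1]
  arr
}

# push <a+_p a+_r a_s a_q> += v entries given spin-orbital indices; all
# vectors.  Every call site supplies patterns in swap-symmetric twin pairs
# ((p,q,r,s) together with (r,s,p,q)), so only three routings are stored:
# alpha-alpha, beta-beta, and the alpha-pair-first mixed block.  The
# beta-pair-first twin carries the same value as its stored alpha-first twin
# and is dropped, as are mixed-spin pair slots (redundant images under
# antisymmetry).
rdm_push2 <- function(acc, p, q, r, s, v, n) {
  sp <- function(x) x <= n
  pa <- sp(p); ra <- sp(r)
  keep <- (pa == sp(q)) & (ra == sp(s)) & !(!pa & ra)
  if (!all(keep)) {
    p <- p[keep]; q <- q[keep]; r <- r[keep]; s <- s[keep]; v <- v[keep]
    pa <- pa[keep]; ra <- ra[keep]
    if (length(p) == 0) return(invisible(acc))
  }
  o <- function(x) ifelse(x > n, x - n, x)
  lin <- function(p0, q0, r0, s0) {
    p0 + n * (q0 - 1) + n^2 * (r0 - 1) + n^3 * (s0 - 1)
  }
  aa <- pa & ra; bb <- !pa & !ra; ab <- pa & !ra
  if (any(aa)) acc$Gaa <- acc_add(acc$Gaa, lin(o(p[aa]), o(q[aa]), o(r[aa]), o(s[aa])), v[aa])
  if (any(bb)) acc$Gbb <- acc_add(acc$Gbb, lin(o(p[bb]), o(q[bb]), o(r[bb]), o(s[bb])), v[bb])
  if (any(ab)) acc$Gab <- acc_add(acc$Gab, lin(o(p[ab]), o(q[ab]), o(r[ab]), o(s[ab])), v[ab])
  invisible(acc)
}

rdm_push1 <- function(acc, p, q, v, n) {
  a <- p <= n
  o <- function(x) ifelse(x > n, x - n, x)
  if (any(a)) acc$ga <- acc_add(acc$ga, o(p[a]) + n * (o(q[a]) - 1), v[a])
  if (any(!a)) acc$gb <- acc_add(acc$gb, o(p[!a]) + n * (o(q[!a]) - 1), v[!a])
  invisible(acc)
}

# diagonal (same-determinant) contributions with weights w per row of occm
rdm_push_diag <- function(acc, occm, w, n) {
  nel <- ncol(occm)
  m <- nrow(occm)
  p1 <- as.vector(occm)
  rdm_push1(acc, p1, p1, rep(w, nel), n)
  if (nel > 1) {
    tpl <- which(outer(seq_len(nel), seq_len(nel), `!=`), arr.ind = TRUE)
    p <- as.vector(occm[, tpl[, 1]])
    q <- as.vector(occm[, tpl[, 2]])
    ww <- rep(w, nrow(tpl))
    rdm_push2(acc, p, p, q, q, ww, n)          # Coulomb-like
    same <- (p <= n) == (q <= n)
    if (any(same))
      rdm_push2(acc, p[same], q[same], q[same], p[same], -ww[same], n)
  }
  invisible(acc)
}

# one iteration of stochastic accumulation: populations -> diagonal,
# proposal events -> off-diagonal (weight pop_parent_sign * pop_child / pgen)
rdm_accumulate <- function(acc, store, events, n) {
  occupied <- store$pop != 0
  if (any(occupied)) {
    w <- store$pop[occupied]^2
    rdm_push_diag(acc, store$occm[occupied, , drop = FALSE], w, n)
    acc$norm <- acc$norm + sum(w)
  }
  vi <- which(events$valid)
  if (length(vi) > 0) {
    ck <- det_key(events$child_a[vi], events$child_b[vi])
    pos <- match(ck, store$key)
    wch <- ifelse(is.na(pos), 0, store$pop[pos])
    w <- sign(store$pop[events$parent[vi]]) * wch / events$pgen[vi]
    keep <- w != 0
    vi <- vi[keep]; w <- w[keep]
    if (length(vi) > 0) {
      ph <- events$phase[vi]
      dbl <- events$kind[vi] == 1L
      if (any(dbl)) {
        I <- events$I[vi][dbl]; J <- events$J[vi][dbl]
        A <- events$A[vi][dbl]; B <- events$B[vi][dbl]
        v <- (w * ph)[dbl]
        rdm_push2(acc, c(A, B), c(I, J), c(B, A), c(J, I), c(v, v), n)
        rdm_push2(acc, c(A, B), c(J, I), c(B, A), c(I, J), -c(v, v), n)
      }
      sgl <- !dbl
      if (any(sgl)) {
        I <- events$I[vi][sgl]; A <- events$A[vi][sgl]
        v <- (w * ph)[sgl]
        rdm_push1(acc, A, I, v, n)
        occm <- store$occm[events$parent[vi][sgl], , drop = FALSE]
        nel <- ncol(occm)
        for (e in seq_len(nel)) {
          P <- occm[, e]
          k2 <- P != I
          if (!any(k2)) next
          Pp <- P[k2]; Ip <- I[k2]; Ap <- A[k2]; vp <- v[k2]
          rdm_push2(acc, c(Ap, Pp), c(Ip, Pp), c(Pp, Ap), c(Pp, Ip),
                    c(vp, vp), n)
          same <- (Pp <= n) == (Ip <= n)
          if (any(same))
            rdm_push2(acc, c(Ap[same], Pp[same]), c(Pp[same], Ip[same]),
                      c(Pp[same], Ap[same]), c(Ip[same], Pp[same]),
                      -c(vp[same], vp[same]), n)
        }
      }
    }
  }
  acc$iters <- acc$iters + 1L
  acc
}

rdm_finalize <- function(acc, n_alpha, n_beta) {
  n <- acc$n
  tr <- sum(diag(acc$ga)) + sum(diag(acc$gb))
  if (tr <= 0) stop("rdm_finalize: empty accumulator")
  f <- (n_alpha + n_beta) / tr
  ga <- acc$ga * f; gb <- acc$gb * f
  Gaa <- acc$Gaa * f; Gbb <- acc$Gbb * f; Gab <- acc$Gab * f
  # hermitian / pair-swap symmetrization
  ga <- (ga + t(ga)) / 2; gb <- (gb + t(gb)) / 2
  herm <- function(G) (G + aperm(G, c(2, 1, 4, 3))) / 2
  Gaa <- herm(Gaa); Gbb <- herm(Gbb); Gab <- herm(Gab)
  Gaa <- (Gaa + aperm(Gaa, c(3, 4, 1, 2))) / 2
  Gbb <- (Gbb + aperm(Gbb, c(3, 4, 1, 2))) / 2
  structure(list(gamma_a = ga, gamma_b = gb, Gaa = Gaa, Gbb = Gbb, Gab = Gab,
                 n_alpha = n_alpha, n_beta = n_beta, n_orb = n),
            class = "rdm_set")
}

#' @export
print.rdm_set <- function(x, ...) {
  cat("RDM set over", x$n_orb, "orbitals; tr(gamma) =",
      format(sum(diag(x$gamma_a)) + sum(diag(x$gamma_b)), digits = 8), "\n")
  invisible(x)
}

# excitation descriptor between two determinants (level <= 2 assumed checked)
excitation_info <- function(ai, bi, aj, bj, n) {
  xa <- bitwXor(ai, aj); xb <- bitwXor(bi, bj)
  rem <- c(mask_orbs(bitwAnd(xa, ai)), mask_orbs(bitwAnd(xb, bi)) + n)
  add <- c(mask_orbs(bitwAnd(xa, aj)), mask_orbs(bitwAnd(xb, bj)) + n)
  lev <- length(rem)
  if (lev == 1L) {
    ph <- (-1)^n_between(ai, bi, rem, add, n)
    return(list(level = 1L, I = rem, A = add, phase = ph))
  }
  I <- min(rem); J <- max(rem); A <- min(add); B <- max(add)
  ph1 <- n_between(ai, bi, I, A, n)
  lo <- min(J, B); hi <- max(J, B)
  adj <- as.integer(I > lo && I < hi) - as.integer(A > lo && A < hi)
  ph2 <- n_between(ai, bi, J, B, n) - adj
  list(level = 2L, I = I, J = J, A = A, B = B, phase = (-1)^(ph1 + ph2))
}

#' Exact reduced density matrices from an eigenvector
#'
#' Direct contraction of an exact-diagonalization solution with the one- and
#' two-body excitation operators over its determinant basis.
#'
#' @param solution An [exact_diagonalization()] result.
#' @param basis Basis override (defaults to `solution$basis`).
#' @return An `rdm_set`: spin-resolved `gamma_a`, `gamma_b` and 2-RDM blocks
#'   `Gaa`, `Gbb`, `Gab` (chemists' pair ordering).
#' @export
exact_rdms <- function(solution, basis = solution$basis) {
  n <- basis$n_orb
  nb <- length(basis$alpha)
  cf <- solution$coefficients
  acc <- rdm_acc_new(n)
  ai <- as.integer(basis$alpha); bi <- as.integer(basis$beta)
  pc <- popcnt16()
  occm <- t(vapply(seq_len(nb), function(i) det_occ_so(basis_det(basis, i)),
                   integer(pc[ai[1] + 1L] + pc[bi[1] + 1L])))
  rdm_push_diag(acc, occm, cf^2, n)
  for (i in seq_len(nb)) {
    lev <- (pc[bitwXor(ai[i], ai) + 1L] + pc[bitwXor(bi[i], bi) + 1L]) / 2
    cand <- which(lev >= 1 & lev <= 2)
    for (j in cand) {
      w <- cf[i] * cf[j]
      if (w == 0) next
      info <- excitation_info(ai[i], bi[i], ai[j], bi[j], n)
      v <- w * info$phase
      if (info$level == 1L) {
        I <- info$I; A <- info$A
        rdm_push1(acc, A, I, v, n)
        P <- setdiff(occm[i, ], I)
        vv <- rep(v, length(P))
        rdm_push2(acc, c(rep(A, length(P)), P), c(rep(I, length(P)), P),
                  c(P, rep(A, length(P))), c(P, rep(I, length(P))),
                  c(vv, vv), n)
        same <- (P <= n) == (I <= n)
        if (any(same)) {
          Ps <- P[same]; vs <- rep(v, length(Ps))
          rdm_push2(acc, c(rep(A, length(Ps)), Ps), c(Ps, rep(I, length(Ps))),
                    c(Ps, rep(A, length(Ps))), c(rep(I, length(Ps)), Ps),
                    -c(vs, vs), n)
        }
      } else {
        I <- info$I; J <- info$J; A <- info$A; B <- info$B
        rdm_push2(acc, c(A, B), c(I, J), c(B, A), c(J, I), c(v, v), n)
        rdm_push2(acc, c(A, B), c(J, I), c(B, A), c(I, J), -c(v, v), n)
      }
    }
  }
  acc$norm <- sum(cf^2)
  n_alpha <- pc[ai[1] + 1L]; n_beta <- pc[bi[1] + 1L]
  rdm_finalize(acc, n_alpha, n_beta)
}

#' Stochastically sampled reduced density matrices
#'
#' Normalizes and symmetrizes the RDM accumulator of a dynamics run
#' performed with `rdm_sample = TRUE`: diagonal contributions come from
#' squared walker populations, off-diagonal contributions from spawn events
#' reweighted by `1/p_gen`; the trace of the 1-RDM is normalized to the
#' electron count exactly.  GAS-forbidden blocks receive no contributions by
#' construction.
#'
#' @param run An [fciqmc()] result with an RDM accumulator.
#' @return An `rdm_set`.
#' @export
sampled_rdms <- function(run) {
  acc <- run$rdm_acc
  if (is.null(acc) || acc$iters < 2)
    stop("sampled_rdms: run has no (or too short an) RDM sampling window")
  ref <- det_from_masks(key_alpha(run$store$ref_key),
                        key_beta(run$store$ref_key), run$store$n_orb)
  rdm_finalize(acc, det_n_alpha(ref), det_n_beta(ref))
}

#' Energy from integrals and RDMs
#'
#' `E = E_core + sum(h * gamma) + 1/2 sum((pq|rs) * Gamma)`.
#'
#' @param rdms An `rdm_set`.
#' @param ints An [integral_table()].
#' @return The total energy.
#' @export
rdm_energy <- function(rdms, ints) {
  e1 <- sum(ints$h * (rdms$gamma_a + rdms$gamma_b))
  Gba <- aperm(rdms$Gab, c(3, 4, 1, 2))
  e2 <- 0.5 * sum(ints$g * (rdms$Gaa + rdms$Gbb + rdms$Gab + Gba))
  ints$core_energy + e1 + e2
}

#' Spin expectation value from RDMs
#'
#' `<S^2> = m_s (m_s + 1) + N_beta - sum_pq Gab[p,q,q,p]` (the spin-flip
#' exchange contraction), and the inferred spin quantum number
#' `s = (-1 + sqrt(1 + 4 <S^2>)) / 2`.
#'
#' @param rdms An `rdm_set`.
#' @param sector Optional list with `n_alpha`, `n_beta` (defaults to the
#'   values stored in the RDM set).
#' @return A list: `S2`, `s`, and `flagged` (`TRUE` when `<S^2>` fell below
#'   the `m_s (m_s + 1)` bound beyond tolerance, indicating noise).
#' @export
spin_expectation <- function(rdms, sector = NULL) {
  na <- if (is.null(sector)) rdms$n_alpha else sector$n_alpha
  nb <- if (is.null(sector)) rdms$n_beta else sector$n_beta
  ms <- (na - nb) / 2
  n <- rdms$n_orb
  idx <- expand.grid(p = seq_len(n), q = seq_len(n))
  flips <- sum(rdms$Gab[cbind(idx$p, idx$q, idx$q, idx$p)])
  S2 <- ms * (ms + 1) + nb - flips
  flagged <- S2 < ms * (ms + 1) - 1e-8
  s <- (-1 + sqrt(max(1 + 4 * S2, 0))) / 2
  list(S2 = S2, s = s, flagged = flagged)
}

#' Pseudonatural orbitals of a GAS wave function
#'
#' Block-diagonalizes the spin-summed 1-RDM, one block per GAS subspace.
#' For disconnected spaces the 1-RDM is block diagonal, so pseudonatural and
#' natural orbitals coincide.
#'
#' @param one_rdm An `rdm_set`, or the spin-summed 1-RDM matrix.
#' @param partition A [gas_partition()].
#' @return A list: `rotation` (block-diagonal orthogonal matrix, columns are
#'   pseudonatural orbitals) and `occupations` (list of per-space occupation
#'   numbers, decreasing within each space).
#' @export
pseudonatural_orbitals <- function(one_rdm, partition) {
  g <- if (inherits(one_rdm, "rdm_set")) one_rdm$gamma_a + one_rdm$gamma_b
       else one_rdm
  stopifnot(nrow(g) == partition$n_orb)
  U <- matrix(0, partition$n_orb, partition$n_orb)
  occs <- vector("list", partition$k)
  for (i in seq_len(partition$k)) {
    orbs <- which(partition$orbital_space == i)
    es <- eigen((g[orbs, orbs, drop = FALSE] +
                 t(g[orbs, orbs, drop = FALSE])) / 2, symmetric = TRUE)
    U[orbs, orbs] <- es$vectors
    occs[[i]] <- es$values
  }
  list(rotation = U, occupations = occs)
}
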