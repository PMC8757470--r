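# Slater-Condon matrix elements.
#
# Fermionic phases follow the fixed spin-orbital ordering (alpha block then
# beta block, ascending spatial index): a single excitation I -> A picks up
# (-1)^(number of occupied spin orbitals strictly between I and A), and a
# double excitation (I, J) -> (A, B) is evaluated as two sequential singles
# I -> A then J -> B on the intermediate occupation.

# bit masks (per spin channel) of positions strictly between two combined
# spin-orbital positions; cached per n_orb
range_masks <- function(n_orb) {
  key <- as.character(n_orb)
  rm <- .gasci_env$range_masks[[key]]
  if (!is.null(rm)) return(rm)
  nso <- 2L * n_orb
  ra <- matrix(0L, nso, nso)
  rb <- matrix(0L, nso, nso)
  for (p in 1:(nso - 1)) for (q in (p + 1):nso) {
    between <- if (q - p >= 2) (p + 1):(q - 1) else integer(0)
    ab <- between[between <= n_orb]
    bb <- between[between > n_orb] - n_orb
    ra[p, q] <- ra[q, p] <- as.integer(mask_from_orbs(ab))
    rb[p, q] <- rb[q, p] <- as.integer(mask_from_orbs(bb))
  }
  if (is.null(.gasci_env$range_masks)) .gasci_env$range_masks <- list()
  .gasci_env$range_masks[[key]] <- list(ra = ra, rb = rb)
  .gasci_env$range_masks[[key]]
}

# occupied count strictly between spin-orbital positions p and q (vectorized)
n_between <- function(amask, bmask, p, q, n_orb) {
  rm <- range_masks(n_orb)
  lo <- pmin(p, q); hi <- pmax(p, q)
  idx <- cbind(lo, hi)
  mask_popcount(bitwAnd(as.integer(amask), rm$ra[idx])) +
    mask_popcount(bitwAnd(as.integer(bmask), rm$rb[idx]))
}

so_spatial <- function(p, n_orb) ifelse(p > n_orb, p - n_orb, p)
so_is_alpha <- function(p, n_orb) p <= n_orb

# diagonal element <D|H|D> including the core energy
diagonal_element <- function(det, ints) {
  n <- ints$n_orb
  occ <- det_occ_so(det)
  sp <- so_spatial(occ, n)
  al <- so_is_alpha(occ, n)
  e <- ints$core_energy + sum(ints$h[cbind(sp, sp)])
  if (length(occ) > 1) {
    prs <- utils::combn(seq_along(occ), 2)
    p <- sp[prs[1, ]]; q <- sp[prs[2, ]]
    same <- al[prs[1, ]] == al[prs[2, ]]
    e <- e + sum(ints$g[cbind(p, p, q, q)]) -
      sum(ints$g[cbind(p, q, q, p)][same])
  }
  e
}

#' Slater-Condon matrix element between two determinants
#'
#' @param det_i,det_j Determinants in the same spin sector.
#' @param ints An [integral_table()].
#' @return The Hamiltonian matrix element (core energy included on the
#'   diagonal); 0 when the determinants differ by more than a double
#'   excitation.
#' @export
matrix_element <- function(det_i, det_j, ints) {
  n <- ints$n_orb
  ai <- as.integer(det_i$alpha); bi <- as.integer(det_i$beta)
  aj <- as.integer(det_j$alpha); bj <- as.integer(det_j$beta)
  if (mask_popcount(ai) != mask_popcount(aj) ||
      mask_popcount(bi) != mask_popcount(bj))
    stop("matrix_element: determinants are in different spin sectors")
  xa <- bitwXor(ai, aj); xb <- bitwXor(bi, bj)
  lev <- (mask_popcount(xa) + mask_popcount(xb)) / 2
  if (lev > 2) return(0)
  if (lev == 0) return(diagonal_element(det_i, ints))
  # spin-orbital positions removed from det_i / added in det_j
  rem <- c(mask_orbs(bitwAnd(xa, ai)), mask_orbs(bitwAnd(xb, bi)) + n)
  add <- c(mask_orbs(bitwAnd(xa, aj)), mask_orbs(bitwAnd(xb, bj)) + n)
  if (lev == 1) {
    I <- rem; A <- add
    i0 <- so_spatial(I, n); a0 <- so_spatial(A, n)
    occ <- setdiff(det_occ_so(det_i), I)
    p0 <- so_spatial(occ, n)
    same <- so_is_alpha(occ, n) == so_is_alpha(I, n)
    val <- ints$h[a0, i0] + sum(ints$g[cbind(a0, i0, p0, p0)]) -
      sum(ints$g[cbind(a0, p0, p0, i0)][same])
    ph <- (-1)^n_between(ai, bi, I, A, n)
    return(ph * val)
  }
  # double excitation: assign (I -> A, J -> B) with I < J, A < B
  I <- min(rem); J <- max(rem); A <- min(add); B <- max(add)
  i0 <- so_spatial(I, n); j0 <- so_spatial(J, n)
  a0 <- so_spatial(A, n); b0 <- so_spatial(B, n)
  sI <- so_is_alpha(I, n); sJ <- so_is_alpha(J, n)
  sA <- so_is_alpha(A, n); sB <- so_is_alpha(B, n)
  t1 <- if (sA == sI && sB == sJ) ints$g[a0, i0, b0, j0] else 0
  t2 <- if (sA == sJ && sB == sI) ints$g[a0, j0, b0, i0] else 0
  ph1 <- n_between(ai, bi, I, A, n)
  # intermediate occupation after I -> A: adjust count between J and B
  lo <- pmin(J, B); hi <- pmax(J, B)
  adj <- as.integer(I > lo & I < hi) - as.integer(A > lo & A < hi)
  ph2 <- n_between(ai, bi, J, B, n) - adj
  ((-1)^(ph1 + ph2)) * (t1 - t2)
}

#' GAS-masked Hamiltonian matrix element
#'
#' Zero when the target determinant's supergroup is not GAS allowed (the
#' decision depends only on the supergroup of the starting determinant and
#' the orbital move); otherwise the plain Slater-Condon element.
#'
#' @inheritParams matrix_element
#' @param sg_table A [build_supergroup_table()] result.
#' @return The masked matrix element.
#' @export
gas_masked_element <- function(det_i, det_j, ints, sg_table) {
  xj <- supergroup_of_determinant(det_j, sg_table$partition)
  if (!is_allowed(xj, sg_table$constraints, sg_table$partition)) return(0)
  matrix_element(det_i, det_j, ints)
}

#' Dense Hamiltonian over an explicit determinant list
#'
#' Used for the semistochastic core space.  All determinants must be GAS
#' allowed when a supergroup table is given.
#'
#' @param core_dets List of determinants.
#' @param ints An [integral_table()].
#' @param sg_table Optional supergroup table; forbidden members raise an
#'   error and couplings leaving the space are zeroed.
#' @return A dense symmetric matrix.
#' @export
core_hamiltonian <- function(core_dets, ints, sg_table = NULL) {
  m <- length(core_dets)
  if (!is.null(sg_table)) {
    for (d in core_dets) {
      x <- supergroup_of_determinant(d, sg_table$partition)
      if (!is_allowed(x, sg_table$constraints, sg_table$partition))
        stop("core_hamiltonian: GAS-forbidden determinant in core list")
    }
  }
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    H[i, i] <- diagonal_element(core_dets[[i]], ints)
    if (i < m) for (j in (i + 1):m) {
      v <- matrix_element(core_dets[[i]], core_dets[[j]], ints)
      H[i, j] <- H[j, i] <- v
    }
  }
  H
}
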