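# Exact diagonalization oracle: sparse Hamiltonian over an enumerated
# determinant basis, lowest eigenpair by dense diagonalization at small
# dimension or Lanczos (full reorthogonalization) above it.

basis_det <- function(basis, i) {
  det_from_masks(basis$alpha[i], basis$beta[i], basis$n_orb)
}

#' Sparse Hamiltonian matrix over an enumerated basis
#'
#' @param basis An [enumerate_determinants()] result.
#' @param ints An [integral_table()].
#' @return A symmetric `Matrix::dgCMatrix`.
#' @export
hamiltonian_matrix <- function(basis, ints) {
  nb <- length(basis$alpha)
  pc <- popcnt16()
  ai <- as.integer(basis$alpha); bi <- as.integer(basis$beta)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  dets <- lapply(seq_len(nb), function(i) basis_det(basis, i))
  diag_v <- vapply(dets, diagonal_element, numeric(1), ints = ints)
  for (i in seq_len(nb)) {
    if (i == nb) break
    rng <- (i + 1):nb
    lev <- (pc[bitwXor(ai[i], ai[rng]) + 1L] +
            pc[bitwXor(bi[i], bi[rng]) + 1L]) / 2
    cand <- rng[lev <= 2]
    for (j in cand) {
      v <- matrix_element(dets[[i]], dets[[j]], ints)
      if (v != 0) {
        ii <- c(ii, i); jj <- c(jj, j); vv <- c(vv, v)
      }
    }
  }
  Matrix::sparseMatrix(i = c(seq_len(nb), ii, jj), j = c(seq_len(nb), jj, ii),
                       x = c(diag_v, vv, vv), dims = c(nb, nb))
}

# Lanczos with full reorthogonalization for the lowest eigenpair
lanczos_lowest <- function(mult, dim, m = min(dim, 120L), tol = 1e-9,
                           seed_vec = NULL) {
  v <- if (is.null(seed_vec)) rep(1, dim) + seq_len(dim) / dim else seed_vec
  v <- v / sqrt(sum(v^2))
  V <- matrix(0, dim, m)
  alpha <- numeric(m); beta <- numeric(m)
  V[, 1] <- v
  w <- mult(v)
  alpha[1] <- sum(w * v)
  w <- w - alpha[1] * v
  for (j in 2:m) {
    beta[j - 1] <- sqrt(sum(w^2))
    if (beta[j - 1] < 1e-13) { m <- j - 1L; break }
    v <- w / beta[j - 1]
    # full reorthogonalization
    v <- v - V[, 1:(j - 1), drop = FALSE] %*%
      crossprod(V[, 1:(j - 1), drop = FALSE], v)
    v <- v / sqrt(sum(v^2))
    V[, j] <- v
    w <- mult(v) - beta[j - 1] * V[, j - 1]
    alpha[j] <- sum(w * v)
    w <- w - alpha[j] * v
  }
  Tm <- diag(alpha[1:m], m, m)
  if (m > 1) for (j in 1:(m - 1)) Tm[j, j + 1] <- Tm[j + 1, j] <- beta[j]
  es <- eigen(Tm, symmetric = TRUE)
  y <- es$vectors[, m]
  x <- as.numeric(V[, 1:m, drop = FALSE] %*% y)
  x <- x / sqrt(sum(x^2))
  list(value = es$values[m], vector = x)
}

#' Exact diagonalization of a (GAS-masked) Hamiltonian
#'
#' Enumerates the GAS determinant basis at the given spin projection, builds
#' the Hamiltonian over it (restricting to the allowed basis is equivalent to
#' masking forbidden couplings), and returns the lowest eigenpair.  Dense
#' symmetric diagonalization below 1200 determinants, Lanczos with dense
#' fallback above.
#'
#' @param partition A [gas_partition()].
#' @param ints An [integral_table()].
#' @param sg_table A [build_supergroup_table()] result.
#' @param m_s Spin projection.
#' @param cap Maximum basis size.
#' @return An object of class `exact_solution`: `energy`, `coefficients`
#'   (normalized, sign fixed so the largest-magnitude entry is positive),
#'   `basis`, `residual`.
#' @export
exact_diagonalization <- function(partition, ints, sg_table, m_s, cap = 2e4) {
  basis <- enumerate_determinants(partition, sg_table, m_s, cap = cap)
  nb <- length(basis$alpha)
  if (nb == 0) stop("exact_diagonalization: empty basis")
  if (nb == 1) {
    d <- basis_det(basis, 1)
    return(structure(list(energy = diagonal_element(d, ints),
                          coefficients = 1, basis = basis, residual = 0),
                     class = "exact_solution"))
  }
  H <- hamiltonian_matrix(basis, ints)
  if (nb <= 1200) {
    es <- eigen(as.matrix(H), symmetric = TRUE)
    val <- es$values[nb]
    vec <- es$vectors[, nb]
  } else {
    res <- lanczos_lowest(function(x) as.numeric(H %*% x), nb)
    val <- res$value
    vec <- res$vector
  }
  if (vec[which.max(abs(vec))] < 0) vec <- -vec
  resid <- sqrt(sum((as.numeric(H %*% vec) - val * vec)^2))
  structure(list(energy = val, coefficients = vec, basis = basis,
                 residual = resid),
            class = "exact_solution")
}

#' @export
print.exact_solution <- function(x, ...) {
  cat("Exact solution: E =", format(x$energy, digits = 10),
      "over", length(x$coefficients), "determinants (residual",
      format(x$residual, digits = 3), ")\n")
  invisible(x)
}
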