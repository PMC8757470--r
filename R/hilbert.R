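# Hilbert-space counting: Slater determinants by spin sector, GAS-restricted
# determinant counts via per-space generating polynomials, and spin-adapted
# (CSF) counts from the van Vleck-Sherman formula.  All counting is exact.

#' Count Slater determinants in a complete active space
#'
#' Number of determinants for `N` electrons in `n_orb` spatial orbitals at
#' spin projection `m_s`: `choose(n_orb, n_alpha) * choose(n_orb, n_beta)`.
#'
#' @param n_orb Number of spatial orbitals.
#' @param N Number of electrons.
#' @param m_s Spin projection (can be half-integer).
#' @return A [bigint()]; infeasible sectors give 0.
#' @examples
#' count_sds(12, 12, 0)               # 853776
#' bi_signif(count_sds(30, 30, 0))    # 2.41e16
#' @export
count_sds <- function(n_orb, N, m_s) {
  n_alpha <- (N + 2 * m_s) / 2
  n_beta <- N - n_alpha
  if (n_alpha != floor(n_alpha) || n_alpha < 0 || n_beta < 0 ||
      n_alpha > n_orb || n_beta > n_orb) return(bigint(0))
  bi_choose(n_orb, n_alpha) * bi_choose(n_orb, n_beta)
}

# generating polynomial (in the alpha count) for one GAS space:
# coefficient of z^a is choose(n_i, a) * choose(n_i, x_i - a), as bigints
space_alpha_poly <- function(n_i, x_i) {
  a_rng <- max(0L, x_i - n_i):min(n_i, x_i)
  coef <- lapply(a_rng, function(a) bi_choose(n_i, a) * bi_choose(n_i, x_i - a))
  list(offset = a_rng[1], coef = coef)
}

poly_convolve <- function(p, q) {
  np <- length(p$coef); nq <- length(q$coef)
  coef <- vector("list", np + nq - 1L)
  for (i in seq_len(np + nq - 1L)) coef[[i]] <- bigint(0)
  for (i in seq_len(np)) {
    for (j in seq_len(nq)) {
      coef[[i + j - 1L]] <- coef[[i + j - 1L]] + p$coef[[i]] * q$coef[[j]]
    }
  }
  list(offset = p$offset + q$offset, coef = coef)
}

#' Count Slater determinants in a GAS space
#'
#' For each supergroup, the per-space alpha-count generating polynomials are
#' convolved exactly and the coefficient with total alpha count
#' `(N + 2 m_s)/2` is extracted; the result is summed over supergroups.
#'
#' @param partition A [gas_partition()].
#' @param table A [build_supergroup_table()] result.
#' @param m_s Spin projection.
#' @return A [bigint()].
#' @examples
#' p <- gas_partition(rep(3, 4))
#' tab <- build_supergroup_table(p, band_constraints(p, rep(3, 4), 1, "local"), 12)
#' count_sds_gas(p, tab, 0)  # 468942
#' @export
count_sds_gas <- function(partition, table, m_s) {
  N <- table$N
  n_alpha <- (N + 2 * m_s) / 2
  if (n_alpha != floor(n_alpha) || n_alpha < 0 || n_alpha > N) return(bigint(0))
  total <- bigint(0)
  for (s in seq_len(nrow(table$supergroups))) {
    x <- table$supergroups[s, ]
    poly <- space_alpha_poly(partition$space_sizes[1], x[1])
    if (partition$k > 1L) {
      for (i in 2:partition$k) {
        poly <- poly_convolve(poly, space_alpha_poly(partition$space_sizes[i], x[i]))
      }
    }
    pos <- n_alpha - poly$offset + 1
    if (pos >= 1 && pos <= length(poly$coef))
      total <- total + poly$coef[[pos]]
  }
  total
}

#' Per-supergroup determinant counts
#'
#' @inheritParams count_sds_gas
#' @return A data frame with one row per supergroup: `i_sg`, the composition,
#'   and the determinant count (as character, exact) plus a double
#'   approximation.
#' @export
count_sds_per_supergroup <- function(partition, table, m_s) {
  N <- table$N
  n_alpha <- (N + 2 * m_s) / 2
  counts <- vapply(seq_len(nrow(table$supergroups)), function(s) {
    x <- table$supergroups[s, ]
    poly <- space_alpha_poly(partition$space_sizes[1], x[1])
    if (partition$k > 1L) for (i in 2:partition$k)
      poly <- poly_convolve(poly, space_alpha_poly(partition$space_sizes[i], x[i]))
    pos <- n_alpha - poly$offset + 1
    if (pos >= 1 && pos <= length(poly$coef))
      as.character(poly$coef[[pos]]) else "0"
  }, character(1))
  df <- as.data.frame(table)
  df$n_sd <- counts
  df$n_sd_num <- vapply(counts, function(s) as.numeric(bigint(s)), numeric(1))
  df
}

#' Count configuration state functions (van Vleck-Sherman)
#'
#' Number of spin-`s` configuration state functions that can be built over
#' `n_open` singly occupied orbitals:
#' `choose(n, n/2 - s) - choose(n, n/2 - s - 1)`, the branching-diagram count.
#'
#' @param n_open Number of singly occupied (open-shell) orbitals.
#' @param s Target total spin (half-integer allowed).
#' @return A double (exact); 0 when `s` and `n_open` have mismatched parity or
#'   `s > n_open/2`.
#' @examples
#' csf_count(4, 0)   # 2
#' csf_count(20, 2)  # 48450, the maximum over s for 20 open shells
#' @export
csf_count <- function(n_open, s) {
  two_s <- 2 * s
  if (two_s != floor(two_s) || two_s < 0) return(0)
  if ((n_open - two_s) %% 2 != 0 || two_s > n_open) return(0)
  m <- (n_open - two_s) / 2
  a <- choose_exact(n_open, m)
  b <- if (m >= 1) choose_exact(n_open, m - 1) else 0
  a - b
}
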