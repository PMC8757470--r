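# Slater determinants as alpha/beta occupation bit vectors.
#
# A determinant over n <= 16 spatial orbitals is stored as two bit masks
# (plain doubles holding exact powers of two), one per spin channel.  Spin
# orbitals are numbered 1..n (alpha block) and n+1..2n (beta block), both in
# ascending spatial order; fermionic phases are counted in this fixed order.
# The compact numeric key alpha * 2^16 + beta identifies a determinant
# uniquely and exactly.

MAX_ORB <- 16L

# popcount lookup for 16-bit masks (built lazily)
popcnt16 <- function() {
  p <- .gasci_env$popcnt16
  if (is.null(p)) {
    v <- 0:65535
    p <- integer(65536)
    for (b in 0:15) p <- p + bitwAnd(bitwShiftR(v, b), 1L)
    .gasci_env$popcnt16 <- p
  }
  p
}

mask_popcount <- function(m) popcnt16()[m + 1L]

# occupied orbital positions (1-based) of a single mask
mask_orbs <- function(m) {
  which(bitwAnd(rep(as.integer(m), MAX_ORB),
                bitwShiftL(1L, 0:(MAX_ORB - 1L))) != 0L)
}

mask_from_orbs <- function(orbs) {
  if (length(orbs) == 0L) return(0)
  sum(2^(orbs - 1))
}

#' Construct a Slater determinant
#'
#' @param alpha_orbs,beta_orbs Integer vectors of occupied spatial orbitals
#'   (1-based) in the alpha and beta channels.
#' @param n_orb Total number of spatial orbitals (at most 16).
#' @return An object of class `determinant` with fields `alpha`, `beta`
#'   (occupation bit masks), and `n_orb`.
#' @examples
#' determinant(1:3, 1:3, 6)  # closed shell, 6 electrons in 6 orbitals
#' @export
determinant <- function(alpha_orbs, beta_orbs, n_orb) {
  stopifnot(n_orb <= MAX_ORB)
  alpha_orbs <- as.integer(alpha_orbs); beta_orbs <- as.integer(beta_orbs)
  stopifnot(!anyDuplicated(alpha_orbs), !anyDuplicated(beta_orbs))
  if (length(c(alpha_orbs, beta_orbs)) &&
      max(c(alpha_orbs, beta_orbs, 0L)) > n_orb)
    stop("determinant: orbital index beyond n_orb")
  structure(list(alpha = mask_from_orbs(alpha_orbs),
                 beta = mask_from_orbs(beta_orbs),
                 n_orb = as.integer(n_orb)),
            class = "determinant")
}

det_from_masks <- function(alpha, beta, n_orb) {
  structure(list(alpha = alpha, beta = beta, n_orb = as.integer(n_orb)),
            class = "determinant")
}

det_key <- function(alpha, beta) alpha * 65536 + beta

key_alpha <- function(key) key %/% 65536
key_beta <- function(key) key %% 65536

#' @export
print.determinant <- function(x, ...) {
  cat("|", paste(mask_orbs(x$alpha), collapse = ","), ";",
      paste(mask_orbs(x$beta), collapse = ","), ">\n", sep = "")
  invisible(x)
}

# occupied spin orbitals (ascending, alpha block then beta block)
det_occ_so <- function(det) {
  c(mask_orbs(det$alpha), mask_orbs(det$beta) + det$n_orb)
}

det_n_alpha <- function(det) mask_popcount(det$alpha)
det_n_beta <- function(det) mask_popcount(det$beta)

# all subsets of `orbs` of size m, as bit masks
subset_masks <- function(orbs, m) {
  if (m < 0 || m > length(orbs)) return(numeric(0))
  if (m == 0L) return(0)
  cmb <- utils::combn(orbs, m)
  if (m == 1L) return(2^(orbs - 1))
  colSums(2^(cmb - 1))
}

#' Enumerate all determinants of a GAS space
#'
#' Builds the complete, duplicate-free determinant basis for a supergroup
#' table at fixed spin projection, ordered by supergroup index and then by
#' ascending (alpha mask, beta mask) within each supergroup.
#'
#' @param partition A [gas_partition()].
#' @param table A [build_supergroup_table()] result (its `N` sets the
#'   electron count).
#' @param m_s Spin projection (half-integer times 1; `(n_alpha - n_beta)/2`).
#' @param cap Maximum basis size to materialize.
#' @return A list with numeric vectors `alpha`, `beta` (bit masks), `key`,
#'   integer `isg` (supergroup index per determinant), and `n_orb`.
#' @export
enumerate_determinants <- function(partition, table, m_s, cap = 1e6) {
  N <- table$N
  n_alpha <- (N + 2 * m_s) / 2
  if (n_alpha != floor(n_alpha) || n_alpha < 0 || n_alpha > N)
    stop("enumerate_determinants: infeasible spin sector")
  total <- count_sds_gas(partition, table, m_s)
  if (bi_cmp(total, bigint(cap)) > 0)
    stop("enumerate_determinants: basis size ", as.character(total),
         " exceeds cap ", cap)
  k <- partition$k
  space_orbs <- split(seq_len(partition$n_orb), partition$orbital_space)
  alpha_all <- numeric(0); beta_all <- numeric(0); isg_all <- integer(0)
  for (s in seq_len(nrow(table$supergroups))) {
    x <- table$supergroups[s, ]
    # per space: list of (alpha mask, beta mask) pairs for each alpha count
    acc <- data.frame(alpha = 0, beta = 0, na = 0L)
    for (i in seq_len(k)) {
      orbs <- space_orbs[[i]]
      xi <- x[i]
      a_rng <- max(0L, xi - length(orbs)):min(length(orbs), xi)
      parts <- do.call(rbind, lapply(a_rng, function(a) {
        am <- subset_masks(orbs, a)
        bm <- subset_masks(orbs, xi - a)
        expand.grid(alpha = am, beta = bm, KEEP.OUT.ATTRS = FALSE)
      }))
      parts$na <- mask_popcount(parts$alpha)
      # combine: masks in different spaces are disjoint, so addition composes
      idx <- expand.grid(p = seq_len(nrow(acc)), q = seq_len(nrow(parts)))
      acc <- data.frame(alpha = acc$alpha[idx$p] + parts$alpha[idx$q],
                        beta = acc$beta[idx$p] + parts$beta[idx$q],
                        na = acc$na[idx$p] + parts$na[idx$q])
      # prune alpha counts that can no longer reach n_alpha
      rem_cap <- if (i < k) sum(pmin(x[(i + 1):k], partition$space_sizes[(i + 1):k])) else 0L
      acc <- acc[acc$na <= n_alpha & acc$na + rem_cap >= n_alpha, , drop = FALSE]
      if (nrow(acc) == 0L) break
    }
    if (nrow(acc) == 0L) next
    acc <- acc[acc$na == n_alpha, , drop = FALSE]
    ord <- order(acc$alpha, acc$beta)
    alpha_all <- c(alpha_all, acc$alpha[ord])
    beta_all <- c(beta_all, acc$beta[ord])
    isg_all <- c(isg_all, rep.int(s, nrow(acc)))
  }
  list(alpha = alpha_all, beta = beta_all,
       key = det_key(alpha_all, beta_all),
       isg = isg_all, n_orb = partition$n_orb)
}
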