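# Compositions, composition indices, and supergroup tables.
#
# Compositions (ordered distributions of N particles over k spaces) are kept
# in decreasing lexicographic order; the composition index of any composition
# is computed in closed form by "jumping over" all compositions with a larger
# leading term, using cached binomials.  A supergroup table stores the
# GAS-allowed compositions together with their (sorted, strictly increasing)
# composition indices, so the supergroup index of a determinant reduces to
# one composition-index evaluation plus a binary search.

#' Number of compositions of n into k ordered nonnegative parts
#'
#' @param k Number of parts (GAS spaces), at least 1.
#' @param n Total (particle number), nonnegative.
#' @return A double holding the exact count `choose(n + k - 1, k - 1)`.
#' @examples
#' n_compositions(3, 3)  # 10
#' @export
n_compositions <- function(k, n) {
  if (k < 1 || n < 0) stop("n_compositions: need k >= 1 and n >= 0")
  choose_exact(n + k - 1, k - 1)
}

#' Enumerate all compositions in decreasing lexicographic order
#'
#' @param k Number of parts.
#' @param n Total.
#' @return An integer matrix with `n_compositions(k, n)` rows and `k` columns.
#' @export
enumerate_compositions <- function(k, n) {
  if (k == 1L) return(matrix(as.integer(n), 1L, 1L))
  total <- n_compositions(k, n)
  if (total > 5e6) stop("enumerate_compositions: composition set too large to materialize")
  blocks <- lapply(n:0, function(first) {
    rest <- enumerate_compositions(k - 1L, n - first)
    cbind(as.integer(first), rest, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

#' Composition index (1-based, decreasing lexicographic order)
#'
#' Position of a composition in the decreasing-lexicographic enumeration,
#' computed without enumeration by summing, for each leading element, the
#' counts of all compositions with a larger value at that position.
#'
#' @param x Integer vector: the composition.
#' @return A double: the 1-based index.
#' @examples
#' composition_index(c(3, 0, 0))  # 1
#' composition_index(c(1, 0, 2))  # 6
#' @export
composition_index <- function(x) {
  k <- length(x)
  n <- sum(x)
  idx <- 1
  rem <- n
  for (j in seq_len(k - 1L)) {
    t <- k - j   # parts remaining after position j
    # sum over larger leading terms L = x[j]+1 .. rem of p(t, rem - L)
    # equals choose(rem - x[j] - 1 + t, t)
    if (rem > x[j]) idx <- idx + choose_exact(rem - x[j] - 1 + t, t)
    rem <- rem - x[j]
    if (rem == 0) break
  }
  idx
}

#' Build the table of GAS-allowed supergroups
#'
#' Enumerates all compositions of `N` over the partition's spaces, filters by
#' per-space spin-orbital capacity and by the constraints, sorts in
#' decreasing lexicographic order (the enumeration order), and stores the
#' composition indices.
#'
#' @param partition A [gas_partition()].
#' @param constraints A `gas_constraints` object.
#' @param N Total particle number.
#' @param validate Run [validate_gas()] first and abort on violations.
#' @return An object of class `supergroup_table`: a list with `supergroups`
#'   (integer matrix, one row per supergroup, decreasing lex order),
#'   `comp_index` (their composition indices, strictly increasing), `N`,
#'   `partition`, and `constraints`.
#' @export
build_supergroup_table <- function(partition, constraints, N, validate = TRUE) {
  if (validate) {
    diag <- validate_gas(partition, constraints, N)
    if (!diag$ok)
      stop("build_supergroup_table: invalid constraints: ",
           paste(diag$violations, collapse = "; "))
  }
  comps <- enumerate_compositions(partition$k, N)
  cap <- 2L * partition$space_sizes
  keep_cap <- rowSums(sweep(comps, 2L, cap, `>`)) == 0L
  comps <- comps[keep_cap, , drop = FALSE]
  keep <- vapply(seq_len(nrow(comps)), function(i) {
    is_allowed(comps[i, ], constraints)
  }, logical(1))
  sgs <- comps[keep, , drop = FALSE]
  if (nrow(sgs) == 0L)
    stop("build_supergroup_table: no composition satisfies the constraints")
  ci <- vapply(seq_len(nrow(sgs)), function(i) composition_index(sgs[i, ]),
               numeric(1))
  structure(list(supergroups = sgs, comp_index = ci, N = N,
                 partition = partition, constraints = constraints),
            class = "supergroup_table")
}

#' @export
print.supergroup_table <- function(x, ...) {
  cat("Supergroup table:", nrow(x$supergroups), "supergroups, N =", x$N, "\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x$supergroups) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.supergroup_table <- function(x, ...) {
  df <- data.frame(i_sg = seq_len(nrow(x$supergroups)), i_C = x$comp_index)
  sg <- as.data.frame(x$supergroups)
  names(sg) <- paste0("x", seq_len(ncol(sg)))
  cbind(df, sg)
}

#' Supergroup index of a composition
#'
#' Computes the composition index and binary-searches the stored (strictly
#' increasing) composition indices of the table.
#'
#' @param x Integer vector: the composition.
#' @param table A [build_supergroup_table()] result.
#' @return Integer supergroup index (1-based).
#' @examples
#' p <- gas_partition(c(1, 1, 1))
#' tab <- build_supergroup_table(p, gas_cumulative(c(0, 1, 3), c(2, 2, 3)), 3)
#' supergroup_index(c(1, 0, 2), tab)  # 3
#' @export
supergroup_index <- function(x, table) {
  if (!is_allowed(x, table$constraints, table$partition))
    stop("supergroup_index: composition is not GAS allowed")
  ci <- composition_index(x)
  pos <- findInterval(ci, table$comp_index)
  if (pos < 1L || table$comp_index[pos] != ci)
    stop("supergroup_index: composition not present in table")
  pos
}

#' Supergroup (per-space particle counts) of a determinant
#'
#' @param det A determinant (see [determinant()]).
#' @param partition A [gas_partition()].
#' @return Integer vector of alpha+beta electron counts per GAS space.
#' @export
supergroup_of_determinant <- function(det, partition) {
  occ <- c(mask_orbs(det$alpha), mask_orbs(det$beta))
  if (length(occ) && max(occ) > partition$n_orb)
    stop("supergroup_of_determinant: determinant orbital outside partition")
  counts <- tabulate(partition$orbital_space[occ], nbins = partition$k)
  as.integer(counts)
}
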