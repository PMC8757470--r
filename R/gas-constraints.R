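# GAS partitions and occupation constraints.
#
# A generalized active space (GAS) splits the active spatial orbitals into k
# subspaces.  Occupation constraints are either *local* (per-space bounds
# N_i^min <= x_i <= N_i^max) or *cumulative* (bounds on the partial sums
# of the particle distribution).  Compositions allowed by the constraints are
# called supergroups.
#
# Index conventions: compositions and supergroups are 1-based (matching the
# tabulated examples in the field); spatial orbitals are 1-based as is usual
# in R.  Spin orbitals are numbered 1..n for the alpha block followed by
# n+1..2n for the beta block, in ascending spatial order.

#' Define a GAS orbital partition
#'
#' @param space_sizes Integer vector: number of spatial orbitals per GAS
#'   space, one entry per space.
#' @return An object of class `gas_partition` with fields `space_sizes`, `k`
#'   (number of spaces), `n_orb` (total spatial orbitals) and
#'   `orbital_space` (space index of each spatial orbital, 1-based).
#' @examples
#' gas_partition(c(6, 6, 6, 6, 6))
#' @export
gas_partition <- function(space_sizes) {
  space_sizes <- as.integer(space_sizes)
  stopifnot(length(space_sizes) >= 1L, all(space_sizes >= 1L))
  structure(list(
    space_sizes = space_sizes,
    k = length(space_sizes),
    n_orb = sum(space_sizes),
    orbital_space = rep.int(seq_along(space_sizes), space_sizes)
  ), class = "gas_partition")
}

#' @export
print.gas_partition <- function(x, ...) {
  cat("GAS partition:", x$k, "spaces over", x$n_orb, "spatial orbitals (",
      paste(x$space_sizes, collapse = ", "), ")\n")
  invisible(x)
}

#' Local (per-space) occupation constraints
#'
#' @param n_min,n_max Integer vectors of per-space minimum and maximum
#'   particle numbers, one entry per GAS space.
#' @return An object of class `c("gas_local", "gas_constraints")`.
#' @export
gas_local <- function(n_min, n_max) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  stopifnot(length(n_min) == length(n_max))
  structure(list(n_min = n_min, n_max = n_max, k = length(n_min)),
            class = c("gas_local", "gas_constraints"))
}

#' Cumulative (partial-sum) occupation constraints
#'
#' @param cum_min,cum_max Integer vectors of bounds on the cumulative particle
#'   numbers over the first i GAS spaces.
#' @return An object of class `c("gas_cumulative", "gas_constraints")`.
#' @export
gas_cumulative <- function(cum_min, cum_max) {
  cum_min <- as.integer(cum_min); cum_max <- as.integer(cum_max)
  stopifnot(length(cum_min) == length(cum_max))
  structure(list(cum_min = cum_min, cum_max = cum_max, k = length(cum_min)),
            class = c("gas_cumulative", "gas_constraints"))
}

#' @export
print.gas_constraints <- function(x, ...) {
  if (inherits(x, "gas_local")) {
    cat("Local GAS constraints\n  n_min:", paste(x$n_min, collapse = " "),
        "\n  n_max:", paste(x$n_max, collapse = " "), "\n")
  } else {
    cat("Cumulative GAS constraints\n  cum_min:", paste(x$cum_min, collapse = " "),
        "\n  cum_max:", paste(x$cum_max, collapse = " "), "\n")
  }
  invisible(x)
}

#' Validate GAS constraints against a partition and particle number
#'
#' Returns diagnostics rather than raising, so callers can decide whether to
#' abort.  Checked: length consistency, bound ordering, spin-orbital capacity
#' (the Pauli bound 2 * space size), totals consistent with `N`, monotonicity
#' of cumulative arrays, and non-emptiness of the resulting supergroup set.
#'
#' @param partition A [gas_partition()].
#' @param constraints A `gas_local` or `gas_cumulative` object.
#' @param N Total particle number.
#' @return A list with `ok` (logical) and `violations` (character vector).
#' @export
validate_gas <- function(partition, constraints, N) {
  v <- character(0)
  k <- partition$k
  cap <- 2L * partition$space_sizes
  if (constraints$k != k) {
    return(list(ok = FALSE,
                violations = "constraint length does not match number of GAS spaces"))
  }
  if (inherits(constraints, "gas_local")) {
    if (any(constraints$n_min > constraints$n_max))
      v <- c(v, "n_min exceeds n_max in some space")
    if (any(constraints$n_min > cap))
      v <- c(v, "minimum occupation exceeds spin-orbital capacity")
    if (any(constraints$n_min < 0))
      v <- c(v, "negative minimum occupation")
    if (sum(constraints$n_min) > N)
      v <- c(v, "no valid composition: total minimum exceeds the particle number")
    if (sum(pmin(constraints$n_max, cap)) < N)
      v <- c(v, "no valid composition: total maximum below the particle number")
  } else {
    if (any(constraints$cum_min > constraints$cum_max))
      v <- c(v, "cum_min exceeds cum_max at some space")
    if (is.unsorted(constraints$cum_min) || is.unsorted(constraints$cum_max))
      v <- c(v, "cumulative bounds are not nondecreasing")
    if (any(constraints$cum_min < 0))
      v <- c(v, "negative cumulative minimum")
    if (constraints$cum_min[k] > N || constraints$cum_max[k] < N)
      v <- c(v, "no valid composition: cumulative bounds on the last space exclude N")
    if (any(constraints$cum_min > cumsum(cap)))
      v <- c(v, "cumulative minimum exceeds spin-orbital capacity")
  }
  if (length(v) == 0) {
    sg <- tryCatch(
      build_supergroup_table(partition, constraints, N, validate = FALSE),
      error = function(e) NULL)
    if (is.null(sg) || nrow(sg$supergroups) == 0L)
      v <- c(v, "no valid composition: supergroup set is empty")
  }
  list(ok = length(v) == 0, violations = v)
}

#' Test whether a composition satisfies GAS constraints
#'
#' @param x Integer vector: particle count per GAS space.
#' @param constraints A `gas_constraints` object.
#' @param partition Optional [gas_partition()]; when supplied, the per-space
#'   spin-orbital capacity is enforced as well.
#' @return Logical.
#' @export
is_allowed <- function(x, constraints, partition = NULL) {
  if (length(x) != constraints$k)
    stop("is_allowed: composition length does not match number of GAS spaces")
  if (any(x < 0)) return(FALSE)
  if (!is.null(partition) && any(x > 2L * partition$space_sizes)) return(FALSE)
  if (inherits(constraints, "gas_local")) {
    all(x >= constraints$n_min & x <= constraints$n_max)
  } else {
    cs <- cumsum(x)
    all(cs >= constraints$cum_min & cs <= constraints$cum_max)
  }
}

#' Occupation-band constraints around a neutral filling
#'
#' Builds the constraint object that permits at most `n_exc` interspace
#' excitations relative to a neutral per-space occupation.  The local form
#' bounds every space to `neutral_occ[i] +- n_exc` (clipped to the
#' spin-orbital capacity); the cumulative form bounds each partial sum to
#' within `n_exc` of the neutral partial sum, with the last space tied
#' exactly to the total particle number.
#'
#' @param partition A [gas_partition()].
#' @param neutral_occ Integer vector of neutral per-space occupations; must
#'   sum to the particle number.
#' @param n_exc Nonnegative number of interspace excitations.
#' @param kind `"local"` or `"cumulative"`.
#' @return A `gas_constraints` object.
#' @examples
#' p <- gas_partition(rep(6, 5))
#' band_constraints(p, rep(6, 5), 1, "local")       # 51 supergroups
#' band_constraints(p, rep(6, 5), 1, "cumulative")  # 81 supergroups
#' @export
band_constraints <- function(partition, neutral_occ, n_exc,
                             kind = c("local", "cumulative")) {
  kind <- match.arg(kind)
  neutral_occ <- as.integer(neutral_occ)
  stopifnot(length(neutral_occ) == partition$k)
  if (n_exc < 0) stop("band_constraints: n_exc must be nonnegative")
  N <- sum(neutral_occ)
  cap <- 2L * partition$space_sizes
  if (kind == "local") {
    gas_local(pmax(0L, neutral_occ - n_exc), pmin(cap, neutral_occ + n_exc))
  } else {
    cum_neutral <- cumsum(neutral_occ)
    cmin <- pmax(0L, cum_neutral - n_exc)
    cmax <- pmin(cumsum(cap), cum_neutral + n_exc)
    cmin[partition$k] <- N
    cmax[partition$k] <- N
    gas_cumulative(cmin, cmax)
  }
}

#' Convert between local and cumulative GAS constraints
#'
#' Applies the interconversion relations (local minima as differences of
#' consecutive cumulative bounds, and cumulative bounds as running sums of
#' local ones), then decides equivalence constructively: both supergroup
#' tables are built and compared.  The two constraint families are not always
#' interconvertible, so `equivalent` may be `FALSE`; bounds that come out
#' negative or non-monotone are sanitized for table construction and flagged
#' inequivalent rather than raised.
#'
#' @param constraints A `gas_constraints` object (either kind).
#' @param partition A [gas_partition()].
#' @param N Total particle number.
#' @return A list with `converted` (the constraint object of the other kind),
#'   `equivalent` (logical), and the two supergroup tables `table_from`,
#'   `table_to`.
#' @export
convert_constraints <- function(constraints, partition, N) {
  k <- constraints$k
  if (inherits(constraints, "gas_cumulative")) {
    cmin <- constraints$cum_min; cmax <- constraints$cum_max
    n_min <- c(cmin[1], cmin[-1] - cmax[-k])
    n_max <- c(cmax[1], cmax[-1] - cmin[-k])
    conv <- gas_local(pmax(0L, n_min), pmax(0L, n_max))
  } else {
    cmin <- cumsum(constraints$n_min)
    cmax <- pmin(cumsum(constraints$n_max), cumsum(2L * partition$space_sizes))
    cmin[k] <- max(cmin[k], N); cmax[k] <- min(cmax[k], N)
    if (cmin[k] > cmax[k]) cmin[k] <- cmax[k] <- N
    conv <- gas_cumulative(cmin, cmax)
  }
  tab_from <- tryCatch(build_supergroup_table(partition, constraints, N,
                                              validate = FALSE),
                       error = function(e) NULL)
  tab_to <- tryCatch(build_supergroup_table(partition, conv, N,
                                            validate = FALSE),
                     error = function(e) NULL)
  equivalent <- !is.null(tab_from) && !is.null(tab_to) &&
    nrow(tab_from$supergroups) == nrow(tab_to$supergroups) &&
    all(tab_from$supergroups == tab_to$supergroups)
  list(converted = conv, equivalent = equivalent,
       table_from = tab_from, table_to = tab_to)
}
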