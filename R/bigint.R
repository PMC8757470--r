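# Arbitrary-precision nonnegative integers.
#
# Hilbert-space counts routinely exceed 2^53 (the exact-integer range of a
# double), so all combinatorial counting in this package runs on an exact
# little-endian base-1e7 digit representation.  Only the operations the
# counting layer needs are provided: add, multiply, compare, binomials via a
# cached Pascal triangle, and decimal formatting.

BI_BASE <- 1e7
BI_BASE_DIGITS <- 7L

.gasci_env <- new.env(parent = emptyenv())

#' Exact nonnegative big integer
#'
#' Construct an arbitrary-precision nonnegative integer.  Used for Hilbert
#' space and configuration-state-function counts, which can exceed the exact
#' integer range of a double.
#'
#' @param x A single nonnegative integer-valued numeric (must be below 2^53),
#'   a decimal digit string, or an existing `bigint`.
#' @return An object of class `bigint`.
#' @examples
#' bigint(155117520) * bigint(155117520)  # SD count of CAS(30,30), m_s = 0
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    s <- gsub("[ ,]", "", x)
    if (!grepl("^[0-9]+$", s)) stop("bigint: invalid digit string")
    n <- nchar(s)
    breaks <- seq(n, 1, by = -BI_BASE_DIGITS)
    dig <- vapply(breaks, function(e) {
      as.numeric(substr(s, max(1L, e - BI_BASE_DIGITS + 1L), e))
    }, numeric(1))
    return(bi_wrap(bi_strip(dig)))
  }
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0)
  if (x != floor(x) || x >= 2^53)
    stop("bigint: numeric input must be an exact integer below 2^53")
  dig <- numeric(0)
  repeat {
    dig <- c(dig, x %% BI_BASE)
    x <- x %/% BI_BASE
    if (x == 0) break
  }
  bi_wrap(dig)
}

bi_wrap <- function(d) structure(d, class = "bigint")

bi_strip <- function(v) {
  n <- length(v)
  while (n > 1L && v[n] == 0) n <- n - 1L
  v[seq_len(n)]
}

# carry propagation; digits may temporarily exceed the base
bi_norm <- function(v) {
  repeat {
    q <- v %/% BI_BASE
    if (all(q == 0)) break
    v <- v - q * BI_BASE
    v <- c(v, 0)
    qq <- c(0, q, 0)
    length(qq) <- length(v)
    qq[is.na(qq)] <- 0
    v <- v + qq
  }
  bi_strip(v)
}

bi_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  bi_norm(a + b)
}

bi_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if ((length(a) == 1L && a == 0) || (length(b) == 1L && b == 0)) return(0)
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
    # keep partial sums well inside the exact-double range
    if (i %% 40L == 0L) res <- c(bi_norm(res), numeric(length(a) + length(b)))[
      seq_len(length(a) + length(b))]
  }
  bi_norm(res)
}

# -1, 0, 1 for a < b, a == b, a > b
bi_cmp <- function(a, b) {
  a <- bi_strip(unclass(a)); b <- bi_strip(unclass(b))
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

bi_sum <- function(lst) {
  acc <- 0
  for (x in lst) acc <- bi_add(acc, unclass(x))
  bi_wrap(acc)
}

#' @export
`+.bigint` <- function(e1, e2) bi_wrap(bi_add(unclass(bigint(e1)), unclass(bigint(e2))))

#' @export
`*.bigint` <- function(e1, e2) bi_wrap(bi_mul(unclass(bigint(e1)), unclass(bigint(e2))))

#' @export
`==.bigint` <- function(e1, e2) bi_cmp(bigint(e1), bigint(e2)) == 0

#' @export
as.character.bigint <- function(x, ...) {
  d <- rev(bi_strip(unclass(x)))
  paste0(d[1], paste(sprintf("%07.0f", d[-1]), collapse = ""))
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.bigint <- function(x, ...) {
  d <- bi_strip(unclass(x))
  sum(d * BI_BASE^(seq_along(d) - 1))
}

#' Round a big integer to significant figures
#'
#' Returns a double holding the value of `x` rounded to `digits` significant
#' figures, the form in which very large determinant counts are reported.
#'
#' @param x A `bigint` (or numeric).
#' @param digits Number of significant figures (default 3).
#' @return A double.
#' @export
bi_signif <- function(x, digits = 3) {
  if (!inherits(x, "bigint")) return(signif(x, digits))
  s <- as.character(x)
  n <- nchar(s)
  keep <- min(n, 16L)
  approx <- as.numeric(substr(s, 1L, keep)) * 10^(n - keep)
  signif(approx, digits)
}

# Exact binomial coefficients from a cached Pascal triangle of bigints.
bi_choose <- function(n, k) {
  stopifnot(n >= 0, length(n) == 1L, length(k) == 1L)
  if (k < 0 || k > n) return(bigint(0))
  tri <- .gasci_env$pascal
  if (is.null(tri)) tri <- list(list(bigint(1)))
  while (length(tri) < n + 1L) {
    prev <- tri[[length(tri)]]
    m <- length(prev)
    row <- vector("list", m + 1L)
    row[[1L]] <- bigint(1); row[[m + 1L]] <- bigint(1)
    if (m > 1L) {
      for (j in 2:m) row[[j]] <- prev[[j - 1L]] + prev[[j]]
    }
    tri[[length(tri) + 1L]] <- row
  }
  .gasci_env$pascal <- tri
  tri[[n + 1L]][[k + 1L]]
}

# Exact binomial as a double; errors if not exactly representable.
choose_exact <- function(n, k) {
  v <- bi_choose(n, k)
  num <- as.numeric(v)
  if (num >= 2^53)
    stop("choose_exact: value exceeds the exact double range; use bi_choose()")
  num
}
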