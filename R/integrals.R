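# Integral storage and FCIDUMP interchange.
#
# One-electron integrals h (n x n, symmetric) and two-electron integrals g in
# chemists' notation (ai|bj) with the full 8-fold permutational symmetry,
# stored as a dense n^4 array (desk scale, n <= 16).  Point-group labels in
# FCIDUMP headers are accepted but symmetry is not exploited (C1 treatment).

#' Construct an integral table
#'
#' @param h Symmetric n x n one-electron integral matrix.
#' @param g n^4 array of two-electron integrals, chemists' notation
#'   `(pq|rs)`; it is completed/symmetrized over the 8-fold permutations.
#' @param core_energy Scalar constant (nuclear repulsion + frozen core).
#' @param nelec,ms2 Optional electron count and 2*m_s carried to FCIDUMP.
#' @return An object of class `integral_table`.
#' @export
integral_table <- function(h, g, core_energy = 0, nelec = NA, ms2 = NA) {
  n <- nrow(h)
  stopifnot(ncol(h) == n, all(dim(g) == n))
  h <- (h + t(h)) / 2
  g <- symmetrize_g(g)
  structure(list(n_orb = n, h = h, g = g, core_energy = core_energy,
                 nelec = nelec, ms2 = ms2),
            class = "integral_table")
}

#' @export
print.integral_table <- function(x, ...) {
  cat("Integral table:", x$n_orb, "orbitals, core energy", x$core_energy, "\n")
  invisible(x)
}

# average over the 8 permutations (pq|rs)=(qp|rs)=(pq|sr)=(qp|sr)=(rs|pq)...
symmetrize_g <- function(g) {
  g2 <- g
  g2 <- (g2 + aperm(g2, c(2, 1, 3, 4))) / 2
  g2 <- (g2 + aperm(g2, c(1, 2, 4, 3))) / 2
  g2 <- (g2 + aperm(g2, c(3, 4, 1, 2))) / 2
  g2
}

# completion from stored representatives: assign a value to all 8 images
g_set_all <- function(g, i, j, k, l, val) {
  g[i, j, k, l] <- val; g[j, i, k, l] <- val
  g[i, j, l, k] <- val; g[j, i, l, k] <- val
  g[k, l, i, j] <- val; g[l, k, i, j] <- val
  g[k, l, j, i] <- val; g[l, k, j, i] <- val
  g
}

#' Read an FCIDUMP integral file
#'
#' Molpro-style FCIDUMP: a namelist header with NORB/NELEC/MS2 (ORBSYM and
#' ISYM are accepted and ignored), then lines `value i j k l` where
#' `i j k l = 0 0 0 0` is the core energy, `k = l = 0` a one-electron
#' integral `h[i, j]`, and otherwise the chemists'-notation two-electron
#' integral `(ij|kl)`.  The stored representative is expanded to the full
#' 8-fold symmetric tensor.
#'
#' @param path File path.
#' @return An [integral_table()].
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # header: everything up to &END or a bare "/"
  end_idx <- grep("(&END|^/$|/\\s*$)", toupper(lines))[1]
  if (is.na(end_idx) || !grepl("&FCI", toupper(lines[1])))
    stop("read_fcidump: malformed header (no &FCI ... &END block)")
  header <- paste(lines[1:end_idx], collapse = " ")
  get_field <- function(name) {
    m <- regmatches(header, regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header,
                                    ignore.case = TRUE))
    if (length(m) == 0) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- get_field("NORB")
  if (is.na(norb)) stop("read_fcidump: malformed header (missing NORB)")
  nelec <- get_field("NELEC")
  ms2 <- get_field("MS2")
  h <- matrix(0, norb, norb)
  g <- array(0, rep(norb, 4))
  core <- 0
  for (ln in lines[-(1:end_idx)]) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 5) stop("read_fcidump: malformed integral line: ", ln)
    val <- as.numeric(parts[1])
    ijkl <- as.integer(parts[2:5])
    if (any(ijkl > norb))
      stop("read_fcidump: orbital index exceeds NORB in line: ", ln)
    i <- ijkl[1]; j <- ijkl[2]; k <- ijkl[3]; l <- ijkl[4]
    if (i == 0 && j == 0 && k == 0 && l == 0) {
      core <- val
    } else if (k == 0 && l == 0) {
      h[i, j] <- val; h[j, i] <- val
    } else {
      g <- g_set_all(g, i, j, k, l, val)
    }
  }
  integral_table(h, g, core, nelec = nelec, ms2 = ms2)
}

#' Write an FCIDUMP integral file
#'
#' Writes canonical-order representatives (`i >= j`, `k >= l`, pair `(ij)`
#' before `(kl)`) at 16 significant digits, so `read_fcidump(write_fcidump(x))`
#' reproduces the table to printed precision.
#'
#' @param table An [integral_table()].
#' @param path Output file path.
#' @param nelec,ms2 Electron count and 2*m_s for the header (default: values
#'   stored in the table, or 0).
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(table, path, nelec = table$nelec, ms2 = table$ms2) {
  n <- table$n_orb
  if (is.na(nelec)) nelec <- 0L
  if (is.na(ms2)) ms2 <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, nelec, ms2), con)
  writeLines(sprintf(" ORBSYM=%s", paste(rep("1", n), collapse = ",")), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16E %3d %3d %3d %3d", v, i, j, k, l)
  out <- character(0)
  for (i in 1:n) for (j in 1:i) {
    ij <- i * (i - 1) / 2 + j
    for (k in 1:i) for (l in 1:k) {
      kl <- k * (k - 1) / 2 + l
      if (kl > ij) next
      v <- table$g[i, j, k, l]
      if (v != 0) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in 1:n) for (j in 1:i) {
    if (table$h[i, j] != 0) out <- c(out, fmt(table$h[i, j], i, j, 0L, 0L))
  }
  out <- c(out, fmt(table$core_energy, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Random symmetric integral table
#'
#' Generates a reproducible random integral table with a diagonally dominant
#' one-electron part (well-separated orbital energies, so the lowest-filled
#' reference determinant dominates the ground state) and a fully
#' 8-fold-symmetric random two-electron tensor.
#'
#' @param n_orb Number of spatial orbitals (intended for n_orb <= 16).
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @param scale Standard deviation of the random one- and two-electron noise.
#' @return An [integral_table()].
#' @export
synthetic_integrals <- function(n_orb, seed, scale = 0.1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  h <- matrix(stats::rnorm(n_orb^2, sd = scale), n_orb, n_orb)
  h <- (h + t(h)) / 2
  diag(h) <- seq(-2, -2 + 0.5 * (n_orb - 1), by = 0.5)
  g <- array(stats::rnorm(n_orb^4, sd = scale), rep(n_orb, 4))
  g <- symmetrize_g(g)
  # modest positive on-site repulsion keeps the spectrum physical-looking
  for (p in 1:n_orb) g[p, p, p, p] <- abs(g[p, p, p, p]) + 0.5
  integral_table(h, g, core_energy = 0)
}

#' Hubbard-chain integrals
#'
#' Nearest-neighbor hopping `-t` and on-site repulsion `U` in the site basis.
#'
#' @param L Number of sites.
#' @param U On-site repulsion.
#' @param t Hopping amplitude.
#' @param periodic Close the chain into a ring.
#' @return An [integral_table()].
#' @export
hubbard_integrals <- function(L, U, t, periodic = FALSE) {
  h <- matrix(0, L, L)
  for (i in seq_len(L - 1)) h[i, i + 1] <- h[i + 1, i] <- -t
  if (periodic && L > 2) h[1, L] <- h[L, 1] <- -t
  g <- array(0, rep(L, 4))
  for (p in seq_len(L)) g[p, p, p, p] <- U
  integral_table(h, g, core_energy = 0)
}
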