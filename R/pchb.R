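# Precomputed heat-bath (PCHB) excitation generation.
#
# Double excitations (I, J) -> (A, B): particles are drawn uniformly from the
# occupied spin-orbital pairs of the parent determinant; holes are drawn from
# a precomputed alias table whose weights are |H_IJ^AB|.  For GAS, one table
# set is stored per supergroup with weights of GAS-forbidden moves set to
# exactly zero, so forbidden children are never proposed.  Single excitations
# pick the particle uniformly and the hole uniformly over the same-spin
# unoccupied orbitals whose target space keeps the composition allowed
# (implemented as per-(supergroup, source-space) orbital bitmasks).  If a
# sampled hole pair is already occupied in the parent the attempt is
# discarded; the rejection is a normal outcome and part of the probability
# bookkeeping.

pair_tables <- function(nso) {
  P <- nso * (nso - 1L) / 2L
  pairA <- integer(P); pairB <- integer(P)
  rank <- matrix(0L, nso, nso)
  r <- 0L
  for (a in 1:(nso - 1L)) for (b in (a + 1L):nso) {
    r <- r + 1L
    pairA[r] <- a; pairB[r] <- b
    rank[a, b] <- rank[b, a] <- r
  }
  list(P = P, pairA = pairA, pairB = pairB, rank = rank)
}

#' Memory estimate for PCHB probability tables
#'
#' Deterministic formula: (number of ordered index pairs)^2 x number of
#' supergroups x bytes per entry.  Pairs run over spin orbitals by default;
#' `spatial = TRUE` gives the reduced spatial-orbital indexing.
#'
#' @param n_orb Number of spatial orbitals.
#' @param n_sg Number of supergroups.
#' @param bytes_per_entry Width of one stored table entry (default 8:
#'   a 4-byte probability plus a 4-byte alias index).
#' @param spatial Index over spatial instead of spin orbitals.
#' @return Estimated bytes (double).
#' @export
memory_estimate <- function(n_orb, n_sg, bytes_per_entry = 8, spatial = FALSE) {
  P <- if (spatial) n_orb * (n_orb - 1) / 2 + n_orb else n_orb * (2 * n_orb - 1)
  P^2 * n_sg * bytes_per_entry
}

#' Build PCHB excitation-generation tables
#'
#' For every supergroup and every particle spin-orbital pair, an alias table
#' over hole pairs with weights `|H_IJ^AB|` (GAS-forbidden or spin-forbidden
#' moves weighted exactly zero), plus the per-supergroup single-excitation
#' hole bitmasks.  With `gas = FALSE` a single implicit supergroup is used and
#' no move is masked: full-CI PCHB is the single-supergroup special case.
#'
#' @param ints An [integral_table()].
#' @param sg_table A [build_supergroup_table()] result (used when
#'   `gas = TRUE`; its partition is also used to label spaces).
#' @param gas Mask GAS-forbidden moves per supergroup.
#' @param p_double Probability of attempting a double rather than a single
#'   excitation.
#' @param memory_cap_gb Refuse construction if the table memory estimate
#'   exceeds this cap.
#' @return An object of class `pchb_tables`.
#' @export
build_pchb_tables <- function(ints, sg_table = NULL, gas = TRUE,
                              p_double = 0.8, memory_cap_gb = 4) {
  n <- ints$n_orb
  nso <- 2L * n
  pt <- pair_tables(nso)
  P <- pt$P
  n_sg <- if (gas) nrow(sg_table$supergroups) else 1L
  est <- memory_estimate(n, n_sg, bytes_per_entry = 24)
  if (est > memory_cap_gb * 2^30)
    stop(sprintf("build_pchb_tables: estimated %.2f GB exceeds the %.2f GB cap",
                 est / 2^30, memory_cap_gb))
  sp <- function(s) ifelse(s > n, s - n, s)
  isa <- function(s) s <= n
  # base weights |<AB||IJ>| on the full hole-pair x particle-pair grid
  Av <- rep(pt$pairA, times = P); Bv <- rep(pt$pairB, times = P)
  Iv <- rep(pt$pairA, each = P); Jv <- rep(pt$pairB, each = P)
  a0 <- sp(Av); b0 <- sp(Bv); i0 <- sp(Iv); j0 <- sp(Jv)
  t1 <- ifelse(isa(Av) == isa(Iv) & isa(Bv) == isa(Jv),
               ints$g[cbind(a0, i0, b0, j0)], 0)
  t2 <- ifelse(isa(Av) == isa(Jv) & isa(Bv) == isa(Iv),
               ints$g[cbind(a0, j0, b0, i0)], 0)
  w0 <- abs(t1 - t2)
  overlap <- Av == Iv | Av == Jv | Bv == Iv | Bv == Jv
  w0[overlap] <- 0
  W0 <- matrix(w0, P, P)  # rows: hole pairs, cols: particle pairs

  if (gas) {
    partition <- sg_table$partition
    k <- partition$k
    space_of <- partition$orbital_space
    # unordered space-pair class of each spin-orbital pair
    cls <- function(pa, pb) {
      s1 <- space_of[sp(pa)]; s2 <- space_of[sp(pb)]
      (pmin(s1, s2) - 1L) * k + pmax(s1, s2)
    }
    cls_hole <- cls(pt$pairA, pt$pairB)
    cls_part <- cls(pt$pairA, pt$pairB)
    classes <- sort(unique(cls_hole))
    # allowed[class_hole, class_particle, sg]
    allowed <- array(FALSE, c(k * k, k * k, n_sg))
    for (s in seq_len(n_sg)) {
      x <- sg_table$supergroups[s, ]
      for (cp in classes) for (ch in classes) {
        sp1 <- (cp - 1L) %/% k + 1L; sp2 <- (cp - 1L) %% k + 1L
        sh1 <- (ch - 1L) %/% k + 1L; sh2 <- (ch - 1L) %% k + 1L
        xx <- x
        xx[sp1] <- xx[sp1] - 1L; xx[sp2] <- xx[sp2] - 1L
        xx[sh1] <- xx[sh1] + 1L; xx[sh2] <- xx[sh2] + 1L
        allowed[ch, cp, s] <- is_allowed(xx, sg_table$constraints, partition)
      }
    }
  } else {
    partition <- NULL
    k <- 1L
    space_of <- rep(1L, n)
  }

  prob <- array(0, c(P, P, n_sg))
  alias <- array(1L, c(P, P, n_sg))
  pnorm <- array(0, c(P, P, n_sg))
  wtot <- matrix(0, P, n_sg)
  for (s in seq_len(n_sg)) {
    for (pr in seq_len(P)) {
      w <- W0[, pr]
      if (gas) w <- w * allowed[cls_hole, cls_part[pr], s]
      tw <- sum(w)
      wtot[pr, s] <- tw
      if (tw > 0) {
        at <- build_alias(w)
        prob[, pr, s] <- at$prob
        alias[, pr, s] <- at$alias
        pnorm[, pr, s] <- at$p_norm
      }
    }
  }

  # single-excitation hole bitmasks: per (source space, supergroup) the union
  # of spatial orbitals in spaces the composition may move one particle to
  full_mask <- as.integer(2^n - 1)
  space_mask <- vapply(seq_len(k), function(i) {
    as.integer(mask_from_orbs(which(space_of == i)))
  }, integer(1))
  smask <- matrix(full_mask, k, n_sg)
  if (gas) {
    for (s in seq_len(n_sg)) {
      x <- sg_table$supergroups[s, ]
      for (src in seq_len(k)) {
        m <- 0L
        for (tgt in seq_len(k)) {
          xx <- x
          xx[src] <- xx[src] - 1L; xx[tgt] <- xx[tgt] + 1L
          if (is_allowed(xx, sg_table$constraints, partition))
            m <- bitwOr(m, space_mask[tgt])
        }
        smask[src, s] <- m
      }
    }
  }

  structure(list(
    n_orb = n, nso = nso, P = P, n_sg = n_sg, gas = gas,
    pairA = pt$pairA, pairB = pt$pairB, pair_rank = pt$rank,
    prob = prob, alias = alias, pnorm = pnorm, wtot = wtot,
    smask = smask, space_of = space_of, full_mask = full_mask,
    p_double = p_double, sg_table = if (gas) sg_table else NULL,
    h = ints$h, g = ints$g,
    memory_bytes = est
  ), class = "pchb_tables")
}

#' @export
print.pchb_tables <- function(x, ...) {
  cat("PCHB tables:", x$n_orb, "orbitals,", x$n_sg, "supergroup(s),",
      if (x$gas) "GAS-masked," else "unmasked,",
      sprintf("~%.1f MB", x$memory_bytes / 2^20), "\n")
  invisible(x)
}

# parent view used by the vectorized sampler
par_view <- function(amask, bmask, isg, occ) {
  list(amask = as.integer(amask), bmask = as.integer(bmask),
       isg = as.integer(isg), occ = occ)
}

par_from_det <- function(det, tables) {
  isg <- if (tables$gas) {
    supergroup_index(supergroup_of_determinant(det, tables$sg_table$partition),
                     tables$sg_table)
  } else 1L
  par_view(det$alpha, det$beta, isg, matrix(det_occ_so(det), nrow = 1))
}

# Batch proposal kernel (compiled).  One row per attempt; columns describe
# the sampled excitation, its exact generation probability, the Hamiltonian
# matrix element (with fermionic phase), and the rejection status:
# reason 0 = proposed, 1 = sampled hole already occupied, 2 = no allowed
# single-excitation hole, 3 = zero-weight particle-pair row.
pchb_propose <- function(tables, par, pidx, kind = NULL) {
  rm <- range_masks(tables$n_orb)
  kf <- if (is.null(kind)) 0L else if (kind == "double") 1L else 2L
  cpp_pchb_propose(tables, par$amask, par$bmask, par$isg, par$occ,
                   as.integer(pidx), kf, rm$ra, rm$rb)
}

# Pure-R reference implementation of the proposal kernel; retained as the
# cross-check for the compiled path (they share the tables but consume the
# RNG differently, so they are compared distributionally, not draw-by-draw).
pchb_propose_r <- function(tables, par, pidx, kind = NULL) {
  n <- tables$n_orb
  nel <- ncol(par$occ)
  nat <- length(pidx)
  M <- tables$P; P <- tables$P
  out <- list(parent = pidx,
              kind = integer(nat), valid = logical(nat), reason = integer(nat),
              I = rep(NA_integer_, nat), J = rep(NA_integer_, nat),
              A = rep(NA_integer_, nat), B = rep(NA_integer_, nat),
              child_a = integer(nat), child_b = integer(nat),
              pgen = numeric(nat), hmat = numeric(nat), phase = integer(nat))
  if (nat == 0) return(out)
  isd <- if (is.null(kind)) stats::runif(nat) < tables$p_double
         else rep(kind == "double", nat)
  out$kind <- 2L - as.integer(isd)
  # bit of the spatial orbital underlying spin orbital s, s in 1..2n
  bitlut <- as.integer(2^(c(0:(n - 1L), 0:(n - 1L))))
  occ_test <- function(rows, s) {
    a <- s <= n
    m <- as.integer(par$amask[rows] * a + par$bmask[rows] * (!a))
    bitwAnd(m, bitlut[s]) != 0L
  }

  d <- which(isd)
  if (length(d) > 0) {
    nd <- length(d)
    pd <- pidx[d]
    r1 <- 1L + as.integer(floor(stats::runif(nd) * nel))
    r2 <- 1L + as.integer(floor(stats::runif(nd) * (nel - 1L)))
    r2 <- r2 + (r2 >= r1)
    I0 <- par$occ[cbind(pd, r1)]; J0 <- par$occ[cbind(pd, r2)]
    I <- pmin(I0, J0); J <- pmax(I0, J0)
    pr <- tables$pair_rank[cbind(I, J)]
    sg <- par$isg[pd]
    wt <- tables$wtot[cbind(pr, sg)]
    ok_row <- wt > 0
    slot <- 1L + as.integer(floor(stats::runif(nd) * M))
    flat <- slot + M * (pr - 1) + M * P * (sg - 1)
    u <- stats::runif(nd)
    hp <- slot
    sw <- u >= tables$prob[flat]
    hp[sw] <- tables$alias[flat][sw]
    A <- tables$pairA[hp]; B <- tables$pairB[hp]
    occA <- occ_test(pd, A); occB <- occ_test(pd, B)
    v <- ok_row & !occA & !occB
    rs <- integer(nd)
    rs[occA | occB] <- 1L
    rs[!ok_row] <- 3L
    out$reason[d] <- rs
    out$valid[d] <- v
    out$I[d] <- I; out$J[d] <- J; out$A[d] <- A; out$B[d] <- B
    pg <- tables$p_double * (2 / (nel * (nel - 1))) *
      tables$pnorm[hp + M * (pr - 1) + M * P * (sg - 1)]
    out$pgen[d] <- pg * ok_row
    if (any(v)) {
      dv <- d[v]; pdv <- pd[v]
      Iv <- I[v]; Jv <- J[v]; Av <- A[v]; Bv <- B[v]
      spf <- function(s) s - n * (s > n)
      i0 <- spf(Iv); j0 <- spf(Jv); a0 <- spf(Av); b0 <- spf(Bv)
      sI <- Iv <= n; sJ <- Jv <= n; sA <- Av <= n; sB <- Bv <= n
      t1 <- (sA == sI & sB == sJ) * tables$g[cbind(a0, i0, b0, j0)]
      t2 <- (sA == sJ & sB == sI) * tables$g[cbind(a0, j0, b0, i0)]
      am <- par$amask[pdv]; bm <- par$bmask[pdv]
      ph1 <- n_between(am, bm, Iv, Av, n)
      lo <- pmin(Jv, Bv); hi <- pmax(Jv, Bv)
      adj <- as.integer(Iv > lo & Iv < hi) - as.integer(Av > lo & Av < hi)
      ph2 <- n_between(am, bm, Jv, Bv, n) - adj
      phv <- 1L - 2L * as.integer((ph1 + ph2) %% 2)
      out$phase[dv] <- phv
      out$hmat[dv] <- phv * (t1 - t2)
      da <- -(sI) * 2^(i0 - 1) - (sJ) * 2^(j0 - 1) +
        (sA) * 2^(a0 - 1) + (sB) * 2^(b0 - 1)
      db <- -(!sI) * 2^(i0 - 1) - (!sJ) * 2^(j0 - 1) +
        (!sA) * 2^(a0 - 1) + (!sB) * 2^(b0 - 1)
      out$child_a[dv] <- as.integer(am + da)
      out$child_b[dv] <- as.integer(bm + db)
    }
  }

  s <- which(!isd)
  if (length(s) > 0) {
    ns <- length(s)
    ps <- pidx[s]
    r <- 1L + as.integer(floor(stats::runif(ns) * nel))
    I <- par$occ[cbind(ps, r)]
    alf <- I <= n
    i0 <- I - n * (!alf)
    src <- tables$space_of[i0]
    sg <- par$isg[ps]
    sm <- tables$smask[cbind(src, sg)]
    occ_sigma <- as.integer(par$amask[ps] * alf + par$bmask[ps] * (!alf))
    cand <- bitwAnd(sm, bitwAnd(bitwNot(occ_sigma), tables$full_mask))
    Ntil <- mask_popcount(cand)
    ok <- Ntil > 0L
    rr <- 1L + as.integer(floor(stats::runif(ns) * pmax(Ntil, 1L)))
    sel <- integer(ns); cnt <- integer(ns)
    for (b in seq_len(n)) {
      bit <- bitwAnd(cand, as.integer(2^(b - 1))) != 0L
      cnt <- cnt + bit
      sel <- sel + b * (bit & cnt == rr & sel == 0L)
    }
    a0 <- sel
    A <- a0 + n * (!alf)
    out$reason[s] <- 2L * (!ok)
    out$valid[s] <- ok
    out$I[s] <- I; out$A[s] <- A
    out$pgen[s] <- ok * (1 - tables$p_double) / (nel * Ntil)
    if (any(ok)) {
      sv <- s[ok]; psv <- ps[ok]
      Ivv <- I[ok]; Avv <- A[ok]
      i0v <- i0[ok]; a0v <- a0[ok]; alfv <- alf[ok]
      val <- tables$h[cbind(a0v, i0v)]
      for (e in seq_len(nel)) {
        Pso <- par$occ[cbind(psv, e)]
        p0 <- Pso - n * (Pso > n)
        val <- val + tables$g[cbind(a0v, i0v, p0, p0)]
        same <- (Pso <= n) == alfv
        val <- val - same * tables$g[cbind(a0v, p0, p0, i0v)]
      }
      am <- par$amask[psv]; bm <- par$bmask[psv]
      ph <- n_between(am, bm, Ivv, Avv, n)
      phv <- 1L - 2L * as.integer(ph %% 2)
      out$phase[sv] <- phv
      out$hmat[sv] <- phv * val
      delta <- 2^(a0v - 1) - 2^(i0v - 1)
      out$child_a[sv] <- as.integer(am + alfv * delta)
      out$child_b[sv] <- as.integer(bm + (!alfv) * delta)
    }
  }
  out
}

event_row <- function(ev, i, n_orb) {
  if (!ev$valid[i]) {
    return(structure(list(rejected = TRUE, reason = ev$reason[i],
                          kind = c("double", "single")[ev$kind[i]],
                          pgen = ev$pgen[i]),
                     class = "excitation_event"))
  }
  structure(list(rejected = FALSE,
                 kind = c("double", "single")[ev$kind[i]],
                 I = ev$I[i], J = ev$J[i], A = ev$A[i], B = ev$B[i],
                 child = det_from_masks(ev$child_a[i], ev$child_b[i], n_orb),
                 pgen = ev$pgen[i], hmat = ev$hmat[i], phase = ev$phase[i]),
            class = "excitation_event")
}

#' Sample a double excitation from a determinant
#'
#' Particles uniform over occupied spin-orbital pairs, holes from the
#' per-supergroup alias table.  If the sampled holes are occupied in the
#' parent the attempt is returned as a rejection (a normal outcome).
#'
#' @param det Parent determinant (must be GAS allowed for GAS tables).
#' @param tables A [build_pchb_tables()] result.
#' @return An `excitation_event`: either `rejected = TRUE` with a reason, or
#'   the orbital indices, child determinant, matrix element and exact
#'   generation probability `pgen` (which includes the probability of
#'   attempting a double and of drawing the particle pair).
#' @export
sample_double <- function(det, tables) {
  par <- par_from_det(det, tables)
  ev <- pchb_propose(tables, par, 1L, kind = "double")
  event_row(ev, 1L, tables$n_orb)
}

#' Sample a single excitation from a determinant
#'
#' Particle uniform over occupied spin orbitals; hole uniform over the
#' same-spin unoccupied orbitals whose target space keeps the composition GAS
#' allowed (per-supergroup bitmasks); `pgen` includes the normalizer (number
#' of allowed holes).
#'
#' @inheritParams sample_double
#' @return An `excitation_event` (see [sample_double()]).
#' @export
sample_single <- function(det, tables) {
  par <- par_from_det(det, tables)
  ev <- pchb_propose(tables, par, 1L, kind = "single")
  event_row(ev, 1L, tables$n_orb)
}

#' Exact generation probability of an excitation event
#'
#' Recomputes the probability that the generator assigns to the move stored
#' in `event` when starting from `det`; 0 for unreachable (e.g. GAS
#' forbidden) events.
#'
#' @param det Parent determinant.
#' @param event An `excitation_event`, or a list with fields `kind` and
#'   orbital indices `I`, `A` (and `J`, `B` for doubles) in spin-orbital
#'   numbering.
#' @param tables A [build_pchb_tables()] result.
#' @return The generation probability (double in `[0, 1]`).
#' @export
pgen <- function(det, event, tables) {
  n <- tables$n_orb
  par <- par_from_det(det, tables)
  nel <- ncol(par$occ)
  occ_test1 <- function(sx) {
    if (sx <= n) bitwAnd(par$amask, as.integer(2^(sx - 1))) != 0L
    else bitwAnd(par$bmask, as.integer(2^(sx - n - 1))) != 0L
  }
  if (event$kind == "double") {
    I <- min(event$I, event$J); J <- max(event$I, event$J)
    A <- min(event$A, event$B); B <- max(event$A, event$B)
    if (!occ_test1(I) || !occ_test1(J) || occ_test1(A) || occ_test1(B)) return(0)
    pr <- tables$pair_rank[I, J]
    hp <- tables$pair_rank[A, B]
    sg <- par$isg
    if (tables$wtot[pr, sg] == 0) return(0)
    tables$p_double * (2 / (nel * (nel - 1))) * tables$pnorm[hp, pr, sg]
  } else {
    I <- event$I; A <- event$A
    if (!occ_test1(I) || occ_test1(A)) return(0)
    if ((I <= n) != (A <= n)) return(0)
    i0 <- if (I <= n) I else I - n
    a0 <- if (A <= n) A else A - n
    sm <- tables$smask[tables$space_of[i0], par$isg]
    occ_sigma <- if (I <= n) par$amask else par$bmask
    cand <- bitwAnd(sm, bitwAnd(bitwNot(occ_sigma), tables$full_mask))
    if (bitwAnd(cand, as.integer(2^(a0 - 1))) == 0L) return(0)
    Ntil <- mask_popcount(cand)
    (1 - tables$p_double) / (nel * Ntil)
  }
}

#' Discarding baseline generator
#'
#' Proposes with unmasked full-CI PCHB tables and discards GAS-forbidden
#' children a posteriori.
#'
#' @param det Parent determinant.
#' @param fci_tables Tables built with `gas = FALSE`.
#' @param sg_table Supergroup table defining the GAS constraints.
#' @return An `excitation_event`; rejections carry `reason = "gas_forbidden"`
#'   when the proposed child left the allowed space.
#' @export
discarding_generator <- function(det, fci_tables, sg_table) {
  ev <- sample_excitation(det, fci_tables)
  if (ev$rejected) return(ev)
  x <- supergroup_of_determinant(ev$child, sg_table$partition)
  if (!is_allowed(x, sg_table$constraints, sg_table$partition)) {
    return(structure(list(rejected = TRUE, reason = "gas_forbidden",
                          kind = ev$kind, pgen = ev$pgen),
                     class = "excitation_event"))
  }
  ev
}

#' Sample an excitation (double or single, by the configured p_double)
#'
#' @inheritParams sample_double
#' @return An `excitation_event`.
#' @export
sample_excitation <- function(det, tables) {
  par <- par_from_det(det, tables)
  ev <- pchb_propose(tables, par, 1L)
  event_row(ev, 1L, tables$n_orb)
}
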