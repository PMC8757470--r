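# FCIQMC: stochastic imaginary-time propagation of signed integer walkers.
#
# One iteration applies 1 - dtau (K - S) stochastically: spawning along
# sampled excitations with acceptance dtau |K_ij| / p_gen (multiplicity > 1
# allowed), a diagonal death/clone step with probability dtau (K_jj - S), and
# annihilation of opposite-sign spawns.  K = H - E_ref 1 with E_ref the
# diagonal element of the initial reference determinant, so the stationary
# shift S approaches the correlation energy.  Optional refinements: initiator
# spawning restriction, adaptive (per-determinant) shift, and semistochastic
# deterministic propagation of a core space.

#' FCIQMC dynamics configuration
#'
#' @param time_step Imaginary-time step; `NULL` picks 0.9 / max(|K|/p_gen)
#'   from a warm-up scan of proposals off the reference and freezes it.
#' @param target_population Walker number the shift update holds.
#' @param initial_population Walkers placed on the reference at start
#'   (default: the target population).
#' @param shift_damping Damping zeta of the shift update.
#' @param shift_interval Iterations A between shift updates.
#' @param initiator Enable the initiator restriction.
#' @param n_add Initiator population threshold.
#' @param adaptive Enable the adaptive shift (implies initiator accounting).
#' @param adaptive_offset_frac Offset Delta as a fraction of the current
#'   shift: 1 recovers conventional initiator FCIQMC, 0 applies the full
#'   correction, 0.5 is the recommended midpoint.
#' @param f_halflife Half-life (iterations) of the exponential forgetting in
#'   the accepted/total spawn-weight ratio f_i.
#' @param core_space_size Semistochastic core size (0 disables).
#' @param ss_start Iteration at which the core space is selected (default:
#'   80 after entering variable-shift mode).
#' @param p_double Probability of attempting a double excitation.
#' @param max_iter Number of iterations.
#' @param equilibration Iterations discarded by the energy estimator
#'   (default: variable-shift start plus 25% of the remainder).
#' @param generator `"gas-pchb"`, `"fci-pchb"`, or `"discarding"` (full-CI
#'   proposals with a posteriori rejection of GAS-forbidden children).
#' @param rdm_sample Accumulate stochastic RDMs.
#' @param rdm_start First RDM sampling iteration (default: equilibration).
#' @param debug_assert_gas Assert after every iteration that no occupied
#'   determinant violates the GAS constraints.
#' @param ref_switch_factor,ref_switch_patience Switch the reference when
#'   another determinant's population exceeds the reference's by this factor
#'   for this many consecutive iterations.
#' @param memory_cap_gb Cap passed to [build_pchb_tables()].
#' @return A list of class `dynamics_config`.
#' @export
dynamics_config <- function(time_step = NULL, target_population = 1e4,
                            initial_population = NULL,
                            shift_damping = 0.05, shift_interval = 5L,
                            initiator = FALSE, n_add = 3,
                            adaptive = FALSE, adaptive_offset_frac = 1,
                            f_halflife = 200,
                            core_space_size = 0L, ss_start = NULL,
                            p_double = 0.8, max_iter = 2000L,
                            equilibration = NULL,
                            generator = c("gas-pchb", "fci-pchb", "discarding"),
                            rdm_sample = FALSE, rdm_start = NULL,
                            debug_assert_gas = FALSE,
                            ref_switch_factor = 1.5,
                            ref_switch_patience = 100L,
                            memory_cap_gb = 4) {
  generator <- match.arg(generator)
  if (is.null(initial_population))
    initial_population <- max(50, target_population / 5)
  stopifnot(is.null(time_step) || time_step > 0)
  structure(as.list(environment()), class = "dynamics_config")
}

# ---- walker store ----------------------------------------------------------

store_empty <- function(ints, tables, sg_table, nel) {
  list(ints = ints, tables = tables, sg_table = sg_table, nel = nel,
       n_orb = ints$n_orb,
       key = numeric(0), amask = integer(0), bmask = integer(0),
       pop = numeric(0), isg = integer(0), diag = numeric(0),
       h0j = numeric(0), occm = matrix(0L, 0, nel),
       is_core = logical(0),
       facc = numeric(0), ftot = numeric(0),
       ref_key = NA_real_, E_ref = NA_real_, ref_idx = NA_integer_)
}

store_meta <- function(store, amask, bmask) {
  n <- store$n_orb
  m <- length(amask)
  isg <- integer(m); diag <- numeric(m); h0j <- numeric(m)
  occm <- matrix(0L, m, store$nel)
  ref <- det_from_masks(key_alpha(store$ref_key), key_beta(store$ref_key), n)
  for (i in seq_len(m)) {
    d <- det_from_masks(amask[i], bmask[i], n)
    isg[i] <- if (store$tables$gas) {
      supergroup_index(supergroup_of_determinant(d, store$sg_table$partition),
                       store$sg_table)
    } else 1L
    diag[i] <- diagonal_element(d, store$ints)
    h0j[i] <- if (det_key(amask[i], bmask[i]) == store$ref_key) 0
              else matrix_element(ref, d, store$ints)
    occm[i, ] <- det_occ_so(d)
  }
  list(isg = isg, diag = diag, h0j = h0j, occm = occm)
}

store_add <- function(store, amask, bmask, pop) {
  meta <- store_meta(store, amask, bmask)
  store$key <- c(store$key, det_key(amask, bmask))
  store$amask <- c(store$amask, as.integer(amask))
  store$bmask <- c(store$bmask, as.integer(bmask))
  store$pop <- c(store$pop, pop)
  store$isg <- c(store$isg, meta$isg)
  store$diag <- c(store$diag, meta$diag)
  store$h0j <- c(store$h0j, meta$h0j)
  store$occm <- rbind(store$occm, meta$occm)
  store$is_core <- c(store$is_core, logical(length(amask)))
  store$facc <- c(store$facc, numeric(length(amask)))
  store$ftot <- c(store$ftot, numeric(length(amask)))
  store$ref_idx <- match(store$ref_key, store$key)
  store
}

store_total <- function(store) sum(abs(store$pop))

# drop zero-population entries (the reference and core entries are retained)
store_compact <- function(store) {
  keep <- store$pop != 0 | store$key == store$ref_key | store$is_core
  if (all(keep)) return(store)
  for (f in c("key", "amask", "bmask", "pop", "isg", "diag", "h0j",
              "is_core", "facc", "ftot"))
    store[[f]] <- store[[f]][keep]
  store$occm <- store$occm[keep, , drop = FALSE]
  store$ref_idx <- match(store$ref_key, store$key)
  store
}

# ---- elementary steps ------------------------------------------------------

#' Spawning step
#'
#' Each walker attempts one excitation; a proposal is accepted with
#' probability `dtau |K_ij| / p_gen` (stochastically rounded, multiplicity
#' above one allowed), with the child's sign set by the parent sign and
#' `-sign(K_ij)`.  With the initiator restriction on, spawns from parents
#' below `n_add` onto unoccupied determinants are vetoed.
#'
#' @param store A walker store (see [fciqmc()]).
#' @param tables A [build_pchb_tables()] result.
#' @param cfg A [dynamics_config()] (fields `time_step`, `initiator`,
#'   `n_add`, `generator` are used).
#' @return A list: `buffer` (child masks and signed spawn counts), `events`
#'   (every proposal with p_gen, matrix element, validity, acceptance), and
#'   counts of GAS rejections for the discarding generator.
#' @export
spawn_step <- function(store, tables, cfg) {
  pops <- store$pop
  fl <- floor(abs(pops))
  natt <- as.integer(fl + (stats::runif(length(pops)) < (abs(pops) - fl)))
  pidx <- rep.int(seq_along(pops), natt)
  par <- par_view(store$amask, store$bmask, store$isg, store$occm)
  ev <- pchb_propose(tables, par, pidx)
  nat <- length(pidx)
  gas_rejected <- 0L
  valid <- ev$valid
  if (cfg$generator == "discarding" && any(valid)) {
    sgp <- store$sg_table$partition
    vv <- which(valid)
    # vectorized allowed-composition test: per-space popcounts encoded into a
    # single code, looked up in the set of allowed supergroup codes
    k <- sgp$k
    base <- 2 * store$nel + 1
    smasks <- vapply(seq_len(k), function(i) {
      as.integer(mask_from_orbs(which(sgp$orbital_space == i)))
    }, integer(1))
    code <- numeric(length(vv))
    for (i in seq_len(k)) {
      cnt <- mask_popcount(bitwAnd(ev$child_a[vv], smasks[i])) +
        mask_popcount(bitwAnd(ev$child_b[vv], smasks[i]))
      code <- code * base + cnt
    }
    sg <- store$sg_table$supergroups
    allowed_codes <- as.numeric(sg %*% base^((k - 1):0))
    okg <- code %in% allowed_codes
    gas_rejected <- sum(!okg)
    valid[vv[!okg]] <- FALSE
  }
  p_acc <- numeric(nat)
  p_acc[valid] <- cfg$time_step * abs(ev$hmat[valid]) / ev$pgen[valid]
  nsp <- floor(p_acc) + (stats::runif(nat) < (p_acc - floor(p_acc)))
  accepted <- valid & nsp > 0
  if (cfg$initiator && any(accepted)) {
    child_key <- det_key(ev$child_a, ev$child_b)
    occupied <- child_key %in% store$key[store$pop != 0]
    keep <- initiator_filter(store$pop[ev$parent], occupied, cfg)
    accepted <- accepted & keep
  }
  sgn <- -sign(ev$hmat) * sign(store$pop[ev$parent])
  idx <- which(accepted)
  list(buffer = list(alpha = ev$child_a[idx], bmask = ev$child_b[idx],
                     key = det_key(ev$child_a[idx], ev$child_b[idx]),
                     count = sgn[idx] * nsp[idx],
                     parent = ev$parent[idx]),
       events = ev, n_attempts = nat, nspawn = nsp, accepted = accepted,
       gas_rejected = gas_rejected)
}

#' Initiator filter
#'
#' @param parent_population Signed parent populations.
#' @param child_occupied Logical: is the child determinant already occupied.
#' @param cfg A [dynamics_config()] (field `n_add`).
#' @return Logical vector: `TRUE` = spawn allowed.
#' @export
initiator_filter <- function(parent_population, child_occupied, cfg) {
  !(abs(parent_population) < cfg$n_add & !child_occupied)
}

#' Diagonal death/cloning step
#'
#' Each walker dies with probability `dtau (K_jj - S_j)` (binomially sampled
#' per determinant); a negative probability clones.  Semistochastic core
#' determinants are skipped (their diagonal update is exact).
#'
#' @param store A walker store.
#' @param S Shift: scalar, or per-determinant vector (adaptive shift).
#' @param cfg A [dynamics_config()].
#' @return The updated store.
#' @export
death_step <- function(store, S, cfg) {
  idx <- which(!store$is_core & store$pop != 0)
  if (length(idx) == 0) return(store)
  K <- store$diag[idx] - store$E_ref
  Sv <- if (length(S) == 1) rep(S, length(idx)) else S[idx]
  p <- cfg$time_step * (K - Sv)
  if (any(abs(p) > 1))
    warning("death_step: |dtau (K_jj - S)| > 1; the time step is too large",
            call. = FALSE)
  size <- as.integer(round(abs(store$pop[idx])))
  dies <- integer(length(idx))
  pos <- p > 0
  if (any(pos))
    dies[pos] <- stats::rbinom(sum(pos), size[pos], pmin(p[pos], 1))
  if (any(!pos))
    dies[!pos] <- -stats::rbinom(sum(!pos), size[!pos], pmin(-p[!pos], 1))
  store$pop[idx] <- store$pop[idx] - sign(store$pop[idx]) * dies
  store
}

#' Annihilation step
#'
#' Signed spawns onto the same determinant are summed and merged into the
#' store; newly occupied determinants get their supergroup index, diagonal
#' element and reference coupling computed once.
#'
#' @param store A walker store.
#' @param buffer The `buffer` element of a [spawn_step()] result.
#' @return The updated store.
#' @export
annihilate <- function(store, buffer) {
  if (length(buffer$key) == 0) return(store_compact(store))
  agg <- rowsum(buffer$count, group = buffer$key)
  keys <- as.numeric(rownames(agg))
  counts <- agg[, 1]
  pos <- match(keys, store$key)
  hit <- !is.na(pos)
  store$pop[pos[hit]] <- store$pop[pos[hit]] + counts[hit]
  if (any(!hit)) {
    new_first <- match(keys[!hit], buffer$key)
    store <- store_add(store, buffer$alpha[new_first], buffer$bmask[new_first],
                       counts[!hit])
  }
  store_compact(store)
}

#' Shift update for population control
#'
#' Damped update `S <- S - zeta/(A dtau) log(N_w(t)/N_w(t - A dtau))`.
#'
#' @param S Current shift.
#' @param nw_now,nw_prev Walker counts now and one update interval ago.
#' @param cfg A [dynamics_config()].
#' @return The updated shift.
#' @export
update_shift <- function(S, nw_now, nw_prev, cfg) {
  S - cfg$shift_damping / (cfg$shift_interval * cfg$time_step) *
    log(nw_now / nw_prev)
}

#' Per-determinant adaptive shift
#'
#' `S_i = Delta + f_i (S - Delta)` with `f_i` the accumulated ratio of
#' initiator-accepted to total spawn weight (first-order perturbation-theory
#' weights `|H_ji| / (H_jj - E)`).  `Delta = S` recovers the conventional
#' initiator algorithm; `Delta = 0` applies the full correction.
#'
#' @param store A walker store carrying `facc`/`ftot` accumulators.
#' @param S Global shift.
#' @param cfg A [dynamics_config()] (field `adaptive_offset_frac`).
#' @return Vector of per-determinant shifts, aligned with the store.
#' @export
adaptive_shift <- function(store, S, cfg) {
  Delta <- cfg$adaptive_offset_frac * S
  f <- ifelse(store$ftot > 0, store$facc / store$ftot, 1)
  f <- pmin(pmax(f, 0), 1)
  Delta + f * (S - Delta)
}

#' Deterministic propagation of the semistochastic core
#'
#' Applies `1 - dtau (H_core - (E_ref + S) 1)` exactly to the core
#' amplitudes.  Core-to-core stochastic spawns must have been excluded by the
#' caller (the driver drops them), so couplings inside the core are handled
#' exactly once.
#'
#' @param store A walker store with `is_core` flags set.
#' @param core_H Dense Hamiltonian over the core determinants (order given by
#'   `which(store$is_core)`).
#' @param S Current shift.
#' @param cfg A [dynamics_config()].
#' @return The updated store.
#' @export
semistochastic_project <- function(store, core_H, S, cfg) {
  idx <- which(store$is_core)
  c0 <- store$pop[idx]
  K <- core_H - diag(store$E_ref + S, length(idx))
  store$pop[idx] <- c0 - cfg$time_step * as.numeric(K %*% c0)
  store
}

# ---- driver ----------------------------------------------------------------

pick_reference <- function(partition, ints, sg_table, m_s, cap = 5e4) {
  basis <- tryCatch(enumerate_determinants(partition, sg_table, m_s, cap = cap),
                    error = function(e) NULL)
  if (!is.null(basis)) {
    diags <- vapply(seq_along(basis$alpha), function(i) {
      diagonal_element(basis_det(basis, i), ints)
    }, numeric(1))
    i <- which.min(diags)
    return(basis_det(basis, i))
  }
  N <- sg_table$N
  n_alpha <- (N + 2 * m_s) / 2
  determinant(seq_len(n_alpha), seq_len(N - n_alpha), ints$n_orb)
}

auto_time_step <- function(ref, tables, n_scan = 500) {
  par <- par_from_det(ref, tables)
  ev <- pchb_propose(tables, par, rep(1L, n_scan))
  ok <- ev$valid & ev$pgen > 0 & ev$hmat != 0
  ratio <- abs(ev$hmat[ok]) / ev$pgen[ok]
  dtau <- if (any(ok)) 0.9 / max(ratio) else 1e-3
  # keep the diagonal death probability comfortably below one as well
  min(dtau, 0.05)
}

#' Run FCIQMC dynamics
#'
#' Propagates signed integer walkers under the GAS-masked (or full-CI)
#' Hamiltonian with PCHB excitation generation.  The shift is held constant
#' until the target population is reached and then varied to keep it fixed;
#' the projected energy is accumulated as separate numerator/denominator
#' series and resolved by [projected_energy()].
#'
#' @param ints An [integral_table()].
#' @param sg_table A [build_supergroup_table()] result (a one-space partition
#'   gives full CI).
#' @param m_s Spin projection.
#' @param config A [dynamics_config()].
#' @param tables Optional prebuilt [build_pchb_tables()]; by default built
#'   according to `config$generator`.
#' @param reference Optional reference determinant; by default the
#'   lowest-diagonal determinant of the enumerated space.
#' @return An object of class `fciqmc_run` with the per-iteration `series`
#'   (shift, walker number, energy numerator/denominator, reference
#'   population), the final `store`, `energy` (from [projected_energy()]),
#'   the frozen `time_step`, and diagnostic counters.
#' @export
fciqmc <- function(ints, sg_table, m_s, config = dynamics_config(),
                   tables = NULL, reference = NULL) {
  cfg <- config
  partition <- sg_table$partition
  if (is.null(tables)) {
    tables <- build_pchb_tables(ints, sg_table,
                                gas = (cfg$generator == "gas-pchb"),
                                p_double = cfg$p_double,
                                memory_cap_gb = cfg$memory_cap_gb)
  }
  if (is.null(reference))
    reference <- pick_reference(partition, ints, sg_table, m_s)
  nel <- sg_table$N
  store <- store_empty(ints, tables, sg_table, nel)
  store$ref_key <- det_key(reference$alpha, reference$beta)
  store$E_ref <- diagonal_element(reference, ints)
  store <- store_add(store, as.integer(reference$alpha),
                     as.integer(reference$beta),
                     round(cfg$initial_population))
  if (is.null(cfg$time_step)) cfg$time_step <- auto_time_step(reference, tables)

  S <- 0
  vary <- FALSE
  vary_iter <- NA_integer_
  nw_hist <- store_total(store)
  lambda <- 0.5^(1 / cfg$f_halflife)
  switch_count <- 0L
  switch_iter <- 0L
  core_H <- NULL
  ss_start <- if (is.null(cfg$ss_start)) Inf else cfg$ss_start
  rdm <- NULL

  n_it <- cfg$max_iter
  series <- data.frame(iter = seq_len(n_it), S = NA_real_, N_w = NA_real_,
                       num = NA_real_, denom = NA_real_, N_ref = NA_real_,
                       n_occ = NA_integer_)
  total_gas_rejected <- 0L

  for (it in seq_len(n_it)) {
    # semistochastic core selection
    if (cfg$core_space_size > 0 && is.null(core_H) &&
        ((vary && it >= vary_iter + 80) || it >= ss_start)) {
      ord <- order(-abs(store$pop), store$key)
      core_idx <- ord[seq_len(min(cfg$core_space_size, length(ord)))]
      store$is_core[core_idx] <- TRUE
      core_dets <- lapply(which(store$is_core), function(i) {
        det_from_masks(store$amask[i], store$bmask[i], store$n_orb)
      })
      core_H <- core_hamiltonian(core_dets, ints,
                                 if (tables$gas) sg_table else NULL)
    }

    sp <- spawn_step(store, tables, cfg)
    total_gas_rejected <- total_gas_rejected + sp$gas_rejected
    buf <- sp$buffer
    if (!is.null(core_H) && length(buf$key) > 0) {
      # drop core -> core spawns: that block is propagated exactly
      core_keys <- store$key[store$is_core]
      drop <- store$is_core[buf$parent] & buf$key %in% core_keys
      if (any(drop)) {
        for (f in c("alpha", "bmask", "key", "count", "parent"))
          buf[[f]] <- buf[[f]][!drop]
      }
    }
    if (cfg$adaptive) {
      ev <- sp$events
      vi <- which(ev$valid)
      if (length(vi) > 0) {
        den <- pmax(store$diag[ev$parent[vi]] - store$E_ref - S, 0.5)
        w <- abs(ev$hmat[vi]) / den
        store$facc <- store$facc * lambda
        store$ftot <- store$ftot * lambda
        tot <- rowsum(w, group = ev$parent[vi])
        rows <- as.integer(rownames(tot))
        store$ftot[rows] <- store$ftot[rows] + tot[, 1]
        accv <- sp$accepted[vi]
        if (any(accv)) {
          acc <- rowsum(w[accv], group = ev$parent[vi][accv])
          rows <- as.integer(rownames(acc))
          store$facc[rows] <- store$facc[rows] + acc[, 1]
        }
      }
    }
    if (cfg$rdm_sample && !is.null(rdm)) {
      rdm <- rdm_accumulate(rdm, store, sp$events, tables$n_orb)
    }

    S_death <- S
    if (cfg$adaptive && cfg$initiator) {
      Si <- adaptive_shift(store, S, cfg)
      # initiators keep the global shift; non-initiators the reduced one
      ini <- abs(store$pop) >= cfg$n_add
      S_death <- ifelse(ini, S, Si)
    }
    if (!is.null(core_H))
      store <- semistochastic_project(store, core_H, S, cfg)
    store <- death_step(store, S_death, cfg)
    store <- annihilate(store, buf)

    nw <- store_total(store)
    ref_i <- store$ref_idx
    num <- sum(store$h0j * store$pop)
    denom <- if (!is.na(ref_i)) store$pop[ref_i] else 0
    series$S[it] <- S; series$N_w[it] <- nw
    series$num[it] <- num; series$denom[it] <- denom
    series$N_ref[it] <- denom
    series$n_occ[it] <- sum(store$pop != 0)

    if (!vary && nw >= cfg$target_population && it > cfg$shift_interval) {
      vary <- TRUE
      vary_iter <- it
      # initialize the shift at the instantaneous growth rate so the
      # population stabilizes immediately instead of overshooting
      prev <- series$N_w[it - cfg$shift_interval]
      S <- -log(nw / prev) / (cfg$shift_interval * cfg$time_step)
      if (is.null(cfg$rdm_start)) cfg$rdm_start <- it + 100
    }
    if (vary && it > vary_iter && (it - vary_iter) %% cfg$shift_interval == 0) {
      prev <- series$N_w[it - cfg$shift_interval]
      S <- update_shift(S, nw, prev, cfg)
    }
    if (cfg$rdm_sample && is.null(rdm) &&
        !is.null(cfg$rdm_start) && it >= cfg$rdm_start) {
      rdm <- rdm_acc_new(tables$n_orb)
    }

    # reference switching
    if (!is.na(ref_i)) {
      mx <- which.max(abs(store$pop))
      if (mx != ref_i &&
          abs(store$pop[mx]) > cfg$ref_switch_factor * abs(store$pop[ref_i])) {
        switch_count <- switch_count + 1L
      } else switch_count <- 0L
      if (switch_count >= cfg$ref_switch_patience) {
        new_ref <- det_from_masks(store$amask[mx], store$bmask[mx], store$n_orb)
        store$ref_key <- store$key[mx]
        store$E_ref <- store$E_ref  # K is pinned to the original offset
        for (i in seq_along(store$key)) {
          d <- det_from_masks(store$amask[i], store$bmask[i], store$n_orb)
          store$h0j[i] <- if (i == mx) 0 else matrix_element(new_ref, d, ints)
        }
        store$ref_idx <- mx
        switch_count <- 0L
        switch_iter <- it
      }
    }

    if (cfg$debug_assert_gas && tables$gas) {
      for (i in which(store$pop != 0)) {
        x <- supergroup_of_determinant(
          det_from_masks(store$amask[i], store$bmask[i], store$n_orb), partition)
        if (!is_allowed(x, sg_table$constraints, partition))
          stop("GAS closure violated at iteration ", it)
      }
    }
  }

  if (is.null(cfg$equilibration)) {
    vs <- if (is.na(vary_iter)) round(n_it / 2) else vary_iter
    cfg$equilibration <- min(n_it - 64, vs + round((n_it - vs) * 0.25))
  }
  cfg$equilibration <- max(cfg$equilibration, switch_iter)
  run <- structure(list(series = series, store = store, config = cfg,
                        E_ref = store$E_ref,
                        H00_ref = store$diag[store$ref_idx],
                        time_step = cfg$time_step,
                        vary_iter = vary_iter, switch_iter = switch_iter,
                        gas_rejected = total_gas_rejected,
                        rdm_acc = rdm),
                   class = "fciqmc_run")
  run$energy <- tryCatch(projected_energy(run), error = function(e) {
    list(estimate = NA_real_, correlation = NA_real_, se = NA_real_,
         blocking = NULL, n_samples = 0L)
  })
  run
}

#' @export
print.fciqmc_run <- function(x, ...) {
  cat("FCIQMC run:", nrow(x$series), "iterations, dtau =",
      format(x$time_step, digits = 4), "\n")
  cat("  E_proj =", format(x$energy$estimate, digits = 10), "+/-",
      format(x$energy$se, digits = 3), "\n")
  cat("  final N_w =", x$series$N_w[nrow(x$series)], "on",
      x$series$n_occ[nrow(x$series)], "determinants\n")
  invisible(x)
}

#' Projected-energy estimate from a dynamics run
#'
#' `E = H_00 + sum(numerator) / sum(denominator)` over post-equilibration
#' iterations (numerator and denominator averaged separately), with the
#' standard error from a blocking analysis of the per-iteration ratio series.
#'
#' @param run An [fciqmc()] result (or a list with `series`, `H00_ref`,
#'   `config`).
#' @param equilibration Override the configured equilibration cutoff.
#' @return A list: `estimate`, `se`, `correlation` (estimate minus H_00),
#'   `blocking` (the block curve), `n_samples`.
#' @export
projected_energy <- function(run, equilibration = NULL) {
  eq <- if (is.null(equilibration)) run$config$equilibration else equilibration
  s <- run$series
  use <- s$iter > eq & !is.na(s$num) & s$denom != 0
  if (sum(use) < 8) stop("projected_energy: no usable post-equilibration samples")
  num <- s$num[use]; den <- s$denom[use]
  corr <- sum(num) / sum(den)
  r <- num / den
  bl <- blocking_error(r)
  list(estimate = run$H00_ref + corr, correlation = corr,
       se = bl$se, blocking = bl, n_samples = sum(use))
}

#' Blocking analysis (successive pair averaging)
#'
#' Estimates the standard error of the mean of a correlated series by
#' repeatedly averaging neighboring pairs and locating the plateau of the
#' naive standard error across blocking levels.
#'
#' @param x Numeric series (length at least 64).
#' @return A list: `se` (plateau standard error), `plateau` (logical; `FALSE`
#'   means no plateau was found and the maximum over levels is returned, with
#'   a warning flag), `curve` (data frame of level, block count, standard
#'   error and its uncertainty).
#' @export
blocking_error <- function(x) {
  n <- length(x)
  if (n < 64) stop("blocking_error: series too short (need >= 64)")
  if (stats::sd(x) == 0) {
    return(list(se = 0, plateau = TRUE,
                curve = data.frame(level = 0L, n = n, se = 0, se_err = 0)))
  }
  lev <- 0L
  curve <- data.frame(level = integer(0), n = integer(0),
                      se = numeric(0), se_err = numeric(0))
  y <- x
  while (length(y) >= 8) {
    m <- length(y)
    se <- stats::sd(y) / sqrt(m)
    curve <- rbind(curve, data.frame(level = lev, n = m, se = se,
                                     se_err = se / sqrt(2 * (m - 1))))
    if (m %% 2 == 1) y <- y[-m]
    y <- (y[seq(1, length(y), by = 2)] + y[seq(2, length(y), by = 2)]) / 2
    lev <- lev + 1L
  }
  # plateau: first level whose successor does not grow beyond its own error bar
  plateau_se <- NA_real_
  found <- FALSE
  for (i in seq_len(nrow(curve) - 1)) {
    if (curve$se[i + 1] <= curve$se[i] + curve$se_err[i]) {
      plateau_se <- max(curve$se[i], curve$se[i + 1])
      found <- TRUE
      break
    }
  }
  if (!found) plateau_se <- max(curve$se)
  list(se = plateau_se, plateau = found, curve = curve)
}
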