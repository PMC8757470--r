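# Alias sampling and the PCHB / GAS-PCHB excitation generators.

test_that("alias tables sample exactly the normalized input weights", {
  expect_error(build_alias(c(0, 0)), "zero")
  expect_error(build_alias(c(-1, 2)), "negative")
  at1 <- build_alias(1)
  expect_identical(unique(alias_sample(at1, 100)), 1L)
  set.seed(31)
  at <- build_alias(c(1, 1, 1, 1))
  n <- 1e5
  tab <- tabulate(alias_sample(at, n), 4)
  chi2 <- sum((tab - n / 4)^2 / (n / 4))
  expect_lt(chi2, qchisq(0.999, df = 3))
  # zero-weight outcome never drawn; 3:1 ratio within 5 sigma
  at2 <- build_alias(c(0, 3, 1))
  draws <- alias_sample(at2, n)
  expect_identical(sum(draws == 1L), 0L)
  p <- 3 / 4
  expect_lt(abs(sum(draws == 2L) - n * p), 5 * sqrt(n * p * (1 - p)))
})

fixture_gas_46 <- function(seed = 19) {
  # 4 electrons in 6 orbitals, two connected (3-orbital) spaces
  ints <- synthetic_integrals(6, seed)
  p <- gas_partition(c(3, 3))
  cons <- band_constraints(p, c(2, 2), 1, "local")
  tab <- build_supergroup_table(p, cons, 4)
  list(ints = ints, partition = p, cons = cons, tab = tab)
}

test_that("PCHB weights are masked exactly and renormalize to one", {
  fx <- fixture_gas_46()
  tables <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  n <- 6
  for (sg in seq_len(tables$n_sg)) {
    x <- fx$tab$supergroups[sg, ]
    for (pr in seq_len(tables$P)) {
      w <- tables$pnorm[, pr, sg]
      if (tables$wtot[pr, sg] > 0) expect_equal(sum(w), 1, tolerance = 1e-12)
      # every positive weight corresponds to a GAS-allowed composition move
      for (hp in which(w > 0)) {
        mv <- x
        for (s in c(tables$pairA[pr], tables$pairB[pr])) {
          sp <- fx$partition$orbital_space[ifelse(s > n, s - n, s)]
          mv[sp] <- mv[sp] - 1L
        }
        for (s in c(tables$pairA[hp], tables$pairB[hp])) {
          sp <- fx$partition$orbital_space[ifelse(s > n, s - n, s)]
          mv[sp] <- mv[sp] + 1L
        }
        expect_true(is_allowed(mv, fx$cons, fx$partition))
      }
    }
  }
})

test_that("full-CI PCHB is the single-supergroup special case", {
  ints <- synthetic_integrals(5, 23)
  tab <- cas_table(5, 4)
  t_fci <- build_pchb_tables(ints, tab, gas = FALSE)
  t_gas <- build_pchb_tables(ints, tab, gas = TRUE)
  expect_identical(t_gas$n_sg, 1L)
  expect_equal(t_fci$prob, t_gas$prob)
  expect_identical(t_fci$alias, t_gas$alias)
  expect_equal(t_fci$pnorm, t_gas$pnorm)
  expect_identical(t_fci$smask[1, 1], t_gas$smask[1, 1])
  # event-for-event identical sampling under the same seed
  d <- determinant(1:2, 1:2, 5)
  set.seed(4); e1 <- replicate(200, sample_excitation(d, t_fci), simplify = FALSE)
  set.seed(4); e2 <- replicate(200, sample_excitation(d, t_gas), simplify = FALSE)
  expect_identical(e1, e2)
})

test_that("sampled events carry their exact generation probability", {
  fx <- fixture_gas_46()
  tables <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  d <- determinant(c(1, 2), c(1, 4), 6)
  set.seed(8)
  for (rep in 1:200) {
    ev <- sample_excitation(d, tables)
    if (ev$rejected) next
    expect_equal(pgen(d, ev, tables), ev$pgen, tolerance = 1e-12)
  }
  # unreachable and forbidden events get probability zero
  expect_identical(pgen(d, list(kind = "single", I = 1L, A = 9L), tables), 0)
})

test_that("generation probabilities sum to one over children plus rejections", {
  fx <- fixture_gas_46()
  tables <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  d <- determinant(c(1, 2), c(1, 4), 6)
  n <- 6; nso <- 12
  occ <- gasci:::det_occ_so(d)
  isg <- supergroup_index(supergroup_of_determinant(d, fx$partition), fx$tab)
  total_valid <- 0; total_reject <- 0
  # doubles: every occupied pair x every hole pair of positive weight
  prs <- combn(occ, 2)
  p_pair <- 2 / (length(occ) * (length(occ) - 1))
  occ_test <- function(s) s %in% occ
  for (c_i in seq_len(ncol(prs))) {
    pr <- tables$pair_rank[prs[1, c_i], prs[2, c_i]]
    if (tables$wtot[pr, isg] == 0) {
      total_reject <- total_reject + tables$p_double * p_pair
      next
    }
    for (hp in seq_len(tables$P)) {
      w <- tables$pnorm[hp, pr, isg]
      if (w == 0) next
      pe <- tables$p_double * p_pair * w
      if (occ_test(tables$pairA[hp]) || occ_test(tables$pairB[hp])) {
        total_reject <- total_reject + pe
      } else total_valid <- total_valid + pe
    }
  }
  # singles: every occupied orbital, allowed-hole mask
  for (I in occ) {
    i0 <- ifelse(I > n, I - n, I)
    sm <- tables$smask[tables$space_of[i0], isg]
    occ_sigma <- if (I <= n) as.integer(d$alpha) else as.integer(d$beta)
    cand <- bitwAnd(sm, bitwAnd(bitwNot(occ_sigma), tables$full_mask))
    Ntil <- gasci:::mask_popcount(cand)
    if (Ntil == 0) total_reject <- total_reject + (1 - tables$p_double) / length(occ)
    else total_valid <- total_valid + (1 - tables$p_double) / length(occ)
  }
  expect_equal(total_valid + total_reject, 1, tolerance = 1e-12)
  # cross-check a sampled batch against the analytic valid mass
  set.seed(12)
  par <- gasci:::par_from_det(d, tables)
  ev <- gasci:::pchb_propose(tables, par, rep(1L, 2e4))
  expect_lt(abs(mean(ev$valid) - total_valid),
            5 * sqrt(total_valid * (1 - total_valid) / 2e4))
})

test_that("GAS-PCHB proposes only allowed children; discarding rejects some", {
  fx <- fixture_gas_46()
  t_gas <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  t_fci <- build_pchb_tables(fx$ints, fx$tab, gas = FALSE)
  d <- determinant(c(1, 2), c(1, 4), 6)
  par <- gasci:::par_from_det(d, t_gas)
  set.seed(3)
  ev <- gasci:::pchb_propose(t_gas, par, rep(1L, 2e5))
  vi <- which(ev$valid)
  forbidden <- 0L
  for (i in vi) {
    ch <- gasci:::det_from_masks(ev$child_a[i], ev$child_b[i], 6)
    if (!is_allowed(supergroup_of_determinant(ch, fx$partition), fx$cons,
                    fx$partition)) forbidden <- forbidden + 1L
  }
  expect_identical(forbidden, 0L)
  # discarding baseline on the same fixture does reject
  set.seed(3)
  rejects <- 0L
  for (rep in 1:2000) {
    e <- discarding_generator(d, t_fci, fx$tab)
    if (e$rejected && identical(e$reason, "gas_forbidden")) rejects <- rejects + 1L
  }
  expect_gt(rejects, 0L)
  # with CAS constraints the discarding generator never rejects for GAS reasons
  cas <- cas_table(6, 4)
  t_cas <- build_pchb_tables(fx$ints, cas, gas = FALSE)
  set.seed(5)
  gas_rejects <- 0L
  for (rep in 1:500) {
    e <- discarding_generator(d, t_cas, cas)
    if (e$rejected && identical(e$reason, "gas_forbidden"))
      gas_rejects <- gas_rejects + 1L
  }
  expect_identical(gas_rejects, 0L)
})

test_that("discarding and a-priori generators agree per particle pair", {
  # conditional on the particle pair and acceptance, the hole distribution of
  # the discarding generator equals the GAS-PCHB one (same weights,
  # renormalized over the allowed set)
  fx <- fixture_gas_46()
  t_gas <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  t_fci <- build_pchb_tables(fx$ints, fx$tab, gas = FALSE)
  d <- determinant(c(1, 2), c(1, 4), 6)
  isg <- supergroup_index(supergroup_of_determinant(d, fx$partition), fx$tab)
  for (pr in seq_len(t_gas$P)) {
    w_gas <- t_gas$pnorm[, pr, isg]
    if (sum(w_gas) == 0) next
    w_fci <- t_fci$pnorm[, pr, 1]
    allowed <- w_gas > 0
    w_disc <- w_fci * allowed
    expect_equal(w_disc / sum(w_disc), w_gas, tolerance = 1e-12)
  }
})

test_that("empirical child frequencies match p_gen (chi-squared harness)", {
  fx <- fixture_gas_46()
  tables <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  d <- determinant(c(1, 2), c(1, 4), 6)
  set.seed(17)
  rep_ <- excitgen_frequency_report(d, tables, draws = 4e4)
  expect_lt(rep_$chi2, qchisq(0.999, df = rep_$df))
  expect_equal(sum(rep_$table$pgen) + rep_$reject_frac, 1, tolerance = 0.02)
})

test_that("memory estimates scale as documented", {
  expect_equal(memory_estimate(10, 81) / memory_estimate(10, 1), 81)
  # quartic in the orbital count: doubling n multiplies by ~16
  expect_equal(memory_estimate(20, 5) / memory_estimate(10, 5),
               (20 * 39 / (10 * 19))^2, tolerance = 1e-12)
  expect_lt(abs(memory_estimate(20, 5) / memory_estimate(10, 5) - 16), 1.5)
  # five-fragment (6,6) stack at three interspace excitations: ~35 GB printed
  est <- memory_estimate(30, 2401)
  expect_lt(est / (34.81 * 2^30), 2)
  expect_gt(est / (34.81 * 2^30), 0.5)
  # spatial indexing reduces the estimate
  expect_lt(memory_estimate(30, 2401, spatial = TRUE), est)
  # construction refuses above the cap with the estimate in the message
  ints <- synthetic_integrals(6, 2)
  expect_error(build_pchb_tables(ints, cas_table(6, 6), memory_cap_gb = 1e-6),
               "exceeds")
})

test_that("compiled and reference proposal kernels agree", {
  fx <- fixture_gas_46()
  tables <- build_pchb_tables(fx$ints, fx$tab, gas = TRUE)
  d <- determinant(c(1, 2), c(1, 4), 6)
  par <- gasci:::par_from_det(d, tables)
  # the R reference path assigns the same exact pgen to every valid event
  set.seed(13)
  ev_r <- gasci:::pchb_propose_r(tables, par, rep(1L, 3000))
  for (i in which(ev_r$valid)[1:50]) {
    evd <- list(kind = c("double", "single")[ev_r$kind[i]],
                I = ev_r$I[i], J = ev_r$J[i], A = ev_r$A[i], B = ev_r$B[i])
    expect_equal(pgen(d, evd, tables), ev_r$pgen[i], tolerance = 1e-12)
  }
  # matrix elements and child masks agree event-for-event where both paths
  # sample the same move
  set.seed(13)
  ev_c <- gasci:::pchb_propose(tables, par, rep(1L, 3000))
  key_r <- paste(ev_r$kind, ev_r$I, ev_r$J, ev_r$A, ev_r$B)
  key_c <- paste(ev_c$kind, ev_c$I, ev_c$J, ev_c$A, ev_c$B)
  common <- intersect(key_r[ev_r$valid], key_c[ev_c$valid])
  expect_gt(length(common), 20)
  for (k in common[1:20]) {
    i <- match(k, key_r); j <- match(k, key_c)
    expect_equal(ev_r$hmat[i], ev_c$hmat[j], tolerance = 1e-12)
    expect_identical(ev_r$child_a[i], ev_c$child_a[j])
    expect_identical(ev_r$child_b[i], ev_c$child_b[j])
    expect_equal(ev_r$pgen[i], ev_c$pgen[j], tolerance = 1e-12)
  }
  # and the valid fractions match within binomial noise
  expect_lt(abs(mean(ev_r$valid) - mean(ev_c$valid)), 5 * sqrt(0.25 / 3000) * 2)
})
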