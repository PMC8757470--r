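# Walker dynamics: elementary steps, refinements, estimators.

mini_run_setup <- function(n = 4, seed = 7, nelec = 4) {
  ints <- synthetic_integrals(n, seed)
  tab <- cas_table(n, nelec)
  tables <- build_pchb_tables(ints, tab, gas = FALSE)
  list(ints = ints, tab = tab, tables = tables)
}

# store with prescribed populations on explicit determinants
manual_store <- function(fx, dets, pops, ref = dets[[1]]) {
  st <- gasci:::store_empty(fx$ints, fx$tables, fx$tab, fx$tab$N)
  st$ref_key <- gasci:::det_key(ref$alpha, ref$beta)
  st$E_ref <- gasci:::diagonal_element(ref, fx$ints)
  for (i in seq_along(dets)) {
    st <- gasci:::store_add(st, as.integer(dets[[i]]$alpha),
                            as.integer(dets[[i]]$beta), pops[i])
  }
  st
}

test_that("spawned weight matches dtau |K_ij| (parent population) in expectation", {
  fx <- mini_run_setup()
  parent <- determinant(1:2, 1:2, 4)
  st <- manual_store(fx, list(parent), 200)
  cfg <- dynamics_config(time_step = 0.01, generator = "fci-pchb")
  set.seed(21)
  # pick a specific child reachable by a double excitation
  child <- determinant(c(1, 3), c(1, 3), 4)
  K <- matrix_element(parent, child, fx$ints)
  got <- 0; reps <- 400
  ck <- gasci:::det_key(child$alpha, child$beta)
  for (r in seq_len(reps)) {
    sp <- spawn_step(st, fx$tables, cfg)
    hit <- sp$buffer$key == ck
    got <- got + sum(sp$buffer$count[hit])
  }
  expected <- -0.01 * K * 200 * reps
  # Poisson-scale noise bound with slack for spawn multiplicity
  expect_lt(abs(got - expected), 5 * sqrt(abs(expected) * 3) + 5)
  # K_ij = 0 (beyond doubles) never spawns
  far <- determinant(3:4, 3:4, 4)
  expect_identical(matrix_element(parent, far, fx$ints) == 0, TRUE)
})

test_that("death step kills at rate dtau (K_jj - S), clones for negative rates", {
  fx <- mini_run_setup()
  d <- determinant(1:2, 1:2, 4)
  st <- manual_store(fx, list(d), 1e4)
  K <- st$diag[1] - st$E_ref  # zero for the reference determinant
  cfg <- dynamics_config(time_step = 0.02)
  cfg$time_step <- 0.02
  # K_jj = S: population unchanged in expectation
  set.seed(2)
  pops <- replicate(200, death_step(st, K, cfg)$pop[1])
  expect_equal(mean(pops), 1e4, tolerance = 1e-3)
  # decay at a known rate over repeated application
  S <- K - 2  # death probability 0.04
  set.seed(3)
  st2 <- st
  for (t in 1:25) st2 <- death_step(st2, S, cfg)
  expected <- 1e4 * (1 - 0.04)^25
  expect_lt(abs(st2$pop[1] - expected), 5 * sqrt(1e4 * 0.36))
  # negative rate clones
  set.seed(4)
  st3 <- death_step(st, K + 2, cfg)
  expect_gt(st3$pop[1], 1e4)
  # large-population limit matches the linear update
  st4 <- manual_store(fx, list(d), 1e6)
  set.seed(5)
  st4 <- death_step(st4, S, cfg)
  expect_equal(st4$pop[1] / 1e6, 1 - 0.04, tolerance = 1e-2)
})

test_that("annihilation sums signed spawns and is order independent", {
  fx <- mini_run_setup()
  ref <- determinant(1:2, 1:2, 4)
  st <- manual_store(fx, list(ref), 10)
  ch <- determinant(c(1, 3), c(1, 2), 4)
  ck <- gasci:::det_key(ch$alpha, ch$beta)
  buf <- list(alpha = rep(as.integer(ch$alpha), 2),
              bmask = rep(as.integer(ch$beta), 2),
              key = rep(ck, 2), count = c(3, -3), parent = c(1L, 1L))
  st2 <- annihilate(st, buf)
  expect_false(ck %in% st2$key[st2$pop != 0])
  # shuffled buffers give the same final store
  set.seed(9)
  keys <- c(rep(ck, 3), rep(st$ref_key, 2))
  counts <- c(2, -1, 4, 1, -2)
  alph <- c(rep(as.integer(ch$alpha), 3), rep(as.integer(ref$alpha), 2))
  bet <- c(rep(as.integer(ch$beta), 3), rep(as.integer(ref$beta), 2))
  perm <- sample(5)
  b1 <- list(alpha = alph, bmask = bet, key = keys, count = counts,
             parent = rep(1L, 5))
  b2 <- list(alpha = alph[perm], bmask = bet[perm], key = keys[perm],
             count = counts[perm], parent = rep(1L, 5))
  s1 <- annihilate(st, b1); s2 <- annihilate(st, b2)
  o1 <- order(s1$key); o2 <- order(s2$key)
  expect_identical(s1$key[o1], s2$key[o2])
  expect_identical(s1$pop[o1], s2$pop[o2])
  # total walker number equals the independent tally
  expect_identical(sum(abs(s1$pop)), sum(abs(c(10 + 1 - 2, 2 - 1 + 4))))
})

test_that("shift control follows the damped log-ratio update", {
  cfg <- dynamics_config(time_step = 0.01)
  cfg$time_step <- 0.01
  expect_equal(update_shift(-0.3, 5000, 5000, cfg), -0.3)
  expect_lt(update_shift(-0.3, 5500, 5000, cfg), -0.3)
  expect_gt(update_shift(-0.3, 4500, 5000, cfg), -0.3)
})

test_that("initiator filter vetoes exactly sub-threshold spawns onto empty space", {
  cfg <- dynamics_config(n_add = 3)
  expect_true(initiator_filter(4, FALSE, cfg))
  expect_false(initiator_filter(1, FALSE, cfg))
  expect_true(initiator_filter(1, TRUE, cfg))
  expect_true(initiator_filter(-5, FALSE, cfg))
  expect_false(initiator_filter(-2, FALSE, cfg))
})

test_that("adaptive shift has the documented limits", {
  fx <- mini_run_setup()
  st <- manual_store(fx, list(determinant(1:2, 1:2, 4)), 5)
  st$facc <- 0.4; st$ftot <- 1
  S <- -0.6
  # Delta = S: S_i = S regardless of f
  cfg1 <- dynamics_config(adaptive_offset_frac = 1)
  expect_equal(adaptive_shift(st, S, cfg1), S)
  # Delta = 0, f = 1: S_i = S
  st$facc <- 1; st$ftot <- 1
  cfg0 <- dynamics_config(adaptive_offset_frac = 0)
  expect_equal(adaptive_shift(st, S, cfg0), S)
  # Delta = 0, f = 0.4: S_i = 0.4 S
  st$facc <- 0.4
  expect_equal(adaptive_shift(st, S, cfg0), 0.4 * S)
})

test_that("adaptive dynamics with Delta = S reproduces conventional i-FCIQMC", {
  fx <- mini_run_setup(seed = 5)
  cfg_conv <- dynamics_config(target_population = 800, max_iter = 250,
                              initiator = TRUE, time_step = 0.02)
  cfg_adap <- dynamics_config(target_population = 800, max_iter = 250,
                              initiator = TRUE, adaptive = TRUE,
                              adaptive_offset_frac = 1, time_step = 0.02)
  set.seed(77)
  r1 <- fciqmc(fx$ints, fx$tab, 0, cfg_conv)
  set.seed(77)
  r2 <- fciqmc(fx$ints, fx$tab, 0, cfg_adap)
  expect_identical(r1$series$N_w, r2$series$N_w)
  expect_identical(r1$series$num, r2$series$num)
  expect_identical(r1$series$S, r2$series$S)
})

test_that("full-basis semistochastic core is exact power iteration", {
  fx <- mini_run_setup(n = 3, seed = 13, nelec = 2)
  basis <- enumerate_determinants(gas_partition(3), fx$tab, 0)
  dets <- lapply(seq_along(basis$key), function(i) {
    gasci:::det_from_masks(basis$alpha[i], basis$beta[i], 3)
  })
  Hc <- core_hamiltonian(dets, fx$ints)
  sol <- exact_diagonalization(gas_partition(3), fx$ints, fx$tab, 0)
  # random start: a symmetric (e.g. flat) vector can be exactly orthogonal
  # to a spin-asymmetric ground state in the m_s = 0 sector
  set.seed(71)
  st <- manual_store(fx, dets, rnorm(length(dets)))
  st$is_core <- rep(TRUE, length(dets))
  cfg <- dynamics_config(time_step = 0.05)
  cfg$time_step <- 0.05
  S <- sol$energy - st$E_ref
  for (t in 1:6000) {
    st <- gasci:::semistochastic_project(st, Hc, S, cfg)
    st$pop <- st$pop / max(abs(st$pop))  # keep amplitudes bounded
  }
  v <- st$pop / sqrt(sum(st$pop^2))
  ray <- as.numeric(t(v) %*% Hc %*% v)
  expect_equal(ray, sol$energy, tolerance = 1e-7)
})

test_that("semistochastic core reduces the energy variance", {
  fx <- mini_run_setup(seed = 3)
  base <- dynamics_config(target_population = 3000, max_iter = 900,
                          time_step = 0.02)
  withcore <- dynamics_config(target_population = 3000, max_iter = 900,
                              time_step = 0.02, core_space_size = 12)
  set.seed(41); r0 <- fciqmc(fx$ints, fx$tab, 0, base)
  set.seed(41); r1 <- fciqmc(fx$ints, fx$tab, 0, withcore)
  eq <- r0$config$equilibration
  v0 <- var((r0$series$num / r0$series$denom)[r0$series$iter > eq])
  v1 <- var((r1$series$num / r1$series$denom)[r1$series$iter > eq])
  expect_lt(v1, v0)
  # both estimates agree with exact diagonalization within 3 sigma
  sol <- exact_diagonalization(gas_partition(4), fx$ints, fx$tab, 0)
  expect_lt(abs(r1$energy$estimate - sol$energy), 3 * r1$energy$se)
})

test_that("projected energy is exact on an injected eigenvector", {
  fx <- mini_run_setup(seed = 29)
  sol <- exact_diagonalization(gas_partition(4), fx$ints, fx$tab, 0)
  basis <- sol$basis
  ref_i <- which.max(abs(sol$coefficients))
  ref <- gasci:::basis_det(basis, ref_i)
  h0 <- vapply(seq_along(basis$key), function(j) {
    if (j == ref_i) 0 else
      matrix_element(ref, gasci:::basis_det(basis, j), fx$ints)
  }, numeric(1))
  num <- sum(h0 * sol$coefficients)
  den <- sol$coefficients[ref_i]
  series <- data.frame(iter = 1:128, S = 0, N_w = 1, num = num, denom = den,
                       N_ref = den, n_occ = 1L)
  run <- list(series = series,
              H00_ref = gasci:::diagonal_element(ref, fx$ints),
              config = list(equilibration = 0))
  pe <- projected_energy(run)
  expect_equal(pe$estimate, sol$energy, tolerance = 1e-10)
  expect_equal(pe$se, 0)
})

test_that("blocking analysis recovers known error structures", {
  set.seed(55)
  n <- 2^14
  sigma <- 0.7
  white <- rnorm(n, sd = sigma)
  bw <- blocking_error(white)
  expect_lt(abs(bw$se - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.2)
  # AR(1): true error inflated by sqrt((1 + phi) / (1 - phi))
  phi <- 0.8
  x <- numeric(n); x[1] <- rnorm(1)
  innov <- rnorm(n)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t]
  sd_x <- sqrt(1 / (1 - phi^2))
  truth <- sd_x / sqrt(n) * sqrt((1 + phi) / (1 - phi))
  ba <- blocking_error(x)
  expect_lt(abs(ba$se - truth) / truth, 0.25)
  expect_true(ba$plateau)
  # constant series
  bc <- blocking_error(rep(3.2, 128))
  expect_identical(bc$se, 0)
  expect_error(blocking_error(rnorm(32)), "too short")
})

test_that("GAS dynamics never occupies a forbidden determinant", {
  ints <- synthetic_integrals(6, 19)
  p <- gas_partition(c(3, 3))
  cons <- band_constraints(p, c(2, 2), 1, "local")
  tab <- build_supergroup_table(p, cons, 4)
  set.seed(31)
  run <- fciqmc(ints, tab, 0,
                dynamics_config(target_population = 1500, max_iter = 250,
                                debug_assert_gas = TRUE))
  expect_s3_class(run, "fciqmc_run")
  expect_identical(run$gas_rejected, 0L)
})

test_that("discarding and a-priori dynamics converge to the same energy", {
  ints <- synthetic_integrals(6, 19)
  p <- gas_partition(c(3, 3))
  tab <- build_supergroup_table(p, gas_local(c(3, 3), c(3, 3)), 6)
  tg <- build_pchb_tables(ints, tab, gas = TRUE)
  tf <- build_pchb_tables(ints, tab, gas = FALSE)
  ref <- gasci:::pick_reference(p, ints, tab, 0)
  set.seed(1)
  dt <- min(gasci:::auto_time_step(ref, tg), gasci:::auto_time_step(ref, tf))
  cfg <- function(gen) dynamics_config(target_population = 3e4,
                                       max_iter = 2000, time_step = dt,
                                       generator = gen)
  set.seed(9)
  rg <- fciqmc(ints, tab, 0, cfg("gas-pchb"), tables = tg)
  set.seed(9)
  rd <- fciqmc(ints, tab, 0, cfg("discarding"), tables = tf)
  # a large fraction of unconstrained proposals leaves the disconnected space
  expect_gt(rd$gas_rejected, 1e6)
  expect_identical(rg$gas_rejected, 0L)
  # both estimators agree with each other within combined errors
  comb <- sqrt(rg$energy$se^2 + rd$energy$se^2)
  expect_lt(abs(rg$energy$estimate - rd$energy$estimate), 3 * comb)
})
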