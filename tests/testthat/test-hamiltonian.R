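# Integrals, Slater-Condon elements, masking, exact diagonalization.

test_that("FCIDUMP round trip reproduces integrals and completes symmetry", {
  ints <- synthetic_integrals(4, 13)
  path <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(ints, path, nelec = 4, ms2 = 0)
  back <- read_fcidump(path)
  expect_equal(back$h, ints$h, tolerance = 1e-12)
  expect_equal(back$g, ints$g, tolerance = 1e-12)
  expect_equal(back$core_energy, ints$core_energy)
  expect_identical(back$nelec, 4L)
  # canonical-order file reconstructs the full 8-fold symmetric tensor
  for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2))) {
    expect_equal(back$g, aperm(back$g, perm), tolerance = 1e-12)
  }
})

test_that("malformed FCIDUMP input raises parse errors", {
  path <- withr::local_tempfile(fileext = ".fcidump")
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "&END",
               "1.0 3 1 0 0"), path)
  expect_error(read_fcidump(path), "exceeds NORB")
  writeLines(c("NOT A HEADER", "1.0 1 1 0 0"), path)
  expect_error(read_fcidump(path), "malformed header")
})

test_that("synthetic generators are reproducible and structurally correct", {
  a <- synthetic_integrals(5, 99)
  b <- synthetic_integrals(5, 99)
  expect_identical(a, b)
  hub <- hubbard_integrals(2, 4, 1)
  expect_equal(hub$h, matrix(c(0, -1, -1, 0), 2, 2))
  nz <- which(hub$g != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] == nz[, 2] & nz[, 2] == nz[, 3] & nz[, 3] == nz[, 4]))
})

test_that("matrix elements agree with the second-quantized operator oracle", {
  ints <- synthetic_integrals(4, 7)
  tab <- cas_table(4, 4)
  basis <- enumerate_determinants(gas_partition(4), tab, 0)
  H_pkg <- as.matrix(hamiltonian_matrix(basis, ints))
  H_orc <- oracle_hamiltonian(basis, ints)
  expect_lt(max(abs(H_pkg - H_orc)), 1e-10)
  expect_lt(max(abs(H_pkg - t(H_pkg))), 1e-12)
})

test_that("excitations beyond doubles give exactly zero", {
  ints <- synthetic_integrals(6, 5)
  di <- determinant(1:3, 1:3, 6)
  dj <- determinant(4:6, c(1, 2, 4), 6)  # triple excitation overall
  expect_identical(matrix_element(di, dj, ints), 0)
  dj2 <- determinant(1:3, 4:6, 6)        # beta triple
  expect_identical(matrix_element(di, dj2, ints), 0)
  expect_error(matrix_element(di, determinant(1:2, 1:4, 6), ints),
               "different spin sectors")
})

test_that("GAS masking zeroes exactly the space-leaving couplings", {
  ints <- synthetic_integrals(4, 21)
  p <- gas_partition(c(2, 2))
  cons <- gas_local(c(2, 2), c(2, 2))  # disconnected
  tab <- build_supergroup_table(p, cons, 4)
  di <- determinant(c(1, 3), c(1, 3), 4)
  # interspace single: orbital 1 -> 4 leaves the composition
  dj <- determinant(c(3, 4), c(1, 3), 4)
  expect_identical(gas_masked_element(di, dj, ints, tab), 0)
  expect_false(matrix_element(di, dj, ints) == 0)
  # intraspace excitation keeps the composition: mask is inert
  dk <- determinant(c(2, 3), c(1, 3), 4)
  expect_identical(gas_masked_element(di, dk, ints, tab),
                   matrix_element(di, dk, ints))
})

test_that("masked CAS Hamiltonian and GAS-basis Hamiltonian give one energy", {
  ints <- synthetic_integrals(4, 31)
  p <- gas_partition(c(2, 2))
  cons <- band_constraints(p, c(2, 2), 1, "local")
  tab <- build_supergroup_table(p, cons, 4)
  # route 1: ED over the enumerated GAS basis
  sol_gas <- exact_diagonalization(p, ints, tab, 0)
  # route 2: masked Hamiltonian over the full CAS basis
  cas <- enumerate_determinants(gas_partition(4), cas_table(4, 4), 0)
  nb <- length(cas$key)
  dets <- lapply(seq_len(nb), function(i) {
    gasci:::det_from_masks(cas$alpha[i], cas$beta[i], 4)
  })
  Hm <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    xi <- supergroup_of_determinant(dets[[i]], p)
    if (!is_allowed(xi, cons, p)) next  # row of a forbidden determinant
    Hm[j, i] <- gas_masked_element(dets[[i]], dets[[j]], ints, tab)
  }
  allowed <- vapply(dets, function(d) {
    is_allowed(supergroup_of_determinant(d, p), cons, p)
  }, logical(1))
  ev <- eigen((Hm[allowed, allowed] + t(Hm[allowed, allowed])) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), sol_gas$energy, tolerance = 1e-10)
})

test_that("exact diagonalization reproduces closed forms", {
  # 2-site Hubbard singlet: (U - sqrt(U^2 + 16 t^2)) / 2
  for (U in c(1, 4, 8)) {
    sol <- exact_diagonalization(gas_partition(2), hubbard_integrals(2, U, 1),
                                 cas_table(2, 2), 0)
    expect_equal(sol$energy, (U - sqrt(U^2 + 16)) / 2, tolerance = 1e-10)
  }
  # U = 0 chain: sum of the lowest tight-binding levels, doubly occupied
  ints0 <- hubbard_integrals(4, 0, 1)
  sol0 <- exact_diagonalization(gas_partition(4), ints0, cas_table(4, 4), 0)
  lev <- sort(eigen(ints0$h, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(sol0$energy, 2 * sum(lev[1:2]), tolerance = 1e-10)
  # single-determinant space: energy equals the diagonal element
  p <- gas_partition(c(1, 1))
  tab1 <- build_supergroup_table(p, gas_local(c(2, 2), c(2, 2)), 4)
  ints <- synthetic_integrals(2, 3)
  sol1 <- exact_diagonalization(p, ints, tab1, 0)
  expect_equal(sol1$energy,
               gasci:::diagonal_element(determinant(1:2, 1:2, 2), ints))
})

test_that("ED is variational under GAS truncation and basis-order invariant", {
  ints <- synthetic_integrals(6, 11)
  e_cas <- exact_diagonalization(gas_partition(6), ints, cas_table(6, 6), 0)$energy
  p <- gas_partition(c(3, 3))
  prev <- Inf
  for (ne in 0:3) {
    cons <- band_constraints(p, c(3, 3), ne, "local")
    tab <- build_supergroup_table(p, cons, 6)
    e <- exact_diagonalization(p, ints, tab, 0)$energy
    expect_gte(e + 1e-12, e_cas)
    expect_lte(e, prev + 1e-12)  # larger bands contain smaller ones
    prev <- e
  }
  # saturated band recovers CAS exactly
  cons_full <- band_constraints(p, c(3, 3), 6, "local")
  tab_full <- build_supergroup_table(p, cons_full, 6)
  expect_equal(exact_diagonalization(p, ints, tab_full, 0)$energy, e_cas,
               tolerance = 1e-9)
  # permutation invariance: shuffle the basis and rediagonalize
  tab <- build_supergroup_table(p, band_constraints(p, c(3, 3), 1, "local"), 6)
  basis <- enumerate_determinants(p, tab, 0)
  set.seed(5)
  ord <- sample(length(basis$key))
  shuf <- list(alpha = basis$alpha[ord], beta = basis$beta[ord],
               key = basis$key[ord], n_orb = 6)
  H1 <- hamiltonian_matrix(basis, ints)
  H2 <- hamiltonian_matrix(shuf, ints)
  e1 <- min(eigen(as.matrix(H1), symmetric = TRUE, only.values = TRUE)$values)
  e2 <- min(eigen(as.matrix(H2), symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("core Hamiltonian is symmetric and consistent with ED", {
  ints <- synthetic_integrals(4, 17)
  p <- gas_partition(c(2, 2))
  cons <- band_constraints(p, c(2, 2), 1, "local")
  tab <- build_supergroup_table(p, cons, 4)
  basis <- enumerate_determinants(p, tab, 0)
  dets <- lapply(seq_along(basis$key), function(i) {
    gasci:::det_from_masks(basis$alpha[i], basis$beta[i], 4)
  })
  Hc <- core_hamiltonian(dets, ints, tab)
  expect_lt(max(abs(Hc - t(Hc))), 1e-12)
  sol <- exact_diagonalization(p, ints, tab, 0)
  expect_equal(min(eigen(Hc, symmetric = TRUE, only.values = TRUE)$values),
               sol$energy, tolerance = 1e-10)
  # single-member core is the bare diagonal
  expect_equal(core_hamiltonian(dets[1], ints, tab)[1, 1],
               gasci:::diagonal_element(dets[[1]], ints))
  # forbidden member is rejected
  bad <- determinant(1:2, 1:2, 4)  # composition (4,0)
  expect_error(core_hamiltonian(c(dets[1], list(bad)), ints, tab), "forbidden")
})
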