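# geometries, feature packing, frame alignment, AO rotations

test_that("pack/unpack is an exact bijection with the documented ordering", {
  expect_equal(as.numeric(pack_symmetric(diag(2))), c(1, 0, 1))
  expect_equal(unpack_symmetric(c(1, 0, 1), 2), diag(2))
  expect_equal(unpack_symmetric(c(5, 2, 7), 2), rbind(c(5, 2), c(2, 7)))
  for (M in c(3, 5, 10)) {
    A <- random_symmetric(M, seed = M)
    expect_identical(unpack_symmetric(pack_symmetric(A), M), A)
    expect_length(pack_symmetric(A), M * (M + 1) / 2)
  }
  # packed Euclidean distance counts off-diagonals once: brute-force oracle
  A <- random_symmetric(3, 1); B <- random_symmetric(3, 2)
  d2 <- 0
  for (i in 1:3) for (j in i:3) d2 <- d2 + (A[i, j] - B[i, j])^2
  expect_equal(sum((pack_symmetric(A) - pack_symmetric(B))^2), d2)
  expect_error(pack_symmetric(matrix(1:6, 2)), "square")
  expect_error(unpack_symmetric(c(1, 2), 2), "length")
})

test_that("geometry invariants are enforced", {
  expect_error(geometry("H", matrix(0, 1, 3)), "odd electron")
  expect_error(geometry(c("O", "H"), matrix(0, 2, 3), multiplicity = 3),
               "closed-shell")
  g <- builtin_molecule("water")
  expect_equal(n_electrons(g), 10)
  expect_error(geometry(c("O", "H"), matrix(0, 1, 3)), "positions")
})

test_that("Kabsch alignment recovers rigid motions exactly", {
  g <- builtin_molecule("water")
  al0 <- align_to_reference(g, g)
  expect_equal(al0$rmsd, 0, tolerance = 1e-12)
  expect_equal(al0$transform$rotation, diag(3), tolerance = 1e-10)

  R <- rot_z(37)
  moved <- g
  moved$positions <- g$positions %*% t(R) + matrix(rep(c(1, -2, 0.5), each = 3), 3)
  al <- align_to_reference(moved, g)
  expect_lt(al$rmsd, 1e-10)
  expect_equal(al$transform$rotation %*% R, diag(3), tolerance = 1e-8)
  # exact round trip through the stored transform
  back <- apply_transform(al$transform, moved$positions)
  expect_equal(back, g$positions, tolerance = 1e-10)
  expect_equal(apply_transform(invert_transform(al$transform), back),
               moved$positions, tolerance = 1e-10)
})

test_that("alignment never increases mass-weighted RMSD (grid-search oracle)", {
  set.seed(8)
  g <- builtin_molecule("water")
  pert <- g
  pert$positions <- g$positions + matrix(rnorm(9, sd = 0.05), 3)
  al <- align_to_reference(pert, g)
  expect_lte(al$rmsd, rmsd(pert, g) + 1e-12)
  # small-angle grid search about z as an independent lower-bound check
  best <- Inf
  for (th in seq(-0.2, 0.2, by = 0.005)) {
    R <- rot_z(th * 180 / pi)
    cand <- pert
    w <- pert$masses / sum(pert$masses)
    cp <- drop(crossprod(pert$positions, w)); cg <- drop(crossprod(g$positions, w))
    cand$positions <- sweep(sweep(pert$positions, 2, cp) %*% t(R), 2, cg, "+")
    best <- min(best, rmsd(cand, g))
  }
  expect_lte(al$rmsd, best + 1e-10)
  expect_error(align_to_reference(builtin_molecule("co2"), g), "alignment error")
})

test_that("AO rotation matches engine recomputation at the rotated geometry", {
  m <- m_sto3g()
  g <- builtin_molecule("water")
  R <- rot_z(90)
  grot <- g
  grot$positions <- g$positions %*% t(R)
  shells <- basis_shells(g, m$basis)
  tr <- structure(list(rotation = R, translation = c(0, 0, 0),
                       center = c(0, 0, 0)), class = "frame_transform")
  for (build in list(overlap_matrix, external_potential_matrix)) {
    M0 <- build(g, m)
    M1 <- build(grot, m)
    expect_equal(rotate_ao_matrix(M0, tr, shells)$values, M1$values,
                 tolerance = 1e-8)
  }
  # converged density transforms covariantly too (per-shell block check)
  P0 <- run_scf(g, m)$gamma
  P1 <- run_scf(grot, m)$gamma
  expect_equal(rotate_ao_matrix(P0, tr, shells)$values, P1$values,
               tolerance = 1e-7)
  # identity transform and group property on a random symmetric matrix
  A <- ao_matrix(random_symmetric(attr(shells, "M"), 4))
  idt <- structure(list(rotation = diag(3)), class = "frame_transform")
  expect_equal(rotate_ao_matrix(A, idt, shells)$values, A$values)
  U <- ao_rotation_matrix(shells, R)
  expect_equal(t(U) %*% U, diag(nrow(U)), tolerance = 1e-12)
  roundtrip <- rotate_ao_matrix(rotate_ao_matrix(A, tr, shells),
                                structure(list(rotation = t(R)),
                                          class = "frame_transform"), shells)
  expect_equal(roundtrip$values, A$values, tolerance = 1e-12)
  expect_error(rotate_ao_matrix(ao_matrix(diag(3)), tr, shells), "dimension")
})

test_that("asymmetric input is rejected by the AO matrix type", {
  A <- matrix(c(1, 2, 0, 1), 2)
  expect_error(ao_matrix(A), "symmetric")
})
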