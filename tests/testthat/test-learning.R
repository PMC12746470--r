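# kernels, KRR gamma-learning, purification, delta-models, model stacks

test_that("kernel_eval implements the three kernels exactly", {
  k_lin <- kernel_spec("LIN")
  expect_equal(kernel_eval(c(1, 2), c(3, 4), k_lin), 11)  # hand dot product
  k_rbf <- kernel_spec("RBF")
  x <- rnorm(6)
  expect_equal(kernel_eval(x, x, k_rbf), 1)
  k_pol <- kernel_spec("POL", gamma_scale = 0.5)
  # Gamma * (x . y) = 1, c = 0, d = 3 -> 1
  expect_equal(kernel_eval(c(2, 0), c(1, 0), k_pol), 1)
  expect_equal(kernel_eval(c(1, 1), c(1, 1), kernel_spec("POL", gamma_scale = 2)),
               (2 * 2)^3)
  expect_error(kernel_eval(1:3, 1:4, k_lin), "mismatch")
})

test_that("kernel_matrix agrees with the scalar double loop and is PSD", {
  set.seed(4)
  X <- matrix(rnorm(20 * 6), 20)
  for (k in list(kernel_spec("LIN"), kernel_spec("RBF"),
                 kernel_spec("POL", gamma_scale = 0.3, offset = 0.1))) {
    K <- kernel_matrix(X, NULL, k)
    Kref <- outer(seq_len(20), seq_len(20),
                  Vectorize(function(i, j) kernel_eval(X[i, ], X[j, ], k)))
    expect_equal(K, Kref, tolerance = 1e-12)
  }
  Krbf <- kernel_matrix(X, NULL, kernel_spec("RBF"))
  expect_equal(diag(Krbf), rep(1, 20))
  expect_gt(min(eigen(Krbf, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  Klin <- kernel_matrix(X, NULL, kernel_spec("LIN"))
  expect_gt(min(eigen(Klin, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("alpha = 0 KRR interpolates a synthetic matrix functional", {
  ts <- synthetic_ts(n = 10, M = 4, seed = 21)
  for (kind in c("LIN", "RBF", "POL")) {
    gm <- fit_gamma(ts, kernel_spec(kind, alpha = 0))
    pred <- kernel_matrix(ts$X, gm$X, gm$kernel) %*% gm$B
    expect_lt(max(abs(pred - ts$Y)), 1e-8)
  }
  # one-point training set: exact return of the single target
  ts1 <- synthetic_ts(n = 1, M = 3, seed = 5)
  gm1 <- fit_gamma(ts1, kernel_spec("LIN", alpha = 0))
  p <- predict_gamma(gm1, ts1$X[1, ])
  expect_equal(pack_symmetric(p), ts1$Y[1, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # duplicate rows with alpha = 0 are rejected with guidance
  tsd <- synthetic_ts(n = 4, M = 3, seed = 9)
  tsd$X[2, ] <- tsd$X[1, ]; tsd$Y[2, ] <- tsd$Y[1, ]
  expect_error(fit_gamma(tsd, kernel_spec("RBF", alpha = 0)), "duplicate")
})

test_that("predictions are symmetric, continuous, and near-trace-consistent", {
  gm <- water_model()
  ts <- water_ts()
  v <- ts$X[3, ]
  p <- predict_gamma(gm, v)
  expect_equal(p$values, t(p$values))
  expect_equal(pack_symmetric(p), ts$Y[3, ], tolerance = 1e-7,
               ignore_attr = TRUE)   # interpolation at a training input
  # Lipschitz smoke test: ||gamma(v + eps u) - gamma(v)|| -> 0
  set.seed(2); u <- rnorm(length(v)); u <- u / sqrt(sum(u^2))
  devs <- vapply(c(0.1, 0.05, 0.02, 0.01, 0.005), function(eps)
    norm(predict_gamma(gm, v + eps * u)$values - p$values, "F"), 0)
  expect_true(all(diff(devs) < 0))
  # soft trace check on held-out geometries
  held <- sample_normal_mode_geometries(water_eq(), water_modes(),
                                        sampler_config(300, 5, seed = 71))
  for (g in held) {
    al <- align_to_reference(g, gm$ref)
    vv <- pack_symmetric(external_potential_matrix(al$geometry, gm$method))
    S <- overlap_matrix(al$geometry, gm$method)$values
    expect_lt(abs(sum(predict_gamma(gm, vv)$values * S) - 10), 1e-3)
  }
  expect_error(predict_gamma(gm, v[-1]), "dimension mismatch")
})

test_that("purification: hand-checkable cases and exact N-representability", {
  # 2-level toy in an orthonormal basis: occupations (1.9, 0.1) -> (2, 0)
  V <- cbind(c(cos(0.3), sin(0.3)), c(-sin(0.3), cos(0.3)))
  raw <- V %*% diag(c(1.9, 0.1)) %*% t(V)
  pur <- purify(raw, diag(2), 2)
  expect_equal(pur$values, V %*% diag(c(2, 0)) %*% t(V), tolerance = 1e-12)
  # fixed point: an already idempotent aufbau density is unchanged
  expect_equal(purify(pur, diag(2), 2)$values, pur$values, tolerance = 1e-10)
  # nonorthogonal basis: exact trace and idempotency, occupations in {0, 2}
  m <- m_sto3g(); g <- water_eq()
  s <- run_scf(g, m)
  noisy <- s$gamma$values + random_symmetric(7, 3) * 0.05
  pur2 <- purify(noisy, s$overlap, 10)
  S <- s$overlap$values
  expect_equal(sum(pur2$values * S), 10, tolerance = 1e-10)
  expect_lt(norm(pur2$values %*% S %*% pur2$values - 2 * pur2$values, "F"),
            1e-8)
  occ <- natural_orbitals(pur2, s$overlap)$occupations
  expect_equal(sort(round(occ, 8)) %in% c(0, 2), rep(TRUE, 7))
  expect_equal(sum(occ), 10, tolerance = 1e-9)
  # idempotent map
  expect_equal(purify(pur2, s$overlap, 10)$values, pur2$values,
               tolerance = 1e-9)
  expect_error(purify(noisy, s$overlap, 9), "even")
})

test_that("delta-refinement recovers affine structure and helps when exact", {
  ts <- synthetic_ts(n = 12, M = 4, seed = 33)
  # identity map
  dm <- fit_delta_refine(ts$Y, ts$Y)
  expect_lt(max(abs(predict(dm, ts$Y) - ts$Y)), 1e-8)
  # fixed bias recovery
  bias <- pack_symmetric(random_symmetric(4, 8))
  Yb <- sweep(ts$Y, 2, -bias)
  dm2 <- fit_delta_refine(ts$Y, Yb)
  expect_lt(max(abs(predict(dm2, ts$Y) - Yb)), 1e-8)
  # constructed systematic linear error: refinement wins by >= 10x
  A <- diag(ncol(ts$Y)) * 0.8
  pred_feats <- ts$Y %*% A + 0.05
  dm3 <- fit_delta_refine(pred_feats, ts$Y)
  test <- synthetic_ts(n = 6, M = 4, seed = 91)
  test_pred <- test$Y %*% A + 0.05
  rmse_raw <- sqrt(mean((test_pred - test$Y)^2))
  rmse_ref <- sqrt(mean((predict(dm3, test_pred) - test$Y)^2))
  expect_lt(rmse_ref, rmse_raw / 10)
  # training residual never above the unrefined residual
  expect_lte(sqrt(mean((predict(dm3, pred_feats) - ts$Y)^2)),
             sqrt(mean((pred_feats - ts$Y)^2)) + 1e-12)
})

test_that("delta property models recover exactly affine targets", {
  ts <- synthetic_ts(n = 15, M = 4, seed = 55)
  h <- random_symmetric(4, 2)
  E <- vapply(seq_len(15), function(i)
    sum(unpack_symmetric(ts$Y[i, ], 4) * h) + 3.7, 0)
  dp <- fit_delta_properties(ts$Y, E)
  expect_lt(max(abs(predict(dp$energy, ts$Y) - E)), 1e-9)
  # affine least squares preserves the training mean
  Fs <- lapply(1:15, function(i) matrix(rnorm(6), 2, 3))
  dp2 <- fit_delta_properties(ts$Y, E, Fs)
  mean_pred <- colMeans(predict(dp2$forces, ts$Y))
  mean_true <- colMeans(t(vapply(Fs, function(f) as.vector(t(f)), numeric(6))))
  expect_equal(mean_pred, mean_true, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("alpha = 0 beats alpha = 0.1 on the water model", {
  ts <- water_ts()
  held <- sample_normal_mode_geometries(water_eq(), water_modes(),
                                        sampler_config(300, 10, seed = 81))
  tts <- build_training_set(held, water_eq(), m_sto3g())
  rmse_for <- function(alpha) {
    gm <- fit_gamma(ts, kernel_spec("RBF", alpha = alpha))
    pred <- kernel_matrix(tts$X, gm$X, gm$kernel) %*% gm$B
    sqrt(mean((pred - tts$Y)^2))
  }
  expect_lt(rmse_for(0), rmse_for(0.1))
})

test_that("model stack flavors wire correctly", {
  gm <- water_model()
  ts <- water_ts()
  # gamma flavor at a training input: energy matches the training label
  pf <- predict_full(model_stack(gm), ts$geometries[[2]])
  expect_equal(pf$energy, ts$energies[2], tolerance = 1e-7)
  # gamma + delta refinement never increases training gamma RMSE
  feats <- t(vapply(seq_len(nrow(ts$X)), function(i) {
    raw <- predict_gamma(gm, ts$X[i, ])
    pack_symmetric(purify(raw, overlap_matrix(ts$geometries[[i]], ts$method),
                          10))
  }, numeric(ncol(ts$Y))))
  dr <- fit_delta_refine(feats, ts$Y)
  rmse_plain <- sqrt(mean((feats - ts$Y)^2))
  rmse_ref <- sqrt(mean((predict(dr, feats) - ts$Y)^2))
  expect_lte(rmse_ref, rmse_plain + 1e-12)
  # delta flavor returns E without any Fock build, but still a purified gamma
  dp <- fit_delta_properties(feats, ts$energies, ts$forces)
  stack3 <- model_stack(gm, "delta_properties", delta_props = dp)
  pf3 <- predict_full(stack3, ts$geometries[[2]], want_forces = TRUE)
  expect_identical(pf3$n_fock_builds, 0L)
  expect_s3_class(pf3$gamma, "ao_matrix")
  S <- overlap_matrix(ts$geometries[[2]], m_sto3g())$values
  expect_equal(sum(pf3$gamma$values * S), 10, tolerance = 1e-9)
  expect_error(model_stack(gm, "delta_properties"), "requires")
})

test_that("parameter recovery: test RMSE decreases with n and approaches noise", {
  sigma <- 1e-3
  test <- synthetic_ts(n = 40, M = 3, seed = 1, noise = 0)
  rmse_n <- vapply(c(5, 15, 45, 135), function(n) {
    tr <- synthetic_ts(n = n, M = 3, seed = 100 + n, noise = sigma)
    gm <- fit_gamma(tr, kernel_spec("RBF", alpha = 0))
    pred <- kernel_matrix(test$X, gm$X, gm$kernel) %*% gm$B
    sqrt(mean((pred - test$Y)^2))
  }, 0)
  expect_true(all(diff(rmse_n) < 0.2 * rmse_n[-length(rmse_n)]))  # mostly down
  expect_lt(rmse_n[4], 20 * sigma)
})

test_that("KRR equals a brute-force normal-equations solver on small problems", {
  ts <- synthetic_ts(n = 15, M = 3, seed = 61, noise = 1e-3)
  k <- kernel_spec("RBF", alpha = 1e-4)
  gm <- fit_gamma(ts, k)
  K <- kernel_matrix(ts$X, NULL, gm$kernel)
  B_ref <- solve(K + diag(1e-4, 15), ts$Y)
  expect_equal(gm$B, B_ref, tolerance = 1e-8, ignore_attr = TRUE)
})
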