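test_that("pure translation predicts U = T everywhere", {
  t_mat <- matrix(c(0.02, 0.003, 0, 0.003, 0.015, 0.001, 0, 0.001, 0.018), 3, 3)
  model <- tls_model(t_mat, matrix(0, 3, 3))
  set.seed(31)
  pos <- rand_cloud(5)
  pred <- predict_adps(model, pos)
  for (u in pred) expect_equal(unclass(u), t_mat, tolerance = 1e-15,
                               ignore_attr = TRUE)
})

test_that("libration about an axis leaves on-axis atoms unmoved", {
  t_mat <- diag(c(0.01, 0.01, 0.01))
  l_mat <- diag(c(0, 0, 0.002))        # libration about z
  model <- tls_model(t_mat, l_mat)
  pos <- matrix(c(0, 0, 3), 1, 3, dimnames = list("A", NULL))
  expect_equal(unclass(predict_adps(model, pos)$A), t_mat,
               tolerance = 1e-15, ignore_attr = TRUE)
  # off-axis atom does acquire extra displacement
  pos2 <- matrix(c(2, 0, 0), 1, 3, dimnames = list("B", NULL))
  expect_gt(predict_adps(model, pos2)$B[2, 2], t_mat[2, 2])
})

test_that("prediction matches a finite-rotation Monte-Carlo covariance", {
  set.seed(32)
  # joint Gaussian over (omega, t) with covariance [[L, S], [S', T]]
  a <- matrix(rnorm(36, sd = 0.1), 6, 6)
  sigma <- crossprod(a)
  scale6 <- diag(c(rep(sqrt(1.5e-3), 3), rep(sqrt(2e-2), 3)))
  sigma <- scale6 %*% (sigma / max(abs(sigma))) %*% scale6
  l_mat <- sigma[1:3, 1:3]; t_mat <- sigma[4:6, 4:6]; s_mat <- sigma[1:3, 4:6]
  model <- tls_model(t_mat, l_mat, s_mat, origin = c(0, 0, 0))
  n <- 4e5
  z <- matrix(rnorm(6 * n), n, 6) %*% chol(sigma)
  rodrigues <- function(w, d) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(d)
    k <- w / th
    d * cos(th) + c(k[2] * d[3] - k[3] * d[2],
                    k[3] * d[1] - k[1] * d[3],
                    k[1] * d[2] - k[2] * d[1]) * sin(th) +
      k * sum(k * d) * (1 - cos(th))
  }
  for (d in list(c(1.5, -0.5, 0.8), c(-2, 1, 0.3))) {
    disp <- t(apply(z, 1, function(row) {
      row[4:6] + rodrigues(row[1:3], d) - d
    }))
    emp <- crossprod(disp) / n
    pred <- predict_adps(model, matrix(d, 1, 3, dimnames = list("A", NULL)))$A
    expect_equal(emp, unclass(pred), tolerance = 0.01, ignore_attr = TRUE)
  }
})

test_that("TLS parameters are recovered exactly from noiseless ADPs", {
  set.seed(33)
  for (rep in 1:5) {
    pos <- rand_cloud(12)
    truth <- rand_tls_model(origin = colMeans(pos))
    adps <- predict_adps(truth, pos)
    fit <- fit_tls(adps, pos)
    expect_lt(max_tls_param_diff(fit$model, truth), 1e-8)
    expect_lt(fit$r, 1e-10)
    expect_equal(sum(diag(fit$model$S)), 0)
    expect_equal(fit$n_obs, 6L * 12L)
    expect_equal(fit$n_par, 20L)
  }
})

test_that("identical isotropic ADPs fit as pure translation", {
  set.seed(34)
  pos <- rand_cloud(8)
  iso <- displacement_tensor(0.017, 0.017, 0.017)
  adps <- setNames(rep(list(iso), 8), rownames(pos))
  fit <- fit_tls(adps, pos)
  expect_equal(fit$model$T, diag(rep(0.017, 3)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(fit$model$L)), 1e-12)
  expect_lt(max(abs(fit$model$S)), 1e-12)
  expect_lt(fit$r, 1e-12)
})

test_that("residual R scales with noise and parameter errors scale linearly", {
  set.seed(35)
  pos <- rand_cloud(12)
  truth <- rand_tls_model(origin = colMeans(pos))
  clean <- predict_adps(truth, pos)
  rmse_at <- function(sigma, reps = 100) {
    errs <- replicate(reps, {
      noisy <- lapply(clean, function(u) {
        eps <- rnorm(6, sd = sigma)
        tlsoniom:::new_u_tensor(unclass(u) + tlsoniom:::comp_to_sym(eps),
                                "cartesian")
      })
      fit <- fit_tls(noisy, pos)
      expect_gt(fit$r, 0)
      max_tls_param_diff(fit$model, truth)
    })
    sqrt(mean(errs^2))
  }
  r1 <- rmse_at(5e-4)
  r2 <- rmse_at(1e-3)
  expect_gt(r1, 0)
  expect_equal(r2 / r1, 2, tolerance = 0.25)
})

test_that("fit residual is invariant under a global rotation", {
  set.seed(36)
  pos <- rand_cloud(10)
  truth <- rand_tls_model(origin = colMeans(pos))
  adps <- predict_adps(truth, pos)
  # perturb to get a non-trivial residual
  adps <- lapply(adps, function(u)
    tlsoniom:::new_u_tensor(unclass(u) +
                              tlsoniom:::comp_to_sym(rnorm(6, sd = 2e-4)),
                            "cartesian"))
  r0 <- fit_tls(adps, pos)$r
  q <- rand_rotation()
  pos_rot <- pos %*% t(q)
  rownames(pos_rot) <- rownames(pos)
  adps_rot <- lapply(adps, function(u)
    tlsoniom:::new_u_tensor(q %*% unclass(u) %*% t(q), "cartesian"))
  expect_lt(abs(fit_tls(adps_rot, pos_rot)$r - r0), 1e-9)
})

test_that("degenerate atom arrangements are rejected with a named reason", {
  pos <- cbind(seq(1, 4), 0, 0)     # collinear
  rownames(pos) <- paste0("X", 1:4)
  iso <- displacement_tensor(0.02, 0.02, 0.02)
  adps <- setNames(rep(list(iso), 4), rownames(pos))
  expect_error(fit_tls(adps, pos), "rank-deficient")
  expect_error(fit_tls(adps[1:3], pos[1:3, ]), "at least 4")
})

test_that("predicted tensors stay PSD for sampled physical models", {
  set.seed(37)
  violations <- 0
  for (rep in 1:20) {
    a <- matrix(rnorm(36, sd = 0.1), 6, 6)
    sigma <- crossprod(a)
    scale6 <- diag(c(rep(sqrt(1e-3), 3), rep(sqrt(1.5e-2), 3)))
    sigma <- scale6 %*% (sigma / max(abs(sigma))) %*% scale6
    model <- tls_model(sigma[4:6, 4:6], sigma[1:3, 1:3], sigma[1:3, 4:6])
    pred <- predict_adps(model, rand_cloud(6))
    for (u in pred) {
      ev <- eigen(unclass(u), symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-12) violations <- violations + 1
    }
  }
  expect_equal(violations, 0)
})

test_that("subtract_internal is an exact inverse of tensor addition", {
  set.seed(38)
  labs <- paste0("A", 1:5)
  obs <- setNames(lapply(1:5, function(i)
    tlsoniom:::new_u_tensor(rand_psd3(0.03), "cartesian")), labs)
  int <- setNames(lapply(1:5, function(i)
    tlsoniom:::new_u_tensor(rand_psd3(0.005), "cartesian")), labs)
  zero <- setNames(lapply(1:5, function(i)
    displacement_tensor(0, 0, 0)), labs)
  expect_equal(max_tensor_diff(subtract_internal(obs, zero), obs), 0)
  ext <- suppressWarnings(subtract_internal(obs, int))
  back <- mapply(function(e, i2)
    tlsoniom:::new_u_tensor(unclass(e) + unclass(i2), "cartesian"),
    ext, int, SIMPLIFY = FALSE)
  expect_lt(max_tensor_diff(back, obs), 1e-15)
  expect_error(subtract_internal(obs, int[1:4]), "missing")
})

test_that("subtraction flags tensors that lose positive-definiteness", {
  obs <- list(A1 = displacement_tensor(0.01, 0.01, 0.01))
  int <- list(A1 = displacement_tensor(0.02, 0.001, 0.001))
  expect_warning(res <- subtract_internal(obs, int), "A1")
  expect_equal(attr(res, "nonpsd"), "A1")
})

test_that("tls_plus_oniom recovers ground-truth hydrogen tensors exactly", {
  fx <- generate_fixture(fixture_spec(temps = c(9, 250)))
  for (key in c("9", "250")) {
    res <- tls_plus_oniom(fx$structures[[key]], fx$modes)
    expect_lt(max_tensor_diff(res$h_adps, fx$truth$h_adps[[key]]), 1e-9)
    expect_lt(res$fit$r, 1e-10)
  }
})

test_that("with all modes below cutoff the prediction is pure TLS", {
  spec <- fixture_spec(temps = 9, cutoff = 5000)
  fx <- suppressWarnings(generate_fixture(spec))  # forward internal term is zero
  st <- fx$structures[["9"]]
  expect_warning(res <- tls_plus_oniom(st, fx$modes, cutoff = 5000),
                 "cutoff")
  # U_H must equal the pure rigid-body prediction, i.e. the ground truth
  expect_lt(max_tensor_diff(res$h_adps, fx$truth$h_adps[["9"]]), 1e-9)
})

test_that("hydrogen observations are never used in the TLS fit", {
  fx <- generate_fixture(fixture_spec(temps = 9))
  st <- fx$structures[["9"]]
  ref <- tls_plus_oniom(st, fx$modes)
  # corrupt every hydrogen ADP grossly; the fit and predictions must not move
  at <- st$atoms
  h_rows <- which(at$element == "H")
  at$u11[h_rows] <- at$u11[h_rows] * 50
  st2 <- crystal_structure(st$cell, at, temperature = st$temperature)
  res <- tls_plus_oniom(st2, fx$modes)
  expect_lt(max_tls_param_diff(res$fit$model, ref$fit$model), 1e-14)
  expect_lt(max_tensor_diff(res$h_adps, ref$h_adps), 1e-14)
})

test_that("tidy() and glance() expose the fit in broom form", {
  set.seed(39)
  pos <- rand_cloud(12)
  truth <- rand_tls_model(origin = colMeans(pos))
  fit <- fit_tls(predict_adps(truth, pos), pos)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6 + 6 + 9)
  expect_setequal(unique(td$tensor), c("T", "L", "S"))
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 20L)
  expect_equal(gl$n_atoms, 12L)
  expect_lt(gl$r, 1e-10)
})
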