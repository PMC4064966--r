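test_that("class_covariance averages trace-normalised trial covariances", {
  # identity trial: E %*% t(E) = I2, trace 2 -> 0.5 * I
  expect_equal(class_covariance(list(diag(2)))$R, diag(2) / 2)

  # hand-computed: E = [[1,1],[0,0]], E Et = [[2,0],[0,0]], trace 2
  E <- rbind(c(1, 1), c(0, 0))
  expect_equal(class_covariance(list(E))$R, rbind(c(1, 0), c(0, 0)))

  # averaging is idempotent on identical trials
  set.seed(31)
  M <- matrix(rnorm(8), 2, 4)
  expect_equal(class_covariance(list(M, M))$R, class_covariance(list(M))$R)

  # unnormalised path keeps scale
  expect_equal(class_covariance(list(diag(2)), normalise = FALSE)$R, diag(2))

  expect_error(class_covariance(list(matrix(0, 2, 3), matrix(0, 3, 3))),
               "same number")
  expect_error(class_covariance(list(matrix(0, 2, 3))), "degenerate")
})

test_that("composite covariance is the elementwise sum with trace additivity", {
  expect_equal(composite_covariance(diag(2), diag(2), diag(2), diag(2))$R,
               4 * diag(2))
  set.seed(32)
  R <- rpsd(3)
  expect_equal(composite_covariance(R, R, R, R)$R, 4 * R)

  # four trace-normalised class covariances sum to trace 4
  specs <- lapply(1:6, function(i) matrix(rnorm(12), 3, 4))
  covs <- lapply(1:4, function(k) class_covariance(specs[sample(6, 3)], k))
  Rc <- composite_covariance(covs[[1]], covs[[2]], covs[[3]], covs[[4]])
  expect_equal(sum(diag(Rc$R)), 4, tolerance = 1e-10)

  expect_error(composite_covariance(diag(2), diag(3), diag(2), diag(2)),
               "size")
})

test_that("whitening satisfies P R Pt = I, with a ridge for singular input", {
  # diagonal closed form
  wm <- whitening(diag(c(4, 1)))
  expect_equal(wm$P %*% diag(c(4, 1)) %*% t(wm$P), diag(2), tolerance = 1e-12)
  expect_equal(abs(wm$P), diag(c(0.5, 1)), tolerance = 1e-12)
  expect_equal(wm$eigvals, c(4, 1))
  expect_equal(wm$ridge, 0)

  # identity composite -> orthogonal P
  wI <- whitening(diag(3))
  expect_equal(wI$P %*% t(wI$P), diag(3), tolerance = 1e-12)

  # singular input succeeds via the recorded ridge
  ws <- whitening(diag(c(1, 0)))
  expect_gt(ws$ridge, 0)
  Rr <- diag(c(1, 0)) + diag(ws$ridge, 2)
  expect_equal(ws$P %*% Rr %*% t(ws$P), diag(2), tolerance = 1e-8)

  expect_error(whitening(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("whitening identity holds for 100 random PSD matrices", {
  withr::with_seed(33, {
    for (i in 1:100) {
      F_ <- sample(2:16, 1)
      R <- rpsd(F_, jitter = if (i %% 5 == 0) 0 else 0.1)
      wm <- whitening(R)
      Rr <- R + diag(wm$ridge, F_)
      expect_lt(max(abs(wm$P %*% Rr %*% t(wm$P) - diag(F_))), 1e-8)
    }
  })
})

test_that("own-class and rest-class eigenvalues are complementary (unit matrix)", {
  withr::with_seed(34, {
    for (i in 1:100) {
      F_ <- sample(2:16, 1)
      Rs <- rpsd_quadruple(F_)
      model <- fit_ovr_csp(Rs, m = 1, warn_overlap = FALSE)
      for (k in 1:4) {
        Rrest <- Reduce(`+`, Rs[-k])
        # W_k R_k W_kt and W_k R_rest W_kt are diagonal and sum to I
        own <- model$W[[k]] %*% Rs[[k]] %*% t(model$W[[k]])
        rest <- model$W[[k]] %*% Rrest %*% t(model$W[[k]])
        expect_lt(max(abs(own + rest - diag(F_))), 1e-8)
        expect_lt(max(abs(diag(own) - model$lam[[k]])), 1e-8)
        expect_true(all(model$lam[[k]] >= -1e-10 &
                          model$lam[[k]] <= 1 + 1e-10))
      }
    }
  })
})

test_that("whitening-route filters solve the generalized eigenproblem", {
  withr::with_seed(35, {
    for (i in 1:50) {
      F_ <- sample(2:16, 1)
      Rs <- rpsd_quadruple(F_)
      Rc <- Reduce(`+`, Rs)
      model <- fit_ovr_csp(Rs, m = 1, warn_overlap = FALSE)
      for (k in 1:4) {
        # independent oracle: eigen of solve(Rc) %*% R_k
        ge <- eigen(solve(Rc) %*% Rs[[k]])
        vals <- sort(Re(ge$values), decreasing = TRUE)
        expect_lt(max(abs(vals - model$lam[[k]])), 1e-8)
        # rows of W_k parallel to the generalized eigenvectors
        ord <- order(Re(ge$values), decreasing = TRUE)
        V <- Re(ge$vectors[, ord, drop = FALSE])
        for (j in seq_len(F_)) {
          w <- model$W[[k]][j, ]; v <- V[, j]
          cosang <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
          expect_gt(cosang, 1 - 1e-6)
        }
      }
    }
  })
})

test_that("degenerate and closed-form CSP cases behave as derived", {
  # all classes share one covariance: no direction preferred, lam = 1/4
  set.seed(36)
  R <- rpsd(5)
  model <- fit_ovr_csp(list(R, R, R, R), m = 2, warn_overlap = FALSE)
  for (k in 1:4)
    expect_equal(model$lam[[k]], rep(0.25, 5), tolerance = 1e-10)

  # 2x2 closed form: class 1 variance on axis 1, rest on axis 2
  Rs <- list(diag(c(1, 0)), diag(c(0, 1 / 3)), diag(c(0, 1 / 3)),
             diag(c(0, 1 / 3)))
  m2 <- fit_ovr_csp(Rs, m = 1)
  top <- m2$Wtil[[1]][1, ]
  expect_gt(abs(top[1]) / sqrt(sum(top^2)), 1 - 1e-6)
  expect_equal(m2$lam[[1]][1], 1, tolerance = 1e-6)
})

test_that("simultaneous whitening and scale invariance hold for the fitted filters", {
  withr::with_seed(37, {
    for (i in 1:20) {
      F_ <- sample(3:12, 1)
      Rs <- rpsd_quadruple(F_)
      model <- fit_ovr_csp(Rs, m = 1, warn_overlap = FALSE)
      Rc <- Reduce(`+`, Rs)
      for (k in 1:4) {
        expect_lt(max(abs(model$W[[k]] %*% Rc %*% t(model$W[[k]]) -
                            diag(F_))), 1e-6)
        expect_false(is.unsorted(rev(model$lam[[k]])))  # descending
      }
      # global rescale leaves filter directions unchanged (rows unit-free
      # up to the whitening scale); eigenvalues are identical
      scaled <- fit_ovr_csp(lapply(Rs, function(R) 7.3 * R), m = 1,
                            warn_overlap = FALSE)
      for (k in 1:4) {
        expect_equal(scaled$lam[[k]], model$lam[[k]], tolerance = 1e-9)
        ratio <- scaled$W[[k]] / model$W[[k]]
        expect_lt(stats::sd(ratio[abs(model$W[[k]]) > 1e-6]), 1e-6)
      }
    }
  })
})

test_that("filter truncation, overlap warning and apply_filters follow the contract", {
  set.seed(38)
  Rs <- rpsd_quadruple(5)
  model <- fit_ovr_csp(Rs, m = 2)
  expect_equal(dim(model$Wtil[[1]]), c(4L, 5L))
  expect_equal(model$Wtil[[3]], model$W[[3]][c(1, 2, 4, 5), ])

  # 2m > F duplicates rows, with a warning
  expect_warning(model3 <- fit_ovr_csp(Rs, m = 3), "overlap")
  expect_equal(nrow(model3$Wtil[[1]]), 6L)
  expect_equal(model3$Wtil[[1]][3, ], model3$Wtil[[1]][4, ])  # row 3 twice

  expect_error(fit_ovr_csp(Rs, m = 0), "m must be")
  expect_error(fit_ovr_csp(Rs, m = 6), "m must be")

  # identity-like application: Z = Wtil %*% E, linear in E
  E <- matrix(rnorm(20), 5, 4)
  Z <- apply_filters(model, 2, E)
  expect_equal(Z, model$Wtil[[2]] %*% E)
  expect_equal(apply_filters(model, 2, 2 * E), 2 * Z)
  expect_true(all(apply_filters(model, 2, matrix(0, 5, 4)) == 0))
  expect_error(apply_filters(model, 1, matrix(0, 4, 4)), "expects")
})

test_that("CSP models round-trip through JSON", {
  set.seed(39)
  model <- fit_ovr_csp(rpsd_quadruple(6), m = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_csp_model(model, path)
  back <- read_csp_model(path)
  expect_equal(back$m, model$m)
  expect_equal(back$F, model$F)
  for (k in 1:4) {
    expect_equal(back$W[[k]], model$W[[k]], tolerance = 1e-12)
    expect_equal(back$Wtil[[k]], model$Wtil[[k]], tolerance = 1e-12)
    expect_equal(back$lam[[k]], model$lam[[k]], tolerance = 1e-12)
  }
})
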