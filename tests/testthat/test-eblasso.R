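test_that("the closed-form prior-variance update maximizes the per-effect objective", {
  # verify sigma2* = (u-1)/S, u = (-S + sqrt(S^2 + 8*lambda*Q^2))/(4*lambda)
  # against a numeric maximizer, across magnitudes
  grid <- expand.grid(S = c(0.5, 5, 50, 5000), Qf = c(1.5, 3, 10),
                      lambda = c(0.01, 1, 50))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]; Q <- grid$Qf[i] * sqrt(S); lam <- grid$lambda[i]
    if (Q^2 - S - 2 * lam <= 0) next
    u <- (-S + sqrt(S^2 + 8 * lam * Q^2)) / (4 * lam)
    s2_closed <- (u - 1) / S
    opt <- optimize(ell_oracle, c(0, 10 * s2_closed + 1), S = S, Q = Q,
                    lambda = lam, maximum = TRUE, tol = 1e-12)
    expect_equal(s2_closed, opt$maximum, tolerance = 1e-5)
    # and the lambda -> 0 limit is the relevance-vector-machine update
    opt0 <- optimize(ell_oracle, c(0, 10 * (Q^2 - S) / S^2 + 1), S = S, Q = Q,
                     lambda = 0, maximum = TRUE, tol = 1e-12)
    expect_equal((Q^2 - S) / S^2, opt0$maximum, tolerance = 1e-5)
  }
})

test_that("a single-column fit at lambda = 0 reproduces the RVM stationary point", {
  set.seed(2)
  n <- 40
  x <- matrix(rnorm(n), n, 1)
  y <- 2 * x[, 1] + rnorm(n)
  s02 <- 1.3
  fit <- eblasso(x, y, lambda = 0, sigma02 = s02)
  # S and Q at the empty model are unchanged by the only column's own entry
  xt <- x[, 1] - mean(x[, 1]); yt <- y - mean(y)
  S <- sum(xt^2) / s02; Q <- sum(xt * yt) / s02
  expect_equal(unname(fit$sigma2), (Q^2 - S) / S^2, tolerance = 1e-8)
  expect_equal(length(fit$retained), 1L)
})

test_that("the compiled and pure-R engines agree", {
  for (seed in c(7, 23)) {
    set.seed(seed)
    n <- 50; M <- 12
    X <- matrix(rnorm(n * M), n, M)
    y <- X[, 2] * 1.2 - X[, 7] * 0.9 + rnorm(n)
    f_cpp <- eblasso(X, y)
    f_r <- eblasso(X, y, engine = "R", check = TRUE)
    expect_equal(names(f_cpp$coefficients), names(f_r$coefficients))
    expect_equal(f_cpp$coefficients, f_r$coefficients, tolerance = 1e-6)
    expect_equal(f_cpp$sigma02, f_r$sigma02, tolerance = 1e-6)
    expect_equal(f_cpp$lambda, f_r$lambda, tolerance = 1e-6)
  }
})

test_that("an overwhelming penalty leaves the model empty", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  y <- rnorm(40)
  fit <- eblasso(X, y, lambda = 1e8)
  expect_equal(length(fit$retained), 0L)
  expect_equal(unname(coef(fit)["(Intercept)"]), mean(y))
})

test_that("greedy selection agrees with a brute-force oracle on a small problem", {
  # independent oracle: same greedy schedule but with S, Q computed from an
  # explicit inverse of C at every step (no incremental bookkeeping)
  set.seed(14)
  n <- 30; M <- 5
  X <- matrix(rnorm(n * M), n, M)
  y <- 1.5 * X[, 2] - 1.1 * X[, 4] + rnorm(n)
  s02 <- 0.8; lam <- 0.5
  Xt <- scale(X, scale = FALSE); yt <- y - mean(y)
  sig2 <- numeric(M)
  for (step in 1:50) {
    C <- s02 * diag(n) + Xt %*% diag(sig2, M) %*% t(Xt)
    Ci <- solve(C)
    S <- Q <- numeric(M)
    for (j in 1:M) {
      # exclude column j's own contribution
      Cj <- C - sig2[j] * tcrossprod(Xt[, j])
      Cji <- solve(Cj)
      S[j] <- drop(t(Xt[, j]) %*% Cji %*% Xt[, j])
      Q[j] <- drop(t(Xt[, j]) %*% Cji %*% yt)
    }
    u <- (-S + sqrt(S^2 + 8 * lam * Q^2)) / (4 * lam)
    s2new <- ifelse(Q^2 - S - 2 * lam > 0, (u - 1) / S, 0)
    gains <- ell_oracle(s2new, S, Q, lam) - ell_oracle(sig2, S, Q, lam)
    if (max(gains) < 1e-10) break
    j <- which.max(gains)
    sig2[j] <- s2new[j]
  }
  fit <- eblasso(X, y, lambda = lam, sigma02 = s02)
  full <- numeric(M); full[fit$retained] <- fit$sigma2
  expect_equal(which(full > 0), which(sig2 > 0))
  expect_equal(full, sig2, tolerance = 1e-4)
})

test_that("converged fits satisfy the retention criterion exactly", {
  for (seed in c(5, 9, 31)) {
    set.seed(seed)
    n <- 60; M <- 40
    X <- matrix(rnorm(n * M), n, M)
    y <- X[, 1] * 1.4 + rnorm(n)
    fit <- eblasso(X, y)
    crit <- fit$Q^2 - fit$S - 2 * fit$lambda
    ret <- logical(M); ret[fit$retained] <- TRUE
    expect_true(all(crit[ret] > 0))
    expect_true(all(crit[!ret & fit$candidate] <= 1e-6))
  }
})

test_that("the penalized marginal likelihood is non-decreasing within every sweep", {
  set.seed(6)
  n <- 80; M <- 60
  X <- matrix(rnorm(n * M), n, M)
  y <- X[, 3] - 0.8 * X[, 10] + rnorm(n)
  for (eng in c("cpp", "R")) {
    fit <- eblasso(X, y, engine = eng)
    for (tr in fit$loglik_trace)
      if (length(tr) > 1) expect_true(all(diff(tr) > -1e-8))
  }
})

test_that("fits are invariant to candidate column order", {
  set.seed(8)
  n <- 70; M <- 30
  X <- matrix(rnorm(n * M), n, M)
  colnames(X) <- paste0("c", 1:M)
  y <- 1.3 * X[, 5] - X[, 20] + rnorm(n)
  fit1 <- eblasso(X, y)
  perm <- sample(M)
  fit2 <- eblasso(X[, perm], y)
  t1 <- test_effects(fit1); t2 <- test_effects(fit2)
  expect_setequal(t1$label, t2$label)
  expect_equal(t1$estimate[order(t1$label)], t2$estimate[order(t2$label)],
               tolerance = 1e-6)
})

test_that("t tests use the posterior variance and residual degrees of freedom", {
  fake <- structure(list(
    coefficients = c(eff = 2), sigma2 = c(eff = 1), retained = 1L,
    Sigma = matrix(1, 1, 1), df = 30, labels = NULL,
    candidate = TRUE, S = 1, Q = 2), class = "eblasso")
  tab <- test_effects(fake)
  expect_equal(tab$t, 2)
  expect_equal(tab$P, 2 * pt(-2, 30), tolerance = 1e-12)  # about 0.0547
  expect_false(tab$significant)
  # monotone: larger |t| gives smaller P
  fake$coefficients <- c(eff = 4)
  expect_lt(test_effects(fake)$P, tab$P)
})

test_that("methods on the fit object are coherent", {
  sim <- sim_additive_pop(seed = 77)
  des <- build_design(sim$parents, sim$y)
  fit <- eblasso(des)
  expect_s3_class(fit, "eblasso")
  expect_equal(fitted(fit) + residuals(fit), sim$y, ignore_attr = TRUE)
  expect_equal(predict(fit), fitted(fit))
  pr <- predict(fit, newx = des$X, new_unpenalized = des$U)
  expect_equal(pr, unname(fitted(fit)), ignore_attr = TRUE)
  s <- summary(fit)
  expect_s3_class(s, "summary.eblasso")
  expect_true(all(c("label", "estimate", "t", "P") %in% names(s$effects)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2))
  expect_output(print(fit), "Empirical Bayesian LASSO")
})

test_that("cross-validation selects hyperparameters deterministically", {
  set.seed(10)
  n <- 45; M <- 10
  X <- matrix(rnorm(n * M), n, M)
  y <- X[, 1] + rnorm(n)
  one <- cv_eblasso(X, y, folds = 3, grid = data.frame(a_gamma = 1, b_gamma = 0.1),
                    seed = 4)
  expect_equal(one$a_gamma, 1)
  expect_equal(one$b_gamma, 0.1)
  g <- data.frame(a_gamma = c(0.5, 0.5), b_gamma = c(0.1, 0.1))
  two <- cv_eblasso(X, y, folds = 3, grid = g, seed = 4)
  expect_equal(two$cv$mse[1], two$cv$mse[2])   # identical points, same folds
  expect_error(cv_eblasso(X, y, folds = 4), "folds")
  expect_error(cv_eblasso(X, y, folds = 3, grid = data.frame()), "grid")
})
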