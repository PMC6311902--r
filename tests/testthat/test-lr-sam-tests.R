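test_that("all five tests are null (p = 1) under the mirrored design", {
  pm <- mirrored_pm(n_half = 8, K = 3)
  res <- lr_sam_tests(pm)
  expect_equal(res$statistic, rep(0, 5), tolerance = 1e-8)
  expect_equal(res$pvalue, rep(1, 5), tolerance = 1e-8)
})

test_that("W, W1 and WS coincide for a single peptide", {
  pm <- toy_pm(n = 30, K = 1, seed = 5)
  fit <- fit_logistic(pm$y, pm$z)
  w <- test_wald_W(fit)
  w1 <- test_wald_W1(fit)
  ws <- test_wald_WS(pm$y, pm$z)
  expect_equal(w$statistic, w1$statistic, tolerance = 1e-10)
  expect_equal(w$statistic, ws$statistic, tolerance = 1e-10)
  expect_equal(w$pvalue, w1$pvalue, tolerance = 1e-10)
  expect_equal(w$pvalue, ws$pvalue, tolerance = 1e-10)
  # scalar case: W is the squared z-statistic
  b <- fit$coefficients[fit$idx_pep]
  expect_equal(w$statistic, unname(b^2 / fit$vcov[2, 2]), tolerance = 1e-10)
})

test_that("L, W, W1 and WS match independent matrix / likelihood oracles", {
  pm <- toy_pm(n = 40, K = 3, seed = 11)
  fit <- fit_logistic(pm$y, pm$z)

  # L: both log-likelihoods recomputed by direct Bernoulli summation
  l <- test_lrt(pm$y, pm$z, full = fit)
  ll_full <- bernoulli_loglik(fit$coefficients, cbind(1, pm$y), pm$z)
  a0 <- stats::qlogis(mean(pm$z))
  ll_null <- bernoulli_loglik(a0, matrix(1, nrow(pm$y)), pm$z)
  expect_equal(l$statistic, 2 * (ll_full - ll_null), tolerance = 1e-8)
  expect_equal(l$pvalue, pchisq(l$statistic, 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # W: quadratic form recomputed with an independent linear solve
  b <- fit$coefficients[fit$idx_pep]
  V <- fit$vcov[fit$idx_pep, fit$idx_pep]
  w <- test_wald_W(fit)
  expect_equal(w$statistic, drop(t(b) %*% solve(V, b)), tolerance = 1e-8)

  # W1: hand-assembled weight vector and quadratic form
  tk <- (1 / diag(V)) / sum(1 / diag(V))
  bp <- sum(tk * b); A <- drop(t(tk) %*% V %*% tk)
  w1 <- test_wald_W1(fit)
  expect_equal(w1$statistic, bp^2 / A, tolerance = 1e-10)
  expect_equal(unname(w1$pooled_estimate), c(bp, A), tolerance = 1e-10)
  # equal variances, zero covariances: pooled estimate is the plain mean
  fit_eq <- fit
  fit_eq$vcov <- diag(4) * 0.3
  fit_eq$idx_pep <- 2:4
  w1_eq <- test_wald_W1(fit_eq)
  expect_equal(w1_eq$pooled_estimate[["estimate"]], mean(b), tolerance = 1e-10)
  expect_equal(w1_eq$pooled_estimate[["variance"]], 0.3 / 3, tolerance = 1e-10)

  # WS: independent refit on the pre-summed column via glm
  ws <- test_wald_WS(pm$y, pm$z)
  g <- stats::glm(pm$z ~ rowSums(pm$y), family = stats::binomial,
                  control = stats::glm.control(epsilon = 1e-12))
  z2 <- (stats::coef(g)[2] / sqrt(stats::vcov(g)[2, 2]))^2
  expect_equal(ws$statistic, unname(z2), tolerance = 1e-6)
})

test_that("SVC matches a dense-algebra oracle and a Monte-Carlo mixture tail", {
  set.seed(7)
  n <- 30; K <- 3
  y <- matrix(rnorm(n * K), n, K)
  z <- rep(c(0L, 1L), length.out = n)
  r <- test_score_SVC(y, z)

  # dense oracle: form Q, P and the eigenvalues explicitly in n x n space
  mu0 <- rep(mean(z), n)
  rr <- z - mu0
  Kmat <- y %*% t(y)
  expect_equal(r$statistic, drop(t(rr) %*% Kmat %*% rr), tolerance = 1e-10)
  V <- diag(mu0 * (1 - mu0))
  X0 <- matrix(1, n, 1)
  P <- V - V %*% X0 %*% solve(t(X0) %*% V %*% X0) %*% t(X0) %*% V
  ev <- eigen(P, symmetric = TRUE)
  Ph <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  lam <- eigen(Ph %*% Kmat %*% Ph, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10]
  expect_equal(sort(r$lambdas), sort(lam), tolerance = 1e-10)

  # Monte-Carlo oracle for the mixture tail (1e6 draws, 3 MC SEs)
  set.seed(2)
  draws <- as.vector(matrix(rchisq(1e6 * length(lam), df = 1),
                            ncol = length(lam)) %*% lam)
  mc <- mean(draws > r$statistic)
  expect_lt(abs(r$pvalue - mc), 3 * sqrt(mc * (1 - mc) / 1e6))

  # all-zero peptide matrix is degenerate: statistic 0, p 1
  r0 <- test_score_SVC(matrix(0, n, K), z)
  expect_identical(r0$statistic, 0)
  expect_identical(r0$pvalue, 1)

  # K = 1: single-eigenvalue mixture is a scaled chi-square tail
  y1 <- matrix(rnorm(n), ncol = 1)
  r1 <- test_score_SVC(y1, z)
  expect_equal(r1$pvalue,
               pchisq(r1$statistic / r1$lambdas, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("mixture_chisq_sf agrees with closed forms and Monte Carlo", {
  q <- 7.31
  # identity mixture is chi-square with K df
  expect_equal(as.numeric(mixture_chisq_sf(rep(1, 4), q)),
               pchisq(q, 4, lower.tail = FALSE), tolerance = 1e-8)
  # a single weight rescales a 1-df chi-square
  expect_equal(as.numeric(mixture_chisq_sf(2.5, q)),
               pchisq(q / 2.5, 1, lower.tail = FALSE), tolerance = 1e-8)
  # lambda = (2, 1), q = 5 versus 1e6 simulated mixture draws
  set.seed(1)
  draws <- 2 * rchisq(1e6, 1) + rchisq(1e6, 1)
  mc <- mean(draws > 5)
  p <- mixture_chisq_sf(c(2, 1), 5)
  expect_lt(abs(p - mc), 3 * sqrt(mc * (1 - mc) / 1e6))
  expect_identical(attr(p, "method"), "davies")
  # the moment fallback is a serviceable approximation of the same tail
  expect_lt(abs(lrsam:::.liu_moment_sf(c(2, 1), 5) - mc), 0.01)

  # monotone non-increasing in q, equal to 1 at q = 0
  qs <- seq(0, 25, by = 0.5)
  ps <- vapply(qs, function(qq) as.numeric(mixture_chisq_sf(c(2, 1, 0.3), qq)),
               numeric(1))
  expect_identical(ps[1], 1)
  expect_true(all(diff(ps) <= 1e-10))

  expect_error(mixture_chisq_sf(c(1, -1), 2), "negative")
  expect_error(mixture_chisq_sf(numeric(0), 2), "zero")
})

test_that("shifting one peptide column is absorbed by the intercept", {
  pm <- toy_pm(n = 36, K = 3, seed = 21)
  base <- lr_sam_tests(pm)
  shifted <- pm
  shifted$y[, 2] <- shifted$y[, 2] + 7.3
  res <- lr_sam_tests(shifted)
  expect_equal(res$pvalue, base$pvalue, tolerance = 1e-8)
})

test_that("batch covariates enter every model without changing the contract", {
  pm <- toy_pm(n = 40, K = 2, seed = 31,
               batch = factor(rep(c("b1", "b2"), each = 20)))
  res <- lr_sam_tests(pm)
  expect_identical(nrow(res), 5L)
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  # the batch coefficient is estimated but excluded from the Wald block
  cov <- stats::model.matrix(~b, data.frame(b = pm$batch))[, -1, drop = FALSE]
  fit <- fit_logistic(pm$y, pm$z, cov)
  expect_identical(length(fit$idx_pep), 2L)
  expect_identical(length(fit$coefficients), 4L)
})
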