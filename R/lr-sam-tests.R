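.test_result <- function(method, statistic, pvalue, df = NULL, lambdas = NULL,
                         pooled_estimate = NULL, diagnostics = character(0)) {
  structure(list(method = method, statistic = statistic, df = df,
                 lambdas = lambdas, pvalue = pvalue,
                 pooled_estimate = pooled_estimate,
                 diagnostics = diagnostics),
            class = "lrsam_test")
}

#' @noRd
#' @method print lrsam_test
#' @export
print.lrsam_test <- function(x, ...) {
  null_desc <- if (!is.null(x$lambdas)) {
    sprintf("mixture, lambda = %s", paste(signif(x$lambdas, 4), collapse = ", "))
  } else if (!is.null(x$df)) sprintf("chi-square, %s df", x$df) else "-"
  cat(sprintf("%s: statistic = %s, p = %s (%s)%s\n", x$method,
              format(x$statistic, digits = 6), format(x$pvalue, digits = 4),
              null_desc,
              if (length(x$diagnostics)) paste0(" [", paste(x$diagnostics,
                                                            collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Likelihood-ratio test (L) on the peptide coefficients
#'
#' Compares the full logistic model (intercept + covariates + K peptide
#' columns) with the null model without peptides. Twice the log-likelihood
#' gap is referred to a chi-square with K degrees of freedom. If the full
#' fit did not reach score convergence the p-value is withheld.
#'
#' @param y,z,covariates as in [fit_logistic()].
#' @param full optionally, a pre-computed full-model [fit_logistic()] fit.
#' @return An `lrsam_test` with `method = "L"`.
#' @export
test_lrt <- function(y, z, covariates = NULL, full = NULL) {
  if (is.null(full)) full <- fit_logistic(y, z, covariates)
  null_fit <- fit_logistic(NULL, z, covariates)
  stat <- max(0, 2 * (full$loglik - null_fit$loglik))
  K <- full$K
  diag <- character(0)
  p <- pchisq(stat, df = K, lower.tail = FALSE)
  if (!full$converged) {
    p <- NA_real_
    diag <- "full fit not converged; p withheld"
  }
  .test_result("L", stat, p, df = K, diagnostics = diag)
}

# peptide-block covariance with a singularity-tolerant quadratic form
.wald_quadform <- function(b, V) {
  Vinv <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (!is.null(Vinv)) {
    list(stat = drop(t(b) %*% Vinv %*% b), df = length(b), note = NULL)
  } else {
    ev <- eigen(V, symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-10
    Vinv <- ev$vectors[, keep, drop = FALSE] %*%
      (t(ev$vectors[, keep, drop = FALSE]) / ev$values[keep])
    list(stat = drop(t(b) %*% Vinv %*% b), df = sum(keep),
         note = "singular peptide covariance; pseudo-inverse, reduced df")
  }
}

#' Full Wald test (W) on the peptide coefficients
#'
#' Quadratic form of the K peptide coefficients in their estimated
#' covariance (covariate and intercept coefficients are excluded), referred
#' to a chi-square with K degrees of freedom. Separated or unconverged fits
#' yield `NA`: the Wald statistic collapses under separation, so flagging is
#' the honest outcome.
#'
#' @param fit a [fit_logistic()] result with at least one peptide column.
#' @return An `lrsam_test` with `method = "W"`.
#' @export
test_wald_W <- function(fit) {
  stopifnot(inherits(fit, "fitted_logistic"), fit$K >= 1L)
  if (!fit$converged || fit$separation_flag) {
    return(.test_result("W", NA_real_, NA_real_, df = fit$K,
                        diagnostics = "unusable fit (separation/non-convergence)"))
  }
  b <- fit$coefficients[fit$idx_pep]
  V <- fit$vcov[fit$idx_pep, fit$idx_pep, drop = FALSE]
  qf <- .wald_quadform(b, V)
  .test_result("W", qf$stat, pchisq(qf$stat, df = qf$df, lower.tail = FALSE),
               df = qf$df,
               diagnostics = if (is.null(qf$note)) character(0) else qf$note)
}

#' Pooled one-degree-of-freedom Wald test (W1)
#'
#' Pools the peptide coefficients by inverse-variance weights
#' `t_k = (1/Var b_k) / sum_j (1/Var b_j)` into `b_p = sum t_k b_k`, with
#' variance `A = t' Var(b) t` using the full peptide-block covariance, and
#' refers `b_p^2 / A` to a chi-square with 1 degree of freedom. Appropriate
#' when peptide effects are homogeneous.
#'
#' @inheritParams test_wald_W
#' @return An `lrsam_test` with `method = "W1"`; `pooled_estimate` carries
#'   `b_p` and `A`.
#' @export
test_wald_W1 <- function(fit) {
  stopifnot(inherits(fit, "fitted_logistic"), fit$K >= 1L)
  if (!fit$converged || fit$separation_flag) {
    return(.test_result("W1", NA_real_, NA_real_, df = 1L,
                        diagnostics = "unusable fit (separation/non-convergence)"))
  }
  b <- fit$coefficients[fit$idx_pep]
  V <- fit$vcov[fit$idx_pep, fit$idx_pep, drop = FALSE]
  v <- diag(V)
  if (any(v <= 0)) {
    stop("test_wald_W1: non-positive coefficient variance", call. = FALSE)
  }
  tk <- (1 / v) / sum(1 / v)
  bp <- sum(tk * b)
  A <- drop(t(tk) %*% V %*% tk)
  stat <- bp^2 / A
  .test_result("W1", stat, pchisq(stat, df = 1, lower.tail = FALSE), df = 1L,
               pooled_estimate = c(estimate = bp, variance = A))
}

#' Summed-covariate Wald test (WS)
#'
#' Fits the reduced model `logit P(z = 1) = alpha + beta* sum_k y_k`
#' (+ covariates) and tests `beta* = 0` by a 1-df Wald statistic. Under
#' homogeneous peptide effects this is the natural collapsed version of the
#' full model.
#'
#' @inheritParams test_lrt
#' @return An `lrsam_test` with `method = "WS"`.
#' @export
test_wald_WS <- function(y, z, covariates = NULL) {
  y <- as.matrix(y)
  s <- matrix(rowSums(y), ncol = 1L, dimnames = list(NULL, "pep_sum"))
  fit <- fit_logistic(s, z, covariates)
  if (!fit$converged || fit$separation_flag) {
    return(.test_result("WS", NA_real_, NA_real_, df = 1L,
                        diagnostics = "unusable fit (separation/non-convergence)"))
  }
  b <- fit$coefficients[fit$idx_pep]
  v <- fit$vcov[fit$idx_pep, fit$idx_pep]
  stat <- unname(drop(b^2 / v))
  .test_result("WS", stat, pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Variance-component score test (SVC)
#'
#' Treats the peptide coefficients as random with common variance `tau`
#' (known prior weights `w_k`, flat by default) and scores the boundary null
#' `tau = 0`. With `r = z - mu0` the residuals of the null logistic model,
#' the statistic is `Q = r' Y W Y' r`. Its null distribution is the weighted
#' mixture `sum_k lambda_k chi^2_1`, with `lambda_k` the nonzero eigenvalues
#' of `P^{1/2} K P^{1/2}` where `K = Y W Y'` and
#' `P = V - V X0 (X0' V X0)^{-1} X0' V` is the score variance of the null
#' model (`V = diag(mu0 (1 - mu0))`, `X0` = intercept plus covariates).
#' Only the K-by-K inner matrix is eigendecomposed, so cost does not grow
#' with the number of subjects. Tail probabilities come from
#' [mixture_chisq_sf()].
#'
#' @inheritParams test_lrt
#' @param weights positive prior weights `w_k`, recycled to K; default 1.
#' @return An `lrsam_test` with `method = "SVC"` and the `lambdas` used.
#' @export
test_score_SVC <- function(y, z, covariates = NULL, weights = NULL) {
  y <- as.matrix(y)
  K <- ncol(y)
  if (is.null(weights)) weights <- rep(1, K)
  weights <- rep_len(weights, K)
  if (any(weights < 0)) stop("test_score_SVC: negative weights", call. = FALSE)
  null_fit <- fit_logistic(NULL, z, covariates)
  X0 <- matrix(1, nrow = length(z), ncol = 1L,
               dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  eta <- drop(X0 %*% null_fit$coefficients)
  mu0 <- plogis(eta)
  r <- z - mu0
  Yw <- sweep(y, 2L, sqrt(weights), `*`)
  Q <- sum(drop(crossprod(Yw, r))^2)
  if (all(y == 0)) {
    return(.test_result("SVC", 0, 1, lambdas = numeric(0),
                        diagnostics = "degenerate: all-zero peptide matrix"))
  }
  v <- mu0 * (1 - mu0)
  M <- crossprod(Yw, Yw * v)
  C <- crossprod(Yw, X0 * v)
  B <- M - C %*% solve(crossprod(X0, X0 * v), t(C))
  lambdas <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambdas <- lambdas[lambdas > max(lambdas) * 1e-10]
  if (!length(lambdas)) {
    return(.test_result("SVC", Q, 1, lambdas = numeric(0),
                        diagnostics = "degenerate: zero-rank kernel"))
  }
  p <- mixture_chisq_sf(lambdas, Q)
  .test_result("SVC", Q, as.numeric(p), lambdas = lambdas,
               diagnostics = paste0("tail: ", attr(p, "method")))
}

#' Upper tail of a weighted mixture of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k chi^2_1 > q)` by numerical inversion of the
#' characteristic function (the Davies/Imhof integral), with absolute
#' accuracy about `1e-6`. If the integration fails or returns an
#' out-of-range value, a Liu-type four-moment chi-square approximation is
#' used instead; the chosen path is recorded in the `"method"` attribute.
#'
#' @param lambdas non-negative weights, not all zero.
#' @param q non-negative quantile.
#' @return Tail probability in `[0, 1]` with attribute `method` equal to
#'   `"davies"` or `"moment"`.
#' @export
mixture_chisq_sf <- function(lambdas, q) {
  if (any(lambdas < 0)) stop("mixture_chisq_sf: negative weights", call. = FALSE)
  lambdas <- lambdas[lambdas > 0]
  if (!length(lambdas)) stop("mixture_chisq_sf: all weights zero", call. = FALSE)
  if (q < 0) stop("mixture_chisq_sf: negative quantile", call. = FALSE)
  if (q == 0) return(structure(1, method = "exact"))
  if (length(unique(lambdas)) == 1L) {
    return(structure(pchisq(q / lambdas[1L], df = length(lambdas),
                            lower.tail = FALSE), method = "exact"))
  }
  p <- .imhof_sf(lambdas, q)
  if (is.finite(p) && p > -1e-4 && p < 1 + 1e-4) {
    return(structure(min(max(p, 0), 1), method = "davies"))
  }
  structure(.liu_moment_sf(lambdas, q), method = "moment")
}

# Characteristic-function inversion (Imhof/Davies integral)
#   P(Q > q) = 1/2 + (1/pi) int_0^inf sin(theta(u)) / (u rho(u)) du
# evaluated panel by panel (one half oscillation period each) so the
# quadrature never sees more than one sign change. The integral is
# truncated when the analytic tail bounds -- 2/(K rho(U)) from the decay
# of rho and 4/(q U rho(U)) from integration by parts of the oscillation
# -- drop below 1e-7, well inside the 1e-6 accuracy target.
.imhof_sf <- function(lambdas, q, acc = 1e-7, max_panels = 5000L) {
  s <- max(lambdas)
  lam <- lambdas / s
  qq <- q / s
  K <- length(lam)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * qq * u
    log_rho <- 0.25 * colSums(log1p(outer(lam^2, u^2)))
    out <- sin(theta) / u * exp(-log_rho)
    out[u == 0] <- 0.5 * (sum(lam) - qq)
    out
  }
  du <- 2 * pi / max(qq, 1)
  total <- 0
  u_hi <- 0
  for (j in seq_len(max_panels)) {
    u_lo <- u_hi
    u_hi <- u_lo + du
    I <- tryCatch(
      integrate(integrand, u_lo, u_hi, rel.tol = 1e-10, abs.tol = 1e-12,
                subdivisions = 200L, stop.on.error = TRUE)$value,
      error = function(e) NA_real_)
    if (!is.finite(I)) return(NA_real_)
    total <- total + I
    rho_u <- exp(0.25 * sum(log1p(lam^2 * u_hi^2)))
    tail_bound <- min(2 / (K * rho_u),
                      if (qq > 0) 4 / (qq * u_hi * rho_u) else Inf)
    if (tail_bound < acc) return(0.5 + total / pi)
  }
  NA_real_
}

# Liu-Tang-Zhang four-moment chi-square approximation to the mixture tail
.liu_moment_sf <- function(lambdas, q) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  t_star <- (q - mu_q) / sigma_q
  min(max(pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta,
                 lower.tail = FALSE), 0), 1)
}

#' Run the LR-SAM test battery on one protein
#'
#' Convenience wrapper fitting the full logistic model once and dispatching
#' the requested tests on a [build_protein_matrix()] object. Batch labels
#' attached to the matrix enter all models (including the SVC null) as
#' fixed indicator columns.
#'
#' @param pm a `protein_matrix`.
#' @param methods subset of `c("L", "W", "W1", "WS", "SVC")`.
#' @param weights prior weights for the SVC test.
#' @return A data.frame with one row per test: `protein`, `method`,
#'   `statistic`, `df_or_lambdas`, `pvalue`, `converged`, `notes`.
#' @export
lr_sam_tests <- function(pm, methods = c("L", "W", "W1", "WS", "SVC"),
                         weights = NULL) {
  stopifnot(inherits(pm, "protein_matrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  covariates <- NULL
  if (!is.null(pm$batch) && nlevels(pm$batch) > 1L) {
    covariates <- stats::model.matrix(~batch, data.frame(batch = pm$batch))[, -1L,
                                                                            drop = FALSE]
  }
  full <- NULL
  if (any(methods %in% c("L", "W", "W1"))) {
    full <- fit_logistic(pm$y, pm$z, covariates)
  }
  res <- lapply(methods, function(m) {
    switch(m,
           L = test_lrt(pm$y, pm$z, covariates, full = full),
           W = test_wald_W(full),
           W1 = test_wald_W1(full),
           WS = test_wald_WS(pm$y, pm$z, covariates),
           SVC = test_score_SVC(pm$y, pm$z, covariates, weights = weights))
  })
  data.frame(
    protein = pm$protein,
    method = methods,
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    df_or_lambdas = vapply(res, function(r) {
      if (!is.null(r$lambdas)) paste(signif(r$lambdas, 8), collapse = ";")
      else as.character(r$df)
    }, character(1)),
    pvalue = vapply(res, function(r) r$pvalue, numeric(1)),
    converged = vapply(res, function(r) !is.na(r$pvalue), logical(1)),
    notes = vapply(res, function(r) paste(r$diagnostics, collapse = "; "),
                   character(1)),
    stringsAsFactors = FALSE)
}
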