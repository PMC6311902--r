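# overflow-safe log(1 + exp(x))
.log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Logistic maximum-likelihood fit by iteratively reweighted least squares
#'
#' Fits `logit P(z = 1) = alpha + covariates + y %*% beta` by Newton/IRLS.
#' Convergence is declared when the largest absolute score component falls
#' below `tol`. The returned covariance is the inverse observed information
#' at the MLE. Quasi-complete separation -- the small-sample failure mode of
#' these reverse regressions -- is flagged when a coefficient exceeds
#' `separation_bound` on the log-odds scale without score convergence, or
#' when the information matrix degenerates along the way; a flagged fit is
#' unusable for Wald-type tests (their p-values become `NA`).
#'
#' @param y n x K matrix of peptide log2 relative intensities, or `NULL`
#'   for an intercept/covariate-only (null) model.
#' @param z binary 0/1 outcome (group indicator), both classes present.
#' @param covariates optional n x c numeric matrix of adjustment columns
#'   (e.g. batch indicators), entering as fixed effects.
#' @param tol convergence tolerance on the maximum absolute score.
#' @param max_iter iteration cap.
#' @param separation_bound log-odds magnitude beyond which an unconverged
#'   coefficient is treated as diverging.
#' @return An object of class `fitted_logistic`: coefficients, `vcov`,
#'   `loglik`, `converged`, `n_iter`, `separation_flag`, and the index of
#'   the peptide block (`idx_pep`).
#' @export
fit_logistic <- function(y, z, covariates = NULL, tol = 1e-8,
                         max_iter = 100L, separation_bound = 15) {
  z <- as.numeric(z)
  n <- length(z)
  if (!all(z %in% c(0, 1))) stop("fit_logistic: z must be 0/1", call. = FALSE)
  if (length(unique(z)) < 2L) {
    stop("fit_logistic: z contains a single class", call. = FALSE)
  }
  X <- matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
  idx_cov <- integer(0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    idx_cov <- ncol(X) + seq_len(ncol(covariates))
    X <- cbind(X, covariates)
  }
  idx_pep <- integer(0)
  if (!is.null(y)) {
    y <- as.matrix(y)
    if (nrow(y) != n) stop("fit_logistic: nrow(y) != length(z)", call. = FALSE)
    if (is.null(colnames(y))) colnames(y) <- paste0("pep", seq_len(ncol(y)))
    idx_pep <- ncol(X) + seq_len(ncol(y))
    X <- cbind(X, y)
  }
  if (!all(is.finite(X))) stop("fit_logistic: non-finite covariates", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("fit_logistic: design is rank deficient; dependent column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  beta <- numeric(ncol(X))
  loglik <- -n * log(2)              # all-zero start: p = 1/2
  converged <- FALSE
  separation <- FALSE
  singular <- FALSE
  iter <- 0L
  score <- crossprod(X, z - 0.5)
  repeat {
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { singular <- TRUE; break }
    # step-halving keeps the likelihood monotone on wild steps
    ll_old <- loglik
    h <- 1
    repeat {
      beta_new <- beta + h * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(z * eta_new - .log1pexp(eta_new))
      if (is.finite(ll_new) && (ll_new >= ll_old - 1e-12 || h < 1e-4)) break
      h <- h / 2
    }
    beta <- drop(beta_new)
    loglik <- ll_new
    p <- plogis(eta_new)
    score <- crossprod(X, z - p)
    if (max(abs(beta)) > separation_bound && max(abs(score)) >= tol &&
        iter >= max_iter) break
  }
  if (!converged && (max(abs(beta)) > separation_bound || singular)) {
    separation <- TRUE
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  info <- crossprod(X, X * pmax(p * (1 - p), 0))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  notes <- character(0)
  if (is.null(vc)) {
    vc <- MASS::ginv(info)
    notes <- "pseudo-inverse covariance (singular information)"
    if (!converged) separation <- TRUE
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, vcov = vc, loglik = loglik,
                 converged = converged, n_iter = iter,
                 separation_flag = separation, idx_pep = idx_pep,
                 idx_cov = idx_cov, n = n, K = length(idx_pep),
                 notes = notes),
            class = "fitted_logistic")
}

#' @noRd
#' @method print fitted_logistic
#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf("fitted_logistic: n=%d, K=%d, loglik=%.4f, %s%s\n",
              x$n, x$K, x$loglik,
              if (x$converged) sprintf("converged in %d iter", x$n_iter)
              else "NOT converged",
              if (x$separation_flag) " [separation]" else ""))
  print(x$coefficients)
  invisible(x)
}
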