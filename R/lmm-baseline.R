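#' Specify a linear mixed model variant
#'
#' The MSstats-style model for absolute log2 intensities is
#' `y = mu + G_i + S(G)_j(i) + P_k + R_l + (GxP)_ik + (PxR)_kl + eps`,
#' where the subject and run effects (the peptide-by-run interaction
#' follows the run) may each be fixed or random, giving the four variants
#' FF, FR, RF and RR. The reference channel is group 0 with its subject and
#' group-by-peptide effects anchored at zero; fixed factors use sum-to-zero
#' contrasts.
#'
#' @param variant one of `"FF"`, `"FR"`, `"RF"`, `"RR"` (subject then run;
#'   F = fixed, R = random).
#' @return A list with `variant`, `subject`, `run`.
#' @export
lmm_spec <- function(variant = c("FF", "FR", "RF", "RR")) {
  variant <- match.arg(variant)
  list(variant = variant,
       subject = if (substr(variant, 1, 1) == "F") "fixed" else "random",
       run = if (substr(variant, 2, 2) == "F") "fixed" else "random")
}

# sum-to-zero contrast columns for a factor (levels sorted), named pfx1..pfx(m-1)
.sum_contrast_cols <- function(f, pfx) {
  lev <- sort(unique(f[!is.na(f)]))
  m <- length(lev)
  out <- matrix(0, nrow = length(f), ncol = m - 1L)
  for (j in seq_len(m - 1L)) {
    out[which(f == lev[j]), j] <- 1
    out[which(f == lev[m]), j] <- -1
  }
  colnames(out) <- paste0(pfx, seq_len(max(m - 1L, 0L)))
  out
}

#' Build the design bundle for one protein's LMM
#'
#' Assembles the response (log2 absolute intensities, reference channel
#' rows included as group 0) and the fixed design / random grouping factors
#' for an [lmm_spec()] variant. The group column is coded +1 / -1 for the
#' two comparison groups and 0 for the reference, so the fitted coefficient
#' is G1 (= -G2) and the group contrast G1 - G2 equals twice it. Batch
#' labels, when present, enter as sum-to-zero fixed columns in the
#' random-subject variants only (with fixed subject effects a
#' subject-constant batch column is collinear with the subject block).
#'
#' @param table an [mrm_table()] on the linear scale with endogenous and
#'   reference channel records.
#' @param protein protein identifier.
#' @param spec an [lmm_spec()] (or a variant name).
#' @return A design bundle: `y`, `X`, grouping `factors`, `spec`, bookkeeping.
#' @export
build_design <- function(table, protein, spec = lmm_spec("FF")) {
  stopifnot(inherits(table, "mrm_table"))
  if (is.character(spec)) spec <- lmm_spec(spec)
  if (table$scale != "linear") {
    stop("build_design: expected linear-scale intensities with channels",
         call. = FALSE)
  }
  rec <- table$records[table$records$protein == protein, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("build_design: protein '", protein, "' not present", call. = FALSE)
  }
  if (!any(rec$channel == "reference")) {
    stop("build_design: reference channel records required (group 0 rows)",
         call. = FALSE)
  }
  is_ref <- rec$channel == "reference"
  y <- log2(rec$value)
  group <- ifelse(is_ref, ".ref", rec$group)
  subject <- ifelse(is_ref, ".ref0", rec$sample_id)
  run <- rec$run
  peptide <- rec$peptide
  groups <- sort(setdiff(unique(group), ".ref"))
  if (length(groups) != 2L) {
    stop("build_design: exactly two non-reference groups required, found ",
         length(groups), call. = FALSE)
  }
  if (length(unique(run)) < 2L) {
    stop("build_design: run effect requested but only one run present",
         call. = FALSE)
  }
  K <- length(unique(peptide))

  grp <- ifelse(group == groups[1L], 1, ifelse(group == groups[2L], -1, 0))
  X <- cbind(`(Intercept)` = 1, grp = grp)
  if (K >= 2L) {
    pep_cols <- .sum_contrast_cols(peptide, "pep")
    X <- cbind(X, pep_cols, grp * pep_cols)
    colnames(X)[(ncol(X) - K + 2L):ncol(X)] <- paste0("gp", seq_len(K - 1L))
  }
  if (spec$subject == "fixed") {
    for (g in groups) {
      subs <- sort(unique(subject[group == g]))
      if (length(subs) >= 2L) {
        sc <- .sum_contrast_cols(ifelse(group == g, subject, NA), "s")
        sc[group != g, ] <- 0
        colnames(sc) <- paste0("s", match(g, groups), "_",
                               seq_len(ncol(sc)))
        X <- cbind(X, sc)
      }
    }
  }
  if (spec$run == "fixed") {
    run_cols <- .sum_contrast_cols(run, "run")
    X <- cbind(X, run_cols)
    if (K >= 2L) {
      pr <- matrix(0, nrow = nrow(rec),
                   ncol = (K - 1L) * ncol(run_cols))
      nm <- character(ncol(pr))
      jj <- 0L
      for (a in seq_len(K - 1L)) {
        for (b in seq_len(ncol(run_cols))) {
          jj <- jj + 1L
          pr[, jj] <- pep_cols[, a] * run_cols[, b]
          nm[jj] <- paste0("pr", a, "_", b)
        }
      }
      colnames(pr) <- nm
      X <- cbind(X, pr)
    }
  }
  if (!is.null(table$batch) && spec$subject == "random") {
    bt <- table$batch[rec$sample_id]
    # reference rows inherit the batch of their run
    for (l in unique(run[is_ref])) {
      bl <- unique(bt[run == l & !is_ref])
      bt[is_ref & run == l] <- bl[1L]
    }
    if (length(unique(bt)) >= 2L) {
      X <- cbind(X, .sum_contrast_cols(bt, "batch"))
    }
  }
  structure(list(y = y, X = X, spec = spec,
                 factors = list(subject = factor(subject), run = factor(run),
                                pep_run = factor(paste(peptide, run, sep = ":"))),
                 groups = groups, protein = protein, K = K,
                 n_obs = length(y)),
            class = "lmm_design")
}

#' Fit one LMM variant by maximum likelihood
#'
#' The all-fixed variant is a constrained least-squares fit; variants with
#' random subject and/or run (plus peptide-by-run) effects are fitted with
#' [lme4::lmer()] using ML (`REML = FALSE`) so that AIC values are
#' comparable across variants with different fixed-effect structures.
#' The group contrast `G1 - G2`, its standard error, and a pragmatic
#' residual degrees-of-freedom convention (observations minus the rank of
#' the fixed design) are extracted for the t-test.
#'
#' @param design an [build_design()] bundle.
#' @return An object of class `lmm_fit` with coefficients, variance
#'   components, `loglik_ml`, `aic`, `group_contrast`, `converged`.
#' @export
fit_lmm <- function(design) {
  stopifnot(inherits(design, "lmm_design"))
  spec <- design$spec
  X <- design$X
  y <- design$y
  n <- length(y)
  rank_x <- qr(X)$rank
  if (rank_x < ncol(X)) {
    stop("fit_lmm: fixed design rank deficient (", ncol(X) - rank_x,
         " dependent columns)", call. = FALSE)
  }
  notes <- character(0)
  if (spec$subject == "fixed" && spec$run == "fixed") {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    sigma2_ml <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
    aic <- -2 * ll + 2 * (rank_x + 1)
    XtXinv <- chol2inv(chol(crossprod(X)))
    sigma2_res <- rss / (n - rank_x)
    se_grp <- sqrt(sigma2_res * XtXinv[2L, 2L])
    coefs <- fit$coefficients
    vc <- c(eps = sigma2_res)
    conv <- TRUE
  } else {
    d <- data.frame(.y = y, check.names = FALSE)
    keep <- setdiff(colnames(X), "(Intercept)")
    for (cn in keep) d[[cn]] <- X[, cn]
    rterms <- c(
      if (spec$subject == "random") "(1 | .subj)",
      if (spec$run == "random") c("(1 | .run)", "(1 | .pepr)"))
    if (spec$subject == "random") d$.subj <- design$factors$subject
    if (spec$run == "random") {
      d$.run <- design$factors$run
      d$.pepr <- design$factors$pep_run
    }
    fml <- stats::as.formula(paste(
      ".y ~ 1 +", paste(c(sprintf("`%s`", keep), rterms), collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
    fe <- lme4::fixef(fit)
    Vf <- as.matrix(stats::vcov(fit))
    gi <- match("grp", gsub("`", "", names(fe)))
    se_grp <- sqrt(Vf[gi, gi])
    coefs <- fe
    vcm <- as.data.frame(lme4::VarCorr(fit))
    vc <- stats::setNames(vcm$vcov, vcm$grp)
    names(vc) <- sub("^\\.subj$", "subject", names(vc))
    names(vc) <- sub("^\\.run$", "run", names(vc))
    names(vc) <- sub("^\\.pepr$", "pep_run", names(vc))
    names(vc) <- sub("^Residual$", "eps", names(vc))
    conv <- length(fit@optinfo$conv$lme4) == 0L
    if (lme4::isSingular(fit)) notes <- c(notes, "boundary (zero variance)")
    coefs <- stats::setNames(as.numeric(fe), gsub("`", "", names(fe)))
  }
  grp_coef <- coefs[["grp"]]
  structure(list(variant = spec$variant, coefficients = coefs,
                 variance_components = vc, loglik_ml = ll, aic = aic,
                 group_contrast = c(estimate = 2 * grp_coef,
                                    se = 2 * se_grp,
                                    df = n - rank_x),
                 converged = conv, n_obs = n, rank_fixed = rank_x,
                 notes = notes),
            class = "lmm_fit")
}

#' @noRd
#' @method print lmm_fit
#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit[%s]: logLik(ML)=%.3f, AIC=%.3f, G1-G2=%.4f (se %.4f)%s\n",
              x$variant, x$loglik_ml, x$aic, x$group_contrast[["estimate"]],
              x$group_contrast[["se"]],
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' t-test for the group effect of a fitted LMM
#'
#' Tests `H0: G1 = G2` by `t = (G1 - G2) / SE` with the fit's residual
#' degrees-of-freedom convention.
#'
#' @param fit an [fit_lmm()] result.
#' @return An `lrsam_test` with `method = "LMM_<variant>"`; statistic is the
#'   t value.
#' @export
test_group_effect <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  est <- fit$group_contrast[["estimate"]]
  se <- fit$group_contrast[["se"]]
  df <- fit$group_contrast[["df"]]
  if (!fit$converged) {
    return(.test_result(paste0("LMM_", fit$variant), NA_real_, NA_real_,
                        df = df, diagnostics = "fit not converged"))
  }
  if (!is.finite(se) || se <= 1e-12) {
    return(.test_result(paste0("LMM_", fit$variant), NA_real_, NA_real_,
                        df = df, diagnostics = "degenerate: zero standard error"))
  }
  tval <- est / se
  .test_result(paste0("LMM_", fit$variant), tval,
               2 * pt(-abs(tval), df = df), df = df)
}

#' Select the best LMM variant by AIC
#'
#' Returns the variant with the smallest ML-based AIC; exact ties are
#' broken in the fixed order FF, FR, RF, RR. Failed fits are excluded.
#'
#' @param fits named list of [fit_lmm()] results (names are variants).
#' @return The selected variant name.
#' @export
select_best_aic <- function(fits) {
  order_pref <- c("FF", "FR", "RF", "RR")
  nm <- intersect(order_pref, names(fits))
  fits <- fits[nm]
  ok <- vapply(fits, function(f) inherits(f, "lmm_fit") && is.finite(f$aic),
               logical(1))
  if (!any(ok)) stop("select_best_aic: no usable fits", call. = FALSE)
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  names(fits)[which.min(aics)]   # which.min keeps the first on exact ties
}

#' Fit all four LMM variants and test the group effect
#'
#' @param table,protein as in [build_design()].
#' @param variants subset of the four variant names.
#' @param best also report the AIC-selected variant as `LMM_best`.
#' @return data.frame of test rows (method `LMM_FF` ... `LMM_best`).
#' @export
lmm_group_tests <- function(table, protein,
                            variants = c("FF", "FR", "RF", "RR"),
                            best = TRUE) {
  fits <- lapply(variants, function(v) {
    tryCatch(fit_lmm(build_design(table, protein, lmm_spec(v))),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "lmm_failed"))
  })
  names(fits) <- variants
  rows <- lapply(variants, function(v) {
    f <- fits[[v]]
    if (inherits(f, "lmm_failed")) {
      data.frame(protein = protein, method = paste0("LMM_", v),
                 statistic = NA_real_, df_or_lambdas = NA_character_,
                 pvalue = NA_real_, converged = FALSE, notes = f$error,
                 stringsAsFactors = FALSE)
    } else {
      r <- test_group_effect(f)
      data.frame(protein = protein, method = r$method, statistic = r$statistic,
                 df_or_lambdas = as.character(r$df), pvalue = r$pvalue,
                 converged = !is.na(r$pvalue),
                 notes = paste(r$diagnostics, collapse = "; "),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (best) {
    usable <- fits[vapply(fits, inherits, logical(1), "lmm_fit")]
    if (length(usable)) {
      bv <- select_best_aic(usable)
      brow <- out[out$method == paste0("LMM_", bv), , drop = FALSE]
      brow$method <- "LMM_best"
      brow$notes <- paste0("selected ", bv,
                           if (nzchar(brow$notes)) paste0("; ", brow$notes) else "")
      out <- rbind(out, brow)
    }
  }
  rownames(out) <- NULL
  out
}
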