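.lr_methods <- c("L", "W", "W1", "WS", "SVC")
.lmm_methods <- c("LMM_FF", "LMM_FR", "LMM_RF", "LMM_RR", "LMM_best")

#' Monte-Carlo rejection-rate estimate for one scenario
#'
#' Simulates `n_reps` datasets under a [sim_config()], runs every requested
#' method on each, and tallies the proportion of p-values below `alpha`.
#' Repetitions are seeded independently from `seed` (counter-based
#' sub-seeding), so results are reproducible and order-invariant. Failed or
#' separated fits yield `NA` p-values; the headline `rate` counts them as
#' non-rejections, while `rate_converged` restricts the denominator to
#' usable repetitions and `n_failed` reports their number.
#'
#' @param config a [sim_config()] (its own `seed` element is ignored here).
#' @param methods any of `"L"`, `"W"`, `"W1"`, `"WS"`, `"SVC"`,
#'   `"LMM_FF"`, `"LMM_FR"`, `"LMM_RF"`, `"LMM_RR"`, `"LMM_best"`.
#' @param n_reps repetitions.
#' @param alpha nominal level.
#' @param seed master seed for the repetition streams.
#' @return data.frame with one row per method: scenario descriptors,
#'   `n_reps`, `n_rejections`, `rate`, `n_failed`, `rate_converged`, `alpha`.
#' @export
estimate_rejection_rate <- function(config, methods = c(.lr_methods),
                                    n_reps = 1000L, alpha = 0.05,
                                    seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1L)
  methods <- match.arg(methods, c(.lr_methods, .lmm_methods),
                       several.ok = TRUE)
  lr <- intersect(methods, .lr_methods)
  lmm <- intersect(methods, .lmm_methods)
  variants <- sub("^LMM_", "", setdiff(lmm, "LMM_best"))
  if ("LMM_best" %in% lmm) variants <- c("FF", "FR", "RF", "RR")
  pmat <- matrix(NA_real_, nrow = n_reps, ncol = length(methods),
                 dimnames = list(NULL, methods))
  for (rep in seq_len(n_reps)) {
    config$seed <- seed_for_rep(seed, rep)
    tab <- simulate_dataset(config)
    if (length(lr)) {
      pm <- build_protein_matrix(log2_relative_intensity(tab),
                                 config$protein_id, ref_group = "1")
      res <- lr_sam_tests(pm, methods = lr)
      pmat[rep, res$method] <- res$pvalue
    }
    if (length(lmm)) {
      res <- lmm_group_tests(tab, config$protein_id, variants = variants,
                             best = "LMM_best" %in% lmm)
      keep <- res$method %in% lmm
      pmat[rep, res$method[keep]] <- res$pvalue[keep]
    }
  }
  n_rej <- colSums(pmat < alpha, na.rm = TRUE)
  n_fail <- colSums(is.na(pmat))
  data.frame(
    subject_type = config$subject_type, run_type = config$run_type,
    n_total = config$n_total, group_scenario = config$group_scenario,
    interaction_scenario = config$interaction_scenario,
    method = methods, n_reps = n_reps, n_rejections = as.integer(n_rej),
    rate = n_rej / n_reps, n_failed = as.integer(n_fail),
    rate_converged = ifelse(n_reps > n_fail, n_rej / (n_reps - n_fail),
                            NA_real_),
    alpha = alpha, row.names = NULL, stringsAsFactors = FALSE)
}

#' Rejection rates over a scenario grid
#'
#' Drives [estimate_rejection_rate()] over the factorial of subject/run
#' types, sample sizes and scenarios, one row per cell and method. Per-cell
#' seeds are derived deterministically from `seed`; a cell whose evaluation
#' fails is recorded with `NA` rates and the grid continues.
#'
#' @param subject_types,run_types,n_totals,group_scenarios,interaction_scenarios
#'   grid axes (vectors of [sim_config()] argument values).
#' @param methods,n_reps,alpha,seed as in [estimate_rejection_rate()].
#' @param ... further arguments to [sim_config()] (e.g. `K`).
#' @return data.frame of per-cell, per-method summaries.
#' @export
run_scenario_grid <- function(subject_types = c("fixed", "random"),
                              run_types = c("fixed", "random"),
                              n_totals = c(20L, 50L, 100L),
                              group_scenarios = "GS0",
                              interaction_scenarios = "none",
                              methods = c(.lr_methods), n_reps = 1000L,
                              alpha = 0.05, seed = 1L, ...) {
  grid <- expand.grid(subject_type = subject_types, run_type = run_types,
                      n_total = n_totals, group_scenario = group_scenarios,
                      interaction_scenario = interaction_scenarios,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- seed_for_rep(seed, i * 1000003L)
    out[[i]] <- tryCatch({
      cfg <- sim_config(n_total = grid$n_total[i],
                        subject_type = grid$subject_type[i],
                        run_type = grid$run_type[i],
                        group_scenario = grid$group_scenario[i],
                        interaction_scenario = grid$interaction_scenario[i],
                        ...)
      estimate_rejection_rate(cfg, methods = methods, n_reps = n_reps,
                              alpha = alpha, seed = cell_seed)
    }, error = function(e) {
      data.frame(grid[i, , drop = FALSE], method = methods, n_reps = n_reps,
                 n_rejections = NA_integer_, rate = NA_real_,
                 n_failed = NA_integer_, rate_converged = NA_real_,
                 alpha = alpha, row.names = NULL)
    })
  }
  do.call(rbind, out)
}

#' Per-protein differential-abundance analysis of an MRM study
#'
#' Runs the requested LR-SAM tests (on log2 relative intensities) and LMM
#' baselines (on absolute log2 intensities including the reference channel)
#' for every protein in a study table, with batch labels entering the
#' logistic models as fixed indicator columns, and flags proteins passing a
#' Bonferroni-corrected threshold `alpha / m` where `m` is the number of
#' proteins in the table. Proteins whose fits fail are reported with their
#' error message, not dropped.
#'
#' @param table an [mrm_table()]: linear scale with channel pairs when LMM
#'   methods are requested, otherwise a `log2_ratio` table is accepted.
#' @param methods as in [estimate_rejection_rate()].
#' @param ref_group group label coded 0 in the logistic models.
#' @param alpha family-wise level.
#' @param correction only `"bonferroni"` is offered.
#' @param normalize quantile-normalize the log2 ratios before testing.
#' @return A `study_result`: list with `results` (tidy data.frame including
#'   a `significant` flag), `threshold`, `m`, `alpha`.
#' @export
analyze_study <- function(table, methods = c("W", "W1", "WS", "SVC"),
                          ref_group = NULL, alpha = 0.05,
                          correction = "bonferroni", normalize = FALSE) {
  stopifnot(inherits(table, "mrm_table"))
  correction <- match.arg(correction)
  methods <- match.arg(methods, c(.lr_methods, .lmm_methods),
                       several.ok = TRUE)
  lr <- intersect(methods, .lr_methods)
  lmm <- intersect(methods, .lmm_methods)
  if (length(lmm) && table$scale != "linear") {
    stop("analyze_study: LMM methods need the linear-scale two-channel table",
         call. = FALSE)
  }
  ratio_tab <- if (table$scale == "log2_ratio") table else
    log2_relative_intensity(table)
  if (normalize) ratio_tab <- quantile_normalize(ratio_tab)
  proteins <- sort(unique(table$records$protein))
  m <- length(proteins)
  if (m == 0L) stop("analyze_study: no proteins", call. = FALSE)
  threshold <- alpha / m
  variants <- sub("^LMM_", "", setdiff(lmm, "LMM_best"))
  if ("LMM_best" %in% lmm) variants <- c("FF", "FR", "RF", "RR")
  rows <- lapply(proteins, function(pr) {
    out <- NULL
    if (length(lr)) {
      out <- tryCatch({
        pm <- build_protein_matrix(ratio_tab, pr, ref_group = ref_group)
        lr_sam_tests(pm, methods = lr)
      }, error = function(e) {
        data.frame(protein = pr, method = lr, statistic = NA_real_,
                   df_or_lambdas = NA_character_, pvalue = NA_real_,
                   converged = FALSE, notes = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
    }
    if (length(lmm)) {
      lm_rows <- tryCatch(
        lmm_group_tests(table, pr, variants = variants,
                        best = "LMM_best" %in% lmm),
        error = function(e) {
          data.frame(protein = pr, method = lmm, statistic = NA_real_,
                     df_or_lambdas = NA_character_, pvalue = NA_real_,
                     converged = FALSE, notes = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
      lm_rows <- lm_rows[lm_rows$method %in% lmm, , drop = FALSE]
      out <- rbind(out, lm_rows)
    }
    out
  })
  results <- do.call(rbind, rows)
  results$significant <- !is.na(results$pvalue) & results$pvalue < threshold
  rownames(results) <- NULL
  structure(list(results = results, threshold = threshold, m = m,
                 alpha = alpha, correction = correction),
            class = "study_result")
}

#' @noRd
#' @method print study_result
#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "study_result: %d proteins, threshold %.3g (%s, alpha = %g)\n",
    x$m, x$threshold, x$correction, x$alpha))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig)) {
    tab <- table(sig$method)
    cat("  significant per method:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("  no significant proteins\n")
  }
  invisible(x)
}

#' Write a tidy results table
#'
#' @param x a `study_result` or the data.frame returned by the test
#'   wrappers.
#' @param path output path (`.csv` comma, otherwise tab).
#' @export
write_results <- function(x, path) {
  if (inherits(x, "study_result")) x <- x$results
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
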