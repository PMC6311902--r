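# Shared fixture builders. Everything is generated in code; no stored data.

# Long-format Area-Ratio records for `n_subj` subjects x `peptides`, one run
# per subject, groups alternating 1/2.
toy_ratio_records <- function(n_subj = 4, peptides = c("p1", "p2"),
                              values = NULL) {
  grid <- expand.grid(peptide = peptides, subj = seq_len(n_subj),
                      stringsAsFactors = FALSE)
  if (is.null(values)) values <- 2^seq_len(nrow(grid))
  data.frame(sample_id = sprintf("S%02d", grid$subj),
             group = as.character(2L - grid$subj %% 2L),
             run = sprintf("R%02d", grid$subj),
             protein = "P1", peptide = grid$peptide,
             value = values, channel = "ratio",
             stringsAsFactors = FALSE)
}

toy_ratio_table <- function(...) mrm_table(toy_ratio_records(...))

# A protein_matrix with standard-normal entries and balanced groups.
toy_pm <- function(n = 12, K = 2, seed = 99, batch = NULL) {
  set.seed(seed)
  y <- matrix(rnorm(n * K), n, K,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              paste0("pep", seq_len(K))))
  z <- rep(c(0L, 1L), length.out = n)
  structure(list(protein = "P1", y = y, z = z, batch = batch,
                 peptide_ids = colnames(y), sample_ids = rownames(y),
                 ref_group = "1", n_dropped = 0L),
            class = "protein_matrix")
}

# Mirrored design: every covariate row appears once with z = 0 and once
# with z = 1, forcing the score at beta = 0 to vanish exactly.
mirrored_pm <- function(n_half = 6, K = 3, seed = 4) {
  set.seed(seed)
  y_half <- matrix(rnorm(n_half * K), n_half, K)
  y <- rbind(y_half, y_half)
  colnames(y) <- paste0("pep", seq_len(K))
  structure(list(protein = "P1", y = y,
                 z = rep(c(0L, 1L), each = n_half), batch = NULL,
                 peptide_ids = colnames(y),
                 sample_ids = sprintf("S%02d", seq_len(2 * n_half)),
                 ref_group = "1", n_dropped = 0L),
            class = "protein_matrix")
}

# Direct Bernoulli log-likelihood (independent of the IRLS code path).
bernoulli_loglik <- function(beta, X, z) {
  eta <- drop(X %*% beta)
  sum(z * eta - log1p(exp(eta)))
}

expect_rate_within <- function(rate, target, n_reps) {
  tol <- 3 * sqrt(target * (1 - target) / n_reps)
  expect_lt(abs(rate - target), max(tol, 1e-12),
            label = sprintf("rate %.4f vs target %.4f (tol %.4f)",
                            rate, target, tol))
}
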