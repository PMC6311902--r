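#' Simulation configuration for a spike-in MRM design
#'
#' Encodes the generative model for a two-group MRM experiment with a
#' spiked-in reference: absolute log2 intensities are
#' `mu + G_i + S(G)_j(i) + P_k + R_l + (GxP)_ik + (PxR)_kl + eps`, with the
#' reference channel's group, subject and group-by-peptide effects set to
#' zero. One run per endogenous sample carries both channels, so log2
#' ratios cancel the peptide, run and peptide-by-run terms exactly. Fixed
#' effects are equally spaced symmetric grids scaled so their population
#' mean square equals the corresponding variance (see
#' [make_effect_grid()]); random effects are independent normals with the
#' same variances. Defaults are the study conditions of the reference
#' simulation design: `mu = 15`, error variance 0.5, K = 4 peptides,
#' subject/run variance 0.25, peptide and peptide-by-run variance 0.1,
#' group scenarios GS0 (no group effect) / GS1 (`G2 - G1 = 1/3`), and
#' interaction scenarios none / IS1 (`sigma2_GP = 0.05`) / IS2
#' (`sigma2_GP = 0.1`) with sign-mirrored profiles `(-1)^i` per group.
#'
#' @param n_total total endogenous sample size, split equally between the
#'   two groups.
#' @param K number of peptides (>= 2).
#' @param subject_type,run_type `"fixed"` or `"random"`; the
#'   peptide-by-run interaction follows the run type.
#' @param group_scenario `"GS0"` or `"GS1"`.
#' @param interaction_scenario `"none"`, `"IS1"` or `"IS2"`.
#' @param mu,sigma2_eps,sigma2_S,sigma2_R,sigma2_PR,sigma2_P model scales.
#' @param seed optional integer seed for [simulate_dataset()].
#' @param protein_id protein label in the generated table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_total = 20L, K = 4L,
                       subject_type = c("fixed", "random"),
                       run_type = c("fixed", "random"),
                       group_scenario = c("GS0", "GS1"),
                       interaction_scenario = c("none", "IS1", "IS2"),
                       mu = 15, sigma2_eps = 0.5, sigma2_S = 0.25,
                       sigma2_R = 0.25, sigma2_PR = 0.1, sigma2_P = 0.1,
                       seed = NULL, protein_id = "PROT1") {
  subject_type <- match.arg(subject_type)
  run_type <- match.arg(run_type)
  group_scenario <- match.arg(group_scenario)
  interaction_scenario <- match.arg(interaction_scenario)
  n_total <- as.integer(n_total)
  if (n_total < 4L || n_total %% 2L != 0L) {
    stop("sim_config: n_total must be even and >= 4", call. = FALSE)
  }
  if (K < 2L) stop("sim_config: K must be >= 2 (grid formulas)", call. = FALSE)
  vars <- c(sigma2_eps, sigma2_S, sigma2_R, sigma2_PR, sigma2_P)
  if (any(vars < 0)) stop("sim_config: negative variance", call. = FALSE)
  structure(list(n_total = n_total, K = as.integer(K),
                 subject_type = subject_type, run_type = run_type,
                 group_scenario = group_scenario,
                 interaction_scenario = interaction_scenario,
                 mu = mu, sigma2_eps = sigma2_eps, sigma2_S = sigma2_S,
                 sigma2_R = sigma2_R, sigma2_PR = sigma2_PR,
                 sigma2_P = sigma2_P,
                 sigma2_GP = switch(interaction_scenario, none = 0,
                                    IS1 = 0.05, IS2 = 0.1),
                 seed = seed, protein_id = protein_id),
            class = "sim_config")
}

#' @noRd
#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: n=%d (2 x %d), K=%d, subject %s, run %s, %s/%s\n",
    x$n_total, x$n_total / 2L, x$K, x$subject_type, x$run_type,
    x$group_scenario, x$interaction_scenario))
  invisible(x)
}

#' Equally spaced symmetric fixed-effect grid
#'
#' Returns the n-point grid `-e + 2 (j - 1) / (n - 1) * e` with
#' `e = sqrt(3 (n - 1) / (n + 1)) * sigma`, which has exact mean zero and
#' population mean square (divisor n) equal to `sigma2`. With
#' `alternating = TRUE` the reversed profile `e - 2 (j - 1) / (n - 1) * e`
#' is returned, the base pattern of the interaction grids whose sign flips
#' with the other index (run parity for peptide-by-run, group for
#' group-by-peptide).
#'
#' @param n_levels number of levels (>= 2).
#' @param sigma2 target population variance (>= 0).
#' @param alternating return the reversed profile used by interaction grids.
#' @return Numeric vector of length `n_levels`.
#' @export
make_effect_grid <- function(n_levels, sigma2, alternating = FALSE) {
  if (n_levels < 2L) stop("make_effect_grid: need >= 2 levels", call. = FALSE)
  if (sigma2 < 0) stop("make_effect_grid: negative variance", call. = FALSE)
  e <- sqrt(3 * (n_levels - 1) / (n_levels + 1) * sigma2)
  g <- -e + 2 * (seq_len(n_levels) - 1) / (n_levels - 1) * e
  if (alternating) -g else g
}

# deterministic per-repetition sub-seed below 2^31
seed_for_rep <- function(master, rep) {
  m <- 2147483647
  as.integer((((as.double(master) %% m) * 48271 + as.double(rep) * 16807) %% m))
}

#' Simulate one MRM dataset
#'
#' Draws a complete two-channel MRM table under a [sim_config()]: for each
#' of the `n_total` subjects (first half group 1, second half group 2) one
#' run carries K endogenous and K paired reference observations. Both
#' channels of a run share the run and peptide-by-run contributions
#' exactly, while each observation gets its own `N(0, sigma2_eps)` error.
#' Values are returned on the linear intensity scale (`2^log2value`).
#'
#' @param config a [sim_config()]; its `seed` (if non-`NULL`) makes the
#'   draw reproducible.
#' @return An [mrm_table()] with `scale = "linear"` and channel pairs.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_total
  J <- n %/% 2L
  K <- config$K
  L <- n                                   # one run per endogenous sample

  G <- if (config$group_scenario == "GS1") c(-1 / 6, 1 / 6) else c(0, 0)
  # groups alternate across runs so the fixed run grid stays balanced
  # between groups; j(i) is the subject's index within its group
  subj_grp <- rep_len(c(1L, 2L), n)
  j_within <- (seq_len(n) + 1L) %/% 2L
  S <- if (config$subject_type == "fixed") {
    make_effect_grid(J, config$sigma2_S)[j_within]
  } else {
    rnorm(n, 0, sqrt(config$sigma2_S))
  }
  P <- make_effect_grid(K, config$sigma2_P)
  R <- if (config$run_type == "fixed") {
    make_effect_grid(L, config$sigma2_R)
  } else {
    rnorm(L, 0, sqrt(config$sigma2_R))
  }
  PR <- if (config$run_type == "fixed") {
    outer(make_effect_grid(K, config$sigma2_PR, alternating = TRUE),
          (-1)^seq_len(L))
  } else {
    matrix(rnorm(K * L, 0, sqrt(config$sigma2_PR)), nrow = K)
  }
  GP <- if (config$sigma2_GP > 0) {
    outer((-1)^(1:2),
          make_effect_grid(K, config$sigma2_GP, alternating = TRUE))
  } else {
    matrix(0, nrow = 2L, ncol = K)
  }

  subj_idx <- rep(seq_len(n), each = K)
  pep_idx <- rep(seq_len(K), times = n)
  grp_idx <- subj_grp[subj_idx]
  run_idx <- subj_idx
  log2_endo <- config$mu + G[grp_idx] + S[subj_idx] + P[pep_idx] +
    R[run_idx] + GP[cbind(grp_idx, pep_idx)] + PR[cbind(pep_idx, run_idx)] +
    rnorm(n * K, 0, sqrt(config$sigma2_eps))
  log2_ref <- config$mu + P[pep_idx] + R[run_idx] +
    PR[cbind(pep_idx, run_idx)] + rnorm(n * K, 0, sqrt(config$sigma2_eps))

  sample_id <- sprintf("S%04d", subj_idx)
  base <- data.frame(
    sample_id = sample_id,
    group = as.character(grp_idx),
    run = sprintf("R%04d", run_idx),
    protein = config$protein_id,
    peptide = sprintf("pep%02d", pep_idx),
    stringsAsFactors = FALSE)
  rec <- rbind(
    cbind(base, value = 2^log2_endo, channel = "endogenous",
          stringsAsFactors = FALSE),
    cbind(base, value = 2^log2_ref, channel = "reference",
          stringsAsFactors = FALSE))
  mrm_table(rec, scale = "linear", validate = FALSE)
}
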