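# Canonical record columns. `channel` is "endogenous"/"reference" when raw
# intensity pairs are supplied, or "ratio" when the export already carries
# Area Ratios (endogenous / spiked-in reference from the same run).
.mrm_cols <- c("sample_id", "group", "run", "protein", "peptide", "value", "channel")

#' Construct an MRM quantification table
#'
#' Bundles long-format MRM records (one value per sample, run, protein,
#' peptide and channel) with optional per-sample batch labels. Values are
#' linear-scale intensities or Area Ratios on input; the canonical internal
#' form for the logistic tests is the log2 ratio produced by
#' [log2_relative_intensity()].
#'
#' @param records data.frame with columns `sample_id`, `group`, `run`,
#'   `protein`, `peptide`, `value` and optionally `channel` (default
#'   `"ratio"`).
#' @param batch optional named vector mapping `sample_id` to a batch label.
#' @param scale `"linear"` (raw intensities / Area Ratios) or `"log2_ratio"`.
#' @param validate skip validation when `FALSE` (internal fast path).
#' @return An object of class `mrm_table`: a list with elements `records`,
#'   `batch` and `scale`.
#' @export
mrm_table <- function(records, batch = NULL, scale = c("linear", "log2_ratio"),
                      validate = TRUE) {
  scale <- match.arg(scale)
  if (is.null(records$channel)) records$channel <- "ratio"
  records <- as.data.frame(records)[, .mrm_cols]
  for (col in setdiff(.mrm_cols, "value")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$value <- as.numeric(records$value)
  if (validate && nrow(records) > 0L) {
    if (anyNA(records$value) || any(!is.finite(records$value))) {
      stop("mrm_table: non-finite values present", call. = FALSE)
    }
    if (scale == "linear" && any(records$value <= 0)) {
      stop("mrm_table: non-positive linear-scale values present; ",
           "use read_mrm_table(..., nonpositive = \"drop\") to filter them",
           call. = FALSE)
    }
    key <- do.call(paste, c(records[c("sample_id", "run", "protein",
                                      "peptide", "channel")], sep = "\r"))
    if (anyDuplicated(key)) {
      dup <- unique(gsub("\r", "/", key[duplicated(key)]))
      stop("mrm_table: duplicated (sample_id, run, protein, peptide, channel) keys: ",
           paste(utils::head(dup, 5L), collapse = ", "),
           if (length(dup) > 5L) " ..." else "", call. = FALSE)
    }
    if (!is.null(batch)) {
      endo <- unique(records$sample_id[records$channel != "reference"])
      missing_b <- setdiff(endo, names(batch))
      if (length(missing_b)) {
        stop("mrm_table: batch labels missing for samples: ",
             paste(utils::head(missing_b, 5L), collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(records = records, batch = batch, scale = scale),
            class = "mrm_table")
}

#' @noRd
#' @method print mrm_table
#' @export
print.mrm_table <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "MRM table: %d records (%s scale), %d samples, %d proteins, %d runs\n",
    nrow(r), x$scale, length(unique(r$sample_id[r$channel != "reference"])),
    length(unique(r$protein)), length(unique(r$run))))
  if (!is.null(x$batch)) {
    cat(sprintf("  batches: %s\n", paste(sort(unique(x$batch)), collapse = ", ")))
  }
  invisible(x)
}

# default column names for the two accepted input layouts
.default_dialect <- c(
  sample_id = "sample_id", group = "group", run = "run", protein = "protein",
  peptide = "peptide", area_ratio = "area_ratio",
  intensity_endogenous = "intensity_endogenous",
  intensity_reference = "intensity_reference", batch = "batch"
)

#' Read an MRM quantification table from delimited text
#'
#' Accepts the Area-Ratio layout (columns `sample_id`, `group`, `run`,
#' `protein`, `peptide`, `area_ratio`) or the raw-pair layout where
#' `intensity_endogenous` and `intensity_reference` replace `area_ratio`;
#' pairs become two channel records sharing the same key. The delimiter is
#' inferred from the file extension (`.csv` comma, otherwise tab).
#'
#' @param path file path.
#' @param dialect named character vector remapping canonical column names to
#'   the file's column names, e.g. `c(sample_id = "Sample ID")`.
#' @param nonpositive `"error"` (default) or `"drop"`: how to treat values
#'   that are not strictly positive, which have no logarithm.
#' @param rollup how to resolve several rows per (sample, run, protein,
#'   peptide, channel) key, as happens when transition-level exports are
#'   read: `"error"` (default), or summarise to one value per peptide by the
#'   `"mean"` or `"median"` of the log2 values.
#' @return An [mrm_table()]; a message reports records read and dropped.
#' @export
read_mrm_table <- function(path, dialect = NULL,
                           nonpositive = c("error", "drop"),
                           rollup = c("error", "mean", "median")) {
  nonpositive <- match.arg(nonpositive)
  rollup <- match.arg(rollup)
  dia <- .default_dialect
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  need <- c("sample_id", "group", "run", "protein", "peptide")
  for (col in need) {
    if (!dia[[col]] %in% names(raw)) {
      stop("read_mrm_table: required column '", dia[[col]], "' (", col,
           ") not found in ", path, call. = FALSE)
    }
  }
  pair_layout <- dia[["intensity_endogenous"]] %in% names(raw) &&
    dia[["intensity_reference"]] %in% names(raw)
  if (!pair_layout && !dia[["area_ratio"]] %in% names(raw)) {
    stop("read_mrm_table: need either column '", dia[["area_ratio"]],
         "' or the pair '", dia[["intensity_endogenous"]], "'/'",
         dia[["intensity_reference"]], "'", call. = FALSE)
  }
  base <- data.frame(sample_id = raw[[dia[["sample_id"]]]],
                     group = raw[[dia[["group"]]]],
                     run = raw[[dia[["run"]]]],
                     protein = raw[[dia[["protein"]]]],
                     peptide = raw[[dia[["peptide"]]]],
                     stringsAsFactors = FALSE)
  if (pair_layout) {
    endo <- ref <- base
    endo$value <- as.numeric(raw[[dia[["intensity_endogenous"]]]])
    endo$channel <- rep("endogenous", nrow(base))
    ref$value <- as.numeric(raw[[dia[["intensity_reference"]]]])
    ref$channel <- rep("reference", nrow(base))
    rec <- rbind(endo, ref)
  } else {
    rec <- base
    rec$value <- as.numeric(raw[[dia[["area_ratio"]]]])
    rec$channel <- rep("ratio", nrow(base))
  }
  n_read <- nrow(rec)
  bad <- !is.finite(rec$value) | rec$value <= 0
  if (any(bad)) {
    if (nonpositive == "error") {
      stop("read_mrm_table: ", sum(bad),
           " non-positive or non-finite values (log2 undefined); ",
           "pass nonpositive = \"drop\" to filter them", call. = FALSE)
    }
    rec <- rec[!bad, , drop = FALSE]
  }
  if (rollup != "error") {
    keyf <- interaction(rec$sample_id, rec$run, rec$protein, rec$peptide,
                        rec$channel, drop = TRUE)
    if (anyDuplicated(keyf)) {
      fun <- if (rollup == "mean") mean else stats::median
      agg <- tapply(log2(rec$value), keyf, fun)
      first <- !duplicated(keyf)
      rec <- rec[first, , drop = FALSE]
      rec$value <- 2^as.numeric(agg[as.character(keyf[first])])
    }
  }
  batch <- NULL
  if (dia[["batch"]] %in% names(raw)) {
    b <- tapply(as.character(raw[[dia[["batch"]]]]),
                as.character(raw[[dia[["sample_id"]]]]),
                function(v) v[[1L]])
    batch <- as.character(b)
    names(batch) <- names(b)
  }
  if (nrow(rec) == 0L) warning("read_mrm_table: no usable records in ", path)
  message(sprintf("read_mrm_table: %d records read, %d dropped", n_read,
                  n_read - nrow(rec)))
  mrm_table(rec, batch = batch, scale = "linear")
}

#' Write an MRM table to delimited text
#'
#' Inverse of [read_mrm_table()]; values are printed at 17 significant
#' digits so tables round-trip losslessly.
#'
#' @param table an [mrm_table()].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @export
write_mrm_table <- function(table, path) {
  stopifnot(inherits(table, "mrm_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  rec <- table$records
  if (all(rec$channel == "ratio")) {
    out <- rec[, c("sample_id", "group", "run", "protein", "peptide")]
    out$area_ratio <- sprintf("%.17g", rec$value)
  } else {
    endo <- rec[rec$channel == "endogenous", , drop = FALSE]
    ref <- rec[rec$channel == "reference", , drop = FALSE]
    key <- function(d) paste(d$sample_id, d$run, d$protein, d$peptide,
                             sep = "\r")
    out <- endo[, c("sample_id", "group", "run", "protein", "peptide")]
    out$intensity_endogenous <- sprintf("%.17g", endo$value)
    out$intensity_reference <-
      sprintf("%.17g", ref$value[match(key(endo), key(ref))])
  }
  if (!is.null(table$batch)) out$batch <- table$batch[out$sample_id]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log2 relative-intensity transform
#'
#' Converts every record to the log2 ratio of endogenous over reference
#' signal. Area-Ratio records are simply log2-transformed; raw channel pairs
#' are matched by (run, protein, peptide) and differenced on the log2 scale,
#' consuming the reference records. Because both channels of a run share the
#' peptide, run and peptide-by-run contributions, those cancel exactly in
#' the ratio -- the reason the downstream logistic models carry no run terms.
#'
#' @param table an [mrm_table()] on the linear scale.
#' @return An [mrm_table()] with `scale = "log2_ratio"`, all channels `"ratio"`.
#' @export
log2_relative_intensity <- function(table) {
  stopifnot(inherits(table, "mrm_table"))
  if (table$scale != "linear") {
    stop("log2_relative_intensity: table is already on the log2 scale",
         call. = FALSE)
  }
  rec <- table$records
  is_ref <- rec$channel == "reference"
  is_endo <- rec$channel == "endogenous"
  if (any(is_endo)) {
    refkey <- paste(rec$run, rec$protein, rec$peptide, sep = "\r")
    ref_val <- rec$value[is_ref]
    names(ref_val) <- refkey[is_ref]
    endo <- rec[is_endo, , drop = FALSE]
    matched <- ref_val[refkey[is_endo]]
    if (anyNA(matched)) {
      orphan <- unique(gsub("\r", "/", refkey[is_endo][is.na(matched)]))
      stop("log2_relative_intensity: endogenous records without a same-run ",
           "same-peptide reference: ",
           paste(utils::head(orphan, 5L), collapse = ", "),
           if (length(orphan) > 5L) " ..." else "", call. = FALSE)
    }
    endo$value <- log2(endo$value) - log2(matched)
    endo$channel <- "ratio"
    ratio <- rec[rec$channel == "ratio", , drop = FALSE]
    ratio$value <- log2(ratio$value)
    rec <- rbind(ratio, endo)
  } else {
    rec <- rec[!is_ref, , drop = FALSE]
    rec$value <- log2(rec$value)
  }
  mrm_table(rec, batch = table$batch, scale = "log2_ratio", validate = FALSE)
}

#' Sample-wise quantile normalization
#'
#' Forces every sample's distribution of log2 ratios onto the common
#' distribution of rank-wise means across samples (the classical algorithm,
#' as used for MRM preprocessing in MSstats). Ties within a sample receive
#' the average of their target quantiles, and samples with unequal numbers
#' of values are normalized by linear interpolation of the target quantiles.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param table an [mrm_table()] on the `log2_ratio` scale.
#' @return The normalized [mrm_table()].
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "mrm_table"))
  if (table$scale != "log2_ratio") {
    stop("quantile_normalize: apply log2_relative_intensity() first",
         call. = FALSE)
  }
  rec <- table$records
  samples <- unique(rec$sample_id)
  if (length(samples) < 2L) {
    warning("quantile_normalize: fewer than two samples; returning input")
    return(table)
  }
  idx <- split(seq_len(nrow(rec)), rec$sample_id)[samples]
  m <- max(lengths(idx))
  mat <- matrix(NA_real_, nrow = m, ncol = length(samples))
  for (j in seq_along(idx)) mat[seq_along(idx[[j]]), j] <- rec$value[idx[[j]]]
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  for (j in seq_along(idx)) rec$value[idx[[j]]] <- norm[seq_along(idx[[j]]), j]
  mrm_table(rec, batch = table$batch, scale = "log2_ratio", validate = FALSE)
}

#' Assemble the per-protein peptide matrix
#'
#' Builds the n-subjects-by-K-peptides matrix of log2 relative intensities
#' for one protein, together with the binary group indicator and optional
#' batch covariate consumed by the logistic tests. Subjects missing any of
#' the protein's peptides are dropped (complete case; the count is
#' reported). Rows are ordered by ascending `sample_id` so the assembly is
#' reproducible regardless of record order.
#'
#' @param table an [mrm_table()] on the `log2_ratio` scale.
#' @param protein protein identifier to extract.
#' @param ref_group group label coded 0 in the indicator; every other label
#'   is coded 1. Defaults to the alphabetically first group.
#' @return An object of class `protein_matrix`: list with `protein`, `y`
#'   (n x K matrix), `z` (0/1 integer vector), `batch` (factor or `NULL`),
#'   `peptide_ids`, `sample_ids`, `ref_group`, `n_dropped`.
#' @export
build_protein_matrix <- function(table, protein, ref_group = NULL) {
  stopifnot(inherits(table, "mrm_table"))
  if (table$scale != "log2_ratio") {
    stop("build_protein_matrix: apply log2_relative_intensity() first",
         call. = FALSE)
  }
  rec <- table$records[table$records$protein == protein, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("build_protein_matrix: protein '", protein, "' not present",
         call. = FALSE)
  }
  peptides <- sort(unique(rec$peptide))
  subjects <- sort(unique(rec$sample_id))
  y <- matrix(NA_real_, nrow = length(subjects), ncol = length(peptides),
              dimnames = list(subjects, peptides))
  y[cbind(match(rec$sample_id, subjects), match(rec$peptide, peptides))] <-
    rec$value
  complete <- stats::complete.cases(y)
  n_dropped <- sum(!complete)
  if (!any(complete)) {
    stop("build_protein_matrix: no subject has complete peptide data for '",
         protein, "'", call. = FALSE)
  }
  if (n_dropped > 0L) {
    message(sprintf("build_protein_matrix: %s: dropped %d incomplete subject(s)",
                    protein, n_dropped))
  }
  y <- y[complete, , drop = FALSE]
  subjects <- subjects[complete]
  grp <- rec$group[match(subjects, rec$sample_id)]
  if (is.null(ref_group)) ref_group <- sort(unique(grp))[1L]
  z <- as.integer(grp != ref_group)
  if (length(unique(z)) < 2L) {
    stop("build_protein_matrix: only one group present for '", protein, "'",
         call. = FALSE)
  }
  batch <- NULL
  if (!is.null(table$batch)) batch <- factor(table$batch[subjects])
  structure(list(protein = protein, y = y, z = z, batch = batch,
                 peptide_ids = peptides, sample_ids = subjects,
                 ref_group = ref_group, n_dropped = n_dropped),
            class = "protein_matrix")
}

#' @noRd
#' @method print protein_matrix
#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %s, %d subjects x %d peptides (z: %d/%d)\n",
              x$protein, nrow(x$y), ncol(x$y), sum(x$z == 0L), sum(x$z == 1L)))
  invisible(x)
}
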