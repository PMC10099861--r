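# GC-MS feature-table statistics, downstream of peak picking: blank
# subtraction, presence/isotope filtering, dry-weight + log10 normalisation,
# Welch tests with Shapiro-Wilk residual flags, and annotation tiering from
# reverse match scores. The pipeline order (blank -> presence -> normalise ->
# test) is fixed; reordering changes the results and is rejected by the
# pipeline runner.

#' Construct a GC-MS feature table
#'
#' @param intensities Feature x sample non-negative matrix (pseudospectrum
#'   intensities).
#' @param blanks Feature x blank-run matrix (same rownames), or `NULL`.
#' @param dry_weights Named positive vector (mg) per sample; `NULL` until
#'   normalisation is needed.
#' @param isotope_flags Named logical per feature (redundant isotope ions);
#'   defaults to all `FALSE`.
#' @param annotations Optional data.frame with columns `feature_id`, `name`,
#'   `r_score` (reverse match score in \[0, 1000\], NA allowed).
#' @return Object of class `"FeatureTable"`.
#' @export
feature_table <- function(intensities, blanks = NULL, dry_weights = NULL,
                          isotope_flags = NULL, annotations = NULL) {
  intensities <- as.matrix(intensities)
  if (any(intensities < 0)) validation_error("intensities must be >= 0")
  if (!is.null(blanks)) {
    blanks <- as.matrix(blanks)
    if (!identical(rownames(blanks), rownames(intensities))) {
      validation_error("blank matrix must share the feature rownames")
    }
    if (any(blanks < 0)) validation_error("blank intensities must be >= 0")
  }
  if (!is.null(dry_weights)) {
    if (is.null(names(dry_weights)) || any(dry_weights <= 0)) {
      validation_error("dry_weights must be a named positive vector")
    }
  }
  if (is.null(isotope_flags)) {
    isotope_flags <- setNames(rep(FALSE, nrow(intensities)), rownames(intensities))
  }
  structure(list(intensities = intensities, blanks = blanks,
                 dry_weights = dry_weights, isotope_flags = isotope_flags,
                 annotations = annotations,
                 log_offset = NULL),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features x %d samples (%s blanks)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              if (is.null(x$blanks)) "no" else ncol(x$blanks),
              if (is.null(x$log_offset)) "" else " [normalised]"))
  invisible(x)
}

#' Blank subtraction
#'
#' For each feature, the maximum intensity observed in any blank run is
#' multiplied by `factor` (default 3) and subtracted from every sample;
#' negative results clip to zero. Blank columns are dropped from the output,
#' making a second pass the identity (with a warning).
#'
#' @param table A [feature_table()].
#' @param factor Multiplier on the per-feature blank maximum.
#' @return The corrected `FeatureTable` (without blanks).
#' @export
blank_subtract <- function(table, factor = 3) {
  if (is.null(table$blanks) || ncol(table$blanks) == 0L) {
    warning("blank_subtract: no blank columns; returning the table unchanged")
    return(table)
  }
  cutoff <- factor * apply(table$blanks, 1L, max)
  table$intensities <- pmax(sweep(table$intensities, 1L, cutoff, "-"), 0)
  table$blanks <- NULL
  table
}

#' Presence and isotope filter
#'
#' Keeps features with strictly positive intensity in at least `min_samples`
#' samples and, when `drop_isotopes` is set, drops features flagged as
#' redundant isotope ions.
#'
#' @param table A [feature_table()].
#' @param min_samples Minimum number of positive samples (default 2).
#' @param drop_isotopes Drop isotope-flagged features (default `TRUE`).
#' @return The filtered `FeatureTable`.
#' @export
presence_filter <- function(table, min_samples = 2L, drop_isotopes = TRUE) {
  n_pos <- rowSums(table$intensities > 0)
  keep <- n_pos >= min_samples
  if (drop_isotopes) {
    flags <- table$isotope_flags[rownames(table$intensities)]
    flags[is.na(flags)] <- FALSE
    keep <- keep & !flags
  }
  subset_features(table, rownames(table$intensities)[keep])
}

subset_features <- function(table, ids) {
  table$intensities <- table$intensities[ids, , drop = FALSE]
  if (!is.null(table$blanks)) table$blanks <- table$blanks[ids, , drop = FALSE]
  table$isotope_flags <- table$isotope_flags[ids]
  if (!is.null(table$annotations)) {
    table$annotations <- table$annotations[table$annotations$feature_id %in% ids, ,
                                           drop = FALSE]
  }
  table
}

#' Dry-weight normalisation and log10 scaling
#'
#' Each intensity is divided by the sample's dry weight (mg) and transformed
#' as `log10(value / dry_weight + offset)`. The offset (default 1) keeps exact
#' zeros finite (`log10(1) = 0`) and is recorded in the table so downstream
#' reports can state it.
#'
#' @param table A [feature_table()] with dry weights for every sample.
#' @param offset Additive offset inside the log (default 1; use 0 for the
#'   offset-free variant when no zeros are present).
#' @return The normalised `FeatureTable` (`log_offset` records the offset).
#' @export
normalize_log <- function(table, offset = 1) {
  if (is.null(table$dry_weights)) {
    validation_error("normalize_log: dry weights missing")
  }
  missing <- setdiff(colnames(table$intensities), names(table$dry_weights))
  if (length(missing)) {
    validation_error(sprintf("missing dry weight for sample(s): %s",
                             paste(missing, collapse = ", ")))
  }
  dw <- table$dry_weights[colnames(table$intensities)]
  vals <- sweep(table$intensities, 2L, dw, "/") + offset
  if (any(vals <= 0)) {
    validation_error("normalize_log: non-positive values under this offset")
  }
  table$intensities <- log10(vals)
  table$log_offset <- offset
  table
}

#' Welch t-tests per feature with Shapiro-Wilk residual flags
#'
#' Tests each feature between two sample groups with an unequal-variance
#' (Welch) t-test and Satterthwaite degrees of freedom, adjusts across
#' features with Benjamini-Hochberg, and flags features whose pooled centred
#' residuals deviate from normality (Shapiro-Wilk p < 0.05). Flagged features
#' are retained, not excluded. Degenerate features (zero variance in both
#' groups) get p = 1 when the group means agree and p = 0 when they differ —
#' the latter typically a feature absent in one condition, which is also what
#' usually trips the normality flag.
#'
#' @param table A normalised [feature_table()].
#' @param group1,group2 Character vectors of sample ids (>= 2 each).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return Data.frame (class `"MetaboliteTestResult"`): `feature_id`,
#'   `mean_group1`, `mean_group2`, `t_statistic`, `df`, `pvalue`, `padj`,
#'   `significant`, `shapiro_p`, `non_normal`, and annotation columns `name`,
#'   `tier` when annotations are present.
#' @export
welch_tests <- function(table, group1, group2, alpha = 0.05) {
  m <- table$intensities
  if (length(group1) < 2L || length(group2) < 2L) {
    validation_error("each group needs >= 2 samples")
  }
  missing <- setdiff(c(group1, group2), colnames(m))
  if (length(missing)) {
    validation_error(sprintf("sample(s) not in table: %s",
                             paste(missing, collapse = ", ")))
  }
  res <- lapply(rownames(m), function(f) {
    x <- m[f, group1]
    y <- m[f, group2]
    if (var(x) == 0 && var(y) == 0) {
      equal <- isTRUE(all.equal(mean(x), mean(y)))
      tt <- list(statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                 parameter = NA_real_, p.value = if (equal) 1 else 0)
    } else {
      fit <- t.test(x, y, var.equal = FALSE)
      tt <- list(statistic = unname(fit$statistic),
                 parameter = unname(fit$parameter), p.value = fit$p.value)
    }
    resid <- c(x - mean(x), y - mean(y))
    sw_p <- if (length(unique(round(resid, 12))) < 3L) NA_real_ else
      tryCatch(shapiro.test(resid)$p.value, error = function(e) NA_real_)
    data.frame(feature_id = f, mean_group1 = mean(x), mean_group2 = mean(y),
               t_statistic = tt$statistic, df = tt$parameter,
               pvalue = tt$p.value, shapiro_p = sw_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- adjust_bh(out$pvalue)
  out$significant <- !is.na(out$padj) & out$padj < alpha
  out$non_normal <- !is.na(out$shapiro_p) & out$shapiro_p < 0.05
  if (!is.null(table$annotations)) {
    idx <- match(out$feature_id, table$annotations$feature_id)
    out$name <- table$annotations$name[idx]
    out$tier <- annotation_tier(table$annotations$r_score[idx])
  }
  rownames(out) <- NULL
  class(out) <- c("MetaboliteTestResult", "data.frame")
  out
}

#' Annotation tier from a reverse match score
#'
#' Library-search reverse match scores R (0-1000) are tiered: `R >= 800` ->
#' `"annotated"`, `700 <= R < 800` -> `"?"`, `600 <= R < 700` -> `"??"`, and
#' `R < 600` (or missing) -> `"unknown"`. Lower bounds are inclusive.
#'
#' @param R Numeric vector of reverse match scores (NA allowed).
#' @return Character vector of tiers.
#' @export
annotation_tier <- function(R) {
  if (any(!is.na(R) & (R < 0 | R > 1000))) {
    validation_error("reverse match scores must lie in [0, 1000]")
  }
  out <- rep("unknown", length(R))
  out[!is.na(R) & R >= 600 & R < 700] <- "??"
  out[!is.na(R) & R >= 700 & R < 800] <- "?"
  out[!is.na(R) & R >= 800] <- "annotated"
  out
}

#' Read a feature table from TSV
#'
#' Expected columns: `feature_id`, optional `isotope` (0/1), optional `name`
#' and `r_score`, blank runs in columns prefixed `blank_`, remaining columns
#' one per sample. Dry weights are supplied separately.
#'
#' @param path Feature-table TSV path.
#' @param dry_weights Optional named per-sample dry weights (mg).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dry_weights = NULL) {
  df <- read_tsv_checked(path, "feature_id")
  meta_cols <- intersect(c("feature_id", "isotope", "name", "r_score"), names(df))
  blank_cols <- grep("^blank_", names(df), value = TRUE)
  sample_cols <- setdiff(names(df), c(meta_cols, blank_cols))
  intens <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(intens) <- df$feature_id
  blanks <- if (length(blank_cols)) {
    b <- as.matrix(df[, blank_cols, drop = FALSE]); rownames(b) <- df$feature_id; b
  }
  iso <- if ("isotope" %in% names(df)) {
    setNames(as.integer(df$isotope) == 1L, df$feature_id)
  }
  ann <- if (any(c("name", "r_score") %in% names(df))) {
    data.frame(feature_id = df$feature_id,
               name = if ("name" %in% names(df)) df$name else NA_character_,
               r_score = if ("r_score" %in% names(df)) df$r_score else NA_real_,
               stringsAsFactors = FALSE)
  }
  feature_table(intens, blanks = blanks, dry_weights = dry_weights,
                isotope_flags = iso, annotations = ann)
}

#' Write a feature table to TSV
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = rownames(table$intensities),
                   isotope = as.integer(table$isotope_flags[rownames(table$intensities)]),
                   stringsAsFactors = FALSE)
  if (!is.null(table$annotations)) {
    idx <- match(df$feature_id, table$annotations$feature_id)
    df$name <- table$annotations$name[idx]
    df$r_score <- table$annotations$r_score[idx]
  }
  if (!is.null(table$blanks)) {
    df <- cbind(df, as.data.frame(table$blanks, check.names = FALSE))
  }
  df <- cbind(df, as.data.frame(table$intensities, check.names = FALSE))
  write_tsv(df, path)
}
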