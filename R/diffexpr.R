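# Negative-binomial Wald differential expression for reaction- or gene-level
# count matrices. The engine is deliberately a clean, documented NB-GLM
# implementation: median-of-ratios size factors, per-feature IRLS fits with
# log(size factor) offsets, per-feature ML dispersion (variance = mu + alpha
# mu^2) with a method-of-moments start, Wald tests on contrast coefficients
# and Benjamini-Hochberg adjustment. Shrinkage priors, outlier replacement and
# independent filtering found in mature DE tools are intentionally absent.

DISPERSION_FLOOR <- 1e-8
DISPERSION_CEILING <- 10

#' Differential-expression configuration
#'
#' @param alpha Adjusted-p threshold for significance calls (default 0.05).
#' @param fold_change Linear fold-change threshold (default 1.5); the call
#'   uses `|log2FC| > log2(fold_change)`.
#' @param min_total_count Features whose total count across the tested samples
#'   is below this are dropped before testing (default 1, i.e. all-zero
#'   features are dropped).
#' @param adjustment Multiple-testing adjustment method (default `"BH"`).
#' @return Object of class `"DEConfig"`.
#' @export
de_config <- function(alpha = 0.05, fold_change = 1.5, min_total_count = 1L,
                      adjustment = "BH") {
  if (!(alpha > 0 && alpha < 1)) validation_error("alpha must be in (0, 1)")
  if (!(fold_change > 1)) validation_error("fold_change must be > 1")
  structure(list(alpha = alpha, fold_change = fold_change,
                 min_total_count = min_total_count, adjustment = adjustment),
            class = "DEConfig")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference features of
#' the ratio between the sample's count and the feature's geometric mean over
#' all samples. Reference features are those with strictly positive counts in
#' every sample; when none exist, `pseudo_reference = TRUE` falls back to
#' computing geometric means over positive counts only (each feature's
#' reference restricted to the samples where it was observed).
#'
#' @param counts Feature x sample count matrix.
#' @param pseudo_reference Enable the fallback for sparse matrices.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  log_counts <- log(counts)
  if (pseudo_reference) {
    log_geo <- apply(log_counts, 1L, function(x) mean(x[is.finite(x)]))
    usable <- is.finite(log_geo) & rowSums(counts > 0) >= 2
  } else {
    log_geo <- rowMeans(log_counts)
    usable <- is.finite(log_geo)
  }
  if (!any(usable)) {
    validation_error(paste(
      "size_factors: no feature has positive counts in all samples;",
      "retry with pseudo_reference = TRUE"))
  }
  sf <- apply(log_counts[usable, , drop = FALSE], 2L, function(col) {
    exp(median((col - log_geo[usable])[is.finite(col)]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    validation_error("size_factors: non-positive factor computed; inspect the count matrix")
  }
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement. `NA`/`NaN`
#' entries are excluded from the ranking (the effective number of tests is the
#' number of finite p-values) and propagated unchanged.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted vector of the same length and order.
#' @export
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    validation_error("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

## ---- NB GLM internals -------------------------------------------------------

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-12) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# IRLS fit of an NB log-linear model at fixed dispersion.
# Weights mu/(1 + alpha*mu) are the expected-information weights for the log
# link; eta is capped to keep divergent fits (e.g. a group of all zeros)
# finite — such features end with huge standard errors, never false positives.
nb_irls <- function(y, X, offset, alpha, beta0 = NULL, max_iter = 100L,
                    tol = 1e-10) {
  p <- ncol(X)
  beta <- beta0 %||% qr.solve(X, log(y + 0.5) - offset)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- pmax(exp(eta), 1e-10)
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    dev <- -2 * nb_loglik(y, mu, alpha)
    if (max(abs(beta_new - beta)) < tol || abs(dev_old - dev) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- pmax(exp(eta), 1e-10)
  list(beta = beta, mu = mu)
}

# Method-of-moments dispersion from a fitted mean, floored/ceilinged.
dispersion_mom <- function(y, mu, p) {
  num <- sum(((y - mu)^2 - mu) / mu^2)
  alpha <- num / max(length(y) - p, 1L)
  min(max(alpha, DISPERSION_FLOOR), DISPERSION_CEILING)
}

# Per-feature ML fit: alternate IRLS for beta at fixed alpha with 1-d ML for
# alpha at fixed mu (coordinate ascent on the joint likelihood), starting from
# the method-of-moments estimate.
nb_fit_feature <- function(y, X, offset, max_outer = 10L) {
  poisson_fit <- nb_irls(y, X, offset, alpha = 0)
  alpha <- dispersion_mom(y, poisson_fit$mu, ncol(X))
  fit <- poisson_fit
  for (i in seq_len(max_outer)) {
    fit <- nb_irls(y, X, offset, alpha, beta0 = fit$beta)
    opt <- optimize(function(la) nb_loglik(y, fit$mu, exp(la)),
                    interval = log(c(DISPERSION_FLOOR, DISPERSION_CEILING)),
                    maximum = TRUE, tol = 1e-6)
    alpha_new <- min(max(exp(opt$maximum), DISPERSION_FLOOR), DISPERSION_CEILING)
    if (abs(log(alpha_new) - log(alpha)) < 1e-6) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  fit <- nb_irls(y, X, offset, alpha, beta0 = fit$beta)
  W <- fit$mu / (1 + alpha * fit$mu)
  info <- t(X * W) %*% X
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  list(beta = fit$beta, se = sqrt(pmax(diag(cov), 0)), mu = fit$mu,
       alpha = alpha)
}

## ---- model construction -----------------------------------------------------

de_design_matrix <- function(design, model, tolerant_communities) {
  design$salinity <- factor(design$salinity, levels = c("NSW100", "NSW15"))
  if (model == "tolerance_x_salinity") {
    design$tolerance <- factor(
      ifelse(design$community %in% tolerant_communities, "tolerant", "intolerant"),
      levels = c("tolerant", "intolerant"))
    X <- stats::model.matrix(~ tolerance * salinity, design)
    contrasts <- c(microbiome = "toleranceintolerant",
                   salinity = "salinityNSW15",
                   interaction = "toleranceintolerant:salinityNSW15")
  } else if (model == "community_with_salinity_cofactor") {
    design$community <- factor(design$community)
    X <- stats::model.matrix(~ community + salinity, design)
    lv <- levels(design$community)
    contrasts <- setNames(paste0("community", lv[2]),
                          sprintf("%s_vs_%s", lv[2], lv[1]))
  } else {  # salinity only (within one community)
    X <- stats::model.matrix(~ salinity, design)
    contrasts <- c(salinity = "salinityNSW15")
  }
  rank <- qr(X)$rank
  if (rank < ncol(X)) {
    aliased <- colnames(X)[!(seq_len(ncol(X)) %in% qr(X)$pivot[seq_len(rank)])]
    validation_error(sprintf("singular design matrix; aliased column(s): %s",
                             paste(aliased, collapse = ", ")))
  }
  list(X = X, contrasts = contrasts)
}

check_replicates <- function(design, vars) {
  cells <- interaction(design[vars], drop = TRUE)
  if (any(table(cells) < 2L)) {
    bad <- names(which(table(cells) < 2L))
    validation_error(sprintf("design cell(s) with < 2 replicates: %s",
                             paste(bad, collapse = ", ")))
  }
}

#' Negative-binomial Wald tests under the study designs
#'
#' Fits, per feature, a negative-binomial log-linear model with log size
#' factors as offsets and performs Wald tests on the requested contrast
#' coefficients. Three model families are supported:
#'
#' * `"salinity_within_community"` — one salinity contrast (15% vs 100%
#'   seawater) per community, each fitted on that community's samples alone.
#' * `"tolerance_x_salinity"` — samples of the freshwater-tolerance-conferring
#'   communities (`tolerant_communities`, default MC1 + MC2) are pooled as
#'   "tolerant" versus the remaining "intolerant" ones, and a two-factor model
#'   with interaction is fitted (treatment coding; references `"tolerant"` and
#'   `"NSW100"`). Three contrasts are returned: `microbiome` (tolerance main
#'   effect at 100% seawater), `salinity` (salinity main effect in the
#'   tolerant group) and `interaction` (the intolerant-specific salinity
#'   response).
#' * `"community_with_salinity_cofactor"` — direct comparison of two
#'   communities with salinity kept as an additive cofactor.
#'
#' @param counts Feature x sample integer matrix (reaction- or gene-level).
#' @param design Data.frame with columns `sample_id`, `community`, `salinity`
#'   (values `NSW100`/`NSW15`), one row per count column.
#' @param model One of the model names above.
#' @param config A [de_config()].
#' @param tolerant_communities Communities pooled as "tolerant" under
#'   `"tolerance_x_salinity"`.
#' @param communities Two communities compared under
#'   `"community_with_salinity_cofactor"` (default the first two levels).
#' @param sf Optional precomputed size factors for all columns of `counts`.
#' @return Named list of `"DEResultTable"` data.frames (one per contrast) with
#'   columns `feature_id`, `base_mean`, `log2_fold_change`, `lfc_se`, `stat`,
#'   `pvalue`, `padj`, `significant`. Features dropped by the
#'   `min_total_count` filter are recorded in the `"dropped"` attribute.
#' @export
nb_fit_test <- function(counts, design,
                        model = c("salinity_within_community",
                                  "tolerance_x_salinity",
                                  "community_with_salinity_cofactor"),
                        config = de_config(),
                        tolerant_communities = c("MC1", "MC2"),
                        communities = NULL, sf = NULL) {
  model <- match.arg(model)
  counts <- as.matrix(counts)
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx)) validation_error("every count column must appear in the design")
  design <- design[idx, , drop = FALSE]
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(counts),
                   error = function(e) size_factors(counts, pseudo_reference = TRUE))
  }

  if (model == "salinity_within_community") {
    out <- list()
    for (cm in unique(design$community)) {
      keep <- design$community == cm
      sub_design <- design[keep, , drop = FALSE]
      check_replicates(sub_design, c("community", "salinity"))
      dm <- de_design_matrix(sub_design, "salinity_only", tolerant_communities)
      res <- nb_test_contrasts(counts[, keep, drop = FALSE], dm$X,
                               dm$contrasts, sf[keep], config)
      names(res) <- sprintf("%s:NSW15_vs_NSW100", cm)
      out <- c(out, res)
    }
    return(out)
  }

  if (model == "community_with_salinity_cofactor") {
    communities <- communities %||% sort(unique(design$community))[1:2]
    keep <- design$community %in% communities
    sub_design <- design[keep, , drop = FALSE]
    sub_design$community <- factor(sub_design$community, levels = communities)
    check_replicates(sub_design, c("community", "salinity"))
    dm <- de_design_matrix(sub_design, model, tolerant_communities)
    return(nb_test_contrasts(counts[, keep, drop = FALSE], dm$X, dm$contrasts,
                             sf[keep], config))
  }

  design$tolerance <- ifelse(design$community %in% tolerant_communities,
                             "tolerant", "intolerant")
  check_replicates(design, c("tolerance", "salinity"))
  dm <- de_design_matrix(design, model, tolerant_communities)
  nb_test_contrasts(counts, dm$X, dm$contrasts, sf, config)
}

nb_test_contrasts <- function(counts, X, contrasts, sf, config) {
  totals <- rowSums(counts)
  keep <- totals >= config$min_total_count & totals > 0
  dropped <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]
  offset <- log(sf)
  norm_counts <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(norm_counts)

  coef_idx <- match(contrasts, colnames(X))
  if (anyNA(coef_idx)) {
    validation_error(sprintf("contrast coefficient(s) not in design matrix: %s",
                             paste(contrasts[is.na(coef_idx)], collapse = ", ")))
  }
  n_feat <- nrow(counts)
  beta_mat <- matrix(NA_real_, n_feat, length(contrasts))
  se_mat <- matrix(NA_real_, n_feat, length(contrasts))
  for (i in seq_len(n_feat)) {
    fit <- nb_fit_feature(as.numeric(counts[i, ]), X, offset)
    beta_mat[i, ] <- fit$beta[coef_idx]
    se_mat[i, ] <- fit$se[coef_idx]
  }
  out <- list()
  for (j in seq_along(contrasts)) {
    log2fc <- beta_mat[, j] / log(2)
    se2 <- se_mat[, j] / log(2)
    stat <- beta_mat[, j] / se_mat[, j]
    pval <- 2 * pnorm(-abs(stat))
    padj <- adjust_bh(pval)
    signif <- !is.na(padj) & padj < config$alpha &
      abs(log2fc) > log2(config$fold_change)
    tab <- data.frame(feature_id = rownames(counts),
                      base_mean = base_mean,
                      log2_fold_change = log2fc,
                      lfc_se = se2,
                      stat = stat,
                      pvalue = pval,
                      padj = padj,
                      significant = signif,
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    attr(tab, "contrast") <- names(contrasts)[j]
    attr(tab, "dropped") <- dropped
    class(tab) <- c("DEResultTable", "data.frame")
    out[[names(contrasts)[j]]] <- tab
  }
  out
}

#' Pathway-level summary of differential expression
#'
#' Flags pathways in which strictly more than `threshold` of the *tested*
#' reactions were called significant. Every tested reaction contributes to
#' each pathway it is annotated to. Because the tested-reaction denominator is
#' a choice (a pathway may contain reactions that never received counts), the
#' annotated-reaction denominator is reported alongside.
#'
#' @param results A `DEResultTable` (one contrast).
#' @param pathway_map Named list: reaction id -> character vector of pathways.
#' @param threshold Strict flagging threshold on the tested-reaction fraction
#'   (default 0.5, i.e. "> 50%").
#' @return Data.frame with one row per pathway: `pathway_id`,
#'   `n_reactions_tested`, `n_significant`, `fraction`, `flagged` (fraction
#'   strictly greater than the threshold), `n_induced`, `n_repressed`,
#'   `n_annotated`, `fraction_annotated`.
#' @export
summarize_pathways <- function(results, pathway_map, threshold = 0.5) {
  if (length(pathway_map) == 0L) {
    return(data.frame(pathway_id = character(0), n_reactions_tested = integer(0),
                      n_significant = integer(0), fraction = numeric(0),
                      flagged = logical(0), n_induced = integer(0),
                      n_repressed = integer(0), n_annotated = integer(0),
                      fraction_annotated = numeric(0), stringsAsFactors = FALSE))
  }
  pwy_all <- sort(unique(unlist(pathway_map)))
  annotated_n <- vapply(pwy_all, function(p) {
    sum(vapply(pathway_map, function(ps) p %in% ps, logical(1)))
  }, integer(1))
  tested <- results$feature_id[results$feature_id %in% names(pathway_map)]
  rows <- lapply(pwy_all, function(p) {
    in_pwy <- tested[vapply(pathway_map[tested], function(ps) p %in% ps, logical(1))]
    if (length(in_pwy) == 0L) {
      return(data.frame(pathway_id = p, n_reactions_tested = 0L,
                        n_significant = 0L, fraction = NA_real_, flagged = FALSE,
                        n_induced = 0L, n_repressed = 0L,
                        n_annotated = annotated_n[[p]],
                        fraction_annotated = 0, stringsAsFactors = FALSE))
    }
    sub <- results[results$feature_id %in% in_pwy, , drop = FALSE]
    n_sig <- sum(sub$significant)
    frac <- n_sig / nrow(sub)
    data.frame(pathway_id = p, n_reactions_tested = nrow(sub),
               n_significant = n_sig, fraction = frac,
               flagged = frac > threshold,
               n_induced = sum(sub$significant & sub$log2_fold_change > 0),
               n_repressed = sum(sub$significant & sub$log2_fold_change < 0),
               n_annotated = annotated_n[[p]],
               fraction_annotated = n_sig / annotated_n[[p]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-transform counts and compute principal components
#'
#' A simple variance-taming transform for ordination: counts are divided by
#' their size factor and shifted-log transformed, `log2(count / sf + 1)`, then
#' features are centred and sample coordinates obtained by singular value
#' decomposition. This is an ordinary log-PCA, not a reimplementation of
#' regularised-log or variance-stabilising transforms.
#'
#' @param counts Feature x sample count matrix.
#' @param sf Size factors (default computed with [size_factors()]).
#' @return List with `transformed` (feature x sample matrix), `coordinates`
#'   (sample x PC matrix) and `percent_var` (variance share per axis, in %).
#' @export
transform_for_ordination <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(counts),
                   error = function(e) rep(1, ncol(counts)))
  }
  if (any(sf <= 0)) validation_error("size factors must be positive")
  transformed <- log2(sweep(counts, 2L, sf, "/") + 1)
  centred <- transformed - rowMeans(transformed)
  sv <- svd(t(centred))
  k <- min(dim(centred)) - 0L
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- colnames(counts)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  ev <- sv$d^2
  pct <- if (sum(ev) > 0) 100 * ev / sum(ev) else rep(0, length(ev))
  list(transformed = transformed, coordinates = coords, percent_var = pct)
}
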