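# Reaction-level aggregation of per-gene metatranscriptome counts and
# bin-level transcriptomic activity. Read coverage of individual microbial
# genes is typically too sparse for gene-by-gene, organism-by-organism
# testing, so counts are pooled: across bins by shared reaction id (the
# microbiome's overall expression of each metabolic function), and within
# bins across genes (each bin's overall transcriptomic activity).

#' Aggregate gene counts into reaction space
#'
#' For every reaction id annotated in at least one catalog network, sums the
#' counts of all (bin, gene) pairs annotated to it, across all bins. A gene
#' annotated to k reactions contributes its full count to each of them (full
#' attribution; the provenance table records every contributor so the sums can
#' be audited). Reactions with no mapped gene are omitted rather than
#' zero-filled, so downstream testing never sees structurally unobservable
#' features.
#'
#' @param counts Integer matrix, genes x samples, with gene ids as rownames.
#' @param catalog A [bin_catalog()].
#' @return Object of class `"ReactionCounts"`: list with `counts` (reaction x
#'   sample integer matrix) and `provenance` (named list: reaction id ->
#'   data.frame `bin_id`, `gene_id`).
#' @export
aggregate_gene_to_reaction <- function(counts, catalog) {
  check_count_matrix(counts)
  gene_to_bin <- catalog$gene_to_bin
  contrib <- list()  # reaction_id -> data.frame(bin_id, gene_id)
  for (bin_id in names(catalog$networks)) {
    net <- catalog$networks[[bin_id]]
    for (r in net$reactions) {
      for (g in r$genes) {
        mapped <- gene_to_bin[[g]]
        if (is.null(mapped)) {
          validation_error(sprintf(
            "gene '%s' (reaction '%s', bin '%s') missing from the gene-to-bin map",
            g, r$id, bin_id))
        }
        if (mapped != bin_id) next  # annotation borrowed from another bin
        contrib[[r$id]] <- rbind(contrib[[r$id]],
                                 data.frame(bin_id = bin_id, gene_id = g,
                                            stringsAsFactors = FALSE))
      }
    }
  }
  contrib <- Filter(function(df) any(df$gene_id %in% rownames(counts)), contrib)
  if (length(contrib) == 0L) {
    return(structure(list(
      counts = matrix(0L, 0, ncol(counts),
                      dimnames = list(character(0), colnames(counts))),
      provenance = list()), class = "ReactionCounts"))
  }
  rmat <- do.call(rbind, lapply(contrib, function(df) {
    genes <- intersect(df$gene_id, rownames(counts))
    as.integer(colSums(counts[genes, , drop = FALSE]))
  }))
  colnames(rmat) <- colnames(counts)
  structure(list(counts = rmat, provenance = contrib), class = "ReactionCounts")
}

#' @export
print.ReactionCounts <- function(x, ...) {
  cat(sprintf("ReactionCounts: %d reactions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    validation_error("counts must be a matrix with gene/feature rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    validation_error("counts must be non-negative integers")
  }
  invisible(counts)
}

#' Per-bin transcriptomic activity fractions
#'
#' Sums gene counts per bin and per sample and normalises by a per-sample
#' denominator: either the total number of mapping read pairs in the sample
#' (`"total_mapped"`, taken from the design — the heat-map convention) or the
#' total bacterial transcript count (`"bacterial_total"`, the column sums of
#' the binned genes — the convention of the activity rule).
#'
#' @param counts Gene x sample integer matrix.
#' @param catalog A [bin_catalog()]; every gene row must be mapped to a bin.
#' @param denominator `"bacterial_total"` (default) or `"total_mapped"`.
#' @param design Sample design data.frame with columns `sample_id` and
#'   `total_mapped`; required for `denominator = "total_mapped"`.
#' @return Bin x sample numeric matrix of fractions in \[0, 1\].
#' @export
bin_activity <- function(counts, catalog,
                         denominator = c("bacterial_total", "total_mapped"),
                         design = NULL) {
  check_count_matrix(counts)
  denominator <- match.arg(denominator)
  bins <- catalog$gene_to_bin[rownames(counts)]
  if (any(is.na(names(bins))) || any(vapply(bins, is.null, logical(1)))) {
    validation_error("every gene row must appear in the catalog's gene-to-bin map")
  }
  bins <- unlist(bins)
  bin_sums <- rowsum(counts, group = bins)
  denom <- if (denominator == "bacterial_total") {
    colSums(counts)
  } else {
    if (is.null(design)) {
      validation_error("denominator = 'total_mapped' requires the sample design")
    }
    idx <- match(colnames(counts), design$sample_id)
    if (anyNA(idx)) {
      validation_error(sprintf("sample(s) missing from design: %s",
                               paste(colnames(counts)[is.na(idx)], collapse = ", ")))
    }
    as.numeric(design$total_mapped[idx])
  }
  zero <- denom <= 0
  if (any(zero)) {
    validation_error(sprintf("zero denominator for sample(s): %s",
                             paste(colnames(counts)[zero], collapse = ", ")))
  }
  sweep(bin_sums, 2L, denom, "/")
}

#' Select the active bacteria of a condition
#'
#' A bin counts as active in a (community, salinity) condition when its
#' activity fraction reaches the threshold in at least `min_replicates` of the
#' condition's replicate samples. Both comparisons are inclusive ("at least"):
#' fraction >= threshold, and the number of qualifying replicates >=
#' `min_replicates`. Defaults encode the 0.2%-in-3-of-4-replicates rule
#' computed on bacterial-total fractions.
#'
#' @param activity Bin x sample fraction matrix from [bin_activity()].
#' @param design Design data.frame (`sample_id`, `community`, `salinity`).
#' @param community,salinity The condition to evaluate.
#' @param threshold Activity fraction threshold (default 0.002).
#' @param min_replicates Minimum qualifying replicates (default 3).
#' @param exclude_bins Bins never reported active regardless of signal —
#'   by default the artificial leftover bin of unbinned contigs
#'   (`"unbinned"`), which is not an organism.
#' @return Object of class `"ActiveCommunity"`: list with `condition`,
#'   `active_bins` (character vector), `rule`, and the evaluated `fractions`
#'   submatrix.
#' @export
select_active_bins <- function(activity, design, community, salinity,
                               threshold = 0.002, min_replicates = 3L,
                               exclude_bins = "unbinned") {
  keep <- design$community == community & design$salinity == salinity
  if (!any(keep)) {
    validation_error(sprintf("condition (%s, %s) absent from design",
                             community, salinity))
  }
  samples <- intersect(design$sample_id[keep], colnames(activity))
  if (length(samples) < min_replicates) {
    validation_error(sprintf(
      "condition (%s, %s): %d replicate sample(s) in the activity matrix, need >= %d",
      community, salinity, length(samples), min_replicates))
  }
  sub <- activity[, samples, drop = FALSE]
  n_hits <- rowSums(sub >= threshold)
  active <- rownames(sub)[n_hits >= min_replicates]
  active <- setdiff(active, exclude_bins)
  structure(list(condition = c(community = community, salinity = salinity),
                 active_bins = sort(active),
                 rule = list(threshold = threshold,
                             min_replicates = as.integer(min_replicates),
                             replicate_total = length(samples)),
                 fractions = sub),
            class = "ActiveCommunity")
}

#' @export
print.ActiveCommunity <- function(x, ...) {
  cat(sprintf("ActiveCommunity (%s, %s): %d active bins [>= %.4g in >= %d of %d replicates]\n",
              x$condition[["community"]], x$condition[["salinity"]],
              length(x$active_bins), x$rule$threshold, x$rule$min_replicates,
              x$rule$replicate_total))
  invisible(x)
}

#' Hierarchical clustering of activity/abundance profiles
#'
#' Clusters matrix rows with the heat-map convention: distance one minus the
#' Pearson correlation between rows, average linkage, optional unit-variance
#' row scaling (each row centred to mean 0 and scaled to standard deviation
#' 1). Rows with zero variance have no defined correlation and are excluded
#' (and reported).
#'
#' @param mat Numeric matrix, rows = profiles, columns = samples.
#' @param scale_rows Apply unit-variance row scaling before output (the
#'   distance is scale-invariant; scaling affects only the returned matrix).
#' @return List with `hclust` (the merge tree), `order` (row labels in
#'   dendrogram order), `scaled` (the possibly scaled matrix actually
#'   clustered) and `dropped` (zero-variance row labels).
#' @export
cluster_profiles <- function(mat, scale_rows = TRUE) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  rv <- apply(mat, 1L, var)
  dropped <- rownames(mat)[rv == 0 | is.na(rv)]
  usable <- mat[!(rownames(mat) %in% dropped), , drop = FALSE]
  if (nrow(usable) < 2L) {
    validation_error("cluster_profiles: fewer than 2 rows with non-zero variance")
  }
  d <- as.dist(1 - cor(t(usable)))
  hc <- hclust(d, method = "average")
  out <- usable
  if (scale_rows) out <- t(scale(t(usable)))
  list(hclust = hc, order = rownames(usable)[hc$order],
       scaled = out, dropped = dropped)
}

#' Bacterial-to-host mRNA ratio comparison
#'
#' Computes the per-sample ratio of bacterial to algal mRNA read counts and
#' compares it across the (community x salinity) groups with a one-way ANOVA
#' followed by Tukey's HSD, summarised as compact letters (groups sharing a
#' letter are not significantly different).
#'
#' @param design Design data.frame (`sample_id`, `community`, `salinity`).
#' @param bacterial_counts,algal_counts Named per-sample totals (names =
#'   sample ids); algal totals must be positive.
#' @param alpha Significance level for the letter display.
#' @return List with `ratios` (data.frame sample/group/ratio), `anova`
#'   (data.frame with `F` and `p_value`), `tukey` (pairwise table from
#'   [stats::TukeyHSD()]) and `letters` (named character vector per group).
#' @export
mrna_ratio <- function(design, bacterial_counts, algal_counts, alpha = 0.05) {
  samples <- design$sample_id
  if (!all(samples %in% names(bacterial_counts)) ||
      !all(samples %in% names(algal_counts))) {
    validation_error("bacterial_counts and algal_counts must cover every design sample")
  }
  alg <- algal_counts[samples]
  if (any(alg <= 0)) {
    validation_error(sprintf("non-positive algal total for sample(s): %s",
                             paste(samples[alg <= 0], collapse = ", ")))
  }
  ratios <- data.frame(
    sample_id = samples,
    group = paste(design$community, design$salinity, sep = "_"),
    ratio = as.numeric(bacterial_counts[samples]) / as.numeric(alg),
    stringsAsFactors = FALSE)
  sizes <- table(ratios$group)
  if (any(sizes < 2L)) {
    validation_error(sprintf("group(s) with < 2 samples: %s",
                             paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  ratios$group <- factor(ratios$group)
  if (var(ratios$ratio) == 0) {
    # no variation at all: nothing to test
    return(list(ratios = ratios,
                anova = data.frame(F = 0, p_value = 1),
                tukey = NULL,
                letters = setNames(rep("a", nlevels(ratios$group)),
                                   levels(ratios$group))))
  }
  fit <- aov(ratio ~ group, data = ratios)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  letters <- tukey_letters(levels(ratios$group), tk[, "p adj"], alpha)
  list(ratios = ratios,
       anova = data.frame(F = fstat, p_value = pval),
       tukey = as.data.frame(tk),
       letters = letters)
}

# Compact letter display by insert-and-absorb over the Tukey p-value vector
# (names "a-b"). Groups sharing a letter are not significantly different.
tukey_letters <- function(groups, p_adj, alpha = 0.05) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (nm in names(p_adj)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(pair) != 2L) next
    if (!is.na(p_adj[[nm]]) && p_adj[[nm]] < alpha) {
      sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- TRUE
    }
  }
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(sig[g, sets[[i]]])) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets <- sets[keep]
  out <- setNames(rep("", k), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
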