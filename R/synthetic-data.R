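# Synthetic holobiont datasets with recorded ground truth. The generator
# emulates the structure of the study system every downstream stage consumes:
# a host plus a few dozen bacterial bins with toy genome-scale networks rooted
# in a glucose-like seed medium, a 3-communities x 2-salinities x 4-replicates
# sample design with negative-binomially distributed gene counts, and GC-MS
# feature tables with blank contamination. Every planted signal (producible
# sets, active bins, differential effects, contaminants) is recorded exactly,
# so pipeline stages can be checked against construction-time truth.

#' Sample design for a multi-community salinity experiment
#'
#' @param communities Community labels (default `MC1`-`MC3`).
#' @param salinities Salinity labels; `NSW100` is the seawater control and
#'   `NSW15` the low-salinity treatment.
#' @param replicates Replicates per (community, salinity) cell (default 4).
#' @return Data.frame with columns `sample_id`, `community`, `salinity`,
#'   `replicate`, `total_mapped` (filled by [simulate_counts()]).
#' @export
make_design <- function(communities = c("MC1", "MC2", "MC3"),
                        salinities = c("NSW100", "NSW15"),
                        replicates = 4L) {
  df <- expand.grid(replicate = seq_len(replicates), salinity = salinities,
                    community = communities, stringsAsFactors = FALSE)
  df <- df[, c("community", "salinity", "replicate")]
  df$sample_id <- sprintf("%s_%s_r%d", df$community, df$salinity, df$replicate)
  df$total_mapped <- NA_real_
  rownames(df) <- NULL
  df[, c("sample_id", "community", "salinity", "replicate", "total_mapped")]
}

#' Generate a synthetic holobiont (networks + catalog + seeds + truth)
#'
#' Builds toy genome-scale networks as random production chains rooted at the
#' seed metabolites, so the exact reachable (producible) set of every network
#' and of the merged community is known by construction. Each bin owns an
#' exclusive product namespace; cross-feeding reactions consume another bin's
#' exclusive product, making some metabolites community-producible that no
#' member produces alone. A fraction of reactions are "dead" (they require a
#' blocked metabolite no network can make) and contribute nothing to the
#' reachable sets. A vitamin-K-like precursor-dependency motif is always
#' planted: the host carries the terminal reaction of a pathway whose
#' precursor only one bacterial bin can make, so the terminal metabolite is in
#' the community's added value but never in the host-alone scope.
#'
#' @param n_bins Number of bacterial bins (default 30).
#' @param reactions_per_bin Reactions per bin (default 40).
#' @param n_metabolites Metabolite budget for new chain products; defaults to
#'   a budget that comfortably fits the requested chains. Chains needing more
#'   products than this are an error.
#' @param seed RNG seed; identical seeds give identical output.
#' @param cross_feed_rate,dead_rate,reversible_rate Per-reaction probabilities
#'   of the cross-feeding, dead and reversible variants.
#' @return List with elements `catalog` ([bin_catalog()]), `host`
#'   (`MetabolicNetwork`), `seeds` (`SeedSet`) and `truth` (list recording the
#'   RNG seed, per-network and community producible sets, and the added-value
#'   motif).
#' @export
generate_holobiont <- function(n_bins = 30L, reactions_per_bin = 40L,
                               n_metabolites = NULL, seed = 1L,
                               cross_feed_rate = 0.15, dead_rate = 0.1,
                               reversible_rate = 0.3) {
  if (n_bins < 1L || reactions_per_bin < 2L) {
    validation_error("need n_bins >= 1 and reactions_per_bin >= 2")
  }
  max_products <- (n_bins + 1L) * reactions_per_bin * 2L + 10L
  n_metabolites <- n_metabolites %||% max_products
  if (n_metabolites < (n_bins + 1L) * reactions_per_bin) {
    validation_error("infeasible parameters: more chain steps than metabolites")
  }
  set.seed(seed)
  seeds <- default_seeds()
  met_budget <- n_metabolites
  met_counter <- 0L
  new_mets <- function(prefix, k) {
    if (met_counter + k > met_budget) {
      validation_error("infeasible parameters: metabolite budget exhausted")
    }
    ids <- sprintf("%s_%04d", prefix, met_counter + seq_len(k))
    met_counter <<- met_counter + k
    ids
  }
  gene_counter <- 0L
  new_genes <- function(bin, k) {
    ids <- sprintf("%s|g%05d", bin, gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    ids
  }

  # Shared seed-rooted reactions reused across bins (same id & stoichiometry)
  n_shared <- max(3L, round(0.1 * reactions_per_bin))
  shared <- lapply(seq_len(n_shared), function(k) {
    subs <- sample(as.character(seeds), sample(1:2, 1))
    prods <- new_mets("MS", sample(1:2, 1))
    list(id = sprintf("SHARED-RXN-%03d", k),
         substrates = setNames(rep(1, length(subs)), subs),
         products = setNames(rep(1, length(prods)), prods),
         reversible = runif(1) < reversible_rate,
         pathway = sprintf("PWY-SHARED-%03d", (k - 1L) %/% 3L + 1L))
  })

  bins <- sprintf("bin%02d", seq_len(n_bins))
  networks <- list()
  truth_producible <- list()
  community_products <- character(0)   # live products of earlier bins
  exclusive_products <- list()         # bin -> its exclusive live products
  blocked_counter <- 0L

  build_reaction <- function(rid, subs, prods, reversible, genes, pwy) {
    reaction(rid, setNames(rep(1, length(subs)), subs),
             setNames(rep(1, length(prods)), prods),
             reversible = reversible, genes = genes, pathways = pwy)
  }

  for (bi in seq_along(bins)) {
    bin <- bins[[bi]]
    reactions <- list()
    own_reachable <- as.character(seeds)
    own_products <- character(0)
    # include a subset of the shared reactions
    incl <- sample(n_shared, size = max(1L, n_shared %/% 2L))
    for (k in incl) {
      s <- shared[[k]]
      reactions[[length(reactions) + 1L]] <- build_reaction(
        s$id, names(s$substrates), names(s$products), s$reversible,
        new_genes(bin, sample(1:2, 1)), s$pathway)
      own_reachable <- unique(c(own_reachable, names(s$products)))
      own_products <- unique(c(own_products, names(s$products)))
    }
    n_own <- reactions_per_bin - length(incl)
    pwy_counter <- 0L
    for (i in seq_len(n_own)) {
      rid <- sprintf("%s-RXN-%03d", toupper(bin), i)
      pwy <- sprintf("PWY-%s-%02d", bin, i %/% 4L + 1L)
      u <- runif(1)
      if (u < dead_rate) {
        blocked_counter <- blocked_counter + 1L
        subs <- c(sprintf("BLOCKED_%04d", blocked_counter),
                  sample(own_reachable, 1))
        prods <- sprintf("DEAD_%s_%03d", bin, i)
        reactions[[length(reactions) + 1L]] <- build_reaction(
          rid, subs, prods, runif(1) < reversible_rate,
          new_genes(bin, sample(1:3, 1)), pwy)
      } else if (u < dead_rate + cross_feed_rate &&
                 length(cross_candidates <- grep("^MS_", community_products,
                                                 value = TRUE, invert = TRUE))) {
        # cross-feed substrate must be unreachable for this bin: another bin's
        # exclusive product, never a shared seed-rooted product
        subs <- unique(c(sample(cross_candidates, 1),
                         sample(own_reachable, 1)))
        prods <- new_mets(paste0("MX_", bin), sample(1:2, 1))
        reactions[[length(reactions) + 1L]] <- build_reaction(
          rid, subs, prods, runif(1) < reversible_rate,
          new_genes(bin, sample(1:3, 1)), pwy)
        # products are community-producible but not own-producible
        exclusive_products[[bin]] <- c(exclusive_products[[bin]], prods)
      } else {
        subs <- sample(own_reachable, sample(1:2, 1))
        prods <- new_mets(paste0("M_", bin), sample(1:2, 1))
        genes <- new_genes(bin, sample(1:3, 1))
        # occasionally annotate a gene to a second reaction (multi-reaction gene)
        if (length(reactions) && runif(1) < 0.1) {
          prev <- reactions[[length(reactions)]]
          genes <- c(genes, prev$genes[[1]])
        }
        reactions[[length(reactions) + 1L]] <- build_reaction(
          rid, subs, prods, runif(1) < reversible_rate, genes, pwy)
        own_reachable <- unique(c(own_reachable, prods))
        own_products <- unique(c(own_products, prods))
        exclusive_products[[bin]] <- c(exclusive_products[[bin]], prods)
      }
    }
    networks[[bin]] <- metabolic_network(bin, reactions)
    truth_producible[[bin]] <- sort(unique(c(as.character(seeds), own_products)))
    cross_prods <- setdiff(exclusive_products[[bin]], own_products)
    community_products <- unique(c(community_products, own_products, cross_prods))
  }

  # Vitamin-K-like motif: one bin makes the precursor; only the host carries
  # the terminal reaction.
  vk_bin <- bins[[1]]
  vk_net <- networks[[vk_bin]]
  vk_rid <- sprintf("%s-RXN-VKP", toupper(vk_bin))
  vk_net$reactions[[vk_rid]] <- build_reaction(
    vk_rid, sample(truth_producible[[vk_bin]], 1), "VK-PRECURSOR",
    FALSE, new_genes(vk_bin, 1), sprintf("PWY-%s-VK", vk_bin))
  networks[[vk_bin]] <- metabolic_network(vk_bin, unname(vk_net$reactions))
  truth_producible[[vk_bin]] <- sort(unique(c(truth_producible[[vk_bin]],
                                              "VK-PRECURSOR")))
  community_products <- unique(c(community_products, "VK-PRECURSOR"))

  # Host: own chain from seeds + terminal vitamin-K step + cross-feed uptake
  host_reactions <- list()
  host_reachable <- as.character(seeds)
  host_products <- character(0)
  for (i in seq_len(reactions_per_bin)) {
    rid <- sprintf("HOST-RXN-%03d", i)
    subs <- sample(host_reachable, sample(1:2, 1))
    prods <- new_mets("MH", sample(1:2, 1))
    host_reactions[[length(host_reactions) + 1L]] <- build_reaction(
      rid, subs, prods, runif(1) < reversible_rate, character(0),
      sprintf("PWY-host-%02d", i %/% 4L + 1L))
    host_reachable <- unique(c(host_reachable, prods))
    host_products <- unique(c(host_products, prods))
  }
  host_reactions[[length(host_reactions) + 1L]] <- build_reaction(
    "HOST-RXN-VK", "VK-PRECURSOR", "VITAMIN-K", FALSE, character(0),
    "PWY-host-VK")
  av_products <- "VITAMIN-K"
  bacterial_only <- setdiff(community_products,
                            c(host_reachable, as.character(seeds)))
  n_uptake <- min(2L, length(bacterial_only))
  if (n_uptake > 0L) {
    uptake_subs <- sample(bacterial_only, n_uptake)
    for (i in seq_len(n_uptake)) {
      prods <- sprintf("MH_AV_%02d", i)
      host_reactions[[length(host_reactions) + 1L]] <- build_reaction(
        sprintf("HOST-RXN-UPT-%02d", i), uptake_subs[[i]], prods, FALSE,
        character(0), "PWY-host-uptake")
      av_products <- c(av_products, prods)
    }
  }
  host <- metabolic_network("host", host_reactions)

  community_truth <- sort(unique(c(as.character(seeds), community_products)))
  host_truth <- sort(unique(c(as.character(seeds), host_products)))
  # host + community scope = host alone + the community metabolites themselves
  # (they enter the augmented seed set) + what the host makes from them
  truth <- list(
    seed = seed,
    producible = c(truth_producible,
                   list(host = host_truth),
                   list(community = community_truth)),
    added_value = sort(unique(c(av_products,
                                setdiff(community_truth, host_truth)))),
    added_value_terminal = sort(av_products),
    vk_motif = list(precursor = "VK-PRECURSOR", metabolite = "VITAMIN-K",
                    host_reaction = "HOST-RXN-VK", bacterial_reaction = vk_rid,
                    bin = vk_bin))
  list(catalog = bin_catalog(networks), host = host, seeds = seeds,
       truth = truth)
}

#' Simulate a feature-level negative-binomial count matrix
#'
#' The count core shared by [simulate_counts()]: per-feature base means drawn
#' uniformly from `mean_range`, per-sample depth factors, planted
#' multiplicative effects, and counts drawn from a negative binomial with
#' `variance = mu + dispersion * mu^2`.
#'
#' @param n_features Number of features (rows).
#' @param design Sample design from [make_design()].
#' @param effects Optional data.frame with columns `feature` (row index or
#'   name), `log2fc`, `type` (`"salinity"`, `"interaction"` or
#'   `"community"`), and optionally `community`; see [simulate_counts()].
#' @param dispersion NB dispersion alpha (> 0).
#' @param mean_range Base-mean range (uniform draw).
#' @param depth_sd Log-normal sd of per-sample depth factors (0 = equal depth).
#' @param seed RNG seed.
#' @param intolerant_communities Communities receiving `"interaction"`
#'   effects (default `"MC3"`).
#' @return List with `counts` (feature x sample integer matrix), `mu` (the
#'   expected values), `depth` (per-sample factors) and `effects`.
#' @export
simulate_count_matrix <- function(n_features, design, effects = NULL,
                                  dispersion = 0.1, mean_range = c(20, 200),
                                  depth_sd = 0.2, seed = 1L,
                                  intolerant_communities = "MC3") {
  if (dispersion <= 0) validation_error("dispersion must be > 0")
  set.seed(seed)
  n_samples <- nrow(design)
  base <- runif(n_features, mean_range[1], mean_range[2])
  depth <- exp(rnorm(n_samples, 0, depth_sd))
  mu <- outer(base, depth)
  rownames(mu) <- sprintf("F%05d", seq_len(n_features))
  colnames(mu) <- design$sample_id
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      f <- if (is.numeric(e$feature)) e$feature else match(e$feature, rownames(mu))
      cols <- switch(as.character(e$type),
        salinity = if (!is.null(e$community) && !is.na(e$community)) {
          design$salinity == "NSW15" & design$community == e$community
        } else design$salinity == "NSW15",
        interaction = design$salinity == "NSW15" &
          design$community %in% intolerant_communities,
        community = design$community %in%
          strsplit(as.character(e$community), ",")[[1]],
        validation_error(sprintf("unknown effect type '%s'", e$type)))
      mu[f, cols] <- mu[f, cols] * 2^e$log2fc
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_features, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  list(counts = counts, mu = mu, depth = depth, effects = effects)
}

#' Simulate gene-level metatranscriptome counts for a holobiont
#'
#' Every bin is assigned a home community (round-robin) and its genes get high
#' expected expression there and strongly reduced expression elsewhere, so
#' each community is dominated by a different set of bins. Counts are drawn
#' per gene from a negative binomial (`variance = mu + dispersion * mu^2`)
#' with per-sample depth factors. Planted differential effects are specified
#' per reaction and applied multiplicatively to all genes of that reaction
#' (`"salinity"` effects in a community's low-salinity samples,
#' `"interaction"` effects only in intolerant-community low-salinity samples).
#' Optionally one (bin, condition) pair is zeroed to emulate a metabolic
#' function absent from a community under one condition. The design's
#' `total_mapped` is filled as if bacterial reads were a small fraction
#' (default 0.7%) of the sequencing yield.
#'
#' @param catalog A [bin_catalog()] (e.g. from [generate_holobiont()]).
#' @param design Sample design from [make_design()].
#' @param effects Optional data.frame with columns `reaction_id`, `log2fc`,
#'   `type`, optionally `community`.
#' @param dispersion,mean_range,depth_sd,seed As in [simulate_count_matrix()].
#' @param active_multiplier,inactive_multiplier Expression multipliers of a
#'   bin's genes in its home community vs elsewhere; defaults separate active
#'   and inactive bins by roughly two orders of magnitude in activity
#'   fraction.
#' @param zero_motif `NULL`, or a list `list(bin=, community=, salinity=)`
#'   naming a bin whose genes are zeroed in one condition; `TRUE` picks the
#'   last intolerant-community bin in (`MC3`, `NSW15`).
#' @param bacterial_fraction Fraction of total mapped reads that is bacterial
#'   (used to fill `total_mapped`).
#' @param intolerant_communities Communities treated as intolerant for
#'   `"interaction"` effects.
#' @return List with `counts`, `design` (with `total_mapped` filled) and
#'   `truth` (home communities, planted active bins per condition, applied
#'   effects, zero motif, depth factors, RNG seed).
#' @export
simulate_counts <- function(catalog, design = make_design(), effects = NULL,
                            dispersion = 0.1, mean_range = c(20, 200),
                            depth_sd = 0.2, seed = 1L,
                            active_multiplier = 1, inactive_multiplier = 0.002,
                            zero_motif = NULL, bacterial_fraction = 0.007,
                            intolerant_communities = "MC3") {
  if (dispersion <= 0) validation_error("dispersion must be > 0")
  set.seed(seed)
  bins <- names(catalog$networks)
  communities <- unique(design$community)
  home <- setNames(communities[(seq_along(bins) - 1L) %% length(communities) + 1L],
                   bins)
  genes <- names(catalog$gene_to_bin)
  gene_bins <- unname(catalog$gene_to_bin)
  n_samples <- nrow(design)
  base <- runif(length(genes), mean_range[1], mean_range[2])
  depth <- exp(rnorm(n_samples, 0, depth_sd))
  act <- matrix(inactive_multiplier, length(bins), n_samples,
                dimnames = list(bins, design$sample_id))
  for (b in bins) act[b, design$community == home[[b]]] <- active_multiplier
  mu <- outer(base, depth) * act[gene_bins, , drop = FALSE]
  rownames(mu) <- genes
  colnames(mu) <- design$sample_id

  gene_reactions <- gene_to_reaction_map(catalog)
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      gs <- names(gene_reactions)[vapply(gene_reactions, function(rs) {
        e$reaction_id %in% rs
      }, logical(1))]
      if (length(gs) == 0L) {
        validation_error(sprintf("planted effect on unknown reaction '%s'",
                                 e$reaction_id))
      }
      cols <- switch(as.character(e$type),
        salinity = if (!is.null(e$community) && !is.na(e$community)) {
          design$salinity == "NSW15" & design$community == e$community
        } else design$salinity == "NSW15",
        interaction = design$salinity == "NSW15" &
          design$community %in% intolerant_communities,
        community = design$community %in%
          strsplit(as.character(e$community), ",")[[1]],
        validation_error(sprintf("unknown effect type '%s'", e$type)))
      mu[gs, cols] <- mu[gs, cols] * 2^e$log2fc
    }
  }

  if (isTRUE(zero_motif)) {
    mc3_bins <- bins[home == intolerant_communities[[1]]]
    zero_motif <- list(bin = mc3_bins[length(mc3_bins)],
                       community = intolerant_communities[[1]],
                       salinity = "NSW15")
  }
  if (!is.null(zero_motif)) {
    cols <- design$community == zero_motif$community &
      design$salinity == zero_motif$salinity
    mu[gene_bins == zero_motif$bin, cols] <- 0
  }

  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = length(genes), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  design$total_mapped <- round(colSums(counts) / bacterial_fraction)

  active_truth <- lapply(split(design$sample_id, paste(design$community,
                                                       design$salinity, sep = "_")),
                         function(s) {
                           cm <- design$community[design$sample_id == s[[1]]]
                           sort(bins[home == cm])
                         })
  list(counts = counts, design = design,
       truth = list(seed = seed, home_community = home,
                    active_bins = active_truth, effects = effects,
                    zero_motif = zero_motif, depth = depth))
}

# gene id -> character vector of reaction ids (within the gene's own bin)
gene_to_reaction_map <- function(catalog) {
  out <- list()
  for (bin in names(catalog$networks)) {
    for (r in catalog$networks[[bin]]$reactions) {
      for (g in r$genes) out[[g]] <- unique(c(out[[g]], r$id))
    }
  }
  out
}

#' Simulate a GC-MS feature table with planted structure
#'
#' Log-normal intensities with four planted feature classes recorded in the
#' truth: blank contaminants (blank signal high enough that the three-fold
#' blank subtraction removes the feature entirely), singleton features
#' (positive in exactly one sample), isotope-flagged redundant ions, and
#' group-shifted features for the Welch tests. Group 1 is the first half of
#' the samples, group 2 the second half.
#'
#' @param n_features Total features (default 200).
#' @param n_samples Samples (even; default 12).
#' @param n_blanks Blank runs (default 3).
#' @param contamination_rate,singleton_rate,isotope_rate Fractions of features
#'   planted per class.
#' @param n_effects Number of group-shifted features.
#' @param effect_log10 Additive shift on the log10 scale planted in group 2.
#' @param seed RNG seed.
#' @return List with `table` (a [feature_table()]), `groups` (list of the two
#'   sample-id vectors) and `truth` (planted ids per class, dry weights, RNG
#'   seed).
#' @export
simulate_feature_table <- function(n_features = 200L, n_samples = 12L,
                                   n_blanks = 3L, contamination_rate = 0.1,
                                   singleton_rate = 0.05, isotope_rate = 0.05,
                                   n_effects = 10L, effect_log10 = 1,
                                   seed = 1L) {
  stopifnot(n_samples >= 4L, n_samples %% 2L == 0L)
  set.seed(seed)
  ids <- sprintf("feat%04d", seq_len(n_features))
  samples <- sprintf("S%02d", seq_len(n_samples))
  base <- rlnorm(n_features, meanlog = runif(n_features, log(1e4), log(1e6)),
                 sdlog = 0.3)
  intens <- matrix(rlnorm(n_features * n_samples, log(base), 0.3),
                   nrow = n_features, dimnames = list(ids, samples))
  blanks <- matrix(rlnorm(n_features * n_blanks, log(50), 0.5),
                   nrow = n_features,
                   dimnames = list(ids, sprintf("blank_%d", seq_len(n_blanks))))

  pool <- ids
  take <- function(k) {
    k <- min(k, length(pool))
    chosen <- sample(pool, k)
    pool <<- setdiff(pool, chosen)
    chosen
  }
  n_of <- function(rate) if (rate > 0) max(1L, round(rate * n_features)) else 0L
  contaminants <- take(n_of(contamination_rate))
  singletons <- take(n_of(singleton_rate))
  isotopes <- take(n_of(isotope_rate))
  shifted <- take(n_effects)

  # contaminant: blank maximum above a third of every sample intensity
  blanks[contaminants, ] <- apply(intens[contaminants, , drop = FALSE], 1L, max) / 2
  # singleton: positive in exactly one sample, clean blanks
  intens[singletons, ] <- 0
  keep_col <- sample(n_samples, length(singletons), replace = TRUE)
  for (i in seq_along(singletons)) {
    intens[singletons[i], keep_col[i]] <- rlnorm(1, log(1e5), 0.3)
  }
  blanks[singletons, ] <- 0
  iso_flags <- setNames(ids %in% isotopes, ids)
  g1 <- samples[seq_len(n_samples / 2)]
  g2 <- setdiff(samples, g1)
  intens[shifted, g2] <- intens[shifted, g2] * 10^effect_log10

  dw <- setNames(runif(n_samples, 5, 15), samples)
  ann <- data.frame(feature_id = ids,
                    name = ifelse(runif(n_features) < 0.3,
                                  sprintf("compound_%04d", seq_len(n_features)),
                                  NA_character_),
                    r_score = sample(c(NA, round(runif(n_features, 300, 1000))),
                                     n_features, replace = TRUE),
                    stringsAsFactors = FALSE)
  tab <- feature_table(intens, blanks = blanks, dry_weights = dw,
                       isotope_flags = iso_flags, annotations = ann)
  list(table = tab, groups = list(group1 = g1, group2 = g2),
       truth = list(seed = seed, contaminants = sort(contaminants),
                    singletons = sort(singletons), isotopes = sort(isotopes),
                    shifted = sort(shifted), dry_weights = dw))
}
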