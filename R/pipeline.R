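# End-to-end orchestration. Each stage reads its inputs from, and writes its
# outputs to, the configured output directory, so any subset of stages can be
# rerun; a manifest JSON records every file written with its md5 checksum, the
# configuration and the package version. Stochastic stages are keyed by the
# configured RNG seed, so identical configurations reproduce identical files.

#' Pipeline configuration
#'
#' Bundles the file paths and the analysis thresholds of a full run. All
#' thresholds default to the package-wide conventions: activity fraction
#' 0.002 in >= 3 replicates, adjusted p < 0.05 with fold change > 1.5,
#' pathway flagging > 0.5, blank factor 3, presence filter 2, annotation
#' tiers 800/700/600.
#'
#' @param outdir Output directory (created if missing).
#' @param networks_dir Directory of `<bin>.reactions.tsv` / `<bin>.genes.tsv`
#'   files plus `host.reactions.tsv`; defaults to `<outdir>/networks` (what
#'   the simulate stage writes).
#' @param counts,design,seeds,feature_table,dry_weights Optional input paths;
#'   default to the simulate stage's outputs inside `outdir`.
#' @param model DE model (see [nb_fit_test()]).
#' @param activity_threshold,min_replicates,alpha,fold_change,
#'   pathway_threshold,blank_factor,presence_min,log_offset Analysis
#'   thresholds.
#' @param seed RNG seed for stochastic stages.
#' @param sim Named list of overrides passed to the simulate stage
#'   (`generate_holobiont()` / `simulate_counts()` /
#'   `simulate_feature_table()` arguments).
#' @return Object of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(outdir,
                            networks_dir = file.path(outdir, "networks"),
                            counts = file.path(outdir, "gene_counts.tsv"),
                            design = file.path(outdir, "design.tsv"),
                            seeds = file.path(outdir, "seeds.tsv"),
                            feature_table = file.path(outdir, "feature_table.tsv"),
                            dry_weights = file.path(outdir, "dry_weights.tsv"),
                            model = "tolerance_x_salinity",
                            activity_threshold = 0.002, min_replicates = 3L,
                            alpha = 0.05, fold_change = 1.5,
                            pathway_threshold = 0.5, blank_factor = 3,
                            presence_min = 2L, log_offset = 1,
                            seed = 1L, sim = list()) {
  stopifnot(activity_threshold > 0, activity_threshold < 1,
            alpha > 0, alpha < 1, fold_change > 1,
            pathway_threshold >= 0, pathway_threshold <= 1,
            blank_factor > 0, presence_min >= 0)
  structure(list(outdir = outdir, networks_dir = networks_dir,
                 counts = counts, design = design, seeds = seeds,
                 feature_table = feature_table, dry_weights = dry_weights,
                 model = model, activity_threshold = activity_threshold,
                 min_replicates = as.integer(min_replicates), alpha = alpha,
                 fold_change = fold_change,
                 pathway_threshold = pathway_threshold,
                 blank_factor = blank_factor,
                 presence_min = as.integer(presence_min),
                 log_offset = log_offset, seed = as.integer(seed), sim = sim),
            class = "PipelineConfig")
}

PIPELINE_STAGES <- c("simulate", "aggregate", "activity", "de", "pathways",
                     "scope", "added_value", "metabolomics")

#' Run pipeline stages in dependency order
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `"simulate"`, `"aggregate"`, `"activity"`, `"de"`,
#'   `"pathways"`, `"scope"`, `"added_value"`, `"metabolomics"`; stages are
#'   always executed in dependency order regardless of the order given.
#' @return Invisibly, a list with `status` (0) and `manifest` (also written to
#'   `<outdir>/manifest.json`). Missing upstream inputs raise a dependency
#'   error naming the stage that produces them.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %5.1fs %s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }
  record <- function(stage, files) {
    outputs[[stage]] <<- c(outputs[[stage]], files)
  }
  for (stage in stages) {
    files <- switch(stage,
      simulate = stage_simulate(config),
      aggregate = stage_aggregate(config),
      activity = stage_activity(config),
      de = stage_de(config),
      pathways = stage_pathways(config),
      scope = stage_scope(config),
      added_value = stage_added_value(config),
      metabolomics = stage_metabolomics(config))
    record(stage, files)
    log_stage(stage, sprintf("wrote %d file(s)", length(files)))
  }
  all_files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    package = "holoscope",
    version = as.character(packageVersion("holoscope")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    stages = lapply(outputs, function(fs) {
      lapply(fs, function(f) list(path = f, md5 = unname(md5sum(f))))
    }))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest,
                 manifest_path = manifest_path))
}

require_input <- function(path, producing_stage) {
  if (!file.exists(path)) {
    dependency_error(sprintf(
      "required input '%s' missing; run the '%s' stage first",
      path, producing_stage))
  }
  path
}

load_catalog_dir <- function(networks_dir) {
  require_input(networks_dir, "simulate")
  rx_files <- list.files(networks_dir, pattern = "\\.reactions\\.tsv$",
                         full.names = TRUE)
  rx_files <- rx_files[!grepl("^host\\.", basename(rx_files))]
  networks <- list()
  for (f in sort(rx_files)) {
    bin <- sub("\\.reactions\\.tsv$", "", basename(f))
    gm <- file.path(networks_dir, paste0(bin, ".genes.tsv"))
    networks[[bin]] <- read_network_tsv(f, if (file.exists(gm)) gm,
                                        organism_id = bin)
  }
  if (length(networks) == 0L) {
    dependency_error(sprintf("no networks found under '%s'", networks_dir))
  }
  bin_catalog(networks)
}

load_host <- function(networks_dir) {
  f <- file.path(networks_dir, "host.reactions.tsv")
  require_input(f, "simulate")
  read_network_tsv(f, organism_id = "host")
}

stage_simulate <- function(config) {
  sim <- config$sim
  holo <- do.call(generate_holobiont, c(
    list(seed = config$seed),
    sim[intersect(names(sim), names(formals(generate_holobiont)))]))
  cnt <- do.call(simulate_counts, c(
    list(catalog = holo$catalog, seed = config$seed),
    sim[intersect(names(sim), setdiff(names(formals(simulate_counts)),
                                      c("catalog", "seed")))]))
  ft <- do.call(simulate_feature_table, c(
    list(seed = config$seed),
    sim[intersect(names(sim), setdiff(names(formals(simulate_feature_table)),
                                      "seed"))]))
  net_dir <- config$networks_dir
  dir.create(net_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (bin in names(holo$catalog$networks)) {
    rp <- file.path(net_dir, paste0(bin, ".reactions.tsv"))
    gp <- file.path(net_dir, paste0(bin, ".genes.tsv"))
    write_network_tsv(holo$catalog$networks[[bin]], rp, gp)
    files <- c(files, rp, gp)
  }
  hp <- file.path(net_dir, "host.reactions.tsv")
  write_network_tsv(holo$host, hp)
  write_matrix_tsv(cnt$counts, config$counts, id_col = "gene_id")
  write_tsv(cnt$design, config$design)
  write_tsv(data.frame(metabolite_id = as.character(holo$seeds)), config$seeds)
  write_feature_table(ft$table, config$feature_table)
  write_tsv(data.frame(sample_id = names(ft$truth$dry_weights),
                       dry_weight_mg = unname(ft$truth$dry_weights)),
            config$dry_weights)
  truth_path <- file.path(config$outdir, "truth.json")
  jsonlite::write_json(list(holobiont = holo$truth, counts = cnt$truth,
                            feature_table = ft$truth),
                       truth_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  c(files, hp, config$counts, config$design, config$seeds,
    config$feature_table, config$dry_weights, truth_path)
}

read_design <- function(config) {
  read_tsv_checked(require_input(config$design, "simulate"),
                   c("sample_id", "community", "salinity", "replicate"))
}

stage_aggregate <- function(config) {
  counts <- read_matrix_tsv(require_input(config$counts, "simulate"))
  storage.mode(counts) <- "integer"
  catalog <- load_catalog_dir(config$networks_dir)
  rc <- aggregate_gene_to_reaction(counts, catalog)
  out <- file.path(config$outdir, "reaction_counts.tsv")
  write_matrix_tsv(rc$counts, out, id_col = "reaction_id")
  prov <- do.call(rbind, lapply(names(rc$provenance), function(r) {
    cbind(reaction_id = r, rc$provenance[[r]])
  }))
  prov_out <- file.path(config$outdir, "reaction_provenance.tsv")
  write_tsv(prov, prov_out)
  c(out, prov_out)
}

stage_activity <- function(config) {
  counts <- read_matrix_tsv(require_input(config$counts, "simulate"))
  storage.mode(counts) <- "integer"
  catalog <- load_catalog_dir(config$networks_dir)
  design <- read_design(config)
  act <- bin_activity(counts, catalog, denominator = "bacterial_total")
  out <- file.path(config$outdir, "bin_activity.tsv")
  write_matrix_tsv(act, out, id_col = "bin_id")
  conds <- unique(design[, c("community", "salinity")])
  active <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    ac <- select_active_bins(act, design, conds$community[i], conds$salinity[i],
                             threshold = config$activity_threshold,
                             min_replicates = config$min_replicates)
    if (length(ac$active_bins) == 0L) return(NULL)
    data.frame(community = conds$community[i], salinity = conds$salinity[i],
               bin_id = ac$active_bins, stringsAsFactors = FALSE)
  }))
  act_out <- file.path(config$outdir, "active_bins.tsv")
  write_tsv(active %||% data.frame(community = character(0),
                                   salinity = character(0),
                                   bin_id = character(0)), act_out)
  c(out, act_out)
}

stage_de <- function(config) {
  rc_path <- file.path(config$outdir, "reaction_counts.tsv")
  counts <- read_matrix_tsv(require_input(rc_path, "aggregate"))
  storage.mode(counts) <- "integer"
  design <- read_design(config)
  cfg <- de_config(alpha = config$alpha, fold_change = config$fold_change)
  res <- nb_fit_test(counts, design, model = config$model, config = cfg)
  vapply(names(res), function(cn) {
    out <- file.path(config$outdir,
                     sprintf("de_%s.tsv", gsub("[^A-Za-z0-9_]+", "_", cn)))
    write_tsv(res[[cn]], out)
    out
  }, character(1))
}

stage_pathways <- function(config) {
  de_files <- list.files(config$outdir, pattern = "^de_.*\\.tsv$",
                         full.names = TRUE)
  de_files <- de_files[!grepl("^de_pathways_", basename(de_files))]
  if (length(de_files) == 0L) {
    dependency_error("no DE result tables found; run the 'de' stage first")
  }
  catalog <- load_catalog_dir(config$networks_dir)
  pmap <- pathway_map(catalog$networks)
  vapply(de_files, function(f) {
    res <- read_tsv_checked(f)
    res$significant <- as.logical(res$significant)
    summ <- summarize_pathways(res, pmap, threshold = config$pathway_threshold)
    out <- file.path(config$outdir,
                     sub("^de_", "de_pathways_", basename(f)))
    write_tsv(summ, out)
    out
  }, character(1), USE.NAMES = FALSE)
}

stage_scope <- function(config) {
  active_path <- file.path(config$outdir, "active_bins.tsv")
  active <- read_tsv_checked(require_input(active_path, "activity"))
  catalog <- load_catalog_dir(config$networks_dir)
  seeds <- read_seeds(require_input(config$seeds, "simulate"))
  conds <- unique(active[, c("community", "salinity")])
  sets <- list()
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    cn <- sprintf("%s_%s", conds$community[i], conds$salinity[i])
    bins <- active$bin_id[active$community == conds$community[i] &
                            active$salinity == conds$salinity[i]]
    sc <- community_scope(catalog$networks[bins], seeds, label = cn)
    sets[[cn]] <- sc$producible
    rows[[cn]] <- data.frame(condition = cn, metabolite_id = sc$producible,
                             first_iteration = unname(sc$first_iteration),
                             stringsAsFactors = FALSE)
  }
  scope_out <- file.path(config$outdir, "community_scope.tsv")
  write_tsv(do.call(rbind, rows), scope_out)
  files <- scope_out
  if (length(sets) >= 2L) {
    upset <- compare_producibility(sets)
    upset_out <- file.path(config$outdir, "scope_upset.tsv")
    write_tsv(upset, upset_out)
    files <- c(files, upset_out)
  }
  files
}

stage_added_value <- function(config) {
  active_path <- file.path(config$outdir, "active_bins.tsv")
  active <- read_tsv_checked(require_input(active_path, "activity"))
  catalog <- load_catalog_dir(config$networks_dir)
  host <- load_host(config$networks_dir)
  seeds <- read_seeds(require_input(config$seeds, "simulate"))
  conds <- unique(active[, c("community", "salinity")])
  rows <- list()
  av_sets <- list()
  for (i in seq_len(nrow(conds))) {
    cn <- sprintf("%s_%s", conds$community[i], conds$salinity[i])
    bins <- active$bin_id[active$community == conds$community[i] &
                            active$salinity == conds$salinity[i]]
    av <- added_value(host, catalog$networks[bins], seeds)
    av_sets[[cn]] <- av$added_value
    rows[[cn]] <- data.frame(
      condition = cn,
      n_host_alone = length(av$host_alone),
      n_community_producible = length(av$community_producible),
      n_host_with_community = length(av$host_with_community),
      n_added_value = length(av$added_value),
      added_value = paste(av$added_value, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- file.path(config$outdir, "added_value.tsv")
  write_tsv(do.call(rbind, rows), out)
  files <- out
  if (length(av_sets) >= 2L) {
    upset_out <- file.path(config$outdir, "added_value_upset.tsv")
    write_tsv(compare_producibility(av_sets), upset_out)
    files <- c(files, upset_out)
  }
  files
}

stage_metabolomics <- function(config) {
  dw_df <- read_tsv_checked(require_input(config$dry_weights, "simulate"),
                            c("sample_id", "dry_weight_mg"))
  dw <- setNames(dw_df$dry_weight_mg, dw_df$sample_id)
  tab <- read_feature_table(require_input(config$feature_table, "simulate"),
                            dry_weights = dw)
  n0 <- nrow(tab$intensities)
  tab <- blank_subtract(tab, factor = config$blank_factor)
  tab <- presence_filter(tab, min_samples = config$presence_min)
  tab <- normalize_log(tab, offset = config$log_offset)
  samples <- colnames(tab$intensities)
  g1 <- samples[seq_len(length(samples) %/% 2)]
  g2 <- setdiff(samples, g1)
  res <- welch_tests(tab, g1, g2, alpha = config$alpha)
  out <- file.path(config$outdir, "metabolite_tests.tsv")
  write_tsv(res, out)
  norm_out <- file.path(config$outdir, "feature_table_normalized.tsv")
  write_matrix_tsv(tab$intensities, norm_out, id_col = "feature_id")
  message(sprintf("metabolomics: %d -> %d features after filtering", n0,
                  nrow(tab$intensities)))
  c(out, norm_out)
}
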