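#' Pipeline configuration
#'
#' Bundles the options of every stage of the transect analysis. All paths
#' are relative to `out_dir`; the `simulate` stage writes the inputs the
#' later stages read, so a full run needs nothing on disk beforehand.
#'
#' @param out_dir directory for all stage artifacts.
#' @param transect a [transect_config()] for the `simulate` stage.
#' @param network_taxa,network_pfam [network_config()]s for the combined
#'   taxon network (soft power 11) and the Pfam network (soft power 12).
#' @param breakpoint_axis `"temperature"` or `"altered_latitude"`.
#' @param amplicon_search 2-vector temperature window for the 16S/18S
#'   breakpoint searches (default `c(7, 29.02)`).
#' @param reduction per-station beta reduction passed to [station_beta()].
#'   The workflow default is `"adjacent"` (local turnover between
#'   latitudinal neighbours), whose rate is the quantity that changes at a
#'   regime boundary; `"mean"` and `"nearest"` remain selectable.
#' @param thresholds [band_thresholds()] for the projection stage.
#' @param warming_offset degrees C of synthetic warming for the projection
#'   stage.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("poleward_run_"),
                            transect = transect_config(),
                            network_taxa = network_config(soft_power = 11,
                                                          min_module_size = 10),
                            network_pfam = network_config(soft_power = 12,
                                                          min_module_size = 30),
                            breakpoint_axis = c("temperature",
                                                "altered_latitude"),
                            amplicon_search = c(7, 29.02),
                            reduction = "adjacent",
                            thresholds = band_thresholds(),
                            warming_offset = 3,
                            seed = 1L) {
  structure(list(out_dir = out_dir, transect = transect,
                 network_taxa = network_taxa, network_pfam = network_pfam,
                 breakpoint_axis = match.arg(breakpoint_axis),
                 amplicon_search = amplicon_search, reduction = reduction,
                 thresholds = thresholds, warming_offset = warming_offset,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

need_artifact <- function(config, file, stage) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    stop("missing artifact '", file, "': run the '", stage, "' stage first")
  }
  p
}

#' Run the transect analysis pipeline
#'
#' Executes one stage (or the whole chain) of the analysis: simulate the
#' transect, normalize the tables (copy numbers, hits per million),
#' diversity statistics, co-occurrence networks, beta-diversity breakpoints,
#' and the warming projection. Each stage writes delimited artifacts under
#' `config$out_dir` and the run report `run_report.json` records inputs,
#' parameters and headline results.
#'
#' @param config a [pipeline_config()].
#' @param stage one of `"simulate"`, `"normalize"`, `"diversity"`,
#'   `"network"`, `"breakpoint"`, `"project"`, `"all"`.
#' @return the run report, invisibly (a named list; also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stage = c("all", "simulate", "normalize",
                                   "diversity", "network", "breakpoint",
                                   "project")) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") c("simulate", "normalize", "diversity",
                                  "network", "breakpoint", "project")
            else stage
  report <- list(seed = config$seed, stages = stages,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 package_version = as.character(utils::packageVersion("poleward")))
  for (s in stages) {
    message("[poleward] stage: ", s)
    report[[s]] <- switch(s,
      simulate = stage_simulate(config),
      normalize = stage_normalize(config),
      diversity = stage_diversity(config),
      network = stage_network(config),
      breakpoint = stage_breakpoint(config),
      project = stage_project(config))
  }
  jsonlite::write_json(report, stage_path(config, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

stage_simulate <- function(config) {
  sim <- simulate_transect(config$transect)
  write_feature_table(sim$tables$taxon_16S, stage_path(config, "t16S_raw.tsv"))
  write_feature_table(sim$tables$taxon_18S, stage_path(config, "t18S_raw.tsv"))
  write_feature_table(sim$tables$pfam, stage_path(config, "pfam_raw.tsv"))
  utils::write.table(sim$env, stage_path(config, "environment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_taxonomy(sim$taxonomy, stage_path(config, "taxonomy.tsv"))
  utils::write.table(sim$reference, stage_path(config, "reference_18S.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(
    data.frame(name = names(sim$truth$copy_numbers_16S),
               copy_number = sim$truth$copy_numbers_16S),
    stage_path(config, "reference_16S.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold_T = sim$truth$threshold_T,
         module_membership = as.list(sim$truth$module_membership)),
    stage_path(config, "truth.json"), auto_unbox = TRUE, digits = NA)
  list(n_stations = nrow(sim$env), threshold_T = sim$truth$threshold_T)
}

stage_normalize <- function(config) {
  t16 <- read_feature_table(need_artifact(config, "t16S_raw.tsv", "simulate"),
                            "taxon_16S")
  t18 <- read_feature_table(need_artifact(config, "t18S_raw.tsv", "simulate"),
                            "taxon_18S")
  pf <- read_feature_table(need_artifact(config, "pfam_raw.tsv", "simulate"),
                           "pfam")
  tax <- read_taxonomy(need_artifact(config, "taxonomy.tsv", "simulate"))
  ref18 <- read_reference_table(need_artifact(config, "reference_18S.tsv",
                                              "simulate"))
  ref16 <- utils::read.table(need_artifact(config, "reference_16S.tsv",
                                           "simulate"),
                             header = TRUE, sep = "\t")

  # 16S: strain/species-averaged copy numbers, lineage-imputed, then divide
  cp16 <- average_copy_numbers_by_species(ref16$name, ref16$copy_number)
  cp16 <- impute_missing_attribute(tax, cp16, colnames(t16))
  t16n <- hits_per_million(normalize_by_copy_number(t16, cp16))

  # 18S: fit the copy-number law on reference species with both values
  # known, impute missing genome sizes from taxonomy ancestors, predict
  # copy numbers from the law, then divide
  known <- ref18[!is.na(ref18$genome_size_Mbp) & !is.na(ref18$copy_number), ]
  model <- fit_copy_number_model(known$genome_size_Mbp, known$copy_number)
  gsizes <- impute_missing_attribute(
    tax, stats::setNames(known$genome_size_Mbp, known$name), colnames(t18))
  cp18 <- predict_copy_number(model, gsizes)
  t18n <- hits_per_million(normalize_by_copy_number(t18, cp18))

  pfn <- hits_per_million(pf)
  write_feature_table(t16n, stage_path(config, "t16S_norm.tsv"))
  write_feature_table(t18n, stage_path(config, "t18S_norm.tsv"))
  write_feature_table(pfn, stage_path(config, "pfam_norm.tsv"))
  list(copy_model = list(slope = model$slope, intercept = model$intercept,
                         r_squared = model$r_squared, n = model$n_points))
}

stage_diversity <- function(config) {
  t16n <- read_feature_table(need_artifact(config, "t16S_norm.tsv",
                                           "normalize"), "taxon_16S")
  env <- utils::read.table(need_artifact(config, "environment.tsv",
                                         "simulate"),
                           header = TRUE, sep = "\t", row.names = 1)
  H <- apply(t16n, 1, shannon)
  covars <- env[, c("temperature", "salinity", "nitrate_nitrite",
                    "phosphate", "silicate")]
  sel <- glm_backward_select(H, covars)
  cca <- vapply(names(covars), function(v) {
    cca_inertia_fraction(t16n, env[[v]])
  }, numeric(1))
  even <- dispersion_evenness(t16n)
  utils::write.table(data.frame(station_id = names(H), shannon = H),
                     stage_path(config, "shannon.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(even, stage_path(config, "evenness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_dissimilarity(bray_curtis_matrix(hellinger(t16n)),
                      stage_path(config, "bray_curtis_16S.tsv"))
  list(selected_covariates = sel$selected, cca_fraction = as.list(cca))
}

stage_network <- function(config) {
  t16n <- read_feature_table(need_artifact(config, "t16S_norm.tsv",
                                           "normalize"), "taxon_16S")
  t18n <- read_feature_table(need_artifact(config, "t18S_norm.tsv",
                                           "normalize"), "taxon_18S")
  pfn <- read_feature_table(need_artifact(config, "pfam_norm.tsv",
                                          "normalize"), "pfam")
  env <- utils::read.table(need_artifact(config, "environment.tsv",
                                         "simulate"),
                           header = TRUE, sep = "\t", row.names = 1)
  run_one <- function(tab, ncfg, tag) {
    sds <- apply(log10(tab + 1), 2, stats::sd)
    tab <- tab[, sds > 0, drop = FALSE]
    adj <- soft_adjacency(tab, ncfg$soft_power,
                          log_transform = ncfg$log_transform,
                          type = ncfg$adjacency_type)
    tom <- tom_matrix(adj)
    labels <- detect_modules(tom, ncfg)
    mods <- setdiff(unique(labels), "grey")
    eg <- vapply(mods, function(m) module_eigengene(tab, labels, m),
                 numeric(nrow(tab)))
    covars <- env[, c("temperature", "salinity", "nitrate_nitrite",
                      "phosphate", "silicate")]
    covars$altered_latitude <- env$altered_latitude
    tr <- if (length(mods) > 0) module_trait_correlation(eg, covars) else NULL
    utils::write.table(data.frame(feature = names(labels), module = labels),
                       stage_path(config, paste0("modules_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(mods) > 0) {
      utils::write.table(data.frame(station_id = rownames(eg), eg),
                         stage_path(config, paste0("eigengenes_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(n_modules = length(mods),
         module_sizes = as.list(table(labels[labels != "grey"])),
         temperature_r = if (!is.null(tr)) as.list(tr$r[, "temperature"]))
  }
  combined <- feature_table(cbind(unclass(t16n), unclass(t18n)), "taxon_16S")
  list(taxa = run_one(combined, config$network_taxa, "taxa"),
       pfam = run_one(pfn, config$network_pfam, "pfam"))
}

stage_breakpoint <- function(config) {
  env <- utils::read.table(need_artifact(config, "environment.tsv",
                                         "simulate"),
                           header = TRUE, sep = "\t", row.names = 1)
  axis <- if (config$breakpoint_axis == "temperature") env$temperature
          else env$altered_latitude
  names(axis) <- rownames(env)
  run_one <- function(file, kind, window) {
    tab <- read_feature_table(need_artifact(config, file, "normalize"), kind)
    beta <- station_beta(sorensen_matrix(presence_absence(tab)),
                         reduction = config$reduction,
                         order_by = env[rownames(tab), "latitude"])
    x <- axis[names(beta)]
    if (!is.null(window)) {
      keep <- x >= window[1] & x <= window[2]
      x <- x[keep]; beta <- beta[keep]
    }
    out <- suppressWarnings(bag_outliers(x, beta))
    fit <- fit_breakpoint(x[!out], beta[!out], search_range = window)
    utils::write.table(
      data.frame(station_id = names(beta), x = x, beta = beta,
                 outlier = out),
      stage_path(config, paste0("beta_", kind, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(psi = fit$psi, p_value = fit$p_value, mse = fit$mse,
         n_used = sum(!out), n_flagged = sum(out))
  }
  window <- if (config$breakpoint_axis == "temperature")
    config$amplicon_search else NULL
  res <- list(
    taxon_16S = run_one("t16S_norm.tsv", "taxon_16S", window),
    taxon_18S = run_one("t18S_norm.tsv", "taxon_18S", window),
    pfam = run_one("pfam_norm.tsv", "pfam", NULL))
  jsonlite::write_json(res, stage_path(config, "breakpoints.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}

stage_project <- function(config) {
  grids <- simulate_sst_grids(seed = config$seed,
                              warming_offset = config$warming_offset)
  corrected <- bias_correct(grids$obs, grids$hist, grids$proj)
  before <- classify_bands(grids$obs, config$thresholds)
  after <- classify_bands(corrected, config$thresholds)
  shift <- band_shift_summary(before, after, grids$obs$latitudes)
  write_grid_csv(grids$obs, stage_path(config, "sst_obs.csv"))
  write_grid_csv(corrected, stage_path(config, "sst_projected_corrected.csv"))
  utils::write.table(as.data.frame.matrix(shift$transitions),
                     stage_path(config, "band_transitions.tsv"),
                     sep = "\t", quote = FALSE)
  list(fraction_before = as.list(shift$fraction_before),
       fraction_after = as.list(shift$fraction_after))
}
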