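#' Configuration for a synthetic pole-to-pole transect
#'
#' Defines the study conditions the generator emulates: a latitudinal
#' station transect with a monotone temperature gradient and anti-correlated
#' nutrients, two latent community regimes (cold and warm) switching at a
#' planted temperature threshold, lognormal abundance noise, and a power-law
#' 18S copy-number versus genome-size relationship.
#'
#' @param n_stations number of stations along the transect (>= 8).
#' @param lat_range latitude extent in degrees, inside `[-90, 90]`.
#' @param T_pole,T_equator sea-surface temperature at the poleward and
#'   equatorial ends, degrees C.
#' @param threshold_T planted regime-switch temperature (the ground-truth
#'   breakpoint), strictly between `T_pole` and `T_equator`.
#' @param n_cold_taxa,n_warm_taxa,n_shared_taxa feature counts per regime
#'   (applied to both the 16S and the 18S table).
#' @param n_pfams_per_module Pfam features per co-occurrence module.
#' @param n_pfams_background unstructured (housekeeping-like) Pfam features
#'   outside any module; they keep the station totals stable under
#'   hits-per-million closure, as the non-module majority of a real
#'   metatranscriptome does.
#' @param noise_sd lognormal noise sigma on log10 abundance.
#' @param copy_slope,copy_intercept planted coefficients of the
#'   log10(copies) ~ log10(genome Mbp) law.
#' @param copy_noise_sd sigma of the Gaussian scatter on log10 copy number
#'   around the law. The default 0.3 is calibrated a priori so that with
#'   log10 genome sizes of sd 0.5 the refitted law has R^2 near 0.55
#'   (signal variance 0.66^2 * 0.25 = 0.109; 0.109 / (0.109 + 0.09) = 0.55).
#' @param logistic_scale temperature scale (degrees C) of the logistic
#'   occupancy curve; turnover concentrates within about 2 scales of the
#'   threshold.
#' @param center_sd per-feature jitter (degrees C) of the turnover midpoint
#'   around `threshold_T`.
#' @param warm_clump_frac fraction of warm taxa whose onset sits at the
#'   regime boundary; the remainder have onsets spread over the warm range
#'   with density increasing toward the warm end (niche packing), which
#'   makes species turnover accumulate linearly above the threshold.
#' @param module_factor_sd sigma (log10 units) of the shared per-station
#'   regime factor that gives features of one module correlated abundance
#'   fluctuations beyond the temperature response.
#' @param pfam_t_effect dynamic range (log10 units) of the temperature
#'   response of regime Pfams; Pfam features stay detected everywhere and
#'   vary in expression rather than switching on and off.
#' @param missing_frac fraction of 18S species with missing genome size in
#'   the emitted reference table (exercises imputation).
#' @param hemisphere `"both"` for a pole-to-pole grid, `"north"` for a
#'   single-hemisphere transect.
#' @param seed integer RNG seed.
#' @return validated list of class `transect_config`.
#' @export
transect_config <- function(n_stations = 60,
                            lat_range = c(-85, 85),
                            T_pole = -2, T_equator = 30,
                            threshold_T = 14,
                            n_cold_taxa = 24, n_warm_taxa = 60,
                            n_shared_taxa = 10,
                            n_pfams_per_module = 60,
                            n_pfams_background = 300,
                            noise_sd = 0.2,
                            copy_slope = 0.66, copy_intercept = 0.75,
                            copy_noise_sd = 0.3,
                            logistic_scale = 1.5,
                            center_sd = 1,
                            warm_clump_frac = 0.5,
                            module_factor_sd = 0.5,
                            pfam_t_effect = 1.0,
                            missing_frac = 0.3,
                            hemisphere = c("both", "north"),
                            seed = 1L) {
  cfg <- list(n_stations = n_stations, lat_range = lat_range,
              T_pole = T_pole, T_equator = T_equator,
              threshold_T = threshold_T,
              n_cold_taxa = n_cold_taxa, n_warm_taxa = n_warm_taxa,
              n_shared_taxa = n_shared_taxa,
              n_pfams_per_module = n_pfams_per_module,
              n_pfams_background = n_pfams_background,
              noise_sd = noise_sd,
              copy_slope = copy_slope, copy_intercept = copy_intercept,
              copy_noise_sd = copy_noise_sd,
              logistic_scale = logistic_scale, center_sd = center_sd,
              warm_clump_frac = warm_clump_frac,
              module_factor_sd = module_factor_sd,
              pfam_t_effect = pfam_t_effect,
              missing_frac = missing_frac,
              hemisphere = match.arg(hemisphere),
              seed = as.integer(seed))
  fail <- function(field, why) {
    stop(sprintf("invalid transect_config field '%s': %s", field, why))
  }
  if (cfg$n_stations < 8) fail("n_stations", "must be >= 8")
  if (length(lat_range) != 2 || any(abs(lat_range) > 90) ||
      lat_range[1] >= lat_range[2]) {
    fail("lat_range", "must be an increasing pair within [-90, 90]")
  }
  if (!(T_pole < threshold_T && threshold_T < T_equator)) {
    fail("threshold_T", "must satisfy T_pole < threshold_T < T_equator")
  }
  for (f in c("n_cold_taxa", "n_warm_taxa", "n_shared_taxa",
              "n_pfams_per_module")) {
    if (cfg[[f]] < 1) fail(f, "must be >= 1")
  }
  if (cfg$n_pfams_background < 0) fail("n_pfams_background", "must be >= 0")
  for (f in c("noise_sd", "copy_noise_sd", "center_sd", "module_factor_sd",
              "pfam_t_effect")) {
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  if (cfg$logistic_scale <= 0) fail("logistic_scale", "must be > 0")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    fail("missing_frac", "must be in [0, 1)")
  }
  if (cfg$warm_clump_frac < 0 || cfg$warm_clump_frac > 1) {
    fail("warm_clump_frac", "must be in [0, 1]")
  }
  structure(cfg, class = "transect_config")
}

station_regions <- function(lat) {
  cut(lat, breaks = c(-91, -66, -23, 23, 66, 91),
      labels = c("southern", "south_atlantic", "tropical",
                 "north_atlantic", "arctic"))
}

# one regime-structured abundance block (stations x features); occupancy is
# a logistic in temperature around per-feature turnover midpoints, with
# multiplicative lognormal noise entering both detection and abundance
simulate_block <- function(Tvec, centers, direction, cfg, module_factor,
                           prefix) {
  n <- length(Tvec)
  n_feat <- length(centers)
  base <- 10^stats::runif(n_feat, 1.5, 3.5)
  eps <- matrix(stats::rnorm(n * n_feat, 0, cfg$noise_sd), n, n_feat)
  vals <- matrix(0, n, n_feat)
  for (f in seq_len(n_feat)) {
    z <- direction * (Tvec - centers[f]) / cfg$logistic_scale
    act <- stats::plogis(z)
    present <- act * 10^eps[, f] > 0.5
    vals[, f] <- ifelse(
      present,
      base[f] * act * 10^(cfg$module_factor_sd * module_factor + eps[, f]),
      0)
  }
  colnames(vals) <- sprintf("%s%03d", prefix, seq_len(n_feat))
  vals
}

# turnover midpoints: cold taxa leave at the regime boundary; half the warm
# taxa arrive there, the rest accumulate equatorward with onset density
# increasing linearly toward the warm end (niche packing)
taxon_centers <- function(cfg, T_max) {
  cold <- cfg$threshold_T + stats::rnorm(cfg$n_cold_taxa, 0, cfg$center_sd)
  n_boundary <- round(cfg$warm_clump_frac * cfg$n_warm_taxa)
  warm <- c(cfg$threshold_T + stats::rnorm(n_boundary, 0, cfg$center_sd),
            cfg$threshold_T + (T_max - cfg$threshold_T) *
              sqrt(stats::runif(cfg$n_warm_taxa - n_boundary)))
  list(cold = cold, warm = warm)
}

# regime Pfams: always detected, expression modulated by temperature
simulate_pfam_block <- function(Tvec, n_feat, direction, cfg, module_factor,
                                prefix) {
  n <- length(Tvec)
  centers <- cfg$threshold_T + stats::rnorm(n_feat, 0, cfg$center_sd)
  base <- 10^stats::runif(n_feat, 1.5, 3.5)
  eps <- matrix(stats::rnorm(n * n_feat, 0, cfg$noise_sd), n, n_feat)
  vals <- matrix(0, n, n_feat)
  for (f in seq_len(n_feat)) {
    z <- direction * (Tvec - centers[f]) / cfg$logistic_scale
    lg <- cfg$pfam_t_effect * stats::plogis(z) +
      cfg$module_factor_sd * module_factor + eps[, f]
    vals[, f] <- base[f] * 10^lg
  }
  colnames(vals) <- sprintf("%s%04d", prefix, seq_len(n_feat))
  vals
}

#' Simulate a pole-to-pole transect with planted ground truth
#'
#' Generates the three community tables (genus-level 16S, species-level 18S,
#' Pfam-level transcripts), the per-station environment, a four-level
#' taxonomy, a genome-size/copy-number reference with missing entries, and
#' the planted truth (regime threshold, module membership, copy numbers).
#'
#' Cold features follow a decreasing and warm features an increasing
#' logistic occupancy curve in temperature centred near the planted
#' threshold; taxa switch on/off (driving presence-absence turnover) while
#' Pfams stay detected and modulate expression (driving the co-occurrence
#' modules). Nutrients anti-correlate and salinity correlates positively
#' with temperature.
#'
#' @param config a [transect_config()].
#' @return list with elements `tables` (named list `taxon_16S`, `taxon_18S`,
#'   `pfam`), `env` (data frame, row names = station ids), `taxonomy`
#'   (data frame), `reference` (18S genome-size/copy-number table with NAs),
#'   `truth` (list: `threshold_T`, `module_membership`, `copy_numbers`,
#'   `genome_sizes`, `copy_numbers_16S`).
#' @export
simulate_transect <- function(config = transect_config()) {
  if (!inherits(config, "transect_config")) config <- do.call(transect_config, config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_stations

  lr <- if (cfg$hemisphere == "north") c(max(0, cfg$lat_range[1]), cfg$lat_range[2])
        else cfg$lat_range
  lat <- seq(lr[1], lr[2], length.out = n)
  ids <- sprintf("st%02d", seq_len(n))
  Tvec <- cfg$T_equator - (cfg$T_equator - cfg$T_pole) * abs(lat) / 90
  rel_cold <- (cfg$T_equator - Tvec) / (cfg$T_equator - cfg$T_pole)
  env <- data.frame(
    station_id = ids,
    latitude = lat,
    altered_latitude = altered_latitude(lat),
    temperature = Tvec,
    salinity = 33 + 2.5 * (1 - rel_cold) + stats::rnorm(n, 0, 0.1),
    nitrate_nitrite = pmax(0, 0.5 + 12 * rel_cold + stats::rnorm(n, 0, 0.5)),
    phosphate = pmax(0, 0.05 + 1.2 * rel_cold + stats::rnorm(n, 0, 0.05)),
    silicate = pmax(0, 1 + 25 * rel_cold + stats::rnorm(n, 0, 1)),
    region = station_regions(lat),
    row.names = ids)

  u_cold <- stats::rnorm(n)
  u_warm <- stats::rnorm(n)
  zero <- rep(0, n)

  make_taxon_table <- function(prefix) {
    cen <- taxon_centers(cfg, max(Tvec))
    cold <- simulate_block(Tvec, cen$cold, -1, cfg, u_cold,
                           paste0(prefix, "_cold"))
    warm <- simulate_block(Tvec, cen$warm, +1, cfg, u_warm,
                           paste0(prefix, "_warm"))
    shared <- simulate_block(Tvec, rep(-1e6, cfg$n_shared_taxa), +1, cfg,
                             zero, paste0(prefix, "_ubiq")) # act ~ 1
    cbind(cold, warm, shared)
  }
  t16 <- make_taxon_table("g16S")
  t18 <- make_taxon_table("sp18S")
  pf_cold <- simulate_pfam_block(Tvec, cfg$n_pfams_per_module, -1, cfg,
                                 u_cold, "PF_cold")
  pf_warm <- simulate_pfam_block(Tvec, cfg$n_pfams_per_module, +1, cfg,
                                 u_warm, "PF_warm")
  pf_bg <- {
    nb <- cfg$n_pfams_background
    base <- 10^stats::runif(nb, 1.5, 3.5)
    # background Pfams vary with their own processes (0.5 log10 units) on
    # top of measurement noise; their bulk keeps station totals stable so
    # per-million closure does not imprint the regime signal on everything
    sd_bg <- sqrt(cfg$noise_sd^2 + 0.25)
    eps <- matrix(stats::rnorm(n * nb, 0, sd_bg), n, nb)
    bg <- sweep(10^eps, 2, base, "*")
    colnames(bg) <- sprintf("PF_bg%04d", seq_len(nb))
    bg
  }
  pfam <- cbind(pf_cold, pf_warm, pf_bg)
  rownames(t16) <- rownames(t18) <- rownames(pfam) <- ids

  membership <- c(
    stats::setNames(rep(c("cold", "warm", "none"),
                        c(cfg$n_cold_taxa, cfg$n_warm_taxa,
                          cfg$n_shared_taxa)), colnames(t16)),
    stats::setNames(rep(c("cold", "warm", "none"),
                        c(cfg$n_cold_taxa, cfg$n_warm_taxa,
                          cfg$n_shared_taxa)), colnames(t18)),
    stats::setNames(rep(c("cold", "warm", "none"),
                        c(cfg$n_pfams_per_module, cfg$n_pfams_per_module,
                          cfg$n_pfams_background)), colnames(pfam)))

  # taxonomy: balanced root -> domain -> class -> genus -> species tree
  # covering the 16S genera (under Bacteria) and 18S species (Eukaryota)
  tax <- build_transect_taxonomy(colnames(t16), colnames(t18))

  # planted 18S copy-number law on genome size (Mbp)
  sp <- colnames(t18)
  genome <- 10^stats::rnorm(length(sp), 1.5, 0.5)
  copies <- 10^(cfg$copy_slope * log10(genome) + cfg$copy_intercept +
                  stats::rnorm(length(sp), 0, cfg$copy_noise_sd))
  names(genome) <- names(copies) <- sp
  masked <- sample(sp, floor(cfg$missing_frac * length(sp)))
  reference <- data.frame(
    name = sp,
    genome_size_Mbp = ifelse(sp %in% masked, NA_real_, genome),
    copy_number = ifelse(sp %in% masked, NA_real_, copies),
    row.names = NULL)

  # 16S copy numbers: modest integer-ish operon counts, all known at genus
  cp16 <- stats::setNames(pmax(1, round(stats::rlnorm(ncol(t16), log(3), 0.4))),
                          colnames(t16))

  list(tables = list(taxon_16S = feature_table(t16, "taxon_16S"),
                     taxon_18S = feature_table(t18, "taxon_18S"),
                     pfam = feature_table(pfam, "pfam")),
       env = env,
       taxonomy = tax,
       reference = reference,
       truth = list(threshold_T = cfg$threshold_T,
                    module_membership = membership,
                    copy_numbers = copies,
                    genome_sizes = genome,
                    copy_numbers_16S = cp16),
       config = cfg)
}

# balanced 4-level taxonomy over the generated features; every 5 species
# share a genus, every 4 genera a class
build_transect_taxonomy <- function(genera_16S, species_18S) {
  rows <- list(data.frame(node_id = "root", parent_id = "root",
                          rank = "root", name = "cellular organisms"),
               data.frame(node_id = "d_bact", parent_id = "root",
                          rank = "domain", name = "Bacteria"),
               data.frame(node_id = "d_euk", parent_id = "root",
                          rank = "domain", name = "Eukaryota"))
  # 16S: genera grouped into classes of 8
  n_cls <- ceiling(length(genera_16S) / 8)
  for (k in seq_len(n_cls)) {
    cid <- sprintf("c_b%02d", k)
    rows[[length(rows) + 1]] <- data.frame(
      node_id = cid, parent_id = "d_bact", rank = "class",
      name = sprintf("Bacteroclassia_%02d", k))
    members <- genera_16S[((k - 1) * 8 + 1):min(k * 8, length(genera_16S))]
    rows[[length(rows) + 1]] <- data.frame(
      node_id = members, parent_id = cid, rank = "genus", name = members)
  }
  # 18S: species grouped 5 per genus, genera grouped 4 per class
  n_gen <- ceiling(length(species_18S) / 5)
  for (g in seq_len(n_gen)) {
    cls_k <- ceiling(g / 4)
    cid <- sprintf("c_e%02d", cls_k)
    if (g %% 4 == 1 || g == 1) {
      if (!any(vapply(rows, function(r) cid %in% r$node_id, logical(1)))) {
        rows[[length(rows) + 1]] <- data.frame(
          node_id = cid, parent_id = "d_euk", rank = "class",
          name = sprintf("Algoclassia_%02d", cls_k))
      }
    }
    gid <- sprintf("g_e%03d", g)
    rows[[length(rows) + 1]] <- data.frame(
      node_id = gid, parent_id = cid, rank = "genus",
      name = sprintf("Algogenus_%03d", g))
    members <- species_18S[((g - 1) * 5 + 1):min(g * 5, length(species_18S))]
    rows[[length(rows) + 1]] <- data.frame(
      node_id = members, parent_id = gid, rank = "species", name = members)
  }
  tax <- do.call(rbind, rows)
  rownames(tax) <- NULL
  validate_taxonomy(tax)
}

#' Simulate observed, historical and projected SST grids
#'
#' The observed climatology follows a squared-cosine meridional gradient
#' with a small zonal ripple; the model historical field carries a smooth
#' spatially varying bias; the projection is the historical field plus a
#' uniform warming offset, each with optional cell noise. The ice mask marks
#' cells at or below the freezing proxy of -1.8 degrees C in the
#' observations.
#'
#' @param n_lat,n_lon grid dimensions (>= 2).
#' @param warming_offset uniform warming of the projection, degrees C.
#' @param seed integer RNG seed.
#' @param noise_sd sigma of cell-level noise on the historical and projected
#'   fields (0 for exact arithmetic checks).
#' @return list of `climate_grid`s: `obs`, `hist`, `proj`, plus `ice_mask`.
#' @export
simulate_sst_grids <- function(n_lat = 60, n_lon = 30, warming_offset = 3,
                               seed = 1L, noise_sd = 0.1) {
  if (n_lat < 2 || n_lon < 2) stop("grid error: n_lat and n_lon must be >= 2")
  set.seed(as.integer(seed))
  lats <- seq(-89, 89, length.out = n_lat)
  lons <- seq(-179, 179, length.out = n_lon)
  merid <- -2.5 + 33 * cos(lats * pi / 180)^2
  ripple <- 0.5 * sin(lons * pi / 180)
  obs <- pmax(outer(merid, ripple, "+"), -2)
  bias <- outer(0.8 * sin(lats * pi / 90), 0.4 * cos(lons * pi / 180), "+")
  hist_f <- obs + bias + matrix(stats::rnorm(n_lat * n_lon, 0, noise_sd),
                                n_lat, n_lon)
  proj_f <- hist_f + warming_offset +
    matrix(stats::rnorm(n_lat * n_lon, 0, noise_sd), n_lat, n_lon)
  clamp <- function(x) pmin(pmax(x, -2), 45)
  ice <- obs <= -1.8
  list(obs = climate_grid(obs, lats, lons, "1961-1990", ice),
       hist = climate_grid(clamp(hist_f), lats, lons, "1961-1990 model", ice),
       proj = climate_grid(clamp(proj_f), lats, lons, "2070-2099", ice),
       ice_mask = ice)
}
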