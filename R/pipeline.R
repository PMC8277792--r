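# End-to-end orchestration: simulate -> env -> sdm -> niche -> shift ->
# traits, driven by one config, writing per-stage CSV/JSON outputs and a run
# manifest. Synthetic inputs (DEM, climate) are regenerated deterministically
# from the config's seeds wherever a stage needs them, so stages communicate
# through small text files only.

#' Default pipeline configuration
#'
#' All tunable parameters of the synthetic study: grid, years, climate trend,
#' virtual species, SDM settings, niche-volume settings and the record
#' filters. Any element can be overridden via `modifyList()` semantics or a
#' YAML file.
#'
#' @param ... named overrides of top-level config entries.
#' @return nested list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid = list(nx = 80, ny = 80, cell_size = 100,
                base_elev = 400, amplitude = 3400, n_ridges = 4),
    years = list(from = 1961, to = 2019),
    climate = list(lapse_rate = 0.0065, warming_rate = 0.04,
                   seasonal_amp = 9, noise_sd = 0.3, prec_base = 90,
                   prec_elev_grad = 0, sea_level_temp = 14,
                   diurnal_delta = 5),
    species = NULL,          # list of species_spec argument lists; NULL =
                             # auto-generate n_species along the gradient
    n_species = 12,
    records_per_year = 8,
    sdm = list(beta = 1, replicates = 20, train_frac = 0.8,
               omission_rate = 0.10, background_per_year = 50),
    niche = list(nu = 0.05, n_mc = 5000),
    filters = list(min_records = 13, low_elev_threshold = 600,
                   max_low_elev_fraction = 0.05, min_sites = 5,
                   min_years = 5),
    seeds = list(dem = 101, climate = 202, records = 303, background = 404,
                 sdm = 505, niche = 606))
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return nested config list.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# virtual species spread along the thermal (altitudinal) gradient, traits
# cycling through all levels; programmed so every trait level is represented
auto_species <- function(cfg) {
  n <- cfg$n_species
  cl <- cfg$climate
  topt <- seq(cl$sea_level_temp - cl$lapse_rate * (cfg$grid$base_elev + 300),
              cl$sea_level_temp - cl$lapse_rate *
                (cfg$grid$base_elev + cfg$grid$amplitude - 500),
              length.out = n)
  disp <- rep(c("sedentary", "intermediate", "mobile"), length.out = n)
  eury <- rep(c("generalist", "specialist"), length.out = n)
  endg <- rep(c("least_concern", "threatened"), length.out = n)
  lapply(seq_len(n), function(i)
    species_spec(sprintf("sp%02d", i), thermal_optimum = topt[i],
                 thermal_breadth = if (eury[i] == "generalist") 2 else 1,
                 prec_optimum = 1100, prec_breadth = 900,
                 records_per_year = cfg$records_per_year,
                 traits = list(euryocy = eury[i], dispersal = disp[i],
                               endangerment = endg[i])))
}

config_species <- function(cfg) {
  if (is.null(cfg$species)) return(auto_species(cfg))
  lapply(cfg$species, function(a) do.call(species_spec, a))
}

#' Species trait table from a configuration
#'
#' @param cfg config list.
#' @return data frame `species, euryocy, dispersal, endangerment`.
#' @export
species_traits_table <- function(cfg) {
  sp <- config_species(cfg)
  data.frame(
    species = vapply(sp, `[[`, "", "name"),
    euryocy = vapply(sp, function(s) s$traits$euryocy, ""),
    dispersal = vapply(sp, function(s) s$traits$dispersal, ""),
    endangerment = vapply(sp, function(s) s$traits$endangerment, ""),
    stringsAsFactors = FALSE)
}

#' Filter species by record count and lowland occurrence
#'
#' Drops species with fewer than `min_records` records and species whose
#' fraction of records below the lowland threshold exceeds the permitted
#' "exceptional" fraction, with a per-reason exclusion report.
#'
#' @param records occurrence data frame.
#' @param min_records minimum record count per species (default 13).
#' @param low_elev_threshold lowland boundary in m (default 600).
#' @param max_low_elev_fraction maximum tolerated fraction of records below
#'   the boundary (default 0.05).
#' @return filtered records; `attr(, "exclusions")` is a data frame
#'   `species, n_records, frac_low, reason`.
#' @export
filter_species <- function(records, min_records = 13,
                           low_elev_threshold = 600,
                           max_low_elev_fraction = 0.05) {
  by_sp <- split(records, records$species)
  info <- do.call(rbind, lapply(by_sp, function(r) data.frame(
    species = r$species[1], n_records = nrow(r),
    frac_low = mean(r$elevation < low_elev_threshold))))
  info$reason <- ifelse(info$n_records < min_records, "too_few_records",
                 ifelse(info$frac_low > max_low_elev_fraction,
                        "lowland_occurrences", "retained"))
  keep <- info$species[info$reason == "retained"]
  out <- records[records$species %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- info[info$reason != "retained", , drop = FALSE]
  out
}

# deterministic world shared by all stages
build_world <- function(cfg) {
  dem <- make_dem(cfg$grid$nx, cfg$grid$ny, cfg$grid$cell_size,
                  relief = list(base_elev = cfg$grid$base_elev,
                                amplitude = cfg$grid$amplitude,
                                n_ridges = cfg$grid$n_ridges),
                  seed = cfg$seeds$dem)
  years <- seq(cfg$years$from, cfg$years$to)
  climate <- do.call(make_climate_series,
                     c(list(dem = dem, years = years, seed = cfg$seeds$climate),
                       cfg$climate))
  insolation <- make_insolation(dem)
  list(dem = dem, years = years, climate = climate, insolation = insolation)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order, writing per-stage outputs under `outdir`
#' and a machine-readable manifest (`manifest.json`). A rerun with an
#' unchanged config reuses existing stage outputs (resumable per stage);
#' `force = TRUE` recomputes everything.
#'
#' Outputs: `records.csv`, `dem.asc`, `swd.csv`, `sdm_eval.csv`,
#' `sdm_annual.csv`, `results_sdm.csv`, `decadal_sdm.csv`, `niche.csv`,
#' `results_records.csv`, `decadal_records.csv`, `trait_glm.csv`,
#' `relations.csv`, `manifest.json`.
#'
#' @param config config list from [default_config()] / [read_config()], or a
#'   YAML path.
#' @param outdir output directory (created if needed).
#' @param seed optional integer overriding every stage seed (offset per
#'   stage).
#' @param force recompute even when outputs exist.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (list with config hash, stage status and
#'   output paths).
#' @export
run_pipeline <- function(config = default_config(), outdir = "oroshift_run",
                         seed = NULL, force = FALSE, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (!is.null(seed))
    cfg$seeds <- as.list(stats::setNames(
      as.integer(seed) + seq_along(cfg$seeds) * 1000L, names(cfg$seeds)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  man_path <- file.path(outdir, "manifest.json")
  prev <- if (file.exists(man_path))
    tryCatch(jsonlite::read_json(man_path), error = function(e) NULL)
  else NULL
  fresh <- force || is.null(prev) || !identical(prev$config_hash, hash)
  say <- function(...) if (!quiet) message(sprintf(...))
  outp <- function(f) file.path(outdir, f)
  have <- function(...) !fresh && all(file.exists(outp(c(...))))
  stages <- list()

  world <- build_world(cfg)
  dem <- world$dem

  ## -- simulate ------------------------------------------------------------
  if (have("records.csv", "dem.asc")) {
    say("[simulate] cached")
    records <- read_occurrences(outp("records.csv"))
    stages$simulate <- "cached"
  } else {
    say("[simulate] sampling records for %d species, %d years",
        length(config_species(cfg)), length(world$years))
    records <- sample_records(config_species(cfg), world$climate, dem,
                              seed = cfg$seeds$records)
    write_occurrences(records, outp("records.csv"))
    write_ascii_grid(dem, outp("dem.asc"))
    stages$simulate <- "done"
  }
  records <- filter_species(records,
                            min_records = cfg$filters$min_records,
                            low_elev_threshold = cfg$filters$low_elev_threshold,
                            max_low_elev_fraction =
                              cfg$filters$max_low_elev_fraction)

  ## -- env -----------------------------------------------------------------
  bioclim <- lapply(world$climate, compute_bioclim)
  if (have("swd.csv")) {
    say("[env] cached")
    swd <- read_swd(outp("swd.csv"))
    stages$env <- "cached"
  } else {
    say("[env] bioclim + PCA spaces + SWD extraction")
    swd <- build_swd(records, bioclim, world, cfg)
    write_swd(swd, outp("swd.csv"))
    stages$env <- "done"
  }
  presence_swd <- swd[swd$species != "background", , drop = FALSE]
  background_swd <- swd[swd$species == "background", , drop = FALSE]
  sp_names <- sort(unique(presence_swd$species))

  ## -- sdm -----------------------------------------------------------------
  if (have("sdm_eval.csv", "sdm_annual.csv", "results_sdm.csv",
           "decadal_sdm.csv")) {
    say("[sdm] cached")
    stages$sdm <- "cached"
  } else {
    say("[sdm] fitting %d species", length(sp_names))
    # PCA spaces must match those used for the SWD extraction
    pcas <- fit_pca_spaces(records, bioclim, world)
    stacks <- env_axis_stacks(bioclim, world$insolation,
                              pcas$climate, pcas$topo, dem)
    fm <- build_features(background_swd)
    evals <- list(); ann_all <- list(); res_all <- list(); ser_all <- list()
    for (sp in sp_names) {
      pres <- presence_swd[presence_swd$species == sp, , drop = FALSE]
      ev <- bootstrap_evaluate(pres, background_swd, fm = fm,
                               beta = cfg$sdm$beta,
                               n_rep = cfg$sdm$replicates,
                               train_frac = cfg$sdm$train_frac,
                               omission_rate = cfg$sdm$omission_rate,
                               seed = cfg$seeds$sdm)
      fit <- fit_maxent(pres, background_swd, fm = fm, beta = cfg$sdm$beta)
      surfaces <- annual_projection(fit, stacks,
                                    ev$omission_threshold_mean, dem)
      ser <- surface_series(surfaces, dem)
      evals[[sp]] <- data.frame(
        species = sp, n_records = nrow(pres),
        auc_training = mean(ev$auc_training),
        auc_test = mean(ev$auc_test),
        threshold = ev$omission_threshold_mean)
      ann <- annual_stats_by_year(ser)
      ann$species <- sp
      ann_all[[sp]] <- ann
      ss <- shift_slopes(ser, source = "sdm",
                         min_sites = cfg$filters$min_sites,
                         min_years = cfg$filters$min_years)
      ss$species <- sp
      res_all[[sp]] <- ss
      ser$species <- sp
      ser_all[[sp]] <- ser
    }
    utils::write.csv(do.call(rbind, evals), outp("sdm_eval.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, ann_all), outp("sdm_annual.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, res_all), outp("results_sdm.csv"),
                     row.names = FALSE)
    dec_sdm <- decadal_median_shift(do.call(rbind, ser_all))
    utils::write.csv(dec_sdm$per_decade, outp("decadal_sdm.csv"),
                     row.names = FALSE)
    stages$sdm <- "done"
  }

  ## -- niche ---------------------------------------------------------------
  if (have("niche.csv")) {
    say("[niche] cached")
    stages$niche <- "cached"
  } else {
    say("[niche] hypervolumes for %d species", length(sp_names))
    pc_cols <- grep("^pc[0-9]+$", names(swd), value = TRUE)
    all_cols <- grep("^(pc|topo)[0-9]+$", names(swd), value = TRUE)
    niche <- do.call(rbind, lapply(sp_names, function(sp) {
      P <- presence_swd[presence_swd$species == sp, , drop = FALSE]
      hv_c <- fit_hypervolume(as.matrix(P[, pc_cols]), nu = cfg$niche$nu,
                              seed = cfg$seeds$niche)
      hv_a <- fit_hypervolume(as.matrix(P[, all_cols]), nu = cfg$niche$nu,
                              seed = cfg$seeds$niche)
      v_c <- estimate_volume(hv_c, n_mc = cfg$niche$n_mc,
                             seed = cfg$seeds$niche)
      v_a <- estimate_volume(hv_a, n_mc = cfg$niche$n_mc,
                             seed = cfg$seeds$niche)
      data.frame(species = sp, volume_climate = v_c$volume,
                 volume_climate_se = v_c$mc_se,
                 volume_climate_topo = v_a$volume,
                 volume_climate_topo_se = v_a$mc_se)
    }))
    utils::write.csv(niche, outp("niche.csv"), row.names = FALSE)
    stages$niche <- "done"
  }

  ## -- shift (record-based) ------------------------------------------------
  if (have("results_records.csv", "decadal_records.csv")) {
    say("[shift] cached")
    stages$shift <- "cached"
  } else {
    say("[shift] record-based statistics")
    res_rec <- do.call(rbind, lapply(sp_names, function(sp) {
      ser <- records[records$species == sp, , drop = FALSE]
      ss <- shift_slopes(ser, source = "records",
                         min_sites = cfg$filters$min_sites,
                         min_years = cfg$filters$min_years)
      ss$species <- sp
      ss
    }))
    utils::write.csv(res_rec, outp("results_records.csv"), row.names = FALSE)
    dec_rec <- decadal_median_shift(records)
    utils::write.csv(dec_rec$per_decade, outp("decadal_records.csv"),
                     row.names = FALSE)
    stages$shift <- "done"
  }

  ## -- traits --------------------------------------------------------------
  if (have("trait_glm.csv", "relations.csv")) {
    say("[traits] cached")
    stages$traits <- "cached"
  } else {
    say("[traits] general linear models")
    res_rec <- utils::read.csv(outp("results_records.csv"))
    niche <- utils::read.csv(outp("niche.csv"))
    traits <- species_traits_table(cfg)
    mrg <- merge(merge(res_rec, traits, by = "species"), niche,
                 by = "species")
    glm_rows <- list()
    for (resp in c("median_alt", "z_alt", "z_range", "z_vmr", "z_skew")) {
      y <- mrg[[resp]]
      ok <- is.finite(y)
      if (sum(ok) < 10) next
      g <- tryCatch(
        fit_trait_glm(y[ok], mrg[ok, c("euryocy", "dispersal",
                                       "endangerment")],
                      covariate = if (resp == "median_alt") NULL
                                  else mrg$median_alt[ok]),
        error = function(e) NULL)
      if (is.null(g)) next
      tab <- g$table
      tab$response <- resp
      tab$r2 <- g$r2
      glm_rows[[resp]] <- tab
    }
    utils::write.csv(do.call(rbind, glm_rows), outp("trait_glm.csv"),
                     row.names = FALSE)
    rel <- data.frame(
      relation = c("z_alt~volume_climate", "z_range~volume_climate",
                   "volume_climate_topo~volume_climate"),
      rbind(as.data.frame(ols_relation(mrg$volume_climate, mrg$z_alt)),
            as.data.frame(ols_relation(mrg$volume_climate, mrg$z_range)),
            as.data.frame(ols_relation(mrg$volume_climate,
                                       mrg$volume_climate_topo))))
    utils::write.csv(rel, outp("relations.csv"), row.names = FALSE)
    stages$traits <- "done"
  }

  manifest <- list(
    config_hash = hash,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages,
    outputs = as.list(stats::setNames(
      file.path(outdir, c("records.csv", "dem.asc", "swd.csv",
                          "sdm_eval.csv", "sdm_annual.csv", "results_sdm.csv",
                          "decadal_sdm.csv", "niche.csv",
                          "results_records.csv", "decadal_records.csv",
                          "trait_glm.csv", "relations.csv")),
      c("records", "dem", "swd", "sdm_eval", "sdm_annual", "results_sdm",
        "decadal_sdm", "niche", "results_records", "decadal_records",
        "trait_glm", "relations"))))
  missing_out <- !vapply(manifest$outputs, file.exists, TRUE)
  if (any(missing_out))
    stop("pipeline finished but outputs missing: ",
         paste(names(manifest$outputs)[missing_out], collapse = ", "),
         call. = FALSE)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# climate PCA trained on the bioclim conditions at the records; topography
# PCA trained on the monthly insolation values over the whole grid
fit_pca_spaces <- function(records, bioclim, world) {
  env_rec <- extract_env(records[, c("species", "x", "y", "year")],
                         bioclim, world$insolation, world$dem)
  bio_cols <- names(bioclim[[1]]$layers)
  ins_cols <- names(world$insolation)
  climate_pca <- fit_env_pca(env_rec[, bio_cols])
  ins_mat <- vapply(world$insolation, as.vector,
                    numeric(prod(dim(world$dem$values))))
  topo_pca <- fit_env_pca(ins_mat)
  list(climate = climate_pca, topo = topo_pca)
}

build_swd <- function(records, bioclim, world, cfg) {
  pcas <- fit_pca_spaces(records, bioclim, world)
  bg <- sample_background(world$years, cfg$sdm$background_per_year,
                          world$dem, seed = cfg$seeds$background)
  pres_swd <- extract_swd(records, bioclim, world$insolation,
                          pcas$climate, pcas$topo, world$dem)
  bg_swd <- extract_swd(bg, bioclim, world$insolation,
                        pcas$climate, pcas$topo, world$dem)
  rbind(pres_swd, bg_swd)
}
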