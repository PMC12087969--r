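# Orchestration: run the full analysis chain from one config, in dependency
# order, with seeds, parameters, per-stage status and checksums recorded in
# a manifest.

#' Pipeline configuration
#'
#' Every stage parameter has a default mirroring the study settings
#' (regularization multiplier 1.5, 20% random test split, 10 niche-model
#' replicates, 200 stochastic maps, 10,000 HMM-simulated sequences, 10-My
#' bins); every random stage draws its seed deterministically from `seed`.
#'
#' @param seed master integer seed.
#' @param sim a [sim_config()] (defaults to one derived from `seed`).
#' @param stages named logical vector toggling stages on/off.
#' @param reg_multiplier,test_fraction,enm_replicates niche-model settings.
#' @param thin_km spatial thinning buffer for extant records (km).
#' @param n_bsm stochastic maps; `biogeo_schemes`/`biogeo_jump` select the
#'   candidate models.
#' @param hmm_n_iter simulated HMM sequences for the logistic regression.
#' @param n_per_slice occurrence records generated per climate slice.
#' @param biogeo_schemes character vector of cladogenesis schemes to fit.
#' @param biogeo_jump fit +j variants too.
#' @param fit_models run the nine-model evolutionary suite (slowest stage).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL,
                            stages = c(enm = TRUE, omi = TRUE,
                                       comparative = TRUE, causal = TRUE,
                                       biogeo = TRUE, dispersal = TRUE,
                                       atmosphere = TRUE,
                                       habitability = TRUE),
                            reg_multiplier = 1.5, test_fraction = 0.2,
                            enm_replicates = 10L, thin_km = 6,
                            n_bsm = 200L, hmm_n_iter = 10000L,
                            n_per_slice = 30L,
                            biogeo_schemes = c("DEC", "DIVALIKE",
                                               "BAYAREALIKE"),
                            biogeo_jump = TRUE, fit_models = TRUE) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), sim = sim, stages = stages,
                 reg_multiplier = reg_multiplier,
                 test_fraction = test_fraction,
                 enm_replicates = as.integer(enm_replicates),
                 thin_km = thin_km, n_bsm = as.integer(n_bsm),
                 hmm_n_iter = as.integer(hmm_n_iter),
                 n_per_slice = as.integer(n_per_slice),
                 biogeo_schemes = biogeo_schemes,
                 biogeo_jump = biogeo_jump, fit_models = fit_models),
            class = "pipeline_config")
}

.checksum <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(obj, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

.stage_deps <- list(enm = character(0), omi = character(0),
                    comparative = character(0), causal = c("comparative"),
                    biogeo = character(0),
                    dispersal = c("biogeo", "comparative"),
                    atmosphere = character(0),
                    habitability = c("comparative"))

#' Run the full pipeline
#'
#' Stages run in dependency order (scenario generation always runs first):
#' niche modelling, OMI through time, comparative statistics, causal
#' inference, biogeography + stochastic mapping, dispersal-vs-wing-length,
#' atmosphere, habitability. A stage whose dependency is toggled off makes
#' the run halt cleanly with the stage and the missing dependency named.
#' The returned manifest records seeds, parameters, per-stage status,
#' timing and a checksum of each stage's results, so a rerun of the same
#' config can be verified bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: `results` (per-stage lists), `manifest`,
#'   `scenario`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- config$stages
  for (st in names(stages)) if (isTRUE(stages[[st]])) {
    miss <- .stage_deps[[st]][!vapply(.stage_deps[[st]], function(dpd)
      isTRUE(stages[[dpd]]), logical(1))]
    if (length(miss))
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(miss, collapse = ", "))
  }
  results <- list()
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("sim", "stages"))],
                   stages = list())
  run_stage <- function(name, fun) {
    if (!isTRUE(stages[[name]])) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    results[[name]] <<- out
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]]
                                                     - t0, 2),
                                     checksum = .checksum(out))
    invisible(NULL)
  }
  scen <- simulate_scenario(config$sim, n_per_slice = config$n_per_slice)
  manifest$stages$synthgen <- list(status = "ok",
                                   checksum = .checksum(scen))
  env_vars <- names(scen$climate[[1L]]$vars)
  ra <- root_age(scen$tree)

  run_stage("enm", function() {
    occ <- scen$occurrences
    scr <- screen_variables(occ[env_vars])
    ext <- occ[occ$status == "extant", , drop = FALSE]
    ext <- thin_records(ext, config$thin_km)
    occ_t <- rbind(occ[occ$status == "fossil", , drop = FALSE], ext)
    pres <- occ_t[scr$selected]
    present <- scen$climate[[length(scen$climate)]]
    bg <- data.frame(lapply(present$vars[scr$selected], as.vector))
    ev <- evaluate_enm(pres, bg, config$test_fraction,
                       config$enm_replicates, config$reg_multiplier,
                       seed = config$seed + 41L)
    model <- fit_maxent_linear(pres, bg, config$reg_multiplier)
    proj_now <- project_suitability(ev$models, present)
    proj_deep <- project_suitability(ev$models, scen$climate[[1L]])
    list(screening = scr, evaluation = ev, model = model,
         projection_present = proj_now, projection_deep = proj_deep,
         n_thinned = nrow(occ_t))
  })

  run_stage("omi", function() {
    sch16 <- bin_scheme(ra, "sixteen")
    sch5 <- bin_scheme(ra, "five")
    occ <- scen$occurrences
    occ$site <- paste(occ$lon, occ$lat, occ$age_ma)
    list(sixteen = np_nb_through_time(occ, sch16, env_vars),
         five = np_nb_through_time(occ, sch5, env_vars),
         schemes = list(sixteen = sch16, five = sch5))
  })

  run_stage("comparative", function() {
    wl <- scen$traits$wing_length
    niche <- scen$traits$niche
    sig_wl <- list(lambda = pagel_lambda(scen$tree, wl),
                   K = blomberg_k(scen$tree, wl, n_perm = 1000L,
                                  seed = config$seed + 7L))
    sig_niche <- list(lambda = pagel_lambda(scen$tree, niche),
                      K = blomberg_k(scen$tree, niche, n_perm = 1000L,
                                     seed = config$seed + 8L))
    asr_wl <- asr_bm(scen$tree, wl)
    asr_niche <- asr_bm(scen$tree, niche)
    asr_shape <- asr_mk(scen$tree, scen$wing_shape)
    all_wl <- c(wl, asr_wl$node_values)
    all_niche <- c(niche, asr_niche$node_values)
    bins1 <- uniform_bins(ra, 1)
    bins10 <- uniform_bins(ra, 10)
    wl_per_my <- branch_bin_means(scen$tree, all_wl, bins1)
    thr <- niche_thresholds_by_bin(scen$tree, all_niche, bins10)
    models_tab <- if (config$fit_models)
      list(wl = fit_evo_models(scen$tree, wl),
           niche = fit_evo_models(scen$tree, niche)) else NULL
    shape_pgls <- pgls(scen$tree, wl,
                       data.frame(shape = factor(scen$wing_shape),
                                  row.names = names(scen$wing_shape)))
    list(signal = list(wing_length = sig_wl, niche = sig_niche),
         asr = list(wing_length = asr_wl, niche = asr_niche,
                    wing_shape = asr_shape),
         wl_per_my = wl_per_my, thresholds10 = thr, bins10 = bins10,
         ltt = ltt(scen$tree),
         rate_proxy = rate_through_time_proxy(scen$tree, niche,
                                              bin_scheme(ra, "sixteen"),
                                              seed = config$seed + 9L),
         evo_models = models_tab, pgls_wl_shape = shape_pgls)
  })

  run_stage("causal", function() {
    gmat <- vapply(scen$climate, slice_global_mean, numeric(1))
    ages <- vapply(scen$climate, `[[`, numeric(1), "age")
    lt <- results$comparative$ltt
    ltt_at <- vapply(ages, function(a) {
      i <- which(lt$age >= a)
      if (length(i)) lt$lineages[max(i)] else 1L
    }, numeric(1))
    corr <- correlate(gmat, ltt_at, "pearson")
    cc <- tryCatch(
      ccm(gmat, ltt_at,
          ccm_config(E = 2, tau = 1, n_samples = 20L, n_surrogates = 50L,
                     seed = config$seed + 10L)),
      error = function(e) NULL)
    list(gmat = data.frame(age = ages, gmat = gmat, ltt = ltt_at),
         correlation_gmat_ltt = corr, ccm_gmat_ltt = cc)
  })

  run_stage("biogeo", function() {
    fit <- biogeo_fit(scen$tree, scen$tip_ranges, scen$realm_history,
                      schemes = config$biogeo_schemes,
                      jump = config$biogeo_jump)
    best <- fit$models[[fit$best]]
    maps <- bsm(scen$tree, scen$tip_ranges, best, scen$realm_history,
                n_maps = config$n_bsm, seed = config$seed + 12L)
    list(fit = fit, best_model = best, bsm = maps)
  })

  run_stage("dispersal", function() {
    per_my <- results$biogeo$bsm$per_my
    wl_my <- results$comparative$wl_per_my
    m <- min(nrow(per_my), nrow(wl_my))
    series <- data.frame(age_older = per_my$age_older[seq_len(m)],
                         events = per_my$events[seq_len(m)],
                         wl = wl_my$mean[seq_len(m)])
    series <- series[is.finite(series$wl), , drop = FALSE]
    rho <- correlate(series$events, series$wl, "spearman")
    reg <- binarize_series(series$events)
    hm <- fit_hmm(reg, series$wl)
    thr <- simulate_and_regress(hm, n_iter = config$hmm_n_iter,
                                seq_length = nrow(series),
                                seed = config$seed + 14L,
                                raw = data.frame(state = reg,
                                                 wl = series$wl))
    shp <- scen$wing_shape
    gc <- group_contrast(scen$traits$wing_length[shp == "oval"],
                         scen$traits$wing_length[shp == "falcate"])
    list(series = series, spearman = rho, regimes = reg, hmm = hm,
         threshold = thr, shape_contrast = gc)
  })

  run_stage("atmosphere", function() {
    occ <- scen$occurrences
    shp <- scen$wing_shape[occ$taxon]
    hb <- split(occ$MAT, shp)
    field_condition_sets(scen$atmo, hmat_by_shape = hb)
  })

  run_stage("habitability", function() {
    thr <- results$comparative$thresholds10
    bins10 <- results$comparative$bins10
    rmap <- synthetic_realm_map(length(scen$climate[[1L]]$lat),
                                length(scen$climate[[1L]]$lon),
                                length(scen$realm_history$realms))
    node_ranges <- scen$tip_ranges
    ages <- node_ages(scen$tree)
    out <- list()
    for (slice in scen$climate) {
      b <- assign_bin(min(slice$age, ra), bins10)
      if (is.na(b) || !is.finite(thr$min[b])) next
      mask <- project_thresholds(list(MAT = c(thr$min[b], thr$max[b])),
                                 slice)
      occ_realms <- unique(unlist(strsplit(
        unname(scen$tip_ranges[ages[seq_len(ape::Ntip(scen$tree))] >=
                                 slice$age - 10]), "\\+")))
      if (!length(occ_realms) || all(is.na(occ_realms)))
        occ_realms <- scen$realm_history$realms[1L]
      out[[sprintf("%g", slice$age)]] <- partition_accessibility(
        mask, rmap, occ_realms, scen$realm_history, slice$age)
    }
    out
  })

  structure(list(results = results, manifest = manifest, scenario = scen,
                 config = config),
            class = "pipeline_result")
}
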