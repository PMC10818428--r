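#' Run the full ash risk-assessment pipeline
#'
#' Orchestrates the whole analysis on one concentration table:
#' descriptive statistics (Pearson correlations, Ryan-Joiner normality),
#' geochemical characterization (UCC-normalized patterns, NASC-based
#' Ce/Eu anomalies, prospectivity), ecological indices (EF, Igeo, E_r,
#' RI), deterministic health risk for the requested receptors, and an
#' optional Monte Carlo stage. Writes one CSV per stage plus a JSON
#' summary into `out_dir`; the run is a pure function of config and
#' seed.
#'
#' @param config A named list or path to a YAML file with fields:
#'   `input` (concentration CSV; optional if `synthetic` given),
#'   `synthetic` (list of [generator_config()] arguments), `reference`
#'   (UCC set name/path), `nasc` (shale set name/path), `toxicology`
#'   (optional CSV path), `receptors` (subset of child/adult), `groups`
#'   (subset of `"rey"`, `"hm"`; non-empty), `mcs` (list: `enabled`,
#'   `n`), `out_dir`, `seed` (required when synthesis or MCS is
#'   enabled).
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_run_config(config)
  es <- element_set()
  elements <- unlist(list(rey = es$reys, hm = es$hms)[cfg$groups],
                     use.names = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  conc <- stage("load", {
    if (!is.null(cfg$input)) {
      read_concentrations(cfg$input)
    } else {
      gc_args <- cfg$synthetic
      if (is.null(gc_args$seed)) gc_args$seed <- cfg$seed
      generate_concentrations(do.call(generator_config, gc_args))
    }
  })
  write_concentrations(conc, out_path("concentrations.csv"))
  ucc <- stage("references", load_reference_set(cfg$reference))
  nasc <- stage("references", load_reference_set(cfg$nasc))
  tox <- stage("references", load_toxicology(cfg$toxicology))

  present <- intersect(elements, conc_elements(conc))
  if (length(present) == 0) {
    stop("pipeline stage 'load' failed: none of the requested elements ",
         "are present in the input table", call. = FALSE)
  }

  stats_out <- stage("stats", {
    cm <- if (nrow(conc) >= 3) {
      pearson_matrix(conc, intersect(es$reys, present))
    } else NULL
    rj <- if (nrow(conc) >= 4) {
      do.call(rbind, lapply(present, function(el) {
        r <- ryan_joiner(as.data.frame(conc)[[el]])
        data.frame(element = el, statistic = r$statistic,
                   critical_value = r$critical_value, normal = r$normal)
      }))
    } else NULL
    list(correlations = cm, normality = rj)
  })
  if (!is.null(stats_out$correlations)) {
    utils::write.csv(as.data.frame(stats_out$correlations$r),
                     out_path("correlation_matrix.csv"))
  }
  if (!is.null(stats_out$normality)) {
    utils::write.csv(stats_out$normality, out_path("normality.csv"),
                     row.names = FALSE)
  }

  rey_present <- intersect(es$reys, present)
  geo <- stage("geochem", {
    if (length(rey_present) == length(es$reys)) {
      pattern_ucc <- normalize_rey(conc, ucc)
      pattern_nasc <- normalize_rey(conc, nasc)
      list(pattern = pattern_ucc,
           anomalies = rey_anomalies(pattern_nasc),
           prospectivity = rey_prospectivity(conc))
    } else NULL
  })
  if (!is.null(geo)) {
    utils::write.csv(geo$pattern, out_path("ucc_pattern.csv"),
                     row.names = FALSE)
    utils::write.csv(geo$anomalies, out_path("anomalies.csv"),
                     row.names = FALSE)
    utils::write.csv(geo$prospectivity, out_path("prospectivity.csv"),
                     row.names = FALSE)
  }

  eco <- stage("eco_risk", {
    ef <- if (ucc$ef_reference %in% names(conc)) {
      enrichment_factor(conc, ucc, setdiff(present, ucc$ef_reference))
    } else NULL
    list(ef = ef,
         igeo = geoaccumulation(conc, ucc, present),
         risk = ecological_risk(
           conc, ucc, tox,
           intersect(present, tox$element[!is.na(tox$tr)]), es))
  })
  if (!is.null(eco$ef)) {
    utils::write.csv(eco$ef, out_path("eco_ef.csv"), row.names = FALSE)
  }
  utils::write.csv(eco$igeo, out_path("eco_igeo.csv"), row.names = FALSE)
  utils::write.csv(eco$risk$er, out_path("eco_er.csv"), row.names = FALSE)
  utils::write.csv(eco$risk$ri, out_path("eco_ri.csv"), row.names = FALSE)

  profiles <- default_exposure_profiles()[cfg$receptors]
  health <- stage("health_risk", {
    list(hazard = hazard(conc, profiles, tox,
                         intersect(present, tox$element[!is.na(tox$rfd)]), es),
         cancer = cancer_risk(conc, profiles, tox,
                              intersect(present, tox$element), es))
  })
  utils::write.csv(merge(health$hazard$summary, health$cancer$summary,
                         by = c("sample_id", "receptor"), sort = FALSE),
                   out_path("health_risk.csv"), row.names = FALSE)

  mcs_res <- NULL
  if (isTRUE(cfg$mcs$enabled)) {
    mcs_res <- stage("monte_carlo", {
      conc_dists <- conc_dists_from_table(conc, present)
      grid <- expand.grid(receptor = cfg$receptors,
                          endpoint = c("HI", "TCR"),
                          stringsAsFactors = FALSE)
      runs <- lapply(seq_len(nrow(grid)), function(i) {
        run_mcs(conc_dists, tox = tox,
                receptor = grid$receptor[i], endpoint = grid$endpoint[i],
                n = cfg$mcs$n, seed = cfg$seed + i)
      })
      names(runs) <- paste(grid$receptor, grid$endpoint, sep = "_")
      runs
    })
    mcs_tab <- do.call(rbind, lapply(mcs_res, function(r) {
      data.frame(receptor = r$receptor, endpoint = r$endpoint,
                 n = r$n_iterations, mean = r$mean, sd = r$sd,
                 p5 = r$percentiles[["5%"]], p25 = r$percentiles[["25%"]],
                 p50 = r$percentiles[["50%"]], p75 = r$percentiles[["75%"]],
                 p95 = r$percentiles[["95%"]],
                 exceedance_prob = r$exceedance_prob,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(mcs_tab, out_path("mcs_summary.csv"), row.names = FALSE)
  }

  summary <- pipeline_summary(cfg, conc, eco, health, mcs_res)
  jsonlite::write_json(summary, out_path("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, concentrations = conc, stats = stats_out,
                 geochem = geo, eco_risk = eco, health_risk = health,
                 mcs = mcs_res, summary = summary))
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  cfg <- list(
    input = config$input,
    synthetic = config$synthetic,
    reference = config$reference %||% "ucc_rudnick_gao_2003",
    nasc = config$nasc %||% "nasc_gromet_1984",
    toxicology = config$toxicology,
    receptors = config$receptors %||% c("child", "adult"),
    groups = config$groups %||% c("rey", "hm"),
    mcs = utils::modifyList(list(enabled = FALSE, n = 10000),
                            config$mcs %||% list()),
    out_dir = config$out_dir,
    seed = config$seed
  )
  if (is.null(cfg$out_dir)) stop("config error: 'out_dir' is required",
                                 call. = FALSE)
  if (is.null(cfg$input) && is.null(cfg$synthetic)) {
    stop("config error: provide 'input' or a 'synthetic' block",
         call. = FALSE)
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop("config error: input file not found: ", cfg$input, call. = FALSE)
  }
  if (length(cfg$groups) == 0 ||
      !all(cfg$groups %in% c("rey", "hm"))) {
    stop("config error: 'groups' must be a non-empty subset of ",
         "c('rey', 'hm')", call. = FALSE)
  }
  bad_rec <- setdiff(cfg$receptors, c("child", "adult"))
  if (length(cfg$receptors) == 0 || length(bad_rec) > 0) {
    stop("config error: 'receptors' must be a non-empty subset of ",
         "c('child', 'adult')", call. = FALSE)
  }
  if (is.null(cfg$seed) && (isTRUE(cfg$mcs$enabled) || is.null(cfg$input))) {
    stop("config error: 'seed' is required when MCS or synthesis is enabled",
         call. = FALSE)
  }
  cfg
}

pipeline_summary <- function(cfg, conc, eco, health, mcs_res) {
  ri <- eco$risk$ri
  hz <- health$hazard$summary
  cz <- health$cancer$summary
  per_receptor <- lapply(cfg$receptors, function(rec) {
    h <- hz[hz$receptor == rec, ]
    cc <- cz[cz$receptor == rec, ]
    list(
      mean_hi = mean(h$hi),
      mean_hi_rey = mean(h$hi_rey),
      rey_share_hi_pct = risk_share(h$hi_rey, h$hi),
      hi_above_1 = mean(h$hi) > 1,
      mean_tcr = mean(cc$tcr),
      mean_tcr_rey = mean(cc$tcr_rey),
      tcr_above_1e6 = mean(cc$tcr) > 1e-6,
      tcr_above_1e4 = mean(cc$tcr) > 1e-4
    )
  })
  names(per_receptor) <- cfg$receptors
  out <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    n_samples = nrow(conc),
    mean_ri_total = mean(ri$ri_total),
    mean_ri_rey = mean(ri$ri_rey),
    rey_share_ri_pct = risk_share(ri$ri_rey, ri$ri_total),
    health = per_receptor
  )
  if (!is.null(mcs_res)) {
    out$mcs <- lapply(mcs_res, function(r) {
      list(mean = r$mean, p5 = r$percentiles[["5%"]],
           p95 = r$percentiles[["95%"]],
           exceedance_prob = r$exceedance_prob)
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
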