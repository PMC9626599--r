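#' Build a pipeline configuration
#'
#' A declarative description of a full analysis run: either file inputs
#' (monitor CSV + tract CSV) or a [synthetic_scenario()], the analysis
#' year, group pairs, category scheme, MDL strategy, bootstrap sizes and
#' the master seed. CLI-style overrides take precedence over values read
#' from a config file.
#'
#' @param scenario a [synthetic_scenario()], or `NULL` when reading files.
#' @param monitor_csv,tract_csv input paths (ignored when a scenario is
#'   given).
#' @param year analysis year.
#' @param minority_groups minority groups for the segregation stage.
#' @param reference_group reference group.
#' @param rrs_scheme `"fixed_thresholds"` or `"tertiles"`.
#' @param mdl_strategy `"keep"` or `"mdl_over_sqrt2"`.
#' @param modes exposure modes to summarise (`"concentration"`,
#'   `"mass_proportion"`).
#' @param expected_n expected samples per monitor-year.
#' @param n_boot bootstrap replicates for disparity CIs.
#' @param moran_k neighbours for the spatial weights.
#' @param n_perm Moran permutations.
#' @param covariate_sets list of covariate vectors for the association
#'   stage (each passed to [fit_loglog()]).
#' @param strata strata to fit (`"all"`, `"urban"`, `"rural"`).
#' @param seed master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, monitor_csv = NULL,
                            tract_csv = NULL, year = 2019,
                            minority_groups = "NHB", reference_group = "NHW",
                            rrs_scheme = "fixed_thresholds",
                            mdl_strategy = "keep",
                            modes = c("concentration", "mass_proportion"),
                            expected_n = 121, n_boot = 2000,
                            moran_k = 8, n_perm = 999,
                            covariate_sets = list(character()),
                            strata = "all", seed = 1) {
  cfg <- structure(list(
    scenario = scenario, monitor_csv = monitor_csv, tract_csv = tract_csv,
    year = as.integer(year), minority_groups = minority_groups,
    reference_group = reference_group, rrs_scheme = rrs_scheme,
    mdl_strategy = mdl_strategy, modes = modes,
    expected_n = expected_n, n_boot = as.integer(n_boot),
    moran_k = as.integer(moran_k), n_perm = as.integer(n_perm),
    covariate_sets = covariate_sets, strata = strata,
    seed = as.integer(seed)
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @noRd
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$scenario) &&
      (is.null(cfg$monitor_csv) || is.null(cfg$tract_csv))) {
    sm_abort("config needs either a scenario or monitor_csv + tract_csv",
             "segmetals_validation_error")
  }
  if (!cfg$rrs_scheme %in% c("fixed_thresholds", "tertiles")) {
    sm_abort("rrs_scheme must be fixed_thresholds or tertiles",
             "segmetals_validation_error")
  }
  if (!cfg$mdl_strategy %in% c("keep", "mdl_over_sqrt2")) {
    sm_abort("mdl_strategy must be keep or mdl_over_sqrt2",
             "segmetals_validation_error")
  }
  if (!all(cfg$modes %in% c("concentration", "mass_proportion"))) {
    sm_abort("modes must be concentration and/or mass_proportion",
             "segmetals_validation_error")
  }
  if (!is.null(cfg$scenario) && "mass_proportion" %in% cfg$modes &&
      !"PM25" %in% cfg$scenario$components) {
    sm_abort("mass_proportion mode requires PM25 among the scenario components",
             "segmetals_validation_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar keys mirror the [pipeline_config()] arguments; a `scenario` block
#' is passed to [synthetic_scenario()]. Explicit arguments in `...`
#' override file values. The config round-trips losslessly through
#' [write_pipeline_config()].
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    sarg <- raw$scenario
    for (nm in c("alpha_m", "beta_m", "mdl", "region_effects",
                 "group_shares")) {
      if (!is.null(sarg[[nm]])) sarg[[nm]] <- unlist(sarg[[nm]])
    }
    raw$scenario <- do.call(synthetic_scenario, sarg)
  }
  if (!is.null(raw$covariate_sets)) {
    raw$covariate_sets <- lapply(raw$covariate_sets, as.character)
  }
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$scenario)) {
    sc <- unclass(x$scenario)
    sc$alpha_m <- as.list(sc$alpha_m)
    sc$beta_m <- as.list(sc$beta_m)
    sc$mdl <- as.list(sc$mdl)
    sc$region_effects <- as.list(sc$region_effects)
    sc$group_shares <- as.list(sc$group_shares)
    x$scenario <- sc
  }
  x$covariate_sets <- lapply(x$covariate_sets, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — synthetic generation (or CSV ingestion),
#' monitor QC and annual county aggregation, dissimilarity index and
#' segregation categories, population-weighted disparity summaries with
#' bootstrap CIs, log-log association fits, and Moran spatial
#' autocorrelation — writing every intermediate table under `output_dir`
#' plus a `manifest.json` listing file MD5 hashes, seeds and the package
#' version. Re-running with an identical config reproduces identical
#' hashes. INFO-level notices narrate the counts surviving each filter.
#'
#' @param config a `pipeline_config` (or a YAML path).
#' @param output_dir directory for outputs (created if needed).
#' @param quiet suppress progress notices.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message("[segmetals] ", sprintf(...))
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sm_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "segmetals_stage_error")
    })
  }

  # --- inputs ---------------------------------------------------------
  truth <- NULL
  stage("input", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      tracts <- generate_tracts(sc)
      di0 <- di_all_pairs(tracts, config$minority_groups[1],
                          config$reference_group)
      ok <- di0[di0$status == "ok", ]
      gen <- generate_monitor_records(sc, stats::setNames(ok$di, ok$county_id))
      records <- gen$records
      truth <- gen$truth
      emit(tracts, "tracts.csv")
      emit(records, "monitor_records.csv")
      tp <- file.path(output_dir, "truth.json")
      jsonlite::write_json(list(seed = truth$seed, table = truth$table),
                           tp, dataframe = "columns", digits = NA)
      paths[["truth.json"]] <- tp
    } else {
      records <- utils::read.csv(config$monitor_csv,
                                 colClasses = c(county_id = "character"))
      tracts <- utils::read.csv(config$tract_csv,
                                colClasses = c(county_id = "character"))
    }
  })
  note("input: %d daily records, %d tracts, %d counties", nrow(records),
       nrow(tracts), length(unique(tracts$county_id)))

  # --- monitor QC -----------------------------------------------------
  stage("monitor_qc", {
    valid <- filter_valid(records)
    note("qc: %d of %d records valid", nrow(valid), nrow(records))
    valid <- impute_below_mdl(valid, config$mdl_strategy)
    mm <- annual_monitor_mean(valid, config$year,
                              expected_n = config$expected_n)
    note("qc: %d of %d monitor-component-years pass the completeness filter",
         sum(mm$retained), nrow(mm))
    exposure <- county_annual_exposure(mm)
    emit(mm, "monitor_annual_means.csv")
    emit(exposure, "annual_county_exposure.csv")
    exposure <- exposure  # keep in frame
  })

  # --- segregation ----------------------------------------------------
  stage("segregation", {
    di <- di_all_pairs(tracts, config$minority_groups, config$reference_group)
    excl <- di[di$status != "ok", ]
    note("segregation: %d county-pair DIs ok, %d excluded/undefined",
         sum(di$status == "ok"), nrow(excl))
    emit(di, "dissimilarity.csv")
    writeLines(
      if (nrow(excl)) sprintf("%s %s: %s", excl$county_id,
                              excl$minority_group, excl$reason)
      else character(),
      file.path(output_dir, "exclusions.log")
    )
    paths[["exclusions.log"]] <- file.path(output_dir, "exclusions.log")
    di_main <- di[di$status == "ok" &
                    di$minority_group == config$minority_groups[1], ]
    di_main$rrs_category <- as.character(
      categorize_rrs(di_main$di, config$rrs_scheme,
                     reference_dis = di_main$di)
    )
    di_main <- di_main  # keep in frame
  })

  # --- exposure disparity ---------------------------------------------
  stage("exposure_disparity", {
    pop <- stats::aggregate(list(population = tracts$total),
                            by = list(county_id = tracts$county_id), FUN = sum)
    base <- merge(merge(exposure, di_main[, c("county_id", "di",
                                              "rrs_category")],
                        by = "county_id"),
                  pop, by = "county_id")
    comps <- setdiff(unique(base$component), character(0))
    rows <- list()
    for (mode in config$modes) {
      for (cm in comps) {
        if (mode == "mass_proportion" && cm == "PM25") next
        d <- base[base$component == cm, , drop = FALSE]
        d$x <- if (mode == "concentration") d$mean_concentration else
          d$mass_proportion
        d <- d[!is.na(d$x), , drop = FALSE]
        if (length(unique(d$rrs_category)) < 2) next
        rows[[paste(cm, mode)]] <- disparity_summary(
          d, component = cm, year = config$year, mode = mode,
          n_boot = config$n_boot,
          seed = stream_seed(config$seed, "disparity", cm, mode)
        )
      }
    }
    disparity <- dplyr::bind_rows(rows)
    note("disparity: %d component x mode summaries", nrow(disparity))
    emit(disparity, "disparity.csv")
    jsonlite::write_json(disparity, file.path(output_dir, "disparity.json"),
                         dataframe = "rows", digits = NA)
    paths[["disparity.json"]] <- file.path(output_dir, "disparity.json")
    base <- base  # keep in frame
  })

  # --- association ----------------------------------------------------
  stage("association", {
    rows <- list()
    for (cm in unique(base$component)) {
      d <- base[base$component == cm, , drop = FALSE]
      d$concentration <- d$mean_concentration
      for (st in config$strata) {
        for (cvs in config$covariate_sets) {
          if ("region_fixed_effects" %in% cvs && !"region" %in% names(d)) next
          key <- paste(cm, st, paste(cvs, collapse = "+"))
          rows[[key]] <- tryCatch(
            fit_loglog(d, covariates = cvs, stratum = st, component = cm),
            segmetals_insufficient_data = function(e) NULL
          )
        }
      }
    }
    assoc <- dplyr::bind_rows(rows)
    note("association: %d fits", nrow(assoc))
    emit(assoc, "association.csv")
    assoc <- assoc  # keep in frame
  })

  # --- spatial --------------------------------------------------------
  stage("spatial_stats", {
    sites <- unique(records[records$component == records$component[1],
                            c("monitor_id", "latitude", "longitude")])
    moran <- list(); local_rows <- list()
    if (nrow(sites) > config$moran_k) {
      wts <- build_knn_weights(sites, k = config$moran_k,
                               site_ids = sites$monitor_id)
      mm2 <- utils::read.csv(paths[["monitor_annual_means.csv"]])
      for (cm in unique(base$component)) {
        v <- mm2[mm2$component == cm & mm2$retained, ]
        v <- v[match(sites$monitor_id, v$monitor_id), ]
        if (any(is.na(v$mean_concentration))) next
        g <- moran_global(v$mean_concentration, wts,
                          n_perm = config$n_perm,
                          seed = stream_seed(config$seed, "moran", cm))
        moran[[cm]] <- list(global_i = g$global_i, expected_i = g$expected_i,
                            p_permutation = g$p_permutation,
                            n_permutations = g$n_permutations)
        loc <- moran_local(v$mean_concentration, wts,
                           n_perm = config$n_perm,
                           seed = stream_seed(config$seed, "moran_local", cm))
        loc$component <- cm
        local_rows[[cm]] <- loc
      }
    }
    jsonlite::write_json(moran, file.path(output_dir, "moran.json"),
                         auto_unbox = TRUE, digits = NA)
    paths[["moran.json"]] <- file.path(output_dir, "moran.json")
    if (length(local_rows)) emit(dplyr::bind_rows(local_rows),
                                 "local_moran.csv")
    note("spatial: global Moran's I for %d components", length(moran))
  })

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "segmetals",
    version = as.character(utils::packageVersion("segmetals")),
    seed = config$seed,
    year = config$year,
    rrs_scheme = config$rrs_scheme,
    mdl_strategy = config$mdl_strategy,
    files = lapply(stats::setNames(nm = sort(names(paths))), function(nm) {
      list(path = nm, md5 = unname(tools::md5sum(paths[[nm]])))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("done: %d files, manifest written", length(paths))
  invisible(manifest)
}
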