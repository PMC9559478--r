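#' Write a trait or meteorology table to CSV
#'
#' Plain CSV, one header row, UTF-8, '.' decimal separator. A leading
#' comment line records the root seed and a configuration tag so every
#' artifact can be traced back to the run that produced it.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param seed integer root seed to record (optional).
#' @param tag short configuration tag to record (optional).
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(x, path, seed = NULL, tag = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# grazemilk seed=%s config=%s",
                     seed %||% "NA", tag %||% "NA"), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait table from CSV
#'
#' Reads a CSV written by [write_trait_csv()] (comment lines starting
#' with `#` are skipped) and validates that the identifier columns and
#' all trait columns of the schema are present; missing columns are
#' reported by name. Rows whose identifier or trait fields fail to parse
#' as the expected type are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param schema trait schema whose `name` column defines the required
#'   trait columns (default [default_trait_schema()]).
#' @return data.frame of typed records (possibly zero rows, with a
#'   warning).
#' @export
read_trait_table <- function(path, schema = default_trait_schema()) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("farm_id", "year", "month", trait_names(schema))
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("trait table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0L) {
    warning("trait table `", path, "` has a header but no records",
            call. = FALSE)
    return(x)
  }
  num_cols <- c("year", "month", trait_names(schema))
  bad <- rep(FALSE, nrow(x))
  for (cc in num_cols) {
    v <- x[[cc]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- bad | (is.na(parsed) & !is.na(v))
      x[[cc]] <- parsed
    }
  }
  bad <- bad | x$month < 1 | x$month > 12 | is.na(x$month)
  if (any(bad)) {
    # +2: one header comment line and one header line precede row 1
    warning("rejecting unparseable row(s) at line(s): ",
            paste(which(bad) + 2L, collapse = ", "), call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  x$month <- as.integer(x$month)
  x$year <- as.integer(x$year)
  x
}

#' Assemble a pipeline configuration
#'
#' Bundles and validates the parameters of the end-to-end run:
#' simulation block, labeling schemes, model block (component cap,
#' folds), and typology block (K, fat threshold, group sizes).
#'
#' @param n_farms,n_years simulated cohort size.
#' @param archetype_mix farm archetype proportions (see
#'   [farm_archetypes()]).
#' @param seed integer root seed for every stage.
#' @param schemes labeling scheme ids to fit (default `1:3`).
#' @param calibration_fraction farm share calibrated (default 0.30).
#' @param max_components latent-variable cap (default 30).
#' @param folds CV folds (default 10).
#' @param K typology cluster count (default 12).
#' @param fat_threshold skimmed-cluster fat cutoff, g/100 g (default 1).
#' @param n_intensive,n_extensive cluster counts for the automatic
#'   intensity-group mapping (default 1 each).
#' @param schema trait schema (default [default_trait_schema()]).
#' @param output_dir directory for CSV artifacts, or `NULL` for none.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_farms = 50, n_years = 3,
                            archetype_mix = c(intensive = 0.30,
                                              intermediate = 0.43,
                                              extensive = 0.25,
                                              skimmed = 0.02),
                            seed = 1, schemes = 1:3,
                            calibration_fraction = 0.30,
                            max_components = 30, folds = 10,
                            K = 12, fat_threshold = 1,
                            n_intensive = 1, n_extensive = 1,
                            schema = default_trait_schema(),
                            output_dir = NULL) {
  n_farms <- check_count(n_farms, "n_farms", min = 2L)
  n_years <- check_count(n_years, "n_years")
  validate_trait_schema(schema)
  if (!all(schemes %in% 1:3)) stop("`schemes` must be within 1:3",
                                   call. = FALSE)
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("`archetype_mix` must sum to 1", call. = FALSE)
  }
  structure(
    list(simulation = list(n_farms = n_farms, n_years = n_years,
                           archetype_mix = archetype_mix, seed = seed,
                           schema = schema),
         labeling = list(schemes = as.integer(schemes),
                         calibration_fraction = calibration_fraction),
         model = list(max_components = min(max_components, 30L),
                      folds = folds),
         typology = list(K = K, fat_threshold = fat_threshold,
                         n_intensive = n_intensive,
                         n_extensive = n_extensive),
         output_dir = output_dir),
    class = "pipeline_config")
}

#' Run the full grazing-detection pipeline
#'
#' Executes, in order: meteorology and trait simulation, month-derived
#' labeling per scheme, farm-level calibration/validation split,
#' CV-based latent-variable selection and PLS-DA fitting per scheme,
#' cross-validated and month-restricted external validation metrics,
#' VIP scores, validation-set monthly probability curves, inter-model
#' probability correlations, probability-meteorology correlations, and
#' Ward.D2 typology clustering with skimmed-cluster flagging and the
#' per-farm intensity index. One log line per stage records record
#' counts so the filtering steps can be audited. Reruns with the same
#' configuration are identical.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress stage log messages (default `FALSE`).
#' @return list of class `pipeline_report` with elements `config`,
#'   `records`, `meteo`, `split`, per-scheme `models` (each with the
#'   fitted model, `A`, `cv`, `external`, `vip`), `curves` (per scheme),
#'   `intermodel_correlation`, `meteo_correlation` (scheme 1 curve),
#'   `typology` (solution, flagged clusters, group map, intensity
#'   index), and `log` (character vector of stage lines).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  sim <- config$simulation
  stage <- "simulate"
  report <- tryCatch({
    meteo <- simulate_meteo(sim$n_years, seed = sim$seed)
    records <- generate_dataset(sim$n_farms, sim$n_years,
                                archetype_mix = sim$archetype_mix,
                                schema = sim$schema, seed = sim$seed,
                                meteo = meteo)
    say("simulate: %d farms x %d years -> %d records",
        sim$n_farms, sim$n_years, nrow(records))

    stage <- "split"
    split <- split_by_farm(records, config$labeling$calibration_fraction,
                           seed = sim$seed)
    say("split: %d calibration farms (%d records), %d validation farms (%d records)",
        length(split$calibration_farms), nrow(split$calibration),
        length(split$validation_farms), nrow(split$validation))

    traits <- trait_names(sim$schema)
    models <- list()
    curves <- list()
    probs <- list()
    for (s in config$labeling$schemes) {
      stage <- paste0("train scheme ", s)
      cal <- build_modeling_subset(label_records(split$calibration, s))
      say("label scheme %d: %d of %d calibration records retained",
          s, nrow(cal), nrow(split$calibration))
      cv <- cross_validate_plsda(cal[, traits], cal$y,
                                 max_A = config$model$max_components,
                                 k = config$model$folds, seed = sim$seed)
      fit <- fit_pls(cal[, traits], cal$y, A = cv$A)
      stage <- paste0("validate scheme ", s)
      ext <- external_validation_accuracy(fit, split$validation)
      prob <- predict_grass_probability(fit, split$validation)
      curves[[paste0("GRASS", s)]] <-
        monthly_probability_curve(split$validation, prob)
      probs[[paste0("GRASS", s)]] <- prob
      models[[paste0("GRASS", s)]] <-
        list(model = fit, A = cv$A, cv = cv, external = ext,
             vip = compute_vip(fit))
      say("scheme %d: A = %d, CV AUC = %.3f, external accuracy = %.3f (n = %d)",
          s, cv$A, cv$mean[["auc"]], ext$accuracy, ext$n_used)
    }

    stage <- "intermodel correlation"
    intercor <- if (length(probs) >= 2) {
      intermodel_probability_correlation(probs)
    } else {
      NULL
    }

    stage <- "meteo correlation"
    meteo_cor <- correlate_with_meteo(curves[[1]], meteo)
    say("meteo: r(THI) = %.2f, r(cloud) = %.2f",
        meteo_cor[["thi"]], meteo_cor[["cloud"]])

    stage <- "typology"
    first <- models[[1]]$model
    all_prob <- predict_grass_probability(first, records)
    profiles <- suppressMessages(build_profiles(records, all_prob))
    say("typology: %d farm-year profiles (%d excluded for coverage)",
        nrow(profiles), attr(profiles, "n_excluded"))
    K <- min(config$typology$K, nrow(profiles))
    tree <- ward_d2_cluster(profiles)
    solution <- cut_and_summarize(tree, K, records)
    flagged <- flag_skimmed(solution, config$typology$fat_threshold)
    group_map <- assign_cluster_groups(
      solution, exclude = flagged,
      n_intensive = config$typology$n_intensive,
      n_extensive = config$typology$n_extensive)
    index <- intensity_index(solution, group_map, exclude = flagged)
    say("typology: K = %d, flagged skimmed cluster(s): %s",
        K, if (length(flagged)) paste(flagged, collapse = ", ") else "none")

    list(config = config, records = records, meteo = meteo, split = split,
         models = models, curves = curves,
         intermodel_correlation = intercor,
         meteo_correlation = meteo_cor,
         typology = list(solution = solution, flagged = flagged,
                         group_map = group_map, intensity = index),
         log = log)
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("farms%d_years%d", sim$n_farms, sim$n_years)
    write_trait_csv(report$records, file.path(config$output_dir, "records.csv"),
                    seed = sim$seed, tag = tag)
    write_trait_csv(report$meteo, file.path(config$output_dir, "meteo.csv"),
                    seed = sim$seed, tag = tag)
    for (nm in names(report$curves)) {
      write_trait_csv(report$curves[[nm]],
                      file.path(config$output_dir,
                                paste0("curve_", nm, ".csv")),
                      seed = sim$seed, tag = tag)
    }
    write_trait_csv(report$typology$solution$assignments,
                    file.path(config$output_dir, "typology_assignments.csv"),
                    seed = sim$seed, tag = tag)
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("grazemilk pipeline report\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
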