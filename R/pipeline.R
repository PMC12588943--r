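# Single-command pipeline: load or simulate a study, compute DSC matrices,
# summaries, heatmaps and statistics, and emit a reproducible report bundle.

#' Build a pipeline run configuration
#'
#' Exactly one input mode must be set: `study_config` (path to a study
#' JSON, see [load_study()]) or `scenario` (a [scenario_spec()] /
#' `"canonical"` for the default synthetic scenario).
#'
#' @param study_config path to a study JSON, or `NULL`.
#' @param scenario a [scenario_spec()], the string `"canonical"`, or `NULL`.
#' @param empty_policy both-empty DSC convention (see [dsc()]).
#' @param bands optional [band_spec()]; default derives the percentage-rule
#'   bands from the observer count.
#' @param adjust Dunn adjustment method.
#' @param alpha overlay opacity.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed used when `scenario = "canonical"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(study_config = NULL, scenario = NULL,
                       empty_policy = "agree", bands = NULL,
                       adjust = "bonferroni", alpha = 0.5,
                       out_dir = "segagree_report", seed = 20251023) {
  structure(list(study_config = study_config, scenario = scenario,
                 empty_policy = empty_policy, bands = bands,
                 adjust = adjust, alpha = alpha,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Returns diagnostics instead of throwing: an empty character vector
#' means the config is executable; each diagnostic names the offending
#' field and the violation.
#'
#' @param config a [run_config()].
#' @return Character vector of diagnostics (possibly empty).
#' @export
validate_config <- function(config) {
  diags <- character(0)
  modes <- c(!is.null(config$study_config), !is.null(config$scenario))
  if (sum(modes) == 0)
    diags <- c(diags, "input: neither study_config nor scenario is set")
  if (sum(modes) == 2)
    diags <- c(diags, "input: both study_config and scenario are set; choose one")
  if (!is.null(config$study_config) && !file.exists(config$study_config))
    diags <- c(diags, paste0("study_config: file does not exist: ",
                             config$study_config))
  if (!config$empty_policy %in% c("agree", "zero", "exclude"))
    diags <- c(diags, paste0("empty_policy: unknown value '",
                             config$empty_policy, "'"))
  if (!config$adjust %in% c("bonferroni", "holm", "none"))
    diags <- c(diags, paste0("adjust: unknown value '", config$adjust, "'"))
  if (!is.numeric(config$alpha) || config$alpha < 0 || config$alpha > 1)
    diags <- c(diags, "alpha: must be in [0, 1]")
  if (!is.null(config$bands)) {
    ok <- tryCatch({
      stopifnot(inherits(config$bands, "band_spec")); TRUE
    }, error = function(e) FALSE)
    if (!ok) diags <- c(diags, "bands: not a valid band_spec")
  }
  if (!is.null(config$scenario) && !identical(config$scenario, "canonical") &&
      !inherits(config$scenario, "scenario_spec"))
    diags <- c(diags, "scenario: must be 'canonical' or a scenario_spec")
  diags
}

#' Run the full agreement pipeline
#'
#' Loads (or simulates) the study, computes the per-image pairwise DSC
#' matrices, the long-form records, group summaries by tumour type, stage,
#' their crossing and experience pairing, the pixel-agreement heatmaps
#' with banded overlays, and the statistical battery; writes everything
#' plus a run manifest to `config$out_dir`. Any stage failure aborts with
#' the stage named and removes partial outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage logging.
#' @return Invisibly, a list: `dataset`, `matrices`, `records`,
#'   `summaries`, `maps`, `stats`, `files` (paths written).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  diags <- validate_config(config)
  if (length(diags))
    stop("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(file.path(out_dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "overlays"), recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  res <- tryCatch({
    dataset <- if (!is.null(config$study_config)) {
      say("stage load: reading study %s", config$study_config)
      load_study(config$study_config)
    } else {
      spec <- if (identical(config$scenario, "canonical"))
        canonical_scenario(master_seed = config$seed) else config$scenario
      say("stage load: simulating scenario (seed %d)", spec$master_seed)
      simulate_study(spec)
    }
    design <- dataset$design
    n_obs <- nrow(design$observers)
    say("stage load: %d images x %d observers, %d masks",
        nrow(design$images), n_obs, length(dataset$masks))

    stage <- "pairwise"
    matrices <- lapply(design$images$image_id, function(img)
      pairwise_dsc_matrix(image_masks(dataset, img), config$empty_policy))
    names(matrices) <- design$images$image_id
    per_img <- n_obs * (n_obs - 1) / 2
    say("stage pairwise: %d DSCs per image, %d images", per_img,
        length(matrices))

    stage <- "records"
    records <- flatten_records(matrices, design)
    say("stage records: %d pairwise records", nrow(records))

    stage <- "summaries"
    summaries <- list(
      tumour_type = group_summary(records, "tumour_type"),
      stage = group_summary(records, "stage"),
      tumour_type_x_stage = group_summary(records, "tumour_type_x_stage"),
      experience_pairing = group_summary(records, "experience_pairing", design))

    stage <- "heatmaps"
    bands <- if (is.null(config$bands)) band_spec(n_obs) else config$bands
    maps <- list()
    files <- character(0)
    for (img in design$images$image_id) {
      amap <- aggregate_map(image_masks(dataset, img))
      banded <- classify_pixels(amap, bands)
      maps[[img]] <- list(counts = amap, bands = banded)
      f <- file.path(out_dir, "matrices", paste0(img, "_dsc.csv"))
      write_matrix_csv(matrices[[img]], f)
      files <- c(files, f)
      base <- dataset$base_images[[img]]
      if (!is.null(base)) {
        ov <- render_overlay(banded, base, alpha = config$alpha)
        f <- file.path(out_dir, "overlays", paste0(img, "_overlay.png"))
        write_overlay_png(ov, f)
        files <- c(files, f)
      }
    }
    say("stage heatmaps: %d maps, bands white %d-%d / red %d-%d / green %d-%d",
        length(maps), bands$white[1], bands$white[2], bands$red[1],
        bands$red[2], bands$green[1], bands$green[2])

    stage <- "stats"
    stats_res <- stats_battery(records, dataset, config$adjust)

    stage <- "write"
    f_records <- file.path(out_dir, "records.csv")
    write_records_csv(records, f_records)
    f_summ <- file.path(out_dir, "group_summaries.csv")
    summ_all <- do.call(rbind, lapply(names(summaries), function(nm) {
      s <- summaries[[nm]]
      data.frame(factor = nm, s, stringsAsFactors = FALSE)
    }))
    summ_all$mean_dsc <- sprintf("%.6f", summ_all$mean_dsc)
    summ_all$sd_dsc <- sprintf("%.6f", summ_all$sd_dsc)
    utils::write.csv(summ_all, f_summ, row.names = FALSE, quote = FALSE)
    f_stats <- file.path(out_dir, "stats.csv")
    utils::write.csv(stats_res$table, f_stats, row.names = FALSE)
    f_manifest <- file.path(out_dir, "manifest.json")
    manifest <- list(
      package = "segagree",
      version = as.character(utils::packageVersion("segagree")),
      input_mode = if (!is.null(config$study_config)) "study_config" else "scenario",
      study_config = config$study_config,
      seed = config$seed,
      empty_policy = config$empty_policy,
      bands = list(white = bands$white, red = bands$red, green = bands$green,
                   n_observers = bands$n_observers),
      dunn_adjustment = config$adjust,
      anova_ss_type = "II",
      sd_definition = "sample (n-1)",
      overlay_alpha = config$alpha,
      n_images = nrow(design$images),
      n_observers = n_obs,
      n_records = nrow(records))
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    files <- c(files, f_records, f_summ, f_stats, f_manifest)
    say("stage write: %d files under %s", length(files), out_dir)
    list(dataset = dataset, matrices = matrices, records = records,
         summaries = summaries, maps = maps, stats = stats_res,
         files = files)
  }, error = function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
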