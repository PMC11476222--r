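#' Pipeline configuration
#'
#' Collects everything a profiling run needs: the input run(s), the
#' target list, the extraction tolerance and the post-search filter
#' thresholds. Fully serializable, so the effective configuration can be
#' written next to the outputs for provenance.
#'
#' @param mzml A [spectrum_run()], an mzML path, or a list/vector of
#'   either (one element per replicate).
#' @param targets A target tibble (see [enumerate_targets()]) or a path
#'   to a target DB CSV.
#' @param tolerance_ppm Extraction/matching tolerance in ppm (default 10).
#' @param rt_min,area_min,score_max Filter thresholds (defaults 2 min,
#'   1000, 0.5).
#' @param min_height Minimum peak apex intensity for detection.
#' @param output_dir Optional directory; when given, every stage artifact
#'   (target DB, areas, filtered table, profile, provenance JSON) is
#'   written there.
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mzml, targets, tolerance_ppm = 10, rt_min = 2,
                            area_min = 1000, score_max = 0.5,
                            min_height = 0, output_dir = NULL,
                            seed = NULL) {
  structure(list(mzml = mzml, targets = targets,
                 tolerance_ppm = tolerance_ppm, rt_min = rt_min,
                 area_min = area_min, score_max = score_max,
                 min_height = min_height, output_dir = output_dir,
                 seed = seed),
            class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  runs <- cfg$mzml
  if (inherits(runs, "spectrum_run")) runs <- list(runs)
  if (is.character(runs)) runs <- as.list(runs)
  if (!is.list(runs) || length(runs) == 0) {
    abort("config error: `mzml` must name at least one run")
  }
  for (r in runs) {
    if (is.character(r) && !file.exists(r)) {
      abort(paste0("config error: mzML file not found: ", r))
    }
    if (!is.character(r) && !inherits(r, "spectrum_run")) {
      abort("config error: `mzml` entries must be paths or spectrum_run objects")
    }
  }
  if (is.character(cfg$targets) && !file.exists(cfg$targets)) {
    abort(paste0("config error: target DB not found: ", cfg$targets))
  }
  if (cfg$tolerance_ppm <= 0) {
    abort("config error: `tolerance_ppm` must be positive")
  }
  runs
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the profiling pipeline
#'
#' Orchestrates target loading, per-replicate chromatogram extraction
#' and integration, post-search filtering and relative-abundance
#' summarization. Deterministic given the configuration and inputs.
#' Replicates are joined on species; there is no cross-run retention
#' time alignment.
#'
#' @param cfg A [pipeline_config()].
#' @return A list with `targets`, `areas` (per replicate quantitation),
#'   `filtered` (rows passing the filters, report attached), `profile`
#'   (percent relative abundance summary) and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  runs <- validate_pipeline_config(cfg)
  targets <- run_stage("targets", {
    if (is.character(cfg$targets)) read_target_db(cfg$targets) else
      as_tibble(cfg$targets)
  })
  areas <- run_stage("extract", {
    purrr::imap(runs, function(r, i) {
      run <- if (is.character(r)) read_mzml(r) else r
      quantify_targets(run, targets, tolerance_ppm = cfg$tolerance_ppm,
                       min_height = cfg$min_height) |>
        mutate(sample = if (is.character(r)) basename(r) else
          paste0("run", i),
          replicate = as.integer(i), .before = 1)
    }) |> bind_rows()
  })
  filtered <- run_stage("filter", {
    apply_filters(areas |> rename(rt = "apex_rt"),
                  rt_min = cfg$rt_min, area_min = cfg$area_min,
                  score_max = cfg$score_max)
  })
  profile <- run_stage("profile", {
    relative_abundance(filtered |> rename(species = "species_name"))
  })
  out <- list(targets = targets, areas = areas, filtered = filtered,
              profile = profile$profile, totals = profile$totals,
              config = cfg)
  if (!is.null(cfg$output_dir)) {
    run_stage("write", {
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      write_target_db(targets, file.path(cfg$output_dir, "targets.csv"))
      readr::write_tsv(areas, file.path(cfg$output_dir, "areas.tsv"))
      readr::write_tsv(filtered, file.path(cfg$output_dir, "filtered.tsv"))
      readr::write_tsv(out$profile, file.path(cfg$output_dir, "profile.tsv"))
      prov <- list(
        package = "gangliotk",
        version = as.character(utils::packageVersion("gangliotk")),
        timestamp = format(Sys.time(), tz = "UTC"),
        config = cfg[c("tolerance_ppm", "rt_min", "area_min", "score_max",
                       "min_height", "seed")],
        n_runs = length(runs), n_targets = nrow(targets),
        filter_report = filter_report(filtered)
      )
      jsonlite::write_json(prov,
                           file.path(cfg$output_dir, "provenance.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  out
}
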