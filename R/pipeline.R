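#' Configure an end-to-end pipeline run
#'
#' Bundles the per-stage configurations (phantom, ASL constants, margins,
#' prescription, dose model, OAR limits) with the rCBF threshold, the seed
#' and an optional output directory.  The scenario preset sets the
#' prescription when none is given: 60 Gy baseline with 20% escalation for
#' `"unilateral"`, 54 Gy with 10% for `"midline"`.
#'
#' @param scenario `"unilateral"` (default) or `"midline"`; forwarded to
#'   [phantom_config()] when `phantom` is not supplied.
#' @param phantom a [phantom_config()].
#' @param asl an [asl_parameters()].
#' @param margins a [margin_policy()].
#' @param rx a [plan_prescription()]; scenario default when `NULL`.
#' @param model a [dose_model_config()].
#' @param constraints an [oar_constraint_table()].
#' @param threshold rCBF segmentation threshold (default 1.4).
#' @param output_dir directory for NIfTI/CSV/JSON artifacts, or `NULL` (no
#'   files written).
#' @param seed integer seed driving all randomness (overrides the phantom
#'   config's seed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = c("unilateral", "midline"),
                       phantom = NULL, asl = asl_parameters(),
                       margins = margin_policy(), rx = NULL,
                       model = dose_model_config(),
                       constraints = oar_constraint_table(),
                       threshold = 1.4, output_dir = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(phantom)) phantom <- phantom_config(scenario = scenario,
                                                  seed = seed)
  else {
    scenario <- phantom$scenario
    phantom$seed <- as.integer(seed)
  }
  if (is.null(rx)) {
    rx <- if (scenario == "unilateral") {
      plan_prescription(baseline_dose_gy = 60, escalation_fraction = 0.20)
    } else {
      plan_prescription(baseline_dose_gy = 54, escalation_fraction = 0.10)
    }
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  structure(list(scenario = scenario, phantom = phantom, asl = asl,
                 margins = margins, rx = rx, model = model,
                 constraints = constraints, threshold = threshold,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Reads a flat configuration file whose top-level keys (`scenario`,
#' `phantom`, `asl`, `margins`, `rx`, `model`, `threshold`, `output_dir`,
#' `seed`) are passed to the corresponding constructors; omitted keys take
#' the documented defaults.  CLI-style overrides can be layered with the
#' `...` arguments, which take precedence over the file.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param ... overrides forwarded to [run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(cfg$scenario)) args$scenario <- cfg$scenario
  if (!is.null(cfg$phantom))
    args$phantom <- do.call(phantom_config,
                            c(cfg$phantom,
                              if (is.null(cfg$phantom$scenario) &&
                                  !is.null(cfg$scenario))
                                list(scenario = cfg$scenario)))
  if (!is.null(cfg$asl)) args$asl <- do.call(asl_parameters, cfg$asl)
  if (!is.null(cfg$margins)) args$margins <- do.call(margin_policy, cfg$margins)
  if (!is.null(cfg$rx)) args$rx <- do.call(plan_prescription, cfg$rx)
  if (!is.null(cfg$model)) args$model <- do.call(dose_model_config, cfg$model)
  for (k in c("threshold", "output_dir", "seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one synthetic patient: phantom generation, CBF
#' quantification, rCBF reference and map, hyper-perfusion segmentation,
#' target-volume cascade, simulation of the three plan variants, and plan
#' evaluation.  When `config$output_dir` is set, all volumes and masks are
#' written as NIfTI, the report tables as CSV, and a manifest (file
#' inventory with MD5 checksums, seed, package version, per-stage wall
#' times, warnings) as JSON.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result`: `phantom`, `cbf`, `rcbf`,
#'   `reference`, `structures` (full cascade plus OARs), `doses`
#'   (plan1--plan3), `report` (a [evaluate_plans()] result),
#'   `ptv_asl_ratio`, `warnings`, and `manifest` (when files were written).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(force(expr), warning = function(w) {
      note(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  phantom <- stage("phantom", generate_phantom(config$phantom, config$asl))

  cbf <- stage("cbf", compute_cbf(phantom$asl_control, phantom$asl_label,
                                  phantom$asl_pd, config$asl))
  reference <- stage("reference", mirror_reference(
    phantom$structure_masks$gtv, phantom$tissue_masks$gray,
    scenario = config$scenario,
    insula = phantom$structure_masks$insula_ref))
  rcbf <- relative_cbf(cbf, reference)

  gtv_asl <- stage("segment", segment_hyperperfusion(
    rcbf, phantom$structure_masks$gtv, threshold = config$threshold))

  cascade <- stage("structures", build_structure_cascade(
    phantom$structure_masks$gtv, gtv_asl, policy = config$margins,
    clip = phantom$tissue_masks$body))
  structures <- c(cascade, phantom$structure_masks[
    setdiff(names(phantom$structure_masks), c("gtv", "core"))])

  doses <- list()
  for (variant in c("plan1", "plan2", "plan3"))
    doses[[variant]] <- stage(variant, simulate_plan(
      structures, config$rx, config$model, variant))

  report <- stage("evaluate", evaluate_plans(
    doses, structures, config$rx, config$constraints))

  result <- structure(list(
    phantom = phantom, cbf = cbf, rcbf = rcbf, reference = reference,
    structures = structures, doses = doses, report = report,
    ptv_asl_ratio = attr(cascade, "ptv_asl_ratio"),
    warnings = warnings_log, timings = timings, config = config),
    class = "pipeline_result")

  if (!is.null(config$output_dir))
    result$manifest <- stage("write", write_pipeline_outputs(result,
                                                             config$output_dir))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s scenario, seed %d\n",
              x$config$scenario, x$config$seed))
  cat(sprintf("  PTV %.1f cc, PTV-ASL %.1f cc (ratio %.1f%%)\n",
              volume_cc(x$structures$ptv), volume_cc(x$structures$ptv_asl),
              100 * x$ptv_asl_ratio))
  print(x$report)
  invisible(x)
}

# write all artifacts and return the manifest (also written as JSON)
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  add(write_phantom(result$phantom, dir, id = "phantom"))
  wv <- function(grid, nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz")); write_volume(grid, p); add(p)
  }
  wv(result$cbf, "cbf")
  wv(result$rcbf, "rcbf")
  for (v in names(result$doses)) wv(result$doses[[v]], paste0("dose_", v))
  for (s in c("gtv_asl", "gtv_sub", "ctv", "ptv", "ptv_asl", "ptv_sub")) {
    p <- file.path(dir, paste0(s, ".nii.gz"))
    write_mask(result$structures[[s]], p); add(p)
  }

  tables <- list(metrics = result$report$metrics,
                 plan_summary = result$report$plan_summary,
                 percent_change = result$report$percent_change,
                 constraints = result$report$constraints)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    add(p)
  }

  structure_volumes <- lapply(
    result$structures[sapply(result$structures, inherits, "structure_mask")],
    volume_cc)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aslboost")),
    scenario = result$config$scenario,
    seed = result$config$seed,
    threshold = result$config$threshold,
    ptv_asl_ratio = result$ptv_asl_ratio,
    structure_volumes_cc = structure_volumes,
    normalization = lapply(result$doses, attr, "normalization"),
    cap_iterations = lapply(result$doses, attr, "cap_iterations"),
    stage_seconds = as.list(result$timings),
    warnings = result$warnings,
    files = data.frame(path = basename(unlist(paths)),
                       md5 = unname(tools::md5sum(unlist(paths))),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
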