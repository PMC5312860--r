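# End-to-end orchestration: generate -> classify -> contacts -> stats ->
# fit, with every stage's table written to the working directory and a
# provenance record sufficient to reproduce the run bit-exactly.

#' Pipeline configuration
#'
#' @param workdir directory for all stage artifacts.
#' @param tier `"bernoulli"` or `"langevin"` (the Langevin tier runs the
#'   classifier and contact stages; the Bernoulli tier skips straight from
#'   outcomes to statistics).
#' @param design a `design_grid`.
#' @param geometry a `pore_geometry`.
#' @param generator a `generator_config`.
#' @param classification a `classification_config` (defaults to one built
#'   from `geometry`).
#' @param contact a `contact_config`.
#' @param truth_model Bernoulli-tier truth (default: reference wild-type
#'   models).
#' @param bound probability bound fed to the model fits (`"upper"`, the
#'   possible-capture bound the published equations describe, or
#'   `"lower"`).
#' @param master_seed integer master seed; recorded in every artifact.
#' @param verbose print per-stage progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir,
                            tier = c("bernoulli", "langevin"),
                            design = design_grid(),
                            geometry = build_default_pore(),
                            generator = generator_config(),
                            classification = NULL,
                            contact = contact_config(),
                            truth_model = alpha_hemolysin_models(),
                            bound = "upper",
                            master_seed = 1,
                            verbose = FALSE) {
  tier <- match.arg(tier)
  if (is.null(classification))
    classification <- classification_config(geometry)
  structure(list(workdir = workdir, tier = tier, design = design,
                 geometry = geometry, generator = generator,
                 classification = classification, contact = contact,
                 truth_model = truth_model, bound = bound,
                 master_seed = master_seed, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full capture-analysis pipeline
#'
#' Stages: dataset generation, capture classification (Langevin tier),
#' contact analysis (Langevin tier), capture-probability statistics, and
#' the height/translation model fits for each orientation.  Each stage
#' writes its table under the working directory (`outcomes.csv`,
#' `contact_summary.csv`, `probabilities.csv`, `models.json`,
#' `provenance.json`).  Deterministic for a fixed master seed.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with `outcomes`, `probabilities`, `fits`
#'   (per orientation), optional `contact_summary`, and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %-9s %6.2f s", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  manifest <- stage("generate",
    generate_dataset(wd, tier = config$tier, design = config$design,
                     geometry = config$geometry, config = config$generator,
                     truth_model = config$truth_model,
                     master_seed = config$master_seed))

  contact_summary <- NULL
  if (config$tier == "langevin") {
    top <- read_topology(file.path(wd, "topology.pdb"))
    outcomes <- stage("classify",
      classify_runs(manifest, wd, top, config$classification,
                    config$geometry))
    names(outcomes)[names(outcomes) == "label"] <- "label"
    write.csv(outcomes, file.path(wd, "outcomes.csv"), row.names = FALSE)
    contact_summary <- stage("contacts", {
      profiles <- lapply(seq_len(nrow(manifest)), function(i) {
        traj <- read_trajectory(top,
                                file.path(wd, manifest$trajectory_path[i]))
        contact_profile(traj, config$contact, config$geometry)
      })
      names(profiles) <- as.character(outcomes$run)
      summarize_contacts(profiles, outcomes, config$contact)
    })
    write.csv(contact_summary, file.path(wd, "contact_summary.csv"),
              row.names = FALSE)
  } else {
    outcomes <- manifest  # sample_outcomes already labelled the runs
  }

  prob <- stage("stats", probability_table(
    outcomes, displacement_height = config$design$translation_height))
  write.csv(prob, file.path(wd, "probabilities.csv"), row.names = FALSE)

  fits <- stage("fit", lapply(
    setNames(config$design$orientations, config$design$orientations),
    function(or) {
      hp <- height_series(prob, or, config$bound)
      tp <- translation_series(prob, or, config$bound,
                               config$design$translation_height)
      if (length(config$design$translations))
        fit_combined_model(hp, tp, orientation = or,
                           series_height = config$design$translation_height)
      else fit_height_model(hp, orientation = or)
    }))
  jsonlite::write_json(
    lapply(fits, function(f) f[c("orientation", "intercept",
                                 "height_slope", "translation_slope",
                                 "metadata")]),
    file.path(wd, "models.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  prov <- list(master_seed = config$master_seed, tier = config$tier,
               bound = config$bound,
               design = unclass(config$design),
               generator = unclass(config$generator),
               classification = unclass(config$classification),
               contact = unclass(config$contact),
               package_version =
                 as.character(utils::packageVersion("porecap")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(wd, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(outcomes = outcomes, probabilities = prob, fits = fits,
                 contact_summary = contact_summary,
                 paths = list(workdir = wd)))
}

#' Render a plain-text summary report
#'
#' Tabulates the observed capture probability (both bounds) against the
#' fitted model's prediction for every release point and orientation, and
#' appends the contact zone summary when contact artifacts are present.
#' Values are read from the stage artifacts; nothing is recomputed.
#'
#' @param results the list returned by [run_pipeline()], or a workdir
#'   containing `probabilities.csv` and `models.json`.
#' @return character vector of report lines (also printed).
#' @export
render_report <- function(results) {
  if (is.character(results)) {
    wd <- results
    pfile <- file.path(wd, "probabilities.csv")
    mfile <- file.path(wd, "models.json")
    if (!file.exists(pfile)) stop("missing artifact: ", pfile)
    if (!file.exists(mfile)) stop("missing artifact: ", mfile)
    prob <- read.csv(pfile)
    fits <- lapply(jsonlite::read_json(mfile, simplifyVector = TRUE),
                   function(m) capture_model(m$intercept, m$height_slope,
                                             m$translation_slope,
                                             m$orientation))
    csfile <- file.path(wd, "contact_summary.csv")
    cs <- if (file.exists(csfile)) read.csv(csfile) else NULL
  } else {
    prob <- results$probabilities
    fits <- results$fits
    cs <- results$contact_summary
  }
  up <- prob[prob$bound == "upper", ]
  lo <- prob[prob$bound == "lower", ]
  key <- paste(up$height, up$translation, up$orientation)
  lo <- lo[match(key, paste(lo$height, lo$translation, lo$orientation)), ]
  pred <- vapply(seq_len(nrow(up)), function(i)
    as.numeric(predict(fits[[up$orientation[i]]], up$height[i],
                       up$translation[i])), numeric(1))
  lines <- c(
    "Capture probability by release point (percent)",
    sprintf("%-6s %-8s %-12s %9s %9s %9s",
            "height", "transl.", "orientation", "lower", "upper",
            "predicted"),
    sprintf("%-6.1f %-8.1f %-12s %9.1f %9.1f %9.1f",
            up$height, up$translation, up$orientation,
            lo$probability, up$probability, pred),
    "",
    sprintf("Fitted models (percent, nm):"),
    vapply(fits, function(f)
      sprintf("  %-5s p = %.1f - %.1f h - %.1f t", f$orientation,
              f$intercept, f$height_slope, f$translation_slope),
      character(1)))
  if (!is.null(cs)) {
    zs <- zone_summary(cs)
    lines <- c(lines, "", "Extended contacts by zone and outcome:",
               if (nrow(zs)) sprintf("  %-9s %-18s %2d residues (%.0f%%)",
                                     zs$label, zs$zone, zs$n_extended,
                                     100 * zs$fraction_of_extended)
               else "  (none)")
  } else {
    message("no contact artifacts present; report omits the contact section")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
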