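#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis in one
#' validated object: the split fraction, the exponent grid, the reference-
#' osmolality policy, the non-detect policy, strictness of eligibility
#' checking, the demographic subgroup definitions and the RNG seed.  The
#' clinical thresholds used by the eligibility rules (albumin-creatinine
#' ratio > 30 mg/g, plasma glucose >= 126 / >= 200 mg/dL, eGFR <
#' 60 mL/min/1.73 m^2) are fixed properties of those rules, not
#' configuration.
#'
#' @param seed integer seed driving the split (and cohort generation when
#'   the pipeline input is a `synthetic_params`).
#' @param fraction training proportion, in (0, 1).
#' @param grid_lo,grid_hi,grid_step exponent grid; default
#'   0 to 1.5 by 0.01.
#' @param osm_ref `"auto"` (training-split median osmolality) or a fixed
#'   positive value in mOsm/kg; 734 is the conventional literature value.
#' @param nondetect non-detect substitution policy for the AsIMM composite.
#' @param strict eligibility strictness (see [apply_exclusions()]).
#' @param age_bands data frame with `band`, `lo`, `hi` defining
#'   non-overlapping, ordered age bands.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, fraction = 0.8,
                            grid_lo = 0, grid_hi = 1.5, grid_step = 0.01,
                            osm_ref = "auto",
                            nondetect = c("as_is", "lod_sqrt2", "zero"),
                            strict = TRUE,
                            age_bands = .default_age_bands) {
  cfg <- structure(
    list(seed = as.integer(seed), fraction = fraction,
         grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step,
         osm_ref = osm_ref, nondetect = match.arg(nondetect),
         strict = strict, age_bands = age_bands),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.finite(cfg$grid_step) || cfg$grid_step <= 0) {
    stop("invalid field grid_step: must be > 0", call. = FALSE)
  }
  if (cfg$grid_lo >= cfg$grid_hi) {
    stop("invalid field grid_lo/grid_hi: need grid_lo < grid_hi", call. = FALSE)
  }
  if (cfg$fraction <= 0 || cfg$fraction >= 1) {
    stop("invalid field fraction: must lie in (0, 1)", call. = FALSE)
  }
  if (!identical(cfg$osm_ref, "auto") &&
      (!is.numeric(cfg$osm_ref) || cfg$osm_ref <= 0)) {
    stop("invalid field osm_ref: 'auto' or a positive value", call. = FALSE)
  }
  ab <- cfg$age_bands
  if (is.unsorted(ab$lo) || any(ab$hi[-nrow(ab)] >= ab$lo[-1])) {
    stop("invalid field age_bands: bands must be ordered and non-overlapping",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; unknown
#' keys are an error so that typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "age_bands")
  unknown <- setdiff(names(raw), c(known, "age_bands"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$age_bands)) raw$age_bands <- as.data.frame(raw$age_bands)
  do.call(pipeline_config, raw)
}

## canonical JSON serialisation of the config, used for the manifest hash
.config_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
}

#' Run the full adjustment-assessment pipeline
#'
#' Executes every stage in order - generate or accept a cohort, apply the
#' eligibility exclusion cascade, partition into training/testing, derive
#' flow-rate exponents on the training split (criterion A for all analytes,
#' criterion B for blood-paired analytes), adjust the testing split by every
#' method and assess performance - writing each intermediate artifact to
#' `out_dir` along with a manifest recording the configuration, seed and an
#' MD5 per artifact.  Re-running with the same configuration and input
#' reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param input either a [cohort()] or a [synthetic_params()] (the cohort is
#'   then generated as the first stage).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results:
#'   `cohort`, `audits`, `split`, `training`, `testing`, `osm_ref`,
#'   `b_table`, `adjusted`, `assessment`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 1),
#'                     synthetic_params(n = 400, seed = 1),
#'                     out_dir = tempfile("run"))
#' res$assessment[res$assessment$analyte == "pb", ]
#' }
#' @export
run_pipeline <- function(config, input, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ch <- stage("input", {
    if (inherits(input, "synthetic_params")) generate_cohort(input)
    else if (inherits(input, "cohort")) input
    else stop("input must be a cohort or synthetic_params")
  })

  filt <- stage("eligibility", apply_exclusions(ch, strict = config$strict))
  write_cohort(filt$cohort, path("cohort_filtered.csv"))
  write_audit(filt$audits, path("audit.json"))

  split <- stage("split", split_cohort(filt$cohort, fraction = config$fraction,
                                       seed = config$seed))
  jsonlite::write_json(unclass(split), path("split.json"), auto_unbox = TRUE)
  halves <- apply_split(filt$cohort, split)

  osm_ref <- if (identical(config$osm_ref, "auto")) {
    stats::median(halves$training$records$osmolality)
  } else config$osm_ref

  grid <- seq(config$grid_lo, config$grid_hi, by = config$grid_step)
  b_table <- stage("derive_b", {
    bt_a <- derive_b(halves$training, criterion = "A", grid = grid)
    bt_b <- derive_b(halves$training, analytes = c("pb", "cd"),
                     criterion = "B", grid = grid)
    out <- rbind(as.data.frame(bt_a), as.data.frame(bt_b))
    attr(out, "split") <- "training"
    class(out) <- c("b_table", "data.frame")
    out
  })
  utils::write.csv(as.data.frame(b_table), path("b_table.csv"), row.names = FALSE)

  adjusted <- stage("adjust", {
    get_b <- function(crit) {
      bt <- b_table[b_table$criterion == crit, ]
      stats::setNames(bt$b_opt, bt$analyte)
    }
    parts <- lapply(c("unadjusted", "creatinine", "osmolality", "er", "erbw"),
                    function(m) adjust_cohort(halves$testing, m,
                                              osm_ref = osm_ref,
                                              nondetect = config$nondetect))
    ba <- get_b("A")
    parts <- c(parts, list(adjust_cohort(halves$testing, "ufr_power", b = ba,
                                         nondetect = config$nondetect)))
    cols <- unique(unlist(lapply(parts, names)))
    parts <- lapply(parts, function(d) {
      for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
      d[cols]
    })
    do.call(rbind, parts)
  })
  utils::write.csv(as.data.frame(adjusted), path("adjusted.csv"), row.names = FALSE)

  assessment <- stage("assess",
                      evaluate_methods(halves$testing, b_table, osm_ref))
  jsonlite::write_json(as.data.frame(assessment), path("assessment.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  artifacts <- c("cohort_filtered.csv", "audit.json", "split.json",
                 "b_table.csv", "adjusted.csv", "assessment.json")
  manifest <- list(
    config = jsonlite::fromJSON(.config_json(config)),
    seed = config$seed,
    osm_ref = osm_ref,
    artifacts = lapply(stats::setNames(artifacts, artifacts),
                       function(f) unname(tools::md5sum(path(f))))
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = filt$cohort, audits = filt$audits, split = split,
                 training = halves$training, testing = halves$testing,
                 osm_ref = osm_ref, b_table = b_table, adjusted = adjusted,
                 assessment = assessment, manifest = manifest))
}
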