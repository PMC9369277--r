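#' Assemble a validated pipeline configuration
#'
#' Collects every stage parameter with its default: input source (a
#' directory of TIFF fields, a design table to simulate, or the built-in
#' study preset), channel aliases, segmentation/quantification parameters,
#' IHS calibration, statistics settings, and the master seed. The resolved
#' configuration is serialized as YAML next to the outputs so every run is
#' auditable.
#'
#' @param input_dir Directory of TIFF fields (with JSON sidecars), or `NULL`.
#' @param simulate Design data frame to simulate, or the string
#'   `"adenomyosis_study"` for the built-in 19 + 19 preset; ignored when
#'   `input_dir` is given.
#' @param preset_pixel_um,preset_n_fields Geometry used when `simulate` is
#'   the preset name.
#' @param aliases Named character vector of channel aliases for ingestion.
#' @param quant See [quant_params()].
#' @param vegf_threshold,ihs_calibration IHS stage parameters.
#' @param alpha Two-tailed significance level for the comparison report.
#' @param stratify_by Stratification column (default `"cycle_phase"`).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = "adenomyosis_study",
                            preset_pixel_um = 0.5, preset_n_fields = 5L,
                            aliases = NULL, quant = quant_params(),
                            vegf_threshold = 0.15,
                            ihs_calibration = c(0.125, 0.375, 0.625, 0.875),
                            alpha = 0.05, stratify_by = "cycle_phase",
                            seed = 1L, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(input_dir = input_dir, simulate = simulate,
                 preset_pixel_um = preset_pixel_um,
                 preset_n_fields = as.integer(preset_n_fields),
                 aliases = aliases, quant = quant,
                 vegf_threshold = vegf_threshold,
                 ihs_calibration = ihs_calibration, alpha = alpha,
                 stratify_by = stratify_by, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_outcome_table <- function(specimens, ihs_specimens, meta) {
  wide <- specimens[specimens$compartment == "stroma", , drop = FALSE]
  myo <- specimens[specimens$compartment == "myometrium", , drop = FALSE]
  # myometrium specimens carry their outcomes in the myometrium compartment
  myo_only <- myo[!(myo$specimen_id %in% wide$specimen_id), , drop = FALSE]
  out <- rbind(wide, myo_only)
  if (!is.null(ihs_specimens) && nrow(ihs_specimens)) {
    for (comp in c("stroma", "glands", "myometrium")) {
      m <- ihs_specimens[ihs_specimens$compartment == comp,
                         c("specimen_id", "ihs")]
      names(m)[2] <- paste0("ihs_", comp)
      out <- merge(out, m, by = "specimen_id", all.x = TRUE)
    }
  }
  merge(meta[, intersect(c("specimen_id", "patient_id", "group", "tissue_type",
                           "cycle_phase", "medication"), names(meta))],
        out, by = "specimen_id")
}

#' Run the full quantification pipeline
#'
#' simulate (or ingest) -> binary layers -> compartments -> vessel counting
#' -> densities -> VEGF IHS -> group statistics. Fields are processed one at
#' a time, so cohort size is bounded by disk, not memory. With identical
#' configuration and seed all tabular artifacts are byte-identical between
#' runs.
#'
#' Written artifacts (when `config$out_dir` is set): `fields.csv` (per-field
#' density records), `specimens.csv` (pooled per-specimen outcomes),
#' `ihs.csv`, `outcomes.csv` (the analysis table), `comparisons.csv` and
#' `comparisons.json` (tests and group summaries), and `config.yaml`.
#'
#' @param config A [pipeline_config()].
#' @param replicate Re-run the quantification a second time and verify the
#'   two passes agree (a determinism audit of the blinded repeat analysis);
#'   adds `replicate_identical` to the result.
#' @return List: `fields`, `specimens`, `ihs_fields`, `ihs_specimens`,
#'   `outcomes`, `report` (a `comparison_report`), `medication_report`, and
#'   `meta`.
#' @export
run_pipeline <- function(config = pipeline_config(), replicate = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))

  # absent compartments (e.g. no myometrium in a pure-endometrium field) are
  # routine in bulk runs, so their per-field warnings are muted here
  quantify_stack <- function(stack) {
    q <- suppressWarnings(quantify_field(stack, config$quant))
    ihs <- suppressWarnings(
      score_field(stack, q$compartments,
                  vegf_threshold = config$vegf_threshold,
                  calibration = config$ihs_calibration))
    list(records = q$records, ihs = ihs)
  }

  field_rows <- list(); ihs_rows <- list()
  if (!is.null(config$input_dir)) {
    paths <- sort(list.files(config$input_dir, pattern = "\\.tif$",
                             full.names = TRUE))
    if (!length(paths)) {
      stop("run_pipeline [ingestion]: no TIFF fields found in ",
           config$input_dir, call. = FALSE)
    }
    meta_path <- file.path(config$input_dir, "metadata.csv")
    meta <- if (file.exists(meta_path)) {
      utils::read.csv(meta_path, stringsAsFactors = FALSE)
    } else {
      stop("run_pipeline [ingestion]: metadata.csv not found in ",
           config$input_dir, call. = FALSE)
    }
    for (p in paths) {
      stack <- read_field(p, aliases = config$aliases)
      res <- quantify_stack(stack)
      field_rows[[length(field_rows) + 1L]] <- res$records
      ihs_rows[[length(ihs_rows) + 1L]] <- res$ihs
    }
  } else {
    design <- config$simulate
    if (is.character(design)) {
      if (!identical(design, "adenomyosis_study")) {
        stop("run_pipeline [ingestion]: unknown preset '", design, "'",
             call. = FALSE)
      }
      design <- adenomyosis_study_design(n_fields = config$preset_n_fields,
                                         pixel_um = config$preset_pixel_um)
    }
    if (!is.data.frame(design) || !nrow(design)) {
      stop("run_pipeline [ingestion]: empty cohort design", call. = FALSE)
    }
    configs <- cohort_configs(design, seed = config$seed)
    meta <- attr(configs, "realized")
    for (cfg in configs) {
      for (f in seq_len(cfg$n_fields)) {
        stack <- generate_field(cfg, f, keep_masks = FALSE)$stack
        res <- quantify_stack(stack)
        field_rows[[length(field_rows) + 1L]] <- res$records
        ihs_rows[[length(ihs_rows) + 1L]] <- res$ihs
      }
    }
  }

  fields <- do.call(rbind, field_rows)
  rownames(fields) <- NULL
  ihs_fields <- do.call(rbind, ihs_rows)
  specimens <- aggregate_specimen(fields)
  ihs_specimens <- if (nrow(ihs_fields)) {
    aggregate_ihs(ihs_fields, config$ihs_calibration)
  } else ihs_fields
  outcomes <- pipeline_outcome_table(specimens, ihs_specimens, meta)
  report <- suppressWarnings(
    compare_tissues(outcomes, alpha = config$alpha,
                    stratify_by = config$stratify_by))
  med_report <- suppressWarnings(
    medication_subgroup(outcomes, alpha = config$alpha))

  out <- list(fields = fields, specimens = specimens,
              ihs_fields = ihs_fields, ihs_specimens = ihs_specimens,
              outcomes = outcomes, report = report,
              medication_report = med_report, meta = meta)

  if (replicate) {
    # blinded repeat: quantification is a pure function of the images
    again <- run_pipeline_requant(config, fields)
    out$replicate_identical <- isTRUE(all.equal(fields, again))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.csv(d, file.path(config$out_dir, f),
                                          row.names = FALSE)
    wr(fields, "fields.csv")
    wr(specimens, "specimens.csv")
    if (nrow(ihs_fields)) wr(ihs_specimens, "ihs.csv")
    wr(outcomes, "outcomes.csv")
    wr(report$tests, "comparisons.csv")
    wr(report$summaries, "group_summaries.csv")
    jsonlite::write_json(
      list(alpha = report$alpha, stratify_by = report$stratify_by,
           tests = report$tests, summaries = report$summaries),
      file.path(config$out_dir, "comparisons.json"), digits = NA)
    cfg_plain <- unclass(config)
    cfg_plain$simulate <- if (is.character(cfg_plain$simulate))
      cfg_plain$simulate else "design_table"
    yaml::write_yaml(cfg_plain, file.path(config$out_dir, "config.yaml"))
  }
  out
}

# second quantification pass over the same inputs (replicate audit)
run_pipeline_requant <- function(config, fields_first) {
  cfg2 <- config
  cfg2$out_dir <- NULL
  res2 <- run_pipeline(cfg2, replicate = FALSE)
  res2$fields
}
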