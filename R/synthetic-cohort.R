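#' Planted group effects of the emulated case-control study
#'
#' Median outcome levels planted per tissue type and cycle phase. The
#' directions encode the study's findings: ectopic blood vessel density
#' about twice the control endometrium, eutopic lymph vessel density
#' elevated in the proliferative phase, eutopic BVD higher in the secretory
#' than the proliferative phase, and a depressed mature:total vessel ratio
#' in the eutopic and ectopic endometrium of cases. VEGF immunoreactivity is
#' planted so the median IHS per compartment is 1 (stroma), 3 (glands) and
#' 4 (myometrium), with no case-control difference.
#'
#' @return Data frame keyed by `tissue_type` and `cycle_phase` with planted
#'   medians: `bvd`, `lvd` (vessels/mm^2), `mature_fraction`, and VEGF
#'   `(fraction, level)` per compartment.
#' @export
study_effects <- function() {
  ef <- expand.grid(
    tissue_type = c("control_endometrium", "eutopic_endometrium",
                    "ectopic_endometrium", "myometrium"),
    cycle_phase = c("proliferative", "secretory"),
    stringsAsFactors = FALSE)
  key <- paste(ef$tissue_type, ef$cycle_phase)
  ef$bvd <- c(control_endometrium = 28, eutopic_endometrium = 30,
              ectopic_endometrium = 60, myometrium = 25)[ef$tissue_type]
  ef$bvd[key == "control_endometrium secretory"] <- 36
  ef$bvd[key == "eutopic_endometrium secretory"] <- 42
  ef$lvd <- c(control_endometrium = 8, eutopic_endometrium = 16,
              ectopic_endometrium = 10, myometrium = 6)[ef$tissue_type]
  ef$lvd[key == "eutopic_endometrium secretory"] <- 9
  ef$mature_fraction <- c(control_endometrium = 0.60,
                          eutopic_endometrium = 0.35,
                          ectopic_endometrium = 0.35,
                          myometrium = 1.0)[ef$tissue_type]
  ef$vegf_stroma_fraction <- 0.05; ef$vegf_stroma_level <- 1
  ef$vegf_glands_fraction <- 0.65; ef$vegf_glands_level <- 1
  ef$vegf_myo_fraction <- 0.30; ef$vegf_myo_level <- 2
  ef
}

#' Study design emulating the 19 + 19 adenomyosis case-control cohort
#'
#' One row per specimen (patient x tissue sample). Nineteen cases (7
#' proliferative, 12 secretory) and nineteen matched controls (6/13);
#' representative material per tissue follows the study: eutopic endometrium
#' analyzable for 14 cases (5P/9S) and 17 controls (6P/11S), ectopic
#' endometrium for 16 cases (6P/10S), myometrium for all. Four cases and
#' five controls carry the anti-angiogenic medication flag (NSAIDs or
#' tranexamic acid). Cases have planted lesion depths well above the 2.5 mm
#' invasion threshold; controls 0.
#'
#' @param n_fields Fields per specimen (default 5).
#' @param pixel_um Pixel size for rendered fields (default 0.5).
#' @param effects Planted medians, see [study_effects()].
#' @return Design data frame consumed by [generate_cohort()],
#'   [run_pipeline()] and [simulate_outcome_table()].
#' @export
adenomyosis_study_design <- function(n_fields = 5L, pixel_um = 0.5,
                                     effects = study_effects()) {
  pat <- data.frame(
    patient_id = c(sprintf("A%02d", 1:19), sprintf("C%02d", 1:19)),
    group = rep(c("adenomyosis", "control"), each = 19L),
    cycle_phase = c(rep(c("proliferative", "secretory"), c(7L, 12L)),
                    rep(c("proliferative", "secretory"), c(6L, 13L))),
    stringsAsFactors = FALSE)
  pat$medication <- ifelse(
    pat$patient_id %in% c("A01", "A08", "A09", "A10",
                          "C01", "C02", "C07", "C08", "C09"),
    "antiangiogenic", "none_other")
  pat$lesion_depth_mm <- ifelse(pat$group == "adenomyosis",
                                3 + ((seq_len(38) * 7) %% 50) / 10, 0)

  tissue_rows <- function(ids, tissue) {
    p <- pat[pat$patient_id %in% ids, , drop = FALSE]
    p$tissue_type <- tissue
    p
  }
  adeno <- pat$patient_id[pat$group == "adenomyosis"]
  ctrl <- pat$patient_id[pat$group == "control"]
  design <- rbind(
    tissue_rows(setdiff(ctrl, c("C18", "C19")), "control_endometrium"),
    tissue_rows(setdiff(adeno, c("A06", "A07", "A17", "A18", "A19")),
                "eutopic_endometrium"),
    tissue_rows(setdiff(adeno, c("A07", "A18", "A19")), "ectopic_endometrium"),
    tissue_rows(c(adeno, ctrl), "myometrium"))
  design$specimen_id <- paste(design$patient_id, design$tissue_type, sep = "_")
  key <- paste(design$tissue_type, design$cycle_phase)
  ei <- match(key, paste(effects$tissue_type, effects$cycle_phase))
  for (col in c("bvd", "lvd", "mature_fraction", "vegf_stroma_fraction",
                "vegf_stroma_level", "vegf_glands_fraction",
                "vegf_glands_level", "vegf_myo_fraction", "vegf_myo_level")) {
    design[[paste0("planted_", col)]] <- effects[[col]][ei]
  }
  design$n_fields <- as.integer(n_fields)
  design$pixel_um <- pixel_um
  rownames(design) <- NULL
  design
}

#' Expand a design table into per-specimen configurations
#'
#' Applies the between-specimen biological variability: planted densities
#' are the design medians times a lognormal multiplier (sdlog 0.25, i.e.
#' ~25% coefficient of variation across patients) and the mature fraction
#' gets additive Gaussian jitter (SD 0.06, clamped to `[0.02, 0.98]`; a
#' planted fraction of exactly 1 is kept, as in the myometrium where every
#' vessel is muralized). Each specimen's randomness derives from
#' `derive_seed(seed, specimen_id)`, so any specimen regenerates in
#' isolation.
#'
#' @param design Design data frame (see [adenomyosis_study_design()]).
#' @param seed Master seed.
#' @param sdlog Between-specimen lognormal spread of planted densities.
#' @param mature_jitter_sd Between-specimen SD of the mature fraction.
#' @param noise Per-field noise vector passed to [specimen_config()].
#' @return List of [specimen_config()] objects; the realized planted values
#'   are attached to each config and summarized in `attr(, "realized")`.
#' @export
cohort_configs <- function(design, seed = 1L, sdlog = 0.25,
                           mature_jitter_sd = 0.06,
                           noise = c(background = 0.05, sigma = 0.02,
                                     bleedthrough = 0)) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L,
            "specimen_id" %in% names(design))
  if (anyDuplicated(design$specimen_id)) {
    stop("cohort_configs: duplicate specimen identifiers", call. = FALSE)
  }
  configs <- vector("list", nrow(design))
  realized <- design
  for (i in seq_len(nrow(design))) {
    r <- design[i, ]
    sseed <- derive_seed(seed, r$specimen_id)
    set.seed(derive_seed(seed, paste0(r$specimen_id, "/bio")))
    bvd <- r$planted_bvd * stats::rlnorm(1, 0, sdlog)
    lvd <- r$planted_lvd * stats::rlnorm(1, 0, sdlog)
    frac <- if (r$planted_mature_fraction >= 1) 1 else
      clamp(stats::rnorm(1, r$planted_mature_fraction, mature_jitter_sd),
            0.02, 0.98)
    ef <- study_effects()[1L, ]   # column defaults for designs without VEGF
    configs[[i]] <- specimen_config(
      group = r$group, tissue_type = r$tissue_type,
      cycle_phase = r$cycle_phase, medication = r$medication,
      n_fields = r$n_fields %||% 5L, pixel_um = r$pixel_um %||% 0.5,
      planted_bvd = bvd, planted_lvd = lvd, planted_mature_fraction = frac,
      planted_vegf = list(
        stroma = c(r$planted_vegf_stroma_fraction %||% ef$vegf_stroma_fraction,
                   r$planted_vegf_stroma_level %||% ef$vegf_stroma_level),
        glands = c(r$planted_vegf_glands_fraction %||% ef$vegf_glands_fraction,
                   r$planted_vegf_glands_level %||% ef$vegf_glands_level),
        myometrium = c(r$planted_vegf_myo_fraction %||% ef$vegf_myo_fraction,
                       r$planted_vegf_myo_level %||% ef$vegf_myo_level)),
      lesion_depth_mm = r$lesion_depth_mm %||% 0, noise = noise, seed = sseed,
      specimen_id = r$specimen_id)
    realized$realized_bvd[i] <- bvd
    realized$realized_lvd[i] <- lvd
    realized$realized_mature_fraction[i] <- frac
  }
  attr(configs, "realized") <- realized
  configs
}

#' Generate a full synthetic cohort
#'
#' Renders every field of every specimen in the design. With `out_dir` set,
#' one multipage TIFF (plus JSON sidecar) is written per field, together
#' with `metadata.csv` (one row per specimen) and `ground_truth.json`.
#'
#' @param design Design data frame (see [adenomyosis_study_design()]).
#' @param seed Master seed; specimen seeds derive from it reproducibly.
#' @param out_dir Output directory (created if needed); `NULL` for in-memory.
#' @param keep_stacks Return the rendered [channel_stack()]s (memory-heavy
#'   for large cohorts).
#' @param ... Passed to [cohort_configs()].
#' @return List: `metadata` (specimen table with realized planted values),
#'   `field_truth` (per-field ground-truth summary), `files` (written TIFF
#'   paths, if any), `stacks` (if `keep_stacks`).
#' @export
generate_cohort <- function(design, seed = 1L, out_dir = NULL,
                            keep_stacks = FALSE, ...) {
  configs <- cohort_configs(design, seed = seed, ...)
  realized <- attr(configs, "realized")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truth_rows <- list(); files <- character(0); stacks <- list()
  for (cfg in configs) {
    for (f in seq_len(cfg$n_fields)) {
      fld <- generate_field(cfg, f, keep_masks = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <-
        cbind(fld$truth$summary, specimen_id = cfg$specimen_id,
              lesion_depth_mm = fld$truth$lesion_depth_mm,
              is_adenomyosis = fld$truth$is_adenomyosis,
              stringsAsFactors = FALSE)
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(fld$stack$field_id, ".tif"))
        write_field(fld$stack, path)
        files <- c(files, path)
      }
      if (keep_stacks) stacks[[fld$stack$field_id]] <- fld$stack
    }
  }
  field_truth <- do.call(rbind, truth_rows)
  rownames(field_truth) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(realized, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(field_truth, file.path(out_dir, "ground_truth.json"),
                         digits = NA)
  }
  out <- list(metadata = realized, field_truth = field_truth, files = files)
  if (keep_stacks) out$stacks <- stacks
  out
}

#' Simulate specimen-level outcomes without rendering images
#'
#' Draws per-specimen outcomes directly from the planted effect medians with
#' the same between-specimen variability model as the image generator
#' (lognormal densities, jittered mature fraction). This is the desk-scale
#' route for validating the statistical layer (type-I error, power), where
#' thousands of replicate cohorts are needed.
#'
#' @param design Design data frame with `specimen_id`, `group`,
#'   `tissue_type`, `cycle_phase`, `medication` and `planted_*` columns
#'   (see [adenomyosis_study_design()]).
#' @param seed Seed for this replicate.
#' @param sdlog,mature_jitter_sd Between-specimen variability (defaults
#'   match [cohort_configs()]).
#' @return Per-specimen outcome table suitable for [compare_tissues()]:
#'   columns `bvd_per_mm2`, `lvd_per_mm2`, `pct_cd31_area`, `pct_pdpn_area`,
#'   `mature_ratio`. Percent-area outcomes are densities times a nominal
#'   mean vessel cross-section (300 um^2), preserving the density ordering.
#' @export
simulate_outcome_table <- function(design, seed = 1L, sdlog = 0.25,
                                   mature_jitter_sd = 0.06) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  if (anyDuplicated(design$specimen_id)) {
    stop("simulate_outcome_table: duplicate specimen identifiers",
         call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(design)
  out <- design[, intersect(c("specimen_id", "patient_id", "group",
                              "tissue_type", "cycle_phase", "medication"),
                            names(design)), drop = FALSE]
  out$bvd_per_mm2 <- design$planted_bvd * stats::rlnorm(n, 0, sdlog)
  out$lvd_per_mm2 <- design$planted_lvd * stats::rlnorm(n, 0, sdlog)
  out$pct_cd31_area <- out$bvd_per_mm2 * 300 / 1e6 * 100
  out$pct_pdpn_area <- out$lvd_per_mm2 * 300 / 1e6 * 100
  out$mature_ratio <- ifelse(
    design$tissue_type == "myometrium", NA_real_,
    clamp(stats::rnorm(n, design$planted_mature_fraction, mature_jitter_sd),
          0, 1))
  rownames(out) <- NULL
  out
}
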