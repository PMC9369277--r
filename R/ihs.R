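#' Percentage-bin score of the immunohistochemical score (IHS)
#'
#' Maps the percentage of immunoreactive cells to the 0-4 bin score:
#' `[1, 10] -> 1`, `(10, 50] -> 2`, `(50, 80] -> 3`, `(80, 100] -> 4`.
#' Staining below 1% scores 0 (the printed bins start at 1%; scoring the
#' sub-1% remainder as 0 matches the intensity scale's inclusion of 0).
#'
#' @param pct Percentage of immunoreactive cells, in `[0, 100]`.
#' @return Integer score 0-4 (vectorized).
#' @export
percentage_score <- function(pct) {
  stopifnot(is.numeric(pct))
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100)) {
    stop("percentage_score: pct must lie in [0, 100]", call. = FALSE)
  }
  as.integer(ifelse(pct < 1, 0L,
              ifelse(pct <= 10, 1L,
               ifelse(pct <= 50, 2L,
                ifelse(pct <= 80, 3L, 4L)))))
}

#' Intensity score of the IHS
#'
#' Maps a mean staining intensity (of the immunoreactive cells, after
#' background subtraction) to the 0-4 intensity scale: the score is the
#' number of calibration cutpoints at or below the intensity, so it is
#' monotone nondecreasing in intensity.
#'
#' @param mean_intensity Mean background-subtracted intensity of positive
#'   cells, on the `[0, 1]` scale.
#' @param calibration Four strictly ascending cutpoints. The default
#'   `c(0.125, 0.375, 0.625, 0.875)` places each cutpoint midway between
#'   consecutive quarters of the dynamic range, so intensities rendered at
#'   level `k/4` score `k`.
#' @return Integer score 0-4 (vectorized over `mean_intensity`).
#' @export
intensity_score <- function(mean_intensity,
                            calibration = c(0.125, 0.375, 0.625, 0.875)) {
  stopifnot(is.numeric(mean_intensity), length(calibration) == 4L)
  if (any(diff(calibration) <= 0)) {
    stop("intensity_score: calibration cutpoints must be strictly ascending",
         call. = FALSE)
  }
  vapply(mean_intensity, function(x) sum(calibration <= x), 0L)
}

#' Combine percentage and intensity into the IHS
#'
#' `ihs = percentage_score(pct) * intensity` - an integer in 0-16.
#'
#' @param pct Percentage of immunoreactive cells in `[0, 100]`.
#' @param intensity Integer intensity score 0-4.
#' @return List with `pct_score`, `intensity_score`, `ihs`.
#' @export
compute_ihs <- function(pct, intensity) {
  stopifnot(is.numeric(intensity), all(intensity %in% 0:4))
  ps <- percentage_score(pct)
  list(pct_score = ps, intensity_score = as.integer(intensity),
       ihs = as.integer(ps * intensity))
}

#' Percentage of immunoreactive cells per compartment
#'
#' Cells are proxied by nuclei segmented from the DAPI channel (connected
#' components of the binarized plane; well-separated nuclei, one component
#' per cell). A cell is immunoreactive iff the mean VEGF intensity in a disk
#' of `cell_radius_px` around its nucleus centroid reaches `vegf_threshold`.
#' Compartments with no detected cells return `NA` (flagged, not zero).
#'
#' @param stack A [channel_stack()] (DAPI and VEGF channels required).
#' @param masks A `compartment_masks` object.
#' @param vegf_threshold Raw-intensity positivity threshold (default 0.15,
#'   above background but below the lowest rendered staining level).
#' @param cell_radius_px Sampling-disk radius; default `round(2.5 um / pixel)`.
#' @param dapi_mask Optional precomputed DAPI `binary_mask`.
#' @return Named numeric vector of percentages (`stroma`, `glands`,
#'   `myometrium`), with attribute `n_cells` (cells per compartment) and
#'   `mean_positive_intensity` (mean background-subtracted VEGF intensity of
#'   the positive cells per compartment, for [intensity_score()]).
#' @export
immunoreactive_fraction <- function(stack, masks, vegf_threshold = 0.15,
                                    cell_radius_px = NULL, dapi_mask = NULL) {
  stopifnot(inherits(stack, "channel_stack"),
            inherits(masks, "compartment_masks"))
  vegf <- stack$planes$VEGF
  if (is.null(stack$planes$DAPI) || is.null(vegf)) {
    stop("immunoreactive_fraction: DAPI and VEGF channels required",
         call. = FALSE)
  }
  r_px <- cell_radius_px %||% max(1L, round(2.5 / stack$pixel_um))
  if (is.null(dapi_mask)) {
    plane <- stack$planes$DAPI
    dapi_mask <- if (diff(range(plane)) == 0) {
      as_binary_mask(matrix(FALSE, nrow(plane), ncol(plane)), "DAPI")
    } else binarize_channel(stack, "DAPI")
  }
  nuclei <- label_objects(clean_mask(dapi_mask,
                                     min_object_px = max(1L, round(2 / stack$pixel_um^2)),
                                     closing_radius_px = 0L),
                          connectivity = 8)
  tab <- nuclei$table
  bg <- stats::median(vegf)    # most pixels carry no VEGF-specific signal
  comp_names <- c("stroma", "glands", "myometrium")
  n_cells <- stats::setNames(integer(3), comp_names)
  n_pos <- stats::setNames(integer(3), comp_names)
  pos_int <- stats::setNames(vector("list", 3), comp_names)
  h <- nrow(vegf); w <- ncol(vegf)
  for (i in seq_len(nrow(tab))) {
    r0 <- round(tab$centroid_row[i]); c0 <- round(tab$centroid_col[i])
    comp <- comp_names[c(masks$stroma[r0, c0], masks$glands[r0, c0],
                         masks$myometrium[r0, c0])]
    if (!length(comp)) next
    rr <- max(1L, r0 - r_px):min(h, r0 + r_px)
    cc <- max(1L, c0 - r_px):min(w, c0 + r_px)
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    m <- mean(vegf[rr, cc][d2 <= r_px^2])
    n_cells[comp] <- n_cells[comp] + 1L
    if (m >= vegf_threshold) {
      n_pos[comp] <- n_pos[comp] + 1L
      pos_int[[comp]] <- c(pos_int[[comp]], m - bg)
    }
  }
  pct <- ifelse(n_cells > 0, 100 * n_pos / n_cells, NA_real_)
  if (any(n_cells == 0)) {
    warning("immunoreactive_fraction: no cells detected in: ",
            paste(comp_names[n_cells == 0], collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(as.numeric(pct), comp_names),
            n_cells = n_cells,
            mean_positive_intensity = vapply(pos_int, function(x)
              if (length(x)) mean(x) else NA_real_, 0))
}

#' VEGF IHS per compartment for one field
#'
#' Combines [immunoreactive_fraction()], [percentage_score()] and
#' [intensity_score()] into one IHS record per compartment.
#'
#' @inheritParams immunoreactive_fraction
#' @param calibration Intensity cutpoints for [intensity_score()].
#' @return Data frame: one row per compartment with cells detected, columns
#'   `immunoreactive_pct`, `pct_score`, `intensity_score`, `ihs`.
#' @export
score_field <- function(stack, masks, vegf_threshold = 0.15,
                        cell_radius_px = NULL,
                        calibration = c(0.125, 0.375, 0.625, 0.875)) {
  fr <- immunoreactive_fraction(stack, masks, vegf_threshold, cell_radius_px)
  mpi <- attr(fr, "mean_positive_intensity")
  ncl <- attr(fr, "n_cells")
  out <- list()
  for (comp in names(fr)) {
    if (is.na(fr[[comp]])) next
    is <- if (is.na(mpi[[comp]])) 0L else
      intensity_score(mpi[[comp]], calibration)
    rec <- compute_ihs(fr[[comp]], is)
    out[[comp]] <- data.frame(
      specimen_id = stack$specimen_id, field_id = stack$field_id,
      compartment = comp, n_cells = ncl[[comp]],
      immunoreactive_pct = fr[[comp]], pct_score = rec$pct_score,
      intensity_score = rec$intensity_score, ihs = rec$ihs,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(specimen_id = character(0), field_id = character(0),
                      compartment = character(0), n_cells = integer(0),
                      immunoreactive_pct = numeric(0), pct_score = integer(0),
                      intensity_score = integer(0), ihs = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pool per-field IHS records into one specimen-level score per compartment
#'
#' Cell counts are pooled across fields (total positive / total cells), then
#' rescored; the intensity score is the cell-weighted mean intensity rescored
#' on the same calibration.
#'
#' @param records Data frame from [score_field()] over several fields.
#' @param calibration Intensity cutpoints.
#' @return One row per specimen x compartment.
#' @export
aggregate_ihs <- function(records, calibration = c(0.125, 0.375, 0.625, 0.875)) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  key <- interaction(records$specimen_id, records$compartment, drop = TRUE)
  out <- lapply(split(records, key), function(r) {
    n <- sum(r$n_cells)
    pct <- sum(r$immunoreactive_pct * r$n_cells) / n
    # cell-weighted mean of per-field intensity scores, rounded to the scale
    is <- as.integer(round(sum(r$intensity_score * r$n_cells) / n))
    rec <- compute_ihs(pct, is)
    data.frame(specimen_id = r$specimen_id[1L], compartment = r$compartment[1L],
               n_fields = nrow(r), n_cells = n, immunoreactive_pct = pct,
               pct_score = rec$pct_score, intensity_score = rec$intensity_score,
               ihs = rec$ihs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
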