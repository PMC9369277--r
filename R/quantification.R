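#' Default quantification parameters
#'
#' Physical parameters are given in micrometres and converted to pixels per
#' field, so results are comparable across scan resolutions.
#'
#' @param min_area_um2 Minimum object area retained as a vessel (um^2).
#'   Default 5 (20 px at 0.5 um/px), below any capillary cross-section.
#' @param closing_um Disc radius for morphological closing of vessel layers.
#' @param lymph_overlap_cut CD31 objects whose fractional overlap with the
#'   podoplanin layer reaches this cut are classed lymphatic (default 0.5).
#' @param maturity_dilation_um Width of the outer boundary band probed for
#'   alpha-SMA mural coverage (default 4.5 um, spanning the pericyte gap).
#' @param maturity_overlap_cut Minimum alpha-SMA-positive fraction of the
#'   boundary band for a blood vessel to count as mature (default 0.1; even
#'   partial mural coverage reads as CD31/aSMA double staining).
#' @param min_contrast Otsu contrast guard passed to [binarize_channel()].
#' @param floor_offset Background floor for sparse channels, see
#'   [binarize_channel()].
#' @return Named list of parameters.
#' @export
quant_params <- function(min_area_um2 = 5, closing_um = 0.5,
                         lymph_overlap_cut = 0.5, maturity_dilation_um = 4.5,
                         maturity_overlap_cut = 0.1, min_contrast = 0.15,
                         floor_offset = 0.3) {
  list(min_area_um2 = min_area_um2, closing_um = closing_um,
       lymph_overlap_cut = lymph_overlap_cut,
       maturity_dilation_um = maturity_dilation_um,
       maturity_overlap_cut = maturity_overlap_cut,
       min_contrast = min_contrast, floor_offset = floor_offset)
}

object_pixels_crop <- function(labels, tab_row, margin = 0L) {
  h <- nrow(labels); w <- ncol(labels)
  rr <- max(1L, tab_row$row_min - margin):min(h, tab_row$row_max + margin)
  cc <- max(1L, tab_row$col_min - margin):min(w, tab_row$col_max + margin)
  list(rr = rr, cc = cc, obj = labels[rr, cc, drop = FALSE] == tab_row$label)
}

#' Turn labeled CD31 objects plus the podoplanin layer into vessel objects
#'
#' Every CD31 component at least `min_area_um2` large becomes a vessel; it is
#' classed lymphatic when its pixel overlap with the podoplanin layer reaches
#' `lymph_overlap_cut`, otherwise blood. Podoplanin components without
#' substantial CD31 overlap are added as lymphatic vessels so purely
#' podoplanin-positive lymphatics are counted once. Each vessel is assigned
#' the compartment holding the majority of its pixels; vessels lying mostly
#' in background (or inside gland lumina) are dropped.
#'
#' @param cd31_objects `labeled_objects` from the cleaned CD31 layer.
#' @param pdpn_mask Cleaned podoplanin `binary_mask` (or logical matrix).
#' @param compartments A `compartment_masks` object.
#' @param min_area_um2 Minimum vessel area (um^2).
#' @param pixel_um Pixel size (um/px).
#' @param lymph_overlap_cut Overlap fraction for lymphatic classification.
#' @return A `vessel_set`: data frame `vessels` (one row per vessel with
#'   class, area, centroid, compartment, maturity slots) plus the label
#'   images needed by [classify_maturity()].
#' @export
extract_vessels <- function(cd31_objects, pdpn_mask, compartments,
                            min_area_um2 = 5, pixel_um = 0.5,
                            lymph_overlap_cut = 0.5) {
  stopifnot(inherits(cd31_objects, "labeled_objects"),
            inherits(compartments, "compartment_masks"))
  pdpn <- mask_pixels(pdpn_mask)
  if (!all(dim(pdpn) == dim(cd31_objects$labels))) {
    stop("extract_vessels: dimensions differ", call. = FALSE)
  }
  min_px <- min_area_um2 / pixel_um^2
  comp_names <- c("stroma", "glands", "myometrium", "background")

  rows <- list()
  majority_comp <- function(rr, cc, obj) {
    votes <- vapply(comp_names, function(nm) {
      sum(compartments[[nm]][rr, cc][obj])
    }, 0)
    comp_names[which.max(votes)]
  }

  tab <- cd31_objects$table
  for (i in seq_len(nrow(tab))) {
    if (tab$area_px[i] < min_px) next
    cr <- object_pixels_crop(cd31_objects$labels, tab[i, ])
    ov <- mean(pdpn[cr$rr, cr$cc][cr$obj])
    comp <- majority_comp(cr$rr, cr$cc, cr$obj)
    if (comp %in% c("background", "glands")) next
    rows[[length(rows) + 1L]] <- data.frame(
      source = "cd31", source_label = tab$label[i],
      vessel_class = if (ov >= lymph_overlap_cut) "lymph" else "blood",
      area_um2 = tab$area_px[i] * pixel_um^2,
      centroid_row = tab$centroid_row[i], centroid_col = tab$centroid_col[i],
      compartment = comp, stringsAsFactors = FALSE)
  }

  pdpn_objects <- label_objects(pdpn, connectivity = 8)
  cd31_pos <- cd31_objects$labels > 0L
  ptab <- pdpn_objects$table
  for (i in seq_len(nrow(ptab))) {
    if (ptab$area_px[i] < min_px) next
    cr <- object_pixels_crop(pdpn_objects$labels, ptab[i, ])
    if (mean(cd31_pos[cr$rr, cr$cc][cr$obj]) >= 0.5) next  # already a CD31 object
    comp <- majority_comp(cr$rr, cr$cc, cr$obj)
    if (comp %in% c("background", "glands")) next
    rows[[length(rows) + 1L]] <- data.frame(
      source = "pdpn", source_label = ptab$label[i],
      vessel_class = "lymph",
      area_um2 = ptab$area_px[i] * pixel_um^2,
      centroid_row = ptab$centroid_row[i], centroid_col = ptab$centroid_col[i],
      compartment = comp, stringsAsFactors = FALSE)
  }

  vessels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), source_label = integer(0),
               vessel_class = character(0), area_um2 = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               compartment = character(0), stringsAsFactors = FALSE)
  vessels$vessel_id <- seq_len(nrow(vessels))
  vessels$is_mature <- rep(NA, nrow(vessels))
  vessels$asma_boundary_overlap <- rep(NA_real_, nrow(vessels))
  structure(list(vessels = vessels, cd31 = cd31_objects, pdpn = pdpn_objects,
                 pixel_um = pixel_um),
            class = "vessel_set")
}

#' Classify blood-vessel maturity by alpha-SMA mural coverage
#'
#' A blood vessel counts as mature (CD31/alpha-SMA double staining) when at
#' least `overlap_cut` of its dilated outer boundary band is alpha-SMA
#' positive. Lymphatic vessels carry no maturity flag; asking for one is an
#' error.
#'
#' @param vessel_set A `vessel_set` from [extract_vessels()].
#' @param asma_mask Cleaned alpha-SMA `binary_mask` (or logical matrix).
#' @param dilation_radius_px Width of the boundary band in pixels; default
#'   `round(4.5 / pixel_um)`, wide enough to span the endothelium-to-mural
#'   gap at any supported resolution.
#' @param overlap_cut Minimum alpha-SMA-positive fraction (default 0.1).
#' @param vessel_ids Vessels to classify; default all blood vessels. An id
#'   belonging to a lymph vessel is an error.
#' @return The `vessel_set` with `is_mature` and `asma_boundary_overlap`
#'   filled in for the classified vessels.
#' @export
classify_maturity <- function(vessel_set, asma_mask, dilation_radius_px = NULL,
                              overlap_cut = 0.1, vessel_ids = NULL) {
  stopifnot(inherits(vessel_set, "vessel_set"))
  asma <- mask_pixels(asma_mask)
  v <- vessel_set$vessels
  if (is.null(vessel_ids)) {
    vessel_ids <- v$vessel_id[v$vessel_class == "blood"]
  } else if (any(v$vessel_class[match(vessel_ids, v$vessel_id)] != "blood")) {
    stop("classify_maturity: maturity is defined for blood vessels only",
         call. = FALSE)
  }
  d <- as.integer(dilation_radius_px %||% max(1, round(4.5 / vessel_set$pixel_um)))
  brush <- EBImage::makeBrush(2L * d + 1L, "disc")
  for (id in vessel_ids) {
    i <- match(id, v$vessel_id)
    labs <- if (v$source[i] == "cd31") vessel_set$cd31 else vessel_set$pdpn
    tabi <- labs$table[match(v$source_label[i], labs$table$label), ]
    cr <- object_pixels_crop(labs$labels, tabi, margin = d + 1L)
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(cr$obj * 1), brush)) > 0.5
    boundary <- dil & !cr$obj
    ov <- if (any(boundary)) mean(asma[cr$rr, cr$cc][boundary]) else 0
    v$asma_boundary_overlap[i] <- ov
    v$is_mature[i] <- ov >= overlap_cut
  }
  vessel_set$vessels <- v
  vessel_set
}

#' Per-field, per-compartment vessel densities and stained-area fractions
#'
#' Computes the four vessel outcomes for each tissue compartment: blood and
#' lymph vessel density (count per mm^2 of compartment area), percent CD31-
#' and podoplanin-positive area, and the mature:total blood-vessel ratio.
#' The maturity ratio is reported for the endometrial stroma only - in the
#' myometrium every vessel is embedded in smooth muscle, so double staining
#' is uninformative there.
#'
#' @param vessel_set A `vessel_set` (after [classify_maturity()]).
#' @param compartments A `compartment_masks` object.
#' @param cd31_mask,pdpn_mask Cleaned binary layers used for percent-area.
#' @param pixel_um Pixel size (um/px).
#' @param specimen_id,field_id Identifiers copied into each record.
#' @return Data frame with one row per non-empty compartment (`stroma`,
#'   `myometrium`): `compartment_area_mm2`, `blood_count`, `lymph_count`,
#'   `mature_count`, `bvd_per_mm2`, `lvd_per_mm2`, `pct_cd31_area`,
#'   `pct_pdpn_area`, `mature_ratio`. Compartments with zero area are
#'   suppressed with a warning.
#' @export
compute_densities <- function(vessel_set, compartments, cd31_mask, pdpn_mask,
                              pixel_um = NULL,
                              specimen_id = "specimen1", field_id = "field1") {
  stopifnot(inherits(vessel_set, "vessel_set"),
            inherits(compartments, "compartment_masks"))
  pixel_um <- pixel_um %||% vessel_set$pixel_um
  cd31 <- mask_pixels(cd31_mask); pdpn <- mask_pixels(pdpn_mask)
  v <- vessel_set$vessels
  out <- list()
  for (comp in c("stroma", "myometrium")) {
    m <- compartments[[comp]]
    area_px <- sum(m)
    area_mm2 <- area_px * pixel_um^2 / 1e6
    if (area_px == 0L) {
      warning("compute_densities: compartment '", comp,
              "' has zero area in field ", field_id, "; record suppressed",
              call. = FALSE)
      next
    }
    vv <- v[v$compartment == comp, , drop = FALSE]
    blood <- sum(vv$vessel_class == "blood")
    lymph <- sum(vv$vessel_class == "lymph")
    mature <- sum(vv$is_mature %in% TRUE & vv$vessel_class == "blood")
    ratio <- if (comp == "stroma" && blood > 0) mature / blood else NA_real_
    out[[comp]] <- data.frame(
      specimen_id = specimen_id, field_id = field_id, compartment = comp,
      compartment_area_mm2 = area_mm2,
      blood_count = blood, lymph_count = lymph, mature_count = mature,
      bvd_per_mm2 = blood / area_mm2, lvd_per_mm2 = lymph / area_mm2,
      pct_cd31_area = 100 * sum(cd31 & m) / area_px,
      pct_pdpn_area = 100 * sum(pdpn & m) / area_px,
      mature_ratio = ratio, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(specimen_id = character(0), field_id = character(0),
                      compartment = character(0),
                      compartment_area_mm2 = numeric(0),
                      blood_count = integer(0), lymph_count = integer(0),
                      mature_count = integer(0), bvd_per_mm2 = numeric(0),
                      lvd_per_mm2 = numeric(0), pct_cd31_area = numeric(0),
                      pct_pdpn_area = numeric(0), mature_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pool field records into per-specimen outcomes
#'
#' Specimens are summarized per compartment by pooling counts over the five
#' multispectral fields: total count divided by total compartment area (and
#' the area-weighted mean for percent-area outcomes). Pooling is robust to
#' unequal compartment areas across fields, unlike a plain mean of per-field
#' densities.
#'
#' @param records Field-level data frame from [compute_densities()] (rows
#'   from several fields of one or more specimens).
#' @return Data frame, one row per specimen x compartment, with pooled
#'   outcomes and the number of fields pooled.
#' @export
aggregate_specimen <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  key <- interaction(records$specimen_id, records$compartment, drop = TRUE)
  out <- lapply(split(records, key), function(r) {
    area <- sum(r$compartment_area_mm2)
    blood <- sum(r$blood_count); lymph <- sum(r$lymph_count)
    mature <- sum(r$mature_count)
    data.frame(
      specimen_id = r$specimen_id[1L], compartment = r$compartment[1L],
      n_fields = nrow(r), compartment_area_mm2 = area,
      blood_count = blood, lymph_count = lymph, mature_count = mature,
      bvd_per_mm2 = blood / area, lvd_per_mm2 = lymph / area,
      pct_cd31_area = sum(r$pct_cd31_area * r$compartment_area_mm2) / area,
      pct_pdpn_area = sum(r$pct_pdpn_area * r$compartment_area_mm2) / area,
      mature_ratio = if (r$compartment[1L] == "stroma" && blood > 0)
        mature / blood else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segment and quantify one field end to end
#'
#' Convenience wrapper running the binary-layer, compartment, vessel and
#' density stages on one [channel_stack()]. Channels with constant intensity
#' (possible in noise-free synthetic fields) yield empty layers rather than
#' an Otsu error.
#'
#' @param stack A [channel_stack()].
#' @param params See [quant_params()].
#' @return List: `records` (from [compute_densities()]), `vessels` (the
#'   classified `vessel_set`), `compartments`, and the cleaned `masks`.
#' @export
quantify_field <- function(stack, params = quant_params()) {
  px <- stack$pixel_um
  min_px <- max(1L, round(params$min_area_um2 / px^2))
  closing <- max(1L, round(params$closing_um / px))
  bin <- function(ch) {
    plane <- stack$planes[[ch]]
    if (diff(range(plane)) == 0) {
      return(as_binary_mask(matrix(FALSE, nrow(plane), ncol(plane)),
                            channel = ch))
    }
    binarize_channel(stack, ch, method = "otsu",
                     min_contrast = params$min_contrast,
                     floor_offset = params$floor_offset)
  }
  cd31 <- clean_mask(bin("CD31"), min_object_px = min_px,
                     closing_radius_px = closing)
  pdpn <- clean_mask(bin("PDPN"), min_object_px = min_px,
                     closing_radius_px = closing)
  asma <- clean_mask(bin("aSMA"), min_object_px = min_px,
                     closing_radius_px = closing)
  cd10 <- bin("CD10")
  dapi <- bin("DAPI")
  compartments <- build_compartment_masks(cd10, asma, dapi,
                                          min_object_px = min_px,
                                          closing_radius_px = 2L)
  objects <- label_objects(cd31, connectivity = 8)
  vset <- extract_vessels(objects, pdpn, compartments,
                          min_area_um2 = params$min_area_um2, pixel_um = px,
                          lymph_overlap_cut = params$lymph_overlap_cut)
  vset <- classify_maturity(vset, asma,
                            dilation_radius_px = max(1, round(params$maturity_dilation_um / px)),
                            overlap_cut = params$maturity_overlap_cut)
  records <- compute_densities(vset, compartments, cd31, pdpn, pixel_um = px,
                               specimen_id = stack$specimen_id,
                               field_id = stack$field_id)
  list(records = records, vessels = vset, compartments = compartments,
       masks = list(cd31 = cd31, pdpn = pdpn, asma = asma, cd10 = cd10,
                    dapi = dapi))
}
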