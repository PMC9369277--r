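#' Threshold a marker channel into a binary layer
#'
#' Converts one intensity plane into the binary layer used for automated
#' counting. With `method = "otsu"` the threshold maximizes the between-class
#' variance over 256 histogram bins (computed by [EBImage::otsu()]); with
#' `method = "fixed"` the caller supplies it. A pixel is positive iff its
#' intensity is greater than or equal to the threshold. The threshold actually
#' applied is recorded in the result for audit.
#'
#' Real multiplex panels include channels with no specific signal in a given
#' field (e.g. CD10 in pure myometrium). Otsu always returns *some* split, so
#' a minimum foreground/background contrast guard (`min_contrast`, on the
#' `[0, 1]` intensity scale) empties the mask when the two classes are closer
#' than biologically plausible staining; set it to 0 to disable.
#'
#' @param stack A [channel_stack()].
#' @param channel Channel name (one of [VQ_CHANNELS]).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold in `[0, 1]`; required when `method = "fixed"`.
#' @param min_contrast Minimum Otsu class-mean separation (default 0.15).
#' @param floor_offset If positive, the Otsu threshold is floored at the
#'   5th intensity percentile plus `floor_offset`. Otsu's split is unstable when specific
#'   staining covers a tiny pixel fraction (a single vessel in a field); the
#'   floor keeps such thresholds out of the background mode while leaving
#'   well-separated splits untouched. 0 (default) disables the floor.
#' @param uniform_level Mean plane intensity above which a field failing the
#'   contrast guard is treated as uniformly stained (mask all-positive)
#'   rather than unstained (mask empty). Distinguishes bulk staining with no
#'   background in the field (e.g. alpha-SMA in pure myometrium) from a
#'   channel with no specific signal.
#' @return A `binary_mask`: list with `pixels` (logical matrix), `channel`,
#'   `method`, `threshold_used`.
#' @export
binarize_channel <- function(stack, channel, method = c("otsu", "fixed"),
                             fixed_threshold = NULL, min_contrast = 0.15,
                             floor_offset = 0, uniform_level = 0.4) {
  stopifnot(inherits(stack, "channel_stack"))
  method <- match.arg(method)
  if (!channel %in% names(stack$planes)) {
    stop("binarize_channel: channel not present: ", channel, call. = FALSE)
  }
  plane <- stack$planes[[channel]]
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("binarize_channel: fixed_threshold required for method = 'fixed'",
           call. = FALSE)
    }
    thr <- fixed_threshold
    px <- plane >= thr
  } else {
    rng <- range(plane)
    if (diff(rng) == 0) {
      stop("binarize_channel: channel '", channel,
           "' has constant intensity; Otsu is undefined - use method = 'fixed'",
           call. = FALSE)
    }
    contrast <- function(px) {
      if (!any(px) || all(px)) return(NA_real_)
      mean(plane[px]) - mean(plane[!px])
    }
    thr <- EBImage::otsu(EBImage::Image(plane), range = c(0, 1), levels = 256)
    px <- plane >= thr
    if (min_contrast > 0 && !isTRUE(contrast(px) >= min_contrast)) {
      # Otsu's split is not a background/signal separation. Three causes:
      # (a) sparse staining (one vessel in the field) pulls the threshold
      #     into the background mode - rescue with a background-floored
      #     threshold (5th percentile + floor_offset);
      # (b) uniform staining with no background in the field (bulk aSMA in
      #     pure myometrium) - the whole plane is positive;
      # (c) no specific signal at all - the mask is empty.
      rescued <- FALSE
      if (floor_offset > 0) {
        thr2 <- stats::quantile(plane, 0.05, names = FALSE) + floor_offset
        px2 <- plane >= thr2
        if (isTRUE(contrast(px2) >= min_contrast)) {
          thr <- thr2; px <- px2; rescued <- TRUE
        }
      }
      if (!rescued) {
        if (mean(plane) >= uniform_level) {
          thr <- rng[1L]; px[] <- TRUE
        } else {
          px[] <- FALSE
        }
      }
    }
  }
  structure(list(pixels = px, channel = channel, method = method,
                 threshold_used = thr),
            class = "binary_mask")
}

#' Wrap a logical matrix as a binary mask
#' @param pixels Logical matrix.
#' @param channel Channel name label.
#' @param method,threshold_used Audit fields.
#' @export
as_binary_mask <- function(pixels, channel = "manual", method = "fixed",
                           threshold_used = NA_real_) {
  stopifnot(is.logical(pixels), is.matrix(pixels))
  structure(list(pixels = pixels, channel = channel, method = method,
                 threshold_used = threshold_used),
            class = "binary_mask")
}

mask_pixels <- function(x) {
  if (inherits(x, "binary_mask")) x$pixels else x
}

#' Morphologically clean a binary layer
#'
#' Closes small dropouts with a disc-shaped structuring element, then removes
#' connected components (8-connectivity) smaller than `min_object_px`. The
#' operation is idempotent for fixed parameters.
#'
#' @param mask A `binary_mask` (or logical matrix).
#' @param min_object_px Minimum component size in pixels (default 20, i.e.
#'   5 um^2 at 0.5 um/px - below any capillary cross-section).
#' @param closing_radius_px Disc radius for morphological closing (0 = skip).
#' @return A `binary_mask`.
#' @export
clean_mask <- function(mask, min_object_px = 20L, closing_radius_px = 1L) {
  stopifnot(min_object_px >= 0, closing_radius_px >= 0)
  px <- mask_pixels(mask)
  if (closing_radius_px > 0 && any(px)) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
    px <- EBImage::imageData(EBImage::closing(EBImage::Image(px * 1), brush)) > 0.5
  }
  if (min_object_px > 0 && any(px)) {
    lab <- label_objects(px, connectivity = 8)
    sizes <- tabulate(lab$labels[lab$labels > 0L])
    drop <- which(sizes < min_object_px)
    if (length(drop)) px[lab$labels %in% drop] <- FALSE
  }
  m <- if (inherits(mask, "binary_mask")) mask else as_binary_mask(px)
  m$pixels <- px
  m
}

#' Label connected components of a binary layer
#'
#' Endothelial cells and cell clusters are counted as connected components of
#' the binary layer. Connectivity 4 counts only edge-adjacent pixels as
#' connected; connectivity 8 (the default elsewhere in the pipeline) also
#' joins diagonals, so ring-shaped vessel walls do not fragment.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param connectivity 4 or 8.
#' @return A `labeled_objects` object: `labels` (integer matrix, 0 =
#'   background, labels consecutive `1..K`) and `table` (per-label pixel
#'   count, centroid, bounding box).
#' @export
label_objects <- function(mask, connectivity = 8) {
  px <- mask_pixels(mask)
  stopifnot(is.logical(px), connectivity %in% c(4, 8))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(px * 1)))
  storage.mode(lab) <- "integer"
  if (connectivity == 8 && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  k <- max(lab)
  if (k > 0L) {
    ij <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[ij]
    tab <- data.frame(
      label = seq_len(k),
      area_px = as.vector(tabulate(l, k)),
      centroid_row = as.vector(tapply(ij[, 1], l, mean)),
      centroid_col = as.vector(tapply(ij[, 2], l, mean)),
      row_min = as.vector(tapply(ij[, 1], l, min)),
      row_max = as.vector(tapply(ij[, 1], l, max)),
      col_min = as.vector(tapply(ij[, 2], l, min)),
      col_max = as.vector(tapply(ij[, 2], l, max)))
  } else {
    tab <- data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      row_min = integer(0), row_max = integer(0),
                      col_min = integer(0), col_max = integer(0))
  }
  structure(list(labels = lab, table = tab, connectivity = connectivity),
            class = "labeled_objects")
}

# Merge 4-connectivity labels that touch diagonally (union-find over the
# label graph), then relabel consecutively. Vectorized over the two diagonal
# shift directions.
merge_diagonal_labels <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  pairs <- NULL
  a <- lab[-h, -w]; b <- lab[-1, -1]            # down-right diagonal
  s <- a > 0L & b > 0L & a != b
  if (any(s)) pairs <- rbind(pairs, cbind(a[s], b[s]))
  a <- lab[-1, -w]; b <- lab[-h, -1]            # up-right diagonal
  s <- a > 0L & b > 0L & a != b
  if (any(s)) pairs <- rbind(pairs, cbind(a[s], b[s]))
  k <- max(lab)
  if (is.null(pairs) || k == 0L) return(relabel_consecutive(lab))
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, 1L)
  map <- c(0L, as.integer(root))
  lab[] <- map[lab + 1L]
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(as.vector(lab)))
  u <- u[u > 0L]
  if (!length(u)) return(lab)
  map <- integer(max(u) + 1L)
  map[u + 1L] <- seq_along(u)
  lab[] <- map[lab + 1L]
  lab
}

#' Delineate tissue compartments from the CD10, aSMA and DAPI layers
#'
#' Produces four mutually exclusive masks that cover the field: endometrial
#' stroma (cleaned CD10 area), glands (enclosed CD10-negative holes inside
#' the endometrial tissue that contain nuclei), myometrium (cleaned aSMA area
#' minus endometrial tissue - stroma takes precedence on overlap, so vascular
#' aSMA rings inside the endometrium are not counted as myometrium), and
#' background (the remainder).
#'
#' @param cd10,asma,dapi `binary_mask` objects (or logical matrices) from the
#'   respective channels, sharing dimensions.
#' @param vessel_masks Optional list of vessel-channel masks (currently
#'   unused by the partition rule; accepted for interface stability).
#' @param min_object_px,closing_radius_px Cleaning parameters applied to the
#'   CD10 and aSMA layers (see [clean_mask()]). Compartment-scale cleaning
#'   uses a larger size floor (`min_object_px * 10`) than vessel layers.
#' @param gland_dapi_min Minimum fraction of DAPI-positive pixels for an
#'   enclosed hole to count as a gland (epithelial lining) rather than an
#'   artefactual dropout. Default 0.02.
#' @return A `compartment_masks` object: logical matrices `stroma`, `glands`,
#'   `myometrium`, `background` (pairwise disjoint, jointly exhaustive).
#' @export
build_compartment_masks <- function(cd10, asma, dapi, vessel_masks = NULL,
                                    min_object_px = 20L, closing_radius_px = 2L,
                                    gland_dapi_min = 0.02) {
  cd10 <- mask_pixels(cd10); asma <- mask_pixels(asma); dapi <- mask_pixels(dapi)
  if (!all(dim(cd10) == dim(asma)) || !all(dim(cd10) == dim(dapi))) {
    stop("build_compartment_masks: mask dimensions differ", call. = FALSE)
  }
  big <- as.integer(min_object_px) * 10L
  stroma <- clean_mask(cd10, min_object_px = big,
                       closing_radius_px = closing_radius_px)$pixels
  asma_c <- clean_mask(asma, min_object_px = min_object_px,
                       closing_radius_px = closing_radius_px)$pixels

  glands <- matrix(FALSE, nrow(cd10), ncol(cd10))
  if (any(stroma)) {
    tissue <- EBImage::imageData(EBImage::fillHull(EBImage::Image(stroma * 1))) > 0.5
    holes <- tissue & !stroma
    if (any(holes)) {
      hl <- label_objects(holes, connectivity = 8)
      if (nrow(hl$table) > 0) {
        dfrac <- vapply(seq_len(nrow(hl$table)), function(i) {
          mean(dapi[hl$labels == i])
        }, 0)
        keep <- hl$table$label[dfrac >= gland_dapi_min]
        glands <- hl$labels %in% keep
        dim(glands) <- dim(holes)
      }
    }
  }
  myometrium <- asma_c & !stroma & !glands
  background <- !(stroma | glands | myometrium)
  structure(list(stroma = stroma, glands = glands, myometrium = myometrium,
                 background = background),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  n <- prod(dim(x$stroma))
  cat(sprintf("<compartment_masks> stroma %.1f%%, glands %.1f%%, myometrium %.1f%%, background %.1f%%\n",
              100 * sum(x$stroma) / n, 100 * sum(x$glands) / n,
              100 * sum(x$myometrium) / n, 100 * sum(x$background) / n))
  invisible(x)
}
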