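#' Configure one synthetic tissue specimen
#'
#' Describes one specimen of the emulated study design: its group and tissue
#' type, cycle phase, medication status, imaging geometry (five multispectral
#' fields of 0.9 x 0.7 mm by default), and the planted ground truth (vessel
#' densities, mature-vessel fraction, VEGF immunoreactivity per compartment,
#' lesion depth) that the quantification pipeline is expected to recover.
#'
#' @param group `"adenomyosis"` or `"control"`.
#' @param tissue_type One of `"eutopic_endometrium"`, `"ectopic_endometrium"`,
#'   `"myometrium"`, `"control_endometrium"`.
#' @param cycle_phase `"proliferative"` or `"secretory"` (metadata label).
#' @param medication `"none_other"` or `"antiangiogenic"` (metadata label).
#' @param n_fields Number of multispectral fields per specimen (default 5).
#' @param field_mm Field width and height in mm (default `c(0.9, 0.7)`, the
#'   x200 field of a Vectra-class scanner).
#' @param pixel_um Pixel edge length in micrometres (default 0.5).
#' @param planted_bvd,planted_lvd Blood / lymph vessels per mm^2 of the
#'   vessel-bearing compartment (endometrial stroma, or myometrium for
#'   myometrium specimens).
#' @param planted_mature_fraction Fraction of planted blood vessels rendered
#'   with a concentric alpha-SMA mural ring, in `[0, 1]`.
#' @param planted_vegf Named list per compartment (`stroma`, `glands`,
#'   `myometrium`), each `c(fraction, level)`: fraction of cells painted
#'   VEGF-positive in `[0, 1]` and staining intensity level 0-4.
#' @param lesion_depth_mm Myometrial invasion depth of ectopic foci (mm);
#'   ground-truth disease label via [classify_adenomyosis()].
#' @param noise Named numeric: `background` (additive offset), `sigma`
#'   (Gaussian noise SD), `bleedthrough` (fraction of each channel added to
#'   its spectral neighbours). All on the `[0, 1]` intensity scale.
#' @param seed Integer seed; rendering is pure in `(seed, field_index)`.
#' @param specimen_id Identifier carried into every record.
#' @return A validated `specimen_config` object.
#' @export
specimen_config <- function(group = c("control", "adenomyosis"),
                            tissue_type = c("control_endometrium",
                                            "eutopic_endometrium",
                                            "ectopic_endometrium",
                                            "myometrium"),
                            cycle_phase = c("proliferative", "secretory"),
                            medication = c("none_other", "antiangiogenic"),
                            n_fields = 5L,
                            field_mm = c(0.9, 0.7),
                            pixel_um = 0.5,
                            planted_bvd = 30,
                            planted_lvd = 8,
                            planted_mature_fraction = 0.6,
                            planted_vegf = list(stroma = c(0.05, 1),
                                                glands = c(0.65, 1),
                                                myometrium = c(0.30, 2)),
                            lesion_depth_mm = 0,
                            noise = c(background = 0.05, sigma = 0.02,
                                      bleedthrough = 0),
                            seed = 1L,
                            specimen_id = "specimen1") {
  group <- match.arg(group)
  tissue_type <- match.arg(tissue_type)
  cycle_phase <- match.arg(cycle_phase)
  medication <- match.arg(medication)
  stopifnot(n_fields >= 1, length(field_mm) == 2L, all(field_mm > 0),
            pixel_um > 0, planted_bvd >= 0, planted_lvd >= 0,
            planted_mature_fraction >= 0, planted_mature_fraction <= 1,
            lesion_depth_mm >= 0)
  noise <- c(background = unname(noise["background"] %||% noise[1]),
             sigma = unname(noise["sigma"] %||% noise[2]),
             bleedthrough = unname(noise["bleedthrough"] %||% noise[3]))
  noise[is.na(noise)] <- 0
  stopifnot(all(noise >= 0), noise["bleedthrough"] <= 1)
  for (cmp in names(planted_vegf)) {
    v <- planted_vegf[[cmp]]
    stopifnot(length(v) == 2L, v[1] >= 0, v[1] <= 1, v[2] %in% 0:4)
  }
  structure(list(group = group, tissue_type = tissue_type,
                 cycle_phase = cycle_phase, medication = medication,
                 n_fields = as.integer(n_fields), field_mm = field_mm,
                 pixel_um = pixel_um, planted_bvd = planted_bvd,
                 planted_lvd = planted_lvd,
                 planted_mature_fraction = planted_mature_fraction,
                 planted_vegf = planted_vegf,
                 lesion_depth_mm = lesion_depth_mm, noise = noise,
                 seed = as.integer(seed), specimen_id = specimen_id),
            class = "specimen_config")
}

#' Ground-truth adenomyosis label from lesion depth
#'
#' A specimen is labelled adenomyotic iff ectopic endometrial tissue invades
#' the myometrium strictly deeper than the threshold (default 2.5 mm).
#'
#' @param lesion_depth_mm Invasion depth, mm (finite, nonnegative).
#' @param threshold_mm Invasion threshold, mm (default 2.5).
#' @return Logical.
#' @export
classify_adenomyosis <- function(lesion_depth_mm, threshold_mm = 2.5) {
  stopifnot(is.numeric(lesion_depth_mm), is.finite(lesion_depth_mm),
            is.numeric(threshold_mm), is.finite(threshold_mm), threshold_mm > 0)
  if (any(lesion_depth_mm < 0)) {
    stop("classify_adenomyosis: negative lesion depth", call. = FALSE)
  }
  lesion_depth_mm > threshold_mm
}

# -- internal geometry helpers -----------------------------------------------

# Rejection-sample n points inside `mask` with pairwise distance >= min_dist_px
# (enforced via a growing blocked-pixel mask). Returns a 2-column matrix of
# (row, col); may return fewer than n points when the mask saturates.
place_points <- function(mask, n, min_dist_px) {
  out <- matrix(numeric(0), 0L, 2L)
  idx <- which(mask)
  if (!length(idx) || n <= 0) return(out)
  h <- nrow(mask)
  blocked <- matrix(FALSE, h, ncol(mask))
  pts <- matrix(0, n, 2L)
  k <- 0L; attempts <- 0L; max_attempts <- as.integer(n * 40L)
  while (k < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    i <- idx[sample.int(length(idx), 1L)]
    r <- ((i - 1L) %% h) + 1L
    c <- ((i - 1L) %/% h) + 1L
    if (blocked[r, c]) next
    k <- k + 1L
    pts[k, ] <- c(r, c)
    blocked[annulus_idx(dim(blocked), r, c, min_dist_px)] <- TRUE
  }
  pts[seq_len(k), , drop = FALSE]
}

# Probe ring: TRUE iff the disk of radius r_px around (row, col) lies inside
# the field and (approximately) inside `mask`, tested at the centre plus 12
# points on the circle.
probe_inside <- function(mask, row0, col0, r_px) {
  h <- nrow(mask); w <- ncol(mask)
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  pr <- round(c(row0, row0 + r_px * sin(ang)))
  pc <- round(c(col0, col0 + r_px * cos(ang)))
  if (any(pr < 1 | pr > h | pc < 1 | pc > w)) return(FALSE)
  all(mask[cbind(pr, pc)])
}

# Tissue geometry per tissue type: logical masks for stroma, glands,
# myometrium plus gland-boundary nucleus positions. Consumes RNG.
build_geometry <- function(tissue_type, dim_hw, pixel_um) {
  h <- dim_hw[1]; w <- dim_hw[2]
  none <- matrix(FALSE, h, w)
  glands <- none
  gland_nuclei <- matrix(numeric(0), 0L, 2L)

  add_gland <- function(glands, row0, col0, a_px, b_px, theta) {
    ellipse_mask(c(h, w), row0, col0, a_px, b_px, theta) | glands
  }
  gland_boundary_pts <- function(row0, col0, a_px, b_px, theta) {
    per_um <- pi * (3 * (a_px + b_px) -
                    sqrt((3 * a_px + b_px) * (a_px + 3 * b_px))) * pixel_um
    npt <- max(6L, round(per_um / 7.5))
    t <- seq(0, 2 * pi, length.out = npt + 1L)[-1L]
    u <- 0.82 * a_px * cos(t); v <- 0.82 * b_px * sin(t)
    cbind(row0 + u * sin(theta) + v * cos(theta),
          col0 + u * cos(theta) - v * sin(theta))
  }

  if (tissue_type == "myometrium") {
    return(list(stroma = none, glands = none,
                myometrium = matrix(TRUE, h, w), gland_nuclei = gland_nuclei))
  }

  if (tissue_type %in% c("eutopic_endometrium", "control_endometrium")) {
    tissue <- matrix(TRUE, h, w)
    area_mm2 <- h * w * pixel_um^2 / 1e6
    n_g <- max(1L, round(13 * area_mm2))          # ~13 glands / mm^2
    centers <- matrix(numeric(0), 0L, 3L)         # row, col, rmax
    for (g in seq_len(n_g)) {
      a <- stats::runif(1, 35, 80) / pixel_um     # semi-axes 35-80 um
      b <- stats::runif(1, 30, 60) / pixel_um
      th <- stats::runif(1, 0, pi)
      rmax <- max(a, b)
      placed <- FALSE
      for (try in 1:60) {
        r0 <- stats::runif(1, rmax + 4, h - rmax - 4)
        c0 <- stats::runif(1, rmax + 4, w - rmax - 4)
        if (nrow(centers) == 0L ||
            all(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) >
                centers[, 3] + rmax + 10 / pixel_um)) {
          placed <- TRUE; break
        }
      }
      if (!placed) next
      glands <- add_gland(glands, r0, c0, a, b, th)
      centers <- rbind(centers, c(r0, c0, rmax))
      gland_nuclei <- rbind(gland_nuclei, gland_boundary_pts(r0, c0, a, b, th))
    }
    stroma <- tissue & !glands
    return(list(stroma = stroma, glands = glands, myometrium = none,
                gland_nuclei = gland_nuclei))
  }

  # ectopic endometrium: CD10+ islands embedded in an aSMA+ myometrial bed
  islands <- none
  centers <- matrix(numeric(0), 0L, 3L)
  for (k in 1:3) {
    a <- stats::runif(1, 130, 220) / pixel_um
    b <- stats::runif(1, 110, 180) / pixel_um
    th <- stats::runif(1, 0, pi)
    rmax <- max(a, b)
    placed <- FALSE
    for (try in 1:80) {
      r0 <- stats::runif(1, rmax + 4, h - rmax - 4)
      c0 <- stats::runif(1, rmax + 4, w - rmax - 4)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) >
              centers[, 3] + rmax + 20 / pixel_um)) {
        placed <- TRUE; break
      }
    }
    if (!placed) next
    islands <- islands | ellipse_mask(c(h, w), r0, c0, a, b, th)
    centers <- rbind(centers, c(r0, c0, rmax))
    rmin <- min(a, b)
    for (g in 1:2) {                              # small glands inside focus
      ga <- stats::runif(1, 25, 50) / pixel_um
      gb <- stats::runif(1, 20, 40) / pixel_um
      gth <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0, 0.45 * rmin - max(ga, gb))
      if (is.na(off) || off < 0) next
      oan <- stats::runif(1, 0, 2 * pi)
      gr <- r0 + off * sin(oan); gc <- c0 + off * cos(oan)
      glands <- add_gland(glands, gr, gc, ga, gb, gth)
      gland_nuclei <- rbind(gland_nuclei, gland_boundary_pts(gr, gc, ga, gb, gth))
    }
  }
  glands <- glands & islands
  stroma <- islands & !glands
  list(stroma = stroma, glands = glands, myometrium = !islands,
       gland_nuclei = gland_nuclei)
}

# -- field generation --------------------------------------------------------

#' Render one synthetic multichannel field with ground truth
#'
#' Renders the six marker channels of one field: CD10 fills the endometrial
#' stroma minus elliptical glands (or CD10-positive ectopic islands inside an
#' alpha-SMA myometrial bed), alpha-SMA fills the myometrium plus concentric
#' mural rings around the mature fraction of blood vessels, CD31 annuli mark
#' every planted blood vessel, podoplanin annuli mark lymphatics, DAPI marks
#' nuclei, and VEGF is painted over the planted fraction of cells at the
#' planted intensity level. Rendering is pure in `(config$seed, field_index)`:
#' repeated calls are bit-identical.
#'
#' @param config A [specimen_config()].
#' @param field_index Field number, `1..config$n_fields`.
#' @param keep_masks Keep the true compartment masks in the ground truth
#'   (needed by validation tests; disable to save memory in cohort loops).
#' @return A list with elements `stack` (a [channel_stack()]) and `truth`:
#'   planted vessel table (`vessels`), per-compartment areas in mm^2 and true
#'   densities (`summary`), planted VEGF settings, lesion depth and disease
#'   label, and (optionally) the true compartment masks.
#' @export
generate_field <- function(config, field_index = 1L, keep_masks = TRUE) {
  stopifnot(inherits(config, "specimen_config"),
            field_index >= 1L, field_index <= config$n_fields)
  set.seed(derive_seed(config$seed, sprintf("field%04d", field_index)))

  px <- config$pixel_um
  w <- round(config$field_mm[1] * 1000 / px)
  h <- round(config$field_mm[2] * 1000 / px)
  geo <- build_geometry(config$tissue_type, c(h, w), px)
  px2mm2 <- px^2 / 1e6
  areas <- c(stroma = sum(geo$stroma), glands = sum(geo$glands),
             myometrium = sum(geo$myometrium)) * px2mm2

  vessel_bed <- if (config$tissue_type == "myometrium") "myometrium" else "stroma"
  bed_mask <- geo[[vessel_bed]]
  bed_area <- areas[[vessel_bed]]

  n_blood <- round(config$planted_bvd * bed_area)
  n_lymph <- round(config$planted_lvd * bed_area)
  n_mature <- round(config$planted_mature_fraction * n_blood)

  # sample vessel geometry first so RNG use is independent of placement order
  vs <- data.frame(
    class = rep(c("blood", "lymph"), c(n_blood, n_lymph)),
    radius_um = c(if (n_blood) stats::runif(n_blood, 4, 15) else numeric(0),
                  if (n_lymph) stats::runif(n_lymph, 8, 20) else numeric(0)),
    wall_um = c(if (n_blood) stats::runif(n_blood, 2, 3) else numeric(0),
                if (n_lymph) rep(2, n_lymph) else numeric(0)),
    has_asma_ring = rep(FALSE, n_blood + n_lymph), stringsAsFactors = FALSE)
  if (n_blood > 0 && n_mature > 0) {
    vs$has_asma_ring[sample.int(n_blood, n_mature)] <- TRUE
  }
  gap_um <- if (nrow(vs)) stats::runif(nrow(vs), 1, 2) else numeric(0)
  mural_wall_um <- 2

  # placement: full footprint inside the vessel bed, no mutual overlap
  vs$row <- vs$col <- rep(NA_real_, nrow(vs))
  placed_r <- placed_c <- placed_ext <- numeric(0)
  sep_px <- 6 / px
  bed_idx <- which(bed_mask)
  if (nrow(vs) > 0 && !length(bed_idx)) {
    stop("generate_field: vessel bed compartment is empty in ",
         config$specimen_id, call. = FALSE)
  }
  for (i in seq_len(nrow(vs))) {
    ext_um <- vs$radius_um[i] +
      if (vs$has_asma_ring[i]) gap_um[i] + mural_wall_um + 1 else 1
    ext_px <- ext_um / px
    ok <- FALSE
    for (try in 1:400) {
      j <- bed_idx[sample.int(length(bed_idx), 1L)]
      r0 <- ((j - 1L) %% h) + 1L
      c0 <- ((j - 1L) %/% h) + 1L
      if (!probe_inside(bed_mask, r0, c0, ext_px)) next
      if (length(placed_r) &&
          any(sqrt((placed_r - r0)^2 + (placed_c - c0)^2) <
              placed_ext + ext_px + sep_px)) next
      ok <- TRUE; break
    }
    if (!ok) {
      stop(sprintf(
        "generate_field: could not place vessel %d/%d in %s field %d without overlap",
        i, nrow(vs), config$specimen_id, field_index), call. = FALSE)
    }
    vs$row[i] <- r0; vs$col[i] <- c0
    placed_r <- c(placed_r, r0); placed_c <- c(placed_c, c0)
    placed_ext <- c(placed_ext, ext_px)
  }
  vs$compartment <- rep(vessel_bed, nrow(vs))

  # nuclei: stromal/myometrial cells plus gland epithelium
  nuc <- matrix(numeric(0), 0L, 2L); nuc_comp <- character(0)
  if (sum(geo$stroma) > 0) {
    p <- place_points(geo$stroma, round(2000 * areas[["stroma"]]), 7 / px)
    nuc <- rbind(nuc, p); nuc_comp <- c(nuc_comp, rep("stroma", nrow(p)))
  }
  if (sum(geo$myometrium) > 0) {
    p <- place_points(geo$myometrium, round(1500 * areas[["myometrium"]]), 7.5 / px)
    nuc <- rbind(nuc, p); nuc_comp <- c(nuc_comp, rep("myometrium", nrow(p)))
  }
  if (nrow(geo$gland_nuclei) > 0) {
    keep <- geo$gland_nuclei[, 1] >= 1 & geo$gland_nuclei[, 1] <= h &
            geo$gland_nuclei[, 2] >= 1 & geo$gland_nuclei[, 2] <= w
    p <- geo$gland_nuclei[keep, , drop = FALSE]
    nuc <- rbind(nuc, p); nuc_comp <- c(nuc_comp, rep("glands", nrow(p)))
  }

  # render channels (signal layer, before noise)
  zero <- matrix(0, h, w)
  planes <- list(DAPI = zero, CD31 = zero, aSMA = zero, PDPN = zero,
                 CD10 = zero, VEGF = zero)
  planes$CD10[geo$stroma] <- 0.8
  planes$aSMA[geo$myometrium] <- 0.75

  nuc_r_px <- 2.5 / px
  dapi <- planes$DAPI
  for (i in seq_len(nrow(nuc))) {
    dapi[annulus_idx(c(h, w), nuc[i, 1], nuc[i, 2], nuc_r_px)] <- 0.8
  }
  planes$DAPI <- dapi

  wall_floor_px <- 1.4                    # keep rasterized rings connected
  cd31 <- planes$CD31; pdpn <- planes$PDPN; asma <- planes$aSMA
  for (i in seq_len(nrow(vs))) {
    r_out <- vs$radius_um[i] / px
    r_in <- max(r_out - max(vs$wall_um[i] / px, wall_floor_px), 0)
    ii <- annulus_idx(c(h, w), vs$row[i], vs$col[i], r_out, r_in)
    if (vs$class[i] == "blood") cd31[ii] <- 0.85 else pdpn[ii] <- 0.85
    if (vs$has_asma_ring[i]) {
      m_in <- r_out + gap_um[i] / px
      m_out <- m_in + max(mural_wall_um / px, wall_floor_px)
      ii <- annulus_idx(c(h, w), vs$row[i], vs$col[i], m_out, m_in)
      asma[ii] <- pmax(asma[ii], 0.85)
    }
  }
  planes$CD31 <- cd31; planes$PDPN <- pdpn; planes$aSMA <- asma

  # VEGF: paint the planted fraction of cells per compartment at level/4
  cell_r_px <- 4 / px
  for (cmp in names(config$planted_vegf)) {
    v <- config$planted_vegf[[cmp]]
    ids <- which(nuc_comp == cmp)
    k <- round(v[1] * length(ids))
    if (k > 0 && v[2] > 0) {
      sel <- ids[sample.int(length(ids), k)]
      amp <- 0.25 * v[2]
      vegf <- planes$VEGF
      for (i in sel) {
        ii <- annulus_idx(c(h, w), nuc[i, 1], nuc[i, 2], cell_r_px)
        vegf[ii] <- pmax(vegf[ii], amp)
      }
      planes$VEGF <- vegf
    }
  }

  # noise model: bleed-through between spectral neighbours, then additive
  # background and Gaussian noise, clamped and quantized to the 16-bit grid
  noise <- config$noise
  if (noise[["bleedthrough"]] > 0) {
    f <- noise[["bleedthrough"]]
    sig <- planes
    for (i in seq_along(VQ_CHANNELS)) {
      nb <- c(i - 1L, i + 1L)
      nb <- nb[nb >= 1L & nb <= length(VQ_CHANNELS)]
      for (j in nb) {
        planes[[VQ_CHANNELS[j]]] <- planes[[VQ_CHANNELS[j]]] +
          f * sig[[VQ_CHANNELS[i]]]
      }
    }
  }
  for (ch in VQ_CHANNELS) {
    p <- planes[[ch]] + noise[["background"]]
    if (noise[["sigma"]] > 0) {
      p <- p + matrix(stats::rnorm(h * w, 0, noise[["sigma"]]), h, w)
    }
    planes[[ch]] <- quantize16(p)
  }

  field_id <- sprintf("%s_f%02d", config$specimen_id, field_index)
  stack <- channel_stack(planes, pixel_um = px, field_id = field_id,
                         specimen_id = config$specimen_id)

  blood_in <- sum(vs$class == "blood")
  lymph_in <- sum(vs$class == "lymph")
  truth <- list(
    field_id = field_id, specimen_id = config$specimen_id,
    vessels = vs[, c("class", "row", "col", "radius_um", "wall_um",
                     "has_asma_ring", "compartment")],
    mural_gap_um = gap_um,
    summary = data.frame(
      field_id = field_id, compartment = vessel_bed,
      area_mm2 = bed_area,
      blood_count = blood_in, lymph_count = lymph_in,
      true_bvd = blood_in / bed_area, true_lvd = lymph_in / bed_area,
      true_mature_ratio = if (vessel_bed == "stroma" && blood_in > 0)
        sum(vs$has_asma_ring[vs$class == "blood"]) / blood_in else NA_real_,
      stringsAsFactors = FALSE),
    areas_mm2 = areas,
    planted_vegf = config$planted_vegf,
    lesion_depth_mm = config$lesion_depth_mm,
    is_adenomyosis = classify_adenomyosis(config$lesion_depth_mm))
  if (keep_masks) {
    truth$masks <- list(stroma = geo$stroma, glands = geo$glands,
                        myometrium = geo$myometrium)
  }
  list(stack = stack, truth = truth)
}
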