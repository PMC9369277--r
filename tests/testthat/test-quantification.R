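# Compartment fixture: left half stroma, right half myometrium.
split_compartments <- function(h = 100, w = 200, split = 100) {
  stroma <- matrix(FALSE, h, w); stroma[, seq_len(split)] <- TRUE
  myo <- matrix(FALSE, h, w); myo[, (split + 1):w] <- TRUE
  structure(list(stroma = stroma, glands = matrix(FALSE, h, w),
                 myometrium = myo,
                 background = !(stroma | myo)),
            class = "compartment_masks")
}

test_that("vessel classification: CD31-only blood, podoplanin-involved lymph", {
  cm <- split_compartments()
  cd31 <- matrix(FALSE, 100, 200)
  cd31 <- mat_disk(cd31, 30, 30, 6, 3, TRUE)      # blood ring, no PDPN
  cd31 <- mat_disk(cd31, 70, 60, 6, 3, TRUE)      # CD31+PDPN ring -> lymph
  pdpn <- matrix(FALSE, 100, 200)
  pdpn <- mat_disk(pdpn, 70, 60, 6, 3, TRUE)
  pdpn <- mat_disk(pdpn, 30, 150, 8, 5, TRUE)     # PDPN-only -> lymph (myo)
  vs <- extract_vessels(label_objects(cd31), pdpn, cm, min_area_um2 = 2,
                        pixel_um = 1)
  v <- vs$vessels[order(vs$vessels$centroid_col), ]
  expect_identical(v$vessel_class, c("blood", "lymph", "lymph"))
  expect_identical(v$compartment, c("stroma", "stroma", "myometrium"))
  # background-majority objects are dropped
  cm0 <- cm; cm0$stroma[] <- FALSE; cm0$background <- !cm0$myometrium
  vs0 <- extract_vessels(label_objects(cd31), pdpn, cm0, min_area_um2 = 2,
                         pixel_um = 1)
  expect_identical(nrow(vs0$vessels), 1L)          # only the myometrial one
})

test_that("maturity requires alpha-SMA on the dilated boundary", {
  cm <- split_compartments()
  cd31 <- mat_disk(matrix(FALSE, 100, 200), 40, 40, 6, 3, TRUE)
  cd31 <- mat_disk(cd31, 40, 80, 6, 3, TRUE)
  asma <- mat_disk(matrix(FALSE, 100, 200), 40, 40, 10, 7, TRUE)  # mural ring
  vs <- extract_vessels(label_objects(cd31), matrix(FALSE, 100, 200), cm,
                        min_area_um2 = 2, pixel_um = 1)
  vs <- classify_maturity(vs, asma, dilation_radius_px = 5, overlap_cut = 0.1)
  v <- vs$vessels[order(vs$vessels$centroid_col), ]
  expect_true(v$is_mature[1])
  expect_false(v$is_mature[2])
  expect_identical(v$asma_boundary_overlap[2], 0)
  # all-false aSMA: overlap 0 everywhere
  vs2 <- classify_maturity(vs, matrix(FALSE, 100, 200))
  expect_true(all(vs2$vessels$asma_boundary_overlap == 0))
  # lymph vessels cannot carry maturity
  pdpn <- mat_disk(matrix(FALSE, 100, 200), 70, 40, 6, 3, TRUE)
  vs3 <- extract_vessels(label_objects(cd31), pdpn, cm, 2, 1)
  lymph_id <- vs3$vessels$vessel_id[vs3$vessels$vessel_class == "lymph"]
  expect_error(classify_maturity(vs3, asma, vessel_ids = lymph_id),
               "blood vessels only")
})

test_that("density arithmetic follows the definitional formulas", {
  # 0.5 mm^2 stroma at 5 um/px -> 20000 px = 100 x 200
  cm <- structure(list(stroma = matrix(TRUE, 100, 200),
                       glands = matrix(FALSE, 100, 200),
                       myometrium = matrix(FALSE, 100, 200),
                       background = matrix(FALSE, 100, 200)),
                  class = "compartment_masks")
  cd31 <- matrix(FALSE, 100, 200)
  centers <- cbind(c(20, 20, 50, 80, 80), c(30, 100, 170, 40, 140))
  for (i in 1:5) cd31 <- mat_disk(cd31, centers[i, 1], centers[i, 2], 4, 0, TRUE)
  vs <- extract_vessels(label_objects(cd31), matrix(FALSE, 100, 200), cm,
                        min_area_um2 = 25, pixel_um = 5)
  vs <- classify_maturity(vs, matrix(FALSE, 100, 200))
  rec <- suppressWarnings(
    compute_densities(vs, cm, cd31, matrix(FALSE, 100, 200), pixel_um = 5))
  expect_identical(rec$compartment, "stroma")
  expect_equal(rec$compartment_area_mm2, 0.5, tolerance = 1e-12)
  expect_identical(rec$blood_count, 5L)
  expect_equal(rec$bvd_per_mm2, 10, tolerance = 1e-12)     # 5 / 0.5 mm^2
  expect_equal(rec$mature_ratio, 0)
  # percent area: stained px / compartment px
  expect_equal(rec$pct_cd31_area, 100 * sum(cd31) / 20000, tolerance = 1e-12)
})

test_that("a 10%-stained compartment reports 10 percent CD31 area", {
  # 0.63 mm^2 compartment at 5 um/px = 25200 px; stain 2520 px = 63000 um^2
  h <- 120; w <- 210
  cm <- structure(list(stroma = matrix(TRUE, h, w),
                       glands = matrix(FALSE, h, w),
                       myometrium = matrix(FALSE, h, w),
                       background = matrix(FALSE, h, w)),
                  class = "compartment_masks")
  cd31 <- matrix(FALSE, h, w); cd31[seq_len(2520)] <- TRUE
  vs <- extract_vessels(label_objects(matrix(FALSE, h, w)), matrix(FALSE, h, w),
                        cm, 25, 5)
  rec <- suppressWarnings(
    compute_densities(vs, cm, cd31, matrix(FALSE, h, w), pixel_um = 5))
  expect_equal(rec$compartment_area_mm2, 0.63, tolerance = 1e-12)
  expect_equal(rec$pct_cd31_area, 10, tolerance = 1e-12)
})

test_that("mature ratio is 3/10 for 3 muralized vessels out of 10", {
  cm <- structure(list(stroma = matrix(TRUE, 150, 200),
                       glands = matrix(FALSE, 150, 200),
                       myometrium = matrix(FALSE, 150, 200),
                       background = matrix(FALSE, 150, 200)),
                  class = "compartment_masks")
  cd31 <- matrix(FALSE, 150, 200); asma <- matrix(FALSE, 150, 200)
  centers <- expand.grid(r = c(25, 75, 125), c = c(25, 75, 125, 175))[1:10, ]
  for (i in 1:10) {
    cd31 <- mat_disk(cd31, centers$r[i], centers$c[i], 5, 2, TRUE)
    if (i <= 3) asma <- mat_disk(asma, centers$r[i], centers$c[i], 9, 6, TRUE)
  }
  vs <- extract_vessels(label_objects(cd31), matrix(FALSE, 150, 200), cm, 5, 1)
  vs <- classify_maturity(vs, asma, dilation_radius_px = 5)
  rec <- suppressWarnings(
    compute_densities(vs, cm, cd31, matrix(FALSE, 150, 200), pixel_um = 1))
  expect_identical(rec$blood_count, 10L)
  expect_identical(rec$mature_count, 3L)
  expect_equal(rec$mature_ratio, 0.3, tolerance = 1e-12)
})

test_that("specimen pooling is count-over-area, not mean of densities", {
  rec <- data.frame(
    specimen_id = "s1", field_id = c("f1", "f2"), compartment = "stroma",
    compartment_area_mm2 = c(0.2, 0.4), blood_count = c(2L, 4L),
    lymph_count = c(1L, 0L), mature_count = c(1L, 1L),
    bvd_per_mm2 = c(10, 10), lvd_per_mm2 = c(5, 0),
    pct_cd31_area = c(1, 4), pct_pdpn_area = c(0.5, 0),
    mature_ratio = c(0.5, 0.25), stringsAsFactors = FALSE)
  agg <- aggregate_specimen(rec)
  expect_equal(agg$bvd_per_mm2, (2 + 4) / (0.2 + 0.4), tolerance = 1e-12)
  expect_equal(agg$mature_ratio, 2 / 6, tolerance = 1e-12)
  expect_equal(agg$pct_cd31_area, (1 * 0.2 + 4 * 0.4) / 0.6, tolerance = 1e-12)
  expect_identical(agg$n_fields, 2L)
  # single field: pooled values equal the field values
  one <- aggregate_specimen(rec[1, ])
  expect_equal(one$bvd_per_mm2, rec$bvd_per_mm2[1])
  expect_equal(one$mature_ratio, rec$mature_ratio[1])
})

test_that("quantification is a pure function of masks and records conserve counts", {
  fld <- generate_field(tiny_config(seed = 23), 1)
  q1 <- suppressWarnings(quantify_field(fld$stack))
  q2 <- suppressWarnings(quantify_field(fld$stack))
  expect_identical(q1$records, q2$records)
  v <- q1$vessels$vessels
  for (comp in unique(v$compartment)) {
    r <- q1$records[q1$records$compartment == comp, ]
    expect_identical(r$blood_count + r$lymph_count,
                     sum(v$compartment == comp))
  }
})

test_that("noise-free field quantification recovers planted counts exactly", {
  fld <- generate_field(tiny_config(noise = noise_free, seed = 29,
                                    planted_bvd = 40, planted_lvd = 10), 1)
  q <- suppressWarnings(quantify_field(fld$stack))
  r <- q$records[q$records$compartment == "stroma", ]
  s <- fld$truth$summary
  expect_identical(r$blood_count, s$blood_count)
  expect_identical(r$lymph_count, s$lymph_count)
  expect_equal(r$mature_ratio, s$true_mature_ratio, tolerance = 1e-12)
})

test_that("myometrium records never carry a maturity ratio", {
  fld <- generate_field(tiny_config(tissue_type = "myometrium", seed = 31), 1)
  q <- suppressWarnings(quantify_field(fld$stack))
  r <- q$records[q$records$compartment == "myometrium", ]
  expect_true(is.na(r$mature_ratio))
  expect_gt(r$blood_count, 0L)
})

test_that("zero-area compartments are suppressed with a warning", {
  fld <- generate_field(tiny_config(seed = 37), 1)
  expect_warning(quantify_field(fld$stack), "zero area")
})

test_that("percent-area and count orderings agree when vessel size is held", {
  bvds <- c(10, 25, 50)
  pct <- bvd <- numeric(3)
  for (i in seq_along(bvds)) {
    fld <- generate_field(tiny_config(seed = 40 + i, planted_bvd = bvds[i],
                                      planted_lvd = 2), 1)
    r <- suppressWarnings(quantify_field(fld$stack))$records
    r <- r[r$compartment == "stroma", ]
    pct[i] <- r$pct_cd31_area; bvd[i] <- r$bvd_per_mm2
  }
  expect_identical(order(pct), order(bvd))
})
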