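test_that("fixed-threshold binarization follows the >= contract", {
  st <- make_stack()
  m <- binarize_channel(st, "CD31", method = "fixed", fixed_threshold = 10 / 255)
  expect_false(any(m$pixels))
  expect_identical(m$threshold_used, 10 / 255)
  st2 <- make_stack(dim_hw = c(2L, 2L), CD31 = matrix(c(0.2, 0.5, 0.5, 0.9), 2, 2))
  m2 <- binarize_channel(st2, "CD31", method = "fixed", fixed_threshold = 0.5)
  expect_identical(sum(m2$pixels), 3L)  # >= threshold is positive
})

test_that("Otsu on a constant plane fails with advice; fixed required iff fixed", {
  st <- make_stack(CD31 = matrix(0.3, 40, 50))
  expect_error(binarize_channel(st, "CD31", method = "otsu"), "fixed")
  expect_error(binarize_channel(st, "CD31", method = "fixed"),
               "fixed_threshold")
  expect_error(binarize_channel(st, "nope"), "not present")
})

test_that("Otsu threshold separates the modes of a bimodal plane", {
  set.seed(21)
  plane <- matrix(0.2 + rnorm(2000, 0, 0.02), 40, 50)
  plane[1:15, 1:30] <- 0.8 + rnorm(450, 0, 0.02)
  plane <- pmin(pmax(plane, 0), 1)
  m <- binarize_channel(make_stack(CD31 = plane), "CD31")
  expect_gt(m$threshold_used, 0.3)
  expect_lt(m$threshold_used, 0.7)
  # the chosen threshold attains the brute-force maximum of the
  # between-class variance (the maximizer is a plateau between the modes,
  # so thresholds are compared through the objective, not by value)
  bcv <- function(thr) {
    fg <- plane >= thr
    w <- mean(fg)
    if (w == 0 || w == 1) return(0)
    w * (1 - w) * (mean(plane[fg]) - mean(plane[!fg]))^2
  }
  expect_equal(bcv(m$threshold_used), bcv(otsu_brute(plane)),
               tolerance = 1e-10)
})

test_that("mask cleaning removes specks, closes dropouts, and is idempotent", {
  m <- matrix(FALSE, 30, 30)
  m[2:3, 2:3] <- TRUE                      # 4-px speck
  m <- mat_disk(m, 18, 18, 8, 6, TRUE)     # ring
  expect_identical(sum(clean_mask(m, min_object_px = 5,
                                  closing_radius_px = 0)$pixels > 0),
                   sum(mat_disk(matrix(FALSE, 30, 30), 18, 18, 8, 6, TRUE)))
  # identity case
  expect_identical(clean_mask(m, 0, 0)$pixels, m)
  # narrow dropouts cutting the ring wall split it; closing heals the cuts
  ring <- mat_disk(matrix(FALSE, 30, 30), 15, 15, 9, 7, TRUE)
  broken <- ring
  broken[15, 22:24] <- FALSE   # right-side cut through the wall
  broken[15, 6:8] <- FALSE     # left-side cut -> two arcs
  expect_gt(max(label_objects(broken)$labels), 1L)
  healed <- clean_mask(broken, min_object_px = 0, closing_radius_px = 2)
  expect_identical(max(label_objects(healed)$labels), 1L)
  # idempotence
  once <- clean_mask(m, 5, 2)
  expect_identical(clean_mask(once, 5, 2)$pixels, once$pixels)
})

test_that("connectivity semantics: diagonals join under 8 but not 4", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(label_objects(m, connectivity = 8)$labels), 1L)
  expect_identical(max(label_objects(m, connectivity = 4)$labels), 2L)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(max(label_objects(empty)$labels), 0L)
  expect_identical(nrow(label_objects(empty)$table), 0L)
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4, 8)) {
      ours <- label_objects(m, connectivity = conn)$labels
      oracle <- flood_fill_label(m, connectivity = conn)
      expect_identical(max(ours), max(oracle))
      # same partition: each of our labels maps to exactly one oracle label
      if (max(ours) > 0) {
        cross <- table(ours[m], oracle[m])
        expect_true(all(rowSums(cross > 0) == 1L))
        expect_true(all(colSums(cross > 0) == 1L))
      }
    }
  }
})

test_that("labels are consecutive and object table matches the label image", {
  set.seed(8)
  m <- matrix(runif(900) < 0.3, 30, 30)
  lo <- label_objects(m, connectivity = 8)
  k <- max(lo$labels)
  expect_identical(sort(unique(as.vector(lo$labels))), c(0L, seq_len(k)))
  expect_identical(lo$table$label, seq_len(k))
  expect_identical(sum(lo$table$area_px), sum(m))
})

test_that("compartment masks partition the field with stroma precedence", {
  set.seed(5)
  cd10 <- matrix(FALSE, 60, 60); cd10[5:40, 5:40] <- TRUE
  asma <- matrix(FALSE, 60, 60); asma[30:58, 30:58] <- TRUE
  dapi <- matrix(runif(3600) < 0.2, 60, 60)
  cm <- build_compartment_masks(cd10, asma, dapi, min_object_px = 5,
                                closing_radius_px = 0)
  total <- cm$stroma + cm$glands + cm$myometrium + cm$background
  expect_true(all(total == 1))                      # disjoint and exhaustive
  expect_false(any(cm$stroma & cm$myometrium))      # precedence rule
  expect_true(any(cm$myometrium))
  # no CD10 signal: stroma empty, myometrium equals the cleaned aSMA area
  cm2 <- build_compartment_masks(matrix(FALSE, 60, 60), asma, dapi,
                                 min_object_px = 5, closing_radius_px = 0)
  expect_false(any(cm2$stroma))
  expect_identical(cm2$myometrium, clean_mask(asma, 5, 0)$pixels)
  expect_error(build_compartment_masks(cd10[1:30, ], asma, dapi), "dimension")
})

test_that("glands are recovered as nucleated enclosed CD10 holes", {
  fld <- generate_field(tiny_config(noise = noise_free, seed = 13), 1)
  q <- suppressWarnings(quantify_field(fld$stack))
  cm <- q$compartments
  truth <- fld$truth$masks
  # stroma area within 2% of the planted footprint
  expect_lt(abs(sum(cm$stroma) - sum(truth$stroma)) / sum(truth$stroma), 0.02)
  # detected gland pixels overlap the planted gland footprint
  if (sum(truth$glands) > 0) {
    expect_gt(sum(cm$glands & truth$glands) / sum(truth$glands), 0.8)
  }
})

test_that("noise-free synthetic CD31 objects equal the planted vessel count", {
  fld <- generate_field(tiny_config(noise = noise_free, seed = 17,
                                    planted_bvd = 35), 1)
  cd31 <- binarize_channel(fld$stack, "CD31", method = "fixed",
                           fixed_threshold = 0.4)
  k <- max(label_objects(cd31, connectivity = 8)$labels)
  expect_identical(k, sum(fld$truth$vessels$class == "blood"))
})
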