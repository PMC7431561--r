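# Colour deconvolution, zone classification, H-score and nuclear scoring.

test_that("deconvolution recovers pure-stain pixels through the forward model", {
  M <- hdab_stain_matrix()
  expect_equal(det(M) != 0, TRUE)
  expect_equal(sqrt(rowSums(M^2)), c(hema = 1, dab = 1, residual = 1))

  # pure white: all OD maps ~ 0
  white <- array(255, dim = c(2, 2, 3))
  od <- deconvolve_hdab(white)
  expect_true(all(od$hema_od <= 0.002) && all(od$dab_od <= 0.002))

  # pixel synthesized from c_hema = 0.5, c_dab = 0
  px <- round(255 * 10^(-(0.5 * M[1, ])))
  img <- array(rep(px, each = 1), dim = c(1, 1, 3))
  od2 <- deconvolve_hdab(img)
  expect_equal(od2$hema_od[1, 1], 0.5, tolerance = 0.01)
  expect_lt(od2$dab_od[1, 1], 0.01)

  # mixed pixel round trip
  px3 <- round(255 * 10^(-(0.3 * M[1, ] + 0.6 * M[2, ])))
  od3 <- deconvolve_hdab(array(px3, dim = c(1, 1, 3)))
  expect_equal(od3$hema_od[1, 1], 0.3, tolerance = 0.02)
  expect_equal(od3$dab_od[1, 1], 0.6, tolerance = 0.02)

  singular <- matrix(rep(c(1, 0, 0), 3), nrow = 3, byrow = TRUE)
  expect_error(deconvolve_hdab(white, singular), "singular")
})

test_that("pixel classification bins by intensity zone and matches brute force", {
  # all pixels at intensity 200 -> negative zone under 60/120/180
  od_200 <- matrix(-log10(200 / 255), 5, 5)
  fr <- classify_dab_pixels(od_200)
  expect_equal(fr$f_negative, 1.0)

  # one pixel per zone: intensities 30 / 90 / 150 / 210
  od4 <- matrix(-log10(c(30, 90, 150, 210) / 255), 2, 2)
  fr4 <- classify_dab_pixels(od4)
  expect_equal(c(fr4$f_negative, fr4$f_low, fr4$f_positive, fr4$f_high),
               c(0.25, 0.25, 0.25, 0.25))

  # randomized raster equals the per-pixel tally oracle exactly
  set.seed(99)
  od_r <- matrix(runif(100 * 100, 0, 1.2), 100, 100)
  zones <- intensity_zones(50, 110, 190)
  got <- classify_dab_pixels(od_r, zones)
  want <- oracle_zone_fractions(od_r, c(50, 110, 190))
  expect_equal(c(got$f_negative, got$f_low, got$f_positive, got$f_high),
               unname(want))
  expect_equal(got$n_pixels, 10000L)

  mask <- matrix(FALSE, 100, 100)
  expect_error(classify_dab_pixels(od_r, zones, mask), "no tissue pixels")
  expect_error(intensity_zones(120, 60, 180), "increasing")
})

test_that("the modified H-score applies the printed weights over [0, 300]", {
  expect_equal(modified_hscore(pixel_class_fractions(1, 0, 0, 0)), 0)
  expect_equal(modified_hscore(pixel_class_fractions(0, 1, 0, 0)), 100)
  expect_equal(modified_hscore(pixel_class_fractions(0, 0, 1, 0)), 200)
  expect_equal(modified_hscore(pixel_class_fractions(0, 0, 0, 1)), 300)
  expect_equal(modified_hscore(pixel_class_fractions(0.25, 0.25, 0.25,
                                                     0.25)), 150)
  # arbitrary valid compositions stay inside the range
  set.seed(1)
  for (i in 1:50) {
    f <- diff(c(0, sort(runif(3)), 1))
    s <- modified_hscore(pixel_class_fractions(f[1], f[2], f[3], f[4]))
    expect_true(s >= 0 && s <= 300)
  }
  expect_error(pixel_class_fractions(0.5, 0.2, 0.2, 0.2), "sum to 1")
})

test_that("H-score is monotone in DAB OD and invariant to rotation", {
  im <- generate_ihc_image(image_sim_config(n_nuclei = 10), seed = 17)
  od <- deconvolve_hdab(im$image)
  tissue <- im$truth$tissue_mask
  s1 <- modified_hscore(classify_dab_pixels(od$dab_od, mask = tissue))
  bumped <- od$dab_od + 0.15
  s2 <- modified_hscore(classify_dab_pixels(bumped, mask = tissue))
  expect_gte(s2, s1)

  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # 90 degrees
  s_rot <- modified_hscore(classify_dab_pixels(rot(od$dab_od),
                                               mask = rot(tissue)))
  expect_equal(s_rot, s1)
})

test_that("segmentation finds planted non-touching nuclei with IoU >= 0.5", {
  im <- generate_ihc_image(image_sim_config(n_nuclei = 20), seed = 23)
  od <- deconvolve_hdab(im$image)
  labels <- segment_nuclei(od)
  expect_equal(max(labels), 20)
  truth <- im$truth$nucleus_labels
  for (k in seq_len(20)) {
    truth_px <- which(truth == k)
    hit <- labels[truth_px]
    hit <- hit[hit > 0]
    expect_gt(length(hit), 0)
    lab <- as.integer(names(which.max(table(hit))))
    inter <- sum(truth == k & labels == lab)
    union <- sum(truth == k | labels == lab)
    expect_gte(inter / union, 0.5)
  }
  # determinism
  expect_identical(labels, segment_nuclei(deconvolve_hdab(im$image)))
  # blank white image: no nuclei
  blank <- array(255, dim = c(32, 32, 3))
  expect_equal(max(segment_nuclei(deconvolve_hdab(blank))), 0)
})

test_that("nuclear positive-percentage counts nuclei above the OD threshold", {
  # constructed fixture: 10 nuclei, 4 with strong DAB
  labels <- matrix(0L, 10, 30)
  dab <- matrix(0, 10, 30)
  for (k in 1:10) {
    rows <- ((k - 1) %% 5) * 2 + 1:2
    cols <- (k > 5) * 15 + 1:4
    labels[rows, cols] <- k
    if (k <= 4) dab[rows, cols] <- 0.6
  }
  expect_equal(nuclear_positive_fraction(labels, dab, 0.15), 40.0)
  expect_equal(nuclear_positive_fraction(labels, dab * 0, 0.15), 0.0)
  # raising the threshold never increases the percentage
  expect_lte(nuclear_positive_fraction(labels, dab, 0.7),
             nuclear_positive_fraction(labels, dab, 0.15))
  # area mode: positive nuclear area / total nuclear area
  expect_equal(nuclear_positive_fraction(labels, dab, 0.15,
                                         mode = "area"), 40.0)
  expect_error(nuclear_positive_fraction(labels * 0L, dab, 0.15),
               "no nuclei")
})

test_that("recovered nuclear percentage tracks planted truth across a sweep", {
  for (frac in c(0.1, 0.5, 0.9)) {
    im <- generate_ihc_image(
      image_sim_config(positive_nucleus_fraction = frac, n_nuclei = 30),
      seed = 100 + round(frac * 10))
    od <- deconvolve_hdab(im$image)
    labels <- segment_nuclei(od)
    got <- nuclear_positive_fraction(labels, od$dab_od)
    expect_lt(abs(got - 100 * mean(im$truth$positive_nuclei)), 5)
  }
})

test_that("sample scoring averages fields and enforces the two-field protocol", {
  im <- generate_ihc_image(image_sim_config(width = 220, height = 220,
                                            n_nuclei = 110), seed = 5)
  fields <- list(im$image, im$image)
  s <- score_sample(fields, "nuclear")
  expect_equal(s$n_fields, 2)
  expect_true(all(s$n_cells_per_field >= 100))
  expect_equal(s$score, s$field_scores[1])  # identical fields
  expect_true(s$score >= 0 && s$score <= 100)

  sc <- score_sample(fields, "cytoplasmic")
  expect_true(sc$score >= 0 && sc$score <= 300)
  expect_equal(sc$score, sc$field_scores[2])

  expect_error(score_sample(list(im$image), "nuclear"), "two fields")
  small <- generate_ihc_image(image_sim_config(n_nuclei = 12), seed = 6)
  w <- testthat::capture_warnings(
    score_sample(list(small$image, small$image), "nuclear"))
  expect_true(all(grepl("detected cells", w)) && length(w) >= 1)
  expect_error(
    suppressWarnings(score_sample(list(small$image, small$image),
                                  "nuclear", strict = TRUE)),
    "detected cells")
})

test_that("fields scoring differently average by the mean rule", {
  im1 <- generate_ihc_image(
    image_sim_config(positive_nucleus_fraction = 0.4, n_nuclei = 20),
    seed = 8)
  im2 <- generate_ihc_image(
    image_sim_config(positive_nucleus_fraction = 0.6, n_nuclei = 20),
    seed = 9)
  s <- suppressWarnings(
    score_sample(list(im1$image, im2$image), "nuclear", min_cells = 10))
  expect_equal(s$score, mean(s$field_scores))
})
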