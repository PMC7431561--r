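#' Ruifrok-Johnston H-DAB stain basis
#'
#' Returns the 3x3 matrix of unit-length stain optical-density vectors used
#' for colour deconvolution of hematoxylin + DAB stained sections: rows are
#' hematoxylin, DAB, and a residual vector (the normalized cross product of
#' the first two); columns are the R, G, B channels.
#'
#' @return A 3x3 numeric matrix with rows `hema`, `dab`, `residual`.
#' @export
hdab_stain_matrix <- function() {
  hema <- c(0.650, 0.704, 0.286)
  dab <- c(0.269, 0.568, 0.778)
  hema <- hema / sqrt(sum(hema^2))
  dab <- dab / sqrt(sum(dab^2))
  res <- c(hema[2] * dab[3] - hema[3] * dab[2],
           hema[3] * dab[1] - hema[1] * dab[3],
           hema[1] * dab[2] - hema[2] * dab[1])
  res <- res / sqrt(sum(res^2))
  m <- rbind(hema = hema, dab = dab, residual = res)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Colour-deconvolve an H-DAB image into stain optical-density maps
#'
#' Per pixel, channel optical density is `OD_c = -log10((I_c + 1) / 256)`
#' (the +1 avoids log of zero); stain concentrations are the OD vector
#' multiplied by the inverse stain matrix, with negative concentrations
#' clamped to zero.
#'
#' @param img `height x width x 3` numeric array of 8-bit values (0-255), or
#'   a path readable by [read_ihc_image()].
#' @param vectors 3x3 stain matrix, rows = unit stain OD triples
#'   (default [hdab_stain_matrix()]).
#'
#' @return A list of class `stain_od_maps` with nonnegative rasters
#'   `hema_od`, `dab_od`, `residual_od` of the image's shape.
#' @export
#' @examples
#' im <- generate_ihc_image(image_sim_config(n_nuclei = 5), seed = 1)
#' od <- deconvolve_hdab(im$image)
#' range(od$dab_od)
deconvolve_hdab <- function(img, vectors = hdab_stain_matrix()) {
  if (is.character(img)) img <- read_ihc_image(img)
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_input("img must be a height x width x 3 array of 8-bit values")
  if (!is.matrix(vectors) || any(dim(vectors) != 3L))
    stop_input("vectors must be a 3x3 stain matrix")
  if (abs(det(vectors)) < 1e-8)
    stop_input("stain matrix is singular; vectors must be independent")
  h <- dim(img)[1]; w <- dim(img)[2]
  od <- -log10((matrix(img, ncol = 3) + 1) / 256)
  conc <- od %*% solve(vectors)
  conc[conc < 0] <- 0
  structure(list(
    hema_od = matrix(conc[, 1], h, w),
    dab_od = matrix(conc[, 2], h, w),
    residual_od = matrix(conc[, 3], h, w)
  ), class = "stain_od_maps")
}

#' Intensity zone cutpoints for four-tier DAB classification
#'
#' Three strictly increasing cutpoints on the 0-255 DAB-intensity axis
#' partition it into high-positive `[0, z1]`, positive `(z1, z2]`,
#' low-positive `(z2, z3]` and negative `(z3, 255]` zones. The defaults
#' 60/120/180 follow the IHC Profiler convention; lower intensity means more
#' DAB.
#'
#' @param z1,z2,z3 cutpoints, `0 < z1 < z2 < z3 < 255`.
#' @return A numeric vector of class `intensity_zones`.
#' @export
intensity_zones <- function(z1 = 60, z2 = 120, z3 = 180) {
  z <- c(z1, z2, z3)
  if (any(z <= 0) || any(z >= 255) || any(diff(z) <= 0))
    stop_input("zone cutpoints must be strictly increasing within (0, 255)")
  structure(as.numeric(z), class = "intensity_zones")
}

#' Construct a pixel-class composition
#'
#' @param f_negative,f_low,f_positive,f_high fractions of tissue pixels in
#'   each DAB intensity class; must sum to 1.
#' @param n_pixels number of pixels tallied (informational).
#' @return A list of class `pixel_class_fractions`.
#' @export
pixel_class_fractions <- function(f_negative, f_low, f_positive, f_high,
                                  n_pixels = NA_integer_) {
  f <- c(f_negative, f_low, f_positive, f_high)
  if (any(!is.finite(f)) || any(f < 0))
    stop_input("class fractions must be finite and nonnegative")
  if (abs(sum(f) - 1) > 1e-9)
    stop_input("class fractions must sum to 1 (got ", format(sum(f)), ")")
  structure(list(f_negative = f[1], f_low = f[2], f_positive = f[3],
                 f_high = f[4], n_pixels = n_pixels),
            class = "pixel_class_fractions")
}

#' Classify tissue pixels into four DAB intensity zones
#'
#' DAB optical density is mapped back to a 0-255 intensity via
#' `I = 255 * 10^-OD` (clamped) and binned by the zone cutpoints.
#'
#' @param dab_od numeric raster of DAB OD, e.g. from [deconvolve_hdab()].
#' @param zones an [intensity_zones()] object.
#' @param mask logical raster selecting tissue pixels; `NULL` uses all.
#' @return A [pixel_class_fractions()] over the masked pixels.
#' @export
classify_dab_pixels <- function(dab_od, zones = intensity_zones(),
                                mask = NULL) {
  if (!inherits(zones, "intensity_zones")) zones <- do.call(intensity_zones,
                                                            as.list(zones))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(dab_od))
  if (!all(dim(mask) == dim(dab_od)))
    stop_input("mask shape must equal the raster shape")
  vals <- dab_od[mask]
  if (length(vals) == 0L) stop_input("no tissue pixels selected by mask")
  intensity <- pmin(pmax(255 * 10^(-vals), 0), 255)
  n <- length(intensity)
  n_high <- sum(intensity <= zones[1])
  n_pos <- sum(intensity > zones[1] & intensity <= zones[2])
  n_low <- sum(intensity > zones[2] & intensity <= zones[3])
  n_neg <- n - n_high - n_pos - n_low
  pixel_class_fractions(n_neg / n, n_low / n, n_pos / n, n_high / n,
                        n_pixels = n)
}

#' Modified H-score from a pixel-class composition
#'
#' The weighted cytoplasmic score
#' `0 * %negative + 100 * %low-positive + 200 * %positive +
#' 300 * %high-positive`, with percentages as proportions of 1, giving a
#' score in 0-300.
#'
#' @param fr a [pixel_class_fractions()] (or a list with the same fields).
#' @return A single number in `[0, 300]`.
#' @export
#' @examples
#' modified_hscore(pixel_class_fractions(0.25, 0.25, 0.25, 0.25)) # 150
modified_hscore <- function(fr) {
  if (!inherits(fr, "pixel_class_fractions"))
    fr <- pixel_class_fractions(fr$f_negative, fr$f_low, fr$f_positive,
                                fr$f_high, fr$n_pixels %||% NA_integer_)
  0 * fr$f_negative + 100 * fr$f_low + 200 * fr$f_positive +
    300 * fr$f_high
}

#' Segment nuclei from stain optical-density maps
#'
#' The nuclear mask is an Otsu threshold on the total stain OD
#' (`hema_od + dab_od`) restricted to tissue; connected components below
#' `min_area` pixels are discarded. No watershed splitting is applied by
#' default (intended for non-touching nuclei); enable `watershed = TRUE`
#' for real sections with touching nuclei.
#'
#' @param od a `stain_od_maps` from [deconvolve_hdab()].
#' @param min_area minimum component area in pixels.
#' @param tissue_mask logical raster; `NULL` derives tissue as pixels with
#'   total OD above `tissue_od_threshold`.
#' @param tissue_od_threshold total-OD cutoff separating tissue from glass.
#' @param watershed if `TRUE`, split touching components with a
#'   distance-map watershed.
#' @return Integer label raster; 0 is background, labels are consecutive
#'   positive integers. Zero components yield an all-zero raster.
#' @export
segment_nuclei <- function(od, min_area = 12, tissue_mask = NULL,
                           tissue_od_threshold = 0.08, watershed = FALSE) {
  stopifnot(inherits(od, "stain_od_maps"))
  total <- od$hema_od + od$dab_od
  if (is.null(tissue_mask)) tissue_mask <- total > tissue_od_threshold
  if (!any(tissue_mask))
    return(matrix(0L, nrow(total), ncol(total)))
  vals <- total[tissue_mask]
  rng <- range(vals)
  if (diff(rng) < 1e-9)
    return(matrix(0L, nrow(total), ncol(total)))
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1)),
                       range = rng, levels = 256L)
  nuclear <- total > thr & tissue_mask
  lab <- EBImage::bwlabel(EBImage::Image(t(nuclear)))
  if (isTRUE(watershed)) {
    dm <- EBImage::distmap(EBImage::Image(t(nuclear)))
    lab <- EBImage::watershed(dm)
  }
  labels <- t(EBImage::imageData(lab))
  storage.mode(labels) <- "integer"
  tab <- tabulate(labels[labels > 0L])
  keep <- which(tab >= min_area)
  relabel <- integer(length(tab))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  labels
}

#' Percentage of DAB-positive nuclei
#'
#' A nucleus is positive when its mean DAB optical density exceeds
#' `positivity_od_threshold` (count mode). Area mode instead reports
#' DAB-positive nuclear area as a percentage of total nuclear area, the
#' native definition of the ImmunoRatio tool.
#'
#' @param labels integer nucleus label raster from [segment_nuclei()].
#' @param dab_od DAB OD raster of the same shape.
#' @param positivity_od_threshold OD above which a nucleus (or pixel, in
#'   area mode) counts as positive. Default 0.15.
#' @param mode `"count"` (default) or `"area"`.
#' @return Percentage in `[0, 100]`.
#' @export
nuclear_positive_fraction <- function(labels, dab_od,
                                      positivity_od_threshold = 0.15,
                                      mode = c("count", "area")) {
  mode <- match.arg(mode)
  if (!all(dim(labels) == dim(dab_od)))
    stop_input("labels and dab_od must have the same shape")
  idx <- labels > 0L
  if (!any(idx)) stop_input("no nuclei detected")
  if (mode == "area") {
    return(100 * sum(dab_od[idx] > positivity_od_threshold) / sum(idx))
  }
  mean_od <- tapply(dab_od[idx], labels[idx], mean)
  100 * mean(mean_od > positivity_od_threshold)
}

#' Score a sample from replicate microscopy fields
#'
#' Applies the full scoring chain (deconvolution, then either four-zone
#' cytoplasmic classification + modified H-score or nuclear segmentation +
#' positive-percentage) to each field and averages the per-field scores.
#' The protocol expects at least two fields of at least `min_cells` detected
#' cells each; a low cell count raises a warning (an error in strict mode),
#' fewer than two fields is always an error.
#'
#' @param fields list of images (arrays or file paths), one per field.
#' @param compartment `"nuclear"` or `"cytoplasmic"`.
#' @param zones [intensity_zones()] for cytoplasmic scoring.
#' @param positivity_od_threshold nuclear positivity OD cutoff.
#' @param min_cells minimum nuclei per field before flagging (default 100).
#' @param strict if `TRUE`, the cell-count warning becomes an error.
#' @param pool_fields if `TRUE`, pool pixels/nuclei across fields instead of
#'   averaging per-field scores.
#' @param vectors stain basis for deconvolution.
#'
#' @return A list of class `sample_score`: `score`, `compartment`,
#'   `n_fields`, `n_cells_per_field`, `field_scores`, `flags`.
#' @export
score_sample <- function(fields, compartment = c("nuclear", "cytoplasmic"),
                         zones = intensity_zones(),
                         positivity_od_threshold = 0.15,
                         min_cells = 100L, strict = FALSE,
                         pool_fields = FALSE,
                         vectors = hdab_stain_matrix()) {
  compartment <- match.arg(compartment)
  if (!is.list(fields) || length(fields) < 2L)
    stop_input("protocol requires at least two fields per sample (got ",
               length(fields), ")")
  flags <- character(0)
  field_scores <- numeric(length(fields))
  n_cells <- integer(length(fields))
  pooled_num <- 0; pooled_den <- 0
  for (i in seq_along(fields)) {
    img <- fields[[i]]
    if (is.character(img)) img <- read_ihc_image(img)
    od <- deconvolve_hdab(img, vectors)
    labels <- segment_nuclei(od)
    n_cells[i] <- max(labels)
    if (n_cells[i] < min_cells) {
      msg <- sprintf("field %d has %d detected cells (< %d required)",
                     i, n_cells[i], min_cells)
      if (strict) stop_input(msg)
      warning(msg, call. = FALSE)
      flags <- c(flags, msg)
    }
    if (compartment == "cytoplasmic") {
      tissue <- od$hema_od + od$dab_od > 0.08
      cyto <- tissue & labels == 0L
      fr <- classify_dab_pixels(od$dab_od, zones, mask = cyto)
      field_scores[i] <- modified_hscore(fr)
      pooled_num <- pooled_num + modified_hscore(fr) * fr$n_pixels
      pooled_den <- pooled_den + fr$n_pixels
    } else {
      if (n_cells[i] == 0L) stop_input("field ", i, ": no nuclei detected")
      mean_od <- tapply(od$dab_od[labels > 0L], labels[labels > 0L], mean)
      field_scores[i] <- 100 * mean(mean_od > positivity_od_threshold)
      pooled_num <- pooled_num + sum(mean_od > positivity_od_threshold)
      pooled_den <- pooled_den + length(mean_od)
    }
  }
  score <- if (pool_fields) {
    if (compartment == "nuclear") 100 * pooled_num / pooled_den
    else pooled_num / pooled_den
  } else mean(field_scores)
  structure(list(score = score, compartment = compartment,
                 n_fields = length(fields), n_cells_per_field = n_cells,
                 field_scores = field_scores, flags = flags),
            class = "sample_score")
}
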