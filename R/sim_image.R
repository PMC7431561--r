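#' Configuration for the synthetic stained-section generator
#'
#' Describes an H-DAB-stained section image composed in optical-density (OD)
#' space: hematoxylin-stained nuclei (elliptical, non-overlapping) on a
#' tissue disc whose cytoplasm pixels carry DAB at one of four planted
#' intensity classes (negative, low-positive, positive, high-positive), on a
#' near-white glass background.
#'
#' @param width,height canvas size in pixels.
#' @param n_nuclei number of non-overlapping elliptical nuclei to place.
#' @param positive_nucleus_fraction fraction of nuclei carrying DAB above the
#'   positivity level.
#' @param cytoplasm_class_fractions four fractions (negative, low-positive,
#'   positive, high-positive) summing to 1.
#' @param dab_od_per_class strictly increasing DAB OD planted for the four
#'   cytoplasm classes. The defaults (0.02, 0.18, 0.42, 0.75) map through
#'   `255 * 10^-OD` to the four default intensity zones of
#'   [classify_dab_pixels()].
#' @param hema_od_nuclei hematoxylin OD planted inside every nucleus.
#' @param dab_od_positive_nucleus DAB OD planted inside positive nuclei.
#' @param background_rgb glass background colour, three 8-bit values.
#' @param nucleus_axes range (min, max) of nucleus semi-axes in pixels.
#' @param tissue_radius_fraction tissue disc radius as a fraction of the
#'   smaller canvas dimension / 2.
#'
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(width = 160, height = 160, n_nuclei = 40,
                             positive_nucleus_fraction = 0.5,
                             cytoplasm_class_fractions =
                               c(0.4, 0.3, 0.2, 0.1),
                             dab_od_per_class = c(0.02, 0.18, 0.42, 0.75),
                             hema_od_nuclei = 1.2,
                             dab_od_positive_nucleus = 0.8,
                             background_rgb = c(250L, 250L, 250L),
                             nucleus_axes = c(3, 6),
                             tissue_radius_fraction = 0.92) {
  check_count(width, "width", 16L); check_count(height, "height", 16L)
  n_nuclei <- check_count(n_nuclei, "n_nuclei", min = 0L)
  check_fraction(positive_nucleus_fraction, "positive_nucleus_fraction")
  if (length(cytoplasm_class_fractions) != 4L ||
      any(cytoplasm_class_fractions < 0) ||
      abs(sum(cytoplasm_class_fractions) - 1) > 1e-9)
    stop_input("cytoplasm_class_fractions must be 4 nonnegative values ",
               "summing to 1")
  if (length(dab_od_per_class) != 4L || any(dab_od_per_class < 0) ||
      any(diff(dab_od_per_class) <= 0))
    stop_input("dab_od_per_class must be 4 strictly increasing ",
               "nonnegative values")
  check_positive(hema_od_nuclei, "hema_od_nuclei")
  if (length(background_rgb) != 3L || any(background_rgb < 0) ||
      any(background_rgb > 255))
    stop_input("background_rgb must be three 8-bit values")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_nuclei = n_nuclei,
    positive_nucleus_fraction = positive_nucleus_fraction,
    cytoplasm_class_fractions = as.numeric(cytoplasm_class_fractions),
    dab_od_per_class = as.numeric(dab_od_per_class),
    hema_od_nuclei = hema_od_nuclei,
    dab_od_positive_nucleus = dab_od_positive_nucleus,
    background_rgb = as.integer(round(background_rgb)),
    nucleus_axes = as.numeric(nucleus_axes),
    tissue_radius_fraction = tissue_radius_fraction
  ), class = "image_sim_config")
}

# Place n non-overlapping ellipses (centres, semi-axes, orientation) inside
# the tissue disc by rejection sampling; overlap is tested conservatively on
# bounding circles.
place_nuclei <- function(cfg, cx, cy, radius, max_tries = 20000L) {
  n <- cfg$n_nuclei
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0)))
  placed <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0))
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n,
           " non-overlapping nuclei on this canvas; reduce n_nuclei ",
           "or enlarge the image")
    a <- runif(1, cfg$nucleus_axes[1], cfg$nucleus_axes[2])
    b <- runif(1, cfg$nucleus_axes[1], cfg$nucleus_axes[2])
    r <- max(a, b)
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (radius - r - 1)
    x <- cx + rad * cos(ang)
    y <- cy + rad * sin(ang)
    if (nrow(placed) > 0) {
      d2 <- (placed$x - x)^2 + (placed$y - y)^2
      if (any(d2 < (pmax(placed$a, placed$b) + r + 1)^2)) next
    }
    placed <- rbind(placed, data.frame(x = x, y = y, a = a, b = b,
                                       theta = runif(1, 0, pi)))
  }
  placed
}

#' Generate a synthetic H-DAB-stained section with per-pixel ground truth
#'
#' The image is composed in OD space: per pixel and colour channel,
#' `RGB = 255 * 10^-(c_hema * S_hema + c_dab * S_dab)` with the
#' Ruifrok-Johnston H-DAB stain vectors (see [hdab_stain_matrix()]).
#' Cytoplasm pixels are partitioned exactly (to within one pixel) into the
#' four requested intensity classes; nuclei receive hematoxylin, and a
#' configured fraction of them additionally receive strong DAB
#' ("positive" nuclei).
#'
#' @param cfg an [image_sim_config()].
#' @param seed integer seed; identical `(cfg, seed)` give identical output.
#'
#' @return A list of class `ihc_image`:
#' \describe{
#'   \item{image}{`height x width x 3` numeric array of 8-bit values.}
#'   \item{truth}{list with `class_raster` (0 = background, 1-4 = cytoplasm
#'     classes negative..high-positive, 5 = nucleus), `nucleus_labels`
#'     (integer raster, 0 = none), `positive_nuclei` (logical per label),
#'     `dab_od` and `hema_od` (planted concentration rasters),
#'     `class_fractions` (realized cytoplasm fractions).}
#' }
#' @export
#' @examples
#' im <- generate_ihc_image(image_sim_config(n_nuclei = 10), seed = 3)
#' dim(im$image)
generate_ihc_image <- function(cfg = image_sim_config(), seed) {
  stopifnot(inherits(cfg, "image_sim_config"))
  with_seed(seed, {
    h <- cfg$height; w <- cfg$width
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    radius <- cfg$tissue_radius_fraction * min(w, h) / 2

    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    tissue <- (xs - cx)^2 + (ys - cy)^2 <= radius^2

    nuc <- place_nuclei(cfg, cx, cy, radius)
    labels <- matrix(0L, h, w)
    for (i in seq_len(nrow(nuc))) {
      ct <- cos(nuc$theta[i]); st <- sin(nuc$theta[i])
      dx <- xs - nuc$x[i]; dy <- ys - nuc$y[i]
      u <- dx * ct + dy * st; v <- -dx * st + dy * ct
      inside <- (u / nuc$a[i])^2 + (v / nuc$b[i])^2 <= 1
      labels[inside] <- i
    }
    n_placed <- nrow(nuc)
    n_pos <- round(cfg$positive_nucleus_fraction * n_placed)
    positive <- rep(FALSE, n_placed)
    if (n_pos > 0) positive[sample.int(n_placed, n_pos)] <- TRUE

    # exact partition of cytoplasm pixels into the four classes
    cyto_idx <- which(tissue & labels == 0L)
    n_cyto <- length(cyto_idx)
    counts <- floor(cfg$cytoplasm_class_fractions * n_cyto)
    rem <- n_cyto - sum(counts)
    if (rem > 0) {
      frac_rem <- cfg$cytoplasm_class_fractions * n_cyto - counts
      counts[order(frac_rem, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(frac_rem, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    class_raster <- matrix(0L, h, w)
    perm <- sample(cyto_idx)
    cls <- rep.int(1:4, counts)
    class_raster[perm] <- cls
    class_raster[labels > 0L] <- 5L

    dab_od <- matrix(0, h, w)
    dab_od[perm] <- cfg$dab_od_per_class[cls]
    hema_od <- matrix(0, h, w)
    hema_od[labels > 0L] <- cfg$hema_od_nuclei
    if (any(positive)) {
      pos_px <- labels > 0L & positive[pmax(labels, 1L)]
      dab_od[pos_px] <- cfg$dab_od_positive_nucleus
    }

    M <- hdab_stain_matrix()
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      od <- hema_od * M[1, ch] + dab_od * M[2, ch]
      plane <- round(255 * 10^(-od))
      plane[!tissue] <- cfg$background_rgb[ch]
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }

    structure(list(
      image = img,
      truth = list(
        class_raster = class_raster,
        nucleus_labels = labels,
        positive_nuclei = positive,
        dab_od = dab_od,
        hema_od = hema_od,
        class_fractions = if (n_cyto > 0) counts / n_cyto else rep(NA_real_, 4),
        tissue_mask = tissue
      )
    ), class = "ihc_image")
  })
}

#' Write a synthetic image and its truth to disk
#'
#' The image is written as 8-bit RGB PNG, the nucleus label raster as 16-bit
#' grayscale TIFF, and scalar truths (positive flags, class fractions) as
#' JSON.
#'
#' @param im an `ihc_image` from [generate_ihc_image()].
#' @param prefix path prefix; files `<prefix>.png`, `<prefix>_labels.tif`
#'   and `<prefix>_truth.json` are created.
#' @return Invisibly, the paths written.
#' @export
write_ihc_image <- function(im, prefix) {
  stopifnot(inherits(im, "ihc_image"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = paste0(prefix, ".png"),
             labels = paste0(prefix, "_labels.tif"),
             truth = paste0(prefix, "_truth.json"))
  EBImage::writeImage(EBImage::Image(aperm(im$image / 255, c(2, 1, 3)),
                                     colormode = "Color"),
                      paths[["image"]], type = "png", bits.per.sample = 8L)
  EBImage::writeImage(EBImage::Image(t(im$truth$nucleus_labels) / 65535),
                      paths[["labels"]], type = "tiff",
                      bits.per.sample = 16L)
  jsonlite::write_json(
    list(positive_nuclei = im$truth$positive_nuclei,
         class_fractions = im$truth$class_fractions),
    paths[["truth"]], digits = NA)
  invisible(paths)
}

#' Read an 8-bit RGB image file into the raster array used by the scorers
#'
#' @param path a PNG or TIFF file.
#' @return `height x width x 3` numeric array with values in 0-255.
#' @export
read_ihc_image <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: ", path)
  x <- EBImage::readImage(path)
  a <- EBImage::imageData(x)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  # EBImage stores x,y,channel in [0,1]; convert to row-major 0-255
  aperm(a, c(2, 1, 3)) * 255
}
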