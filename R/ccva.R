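#' Parameters of the classical computer-vision classifier
#'
#' The five tunables of the threshold -> filter -> ellipse-fit -> rule
#' pipeline.  Defaults were calibrated once on 175 synthetic validation
#' wells (mixed clean and degraded renders at the default 1 um/px, 176 px
#' geometry) and are frozen here; they are in pixels of that geometry and
#' should be rescaled for other magnifications.
#'
#' @param min_area_px,max_area_px inclusive size-filter bounds (px).  The
#'   lower bound rejects noise specks, the upper bound rim fragments and
#'   out-of-range artifacts.
#' @param single_area_max_px largest object area still compatible with one
#'   cell; a single larger object is called `Multiple` (merged clump).
#' @param roundness_min minimum roundness (`4*area / (pi * major_axis^2)`,
#'   1 for a circle) for a live single cell; a lone less-round object is
#'   called `Death`.
#' @param border_margin_px objects with any pixel within this margin of the
#'   frame edge are discarded (well-rim arcs, half-cropped neighbors).
#' @return An object of class `ccva_params`.
#' @export
ccva_params <- function(min_area_px = 30,
                        max_area_px = 2500,
                        single_area_max_px = 700,
                        roundness_min = 0.92,
                        border_margin_px = 2) {
  check(min_area_px < max_area_px, "min_area_px must be < max_area_px")
  check(roundness_min > 0 && roundness_min <= 1,
        "roundness_min must be in (0, 1]")
  check(border_margin_px >= 0, "border_margin_px must be >= 0")
  structure(list(min_area_px = min_area_px, max_area_px = max_area_px,
                 single_area_max_px = single_area_max_px,
                 roundness_min = roundness_min,
                 border_margin_px = border_margin_px),
            class = "ccva_params")
}

#' Otsu intensity threshold
#'
#' Histogram-based threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all candidate levels.  For integer images
#' (8- or 16-bit) every occurring level is a candidate; the returned
#' threshold is `level* + 0.5`, i.e. it separates the two classes strictly:
#' background pixels satisfy `x > threshold`, foreground (dark) pixels
#' `x < threshold`.  Ties take the lowest level.
#'
#' @param image numeric matrix of pixel intensities.
#' @return Numeric threshold with attributes `level` (the argmax level) and
#'   `degenerate` (`TRUE` for a constant image, in which case the constant
#'   itself is returned and no pixel is foreground).
#' @export
compute_otsu_threshold <- function(image) {
  v <- as.numeric(image)
  ux <- sort(unique(v))
  if (length(ux) < 2) {
    return(structure(ux[1], level = ux[1], degenerate = TRUE))
  }
  # histogram over occurring levels (exact for integer-valued images)
  cnt <- tabulate(match(v, ux), nbins = length(ux))
  n <- length(v)
  w0 <- cumsum(cnt) / n
  mu <- cumsum(cnt * ux) / n
  mu_t <- mu[length(mu)]
  # between-class variance for split {<= ux[k]} vs {> ux[k]}
  k <- seq_len(length(ux) - 1)
  bcv <- (mu_t * w0[k] - mu[k])^2 / (w0[k] * (1 - w0[k]))
  best <- which.max(bcv)            # lowest index on ties
  lev <- ux[best]
  structure((lev + ux[best + 1]) / 2, level = lev, degenerate = FALSE)
}

#' Segment dark objects by thresholding and connected components
#'
#' Foreground polarity is fixed: cells appear as blobs darker than the
#' background, so foreground is `image < threshold` (the bright halo ring
#' stays above threshold and does not merge neighboring cells).
#' Components use 8-connectivity.
#'
#' @param image numeric matrix.
#' @param threshold intensity threshold, e.g. from
#'   [compute_otsu_threshold()].
#' @param border_margin_px margin (px) within which a pixel marks its
#'   object as border-touching.
#' @return List of `segmented_object`: `mask` (logical matrix), `area_px`,
#'   `centroid` (row, col), `touches_border`.
#' @export
segment_objects <- function(image, threshold, border_margin_px = 2) {
  fg <- unclass(image) < threshold
  lab <- label_components_cpp(fg, 8L)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  h <- nrow(lab); w <- ncol(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  ri <- ((idx - 1) %% h) + 1
  ci <- ((idx - 1) %/% h) + 1
  m <- border_margin_px
  out <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    sel <- l == k
    rows <- ri[sel]; cols <- ci[sel]
    mask <- matrix(FALSE, h, w)
    mask[idx[sel]] <- TRUE
    out[[k]] <- structure(list(
      mask = mask,
      area_px = sum(sel),
      centroid = c(row = mean(rows), col = mean(cols)),
      touches_border = any(rows <= m | rows > h - m |
                             cols <= m | cols > w - m)),
      class = "segmented_object")
  }
  out
}

#' Size and border filtering of segmented objects
#'
#' Keeps objects whose area lies in the inclusive range
#' `[min_area_px, max_area_px]` and which do not touch the border margin;
#' input order is preserved.
#'
#' @param objects list of `segmented_object`.
#' @param params a [ccva_params()].
#' @return Filtered list.
#' @export
filter_objects <- function(objects, params) {
  check(inherits(params, "ccva_params"), "need ccva_params")
  keep <- vapply(objects, function(o) {
    o$area_px >= params$min_area_px && o$area_px <= params$max_area_px &&
      !o$touches_border
  }, logical(1))
  objects[keep]
}

#' Fit an ellipse to a segmented object by second-order moments
#'
#' Axis lengths follow the image-moments convention: the ellipse with the
#' same normalized second central moments as the pixel mask, full axes
#' `4 * sqrt(eigenvalue)`.  Roundness is `4 * area / (pi * major_axis^2)`
#' (1 for a circle, ~0.5 for a 2:1 ellipse), clamped to 1 since pixel
#' quantization can push a perfect disk marginally above 1.
#'
#' @param object a `segmented_object` with `area_px >= 5` (smaller masks
#'   have degenerate moments and are rejected).
#' @return List of class `ellipse_params`: `major_axis_px`,
#'   `minor_axis_px`, `orientation_rad`, `roundness`.
#' @export
fit_ellipse_to_object <- function(object) {
  check(inherits(object, "segmented_object"), "need a segmented_object")
  check(object$area_px >= 5, "object too small for moment-based ellipse fit")
  idx <- which(object$mask)
  h <- nrow(object$mask)
  r <- ((idx - 1) %% h) + 1
  c <- ((idx - 1) %/% h) + 1
  n <- length(idx)
  mr <- mean(r); mc <- mean(c)
  # +1/12: second moment of the unit pixel itself
  mu20 <- mean((r - mr)^2) + 1 / 12
  mu02 <- mean((c - mc)^2) + 1 / 12
  mu11 <- mean((r - mr) * (c - mc))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 0))
  structure(list(major_axis_px = major,
                 minor_axis_px = minor,
                 orientation_rad = 0.5 * atan2(2 * mu11, mu20 - mu02),
                 roundness = min(1, 4 * n / (pi * major^2))),
            class = "ellipse_params")
}

#' Classify a microwell frame with the classical pipeline
#'
#' Otsu threshold, dark-object segmentation, size and border filtering,
#' ellipse fitting, then the rule table: no surviving object is `Empty`;
#' two or more objects are `Multiple`; one object larger than
#' `single_area_max_px` is `Multiple` (merged clump); one object rounder
#' than `roundness_min` is `Single`; otherwise `Death`.
#'
#' @param image numeric matrix (a `well_image`).
#' @param params a [ccva_params()].
#' @return Character class label (one of [well_classes()]), with attribute
#'   `objects` (the surviving segmented objects).
#' @export
classify_well_ccva <- function(image, params = ccva_params()) {
  thr <- compute_otsu_threshold(image)
  objs <- if (isTRUE(attr(thr, "degenerate"))) list() else
    segment_objects(image, thr, params$border_margin_px)
  objs <- filter_objects(objs, params)
  # tiny objects that survive the size filter but are below the moment
  # minimum cannot be live single cells; drop them like noise
  objs <- Filter(function(o) o$area_px >= 5, objs)
  label <- if (length(objs) == 0) {
    "Empty"
  } else if (length(objs) >= 2) {
    "Multiple"
  } else {
    o <- objs[[1]]
    if (o$area_px > params$single_area_max_px) {
      "Multiple"
    } else {
      ell <- fit_ellipse_to_object(o)
      if (ell$roundness < params$roundness_min) "Death" else "Single"
    }
  }
  structure(label, objects = objs)
}
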