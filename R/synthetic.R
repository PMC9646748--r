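#' Specification of a synthetic microwell scene
#'
#' Describes one brightfield microwell frame for the renderer: a circular
#' agarose well (default 200 um diameter) imaged at `pixel_size_um`, holding
#' zero, one or several round-to-irregular cell blobs, degraded by an
#' illumination gradient, defocus blur and additive Gaussian noise.
#'
#' The default geometry (176 px frame at 1 um/px) makes the 200 um well
#' slightly overfill the frame so its dark rim enters the image only as
#' border-touching arcs near the corners, as in pre-cropped microwell chips.
#'
#' @param content one of `"empty"`, `"single"`, `"multiple"`, `"dead"`.
#' @param well_diameter_um well diameter in micrometers.
#' @param pixel_size_um micrometers per pixel (1.0 emulates 20x; 2.0
#'   emulates 10x magnification).
#' @param image_size_px frame side in pixels (square frames).
#' @param cell_radii_um radii of the living cells, in micrometers; `NULL`
#'   draws each radius uniformly from [5, 12] um.  Must satisfy
#'   `content` (length 1 for `"single"`, >= 2 for `"multiple"`).
#' @param defocus_sigma_px Gaussian defocus blur sigma, pixels (>= 0).
#' @param illum_gradient_amp amplitude of a linear illumination gradient as
#'   a fraction of the dynamic range (0 = flat illumination).
#' @param noise_sd additive Gaussian noise standard deviation, as a fraction
#'   of the dynamic range.
#' @param seed integer seed; every stochastic choice (cell positions, radii,
#'   gradient direction, noise) derives from it, so renders are
#'   bit-reproducible.
#' @return An object of class `well_scene_spec`.
#' @export
well_scene_spec <- function(content = c("empty", "single", "multiple", "dead"),
                            well_diameter_um = 200,
                            pixel_size_um = 1.0,
                            image_size_px = 176L,
                            cell_radii_um = NULL,
                            defocus_sigma_px = 0,
                            illum_gradient_amp = 0,
                            noise_sd = 0,
                            seed = 1L) {
  content <- match.arg(content)
  check(well_diameter_um > 0 && pixel_size_um > 0 && image_size_px >= 16,
        "invalid well geometry")
  # The rim must be visible within the frame: allow overfilling up to the
  # frame diagonal, but not a well so large that no rim arc is imaged.
  check(well_diameter_um / pixel_size_um <= sqrt(2) * image_size_px,
        "well does not fit the frame (no rim arc would be visible)")
  check(defocus_sigma_px >= 0 && illum_gradient_amp >= 0 && noise_sd >= 0,
        "degradation parameters must be nonnegative")
  if (!is.null(cell_radii_um)) {
    check(all(cell_radii_um > 0), "cell radii must be positive")
    check(all(cell_radii_um < well_diameter_um / 2),
          "cell radius larger than well radius")
    n <- length(cell_radii_um)
    check(switch(content, empty = n == 0, single = n == 1,
                 multiple = n >= 2, dead = n == 1),
          sprintf("content '%s' incompatible with %d cell radii", content, n))
  }
  structure(list(content = content,
                 well_diameter_um = well_diameter_um,
                 pixel_size_um = pixel_size_um,
                 image_size_px = as.integer(image_size_px),
                 cell_radii_um = cell_radii_um,
                 defocus_sigma_px = defocus_sigma_px,
                 illum_gradient_amp = illum_gradient_amp,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "well_scene_spec")
}

#' Frozen degradation presets
#'
#' The two imaging conditions the synthetic benchmark distinguishes:
#' `"clean"` (flat illumination, in-focus, noise-free) and `"degraded"`
#' (linear illumination gradient of 20% of the dynamic range, 2.5 px
#' defocus blur, 2% additive noise — the kind of variability that defeats
#' fixed-threshold segmentation on real brightfield data).
#'
#' @param kind `"clean"` or `"degraded"`.
#' @return Named list with `illum_gradient_amp`, `defocus_sigma_px`,
#'   `noise_sd`.
#' @export
scene_conditions <- function(kind = c("clean", "degraded")) {
  kind <- match.arg(kind)
  if (kind == "clean") {
    list(illum_gradient_amp = 0, defocus_sigma_px = 0, noise_sd = 0)
  } else {
    list(illum_gradient_amp = 0.20, defocus_sigma_px = 2.5, noise_sd = 0.02)
  }
}

# Rendering constants (unit dynamic range before 16-bit quantization).
.render_levels <- list(
  background   = 0.72,   # well interior
  outside      = 0.55,   # agarose outside the well
  rim          = 0.30,   # dark well rim
  cell_core    = 0.35,   # live cell body (dark blob)
  halo         = 0.88,   # bright phase-contrast-like halo ring
  dead_contrast = 0.60   # dead-cell contrast multiplier (40% reduction)
)

# Sample cell geometry for a scene: centers (px, row/col) and radii (px).
# Called inside with_seed().
sample_scene_geometry <- function(spec) {
  half <- spec$image_size_px / 2
  well_r <- spec$well_diameter_um / 2 / spec$pixel_size_um
  n_cells <- switch(spec$content, empty = 0L, single = 1L, dead = 1L,
                    multiple = sample(2:4, 1L))
  radii_um <- spec$cell_radii_um
  if (is.null(radii_um) && n_cells > 0)
    radii_um <- stats::runif(n_cells, 5, 12)
  radii <- radii_um / spec$pixel_size_um
  centers <- matrix(numeric(0), 0, 2)
  if (n_cells > 0) {
    # keep cells inside both the well and the frame, clear of the border
    # margin so the border filter never removes a genuine cell
    for (i in seq_len(n_cells)) {
      rmax <- min(well_r, half) - radii[i] - 5
      check(rmax > 0, "cell radius larger than well radius")
      for (try in 1:200) {
        rho <- sqrt(stats::runif(1)) * rmax
        th <- stats::runif(1, 0, 2 * pi)
        cand <- c(half + rho * sin(th), half + rho * cos(th))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                               byrow = TRUE))^2)) >
                radii[seq_len(nrow(centers))] + radii[i] + 4)) break
      }
      centers <- rbind(centers, cand)
    }
  }
  list(n_cells = n_cells, centers = centers, radii = radii, well_r = well_r)
}

# Paint one live cell (dark disk + bright halo) or a dead clump (union of
# 3-6 offset sub-blobs at reduced contrast) onto `img`.  D2 is the squared
# distance field helper.
paint_cell <- function(img, center, radius, dead = FALSE) {
  lv <- .render_levels
  h <- nrow(img)
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(h) - center[2])^2, "+")
  if (!dead) {
    core <- d2 <= radius^2
    halo <- d2 > radius^2 & d2 <= (radius + 2)^2
    img[halo] <- lv$halo
    img[core] <- lv$cell_core
  } else {
    k <- lv$dead_contrast
    core_val <- lv$background - k * (lv$background - lv$cell_core)
    halo_val <- lv$background + k * (lv$halo - lv$background)
    n_blob <- sample(3:6, 1L)
    # sub-blobs overlap the central one (offset < 2 * sub-blob radius) so
    # the clump stays one connected but clearly irregular object
    ang <- stats::runif(n_blob, 0, 2 * pi)
    dist <- stats::runif(n_blob, 0.5, 0.9) * radius
    offs <- cbind(dist * sin(ang), dist * cos(ang))
    offs[1, ] <- 0
    rb <- stats::runif(n_blob, 0.45, 0.65) * radius
    rb[1] <- 0.6 * radius
    core <- matrix(FALSE, h, h)
    for (b in seq_len(n_blob)) {
      db <- outer((seq_len(h) - center[1] - offs[b, 1])^2,
                  (seq_len(h) - center[2] - offs[b, 2])^2, "+")
      core <- core | (db <= rb[b]^2)
    }
    halo <- !core & d2 <= (radius + 2)^2
    img[halo] <- halo_val
    img[core] <- core_val
  }
  img
}

# Paint the static scene (no degradation) and return it with its geometry.
render_scene_clean <- function(spec, geom) {
  lv <- .render_levels
  n <- spec$image_size_px
  half <- n / 2
  d2 <- outer((seq_len(n) - half)^2, (seq_len(n) - half)^2, "+")
  img <- matrix(lv$background, n, n)
  img[d2 > geom$well_r^2] <- lv$outside
  rim <- abs(sqrt(d2) - geom$well_r) <= 2.5
  img[rim] <- lv$rim
  if (geom$n_cells > 0) {
    for (i in seq_len(geom$n_cells)) {
      img <- paint_cell(img, geom$centers[i, ], geom$radii[i],
                        dead = spec$content == "dead")
    }
  }
  img
}

# Apply illumination gradient, defocus and noise, then quantize to 16 bits.
degrade_and_quantize <- function(img, spec, grad_theta) {
  n <- nrow(img)
  if (spec$illum_gradient_amp > 0) {
    u <- (seq_len(n) - (n + 1) / 2) / n
    ramp <- outer(u * sin(grad_theta), u * cos(grad_theta), "+")
    img <- img + spec$illum_gradient_amp * ramp
  }
  img <- gaussian_blur(img, spec$defocus_sigma_px)
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)
  round(img * 65535)
}

#' Render one synthetic microwell frame
#'
#' Draws a dark well rim, a background with the requested illumination
#' gradient, and cell blobs matching the scene content: live cells are dark
#' disks with a bright halo ring (phase-contrast-like), dead cells are
#' connected unions of 3-6 offset sub-blobs at 40% reduced contrast.
#' Degradations are applied in the order gradient, defocus, noise; the
#' result is quantized to 16-bit grayscale.
#'
#' @param spec a [well_scene_spec()].
#' @return A `well_image`: numeric matrix of integers in [0, 65535] with
#'   attributes `pixel_size_um`, `bit_depth` and `scene` (ground-truth
#'   geometry: content, centers, radii in px).
#' @export
render_well <- function(spec) {
  check(inherits(spec, "well_scene_spec"), "spec must be a well_scene_spec")
  with_seed(spec$seed, {
    geom <- sample_scene_geometry(spec)
    img <- render_scene_clean(spec, geom)
    theta <- stats::runif(1, 0, 2 * pi)
    img <- degrade_and_quantize(img, spec, theta)
    structure(img,
              pixel_size_um = spec$pixel_size_um,
              bit_depth = 16L,
              scene = list(content = spec$content,
                           centers_px = geom$centers,
                           radii_px = geom$radii),
              class = c("well_image", class(img)))
  })
}

#' Render a synthetic microwell time-lapse with an optional fate event
#'
#' Frames share one well and cell geometry; the cell performs a small
#' reflected random walk (cells never leave the well).  A division event
#' replaces the single blob by two separated daughter blobs from the event
#' frame on; a death event switches to the dead-clump morphology.  Event
#' times not aligned to the frame grid snap to the next frame; the snapped
#' time is recorded in the ground truth.
#'
#' @param spec a [well_scene_spec()]; must have `content = "single"` when an
#'   event is requested.
#' @param event `NULL`, or `list(type = "division"|"death", time_min = t)`.
#' @param n_frames number of frames (>= 1); alternatively give `duration_h`.
#' @param frame_interval_min minutes between frames (paper-style intervals
#'   are 30, 40 or 80 min).
#' @param duration_h total duration in hours; used when `n_frames` is NULL.
#' @param render if `FALSE`, skip pixel rendering (frames are `NULL`) and
#'   return geometry-free ground truth only — used for large cohorts where
#'   only the oracle probability traces are needed.
#' @return `list(timelapse = well_timelapse, truth = well_truth)`.
#'   The truth holds the initial class, the 7-level outcome
#'   (NoCell / MultipleAtStart / DeadAtStart / Divided / Died /
#'   AliveQuiescent), the (snapped) event time in minutes and the per-frame
#'   true class labels.
#' @export
render_timelapse <- function(spec, event = NULL, n_frames = NULL,
                             frame_interval_min = 40, duration_h = NULL,
                             render = TRUE) {
  check(inherits(spec, "well_scene_spec"), "spec must be a well_scene_spec")
  if (is.null(n_frames)) {
    check(!is.null(duration_h), "give n_frames or duration_h")
    nf <- duration_h * 60 / frame_interval_min
    check(abs(nf - round(nf)) < 1e-9,
          "duration_h must be an integer number of frame intervals")
    n_frames <- as.integer(round(nf)) + 1L
  }
  n_frames <- as.integer(n_frames)
  check(n_frames >= 1, "need at least one frame")
  times <- (seq_len(n_frames) - 1L) * frame_interval_min

  event_frame <- NA_integer_
  snapped <- NA_real_
  if (!is.null(event)) {
    check(spec$content == "single",
          "events are rendered on wells with initial content 'single'")
    check(event$type %in% c("division", "death"), "unknown event type")
    check(event$time_min >= 0 && event$time_min <= max(times),
          "event_time outside the time-lapse duration")
    event_frame <- as.integer(ceiling(event$time_min / frame_interval_min))
    snapped <- event_frame * frame_interval_min
  }

  frame_classes <- rep(switch(spec$content, empty = "Empty",
                              single = "Single", multiple = "Multiple",
                              dead = "Death"), n_frames)
  if (!is.null(event)) {
    post <- seq_len(n_frames) - 1L >= event_frame
    frame_classes[post] <- if (event$type == "division") "Multiple" else "Death"
  }
  initial_class <- frame_classes[1]
  outcome <- switch(initial_class,
                    Empty = "NoCell", Multiple = "MultipleAtStart",
                    Death = "DeadAtStart", Single = "AliveQuiescent")
  event_time_out <- NA_real_
  if (!is.null(event) && initial_class == "Single") {
    outcome <- if (event$type == "division") "Divided" else "Died"
    event_time_out <- snapped
  }

  frames <- NULL
  if (render) {
    frames <- with_seed(spec$seed, {
      geom <- sample_scene_geometry(spec)
      theta <- stats::runif(1, 0, 2 * pi)
      half <- spec$image_size_px / 2
      split_dir <- stats::runif(1, 0, 2 * pi)
      pos <- geom$centers
      out <- vector("list", n_frames)
      for (f in seq_len(n_frames)) {
        fgeom <- geom
        fgeom$centers <- pos
        post_event <- !is.null(event) && (f - 1L) >= event_frame
        fspec <- spec
        if (post_event && event$type == "division" && geom$n_cells == 1) {
          r0 <- geom$radii[1]
          off <- (r0 * 0.95 + 1.5) * c(sin(split_dir), cos(split_dir))
          fgeom$centers <- rbind(pos[1, ] + off, pos[1, ] - off)
          fgeom$radii <- rep(r0 * 0.8, 2)
          fgeom$n_cells <- 2L
        }
        if (post_event && event$type == "death") fspec$content <- "dead"
        img <- render_scene_clean(fspec, fgeom)
        img <- degrade_and_quantize(img, fspec, theta)
        out[[f]] <- structure(img, pixel_size_um = spec$pixel_size_um,
                              bit_depth = 16L,
                              class = c("well_image", "matrix", "array"))
        if (geom$n_cells > 0) {
          # reflected random walk, confined to the well
          step <- matrix(stats::rnorm(2 * geom$n_cells, 0, 0.8),
                         ncol = 2)
          cand <- pos + step
          for (i in seq_len(geom$n_cells)) {
            rmax <- min(geom$well_r, half) - geom$radii[i] - 5
            d <- sqrt(sum((cand[i, ] - half)^2))
            if (d > rmax) cand[i, ] <- half + (cand[i, ] - half) * rmax / d
          }
          pos <- cand
        }
      }
      out
    })
  }

  timelapse <- structure(list(frames = frames, times_min = times,
                              pixel_size_um = spec$pixel_size_um),
                         class = "well_timelapse")
  truth <- structure(list(initial_class = initial_class,
                          outcome = outcome,
                          event_time_min = event_time_out,
                          frame_classes = frame_classes,
                          times_min = times),
                     class = "well_truth")
  list(timelapse = timelapse, truth = truth)
}

#' Kinetic parameters of a synthetic microwell cohort
#'
#' States the composition and fate kinetics of a cohort of microwells over a
#' 96-h time-lapse.  Defaults mirror the annotated time-lapse cohorts:
#' roughly 28% of wells start with a single cell; among single cells, 17%
#' divide and 38% die within 96 h.
#'
#' @param n_wells number of wells.
#' @param frac_single_at_start fraction of wells with exactly one cell at t0.
#'   The remaining wells split 45% empty / 55% multiple (dead-at-start wells
#'   are rare in the annotated cohorts and default to 0, see
#'   `frac_dead_at_start`).
#' @param division_fraction_96h fraction of initial single cells dividing
#'   within `duration_h`.
#' @param death_fraction_96h fraction of initial single cells dying within
#'   `duration_h`; `division + death <= 1`.
#' @param frame_interval_min frame interval (30, 40 and 80 min are the
#'   intervals used on real chips).
#' @param duration_h total duration (default 96 h); must yield an integer
#'   frame count and at least 3 frames (the initial vote needs 3).
#' @param frac_dead_at_start fraction of wells containing dead cells at t0.
#' @param event_time_law `"uniform"` (events uniform on (0, duration]) or
#'   `"constant_hazard"` (truncated-exponential event times whose 96-h
#'   cumulative incidence equals the requested fraction).
#' @param seed integer seed.
#' @return An object of class `cohort_kinetics`.
#' @export
cohort_kinetics <- function(n_wells,
                            frac_single_at_start = 0.28,
                            division_fraction_96h = 0.17,
                            death_fraction_96h = 0.38,
                            frame_interval_min = 30,
                            duration_h = 96,
                            frac_dead_at_start = 0,
                            event_time_law = c("uniform", "constant_hazard"),
                            seed = 1L) {
  event_time_law <- match.arg(event_time_law)
  check(n_wells >= 1, "need at least one well")
  check(frac_single_at_start >= 0 && frac_single_at_start <= 1 &&
          frac_dead_at_start >= 0 &&
          frac_single_at_start + frac_dead_at_start <= 1,
        "invalid start-composition fractions")
  check(division_fraction_96h >= 0 && death_fraction_96h >= 0 &&
          division_fraction_96h + death_fraction_96h <= 1,
        "division_fraction_96h + death_fraction_96h must be <= 1")
  nf <- duration_h * 60 / frame_interval_min
  check(abs(nf - round(nf)) < 1e-9 && round(nf) + 1 >= 3,
        "duration must be an integer number of intervals with >= 3 frames")
  structure(list(n_wells = as.integer(n_wells),
                 frac_single_at_start = frac_single_at_start,
                 division_fraction_96h = division_fraction_96h,
                 death_fraction_96h = death_fraction_96h,
                 frame_interval_min = frame_interval_min,
                 duration_h = duration_h,
                 frac_dead_at_start = frac_dead_at_start,
                 event_time_law = event_time_law,
                 seed = as.integer(seed)),
            class = "cohort_kinetics")
}

#' Simulate a cohort of microwell time-lapses with ground truth
#'
#' Assigns each well a starting content, each initial single cell a fate
#' (division / death / quiescence by independent draws at the requested
#' fractions) and an event time, then builds each well's time-lapse and
#' truth via [render_timelapse()].  Realized fractions converge to the
#' requested ones as `n_wells` grows (binomial sampling).
#'
#' @param kinetics a [cohort_kinetics()].
#' @param render render pixel frames (`TRUE`) or produce frame-free
#'   time-lapses carrying only timestamps and ground truth (`FALSE`,
#'   default — sufficient for oracle-probability studies and much faster).
#' @param ... scene arguments forwarded to [well_scene_spec()]
#'   (degradations, geometry).
#' @return List of `list(timelapse, truth)` of length `n_wells`, with the
#'   kinetics attached as attribute `kinetics`.
#' @export
simulate_cohort <- function(kinetics, render = FALSE, ...) {
  check(inherits(kinetics, "cohort_kinetics"), "need a cohort_kinetics")
  k <- kinetics
  T_min <- k$duration_h * 60
  draws <- with_seed(k$seed, {
    u_class <- stats::runif(k$n_wells)
    p_single <- k$frac_single_at_start
    p_dead <- k$frac_dead_at_start
    p_empty <- (1 - p_single - p_dead) * 0.45
    content <- ifelse(u_class < p_single, "single",
                ifelse(u_class < p_single + p_dead, "dead",
                 ifelse(u_class < p_single + p_dead + p_empty,
                        "empty", "multiple")))
    u_fate <- stats::runif(k$n_wells)
    fate <- ifelse(content != "single", "none",
             ifelse(u_fate < k$division_fraction_96h, "division",
              ifelse(u_fate < k$division_fraction_96h + k$death_fraction_96h,
                     "death", "none")))
    u_t <- stats::runif(k$n_wells)
    t_ev <- if (k$event_time_law == "uniform") {
      u_t * T_min
    } else {
      f <- ifelse(fate == "division", k$division_fraction_96h,
                  k$death_fraction_96h)
      h <- -log(1 - pmin(f, 0.999)) / T_min   # hazard matching 96-h incidence
      -log(1 - u_t * (1 - exp(-h * T_min))) / h
    }
    seeds <- sample.int(.Machine$integer.max - 1L, k$n_wells)
    list(content = content, fate = fate, t_ev = t_ev, seeds = seeds)
  })
  out <- vector("list", k$n_wells)
  for (i in seq_len(k$n_wells)) {
    spec <- well_scene_spec(content = draws$content[i],
                            seed = draws$seeds[i], ...)
    ev <- NULL
    if (draws$content[i] == "single" && draws$fate[i] != "none")
      ev <- list(type = draws$fate[i], time_min = draws$t_ev[i])
    out[[i]] <- render_timelapse(spec, event = ev,
                                 frame_interval_min = k$frame_interval_min,
                                 duration_h = k$duration_h, render = render)
  }
  attr(out, "kinetics") <- k
  out
}

#' Oracle class-probability traces from ground truth
#'
#' Builds the per-frame 4-class probability series a perfect (or uniformly
#' confident) classifier would emit for a well with known ground truth: each
#' frame's true class receives probability `confidence`, the remainder is
#' split uniformly over the other three classes.  This lets the temporal
#' decision tree and the dynamics stage be exercised without a trained
#' network.
#'
#' @param truth a `well_truth` from [render_timelapse()].
#' @param confidence probability mass on the true class, in (0.25, 1]
#'   (above 0.25 so the true class stays the argmax).
#' @param jitter_sd optional Gaussian jitter added to each vector before
#'   re-normalization (0 = deterministic).
#' @param seed seed for the jitter.
#' @return Numeric matrix `n_frames x 4` (columns [well_classes()]), rows
#'   summing to 1, with attribute `times_min`.
#' @export
oracle_probabilities <- function(truth, confidence = 1, jitter_sd = 0,
                                 seed = 1L) {
  check(inherits(truth, "well_truth"), "need a well_truth")
  check(confidence > 0.25 && confidence <= 1,
        "confidence must be in (0.25, 1]")
  cls <- well_classes()
  n <- length(truth$frame_classes)
  P <- matrix((1 - confidence) / 3, n, 4, dimnames = list(NULL, cls))
  P[cbind(seq_len(n), match(truth$frame_classes, cls))] <- confidence
  if (jitter_sd > 0) {
    P <- with_seed(seed, {
      Q <- pmax(P + matrix(stats::rnorm(n * 4, 0, jitter_sd), n, 4), 1e-12)
      Q / rowSums(Q)
    })
    dimnames(P) <- list(NULL, cls)
  }
  attr(P, "times_min") <- truth$times_min
  P
}

#' Generate an annotated classification dataset
#'
#' Renders `n_per_class` microwell images per class and returns a manifest
#' mapping each image to its label, mirroring the structure of a manually
#' annotated brightfield training set (which is strongly imbalanced in the
#' real assay: empties dominate, dead cells are rare).
#'
#' @param n_per_class integer vector of length 4 (order
#'   [well_classes()]), or a single count used for all classes.
#' @param out_dir if non-`NULL`, single-frame 16-bit TIFFs are written there
#'   together with `manifest.csv`.
#' @param keep_images keep the rendered matrices in the returned object
#'   (needed for in-memory training).
#' @param image_size_px,illum_gradient_amp,defocus_sigma_px,noise_sd scene
#'   parameters forwarded to [well_scene_spec()].
#' @param seed integer seed; the same seed reproduces the identical
#'   manifest and images.
#' @return `list(manifest = data.frame(id, path, label), images = list|NULL)`.
#' @export
make_classification_dataset <- function(n_per_class, out_dir = NULL,
                                        keep_images = is.null(out_dir),
                                        image_size_px = 176L,
                                        illum_gradient_amp = 0,
                                        defocus_sigma_px = 0,
                                        noise_sd = 0,
                                        seed = 1L) {
  cls <- well_classes()
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, 4)
  check(length(n_per_class) == 4 && all(n_per_class > 0),
        "n_per_class must be 4 positive counts")
  content_of <- c(Single = "single", Multiple = "multiple",
                  Death = "dead", Empty = "empty")
  labels <- rep(cls, times = n_per_class)
  n <- length(labels)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("well_%05d", seq_len(n))
  paths <- if (is.null(out_dir)) NA_character_ else
    file.path(out_dir, paste0(ids, ".tif"))
  images <- if (keep_images) vector("list", n) else NULL
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  if (keep_images || !is.null(out_dir)) {
    for (i in seq_len(n)) {
      spec <- well_scene_spec(content = content_of[[labels[i]]],
                              image_size_px = image_size_px,
                              illum_gradient_amp = illum_gradient_amp,
                              defocus_sigma_px = defocus_sigma_px,
                              noise_sd = noise_sd, seed = seeds[i])
      img <- render_well(spec)
      if (keep_images) images[[i]] <- img
      if (!is.null(out_dir)) write_well_image(img, paths[i])
    }
  }
  manifest <- data.frame(id = ids, path = paths, label = labels,
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, images = images)
}

#' Ground-truth fate table of a simulated cohort
#'
#' Collects each well's true initial state and outcome into the fate-record
#' layout used by the tracking and dynamics stages, so simulated truth and
#' tracked calls can be compared directly.
#'
#' @param cohort result of [simulate_cohort()].
#' @return Data frame with `well_id`, `initial_state`, `outcome`,
#'   `event_time_min`.
#' @export
cohort_truth_records <- function(cohort) {
  init_of <- c(Single = "SingleCell", Multiple = "MultipleAtStart",
               Death = "DeadAtStart", Empty = "NoCell")
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    tr <- cohort[[i]]$truth
    data.frame(well_id = sprintf("well_%d", i),
               initial_state = init_of[[tr$initial_class]],
               outcome = if (tr$initial_class == "Single") tr$outcome
                         else "NotTracked",
               event_time_min = if (tr$initial_class == "Single")
                 tr$event_time_min else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Oracle probability traces for every well of a cohort
#'
#' @param cohort result of [simulate_cohort()].
#' @param confidence,jitter_sd,seed forwarded to [oracle_probabilities()]
#'   (per-well seeds derive from `seed`).
#' @return List of probability matrices, one per well.
#' @export
cohort_oracle_probabilities <- function(cohort, confidence = 1,
                                        jitter_sd = 0, seed = 1L) {
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max - 1L, length(cohort)))
  lapply(seq_along(cohort), function(i)
    oracle_probabilities(cohort[[i]]$truth, confidence = confidence,
                         jitter_sd = jitter_sd, seed = seeds[i]))
}
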