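# Shared fixtures built in code.

CLS <- well_classes()

# Probability row: named values, remainder on Single.
prow <- function(multiple = 0, death = 0, empty = 0,
                 single = 1 - multiple - death - empty) {
  c(Single = single, Multiple = multiple, Death = death, Empty = empty)
}

# Probability matrix from a list of rows, with timestamps attached.
pmat <- function(rows, interval_min = 40) {
  p <- do.call(rbind, rows)
  colnames(p) <- CLS
  attr(p, "times_min") <- (seq_len(nrow(p)) - 1) * interval_min
  p
}

# Random probability matrix (n frames) with occasional strong
# Multiple / Death frames so event rules actually fire.
random_pmat <- function(n = 12, interval_min = 40) {
  rows <- lapply(seq_len(n), function(i) {
    r <- stats::runif(1)
    if (r < 0.15) prow(multiple = stats::runif(1, 0.9, 1))
    else if (r < 0.3) prow(death = stats::runif(1, 0.45, 1))
    else {
      v <- stats::runif(4)
      v <- v / sum(v)
      names(v) <- CLS
      v
    }
  })
  pmat(rows, interval_min)
}

# Binary mask image of given disks: list of c(row, col, radius).
disk_mask_image <- function(size, disks, fg = 1000, bg = 40000) {
  img <- matrix(bg, size, size)
  for (d in disks) {
    d2 <- outer((seq_len(size) - d[1])^2, (seq_len(size) - d[2])^2, "+")
    img[d2 <= d[3]^2] <- fg
  }
  img
}

# Ideal threshold for clean renders: above every cell level (live core
# 0.35, dead clump 0.498) but below the outside-well level (0.55).
IDEAL_THR <- 0.52 * 65535

# Count non-border foreground objects of a clean render at the ideal
# threshold (the well rim and outside-well corners always touch the
# border and are excluded).
ideal_object_count <- function(img, min_area = 5) {
  objs <- segment_objects(img, IDEAL_THR, 2)
  sum(vapply(objs, function(o)
    !o$touches_border && o$area_px >= min_area, logical(1)))
}

# Fate table with the given event times (minutes); NA = quiescent.
fate_table <- function(div_times = numeric(0), death_times = numeric(0),
                       n_quiet = 0, n_untracked = 0) {
  rbind(
    if (length(div_times))
      data.frame(well_id = NA, initial_state = "SingleCell",
                 outcome = "Divided", event_time_min = div_times),
    if (length(death_times))
      data.frame(well_id = NA, initial_state = "SingleCell",
                 outcome = "Died", event_time_min = death_times),
    if (n_quiet > 0)
      data.frame(well_id = NA, initial_state = "SingleCell",
                 outcome = "AliveQuiescent",
                 event_time_min = rep(NA_real_, n_quiet)),
    if (n_untracked > 0)
      data.frame(well_id = NA, initial_state = "NoCell",
                 outcome = "NotTracked",
                 event_time_min = rep(NA_real_, n_untracked)))
}
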