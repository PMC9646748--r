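#' Thresholds of the temporal fate-calling rules
#'
#' A division is called when at least two frames are classified `Multiple`
#' with probability above `p_multiple_lo`, at least one of them above
#' `p_multiple_hi`; a death when any frame is classified `Death` with
#' probability above `p_death`.  All comparisons are strict, as in the
#' decision tree.
#'
#' @param p_multiple_lo lower `Multiple` probability threshold (0.9).
#' @param p_multiple_hi higher `Multiple` probability threshold (0.99).
#' @param p_death `Death` probability threshold (0.5).
#' @param n_initial_frames frames entering the initial content vote (3).
#' @return Object of class `fate_rule_params`.
#' @export
fate_rule_params <- function(p_multiple_lo = 0.9, p_multiple_hi = 0.99,
                             p_death = 0.5, n_initial_frames = 3L) {
  check(p_multiple_lo >= 0.5 && p_multiple_lo < p_multiple_hi &&
          p_multiple_hi < 1, "need 0.5 <= p_multiple_lo < p_multiple_hi < 1")
  check(p_death > 0 && p_death < 1, "p_death must be in (0, 1)")
  check(n_initial_frames >= 1, "n_initial_frames must be >= 1")
  structure(list(p_multiple_lo = p_multiple_lo,
                 p_multiple_hi = p_multiple_hi,
                 p_death = p_death,
                 n_initial_frames = as.integer(n_initial_frames)),
            class = "fate_rule_params")
}

# Validate an n x 4 probability matrix and return it with canonical
# column order.
as_prob_matrix <- function(p) {
  cls <- well_classes()
  p <- as.matrix(p)
  check(ncol(p) == 4, "probability matrix must have 4 columns")
  if (!is.null(colnames(p))) {
    check(all(cls %in% colnames(p)), "columns must be the four classes")
    p <- p[, cls, drop = FALSE]
  } else {
    colnames(p) <- cls
  }
  check(all(p >= -1e-9) && all(abs(rowSums(p) - 1) < 1e-6),
        "rows must be probability vectors summing to 1")
  p
}

#' Frame-level class from a probability vector
#'
#' Argmax over the four classes; exact ties resolve by the fixed order
#' `Single > Multiple > Death > Empty`.
#'
#' @param p numeric length-4 probability vector (named or in canonical
#'   order), or an `n x 4` matrix (one label per row).
#' @return Character label(s).
#' @export
argmax_label <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1, 4, dimnames = list(NULL, names(p)))
  p <- as_prob_matrix(p)
  well_classes()[max.col(p, ties.method = "first")]
}

#' Initial well content from the first frames
#'
#' Vote over the first three frame labels: any `Multiple` means the well
#' held multiple cells at start; otherwise any `Death` means dead cells at
#' start; all `Empty` means no cell; all `Single` means a tracked single
#' cell.  A mixture of `Single` and `Empty` frames matches none of the
#' rules and is reported `Ambiguous` (excluded from tracking).
#'
#' @param labels character vector of exactly `n_initial_frames` frame
#'   labels.
#' @param params a [fate_rule_params()].
#' @return One of `"NoCell"`, `"MultipleAtStart"`, `"DeadAtStart"`,
#'   `"SingleCell"`, `"Ambiguous"`.
#' @export
classify_initial_state <- function(labels, params = fate_rule_params()) {
  check(length(labels) == params$n_initial_frames,
        sprintf("need exactly %d initial frame labels",
                params$n_initial_frames))
  check(all(labels %in% well_classes()), "unknown frame label")
  if (any(labels == "Multiple")) return("MultipleAtStart")
  if (any(labels == "Death")) return("DeadAtStart")
  if (all(labels == "Empty")) return("NoCell")
  if (all(labels == "Single")) return("SingleCell")
  "Ambiguous"
}

#' Detect a cell division in a probability series
#'
#' Scans for the earliest time by which at least two frames have
#' `p(Multiple) > p_multiple_lo`, at least one of them with
#' `p(Multiple) > p_multiple_hi`.  Frames whose argmax label is `Empty`
#' are ignored (a tracked single cell cannot vanish from a well).
#'
#' @param probs `n x 4` probability matrix.
#' @param times_min frame timestamps (minutes), strictly increasing;
#'   defaults to the matrix's `times_min` attribute.
#' @param params a [fate_rule_params()].
#' @return Event time in minutes (timestamp of the frame completing the
#'   rule), or `NA_real_` if no division is detected.
#' @export
detect_division <- function(probs, times_min = attr(probs, "times_min"),
                            params = fate_rule_params()) {
  p <- as_prob_matrix(probs)
  check(!is.null(times_min) && length(times_min) == nrow(p),
        "need one timestamp per frame")
  check(nrow(p) == 0 || all(diff(times_min) > 0),
        "timestamps must be strictly increasing")
  keep <- argmax_label(p) != "Empty"
  pm <- p[keep, "Multiple"]
  tt <- times_min[keep]
  lo <- pm > params$p_multiple_lo
  hi <- pm > params$p_multiple_hi
  ok <- cumsum(lo) >= 2 & cumsum(hi) >= 1 & lo
  if (!any(ok)) return(NA_real_)
  tt[which(ok)[1]]
}

#' Detect a cell death in a probability series
#'
#' Earliest frame with `p(Death) > p_death` (strict); argmax-`Empty`
#' frames are ignored, as for division.
#'
#' @inheritParams detect_division
#' @return Event time in minutes or `NA_real_`.
#' @export
detect_death <- function(probs, times_min = attr(probs, "times_min"),
                         params = fate_rule_params()) {
  p <- as_prob_matrix(probs)
  check(!is.null(times_min) && length(times_min) == nrow(p),
        "need one timestamp per frame")
  check(nrow(p) == 0 || all(diff(times_min) > 0),
        "timestamps must be strictly increasing")
  keep <- argmax_label(p) != "Empty"
  hit <- which(p[keep, "Death"] > params$p_death)
  if (length(hit) == 0) return(NA_real_)
  times_min[keep][hit[1]]
}

#' Call the fate of one well from its probability series
#'
#' The full temporal decision tree: the initial state is voted from the
#' first three frame labels; wells that do not start with a single cell
#' are not tracked.  For a tracked single cell, a division signature takes
#' precedence over a death signature (evaluated over the whole series, in
#' the rule order "division, else death, else quiescent"), and the
#' remaining case is a living, non-dividing cell.  The rules are scanned
#' over all frames including the initial window; argmax-`Empty` frames
#' after the vote are ignored.
#'
#' @param probs `n x 4` probability matrix (`n >= n_initial_frames`).
#' @param times_min frame timestamps in minutes.
#' @param params a [fate_rule_params()].
#' @param well_id optional identifier copied into the record.
#' @return A one-row data frame (`fate_record`): `well_id`,
#'   `initial_state`, `outcome` (`Divided`, `Died`, `AliveQuiescent` or
#'   `NotTracked`), `event_time_min` (`NA` unless divided or died).
#' @export
track_well <- function(probs, times_min = attr(probs, "times_min"),
                       params = fate_rule_params(), well_id = NA_character_) {
  p <- as_prob_matrix(probs)
  check(nrow(p) >= params$n_initial_frames,
        sprintf("need at least %d frames", params$n_initial_frames))
  check(!is.null(times_min) && length(times_min) == nrow(p),
        "need one timestamp per frame")
  labels <- argmax_label(p[seq_len(params$n_initial_frames), , drop = FALSE])
  init <- classify_initial_state(labels, params)
  outcome <- "NotTracked"
  t_ev <- NA_real_
  if (init == "SingleCell") {
    t_div <- detect_division(p, times_min, params)
    t_die <- detect_death(p, times_min, params)
    if (!is.na(t_div)) {
      outcome <- "Divided"; t_ev <- t_div
    } else if (!is.na(t_die)) {
      outcome <- "Died"; t_ev <- t_die
    } else {
      outcome <- "AliveQuiescent"
    }
  }
  structure(data.frame(well_id = well_id, initial_state = init,
                       outcome = outcome, event_time_min = t_ev,
                       stringsAsFactors = FALSE),
            class = c("fate_record", "data.frame"))
}

#' Track every well of a cohort
#'
#' Applies [track_well()] to a list of probability matrices (or to a
#' simulated cohort via oracle probabilities).
#'
#' @param prob_list list of `n x 4` probability matrices with `times_min`
#'   attributes.
#' @param params a [fate_rule_params()].
#' @param well_ids identifiers (defaults to `well_1 ... well_n`).
#' @return Data frame of fate records, one row per well.
#' @export
track_cohort <- function(prob_list, params = fate_rule_params(),
                         well_ids = sprintf("well_%d", seq_along(prob_list))) {
  out <- lapply(seq_along(prob_list), function(i)
    track_well(prob_list[[i]], params = params, well_id = well_ids[i]))
  do.call(rbind, out)
}
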