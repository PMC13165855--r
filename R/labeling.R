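#' Deviation-event session
#'
#' Behavioral record of one simulated-driving session: for each lateral
#' deviation event `i`, `dep[i]` is the deviation onset time and `act[i]`
#' the time the subject began the corrective response (both in seconds,
#' `act >= dep`, onsets strictly increasing).
#'
#' @param dep Numeric vector of deviation onset times (s).
#' @param act Numeric vector of response times (s), same length.
#' @param subject_id Subject label.
#' @return A `session_events` object.
#' @export
session_events <- function(dep, act, subject_id = NA_character_) {
  stopifnot(length(dep) == length(act))
  if (length(dep) > 1L && any(diff(dep) <= 0)) {
    stop("deviation onsets must be strictly increasing")
  }
  bad <- which(act < dep)
  if (length(bad)) {
    stop("response precedes deviation onset at event(s) ",
         paste(bad, collapse = ", "))
  }
  structure(list(dep = as.numeric(dep), act = as.numeric(act),
                 subject_id = as.character(subject_id)),
            class = "session_events")
}

#' Local reaction time
#'
#' The per-event local reaction time `LRT(i) = Act(i) - Dep(i)`: elapsed
#' time from deviation onset to the first corrective response.
#'
#' @param session A [session_events()] object.
#' @return Numeric vector of reaction times (s), one per event (empty for
#'   an empty session).
#' @export
compute_lrt <- function(session) {
  stopifnot(inherits(session, "session_events"))
  session$act - session$dep
}

#' Global reaction time
#'
#' For each event `i`, the mean LRT over all *prior* events whose onsets
#' fall in the preceding look-back window:
#' `GRT(i) = mean{ LRT(j) : j < i, 0 <= Dep(i) - Dep(j) <= window_s }`.
#' Events with fewer than two qualifying prior events have undefined GRT
#' and are returned as `NA` (such events cannot be labeled and are
#' discarded downstream).
#'
#' @param session A [session_events()] object.
#' @param lrt Per-event LRT vector aligned with the session (defaults to
#'   [compute_lrt()] of the session).
#' @param window_s Look-back window in seconds (default 90).
#' @return Numeric vector with `NA` where GRT is undefined.
#' @export
compute_grt <- function(session, lrt = compute_lrt(session), window_s = 90) {
  stopifnot(inherits(session, "session_events"),
            length(lrt) == length(session$dep))
  n <- length(lrt)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- which(session$dep[seq_len(i - 1L)] >= session$dep[i] - window_s)
    if (length(j) >= 2L) out[i] <- mean(lrt[j])
  }
  out
}

#' Alert reaction-time threshold
#'
#' The 95th percentile of all LRT values (alert and fatigued pooled),
#' computed by linear interpolation between order statistics
#' (`stats::quantile` type 7, the common default). The percentile
#' convention is configurable via `type`.
#'
#' @param all_lrt Non-empty numeric vector of LRT values (s).
#' @param percentile Percentile in (0, 100]; default 95.
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return The threshold in seconds.
#' @export
compute_art <- function(all_lrt, percentile = 95, type = 7) {
  if (length(all_lrt) == 0L) stop("cannot compute ART from an empty LRT list")
  stopifnot(all(is.finite(all_lrt)))
  unname(stats::quantile(all_lrt, probs = percentile / 100, type = type))
}

#' Label events from reaction times
#'
#' The two-threshold rule on local and global reaction time: an event is
#' FATIGUED when both `lrt > 2.5 * art` and `grt > 2.5 * art`, ALERT when
#' both `lrt < 1.5 * art` and `grt < 1.5 * art`, and DISCARD otherwise —
#' including undefined (`NA`) GRT and any value falling in the ambiguous
#' band `[1.5 * art, 2.5 * art]` (the inequalities are strict on both
#' sides, so exact boundary values are discarded).
#'
#' @param lrt,grt Numeric vectors (s); `grt` may contain `NA`.
#' @param art Alert reaction-time threshold (s), positive.
#' @return Character vector with values `"fatigued"`, `"alert"`,
#'   `"discard"`.
#' @export
label_rt_event <- function(lrt, grt, art) {
  stopifnot(length(lrt) == length(grt), is.finite(art), art > 0)
  out <- rep("discard", length(lrt))
  ok <- !is.na(grt)
  out[ok & lrt > 2.5 * art & grt > 2.5 * art] <- "fatigued"
  out[ok & lrt < 1.5 * art & grt < 1.5 * art] <- "alert"
  out
}

#' Label a whole session under the reaction-time scheme
#'
#' Convenience pipeline: LRT, GRT and labels for one session. `art` is
#' normally the dataset-level threshold from pooled LRTs; when `NULL` it
#' is computed from this session alone (per-session mode).
#'
#' @param session A [session_events()] object.
#' @param art Threshold in seconds, or `NULL` for per-session computation.
#' @param window_s GRT look-back window (s).
#' @return Data frame with columns `dep`, `act`, `lrt`, `grt`, `label`.
#' @export
label_rt_session <- function(session, art = NULL, window_s = 90) {
  lrt <- compute_lrt(session)
  grt <- compute_grt(session, lrt, window_s)
  if (is.null(art)) art <- compute_art(lrt)
  data.frame(dep = session$dep, act = session$act, lrt = lrt, grt = grt,
             label = label_rt_event(lrt, grt, art))
}

#' Retain subjects with enough labeled segments
#'
#' Keeps exactly the subjects with at least `min_per_class` labeled
#' segments in *both* classes.
#'
#' @param counts Data frame with columns `subject_id`, `n_fatigued`,
#'   `n_alert`.
#' @param min_per_class Minimum per-class count (default 50).
#' @return Character vector of retained subject ids.
#' @export
filter_retained_subjects <- function(counts, min_per_class = 50) {
  stopifnot(all(c("subject_id", "n_fatigued", "n_alert") %in% names(counts)),
            all(counts$n_fatigued >= 0), all(counts$n_alert >= 0))
  as.character(counts$subject_id[counts$n_fatigued >= min_per_class &
                                 counts$n_alert >= min_per_class])
}

#' Percentage of eyelid closure (PERCLOS)
#'
#' The fraction of the observable interval during which the eyes were
#' fully closed: `t_closure / (t_blink + t_fixation + t_saccade +
#' t_closure)`. The observable interval may be shorter than the epoch when
#' eye tracking drops out; epochs with zero observable interval have no
#' defined PERCLOS and are returned as `NA` (the caller must leave them
#' unlabeled).
#'
#' @param t_blink,t_fixation,t_saccade,t_closure Non-negative durations in
#'   seconds (vectors recycled to common length).
#' @return Numeric vector of ratios in `[0, 1]`, `NA` where undefined.
#' @export
compute_perclos <- function(t_blink, t_fixation, t_saccade, t_closure) {
  d <- cbind(t_blink, t_fixation, t_saccade, t_closure)
  if (any(d < 0)) stop("durations must be non-negative")
  interval <- rowSums(d)
  out <- ifelse(interval > 0, t_closure / interval, NA_real_)
  unname(out)
}

#' Label epochs from PERCLOS
#'
#' Binary threshold rule: FATIGUED when `perclos > threshold` (strict),
#' ALERT otherwise. PERCLOS labeling never discards an epoch; `NA` PERCLOS
#' (no eye-tracking coverage) propagates as `NA`.
#'
#' @param perclos Numeric vector of ratios in `[0, 1]` (may contain `NA`).
#' @param threshold Decision threshold, default 0.5.
#' @return Character vector `"fatigued"` / `"alert"` (with `NA` where
#'   PERCLOS is undefined).
#' @export
label_perclos <- function(perclos, threshold = 0.5) {
  ok <- !is.na(perclos)
  if (any(perclos[ok] < 0 | perclos[ok] > 1)) {
    stop("perclos values must lie in [0, 1]")
  }
  ifelse(is.na(perclos), NA_character_,
         ifelse(perclos > threshold, "fatigued", "alert"))
}
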