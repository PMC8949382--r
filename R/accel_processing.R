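#' Epoch-processing rules
#'
#' Bundles the wear-time, intensity and bout rules applied to minute-epoch
#' accelerometer data. Defaults follow the GT1M-era conventions: non-wear is
#' >= 90 min of consecutive zero counts allowing interruptions of up to 2
#' consecutive non-zero minutes; sedentary behaviour (SB) is < 100 counts/min,
#' light activity (LIPA) 100--1951, moderate-to-vigorous activity (MVPA)
#' >= 1952; an MVPA bout is >= 10 consecutive MVPA minutes and an SB bout
#' >= 30 consecutive SB minutes; a valid day has >= 600 min (10 h) of wear and
#' a valid participant-wave >= 3 valid days; the weekly activity guideline is
#' 150 min of MVPA.
#'
#' @param nonwear_window Minimum total zero-count minutes in a non-wear run.
#' @param nonwear_allowance Maximum length (minutes) of a non-zero
#'   interruption that a non-wear run may absorb.
#' @param sb_upper Upper count bound (inclusive) for SB.
#' @param lipa_upper Upper count bound (inclusive) for LIPA.
#' @param mvpa_lower Lower count bound (inclusive) for MVPA; must equal
#'   `lipa_upper + 1`.
#' @param mvpa_bout_min Minimum length (minutes) of an MVPA bout.
#' @param sb_bout_min Minimum length (minutes) of an SB bout.
#' @param valid_day_wear Minimum wear minutes for a valid day.
#' @param valid_file_days Minimum valid days for a retained participant-wave.
#' @param guideline_weekly_mvpa Weekly MVPA guideline in minutes.
#' @param choi_flank If `TRUE`, apply the stricter variant in which a
#'   non-zero interruption is only absorbed into a non-wear run when it is
#'   flanked on both sides by >= 30 consecutive zero-count minutes.
#' @return An object of class `pa_rules`.
#' @export
processing_rules <- function(nonwear_window = 90L, nonwear_allowance = 2L,
                             sb_upper = 99L, lipa_upper = 1951L,
                             mvpa_lower = 1952L, mvpa_bout_min = 10L,
                             sb_bout_min = 30L, valid_day_wear = 600L,
                             valid_file_days = 3L,
                             guideline_weekly_mvpa = 150,
                             choi_flank = FALSE) {
  stopifnot(sb_upper < lipa_upper, mvpa_lower == lipa_upper + 1L)
  thresholds <- c(nonwear_window, nonwear_allowance, sb_upper, lipa_upper,
                  mvpa_lower, mvpa_bout_min, sb_bout_min, valid_day_wear,
                  valid_file_days, guideline_weekly_mvpa)
  if (any(thresholds <= 0)) stop("all processing thresholds must be positive")
  structure(list(nonwear_window = as.integer(nonwear_window),
                 nonwear_allowance = as.integer(nonwear_allowance),
                 sb_upper = as.integer(sb_upper),
                 lipa_upper = as.integer(lipa_upper),
                 mvpa_lower = as.integer(mvpa_lower),
                 mvpa_bout_min = as.integer(mvpa_bout_min),
                 sb_bout_min = as.integer(sb_bout_min),
                 valid_day_wear = as.integer(valid_day_wear),
                 valid_file_days = as.integer(valid_file_days),
                 guideline_weekly_mvpa = guideline_weekly_mvpa,
                 choi_flank = isTRUE(choi_flank)),
            class = "pa_rules")
}

#' Detect non-wear minutes in one day of epoch counts
#'
#' A non-wear period is a run of zero-count epochs totalling at least
#' `rules$nonwear_window` zero minutes; the run may absorb interior
#' interruptions of at most `rules$nonwear_allowance` consecutive non-zero
#' epochs (absorbed interruption minutes are marked non-wear too). No
#' flanking-window condition is imposed unless `rules$choi_flank` is set.
#'
#' @param counts Integer vector of epoch counts for one day.
#' @param rules A [processing_rules()] object.
#' @return Logical vector, `TRUE` where the epoch is worn.
#' @export
detect_nonwear <- function(counts, rules = processing_rules()) {
  n <- length(counts)
  if (n == 0L) return(logical(0))
  if (any(counts < 0)) stop("negative counts in epoch stream")
  r <- rle(counts == 0)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wear <- rep(TRUE, n)
  # zero-run indices in the rle; merge consecutive zero runs whose separating
  # non-zero gap is within the allowance (and, under choi_flank, whose
  # neighbouring zero runs are both >= 30 min)
  zi <- which(r$values)
  nz <- length(zi)
  if (nz == 0L) return(wear)
  if (nz > 1L) {
    gaps <- starts[zi[-1L]] - ends[zi[-nz]] - 1L
    absorb <- gaps <= rules$nonwear_allowance
    if (rules$choi_flank) {
      absorb <- absorb & r$lengths[zi[-nz]] >= 30L &
        r$lengths[zi[-1L]] >= 30L
    }
    grp <- cumsum(c(TRUE, !absorb))
  } else {
    grp <- 1L
  }
  zero_tot <- rowsum(r$lengths[zi], grp)[, 1]
  for (g in which(zero_tot >= rules$nonwear_window)) {
    members <- zi[grp == g]
    wear[starts[members[1L]]:ends[members[length(members)]]] <- FALSE
  }
  wear
}

#' Classify epochs into intensity categories
#'
#' Wear epochs are labelled by counts-per-minute cut-points; non-wear epochs
#' are labelled `"nonwear"` regardless of counts.
#'
#' @param counts Integer vector of epoch counts.
#' @param wear Logical wear flags from [detect_nonwear()].
#' @param rules A [processing_rules()] object.
#' @return Character vector with values in `c("nonwear","SB","LIPA","MVPA")`.
#' @export
classify_intensity <- function(counts, wear, rules = processing_rules()) {
  if (any(counts < 0)) stop("negative counts in epoch stream")
  stopifnot(length(counts) == length(wear))
  cls <- rep("SB", length(counts))
  cls[counts > rules$sb_upper] <- "LIPA"
  cls[counts >= rules$mvpa_lower] <- "MVPA"
  cls[!wear] <- "nonwear"
  cls
}

#' Detect bouts of a target intensity
#'
#' A bout is a maximal run of strictly consecutive epochs in the target class
#' with length at least `min_length`; no tolerance minutes are allowed. Runs
#' truncated by the day boundary count if long enough.
#'
#' @param classes Character vector of per-epoch intensity classes.
#' @param target Class to detect bouts of (e.g. `"MVPA"`).
#' @param min_length Minimum bout length in epochs.
#' @return A data.frame with columns `start` (0-based) and `length`; the bout
#'   covers the half-open epoch interval `[start, start + length)`.
#' @export
detect_bouts <- function(classes, target, min_length) {
  r <- rle(classes == target)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_length
  data.frame(start = (ends - r$lengths)[keep], length = r$lengths[keep])
}

#' Summarise one classified day
#'
#' @param counts,steps Integer epoch vectors for the day.
#' @param rules A [processing_rules()] object.
#' @return One-row data.frame: wear/SB/LIPA/MVPA minutes, bout counts and
#'   minutes, total counts and steps, and a `valid` flag
#'   (wear >= `rules$valid_day_wear`).
#' @export
summarise_day <- function(counts, steps = NULL, rules = processing_rules()) {
  as.data.frame(.summarise_day_list(counts, steps, rules))
}

# list-returning core, used directly in grouped data.table aggregation
.summarise_day_list <- function(counts, steps, rules) {
  if (is.null(steps)) steps <- integer(length(counts))
  wear <- detect_nonwear(counts, rules)
  cls <- classify_intensity(counts, wear, rules)
  sb_bouts <- detect_bouts(cls, "SB", rules$sb_bout_min)
  mvpa_bouts <- detect_bouts(cls, "MVPA", rules$mvpa_bout_min)
  wear_minutes <- sum(wear)
  list(
    wear_minutes = wear_minutes,
    sb_minutes = sum(cls == "SB"),
    lipa_minutes = sum(cls == "LIPA"),
    mvpa_minutes = sum(cls == "MVPA"),
    sb_bout_count = nrow(sb_bouts),
    sb_bout_minutes = sum(sb_bouts$length),
    mvpa_bout_count = nrow(mvpa_bouts),
    mvpa_bout_minutes = sum(mvpa_bouts$length),
    total_counts = sum(counts[wear]),
    total_steps = sum(steps[wear]),
    valid = wear_minutes >= rules$valid_day_wear
  )
}

#' Process an epoch table into per-day summaries
#'
#' @param epochs data.frame/data.table with columns `participant_id`,
#'   `wave_month`, `day_index`, `epoch_index`, `counts`, `steps` (the epoch
#'   CSV dialect written by [write_cohort()]).
#' @param rules A [processing_rules()] object.
#' @return data.table of [summarise_day()] rows keyed by participant, wave
#'   and day.
#' @export
process_epochs <- function(epochs, rules = processing_rules()) {
  dt <- data.table::as.data.table(epochs)
  req <- c("participant_id", "wave_month", "day_index", "epoch_index",
           "counts", "steps")
  if (!all(req %in% names(dt))) {
    stop("epoch table must have columns: ", paste(req, collapse = ", "))
  }
  data.table::setorderv(dt, c("participant_id", "wave_month", "day_index",
                              "epoch_index"))
  out <- dt[, .summarise_day_list(counts, steps, rules),
            by = c("participant_id", "wave_month", "day_index")]
  out[]
}

#' Apply the wear-time validity filter
#'
#' A participant-wave is retained iff it has at least `rules$valid_file_days`
#' valid days; invalid days are dropped from retained waves. Participants with
#' no retained wave are excluded from modelling.
#'
#' @param day_summaries Output of [process_epochs()].
#' @param rules A [processing_rules()] object.
#' @return List with `days` (valid days of retained waves), `waves` (retained
#'   participant-waves with day counts), and `exclusions` (dropped
#'   participant-waves and fully excluded participants).
#' @export
filter_valid_waves <- function(day_summaries, rules = processing_rules()) {
  dt <- data.table::as.data.table(day_summaries)
  valid <- NULL  # NSE note
  wv <- dt[, list(n_valid = sum(valid), n_days = .N),
           by = c("participant_id", "wave_month")]
  wv$retained <- wv$n_valid >= rules$valid_file_days
  days <- dt[valid == TRUE][wv[wv$retained, c("participant_id", "wave_month")],
                            on = c("participant_id", "wave_month")]
  all_ids <- unique(dt$participant_id)
  kept_ids <- unique(wv$participant_id[wv$retained])
  list(days = days[],
       waves = wv[wv$retained, ][],
       exclusions = list(
         dropped_waves = wv[!wv$retained, ][],
         excluded_participants = setdiff(all_ids, kept_ids)))
}

#' Weekly MVPA and guideline achievement for one participant-wave
#'
#' Mean daily MVPA over the included valid days, multiplied by 7; the
#' guideline flag is `TRUE` when the weekly value reaches
#' `rules$guideline_weekly_mvpa` (inclusive).
#'
#' @param mvpa_daily Numeric vector of daily MVPA minutes (valid days only).
#' @param rules A [processing_rules()] object.
#' @return List with `weekly_mvpa` (min/week) and `meets_guideline`.
#' @export
weekly_mvpa <- function(mvpa_daily, rules = processing_rules()) {
  stopifnot(length(mvpa_daily) >= 1)
  wk <- mean(mvpa_daily) * 7
  list(weekly_mvpa = wk, meets_guideline = wk >= rules$guideline_weekly_mvpa)
}
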