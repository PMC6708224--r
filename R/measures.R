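# The 15 physical-behavior measures: amount and intensity (%Active, %MVPA,
# CPD, CPM, %SB), frequency and duration (MVPA BL/NoB/tt, SB BL/NoB/tt) and
# day patterns (dMVPA1/2, dSB1/2). Weekly totals are sums over valid days
# rescaled to a 7-day week; percentage measures are wear-time-normalized
# over all valid days pooled; day-part percentages are averaged across days
# before differencing.

#' Day-part window definition
#'
#' Half-open clock-hour windows \[start, end). Defaults are conventional
#' tertiles of the waking day: morning 06-12, afternoon 12-18, evening
#' 18-24.
#'
#' @param morning,afternoon,evening numeric length-2 vectors of decimal
#'   hours.
#' @return object of class `daypart_definition`.
#' @export
daypart_definition <- function(morning = c(6, 12), afternoon = c(12, 18),
                               evening = c(18, 24)) {
  w <- rbind(morning, afternoon, evening)
  if (any(diff(as.vector(t(w))) < 0))
    stop("day-part windows must be ordered and non-overlapping")
  structure(list(morning = morning, afternoon = afternoon,
                 evening = evening),
            class = "daypart_definition")
}

daypart_of <- function(timestamp, dayparts) {
  h <- as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60
  part <- rep(NA_character_, length(h))
  part[h >= dayparts$morning[1] & h < dayparts$morning[2]] <- "morning"
  part[h >= dayparts$afternoon[1] & h < dayparts$afternoon[2]] <- "afternoon"
  part[h >= dayparts$evening[1] & h < dayparts$evening[2]] <- "evening"
  factor(part, levels = c("morning", "afternoon", "evening"))
}

#' Compute the 15 physical-behavior measures for one participant
#'
#' Only valid days contribute. Weekly totals (tt MVPA, tt SB, MVPA NoB,
#' SB NoB) are summed over valid days and rescaled by 7 / #valid-days.
#' Sedentary bouts are any uninterrupted sedentary run (minimum 1 epoch);
#' prolonged MVPA bouts require at least `mvpa_bout_min` uninterrupted
#' minutes. Day-part percentages are computed within each window over the
#' wear time in that window, averaged across valid days with wear in the
#' window, then differenced into the four change scores. If a day part has
#' no wear on every valid day the change scores are `NA` and the
#' participant is flagged.
#'
#' @param df labeled epoch data for one participant: columns `timestamp`,
#'   `counts`, `label` (from [classify_intensity()]).
#' @param valid_dates the Dates of this participant's valid days.
#' @param dayparts a [daypart_definition()].
#' @param mvpa_bout_min minimum prolonged-MVPA bout duration, minutes.
#' @param sb_bout_min minimum sedentary bout duration, minutes.
#' @param epoch_length epoch length, seconds.
#' @return named list: the 15 measures, `n_valid_days`, auxiliary day-part
#'   sedentary percentages (`sb_morning`, `sb_afternoon`, `sb_evening`) and
#'   logical `daypart_flag`.
#' @export
compute_measures <- function(df, valid_dates, dayparts = daypart_definition(),
                             mvpa_bout_min = 10, sb_bout_min = 1,
                             epoch_length = 60L) {
  epk <- epoch_length / 60
  date <- as.Date(df$timestamp, tz = "UTC")
  df <- df[date %in% valid_dates & df$label != "nonwear", , drop = FALSE]
  date <- as.Date(df$timestamp, tz = "UTC")
  v <- length(valid_dates)
  if (!nrow(df) || v == 0) stop("participant has no worn epochs on valid days")

  wear_min <- nrow(df) * epk
  sb_min <- sum(df$label == "SB") * epk
  mvpa_min <- sum(df$label == "MVPA") * epk

  pct_sb <- 100 * sb_min / wear_min
  pct_active <- 100 - pct_sb
  pct_mvpa <- 100 * mvpa_min / wear_min
  cpd <- sum(df$counts) / v
  cpm <- sum(df$counts) / wear_min

  # runs must not join across recording gaps (non-worn epochs are usually
  # absent as rows): split days at timestamp discontinuities
  day_bouts <- function(ix, state, mind) {
    gap_seg <- cumsum(c(0, diff(as.numeric(df$timestamp[ix])) >
                          epoch_length))
    do.call(rbind, lapply(split(ix, gap_seg), function(jx)
      detect_bouts(df$label[jx], state, mind, epoch_length = epoch_length)))
  }
  by_day <- split(seq_len(nrow(df)), date)
  sb_bouts <- do.call(rbind, lapply(by_day, day_bouts, state = "SB",
                                    mind = sb_bout_min))
  mvpa_bouts <- do.call(rbind, lapply(by_day, day_bouts, state = "MVPA",
                                      mind = mvpa_bout_min))
  scale7 <- 7 / v
  sb_nob <- nrow(sb_bouts) * scale7
  tt_sb <- if (nrow(sb_bouts)) sum(sb_bouts$duration) * scale7 else 0
  sb_bl <- if (nrow(sb_bouts)) mean(sb_bouts$duration) else 0
  mvpa_nob <- nrow(mvpa_bouts) * scale7
  tt_mvpa <- if (nrow(mvpa_bouts)) sum(mvpa_bouts$duration) * scale7 else 0
  mvpa_bl <- if (nrow(mvpa_bouts)) mean(mvpa_bouts$duration) else 0

  # day-part percentages: per valid day within-window, then averaged
  part <- daypart_of(df$timestamp, dayparts)
  pct_part <- function(state) {
    tab <- tapply(df$label == state, list(date, part), mean)
    colMeans(tab * 100, na.rm = TRUE)  # NaN when no wear in window any day
  }
  sbp <- pct_part("SB")
  mvp <- pct_part("MVPA")
  daypart_flag <- anyNA(sbp) || any(is.nan(sbp))

  list(pct_active = pct_active, pct_mvpa = pct_mvpa, pct_sb = pct_sb,
       cpd = cpd, cpm = cpm,
       mvpa_bl = mvpa_bl, mvpa_nob = mvpa_nob, tt_mvpa = tt_mvpa,
       sb_bl = sb_bl, sb_nob = sb_nob, tt_sb = tt_sb,
       d_mvpa1 = mvp[["afternoon"]] - mvp[["morning"]],
       d_mvpa2 = mvp[["evening"]] - mvp[["afternoon"]],
       d_sb1 = sbp[["afternoon"]] - sbp[["morning"]],
       d_sb2 = sbp[["evening"]] - sbp[["afternoon"]],
       n_valid_days = v,
       sb_morning = sbp[["morning"]], sb_afternoon = sbp[["afternoon"]],
       sb_evening = sbp[["evening"]],
       daypart_flag = daypart_flag)
}

#' Compute the per-participant measure table for a cohort
#'
#' Classifies intensities, applies the wear-validity rules and computes the
#' 15 measures for every included participant.
#'
#' @param epochs epoch data.frame (`participant_id`, `timestamp`, `counts`,
#'   `worn`), e.g. from [read_epoch_csv()] or [simulate_cohort()].
#' @param cutpoints a [cutpoint_config()].
#' @param dayparts a [daypart_definition()].
#' @param min_valid_days,min_wear_min wear-validity thresholds.
#' @param mvpa_bout_min minimum prolonged-MVPA bout duration, minutes.
#' @return list with `measures` (one row per included participant: 15
#'   measures, `n_valid_days`, auxiliary day-part columns) and `exclusions`
#'   (data.frame `participant_id`, `reason`).
#' @export
measures_table <- function(epochs, cutpoints = cutpoint_config(),
                           dayparts = daypart_definition(),
                           min_valid_days = 5, min_wear_min = 660,
                           mvpa_bout_min = 10) {
  if (is.null(epochs) || !nrow(epochs)) stop("empty epoch table")
  epochs <- epochs[order(epochs$participant_id, epochs$timestamp), ,
                   drop = FALSE]
  epochs$label <- classify_intensity(epochs$counts, epochs$worn, cutpoints)
  prof <- day_profiles(epochs, cutpoints$epoch_length)
  vw <- validate_wear(prof, min_valid_days, min_wear_min)

  rows <- list()
  excl <- list()
  by_pid <- split(seq_len(nrow(epochs)), epochs$participant_id)
  valid_by_pid <- split(vw$profiles$date[vw$profiles$valid],
                        vw$profiles$participant_id[vw$profiles$valid])
  for (i in seq_len(nrow(vw$participants))) {
    prow <- vw$participants[i, ]
    pid <- prow$participant_id
    if (!prow$included) {
      excl[[pid]] <- data.frame(participant_id = pid,
                                reason = sprintf("only %d valid days",
                                                 prow$n_valid_days))
      next
    }
    m <- compute_measures(epochs[by_pid[[pid]], ],
                          valid_dates = valid_by_pid[[pid]],
                          dayparts = dayparts,
                          mvpa_bout_min = mvpa_bout_min,
                          epoch_length = cutpoints$epoch_length)
    rows[[pid]] <- data.frame(participant_id = pid,
                              m[setdiff(names(m), "daypart_flag")],
                              daypart_flag = m$daypart_flag,
                              stringsAsFactors = FALSE)
  }
  measures <- if (length(rows)) do.call(rbind, rows) else
    stop("no participant passed wear-time validation")
  rownames(measures) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(0), reason = character(0))
  rownames(exclusions) <- NULL
  list(measures = measures, exclusions = exclusions)
}

#' Write a measure table to CSV
#'
#' @param measures measure data.frame from [measures_table()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_measures_csv <- function(measures, path) {
  cols <- c("participant_id", pb_measure_info()$measure, "n_valid_days")
  write.csv(measures[intersect(cols, names(measures))], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
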