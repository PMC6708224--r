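# Epoch-level accelerometry: CSV reading, wear-time validation, intensity
# classification by counts-per-minute cut-points, and bout detection.

#' Intensity cut-point configuration
#'
#' Defaults are the standard adult vertical-axis cut-points: sedentary below
#' 100 counts/min, MVPA at or above 1952 counts/min. The source analysis
#' delegated its cut-offs to an earlier calibration study without printing
#' them, so these defaults are declared, configurable conventions.
#'
#' @param epoch_length epoch length in seconds.
#' @param sedentary_max exclusive counts-per-minute upper bound for
#'   sedentary behavior.
#' @param mvpa_min inclusive counts-per-minute lower bound for MVPA.
#' @return object of class `cutpoint_config`.
#' @export
cutpoint_config <- function(epoch_length = 60L, sedentary_max = 100L,
                            mvpa_min = 1952L) {
  if (!(sedentary_max > 0 && sedentary_max <= mvpa_min))
    stop("cut-points must satisfy 0 < sedentary_max <= mvpa_min")
  structure(list(epoch_length = as.integer(epoch_length),
                 sedentary_max = as.integer(sedentary_max),
                 mvpa_min = as.integer(mvpa_min)),
            class = "cutpoint_config")
}

#' Read an epoch-count CSV
#'
#' Expects columns `participant_id`, `timestamp` (ISO 8601,
#' `YYYY-MM-DDTHH:MM:SS`), `counts`, and optionally `worn`. Rows are sorted
#' by participant then time. When `worn` is absent, non-wear is inferred as
#' any run of >= 60 consecutive zero-count minutes.
#'
#' @param path CSV file path.
#' @param epoch_length epoch length in seconds.
#' @return data.frame with columns `participant_id`, `timestamp` (POSIXct),
#'   `counts` (integer), `worn` (logical).
#' @export
read_epoch_csv <- function(path, epoch_length = 60L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "timestamp", "counts")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("malformed timestamp at row ", bad, ": ", df$timestamp[bad])
  }
  if (any(df$counts < 0)) {
    bad <- which(df$counts < 0)[1]
    stop("negative counts at row ", bad, ": ", df$counts[bad])
  }
  df$timestamp <- ts
  key <- paste(df$participant_id, format(ts, "%Y-%m-%dT%H:%M:%S"))
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate (participant, timestamp) at row ", bad)
  }
  df <- df[order(df$participant_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df$counts <- as.integer(df$counts)
  if (is.null(df$worn)) {
    df$worn <- infer_worn(df, epoch_length = epoch_length)
  } else {
    df$worn <- as.logical(df$worn)
  }
  df[c("participant_id", "timestamp", "counts", "worn")]
}

#' Infer worn flags from zero-count runs
#'
#' Runs of >= `nonwear_min` consecutive zero-count minutes are flagged as
#' non-wear, per participant in row order.
#'
#' @param df epoch data.frame sorted by participant and time.
#' @param nonwear_min minimum zero-run length, minutes.
#' @param epoch_length epoch length in seconds.
#' @return logical vector, TRUE when worn.
#' @export
infer_worn <- function(df, nonwear_min = 60, epoch_length = 60L) {
  run_epochs <- nonwear_min * 60 / epoch_length
  if (is.unsorted(df$participant_id)) stop("df must be sorted by participant")
  unlist(lapply(split(df$counts == 0, df$participant_id), function(z) {
    r <- rle(z)
    nonwear <- r$values & r$lengths >= run_epochs
    rep(!nonwear, r$lengths)
  }), use.names = FALSE)
}

#' Classify worn epochs into sedentary / light / MVPA
#'
#' Counts are scaled to counts-per-minute; cpm below `sedentary_max` is
#' `SB`, at or above `mvpa_min` is `MVPA`, otherwise `light`. Non-worn
#' epochs are labeled `nonwear`.
#'
#' @param counts integer epoch counts.
#' @param worn logical worn flags (default all worn).
#' @param cutpoints a [cutpoint_config()].
#' @return factor with levels SB, light, MVPA, nonwear.
#' @export
classify_intensity <- function(counts, worn = TRUE,
                               cutpoints = cutpoint_config()) {
  worn <- rep_len(worn, length(counts))
  cpm <- counts * 60 / cutpoints$epoch_length
  lab <- ifelse(cpm < cutpoints$sedentary_max, "SB",
                ifelse(cpm >= cutpoints$mvpa_min, "MVPA", "light"))
  lab[!worn] <- "nonwear"
  factor(lab, levels = c("SB", "light", "MVPA", "nonwear"))
}

#' Per-day wear summaries for one or more participants
#'
#' @param df labeled epoch data.frame (columns `participant_id`,
#'   `timestamp`, `worn`).
#' @param epoch_length epoch length in seconds.
#' @return data.frame with one row per participant-day: `participant_id`,
#'   `date`, `wear_minutes`.
#' @export
day_profiles <- function(df, epoch_length = 60L) {
  date <- as.Date(df$timestamp, tz = "UTC")
  agg <- aggregate(df$worn,
                   by = list(participant_id = df$participant_id,
                             date = date),
                   FUN = function(w) sum(w) * epoch_length / 60)
  names(agg)[3] <- "wear_minutes"
  agg <- agg[order(agg$participant_id, agg$date), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Apply the wear-validity rules
#'
#' A day is valid when its wear time is at least `min_wear_min` (inclusive);
#' a participant is included when they have at least `min_valid_days` valid
#' days (inclusive).
#'
#' @param profiles output of [day_profiles()].
#' @param min_valid_days minimum number of valid days.
#' @param min_wear_min minimum daily wear minutes.
#' @return list with `profiles` (input plus logical `valid`) and
#'   `participants` (data.frame `participant_id`, `n_valid_days`,
#'   `included`).
#' @export
validate_wear <- function(profiles, min_valid_days = 5, min_wear_min = 660) {
  if (!nrow(profiles)) stop("no day profiles supplied")
  profiles$valid <- profiles$wear_minutes >= min_wear_min
  nv <- tapply(profiles$valid, profiles$participant_id, sum)
  participants <- data.frame(participant_id = names(nv),
                             n_valid_days = as.integer(nv),
                             included = as.integer(nv) >= min_valid_days,
                             stringsAsFactors = FALSE)
  rownames(participants) <- NULL
  list(profiles = profiles, participants = participants)
}

#' Detect bouts of one intensity state
#'
#' A bout is a maximal run of epochs in `state` lasting at least
#' `min_duration_min`. With a positive `interruption_allowance_min`,
#' consecutive runs separated by interruptions of at most the allowance are
#' joined (interruption minutes are not counted toward the bout duration).
#' Bouts never span non-wear epochs.
#'
#' @param labels factor/character intensity labels for one participant-day
#'   in time order (levels SB, light, MVPA, nonwear).
#' @param state `"SB"` or `"MVPA"`.
#' @param min_duration_min minimum bout duration in minutes.
#' @param interruption_allowance_min maximal tolerated interruption, minutes.
#' @param epoch_length epoch length in seconds.
#' @return data.frame with columns `start`, `end` (epoch indices, inclusive)
#'   and `duration` (in-state minutes).
#' @export
detect_bouts <- function(labels, state, min_duration_min,
                         interruption_allowance_min = 0,
                         epoch_length = 60L) {
  if (!state %in% c("SB", "MVPA")) stop("unknown bout state: ", state)
  labels <- as.character(labels)
  epk <- epoch_length / 60  # minutes per epoch
  allow_epochs <- floor(interruption_allowance_min / epk)
  empty <- data.frame(start = integer(0), end = integer(0),
                      duration = numeric(0))
  if (!length(labels)) return(empty)

  out <- list()
  # segments between nonwear epochs
  seg_id <- cumsum(labels == "nonwear")
  for (seg in split(seq_along(labels), seg_id)) {
    seg <- seg[labels[seg] != "nonwear"]
    if (!length(seg)) next
    r <- rle(labels[seg] == state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (!length(runs)) next
    # join state runs across tolerated interruptions
    cur_start <- starts[runs[1]]; cur_epochs <- r$lengths[runs[1]]
    cur_end <- ends[runs[1]]
    flush <- function(s, e, n) {
      if (n * epk >= min_duration_min)
        out[[length(out) + 1]] <<- data.frame(start = seg[s], end = seg[e],
                                              duration = n * epk)
    }
    if (length(runs) > 1) {
      for (j in runs[-1]) {
        gap <- starts[j] - cur_end - 1
        if (gap <= allow_epochs) {
          cur_epochs <- cur_epochs + r$lengths[j]
          cur_end <- ends[j]
        } else {
          flush(cur_start, cur_end, cur_epochs)
          cur_start <- starts[j]; cur_end <- ends[j]
          cur_epochs <- r$lengths[j]
        }
      }
    }
    flush(cur_start, cur_end, cur_epochs)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
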