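# Synthetic cohort generator. Emulates week-long 60-s-epoch ActiGraph
# recordings of a fatigued-MS cohort with three latent physical-behavior
# subtypes, so the whole downstream pipeline is testable without the
# (non-public) clinical data.
#
# Generative model: per participant, a day-part-modulated three-state
# (sedentary / light / MVPA) semi-Markov construction. The drawn key-measure
# targets fix, per day part, the sedentary occupancy (from %SB, dSB1, dSB2),
# the number of sedentary runs (from SB NoB) and the scheduled prolonged
# MVPA bouts (from tt MVPA); run lengths are random compositions of the
# occupancy quotas, so bout-length distributions emerge rather than being
# imposed. Counts within a state are uniform between the relevant
# cut-points; only their ordering across cut-points matters downstream.

KEY_MEASURES <- c("pct_sb", "tt_mvpa", "sb_nob", "d_sb1", "d_sb2")

#' Define a latent physical-behavior subtype
#'
#' @param name subtype label.
#' @param proportion fraction of the cohort drawn from this subtype.
#' @param target_means,target_sds named numeric vectors over the five key
#'   measures (`pct_sb`, `tt_mvpa`, `sb_nob`, `d_sb1`, `d_sb2`); units as in
#'   [pb_reference_profiles()].
#' @param covariates list with elements `male_fraction`, `ms_type`
#'   (named probabilities over RR/PP/SP/EU), `age`, `bmi`, `cis20r`
#'   (mean/sd vectors), `edss`, `duration` (median/iqr vectors).
#' @return an object of class `subtype_spec`.
#' @export
subtype_spec <- function(name, proportion, target_means, target_sds,
                         covariates) {
  stopifnot(is.character(name), length(name) == 1,
            proportion >= 0, proportion <= 1)
  unknown <- setdiff(names(target_means), KEY_MEASURES)
  if (length(unknown))
    stop("unknown measure name in subtype spec: ",
         paste(unknown, collapse = ", "))
  if (!all(KEY_MEASURES %in% names(target_means)) ||
      !all(KEY_MEASURES %in% names(target_sds)))
    stop("target_means/target_sds must cover all five key measures")
  if (any(target_sds < 0)) stop("all target SDs must be >= 0")
  if (!is.null(covariates$cis20r) && covariates$cis20r[["mean"]] < 35)
    stop("CIS20r mean below the severe-fatigue inclusion criterion (>= 35)")
  structure(list(name = name, proportion = proportion,
                 target_means = target_means[KEY_MEASURES],
                 target_sds = target_sds[KEY_MEASURES],
                 covariates = covariates),
            class = "subtype_spec")
}

#' Default three-subtype specification
#'
#' Subtype proportions, key-measure means/SDs and covariate distributions of
#' the reference clinical cohort ([pb_reference_profiles()]). Proportions
#' are the published cluster sizes 46/114/48 over the 208 clustered
#' patients.
#'
#' @param sd_scale multiplier applied to every key-measure SD (1 = as
#'   published; 0.5 halves within-subtype spread).
#' @return list of three `subtype_spec` objects.
#' @export
default_subtype_specs <- function(sd_scale = 1) {
  ref <- pb_reference_profiles()
  props <- ref$n / sum(ref$n)
  lapply(names(ref$n), function(nm) {
    subtype_spec(nm, props[[nm]],
                 target_means = ref$measures[[nm]]$mean,
                 target_sds = ref$measures[[nm]]$sd * sd_scale,
                 covariates = ref$covariates[[nm]])
  })
}

#' Cohort generation configuration
#'
#' @param n_participants cohort size (>= 2).
#' @param days recording days per participant.
#' @param epoch_length epoch length in seconds; must divide 60 evenly into
#'   whole minutes (the generator itself emits 60-s epochs).
#' @param wear_start,wear_end nominal wear window, decimal clock hours.
#' @param wear_jitter_min uniform jitter (+/- minutes) applied independently
#'   to each day's wear start and end.
#' @param invalid_day_rate probability that a day is truncated below the
#'   660-min wear-validity threshold.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 212L, days = 7L,
                          epoch_length = 60L, wear_start = 7, wear_end = 23,
                          wear_jitter_min = 20, invalid_day_rate = 0.1,
                          seed = 1L) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (days < 1) stop("days must be >= 1")
  if (60 %% epoch_length != 0)
    stop("epoch_length must divide 60 evenly into minutes")
  stopifnot(wear_end > wear_start, invalid_day_rate >= 0,
            invalid_day_rate <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 days = as.integer(days),
                 epoch_length = as.integer(epoch_length),
                 wear_start = wear_start, wear_end = wear_end,
                 wear_jitter_min = wear_jitter_min,
                 invalid_day_rate = invalid_day_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Day-part sedentary occupancies implied by (%SB, dSB1, dSB2) under the
# nominal wear schedule. Weights are the worn minutes falling in each
# day-part window.
daypart_occupancy <- function(pct_sb, d_sb1, d_sb2, weights) {
  w <- weights / sum(weights)
  s_afternoon <- pct_sb + w[[1]] * d_sb1 - w[[3]] * d_sb2
  c(morning = s_afternoon - d_sb1,
    afternoon = s_afternoon,
    evening = s_afternoon + d_sb2)
}

nominal_part_weights <- function(config,
                                 dayparts = daypart_definition()) {
  starts <- pmax(c(dayparts$morning[1], dayparts$afternoon[1],
                   dayparts$evening[1]), config$wear_start)
  ends <- pmin(c(dayparts$morning[2], dayparts$afternoon[2],
                 dayparts$evening[2]), config$wear_end)
  pmax(ends - starts, 0) * 60
}

#' Draw one participant's key-measure targets
#'
#' Independent normals per key measure, truncated by rejection to
#' admissible ranges: percentages to \[0, 100\], times and counts to >= 0,
#' and the three day-part sedentary occupancies implied by (%SB, dSB1,
#' dSB2) each to \[0, 100\].
#'
#' @param spec a [subtype_spec()].
#' @param weights worn minutes per day part under the nominal schedule.
#' @param max_tries bounded rejection attempts before declaring the spec
#'   infeasible.
#' @return named numeric vector over the five key measures.
#' @export
draw_measure_targets <- function(spec, weights = c(300, 360, 300),
                                 max_tries = 200L) {
  stopifnot(inherits(spec, "subtype_spec"))
  mu <- spec$target_means
  sdv <- spec$target_sds
  lower <- c(pct_sb = 0, tt_mvpa = 0, sb_nob = 0, d_sb1 = -100, d_sb2 = -100)
  upper <- c(pct_sb = 100, tt_mvpa = Inf, sb_nob = Inf,
             d_sb1 = 100, d_sb2 = 100)
  for (try in seq_len(max_tries)) {
    x <- rnorm(length(mu), mu, sdv)
    names(x) <- names(mu)
    if (any(x < lower[names(x)] | x > upper[names(x)])) next
    occ <- daypart_occupancy(x[["pct_sb"]], x[["d_sb1"]], x[["d_sb2"]],
                             weights)
    if (all(occ >= 0 & occ <= 100)) return(x)
  }
  stop("infeasible subtype spec '", spec$name,
       "': no admissible target after ", max_tries, " rejection attempts")
}

#' Draw one participant's covariates
#'
#' Age is drawn normal and clipped to 18-70 years; BMI normal; EDSS is a
#' normal on the median with SD = IQR/1.349, rounded to 0.5 steps and
#' clipped to \[0, 5.5\] (inclusion required EDSS < 6); CIS20r fatigue is
#' normal clipped to \[35, 56\] (severe-fatigue inclusion); disease duration
#' is log-normal matched to the median and IQR.
#'
#' @param spec a [subtype_spec()].
#' @return one-row data.frame of covariates.
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "subtype_spec"))
  cv <- spec$covariates
  age <- min(70, max(18, rnorm(1, cv$age[["mean"]], cv$age[["sd"]])))
  bmi <- max(14, rnorm(1, cv$bmi[["mean"]], cv$bmi[["sd"]]))
  sex <- if (runif(1) < cv$male_fraction) "M" else "F"
  ms_type <- sample(names(cv$ms_type), 1, prob = cv$ms_type)
  edss <- rnorm(1, cv$edss[["median"]], cv$edss[["iqr"]] / 1.349)
  edss <- min(5.5, max(0, round(edss * 2) / 2))
  cis <- min(56, max(35, rnorm(1, cv$cis20r[["mean"]], cv$cis20r[["sd"]])))
  med <- cv$duration[["median"]]
  sdlog <- asinh(cv$duration[["iqr"]] / (2 * med)) / 0.6745
  dur <- min(50, rlnorm(1, log(med), sdlog))
  data.frame(age = age, sex = sex, bmi = bmi, ms_type = ms_type,
             edss = edss, duration_ms_years = dur, cis20r = cis,
             stringsAsFactors = FALSE)
}

# Decompose `total` prolonged-MVPA minutes into bout lengths of >= 10 min
# (typical lengths 10-25; a remainder < 10 is absorbed by the last bout).
mvpa_bout_lengths <- function(total) {
  total <- round(total)
  if (total < 5) return(integer(0))
  if (total < 10) return(10L)
  lengths <- integer(0)
  rem <- total
  while (rem >= 20) {
    l <- resample(10:min(25, rem - 10), 1)
    lengths <- c(lengths, l)
    rem <- rem - l
  }
  as.integer(c(lengths, rem))  # rem in [10, 19] absorbed as final bout
}

# Assemble one day part as a run-length encoded state sequence.
# States: 1 = SB, 2 = light, 3 = MVPA. When light time allows, the part
# begins and ends with light so sedentary runs never merge across parts.
assemble_part <- function(wear_min, sb_min, n_sb_runs, mvpa_lengths) {
  wear_min <- as.integer(wear_min)
  if (wear_min <= 0) return(integer(0))
  mvpa_lengths <- as.integer(mvpa_lengths)
  if (sum(mvpa_lengths) > wear_min)
    mvpa_lengths <- mvpa_lengths[cumsum(mvpa_lengths) <= wear_min]
  mvpa_min <- sum(mvpa_lengths)
  sb_min <- max(0L, min(as.integer(round(sb_min)), wear_min - mvpa_min))
  light_min <- wear_min - sb_min - mvpa_min

  if (sb_min == 0L) {
    states <- if (light_min > 0) 2L else integer(0)
    lens <- if (light_min > 0) light_min else integer(0)
  } else if (light_min == 0L) {
    states <- 1L
    lens <- sb_min
  } else {
    n_runs <- max(1L, min(as.integer(n_sb_runs), sb_min))
    if (light_min >= n_runs + 1L) {
      # light | SB | light | ... | SB | light
      sb_runs <- rand_composition(sb_min, n_runs)
      gaps <- rand_composition(light_min, n_runs + 1L)
      states <- c(rbind(rep(2L, n_runs), rep(1L, n_runs)), 2L)
      lens <- c(rbind(gaps[seq_len(n_runs)], sb_runs), gaps[n_runs + 1L])
    } else {
      # scarce light: internal 1-min-class separators only
      n_runs <- min(n_runs, light_min + 1L)
      sb_runs <- rand_composition(sb_min, n_runs)
      if (n_runs == 1L) {
        states <- c(1L, 2L)
        lens <- c(sb_min, light_min)
      } else {
        gaps <- rand_composition(light_min, n_runs - 1L)
        states <- c(rbind(rep(1L, n_runs - 1L), rep(2L, n_runs - 1L)), 1L)
        lens <- c(rbind(sb_runs[seq_len(n_runs - 1L)], gaps),
                  sb_runs[n_runs])
      }
    }
  }

  # insert MVPA bouts by splitting light runs (merging of two MVPA bouts is
  # possible but harmless: total prolonged time is what the target fixes)
  for (L in mvpa_lengths) {
    lp <- which(states == 2L & lens >= 1L)
    if (!length(lp)) {
      states <- c(states, 3L)
      lens <- c(lens, L)
      next
    }
    g <- resample(lp, 1)
    u <- sample.int(lens[g] + 1L, 1) - 1L  # 0..lens[g] minutes kept before
    states <- append(states, c(3L, 2L), after = g)
    lens <- append(lens, c(L, lens[g] - u), after = g)
    lens[g] <- u
  }
  keep <- lens > 0L
  rep(states[keep], lens[keep])
}

# Simulate one participant's worn-epoch state sequence for the whole
# recording period. Returns a data.frame(day, minute_of_day, state).
simulate_participant_days <- function(target, config, dayparts) {
  part_bounds <- rbind(dayparts$morning, dayparts$afternoon,
                       dayparts$evening) * 60  # minutes of day
  days <- config$days
  jit <- config$wear_jitter_min
  invalid <- runif(days) < config$invalid_day_rate
  starts <- round(config$wear_start * 60 + runif(days, -jit, jit))
  ends <- round(config$wear_end * 60 + runif(days, -jit, jit))
  # invalid days: truncate wear below the 660-min validity threshold
  ends[invalid] <- starts[invalid] + round(runif(sum(invalid), 300, 600))
  v <- sum(!invalid)
  if (v == 0) { invalid[1] <- FALSE; ends[1] <- starts[1] + 960; v <- 1 }

  occ <- daypart_occupancy(target[["pct_sb"]], target[["d_sb1"]],
                           target[["d_sb2"]],
                           nominal_part_weights(config, dayparts))
  # weekly quotas scaled so that rescaling by 7/#valid-days recovers the
  # target: valid days carry total = target * v / 7
  week_bouts <- mvpa_bout_lengths(target[["tt_mvpa"]] * v / 7)
  bout_day <- if (length(week_bouts))
    resample(rep(which(!invalid), length.out = length(week_bouts))) else
    integer(0)
  nob_day_quota <- apportion(round(target[["sb_nob"]] * v / 7),
                             rep(1 / v, v))
  quota_idx <- 0L

  out <- vector("list", days)
  for (d in seq_len(days)) {
    w0 <- starts[d]; w1 <- ends[d]
    p_start <- pmax(part_bounds[, 1], w0)
    p_end <- pmin(part_bounds[, 2], w1)
    w_part <- pmax(p_end - p_start, 0)
    if (!invalid[d]) {
      quota_idx <- quota_idx + 1L
      day_nob <- nob_day_quota[quota_idx]
      day_bouts <- week_bouts[bout_day == d]
    } else {
      day_nob <- round(sum(w_part) / 960 * target[["sb_nob"]] / 7)
      day_bouts <- integer(0)
    }
    sb_part <- round(occ / 100 * w_part)
    # assign MVPA bouts to the part with most slack
    bouts_part <- vector("list", 3)
    if (length(day_bouts)) {
      slack <- w_part - sb_part
      for (b in day_bouts) {
        g <- which.max(slack)
        bouts_part[[g]] <- c(bouts_part[[g]], b)
        slack[g] <- slack[g] - b
      }
    }
    # sedentary-run quota split across parts proportional to SB minutes,
    # then redistributed where the light-time budget (one separating light
    # minute per run, plus flanking) cannot host the quota
    nob_part <- if (sum(sb_part) > 0)
      apportion(day_nob, sb_part / sum(sb_part)) else rep(0L, 3)
    mvpa_part <- vapply(bouts_part, sum, numeric(1))
    cap <- pmax(0, pmin(w_part - sb_part - mvpa_part - 1, sb_part))
    deficit <- sum(pmax(nob_part - cap, 0))
    nob_part <- pmin(nob_part, cap)
    room <- cap - nob_part
    while (deficit > 0 && sum(room) > 0) {
      j <- which.max(room)
      take <- min(deficit, room[j])
      nob_part[j] <- nob_part[j] + take
      room[j] <- room[j] - take
      deficit <- deficit - take
    }
    seqs <- lapply(1:3, function(p) {
      if (w_part[p] <= 0) return(integer(0))
      assemble_part(w_part[p], sb_part[p], nob_part[p], bouts_part[[p]])
    })
    minutes <- unlist(lapply(1:3, function(p)
      if (w_part[p] > 0) seq.int(p_start[p], p_end[p] - 1L) else integer(0)))
    out[[d]] <- data.frame(day = d, minute_of_day = minutes,
                           state = unlist(seqs))
  }
  do.call(rbind, out)
}

state_counts <- function(states, cut) {
  n <- length(states)
  lo <- c(0L, cut$sedentary_max, cut$mvpa_min)
  hi <- c(cut$sedentary_max - 1L, cut$mvpa_min - 1L, 3L * cut$mvpa_min)
  lo[states] + floor(runif(n) * (hi[states] - lo[states] + 1L))
}

#' Generate a synthetic cohort
#'
#' Draws each participant's latent subtype, key-measure targets and
#' covariates, and (in `"epoch"` mode) simulates a worn-epoch activity-count
#' series whose downstream measures recover the targets. In `"measures"`
#' (fast) mode the drawn key-measure targets are emitted directly as the
#' measure table and no epochs are simulated.
#'
#' @param config a [cohort_config()].
#' @param specs list of [subtype_spec()]; proportions must sum to 1.
#' @param mode `"epoch"` or `"measures"`.
#' @param cutpoints a [cutpoint_config()] used to draw counts within states.
#' @param dayparts a [daypart_definition()].
#' @param start_date first recording date.
#' @return list with elements `epochs` (epoch-mode only; data.frame
#'   `participant_id`, `timestamp`, `counts`, `worn`), `measures`
#'   (fast mode only), `covariates`, `labels` (participant -> subtype), and
#'   `targets` (drawn per-participant key-measure targets).
#' @export
simulate_cohort <- function(config, specs = default_subtype_specs(),
                            mode = c("epoch", "measures"),
                            cutpoints = cutpoint_config(),
                            dayparts = daypart_definition(),
                            start_date = as.Date("2023-05-01")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "cohort_config"))
  props <- vapply(specs, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("subtype proportions must sum to 1 (got ", sum(props), ")")
  if (mode == "epoch" && config$epoch_length != 60L)
    stop("epoch-level simulation is implemented for 60-s epochs only")

  with_seed(config$seed, {
    n <- config$n_participants
    counts_per <- apportion(n, props)
    subtype <- rep(vapply(specs, `[[`, character(1), "name"), counts_per)
    ids <- sprintf("P%03d", seq_len(n))
    weights <- nominal_part_weights(config, dayparts)

    targets <- matrix(NA_real_, n, length(KEY_MEASURES),
                      dimnames = list(ids, KEY_MEASURES))
    cov_rows <- vector("list", n)
    epoch_rows <- if (mode == "epoch") vector("list", n) else NULL
    spec_by_name <- setNames(specs, vapply(specs, `[[`, character(1), "name"))

    # latent draws first, so matched seeds give identical targets and
    # covariates in epoch and measure-level mode
    for (i in seq_len(n)) {
      sp <- spec_by_name[[subtype[i]]]
      targets[i, ] <- draw_measure_targets(sp, weights)
      cov_rows[[i]] <- cbind(participant_id = ids[i], generate_covariates(sp))
    }
    if (mode == "epoch") {
      for (i in seq_len(n)) {
        dd <- simulate_participant_days(targets[i, ], config, dayparts)
        ts <- as.POSIXct(start_date, tz = "UTC") +
          (dd$day - 1) * 86400 + dd$minute_of_day * 60
        epoch_rows[[i]] <- data.frame(
          participant_id = ids[i], timestamp = ts,
          counts = state_counts(dd$state, cutpoints), worn = TRUE,
          stringsAsFactors = FALSE)
      }
    }

    res <- list(
      covariates = do.call(rbind, cov_rows),
      labels = data.frame(participant_id = ids, subtype = subtype,
                          stringsAsFactors = FALSE),
      targets = data.frame(participant_id = ids,
                           as.data.frame(targets, row.names = NULL),
                           stringsAsFactors = FALSE)
    )
    if (mode == "epoch") {
      res$epochs <- do.call(rbind, epoch_rows)
      rownames(res$epochs) <- NULL
    } else {
      res$measures <- data.frame(participant_id = ids,
                                 as.data.frame(targets, row.names = NULL),
                                 stringsAsFactors = FALSE)
    }
    res
  })
}

#' Write a simulated cohort to CSV files
#'
#' Writes `epochs.csv` (epoch dialect: `participant_id,timestamp,counts,
#' worn`), `covariates.csv`, `labels.csv` and `targets.csv` (or
#' `measures.csv` in fast mode) into `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    if (name == "epochs.csv")
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  if (!is.null(cohort$epochs)) paths <- c(paths, wr(cohort$epochs, "epochs.csv"))
  if (!is.null(cohort$measures))
    paths <- c(paths, wr(cohort$measures, "measures.csv"))
  paths <- c(paths, wr(cohort$covariates, "covariates.csv"),
             wr(cohort$labels, "labels.csv"),
             wr(cohort$targets, "targets.csv"))
  invisible(paths)
}
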