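# The 15 physical-behavior measures against hand-computed values.

# Two identical days; within each day three worn hours, one per day part:
#   08:00-09:00  SB*30, light*20, MVPA*10   (%SB 50, one 10-min MVPA bout)
#   13:00-14:00  SB*24, light*36            (%SB 40)
#   19:00-20:00  SB*42, light*18            (%SB 70)
toy_participant <- function() {
  day_states <- c(rep("SB", 30), rep("light", 20), rep("MVPA", 10),
                  rep("SB", 24), rep("light", 36),
                  rep("SB", 42), rep("light", 18))
  mk_day <- function(date) {
    ts <- as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC") +
      60 * c(480:539, 780:839, 1140:1199)
    df <- build_epochs(day_states)
    df$timestamp <- ts
    df
  }
  df <- rbind(mk_day("2023-05-01"), mk_day("2023-05-02"))
  df$label <- classify_intensity(df$counts, df$worn)
  df
}

test_that("the toy participant reproduces the hand-computed measure vector", {
  df <- toy_participant()
  m <- compute_measures(df, valid_dates = as.Date(c("2023-05-01",
                                                    "2023-05-02")))
  expect_equal(m$pct_sb, 96 / 180 * 100, tolerance = 1e-12)
  expect_equal(m$pct_active, 100 - 96 / 180 * 100)
  expect_equal(m$pct_mvpa, 10 / 180 * 100)
  expect_equal(m$cpd, 96 * 50 + 74 * 500 + 10 * 2500)  # 66800 per day
  expect_equal(m$cpm, 66800 / 180)
  expect_equal(m$sb_nob, 6 * 7 / 2)          # 3 bouts/day, rescaled
  expect_equal(m$sb_bl, mean(c(30, 24, 42)))
  expect_equal(m$tt_sb, 192 * 7 / 2)
  expect_equal(m$mvpa_nob, 2 * 7 / 2)
  expect_equal(m$mvpa_bl, 10)
  expect_equal(m$tt_mvpa, 20 * 7 / 2)
  expect_equal(m$d_sb1, 40 - 50)
  expect_equal(m$d_sb2, 70 - 40)
  expect_equal(m$d_mvpa1, 0 - 100 / 6)
  expect_equal(m$d_mvpa2, 0)
  expect_equal(m$n_valid_days, 2)
  expect_false(m$daypart_flag)
  # telescoping identity and the tt = bl * nob consistency
  expect_equal(m$d_sb1 + m$d_sb2, m$sb_evening - m$sb_morning)
  expect_equal(m$mvpa_bl * m$mvpa_nob, m$tt_mvpa)
})

test_that("a half-sedentary single day gives the textbook percentages", {
  states <- c(rep("SB", 480), rep("light", 480))
  df <- build_epochs(states, start = "2023-05-01 07:00:00")
  df$label <- classify_intensity(df$counts, df$worn)
  m <- compute_measures(df, valid_dates = as.Date("2023-05-01"))
  expect_equal(m$pct_sb, 50)
  expect_equal(m$pct_active, 50)
  expect_equal(m$pct_mvpa, 0)
  expect_equal(m$tt_mvpa, 0)
  expect_equal(m$mvpa_nob, 0)
})

test_that("measures are invariant to dropping identical valid days", {
  df <- toy_participant()
  # replicate the same day across a week
  week <- do.call(rbind, lapply(0:6, function(d) {
    x <- df[df$timestamp < as.POSIXct("2023-05-02", tz = "UTC"), ]
    x$timestamp <- x$timestamp + d * 86400
    x
  }))
  all7 <- compute_measures(week, valid_dates = as.Date("2023-05-01") + 0:6)
  any5 <- compute_measures(week, valid_dates = as.Date("2023-05-01") +
                             c(0, 2, 3, 5, 6))
  for (v in pb_measure_info()$measure)
    expect_equal(all7[[v]], any5[[v]], tolerance = 1e-12)
})

test_that("doubling counts doubles CPD/CPM when classes are unchanged", {
  states <- c(rep("SB", 100), rep("light", 60), rep("MVPA", 20))
  df <- build_epochs(states, start = "2023-05-01 08:00:00")
  df$counts <- c(SB = 40L, light = 600L, MVPA = 2500L)[states]
  df$label <- classify_intensity(df$counts, df$worn)
  m1 <- compute_measures(df, valid_dates = as.Date("2023-05-01"))
  df2 <- df
  df2$counts <- df$counts * 2L
  df2$label <- classify_intensity(df2$counts, df2$worn)
  m2 <- compute_measures(df2, valid_dates = as.Date("2023-05-01"))
  expect_equal(m2$cpd, 2 * m1$cpd)
  expect_equal(m2$cpm, 2 * m1$cpm)
  expect_equal(m2$pct_sb, m1$pct_sb)
  expect_equal(m2$sb_nob, m1$sb_nob)
})

test_that("a day part with no wear at all flags the participant", {
  states <- c(rep("SB", 200), rep("light", 200))  # morning+afternoon only
  df <- build_epochs(states, start = "2023-05-01 08:00:00")
  df$label <- classify_intensity(df$counts, df$worn)
  m <- compute_measures(df, valid_dates = as.Date("2023-05-01"))
  expect_true(m$daypart_flag)
  expect_true(is.na(m$d_sb2))
})

test_that("measures_table excludes short-wear participants with a reason", {
  mk <- function(pid, n_days) {
    do.call(rbind, lapply(seq_len(n_days), function(d) {
      df <- build_epochs(rep(c("SB", "light"), 350),
                         start = sprintf("2023-05-%02d 07:00:00", d),
                         pid = pid)
      df
    }))
  }
  epochs <- rbind(mk("A", 6), mk("B", 3))
  mt <- measures_table(epochs)
  expect_equal(mt$measures$participant_id, "A")
  expect_equal(mt$exclusions$participant_id, "B")
  expect_match(mt$exclusions$reason, "3 valid days")
  expect_error(measures_table(epochs[0, ]), "empty")
})
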