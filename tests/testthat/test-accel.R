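rules <- processing_rules()

test_that("non-wear boundaries and allowance semantics", {
  fx <- generate_worked_fixture()
  expect_false(any(detect_nonwear(fx$zeros90$counts, rules)))
  expect_true(all(detect_nonwear(fx$zeros89$counts, rules)))
  # 45 zeros + 2 nonzero + 45 zeros: merged run with 90 zero minutes
  expect_false(any(detect_nonwear(fx$split_interrupt$counts, rules)))
  # 3-min interruption exceeds the allowance
  expect_true(all(detect_nonwear(fx$split_blocked$counts, rules)))
  expect_length(detect_nonwear(integer(0), rules), 0)
  expect_error(detect_nonwear(c(-1L, 0L), rules), "negative")
})

test_that("stricter flanking variant only absorbs well-flanked gaps", {
  strict <- processing_rules(choi_flank = TRUE)
  day <- c(rep(0L, 20), 5L, 5L, rep(0L, 100))
  # simple reading: merged run has 120 zeros -> all non-wear
  expect_false(any(detect_nonwear(day, rules)))
  # flanked reading: the 20-zero side is < 30 min, gap not absorbed; only
  # the 100-zero run qualifies on its own
  w <- detect_nonwear(day, strict)
  expect_true(all(w[1:22]))
  expect_false(any(w[23:122]))
})

test_that("cut-point classification and non-wear precedence", {
  counts <- c(99L, 100L, 1951L, 1952L, 0L)
  wear <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_identical(classify_intensity(counts, wear, rules),
                   c("SB", "LIPA", "LIPA", "MVPA", "nonwear"))
  expect_error(classify_intensity(c(-5L), TRUE, rules), "negative")
})

test_that("classification matches brute-force comparator on random days", {
  set.seed(42)
  for (i in 1:5) {
    counts <- random_day(200)
    wear <- detect_nonwear(counts, rules)
    expect_identical(classify_intensity(counts, wear, rules),
                     oracle_intensity(counts, wear))
  }
})

test_that("bout detection thresholds are inclusive and strictly consecutive", {
  mv <- function(n) rep("MVPA", n)
  expect_equal(detect_bouts(mv(10), "MVPA", 10),
               data.frame(start = 0L, length = 10L))
  expect_identical(nrow(detect_bouts(c(mv(9), "LIPA", mv(9)), "MVPA", 10)),
                   0L)
  expect_identical(detect_bouts(rep("SB", 30), "SB", 30)$length, 30L)
  expect_identical(nrow(detect_bouts(rep("SB", 29), "SB", 30)), 0L)
  fx <- generate_worked_fixture()
  cls <- classify_intensity(fx$mvpa12$counts,
                            detect_nonwear(fx$mvpa12$counts, rules), rules)
  expect_equal(detect_bouts(cls, "MVPA", 10),
               data.frame(start = 20L, length = 12L))
})

test_that("non-wear and bout detectors agree with oracles on random days", {
  set.seed(7)
  for (i in 1:200) {
    counts <- random_day(sample(c(200, 700, 1440), 1))
    expect_identical(detect_nonwear(counts, rules), oracle_nonwear(counts))
    cls <- classify_intensity(counts, detect_nonwear(counts, rules), rules)
    for (target in c("MVPA", "SB")) {
      ml <- if (target == "MVPA") 10 else 30
      expect_identical(detect_bouts(cls, target, ml),
                       oracle_bouts(cls, target, ml))
    }
  }
})

test_that("day summary matches the hand-computed worked fixture", {
  fx <- generate_worked_fixture()
  s <- summarise_day(fx$hand_day$counts, fx$hand_day$steps, rules)
  expect_identical(s$wear_minutes, 840L)
  expect_identical(s$sb_minutes, 751L)
  expect_identical(s$lipa_minutes, 68L)
  expect_identical(s$mvpa_minutes, 21L)
  expect_identical(s$sb_bout_count, 2L)
  expect_identical(s$sb_bout_minutes, 751L)
  expect_identical(s$mvpa_bout_count, 1L)
  expect_identical(s$mvpa_bout_minutes, 12L)
  expect_identical(s$total_counts, 103760L)
  expect_identical(s$total_steps, 3960L)
  expect_true(s$valid)
  # invariants
  expect_identical(s$sb_minutes + s$lipa_minutes + s$mvpa_minutes,
                   s$wear_minutes)
})

test_that("valid-day threshold is inclusive at 600 wear minutes", {
  d600 <- summarise_day(rep(50L, 600), rules = rules)
  expect_true(d600$valid)
  expect_gte(d600$sb_bout_count, 1L)
  d599 <- summarise_day(rep(50L, 599), rules = rules)
  expect_false(d599$valid)
})

test_that("partition: nonwear + SB + LIPA + MVPA covers every epoch", {
  set.seed(11)
  for (i in 1:20) {
    counts <- random_day(sample(300:1440, 1))
    wear <- detect_nonwear(counts, rules)
    cls <- classify_intensity(counts, wear, rules)
    expect_identical(length(counts),
                     sum(cls == "nonwear") + sum(cls == "SB") +
                       sum(cls == "LIPA") + sum(cls == "MVPA"))
  }
})

test_that("wave filter retains >=3 valid days and drops the rest", {
  mk <- function(id, wave, nvalid, ninvalid) {
    rbind(
      if (nvalid) data.frame(participant_id = id, wave_month = wave,
                             day_index = seq_len(nvalid), wear_minutes = 700,
                             sb_minutes = 600, lipa_minutes = 80,
                             mvpa_minutes = 20, sb_bout_count = 1,
                             sb_bout_minutes = 100, mvpa_bout_count = 0,
                             mvpa_bout_minutes = 0, total_counts = 1e5,
                             total_steps = 5000, valid = TRUE),
      if (ninvalid) data.frame(participant_id = id, wave_month = wave,
                               day_index = nvalid + seq_len(ninvalid),
                               wear_minutes = 300, sb_minutes = 250,
                               lipa_minutes = 40, mvpa_minutes = 10,
                               sb_bout_count = 0, sb_bout_minutes = 0,
                               mvpa_bout_count = 0, mvpa_bout_minutes = 0,
                               total_counts = 5e4, total_steps = 2000,
                               valid = FALSE))
  }
  ds <- rbind(mk("A", 0, 3, 4), mk("B", 0, 2, 5), mk("A", 6, 7, 0))
  fl <- filter_valid_waves(ds, rules)
  expect_identical(nrow(fl$days[fl$days$participant_id == "A" &
                                  fl$days$wave_month == 0, ]), 3L)
  expect_false(any(fl$waves$participant_id == "B"))
  expect_identical(fl$exclusions$excluded_participants, "B")
  expect_true(all(fl$days$valid))
})

test_that("raising the wear threshold never increases valid days", {
  set.seed(3)
  days <- replicate(30, random_day(1440), simplify = FALSE)
  nv <- vapply(c(480, 600, 720), function(thr) {
    r <- processing_rules(valid_day_wear = thr)
    sum(vapply(days, function(d) summarise_day(d, rules = r)$valid, TRUE))
  }, 0)
  expect_true(all(diff(nv) <= 0))
})

test_that("weekly MVPA averages over days, times seven, inclusive at 150", {
  w <- weekly_mvpa(c(20, 22, 24), rules)
  expect_equal(w$weekly_mvpa, 154)   # mean 22 * 7, arithmetic oracle
  expect_true(w$meets_guideline)
  w0 <- weekly_mvpa(c(0, 0, 0), rules)
  expect_identical(w0$weekly_mvpa, 0)
  expect_false(w0$meets_guideline)
  wb <- weekly_mvpa(rep(150 / 7, 5), rules)
  expect_equal(wb$weekly_mvpa, 150)
  expect_true(wb$meets_guideline)
  expect_error(weekly_mvpa(numeric(0), rules))
})
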