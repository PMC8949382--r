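test_that("spec and profile validation reject bad inputs", {
  expect_error(cohort_spec(10, class_proportions = c(0.6, 0.5)), "sum to 1")
  expect_error(cohort_spec(10, waves = c(0, 6, 6)), "increasing")
  expect_error(cohort_spec(10, epoch_length = 30), "60")
  expect_error(class_profile("x", sb = -1, lipa = 200, mvpa = 20),
               "non-negative")
  # per-wave targets above the 840-min waking wear window are refused,
  # naming the class and wave
  spec <- cohort_spec(5, class_proportions = 1, waves = c(0, 12))
  bad <- class_profile("heavy", sb = c(700, 700), lipa = c(200, 200),
                       mvpa = c(10, 10))
  expect_error(generate_cohort(spec, list(bad)), "heavy.*wave month 0")
})

test_that("generation is byte-identical under a fixed seed", {
  pre <- cohort_preset("paper_like", n_participants = 10, seed = 1)
  a <- generate_cohort(pre$spec, pre$profiles)
  b <- generate_cohort(pre$spec, pre$profiles)
  expect_identical(a, b)
  # a different seed changes the draw
  pre2 <- cohort_preset("paper_like", n_participants = 10, seed = 2)
  expect_false(identical(generate_cohort(pre2$spec, pre2$profiles)$epochs,
                         a$epochs))
})

test_that("cohort structure: waves, day counts, 1440-epoch days", {
  pre <- cohort_preset("paper_like", n_participants = 15, seed = 4)
  co <- generate_cohort(pre$spec, pre$profiles)
  ep <- co$epochs
  # every participant has at least one wave (baseline always present)
  expect_setequal(unique(ep$participant_id), co$covariates$participant_id)
  expect_true(all(tapply(ep$wave_month, ep$participant_id,
                         function(w) 0 %in% w)))
  per_day <- table(paste(ep$participant_id, ep$wave_month, ep$day_index))
  expect_true(all(per_day == 1440))
  key <- unique(data.frame(id = ep$participant_id, w = ep$wave_month,
                           d = ep$day_index))
  days_per_wave <- table(paste(key$id, key$w))
  expect_true(all(days_per_wave >= 3 & days_per_wave <= 7))
  # covariate table is complete and typed
  expect_true(all(co$covariates$gender %in% c("F", "M")))
  expect_true(all(co$covariates$randomisation %in%
                    c("multi", "single", "control")))
  expect_true(all(co$truth$class$true_class %in% 1:2))
})

test_that("a class with zero MVPA target produces zero processed MVPA", {
  spec <- cohort_spec(6, class_proportions = 1, waves = c(0, 6),
                      seed = 9)
  prof <- class_profile("sedentary", sb = c(650, 650), lipa = c(150, 150),
                        mvpa = c(0, 0))
  co <- generate_cohort(spec, list(prof))
  ds <- process_epochs(co$epochs)
  expect_identical(sum(ds$mvpa_minutes), 0L)
})

test_that("pooled processed daily means calibrate to class targets", {
  # law-of-large-numbers check on the generator's own state process:
  # person-level heterogeneity off, ~250 pooled days, +-3 min tolerance
  spec <- cohort_spec(50, class_proportions = 1, waves = 0, seed = 5,
                      wave_missingness_prob = 0)
  prof <- class_profile("target", sb = 600, lipa = 210, mvpa = 30,
                        person_sd = c(sb = 0, lipa = 0, mvpa = 0),
                        person_slope_sd = c(sb = 0, lipa = 0, mvpa = 0))
  co <- generate_cohort(spec, list(prof))
  fl <- filter_valid_waves(process_epochs(co$epochs))
  expect_gt(nrow(fl$days), 200)
  expect_lt(abs(mean(fl$days$sb_minutes) - 600), 3)
  expect_lt(abs(mean(fl$days$lipa_minutes) - 210), 3)
  expect_lt(abs(mean(fl$days$mvpa_minutes) - 30), 3)
})

test_that("counts drawn per state are recovered by cut-point classification", {
  pre <- cohort_preset("high_separation", n_participants = 6, seed = 2)
  co <- generate_cohort(pre$spec, pre$profiles)
  one <- co$epochs[co$epochs$participant_id == co$epochs$participant_id[1] &
                     co$epochs$wave_month == 0 & co$epochs$day_index == 1, ]
  wear <- detect_nonwear(one$counts)
  cls <- classify_intensity(one$counts, wear)
  # the nocturnal block alone guarantees a long non-wear stretch
  expect_gte(sum(cls == "nonwear"), 480)
  # almost all non-wear minutes are zero counts (a few absorbed
  # interruption minutes may not be)
  expect_gte(mean(one$counts[cls == "nonwear"] == 0), 0.99)
  expect_true(all(one$counts[cls == "SB"] <= 99))
  expect_true(all(one$counts[cls == "LIPA"] >= 100 &
                    one$counts[cls == "LIPA"] <= 1951))
  expect_true(all(one$counts[cls == "MVPA"] >= 1952))
})

test_that("short-wear days land below the validity threshold", {
  spec <- cohort_spec(25, class_proportions = 1, waves = 0, seed = 11,
                      wave_missingness_prob = 0)
  prof <- class_profile("x", sb = 600, lipa = 200, mvpa = 25,
                        short_wear_prob = 0.3)
  co <- generate_cohort(spec, list(prof))
  ds <- process_epochs(co$epochs)
  expect_gt(sum(!ds$valid), 0)
  expect_gt(sum(ds$valid), 0)
})

test_that("cohort CSV round-trip preserves the epoch dialect", {
  pre <- cohort_preset("paper_like", n_participants = 4, seed = 3)
  co <- generate_cohort(pre$spec, pre$profiles)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  ep <- read_epochs(paths[1])
  expect_equal(as.data.frame(ep), as.data.frame(co$epochs))
  cv <- read_covariates(paths[2])
  expect_identical(cv$participant_id, co$covariates$participant_id)
  expect_error(read_epochs(paths[2]), "epoch CSV")
})
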