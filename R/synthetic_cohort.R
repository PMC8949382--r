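#' Cohort-level simulation settings
#'
#' @param n_participants Number of participants.
#' @param class_proportions Mixing proportions of the true classes; must sum
#'   to 1.
#' @param waves Measurement waves as month offsets, strictly increasing.
#' @param wave_missingness_prob Probability that a non-baseline wave is
#'   missing (completely at random); the baseline wave is always present so
#'   every participant contributes at least one wave.
#' @param days_range Integer range of generated days per wave.
#' @param epoch_length Epoch length in seconds; fixed at 60.
#' @param seed Integer seed governing all randomness in [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, class_proportions = c(0.5, 0.5),
                        waves = c(0, 6, 12, 18, 24),
                        wave_missingness_prob = 0.1,
                        days_range = c(3L, 7L), epoch_length = 60L,
                        seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    stop("class_proportions must sum to 1")
  }
  if (any(diff(waves) <= 0)) stop("waves must be strictly increasing")
  if (epoch_length != 60L) stop("epoch_length is fixed at 60 s")
  stopifnot(n_participants >= 1, wave_missingness_prob >= 0,
            wave_missingness_prob < 1,
            days_range[1] >= 1, days_range[2] >= days_range[1])
  structure(list(n_participants = as.integer(n_participants),
                 class_proportions = class_proportions,
                 waves = waves,
                 wave_missingness_prob = wave_missingness_prob,
                 days_range = as.integer(days_range),
                 epoch_length = 60L, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Class trajectory and covariate profile
#'
#' Describes one latent class of the synthetic cohort: target mean daily
#' minutes of SB/LIPA/MVPA per wave, between-day and between-person spread,
#' bout structure, daytime non-wear behaviour, step rates, and baseline
#' covariate distributions.
#'
#' @param name Class label.
#' @param sb,lipa,mvpa Target mean daily minutes per wave (recycled to the
#'   number of waves). A behaviour whose target is exactly 0 at a wave is
#'   absent from generated days at that wave.
#' @param day_sd Between-day SDs, named `c(sb=, lipa=, mvpa=)` (min).
#' @param person_sd Between-person SDs of the personal intercept offsets
#'   (min), same naming.
#' @param person_slope_sd Between-person SDs of personal slope offsets
#'   (min/year).
#' @param run_mean Mean dwell (run length, min) of the semi-Markov state
#'   process per behaviour; `mvpa` acts as the MVPA-bout propensity.
#' @param nonwear_rate Expected number of daytime non-wear insertions per day.
#' @param nonwear_len Integer range of daytime non-wear insertion lengths
#'   (min).
#' @param short_wear_prob Probability that a day is a short-wear day (device
#'   worn for only a fraction of the waking window, drawn uniformly from
#'   30--65%); such days fall below the 10-h validity threshold and exercise
#'   the valid-day filter without biasing valid-day behaviour means.
#' @param steps_lipa,steps_mvpa Mean steps per LIPA / MVPA minute.
#' @param age_mean,age_sd,prop_female,bmi_mean,bmi_sd Covariate generators.
#' @param p_hypertension,p_copd,p_other Comorbidity probabilities.
#' @param rand_probs Randomisation allocation probabilities
#'   (multi, single, control).
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(name, sb, lipa, mvpa,
                          day_sd = c(sb = 25, lipa = 20, mvpa = 8),
                          person_sd = c(sb = 30, lipa = 25, mvpa = 6),
                          person_slope_sd = c(sb = 8, lipa = 4, mvpa = 3),
                          run_mean = c(sb = 20, lipa = 8, mvpa = 6),
                          nonwear_rate = 0.25, nonwear_len = c(90L, 240L),
                          short_wear_prob = 0.08,
                          steps_lipa = 45, steps_mvpa = 110,
                          age_mean = 64, age_sd = 7.5, prop_female = 0.39,
                          bmi_mean = 30, bmi_sd = 4.7,
                          p_hypertension = 0.76, p_copd = 0.10,
                          p_other = 0.19,
                          rand_probs = c(multi = 0.36, single = 0.30,
                                         control = 0.34)) {
  if (any(sb < 0) || any(lipa < 0) || any(mvpa < 0)) {
    stop("behaviour targets must be non-negative")
  }
  structure(list(name = name, sb = sb, lipa = lipa, mvpa = mvpa,
                 day_sd = day_sd, person_sd = person_sd,
                 person_slope_sd = person_slope_sd, run_mean = run_mean,
                 nonwear_rate = nonwear_rate,
                 nonwear_len = as.integer(nonwear_len),
                 short_wear_prob = short_wear_prob,
                 steps_lipa = steps_lipa, steps_mvpa = steps_mvpa,
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 p_hypertension = p_hypertension, p_copd = p_copd,
                 p_other = p_other,
                 rand_probs = rand_probs / sum(rand_probs)),
            class = "class_profile")
}

#' Bundled cohort presets
#'
#' `"paper_like"` mimics the two-profile structure reported for a two-year
#' activity trial in prediabetes/type-2 diabetes: a small "increased
#' activity" class (22%) whose MVPA rises across waves while SB falls, and a
#' large flat "no change" class, with class-linked age, BMI, comorbidity and
#' baseline-guideline distributions. `"high_separation"` plants two equal
#' classes whose MVPA (and SB) slopes differ by well over one pooled SD per
#' year, for recovery experiments. `"zero_separation"` uses two identical
#' classes, so any apparent 2-class structure is spurious.
#'
#' @param name Preset name.
#' @param n_participants,seed Passed to [cohort_spec()].
#' @return List with `spec` and `profiles`, ready for [generate_cohort()].
#' @export
cohort_preset <- function(name = c("paper_like", "high_separation",
                                   "zero_separation"),
                          n_participants = 168L, seed = 1L) {
  name <- match.arg(name)
  waves <- c(0, 6, 12, 18, 24)
  t <- waves / 12
  lin <- function(a, b) a + b * t  # intercept (min/day), slope (min/day/yr)
  flat_a <- class_profile("A", sb = lin(620, 0), lipa = lin(200, 0),
                          mvpa = lin(20, 0))
  switch(name,
    paper_like = list(
      spec = cohort_spec(n_participants, class_proportions = c(0.22, 0.78),
                         waves = waves, seed = seed),
      profiles = list(
        class_profile("increased", sb = lin(600, -30), lipa = lin(205, 10),
                      mvpa = lin(28, 11),
                      age_mean = 60.6, age_sd = 8.4, prop_female = 0.41,
                      bmi_mean = 29.5, bmi_sd = 4.2, p_hypertension = 0.65,
                      p_copd = 0.03, p_other = 0.22,
                      rand_probs = c(multi = 0.38, single = 0.41,
                                     control = 0.21),
                      person_sd = c(sb = 35, lipa = 25, mvpa = 8)),
        class_profile("no_change", sb = lin(590, 0), lipa = lin(215, 0),
                      mvpa = lin(21, 0),
                      age_mean = 65.3, age_sd = 7.2, prop_female = 0.38,
                      bmi_mean = 30.3, bmi_sd = 4.8, p_hypertension = 0.79,
                      p_copd = 0.12, p_other = 0.18,
                      rand_probs = c(multi = 0.36, single = 0.27,
                                     control = 0.37),
                      person_sd = c(sb = 35, lipa = 25, mvpa = 8)))),
    high_separation = list(
      spec = cohort_spec(n_participants, class_proportions = c(0.5, 0.5),
                         waves = waves, seed = seed),
      profiles = list(
        flat_a,
        class_profile("B", sb = lin(620, -50), lipa = lin(200, 0),
                      mvpa = lin(20, 25), run_mean = c(sb = 20, lipa = 8,
                                                       mvpa = 10)))),
    zero_separation = list(
      spec = cohort_spec(n_participants, class_proportions = c(0.5, 0.5),
                         waves = waves, seed = seed),
      profiles = list(flat_a, flat_a)))
}

# Minimum nocturnal non-wear block; with it, the waking window never exceeds
# 960 min, so per-wave targets must satisfy sb+lipa+mvpa <= 840 (14 h nominal
# waking wear) with headroom for between-day noise.
.MIN_NOCTURNAL <- 480L
.WAKING_MAX <- 1440L - .MIN_NOCTURNAL

.check_feasible <- function(profiles, waves) {
  for (g in seq_along(profiles)) {
    p <- profiles[[g]]
    for (s in c("sb", "lipa", "mvpa")) {
      if (length(p[[s]]) == 1L) p[[s]] <- rep(p[[s]], length(waves))
      if (length(p[[s]]) != length(waves)) {
        stop("profile ", g, ": '", s, "' targets must match the waves")
      }
      profiles[[g]] <- p
    }
    tot <- p$sb + p$lipa + p$mvpa
    bad <- which(tot > 840)
    if (length(bad)) {
      stop(sprintf(
        "infeasible targets: class '%s', wave month %s: SB+LIPA+MVPA = %.0f min exceeds the 840-min waking wear window",
        p$name, waves[bad[1]], tot[bad[1]]))
    }
  }
  profiles
}

# semi-Markov waking state sequence with exact per-state totals; dwell times
# 1 + geometric, capped by the remaining budget of the chosen state; the next
# state is drawn with probability proportional to remaining minutes, avoiding
# an immediate repeat while another state still has budget
.state_sequence <- function(minutes, run_mean) {
  rem <- as.integer(minutes)
  tot <- sum(rem)
  if (tot == 0L) return(integer(0))
  states <- integer(tot)
  lens <- integer(tot)
  nr <- 0L
  last <- 0L
  # pooled RNG draws (refilled on exhaustion) to cut per-run call overhead
  us <- stats::runif(64L)
  iu <- 0L
  pools <- lapply(run_mean, function(m) 1L + stats::rgeom(32L, 1 / m))
  ip <- c(0L, 0L, 0L)
  while (tot > 0L) {
    w <- rem
    if (last > 0L && sum(rem > 0L) > 1L) w[last] <- 0L
    iu <- iu + 1L
    if (iu > 64L) {
      us <- stats::runif(64L)
      iu <- 1L
    }
    r <- us[iu] * sum(w)
    s <- if (r < w[1]) 1L else if (r < w[1] + w[2]) 2L else 3L
    ip[s] <- ip[s] + 1L
    if (ip[s] > 32L) {
      pools[[s]] <- 1L + stats::rgeom(32L, 1 / run_mean[s])
      ip[s] <- 1L
    }
    d <- min(pools[[s]][ip[s]], rem[s])
    nr <- nr + 1L
    states[nr] <- s
    lens[nr] <- d
    rem[s] <- rem[s] - d
    tot <- tot - d
    last <- s
  }
  rep.int(states[seq_len(nr)], lens[seq_len(nr)])
}

#' Generate a synthetic accelerometer cohort
#'
#' Builds, for each participant, per-wave days of 1440 one-minute epochs: a
#' contiguous nocturnal non-wear block (zero counts), optional daytime
#' non-wear insertions, and waking minutes whose SB/LIPA/MVPA state follows a
#' semi-Markov process with geometric dwell times, tuned so that realised
#' daily behaviour totals match the class-wave targets plus person- and
#' day-level noise. Counts are drawn per state inside the corresponding
#' cut-point band (SB in [0, 99] with positive mass at 0; LIPA in
#' [100, 1951]; MVPA >= 1952), so cut-point classification recovers the
#' state. All randomness derives from `spec$seed`; the caller's RNG state is
#' restored on exit.
#'
#' @param spec A [cohort_spec()].
#' @param profiles List of [class_profile()] objects, one per class.
#' @return List with `epochs` (data.table in the epoch CSV dialect),
#'   `covariates` (one row per participant) and `truth` (`class`: true
#'   labels; `waves`: per participant-wave expected daily SB/LIPA/MVPA
#'   minutes including person effects).
#' @export
generate_cohort <- function(spec, profiles) {
  stopifnot(inherits(spec, "cohort_spec"),
            length(profiles) == length(spec$class_proportions))
  profiles <- .check_feasible(profiles, spec$waves)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  n <- spec$n_participants
  waves <- spec$waves
  tyr <- waves / 12
  G <- length(profiles)
  cls <- sample.int(G, n, replace = TRUE, prob = spec$class_proportions)
  ids <- sprintf("P%04d", seq_len(n))

  covariates <- data.frame(
    participant_id = ids, age = NA_real_, gender = NA_character_,
    bmi = NA_real_, randomisation = NA_character_,
    hypertension = NA_integer_, copd = NA_integer_,
    other_disease = NA_integer_, stringsAsFactors = FALSE)
  truth_waves <- vector("list", n)
  state_chunks <- list()
  meta <- list()
  chunk <- 0L

  for (i in seq_len(n)) {
    p <- profiles[[cls[i]]]
    covariates$age[i] <- round(stats::rnorm(1, p$age_mean, p$age_sd), 1)
    covariates$gender[i] <- if (stats::runif(1) < p$prop_female) "F" else "M"
    covariates$bmi[i] <- round(stats::rnorm(1, p$bmi_mean, p$bmi_sd), 1)
    covariates$randomisation[i] <- sample(names(p$rand_probs), 1L,
                                          prob = p$rand_probs)
    covariates$hypertension[i] <- stats::rbinom(1, 1, p$p_hypertension)
    covariates$copd[i] <- stats::rbinom(1, 1, p$p_copd)
    covariates$other_disease[i] <- stats::rbinom(1, 1, p$p_other)

    u <- stats::rnorm(3, 0, p$person_sd)        # intercept offsets (min)
    v <- stats::rnorm(3, 0, p$person_slope_sd)  # slope offsets (min/yr)
    targ <- rbind(sb = p$sb, lipa = p$lipa, mvpa = p$mvpa)
    pers <- targ + (u + outer(v, tyr))
    pers[targ == 0] <- 0          # a behaviour absent from the class stays absent
    pers <- pmax(pers, 0)
    truth_waves[[i]] <- data.frame(
      participant_id = ids[i], wave_month = waves,
      true_sb = pers["sb", ], true_lipa = pers["lipa", ],
      true_mvpa = pers["mvpa", ], row.names = NULL)

    present <- c(TRUE, stats::runif(length(waves) - 1L) >=
                         spec$wave_missingness_prob)
    for (w in which(present)) {
      n_days <- sample(seq(spec$days_range[1], spec$days_range[2]), 1L)
      for (d in seq_len(n_days)) {
        m <- round(stats::rnorm(3, pers[, w], p$day_sd))
        m[pers[, w] == 0] <- 0
        m <- pmax(m, 0L)
        if (stats::runif(1) < p$short_wear_prob) {
          m <- round(m * stats::runif(1, 0.30, 0.65))
        }
        n_ins <- stats::rpois(1, p$nonwear_rate)
        ins_len <- if (n_ins > 0) {
          sample(seq(p$nonwear_len[1], p$nonwear_len[2]), n_ins,
                 replace = TRUE)
        } else integer(0)
        if (sum(m) + sum(ins_len) > .WAKING_MAX) ins_len <- integer(0)
        if (sum(m) > .WAKING_MAX) {
          m <- floor(m * .WAKING_MAX / sum(m))
        }
        wake <- .state_sequence(m, p$run_mean)
        if (length(ins_len)) {
          cut <- sort(sample.int(length(wake) + 1L, length(ins_len),
                                 replace = TRUE)) - 1L
          pieces <- list()
          prev <- 0L
          for (b in seq_along(cut)) {
            pieces[[2L * b - 1L]] <-
              if (cut[b] > prev) wake[(prev + 1L):cut[b]] else integer(0)
            pieces[[2L * b]] <- rep.int(0L, ins_len[b])
            prev <- cut[b]
          }
          pieces[[2L * length(cut) + 1L]] <-
            if (prev < length(wake)) wake[(prev + 1L):length(wake)] else integer(0)
          wake <- unlist(pieces)
        }
        day <- c(rep.int(0L, 1440L - length(wake)), wake)
        chunk <- chunk + 1L
        state_chunks[[chunk]] <- day
        meta[[chunk]] <- c(i, waves[w], d)
      }
    }
  }

  states <- unlist(state_chunks)
  md <- do.call(rbind, meta)
  day_len <- lengths(state_chunks)   # all 1440
  n_epochs <- length(states)
  class_per_day <- cls[md[, 1]]

  counts <- integer(n_epochs)
  steps <- integer(n_epochs)
  class_per_epoch <- rep(class_per_day, day_len)
  lipa_rate <- vapply(profiles, `[[`, 0, "steps_lipa")
  mvpa_rate <- vapply(profiles, `[[`, 0, "steps_mvpa")
  i_sb <- which(states == 1L)
  i_li <- which(states == 2L)
  i_mv <- which(states == 3L)
  if (length(i_sb)) {
    cnt <- sample(1:99, length(i_sb), replace = TRUE)
    cnt[stats::runif(length(i_sb)) < 0.35] <- 0L
    counts[i_sb] <- cnt
    steps[i_sb] <- stats::rpois(length(i_sb), 1)
  }
  if (length(i_li)) {
    counts[i_li] <- sample(100:1951, length(i_li), replace = TRUE)
    steps[i_li] <- stats::rpois(length(i_li),
                                lipa_rate[class_per_epoch[i_li]])
  }
  if (length(i_mv)) {
    counts[i_mv] <- sample(1952:5724, length(i_mv), replace = TRUE)
    steps[i_mv] <- stats::rpois(length(i_mv),
                                mvpa_rate[class_per_epoch[i_mv]])
  }

  epochs <- data.table::data.table(
    participant_id = rep(ids[md[, 1]], day_len),
    wave_month = rep(md[, 2], day_len),
    day_index = rep(md[, 3], day_len),
    epoch_index = rep.int(0:1439, length(day_len)),
    counts = counts, steps = steps)

  list(epochs = epochs,
       covariates = covariates,
       truth = list(class = data.frame(participant_id = ids,
                                       true_class = cls),
                    waves = do.call(rbind, truth_waves)))
}

#' Hand-specified worked epoch fixtures
#'
#' Tiny epoch series with known non-wear runs, bout structure and
#' classification, used as oracle fixtures. `hand_day` is a full 1440-min
#' day whose summary is hand-computable: 600 nonwear, 751 SB (two bouts of
#' 300 and 451 min), 68 LIPA, 21 MVPA (one 12-min bout plus a 9-min run),
#' total counts 103760, total steps 3960.
#'
#' @return Named list of data.frames with columns `counts` and `steps`.
#' @export
generate_worked_fixture <- function() {
  seg <- function(n, counts, steps = 0L) {
    data.frame(counts = rep.int(as.integer(counts), n),
               steps = rep.int(as.integer(steps), n))
  }
  list(
    zeros90 = seg(90, 0),
    zeros89 = seg(89, 0),
    mvpa12 = rbind(seg(20, 50), seg(12, 2500, 110), seg(20, 500, 40)),
    split_interrupt = rbind(seg(45, 0), seg(2, 50), seg(45, 0)),
    split_blocked = rbind(seg(45, 0), seg(3, 50), seg(45, 0)),
    hand_day = rbind(seg(600, 0), seg(60, 500, 40), seg(35, 0),
                     seg(265, 50), seg(12, 2500, 110), seg(8, 1000, 30),
                     seg(9, 2000, 0), seg(451, 10, 0)))
}

#' Write a generated cohort to plain-text CSV files
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`epochs.csv`, `covariates.csv`,
#'   `ground_truth.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("epochs.csv", "covariates.csv",
                            "ground_truth.csv"))
  data.table::fwrite(cohort$epochs, paths[1])
  data.table::fwrite(cohort$covariates, paths[2])
  data.table::fwrite(cohort$truth$class, paths[3])
  invisible(paths)
}

#' Read an epoch CSV in the dialect written by [write_cohort()]
#' @param path CSV path.
#' @return data.table of epochs.
#' @export
read_epochs <- function(path) {
  dt <- data.table::fread(path)
  req <- c("participant_id", "wave_month", "day_index", "epoch_index",
           "counts", "steps")
  if (!all(req %in% names(dt))) {
    stop("not an epoch CSV; expected columns: ", paste(req, collapse = ", "))
  }
  dt
}

#' Read a covariates CSV in the dialect written by [write_cohort()]
#' @param path CSV path.
#' @return data.frame of baseline covariates.
#' @export
read_covariates <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!"participant_id" %in% names(df)) stop("not a covariates CSV")
  df
}
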