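#' Integer percent, rounded half away from zero
#' @param count,denom Numerator and denominator counts.
#' @return Integer percent.
#' @export
percent_round <- function(count, denom) {
  x <- 100 * count / denom
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `synthetic` (a preset name or a list with `preset`,
#' `n_participants`) or `input` (list with `epochs` and `covariates` CSV
#' paths) must be given.
#'
#' @param synthetic Synthetic-cohort request, e.g.
#'   `list(preset = "paper_like", n_participants = 60)`.
#' @param input Input CSV paths, `list(epochs =, covariates =)`.
#' @param rules A [processing_rules()] object.
#' @param pruning List with `policy` and `threshold` for
#'   [prune_collinear()].
#' @param G_list Candidate class numbers for [sweep_classes()].
#' @param n_starts,max_iter,tol EM settings, see [lclmm_spec()].
#' @param predictor_criterion `"AIC"` or `"BIC"` for backward elimination.
#' @param out_dir Output directory; `NULL` for no file output.
#' @param seed Master seed for synthetic generation and multistart EM.
#' @return Object of class `pa_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            rules = processing_rules(),
                            pruning = list(policy = "paper_list",
                                           threshold = 0.9),
                            G_list = 2:5, n_starts = 3L, max_iter = 300L,
                            tol = 1e-6, predictor_criterion = "AIC",
                            out_dir = NULL, seed = 1L) {
  if (is.null(synthetic) == is.null(input)) {
    stop("exactly one of 'synthetic' or 'input' must be set")
  }
  if (is.character(synthetic)) synthetic <- list(preset = synthetic)
  structure(list(synthetic = synthetic, input = input, rules = rules,
                 pruning = pruning, G_list = G_list,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 predictor_criterion = predictor_criterion,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pa_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON config path.
#' @return A `pa_config` object.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- do.call(processing_rules, as.list(js$rules))
  args <- js[setdiff(names(js), "rules")]
  args$rules <- rules
  if (!is.null(args$G_list)) args$G_list <- as.integer(args$G_list)
  do.call(pipeline_config, args)
}

#' Baseline characteristics by profile
#'
#' Mean (SD) for continuous covariates and n (%) for categorical ones, for
#' the whole sample and per assigned profile; percentages are rounded to the
#' nearest integer (half away from zero) with the column size as
#' denominator. Profiles with no members are flagged.
#'
#' @param covariates Baseline covariate table (one row per participant).
#' @param assignments Profile label per participant (aligned with
#'   `covariates`); pass a factor to force columns for profiles with no
#'   members (they are reported empty and flagged).
#' @param guideline Logical baseline guideline-achievement flag per
#'   participant (optional, may contain NA).
#' @return data.frame in long format: `variable`, `level`, `group`, `n`
#'   (column size), `count`, `percent`, `mean`, `sd`; attribute
#'   `empty_profiles` lists profiles without members.
#' @export
summarize_by_profile <- function(covariates, assignments,
                                 guideline = NULL) {
  stopifnot(nrow(covariates) == length(assignments))
  lev <- if (is.factor(assignments)) levels(assignments) else
    sort(unique(assignments))
  groups <- c(list(All = rep(TRUE, nrow(covariates))),
              lapply(stats::setNames(nm = lev),
                     function(g) assignments == g))
  rows <- list()
  add_cat <- function(variable, level, flag) {
    for (gn in names(groups)) {
      idx <- groups[[gn]]
      n <- sum(idx)
      cnt <- sum(flag[idx], na.rm = TRUE)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = level, group = gn, n = n,
        count = cnt,
        percent = if (n > 0) percent_round(cnt, n) else NA_integer_,
        mean = NA_real_, sd = NA_real_)
    }
  }
  add_cont <- function(variable, x) {
    for (gn in names(groups)) {
      idx <- groups[[gn]]
      n <- sum(idx)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = NA_character_, group = gn,
        n = n, count = NA_integer_, percent = NA_integer_,
        mean = if (n > 0) mean(x[idx], na.rm = TRUE) else NA_real_,
        sd = if (n > 1) stats::sd(x[idx], na.rm = TRUE) else NA_real_)
    }
  }
  add_cat("gender", "F", covariates$gender == "F")
  add_cont("age", covariates$age)
  add_cont("bmi", covariates$bmi)
  for (lv in c("multi", "single", "control")) {
    add_cat("randomisation", lv, covariates$randomisation == lv)
  }
  add_cat("hypertension", "1", covariates$hypertension == 1)
  add_cat("copd", "1", covariates$copd == 1)
  add_cat("other_disease", "1", covariates$other_disease == 1)
  if (!is.null(guideline)) {
    add_cat("guideline_baseline", "TRUE", guideline)
  }
  out <- do.call(rbind, rows)
  attr(out, "empty_profiles") <-
    names(groups)[vapply(groups, sum, 0) == 0]
  out
}

#' Mean z-value trajectories by profile with 95% confidence intervals
#'
#' @param zpanel Z-scored feature panel with `participant_id`, `wave_month`.
#' @param assignments Named profile vector (names = participant ids).
#' @param features Feature columns to summarise.
#' @return data.frame: profile, wave_month, feature, n, mean_z, ci_low,
#'   ci_high (normal approximation, mean +- 1.96 SE).
#' @export
trajectory_table <- function(zpanel, assignments, features) {
  prof <- assignments[as.character(zpanel$participant_id)]
  out <- list()
  for (ft in features) {
    agg <- stats::aggregate(zpanel[[ft]],
                            by = list(profile = prof,
                                      wave_month = zpanel$wave_month),
                            FUN = function(v) c(n = length(v),
                                                mean = mean(v),
                                                se = stats::sd(v) /
                                                  sqrt(length(v))))
    m <- as.data.frame(agg$x)
    out[[ft]] <- data.frame(profile = agg$profile,
                            wave_month = agg$wave_month, feature = ft,
                            n = m$n, mean_z = m$mean,
                            ci_low = m$mean - 1.96 * m$se,
                            ci_high = m$mean + 1.96 * m$se)
  }
  do.call(rbind, out)
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", name,
                                          conditionMessage(e)),
                        call = sys.call(-1), stage = name)))
  })
  log(sprintf("stage %-10s done in %.2f s", name, proc.time()[3] - t0))
  res
}

#' Run the full trajectory-profile pipeline
#'
#' Stages: synthetic generation (or CSV input) -> epoch processing and
#' wear-time filtering -> 15-variable feature panel, pruning and pooled
#' z-scoring -> latent-class sweep and class-number selection -> profile
#' assignment and labelling (the profile with the largest fitted MVPA slope
#' is labelled `"increased"`, the reference profile `"no_change"`; with
#' more than two profiles the non-increased ones are numbered) -> baseline
#' characteristics table -> logistic predictor model with backward
#' elimination and diagnostics -> per-profile z-trajectory table. All
#' result surfaces are returned and, when `config$out_dir` is set, written
#' as CSV/JSON with a run log.
#'
#' @param config A [pipeline_config()].
#' @param through Last stage to run: `"simulate"`, `"process"`,
#'   `"features"`, `"fit"` or `"predict"` (default, everything).
#' @return List bundle with the stage outputs produced.
#' @export
run_pipeline <- function(config, through = "predict") {
  stopifnot(inherits(config, "pa_config"))
  stages <- c("simulate", "process", "features", "fit", "predict")
  through <- match.arg(through, stages)
  upto <- match(through, stages)
  log_lines <- character(0)
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  bundle <- list(config = config)

  bundle$cohort <- .stage("simulate", log, {
    if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      preset <- cohort_preset(sy$preset %||% "paper_like",
                              n_participants = sy$n_participants %||% 168L,
                              seed = config$seed)
      cohort <- generate_cohort(preset$spec, preset$profiles)
      cohort$waves <- preset$spec$waves
      cohort
    } else {
      ep <- read_epochs(config$input$epochs)
      list(epochs = ep, covariates = read_covariates(config$input$covariates),
           truth = NULL, waves = sort(unique(ep$wave_month)))
    }
  })
  if (upto < 2) return(.finish(bundle, log_lines))

  bundle$processing <- .stage("process", log, {
    ds <- process_epochs(bundle$cohort$epochs, config$rules)
    fv <- filter_valid_waves(ds, config$rules)
    n_in <- length(unique(ds$participant_id))
    n_keep <- length(unique(fv$days$participant_id))
    log(sprintf("participants in: %d; retained: %d; excluded for lack of valid data: %d",
                n_in, n_keep, n_in - n_keep))
    list(day_summaries = ds, filtered = fv)
  })
  if (upto < 3) return(.finish(bundle, log_lines))

  bundle$features <- .stage("features", log, {
    panel <- build_feature_vectors(bundle$processing$filtered$days)
    if (any(panel$zero_replaced)) {
      log(sprintf("ilr zero-replacement applied to %d participant-wave(s)",
                  sum(panel$zero_replaced)))
    }
    pruning <- prune_collinear(panel,
                               threshold = config$pruning$threshold,
                               policy = config$pruning$policy)
    std <- standardize_features(panel)
    # baseline guideline flags from the first wave, where retained
    base_wave <- min(bundle$cohort$waves)
    dd <- bundle$processing$filtered$days
    base <- dd[dd$wave_month == base_wave, ]
    gl <- vapply(split(base$mvpa_minutes, base$participant_id),
                 function(v) weekly_mvpa(v, config$rules)$meets_guideline,
                 TRUE)
    list(panel = panel, pruning = pruning, std = std,
         guideline_baseline = gl)
  })
  if (upto < 4) return(.finish(bundle, log_lines))

  bundle$fit <- .stage("fit", log, {
    z <- bundle$features$std$z
    z$time <- z$wave_month / 12
    outcomes <- bundle$features$pruning$retained
    dat <- lclmm_data(z, outcomes)
    base_spec <- lclmm_spec(2L, outcomes, n_starts = config$n_starts,
                            seed = config$seed, max_iter = config$max_iter,
                            tol = config$tol)
    sweep <- sweep_classes(dat, base_spec, config$G_list)
    sel <- select_classes(sweep$table)
    chosen <- sweep$fits[[as.character(sel$G)]]
    log(sprintf("selected G = %d (lowest mean posterior %.3f, entropy %.3f)",
                sel$G, chosen$lowest_mean_posterior, chosen$entropy))
    # label profiles by fitted MVPA slope where available
    slope_ft <- if ("mean_mvpa" %in% outcomes) "mean_mvpa" else outcomes[1]
    slopes <- chosen$beta[2, match(slope_ft, outcomes), ]
    labels <- rep(NA_character_, sel$G)
    labels[which.max(slopes)] <- "increased"
    rest <- setdiff(seq_len(sel$G), which.max(slopes))
    labels[rest] <- if (length(rest) == 1) "no_change" else
      paste0("no_change_", seq_along(rest))
    prof <- stats::setNames(labels[chosen$assignments], dat$ids)
    list(data = dat, sweep = sweep, selection = sel, model = chosen,
         profile_labels = labels, profiles = prof)
  })
  if (upto < 5) return(.finish(bundle, log_lines))

  bundle$results <- .stage("predict", log, {
    ids <- bundle$fit$data$ids
    cov <- bundle$cohort$covariates
    cov <- cov[match(ids, cov$participant_id), ]
    prof <- bundle$fit$profiles[ids]
    gl <- bundle$features$guideline_baseline[ids]
    chars <- summarize_by_profile(cov, prof, gl)
    traj <- trajectory_table(bundle$features$std$z, bundle$fit$profiles,
                             bundle$fit$data$outcomes)
    pd <- data.frame(
      increased = as.integer(prof == "increased"),
      gender = factor(cov$gender, levels = c("F", "M")),
      age = cov$age,
      randomisation = factor(cov$randomisation,
                             levels = c("multi", "single", "control")),
      bmi = cov$bmi, hypertension = cov$hypertension, copd = cov$copd,
      other_disease = cov$other_disease,
      guideline_baseline = as.integer(gl))
    n_na <- sum(!stats::complete.cases(pd))
    if (n_na) {
      log(sprintf("predictor stage: %d participant(s) without baseline guideline data dropped",
                  n_na))
      pd <- pd[stats::complete.cases(pd), ]
    }
    be <- backward_eliminate(pd, "increased",
                             forced = c("gender", "age", "randomisation"),
                             candidates = c("bmi", "hypertension", "copd",
                                            "other_disease",
                                            "guideline_baseline"),
                             criterion = config$predictor_criterion)
    diag <- logistic_diagnostics(be$fit, pd)
    list(characteristics = chars, trajectories = traj, predictor = be,
         diagnostics = diag)
  })
  .finish(bundle, log_lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.finish <- function(bundle, log_lines) {
  bundle$log <- log_lines
  out_dir <- bundle$config$out_dir
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  if (!is.null(bundle$cohort) && !is.null(bundle$config$synthetic)) {
    write_cohort(bundle$cohort, dir)
  }
  if (!is.null(bundle$processing)) {
    w(bundle$processing$day_summaries, "day_summaries.csv")
    w(bundle$processing$filtered$waves, "wave_summary.csv")
  }
  if (!is.null(bundle$features)) {
    p <- bundle$features$panel
    z <- bundle$features$std$z
    long <- do.call(rbind, lapply(activity_feature_names(), function(ft) {
      data.frame(participant_id = p$participant_id,
                 wave_month = p$wave_month, feature = ft,
                 raw_value = p[[ft]], z_value = z[[ft]])
    }))
    w(long, "features.csv")
    pr <- bundle$features$pruning
    jsonlite::write_json(list(policy = pr$policy, threshold = pr$threshold,
                              retained = pr$retained,
                              excluded = pr$excluded),
                         file.path(dir, "pruning.json"), auto_unbox = TRUE)
  }
  if (!is.null(bundle$fit)) {
    w(bundle$fit$sweep$table, "fit_table.csv")
    jsonlite::write_json(
      list(G = bundle$fit$selection$G, rule = bundle$fit$selection$rule,
           rationale = bundle$fit$selection$rationale),
      file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    m <- bundle$fit$model
    jsonlite::write_json(
      list(pi = m$pi, beta = m$beta, D = m$D, sigma2 = m$sigma2,
           loglik = m$loglik, n_params = m$n_params, AIC = m$AIC,
           BIC = m$BIC, entropy = m$entropy,
           lowest_mean_posterior = m$lowest_mean_posterior,
           outcomes = m$outcomes, profile_labels = bundle$fit$profile_labels),
      file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
    w(data.frame(participant_id = bundle$fit$data$ids,
                 profile = bundle$fit$profiles,
                 m$posterior), "posteriors.csv")
  }
  if (!is.null(bundle$results)) {
    w(bundle$results$characteristics, "characteristics.csv")
    w(bundle$results$trajectories, "trajectories.csv")
    w(bundle$results$predictor$fit$table, "predictors.csv")
    w(bundle$results$predictor$trace, "elimination_trace.csv")
    dg <- bundle$results$diagnostics
    jsonlite::write_json(
      list(box_tidwell = dg$box_tidwell,
           vif = dg$vif,
           influence = list(cutoff = dg$influence$cutoff,
                            flagged = dg$influence$flagged)),
      file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(bundle$log, file.path(dir, "log.txt"))
  invisible(dir)
}
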