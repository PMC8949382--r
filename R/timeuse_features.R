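#' Names of the 15 activity variables, in canonical order
#' @export
activity_feature_names <- function() {
  c("mean_sb", "mean_lipa", "mean_mvpa",
    "sd_sb", "sd_lipa", "sd_mvpa",
    "sb_bout_minutes", "mvpa_bout_minutes",
    "sb_bout_count", "mvpa_bout_count",
    "total_counts", "steps",
    "ilr_sb", "ilr_lipa", "ilr_mvpa")
}

#' Isometric log-ratio pivot coordinates of the 3-part time-use composition
#'
#' For the composition (SB, LIPA, MVPA) the pivot coordinate of a behaviour
#' x against the remaining two (y, z) is `sqrt(2/3) * ln(x / sqrt(y*z))`:
#' relative time in one behaviour against the geometric mean of the other
#' two. The three coordinates sum to zero and are invariant to rescaling of
#' the whole composition. Zero parts are replaced by `zero_replace` (min/day)
#' before the transform; the result carries a `zero_replaced` attribute
#' flagging affected rows. Negative parts are rejected.
#'
#' @param sb,lipa,mvpa Mean daily minutes (vectors of equal length).
#' @param zero_replace Replacement value for zero parts.
#' @return data.frame with columns `ilr_sb`, `ilr_lipa`, `ilr_mvpa` and
#'   attribute `zero_replaced`.
#' @export
ilr_coordinates <- function(sb, lipa, mvpa, zero_replace = 0.5) {
  parts <- cbind(sb, lipa, mvpa)
  if (any(parts < 0)) stop("composition parts must be non-negative")
  flagged <- rowSums(parts == 0) > 0
  parts[parts == 0] <- zero_replace
  k <- sqrt(2 / 3)
  out <- data.frame(
    ilr_sb   = k * log(parts[, 1] / sqrt(parts[, 2] * parts[, 3])),
    ilr_lipa = k * log(parts[, 2] / sqrt(parts[, 1] * parts[, 3])),
    ilr_mvpa = k * log(parts[, 3] / sqrt(parts[, 1] * parts[, 2])))
  attr(out, "zero_replaced") <- flagged
  out
}

#' Build the 15-variable activity feature panel
#'
#' One row per retained participant-wave, computed over its valid days only:
#' mean and between-day SD (sample, n-1) of daily SB/LIPA/MVPA minutes; mean
#' daily bout minutes and bout counts for SB and MVPA; mean daily total
#' counts and steps; and the three ilr pivot coordinates of the mean daily
#' composition. Bout features are per-day means so waves with different
#' numbers of valid days are comparable.
#'
#' @param days Valid-day summaries of retained waves, as returned in
#'   `filter_valid_waves()$days`.
#' @return data.frame with `participant_id`, `wave_month`, the 15 features,
#'   and a `zero_replaced` flag for waves whose composition needed
#'   zero-replacement.
#' @export
build_feature_vectors <- function(days) {
  dt <- data.table::as.data.table(days)
  sb_minutes <- lipa_minutes <- mvpa_minutes <- NULL
  sb_bout_minutes <- mvpa_bout_minutes <- NULL
  sb_bout_count <- mvpa_bout_count <- total_counts <- total_steps <- NULL
  fv <- dt[, list(
    mean_sb = mean(sb_minutes), mean_lipa = mean(lipa_minutes),
    mean_mvpa = mean(mvpa_minutes),
    sd_sb = stats::sd(sb_minutes), sd_lipa = stats::sd(lipa_minutes),
    sd_mvpa = stats::sd(mvpa_minutes),
    sb_bout_minutes = mean(sb_bout_minutes),
    mvpa_bout_minutes = mean(mvpa_bout_minutes),
    sb_bout_count = mean(sb_bout_count),
    mvpa_bout_count = mean(mvpa_bout_count),
    total_counts = mean(total_counts), steps = mean(total_steps)),
    by = c("participant_id", "wave_month")]
  ilr <- ilr_coordinates(fv$mean_sb, fv$mean_lipa, fv$mean_mvpa)
  out <- cbind(as.data.frame(fv), ilr)
  out$zero_replaced <- attr(ilr, "zero_replaced")
  out
}

#' Pooled z-scoring of a feature panel
#'
#' One mean and SD per feature, pooled over all retained participant-waves
#' (not per wave), so within-profile z-values can drift across time. The
#' scaling constants are stored for back-transformation.
#'
#' @param panel Feature panel from [build_feature_vectors()] (or any
#'   data.frame containing `features` columns).
#' @param features Feature columns to standardize.
#' @return Object of class `pa_std_panel`: list with `z` (panel with
#'   features replaced by z-scores), `center`, `scale`.
#' @export
standardize_features <- function(panel, features = activity_feature_names()) {
  stopifnot(nrow(panel) >= 2, all(features %in% names(panel)))
  x <- as.matrix(panel[, features])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance feature(s): ",
         paste(features[scl == 0], collapse = ", "))
  }
  z <- panel
  z[, features] <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(z = z, center = ctr, scale = scl, features = features),
            class = "pa_std_panel")
}

#' Back-transform z-scores to the raw feature scale
#' @param std A `pa_std_panel` from [standardize_features()].
#' @return data.frame on the original scale.
#' @export
unstandardize_features <- function(std) {
  stopifnot(inherits(std, "pa_std_panel"))
  x <- std$z
  x[, std$features] <- sweep(sweep(as.matrix(x[, std$features]), 2,
                                   std$scale, "*"), 2, std$center, "+")
  x
}

#' Prune collinear features by Spearman correlation
#'
#' Two policies. `"paper_list"` excludes the fixed ten variables dropped in
#' the reproduced analysis (bout counts and minutes for SB/MVPA, total
#' counts, steps, ilr LIPA/MVPA, SD of SB/LIPA), retaining
#' `mean_sb, mean_lipa, mean_mvpa, sd_mvpa, ilr_sb`. `"greedy"` iteratively
#' drops, from the pair with the largest absolute Spearman correlation at or
#' above `threshold`, the member with the larger mean absolute correlation
#' to all other retained features (ties: the later one in canonical order),
#' until no pair reaches the threshold.
#'
#' @param panel Feature panel (raw or z-scored).
#' @param threshold Absolute Spearman correlation threshold in (0, 1].
#' @param policy `"paper_list"` or `"greedy"`.
#' @param features Feature columns considered.
#' @return Object of class `pa_pruning`: list with `correlation` (Spearman
#'   matrix), `threshold`, `policy`, `excluded`, `retained`.
#' @export
prune_collinear <- function(panel, threshold = 0.9,
                            policy = c("paper_list", "greedy"),
                            features = activity_feature_names()) {
  policy <- match.arg(policy)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  stopifnot(all(features %in% names(panel)))
  rho <- stats::cor(as.matrix(panel[, features]), method = "spearman")
  if (policy == "paper_list") {
    retained <- c("mean_sb", "mean_lipa", "mean_mvpa", "sd_mvpa", "ilr_sb")
    excluded <- setdiff(features, retained)
  } else {
    retained <- features
    excluded <- character(0)
    repeat {
      sub <- abs(rho[retained, retained, drop = FALSE])
      sub[is.na(sub)] <- 0   # zero-variance columns correlate with nothing
      diag(sub) <- 0
      if (max(sub, na.rm = TRUE) < threshold) break
      pair <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
      cand <- retained[pair]
      load <- rowMeans(sub[cand, , drop = FALSE])
      drop_ft <- if (diff(load) == 0) {
        cand[which.max(match(cand, features))]
      } else cand[which.max(load)]
      excluded <- c(excluded, drop_ft)
      retained <- setdiff(retained, drop_ft)
    }
  }
  structure(list(correlation = rho, threshold = threshold, policy = policy,
                 excluded = excluded, retained = retained),
            class = "pa_pruning")
}
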