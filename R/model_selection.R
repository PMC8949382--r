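#' Fit latent class models across candidate class numbers
#'
#' Fits one model per requested number of classes under a shared seed
#' protocol and assembles a fit-index table (AIC, BIC, lowest mean posterior
#' probability per profile, entropy). Non-convergence is recorded, not
#' fatal.
#'
#' @param data An [lclmm_data()] object.
#' @param base_spec An [lclmm_spec()] whose `n_classes` is overridden.
#' @param G_list Integer vector of class numbers to fit.
#' @return Object of class `lclmm_sweep`: list with `table` (one row per G)
#'   and `fits` (the `lclmm_fit` objects, named by G).
#' @export
sweep_classes <- function(data, base_spec, G_list = 2:5) {
  stopifnot(length(G_list) >= 1)
  fits <- lapply(G_list, function(G) {
    sp <- base_spec
    sp$n_classes <- as.integer(G)
    lclmm_fit(data, sp)
  })
  names(fits) <- G_list
  tab <- data.frame(
    G = G_list,
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    lowest_mean_posterior = vapply(fits, `[[`, 0, "lowest_mean_posterior"),
    entropy = vapply(fits, `[[`, 0, "entropy"),
    min_class_prop = vapply(fits, function(f) min(f$pi), 0),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    best_start = vapply(fits, `[[`, 0L, "best_start"),
    row.names = NULL)
  structure(list(table = tab, fits = fits), class = "lclmm_sweep")
}

#' Choose the number of classes from a fit-index table
#'
#' Rule: among converged candidates whose smallest class holds at least
#' `min_class_prop` of the sample (the floor is skipped for rows where the
#' class-size information is `NA`, e.g. when applying the rule to a printed
#' table), prefer the highest lowest-mean-posterior probability, then the
#' highest entropy, then the smaller G (parsimony). A single-class row is a
#' reference only: posterior and entropy are identically 1 at G = 1, so it
#' is excluded from the comparison unless no multi-class candidate is
#' eligible. AIC and BIC are reported alongside but are not dispositive;
#' substantive meaningfulness of the profiles remains a human judgement and
#' is only flagged in the rationale.
#'
#' @param fit_table data.frame with columns `G`, `AIC`, `BIC`,
#'   `lowest_mean_posterior`, `entropy` and optionally `min_class_prop`,
#'   `converged` (assumed converged when absent), e.g.
#'   `sweep_classes()$table`.
#' @param min_class_prop Minimum share of subjects in the smallest class.
#' @return List: `G` (chosen), `rationale` (data.frame of criterion values
#'   with the eligibility and choice flags), `rule`.
#' @export
select_classes <- function(fit_table, min_class_prop = 0.05) {
  tb <- as.data.frame(fit_table)
  stopifnot(all(c("G", "lowest_mean_posterior", "entropy") %in% names(tb)))
  if (is.null(tb$converged)) tb$converged <- TRUE
  if (is.null(tb$min_class_prop)) tb$min_class_prop <- NA_real_
  eligible <- tb$converged &
    (is.na(tb$min_class_prop) | tb$min_class_prop >= min_class_prop)
  if (any(eligible & tb$G >= 2)) eligible <- eligible & tb$G >= 2
  if (!any(eligible)) stop("no converged candidate model")
  cand <- tb[eligible, ]
  ord <- order(-cand$lowest_mean_posterior, -cand$entropy, cand$G)
  chosen <- cand$G[ord[1]]
  tb$eligible <- eligible
  tb$chosen <- tb$G == chosen
  list(G = chosen, rationale = tb, rule = paste(
    "highest lowest-mean-posterior, then highest entropy, then smallest G;",
    sprintf("class-size floor %.0f%%;", 100 * min_class_prop),
    "AIC/BIC reported but not dispositive"))
}
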