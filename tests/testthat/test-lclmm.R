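# a small fixed parameter set used across likelihood tests
pars2 <- function() {
  list(pi = c(0.6, 0.4),
       beta = array(c(0.5, 0.2, -0.5, -0.2), c(2, 1, 2)),
       D = array(c(0.4, 0.05, 0.05, 0.1), c(2, 2, 1)),
       sigma2 = 0.3)
}

test_that("log-likelihood matches the closed form at G=1, K=1, one wave", {
  set.seed(1)
  n <- 30
  y <- rnorm(n, 1.2, 1)
  t0 <- 0.5
  panel <- data.frame(participant_id = sprintf("S%02d", 1:n), time = t0,
                      y1 = y)
  dat <- lclmm_data(panel, "y1")
  b0 <- 0.9; b1 <- 0.3
  D <- matrix(c(0.5, 0.1, 0.1, 0.2), 2)
  s2 <- 0.4
  pars <- list(pi = 1, beta = array(c(b0, b1), c(2, 1, 1)),
               D = array(D, c(2, 2, 1)), sigma2 = s2)
  # closed form: y_i ~ N(b0 + b1 t, v00 + 2 t v01 + t^2 v11 + sigma2)
  vtot <- D[1, 1] + 2 * t0 * D[1, 2] + t0^2 * D[2, 2] + s2
  expect_equal(lclmm_loglik(dat, pars),
               sum(dnorm(y, b0 + b1 * t0, sqrt(vtot), log = TRUE)),
               tolerance = 1e-10)
})

test_that("log-likelihood additivity and label-permutation invariance", {
  sim <- sim_lclmm_panel(25, c(0.5, 0.5),
                         array(c(0.8, 0.5, -0.8, -0.5), c(2, 1, 2)),
                         array(c(0.3, 0, 0, 0.1), c(2, 2, 1)), 0.25,
                         times = c(0, 0.5, 1, 2), seed = 5)
  dat <- lclmm_data(sim$panel, "y1", time = "time")
  p <- pars2()
  ll <- lclmm_loglik(dat, p)
  # duplicating every participant doubles the log-likelihood
  p2 <- sim$panel
  p2$participant_id <- paste0(p2$participant_id, "_dup")
  dat2 <- lclmm_data(rbind(sim$panel, p2), "y1")
  expect_equal(lclmm_loglik(dat2, p), 2 * ll, tolerance = 1e-9)
  # permuting class labels leaves it unchanged
  pp <- list(pi = p$pi[2:1], beta = p$beta[, , 2:1, drop = FALSE],
             D = p$D, sigma2 = p$sigma2)
  expect_equal(lclmm_loglik(dat, pp), ll, tolerance = 1e-10)
  # invalid parameters rejected
  bad <- p
  bad$sigma2 <- -1
  expect_error(lclmm_loglik(dat, bad), "positive")
  bad2 <- p
  bad2$D[, , 1] <- matrix(c(1, 2, 2, 1), 2)
  expect_error(lclmm_loglik(dat, bad2), "positive definite")
})

test_that("G=1 collapses to a single linear mixed model (lme4 oracle)", {
  sim <- sim_lclmm_panel(60, 1, array(c(0.4, -0.6), c(2, 1, 1)),
                         array(c(0.5, 0.1, 0.1, 0.2), c(2, 2, 1)), 0.3,
                         times = c(0, 0.5, 1, 1.5, 2), seed = 8)
  lmer_fit <- lme4::lmer(y1 ~ time + (time | participant_id),
                         data = sim$panel, REML = FALSE)
  vc <- lme4::VarCorr(lmer_fit)$participant_id
  pars <- list(pi = 1,
               beta = array(lme4::fixef(lmer_fit), c(2, 1, 1)),
               D = array(vc[1:2, 1:2], c(2, 2, 1)),
               sigma2 = attr(lme4::VarCorr(lmer_fit), "sc")^2)
  dat <- lclmm_data(sim$panel, "y1")
  # oracle equivalence of the likelihood function at the lme4 ML estimates
  expect_equal(lclmm_loglik(dat, pars), as.numeric(logLik(lmer_fit)),
               tolerance = 1e-6)
  # the EM optimum agrees with the direct mixed-model optimum
  fit <- lclmm_fit(dat, lclmm_spec(1, "y1", n_starts = 1, seed = 1,
                                   max_iter = 5000, tol = 1e-10))
  expect_equal(fit$loglik, as.numeric(logLik(lmer_fit)), tolerance = 1e-3)
  expect_identical(fit$pi, 1)
  expect_true(all(fit$posterior == 1))
})

test_that("EM log-likelihood is monotone on every tested dataset", {
  for (seed in 1:3) {
    sim <- sim_lclmm_panel(40, c(0.5, 0.5),
                           array(c(0.6, 0.8, -0.6, -0.8), c(2, 1, 2)),
                           array(c(0.3, 0, 0, 0.1), c(2, 2, 1)), 0.25,
                           times = c(0, 0.5, 1, 1.5, 2), seed = seed)
    dat <- lclmm_data(sim$panel, "y1")
    fit <- lclmm_fit(dat, lclmm_spec(2, "y1", n_starts = 2, seed = seed))
    expect_true(all(diff(fit$ll_trace) > -1e-8))
  }
})

test_that("entropy: degenerate, uniform, hand-computed and G=1 cases", {
  expect_identical(lclmm_entropy(cbind(c(1, 1), c(0, 0))), 1)
  expect_equal(lclmm_entropy(cbind(c(0.5, 0.5), c(0.5, 0.5))), 0)
  # hand arithmetic: 1 - (0.325083 + 0.500402) / (2 ln 2)
  expect_equal(lclmm_entropy(rbind(c(0.9, 0.1), c(0.8, 0.2))), 0.4045384,
               tolerance = 1e-6)
  expect_identical(lclmm_entropy(matrix(1, 5, 1)), 1)
})

test_that("classification: argmax, tie-break, per-class mean posteriors", {
  expect_identical(lclmm_classify(rbind(c(0.6, 0.4)))$assignments, 1L)
  expect_identical(lclmm_classify(rbind(c(0.5, 0.5)))$assignments, 1L)
  perfect <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_identical(lclmm_classify(perfect)$lowest_mean_posterior, 1)
  # hand computation on a fixture posterior matrix
  post <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.3, 0.7))
  cl <- lclmm_classify(post)
  expect_identical(cl$assignments, c(1L, 1L, 2L))
  expect_equal(cl$class_mean_posterior, c(0.75, 0.7))
  expect_equal(cl$lowest_mean_posterior, 0.7)
  # empty class flagged
  cl2 <- lclmm_classify(rbind(c(0.9, 0.1), c(0.8, 0.2)))
  expect_identical(cl2$empty_classes, 2L)
  expect_true(is.na(cl2$class_mean_posterior[2]))
})

test_that("fit indices follow the definitions with hand-counted n_params", {
  sim <- sim_lclmm_panel(30, c(0.5, 0.5),
                         array(c(1, 1, -1, -1, 0.5, 0, -0.5, 0), c(2, 2, 2)),
                         array(c(0.3, 0, 0, 0.1, 0.3, 0, 0, 0.1),
                               c(2, 2, 2)), c(0.25, 0.25),
                         times = c(0, 1, 2), seed = 2)
  dat <- lclmm_data(sim$panel, c("y1", "y2"))
  fit <- lclmm_fit(dat, lclmm_spec(2, c("y1", "y2"), n_starts = 1,
                                   seed = 1))
  # G=2, K=2: (G-1) + 2KG + 4K = 1 + 8 + 8 = 17
  expect_identical(fit$n_params, 17)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * 17)
  expect_equal(fit$BIC, -2 * fit$loglik + 17 * log(30))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$posterior), rep(1, 30), tolerance = 1e-9)
  expect_identical(fit$assignments, lclmm_classify(fit$posterior)$assignments)
  # canonical order: descending mixing proportions
  expect_true(all(diff(fit$pi) <= 1e-12))
})

test_that("fits are deterministic given the seed and recover planted classes", {
  beta <- array(c(0.9, 0.7, -0.9, -0.7), c(2, 1, 2))
  sim <- sim_lclmm_panel(80, c(0.5, 0.5), beta,
                         array(c(0.2, 0, 0, 0.05), c(2, 2, 1)), 0.2,
                         times = c(0, 0.5, 1, 1.5, 2), seed = 4)
  dat <- lclmm_data(sim$panel, "y1")
  spec <- lclmm_spec(2, "y1", n_starts = 3, seed = 11)
  f1 <- lclmm_fit(dat, spec)
  f2 <- lclmm_fit(dat, spec)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$assignments, f2$assignments)
  expect_gte(best_agreement(f1$assignments, sim$truth), 0.9)
})

test_that("missing waves are handled through the observed-data likelihood", {
  sim <- sim_lclmm_panel(40, c(0.5, 0.5),
                         array(c(0.9, 0.7, -0.9, -0.7), c(2, 1, 2)),
                         array(c(0.2, 0, 0, 0.05), c(2, 2, 1)), 0.2,
                         times = c(0, 0.5, 1, 1.5, 2), seed = 6)
  pan <- sim$panel
  set.seed(9)
  drop <- sample(nrow(pan), 40)  # remove random waves, keep >=1 per subject
  pan <- pan[-drop, ]
  keep <- names(which(table(pan$participant_id) >= 1))
  pan <- pan[pan$participant_id %in% keep, ]
  dat <- lclmm_data(pan, "y1")
  fit <- lclmm_fit(dat, lclmm_spec(2, "y1", n_starts = 2, seed = 3))
  expect_true(is.finite(fit$loglik))
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  expect_equal(rowSums(fit$posterior), rep(1, dat$N), tolerance = 1e-9)
})
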