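#' Specification of a latent class linear mixed model
#'
#' The model: subject i with observation times t (years) has, for each
#' outcome k, y_ik = X_i beta_kg + X_i b_ik + e_ik conditional on latent
#' class g, where X_i = (1, t), b_ik ~ N(0, D_k) is a correlated random
#' intercept+slope, e_ik ~ N(0, sigma2_k I), outcomes are conditionally
#' independent given class and their own random effects, and variance
#' components are common across classes. Class membership has mixing
#' probabilities pi_g.
#'
#' @param n_classes Number of latent classes G (>= 1).
#' @param outcomes Character vector of outcome (feature) names.
#' @param n_starts Number of EM initializations: one deterministic
#'   (k-means on per-subject OLS intercept/slope summaries) plus
#'   `n_starts - 1` seeded random-assignment starts.
#' @param seed Integer seed for the multistart protocol.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @return Object of class `lclmm_spec`.
#' @export
lclmm_spec <- function(n_classes, outcomes, n_starts = 5L, seed = 1L,
                       max_iter = 500L, tol = 1e-6) {
  stopifnot(n_classes >= 1, length(outcomes) >= 1, tol > 0, n_starts >= 1)
  structure(list(n_classes = as.integer(n_classes), outcomes = outcomes,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "lclmm_spec")
}

#' Assemble longitudinal data for the latent class mixed model
#'
#' Groups subjects by their observed-wave pattern so likelihood and EM
#' computations vectorize over subjects sharing a design matrix. Missing
#' waves are simply absent rows (MAR handling through the observed-data
#' likelihood); every subject needs at least one observed wave.
#'
#' @param panel data.frame with one row per subject-wave: an id column, a
#'   time column (years), and the outcome columns.
#' @param outcomes Outcome column names.
#' @param id,time Column names.
#' @return Object of class `lclmm_data`.
#' @export
lclmm_data <- function(panel, outcomes, id = "participant_id",
                       time = "time") {
  stopifnot(all(c(id, time, outcomes) %in% names(panel)))
  panel <- panel[order(panel[[id]], panel[[time]]), ]
  ids <- unique(panel[[id]])
  sub <- match(panel[[id]], ids)
  key <- vapply(split(panel[[time]], sub),
                function(t) paste(signif(t, 10), collapse = "|"), "")
  pat_of_subject <- key[as.character(seq_along(ids))]
  pats <- unique(pat_of_subject)
  patterns <- lapply(pats, function(pk) {
    sidx <- which(pat_of_subject == pk)
    rows <- which(sub %in% sidx)
    t <- panel[[time]][rows[sub[rows] == sidx[1]]]
    n_p <- length(t)
    Y <- lapply(outcomes, function(o) {
      matrix(panel[[o]][rows], nrow = length(sidx), ncol = n_p, byrow = TRUE)
    })
    names(Y) <- outcomes
    list(X = cbind(1, t), t = t, sub_idx = sidx, Y = Y, m = length(sidx),
         n_p = n_p)
  })
  structure(list(ids = ids, N = length(ids), K = length(outcomes),
                 outcomes = outcomes, patterns = patterns,
                 n_obs = sum(vapply(patterns, function(p) p$m * p$n_p, 0))),
            class = "lclmm_data")
}

.check_params <- function(params, K, G) {
  stopifnot(length(params$pi) == G, abs(sum(params$pi) - 1) < 1e-8,
            all(dim(params$beta) == c(2, K, G)),
            all(dim(params$D) == c(2, 2, K)),
            length(params$sigma2) == K)
  if (any(params$sigma2 <= 0)) stop("residual variances must be positive")
  for (k in seq_len(K)) {
    ev <- eigen(params$D[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("random-effect covariance D must be positive definite")
  }
  invisible(TRUE)
}

# per-subject log component densities: N x G matrix of
# log pi_g + sum_k log phi(y_ik; X beta_kg, X D_k X' + sigma2_k I)
.log_weights <- function(data, params) {
  G <- length(params$pi)
  lw <- matrix(rep(log(params$pi), each = data$N), data$N, G)
  for (p in data$patterns) {
    X <- p$X
    for (k in seq_len(data$K)) {
      V <- X %*% params$D[, , k] %*% t(X) +
        diag(params$sigma2[k], p$n_p)
      ch <- chol(V)
      logdet <- 2 * sum(log(diag(ch)))
      Vinv <- chol2inv(ch)
      Yk <- p$Y[[k]]
      for (g in seq_len(G)) {
        mu <- as.vector(X %*% params$beta[, k, g])
        R <- sweep(Yk, 2, mu)
        quad <- rowSums((R %*% Vinv) * R)
        lw[p$sub_idx, g] <- lw[p$sub_idx, g] -
          0.5 * (p$n_p * log(2 * pi) + logdet + quad)
      }
    }
  }
  lw
}

.loglik_from_lw <- function(lw) {
  mx <- apply(lw, 1, max)
  sum(mx + log(rowSums(exp(lw - mx))))
}

#' Observed-data log-likelihood of a latent class linear mixed model
#'
#' @param data An [lclmm_data()] object.
#' @param params List with `pi` (length G), `beta` (2 x K x G array of
#'   intercepts/slopes), `D` (2 x 2 x K random-effect covariances), `sigma2`
#'   (length K residual variances).
#' @return Scalar log-likelihood.
#' @export
lclmm_loglik <- function(data, params) {
  stopifnot(inherits(data, "lclmm_data"))
  .check_params(params, data$K, length(params$pi))
  .loglik_from_lw(.log_weights(data, params))
}

#' Relative classification entropy
#'
#' `1 - sum_i sum_g (-p_ig log p_ig) / (N log G)`: 1 for degenerate 0/1
#' posteriors, 0 for uniform posteriors; defined as 1 when G = 1.
#'
#' @param posterior N x G matrix of posterior class probabilities.
#' @return Scalar in [0, 1].
#' @export
lclmm_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G == 1L) return(1)
  pl <- posterior * log(posterior)
  pl[posterior == 0] <- 0
  1 - sum(-pl) / (nrow(posterior) * log(G))
}

#' Modal class assignment and per-class mean posteriors
#'
#' Subjects are assigned to the class with the highest posterior probability
#' (ties to the lowest class index). For each class the mean posterior among
#' its members is reported, together with the minimum of those means (the
#' "lowest mean posterior probability"); empty classes yield `NA` and are
#' flagged.
#'
#' @param posterior N x G posterior matrix.
#' @return List: `assignments`, `class_mean_posterior`,
#'   `lowest_mean_posterior`, `empty_classes`.
#' @export
lclmm_classify <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  assign <- max.col(posterior, ties.method = "first")
  cmp <- vapply(seq_len(G), function(g) {
    if (any(assign == g)) mean(posterior[assign == g, g]) else NA_real_
  }, 0)
  list(assignments = assign, class_mean_posterior = cmp,
       lowest_mean_posterior = if (all(is.na(cmp))) NA_real_
                               else min(cmp, na.rm = TRUE),
       empty_classes = which(is.na(cmp)))
}

# per-subject OLS intercept/slope per outcome, for the k-means start
.ols_summaries <- function(data) {
  S <- matrix(0, data$N, 2 * data$K)
  for (p in data$patterns) {
    t <- p$t
    for (k in seq_len(data$K)) {
      Yk <- p$Y[[k]]
      if (p$n_p >= 2 && stats::var(t) > 0) {
        sl <- as.vector((Yk %*% (t - mean(t))) / sum((t - mean(t))^2))
        ic <- rowMeans(Yk) - sl * mean(t)
      } else {
        ic <- rowMeans(Yk)
        sl <- rep(0, p$m)
      }
      S[p$sub_idx, 2 * k - 1] <- ic
      S[p$sub_idx, 2 * k] <- sl
    }
  }
  S
}

.init_from_labels <- function(data, labels, G) {
  K <- data$K
  beta <- array(0, c(2, K, G))
  ols <- .ols_summaries(data)
  for (g in seq_len(G)) {
    idx <- which(labels == g)
    if (!length(idx)) idx <- seq_len(data$N)  # guard empty class
    for (k in seq_len(K)) {
      beta[1, k, g] <- mean(ols[idx, 2 * k - 1])
      beta[2, k, g] <- mean(ols[idx, 2 * k])
    }
  }
  pi0 <- tabulate(labels, G) / length(labels)
  pi0 <- pmax(pi0, 1 / (4 * data$N))
  pi0 <- pi0 / sum(pi0)
  list(pi = pi0, beta = beta,
       D = array(rep(c(0.3, 0, 0, 0.1), K), c(2, 2, K)),
       sigma2 = rep(0.5, K))
}

.em_run <- function(data, params, G, max_iter, tol) {
  K <- data$K
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- .log_weights(data, params)
    mx <- apply(lw, 1, max)
    w <- exp(lw - mx)
    ll <- sum(mx + log(rowSums(w)))
    P <- w / rowSums(w)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    pi_new <- pmax(colMeans(P), 1e-12)
    pi_new <- pi_new / sum(pi_new)

    # conditional random-effect moments per pattern/outcome/class
    cache <- vector("list", length(data$patterns))
    A <- array(0, c(2, 2, K, G))      # sum p_ig X'X
    bvec <- array(0, c(2, K, G))      # sum p_ig X'(y - X m)
    for (ip in seq_along(data$patterns)) {
      p <- data$patterns[[ip]]
      X <- p$X
      XtX <- crossprod(X)
      Pg <- P[p$sub_idx, , drop = FALSE]
      ck <- vector("list", K)
      for (k in seq_len(K)) {
        Dk <- params$D[, , k]
        Dinv <- tryCatch(solve(Dk), error = function(e) {
          solve(Dk + diag(1e-8, 2))
        })
        S <- solve(XtX / params$sigma2[k] + Dinv)
        Yk <- p$Y[[k]]
        Mg <- vector("list", G)
        for (g in seq_len(G)) {
          mu <- as.vector(X %*% params$beta[, k, g])
          R <- sweep(Yk, 2, mu)
          M <- (R %*% X %*% S) / params$sigma2[k]   # m x 2 posterior means
          Mg[[g]] <- M
          Ytil <- Yk - M %*% t(X)
          pv <- Pg[, g]
          A[, , k, g] <- A[, , k, g] + sum(pv) * XtX
          bvec[, k, g] <- bvec[, k, g] +
            as.vector(t(X) %*% crossprod(Ytil, pv))
        }
        ck[[k]] <- list(S = S, Mg = Mg)
      }
      cache[[ip]] <- ck
    }
    beta_new <- params$beta
    for (k in seq_len(K)) for (g in seq_len(G)) {
      beta_new[, k, g] <- solve(A[, , k, g], bvec[, k, g])
    }

    D_new <- array(0, c(2, 2, K))
    rss <- numeric(K)
    for (ip in seq_along(data$patterns)) {
      p <- data$patterns[[ip]]
      X <- p$X
      Pg <- P[p$sub_idx, , drop = FALSE]
      for (k in seq_len(K)) {
        S <- cache[[ip]][[k]]$S
        trXSX <- sum(X * (X %*% S))
        Yk <- p$Y[[k]]
        for (g in seq_len(G)) {
          M <- cache[[ip]][[k]]$Mg[[g]]
          pv <- Pg[, g]
          D_new[, , k] <- D_new[, , k] + crossprod(M, pv * M) + sum(pv) * S
          mu <- as.vector(X %*% beta_new[, k, g])
          E <- sweep(Yk, 2, mu) - M %*% t(X)
          rss[k] <- rss[k] + sum(pv * rowSums(E^2)) + sum(pv) * trXSX
        }
      }
    }
    D_new <- D_new / data$N
    sig_new <- pmax(rss / (data$n_obs), 1e-10)
    for (k in seq_len(K)) {
      if (min(eigen(D_new[, , k], symmetric = TRUE,
                    only.values = TRUE)$values) < 1e-10) {
        D_new[, , k] <- D_new[, , k] + diag(1e-8, 2)
      }
    }
    params <- list(pi = pi_new, beta = beta_new, D = D_new,
                   sigma2 = sig_new)
  }
  lw <- .log_weights(data, params)
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  list(params = params, loglik = sum(mx + log(rowSums(w))),
       posterior = w / rowSums(w), converged = converged,
       n_iter = length(ll_trace), ll_trace = ll_trace)
}

#' Fit a latent class linear mixed model by multistart EM
#'
#' EM alternates posterior class probabilities (E-step) with closed-form
#' conditional-maximization updates of the mixing proportions,
#' class-specific fixed effects, and common random-effect and residual
#' variances (random effects treated as missing data), which makes the
#' observed-data log-likelihood monotone non-decreasing. The best
#' log-likelihood over `spec$n_starts` initializations wins (ties: lowest
#' start index) and classes are reported in canonical order of descending
#' mixing proportion to fix label switching. The caller's RNG state is
#' restored on exit.
#'
#' @param data An [lclmm_data()] object (outcomes assumed z-scored).
#' @param spec An [lclmm_spec()].
#' @return Object of class `lclmm_fit`: parameters, log-likelihood,
#'   `n_params`, AIC, BIC (N = subjects), posterior matrix, assignments,
#'   entropy, per-class mean posteriors, convergence info.
#' @export
lclmm_fit <- function(data, spec) {
  stopifnot(inherits(data, "lclmm_data"), inherits(spec, "lclmm_spec"),
            identical(spec$outcomes, data$outcomes))
  G <- spec$n_classes
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))

  starts <- vector("list", spec$n_starts)
  for (s in seq_len(spec$n_starts)) {
    set.seed(spec$seed + 7919L * (s - 1L))
    labels <- if (G == 1L) {
      rep(1L, data$N)
    } else if (s == 1L) {
      ols <- scale(.ols_summaries(data))
      ols[!is.finite(ols)] <- 0
      stats::kmeans(ols, centers = G, nstart = 5, iter.max = 50)$cluster
    } else {
      sample.int(G, data$N, replace = TRUE)
    }
    init <- .init_from_labels(data, labels, G)
    starts[[s]] <- .em_run(data, init, G, spec$max_iter, spec$tol)
  }
  lls <- vapply(starts, `[[`, 0, "loglik")
  best <- which.max(lls)            # which.max takes the first on ties
  fit <- starts[[best]]

  # canonical label order: descending pi, ties by first outcome intercept
  ord <- order(-fit$params$pi, fit$params$beta[1, 1, ],
               method = "radix")
  params <- fit$params
  params$pi <- params$pi[ord]
  params$beta <- params$beta[, , ord, drop = FALSE]
  posterior <- fit$posterior[, ord, drop = FALSE]

  cl <- lclmm_classify(posterior)
  K <- data$K
  n_params <- (G - 1) + 2 * K * G + 4 * K
  structure(list(
    spec = spec, N = data$N, n_obs = data$n_obs, outcomes = data$outcomes,
    pi = params$pi, beta = params$beta, D = params$D,
    sigma2 = params$sigma2,
    loglik = fit$loglik, n_params = n_params,
    AIC = -2 * fit$loglik + 2 * n_params,
    BIC = -2 * fit$loglik + n_params * log(data$N),
    posterior = posterior, assignments = cl$assignments,
    class_sizes = tabulate(cl$assignments, G),
    entropy = lclmm_entropy(posterior),
    class_mean_posterior = cl$class_mean_posterior,
    lowest_mean_posterior = cl$lowest_mean_posterior,
    empty_classes = cl$empty_classes,
    degenerate_classes = which(params$pi < 1 / (2 * data$N)),
    converged = fit$converged, n_iter = fit$n_iter,
    ll_trace = fit$ll_trace, best_start = best,
    start_logliks = lls), class = "lclmm_fit")
}

#' @export
print.lclmm_fit <- function(x, ...) {
  cat("Latent class linear mixed model:", length(x$pi), "class(es),",
      length(x$outcomes), "outcome(s),", x$N, "subjects\n")
  cat(sprintf("logLik %.3f | AIC %.1f | BIC %.1f | entropy %.3f\n",
              x$loglik, x$AIC, x$BIC, x$entropy))
  cat("pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("lowest mean posterior:",
      sprintf("%.3f", x$lowest_mean_posterior), "\n")
  invisible(x)
}
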