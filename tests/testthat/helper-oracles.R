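# Independent brute-force oracles and small simulators used across tests.
# These are intentionally written by a different route than the package
# implementations they check.

# Non-wear oracle: regex over the zero/non-zero string. A merged run is a
# maximal match of 0+ blocks joined by gaps of at most `allowance` non-zero
# minutes; it qualifies when it contains at least `window` zero minutes.
oracle_nonwear <- function(counts, window = 90, allowance = 2) {
  s <- paste(ifelse(counts == 0, "0", "1"), collapse = "")
  pat <- sprintf("0+(1{1,%d}0+)*", allowance)
  m <- gregexpr(pat, s)[[1]]
  wear <- rep(TRUE, length(counts))
  if (m[1] == -1) return(wear)
  lens <- attr(m, "match.length")
  for (i in seq_along(m)) {
    seg <- substring(s, m[i], m[i] + lens[i] - 1)
    nzeros <- nchar(gsub("1", "", seg))
    if (nzeros >= window) wear[m[i]:(m[i] + lens[i] - 1)] <- FALSE
  }
  wear
}

# Bout oracle: explicit forward scan.
oracle_bouts <- function(classes, target, min_length) {
  out <- list()
  i <- 1L
  n <- length(classes)
  while (i <= n) {
    if (classes[i] == target) {
      j <- i
      while (j < n && classes[j + 1] == target) j <- j + 1L
      if (j - i + 1L >= min_length) {
        out[[length(out) + 1L]] <- c(start = i - 1L, length = j - i + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# Per-epoch intensity comparator (no vectorized tricks).
oracle_intensity <- function(counts, wear) {
  vapply(seq_along(counts), function(i) {
    if (!wear[i]) return("nonwear")
    if (counts[i] < 100) "SB" else if (counts[i] <= 1951) "LIPA" else "MVPA"
  }, "")
}

# Random epoch day with realistic mixture of zeros and all intensity bands.
random_day <- function(n = 1440) {
  counts <- sample(c(0L, 0L, 0L, sample(1:99, 3), sample(100:1951, 2),
                     sample(1952:6000, 1)), n, replace = TRUE)
  # splice in a few long zero stretches so the non-wear path is exercised
  for (k in seq_len(sample(0:3, 1))) {
    len <- sample(c(30, 85, 90, 95, 180), 1)
    st <- sample(seq_len(max(1, n - len)), 1)
    counts[st:(st + len - 1)] <- 0L
  }
  counts
}

# Direct simulation from the latent class linear mixed model (z scale),
# independent of the epoch-level generator.
sim_lclmm_panel <- function(N, pi, beta, D, sigma2, times, seed = 1) {
  # beta: 2 x K x G; D: 2 x 2 x K; sigma2: length K
  set.seed(seed)
  K <- dim(beta)[2]
  G <- dim(beta)[3]
  cls <- sample.int(G, N, replace = TRUE, prob = pi)
  rows <- list()
  for (i in seq_len(N)) {
    X <- cbind(1, times)
    df <- data.frame(participant_id = sprintf("S%03d", i), time = times)
    for (k in seq_len(K)) {
      b <- MASS_mvrnorm(1, c(0, 0), D[, , k])
      df[[paste0("y", k)]] <- as.vector(X %*% (beta[, k, cls[i]] + b)) +
        rnorm(length(times), 0, sqrt(sigma2[k]))
    }
    rows[[i]] <- df
  }
  list(panel = do.call(rbind, rows), truth = cls)
}

# tiny local multivariate normal sampler (avoids a MASS dependency)
MASS_mvrnorm <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  mu + as.vector(matrix(rnorm(n * length(mu)), n) %*% L)
}

# align 2-class assignments with truth, returning best agreement
best_agreement <- function(assign, truth) {
  max(mean(assign == truth), mean(assign == 3L - truth))
}
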