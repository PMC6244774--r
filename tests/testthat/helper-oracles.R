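# Independent oracles used across test files.

# Brute-force Mann-Whitney: U statistic for every labeling of the pooled
# sample, giving the exact null distribution and two-sided p.
brute_u_pvalue <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) {
    xx <- pooled[ii]; yy <- pooled[-ii]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  u_obs <- min(sum(outer(x, y, ">")), sum(outer(y, x, ">")))
  list(u = u_obs,
       p = min(1, 2 * mean(us <= u_obs)),
       null_counts = table(us))
}

# Explicit Breslow log partial likelihood for a single covariate (used with
# a golden-section/optimize maximizer as the Cox oracle).
brute_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Hand product-limit computation.
brute_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(times = ut, survival = surv)
}

# Set-based 3D dilation oracle: union of 3x3x3 neighborhoods of every
# foreground voxel.
brute_dilate <- function(m) {
  dims <- dim(m)
  out <- array(FALSE, dims)
  fg <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    xs <- max(1, fg[r, 1] - 1):min(dims[1], fg[r, 1] + 1)
    ys <- max(1, fg[r, 2] - 1):min(dims[2], fg[r, 2] + 1)
    zs <- max(1, fg[r, 3] - 1):min(dims[3], fg[r, 3] + 1)
    out[xs, ys, zs] <- TRUE
  }
  out
}

# Small survival dataset with tied event times for tie-method tests.
toy_surv <- function(seed = 1, n = 30, tie = TRUE) {
  set.seed(seed)
  x <- rnorm(n)
  t <- rexp(n, exp(0.5 * x))
  if (tie) t <- round(t * 4) / 4 + 0.25
  ev <- rbinom(n, 1, 0.8)
  list(time = t, event = ev, x = x)
}
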