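# Independent oracles and small simulation helpers shared across tests.
# Each oracle takes a deliberately different route from the implementation
# it checks (enumeration, a different optimizer, a textbook decomposition).

# Brute-force argmin over a pair pool: returns the minimal achievable
# distance and the full tied index set.
oracle_closest <- function(ratio, pool) {
  d <- abs(pool$delta_m / (pool$delta_s + pool$delta_m) - ratio)
  m <- min(d)
  list(dist = m, idx = which(d <= m + 1e-12))
}

# Simulate one subject's choices at known parameters on a fresh trial set.
sim_subject <- function(kappa, gamma, n_per_cell = 60, seed = 1) {
  ts <- build_trialset(n_per_cell, seed = seed)
  set.seed(seed + 7L)
  simulate_choices(kappa, gamma, ts)
}

# Dense grid search over (kappa, gamma) for a single-cell dataset.
oracle_grid_nll <- function(data, kappas = seq(0, 1, length.out = 201),
                            gammas = seq(0.01, 10, length.out = 201)) {
  y <- data$choice
  best <- Inf
  for (g in gammas) {
    for (k in kappas) {
      p <- plogis(g * (k * data$delta_s - (1 - k) * data$delta_m))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      nll <- -sum(y * log(p) + (1 - y) * log(1 - p))
      if (nll < best) best <- nll
    }
  }
  best
}

# Ridge-penalized logistic deviance minimized with optim (BFGS with its own
# analytic gradient) -- a different algorithm from the package's Newton
# iterations.
oracle_penalized_logit <- function(data, ridge = 1e-4) {
  X <- cbind(1, data$delta_m, data$delta_s)
  y <- data$choice
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      0.5 * ridge * sum(b[2:3]^2)
  }
  grad <- function(b) {
    p <- plogis(drop(X %*% b))
    -drop(crossprod(X, y - p)) + ridge * c(0, b[2], b[3])
  }
  o <- optim(c(0, 0, 0), obj, grad, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  o$par
}

# Long-format 2x2 within-subject fixture used by the ANOVA oracle tests.
# Columns of Y are the cells (a1b1, a1b2, a2b1, a2b2).
anova_fixture_long <- function(Y) {
  n <- nrow(Y)
  df <- expand.grid(subject_id = seq_len(n), A = c("a1", "a2"),
                    B = c("b1", "b2"), stringsAsFactors = FALSE)
  j <- match(paste0(df$A, df$B), c("a1b1", "a1b2", "a2b1", "a2b2"))
  df$value <- Y[cbind(df$subject_id, j)]
  df
}

# Exact permutation distribution of the tie-corrected Friedman statistic,
# via independent enumeration (differs from the package's counter loop).
oracle_friedman_exact <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  R <- t(apply(x, 1, rank))
  ties <- sum(apply(x, 1, function(row) { t <- table(row); sum(t^3 - t) }))
  Ccorr <- 1 - ties / (n * k * (k^2 - 1))
  stat <- function(R) {
    s <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
    if (Ccorr > 0) s / Ccorr else 0
  }
  obs <- stat(R)
  perms <- gtools_permutations(k)
  grid <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
  stats <- apply(grid, 1, function(sel) {
    Rp <- do.call(rbind, lapply(seq_len(n), function(i) R[i, perms[sel[i], ]]))
    stat(Rp)
  })
  list(obs = obs, p = mean(stats >= obs - 1e-12))
}

# All permutations of 1..k (recursive, independent of the package internal).
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- gtools_permutations(k - 1)
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[c(sub)], nrow(sub), k - 1)))
  }
  unname(out)
}

# Build a mediation table directly from generative equations (no choices).
sim_mediation_data <- function(n, a_gain = -0.75, a_loss = 0, b = 0.04,
                               c_prime = 0, sd_m = 1.5, sd_y = 0.1,
                               seed = 1) {
  set.seed(seed)
  IH <- rnorm(n, 3, 1)
  IB <- rnorm(n, 4, 1)
  EC <- rnorm(n, 3.8, 0.6)
  rows <- lapply(c(1, 0), function(dc) {
    a <- if (dc == 1) a_gain else a_loss
    M <- a * IH + rnorm(n, 0, sd_m)
    Y <- b * M + c_prime * IH + rnorm(n, 0, sd_y)
    data.frame(subject_id = seq_len(n), context = dc, IH = IH, IB = IB,
               EC = EC, M = M, Y = Y)
  })
  do.call(rbind, rows)
}
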