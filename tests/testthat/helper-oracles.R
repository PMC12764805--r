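# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: the batch solver treats the whole state sequence
# as one joint Gaussian, the Higuchi oracle evaluates the coarse-grained
# length definition term by term, and the GLM oracle is stats::glm.

# Joint-Gaussian batch solve of a time-invariant linear-Gaussian state-space
# model: states x_0..x_T stacked, prior on x_0, transition and observation
# constraints assembled into one precision matrix. Returns smoothed
# (full-record posterior) means/covariances for t = 1..T.
batch_lgss <- function(F, G, H, Q, R, x0, V0, y, flag) {
  p <- nrow(F)
  T_ <- nrow(y)
  n <- p * (T_ + 1)
  blk <- function(t) ((t * p) + 1):((t + 1) * p)  # t = 0..T
  Lam <- matrix(0, n, n)
  eta <- numeric(n)
  V0i <- solve(V0)
  Lam[blk(0), blk(0)] <- V0i
  eta[blk(0)] <- V0i %*% x0
  Wi <- solve(G %*% Q %*% t(G))
  Ri <- solve(R)
  for (t in seq_len(T_)) {
    i0 <- blk(t - 1); i1 <- blk(t)
    Lam[i0, i0] <- Lam[i0, i0] + t(F) %*% Wi %*% F
    Lam[i0, i1] <- Lam[i0, i1] - t(F) %*% Wi
    Lam[i1, i0] <- Lam[i1, i0] - Wi %*% F
    Lam[i1, i1] <- Lam[i1, i1] + Wi
    if (flag[t]) {
      Lam[i1, i1] <- Lam[i1, i1] + t(H) %*% Ri %*% H
      eta[i1] <- eta[i1] + t(H) %*% Ri %*% y[t, ]
    }
  }
  Sig <- solve(Lam)
  mu <- Sig %*% eta
  list(mean = t(vapply(seq_len(T_), function(t) mu[blk(t)], numeric(p))),
       cov = lapply(seq_len(T_), function(t) Sig[blk(t), blk(t)]))
}

# Term-by-term evaluation of the coarse-grained length definition.
brute_Lmk <- function(xy, k, m) {
  xy <- as.matrix(xy)
  N <- nrow(xy)
  n_inc <- floor((N - m) / k)
  s <- 0
  for (i in seq_len(n_inc)) {
    d <- xy[m + i * k, ] - xy[m + (i - 1) * k, ]
    s <- s + sqrt(sum(d^2))
  }
  (s * (N - 1) / (n_inc * k)) / k
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments.
brute_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  combs <- utils::combn(length(pooled), n_a)
  U_of <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  U_obs <- U_of(seq_len(n_a))
  Us <- apply(combs, 2, U_of)
  mu <- n_a * (length(pooled) - n_a) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Interaction-term F from a pooled full-rank regression.
interaction_f <- function(a, b) {
  d <- rbind(cbind(a, g = 0), cbind(b, g = 1))
  fit <- lm(y ~ x * g, data = d)
  an <- anova(fit)
  c(F = an["x:g", "F value"], p = an["x:g", "Pr(>F)"])
}

# Simulated observation series: planar random walk plus observation noise.
sim_rw_obs <- function(T_, sigma, tau, start = c(40, 40), seed = 1) {
  benthtrack_seed <- seed
  set.seed(benthtrack_seed)
  x <- start[1] + cumsum(rnorm(T_, 0, sigma))
  y <- start[2] + cumsum(rnorm(T_, 0, sigma))
  cbind(x + rnorm(T_, 0, tau), y + rnorm(T_, 0, tau))
}

digest_file <- function(f) unname(tools::md5sum(f))
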