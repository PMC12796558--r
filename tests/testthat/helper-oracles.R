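# Independent brute-force oracles, deliberately coded with plain double
# loops / explicit matrix algebra so they share no code path with the
# package implementations they check.

# O(N^2) Getis-Ord Gi* with binary distance weights, self included
oracle_gi_star <- function(values, coords, radius, include_self = TRUE) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wsum <- 0; wx <- 0; w2 <- 0
    for (j in seq_len(n)) {
      if (!include_self && i == j) next
      d <- sqrt((coords[i, 1] - coords[j, 1])^2 + (coords[i, 2] - coords[j, 2])^2)
      if (d <= radius) {
        wsum <- wsum + 1
        wx <- wx + values[j]
        w2 <- w2 + 1
      }
    }
    z[i] <- (wx - xbar * wsum) / (S * sqrt((n * w2 - wsum^2) / (n - 1)))
  }
  z
}

# explicit hat-matrix RDA oracle: projection + full eigendecomposition
oracle_rda <- function(Y, X, standardize_y = TRUE) {
  Yc <- scale(Y, center = TRUE, scale = standardize_y)
  Yc[is.nan(Yc)] <- 0
  Xc <- scale(X, center = TRUE, scale = FALSE)
  H <- Xc %*% solve(t(Xc) %*% Xc) %*% t(Xc)
  Yhat <- H %*% Yc
  eg <- eigen(t(Yhat) %*% Yhat / (nrow(Y) - 1), symmetric = TRUE)
  total <- sum(diag(t(Yc) %*% Yc / (nrow(Y) - 1)))
  list(values = eg$values, vectors = eg$vectors,
       prop = sum(pmax(eg$values, 0)[seq_len(qr(Xc)$rank)]) / total)
}

# direct Tweedie ML oracle over mgcv::ldTweedie (independent density code)
oracle_tweedie_ml <- function(y) {
  nll <- function(par) {
    p <- 1.01 + 0.98 * stats::plogis(par[2])
    -sum(mgcv::ldTweedie(y, mu = exp(par[1]), p = p, phi = exp(par[3]))[, 1])
  }
  o <- stats::nlminb(c(log(mean(y) + 1e-3), 0, 0), nll)
  list(mu = exp(o$par[1]), p = 1.01 + 0.98 * stats::plogis(o$par[2]),
       phi = exp(o$par[3]))
}

# empirical semivariogram of a set of replicate fields on a grid
oracle_variogram <- function(reps, coords, breaks) {
  D <- as.matrix(dist(coords))
  bin <- cut(D[upper.tri(D)], breaks)
  # mean over replicates of squared differences, per distance bin
  nrep <- ncol(reps)
  acc <- 0
  for (r in seq_len(nrep)) {
    f <- reps[, r]
    dd <- outer(f, f, "-")^2
    acc <- acc + dd[upper.tri(dd)]
  }
  gamma <- tapply(acc / (2 * nrep), bin, mean)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  data.frame(dist = mids, gamma = as.numeric(gamma))
}
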