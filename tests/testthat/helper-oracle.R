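# Deterministic quadrature oracle for one breeder-equation step of the
# univariate linear reaction norm y = a + b(u - c) + e under Gaussian
# stabilizing selection W = w_max exp(-(y - theta)^2 / (2 omega^2)).
#
# Independent of the package's Monte-Carlo path: the (b, c) marginal is
# integrated by Gauss-Hermite quadrature, while the Gaussian directions
# (a given (b, c), and e) are integrated in closed form via the
# product-of-Gaussians identities
#   E[exp(-(s - tau)^2 / 2w^2)]   = sqrt(w^2/(w^2+v)) exp(-(mu-tau)^2/(2(w^2+v)))
#   E[s exp(-(s - tau)^2 / 2w^2)] = E[...] * (w^2 mu + v tau)/(w^2 + v)
# for s ~ N(mu, v).
#
# mean, P, G are over the trait order (a, b, c). Handles a pinned reference
# trait (P[3,3] = 0) by dropping the c integration (the Lande reduction).
oracle_step <- function(mean, P, G, sigma_e_sq, u, theta, omega_sq,
                        w_max = 1, n_nodes = 80) {
  gh <- pracma::gaussHermite(n_nodes)
  w2 <- omega_sq

  vcc <- P[3, 3]
  if (vcc > 0) {
    P22 <- P[2:3, 2:3]
    L <- t(chol(P22))
    nodes <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
    xi <- rbind(gh$x[nodes$i], gh$x[nodes$j])
    wts <- gh$w[nodes$i] * gh$w[nodes$j] / pi
    X2 <- sqrt(2) * (L %*% xi) + mean[2:3]   # 2 x K matrix of (b, c)
    Sig12 <- P[1, 2:3, drop = FALSE]
    K22inv_dev <- solve(P22, X2 - mean[2:3])
    mu_a <- mean[1] + as.numeric(Sig12 %*% K22inv_dev)
    va <- P[1, 1] - as.numeric(Sig12 %*% solve(P22, t(Sig12)))
  } else {
    # c pinned at its mean: integrate over b only
    vbb <- P[2, 2]
    wts <- gh$w / sqrt(pi)
    X2 <- rbind(sqrt(2 * vbb) * gh$x + mean[2],
                rep(mean[3], n_nodes))
    mu_a <- mean[1] + P[1, 2] / vbb * (X2[1, ] - mean[2])
    va <- P[1, 1] - P[1, 2]^2 / vbb
  }

  b <- X2[1, ]; cc <- X2[2, ]
  vs <- va + sigma_e_sq                     # var of s = a + e given (b, c)
  tau <- theta - b * (u - cc)               # W = f(s - tau)
  phi0 <- w_max * sqrt(w2 / (w2 + vs)) * exp(-(mu_a - tau)^2 / (2 * (w2 + vs)))
  mu_post <- (w2 * mu_a + vs * tau) / (w2 + vs)
  EsW <- phi0 * mu_post
  EaW <- mu_a * phi0 + if (vs > 0) (va / vs) * (EsW - mu_a * phi0) else 0

  w_bar <- sum(wts * phi0)
  s_cov <- c(sum(wts * EaW), sum(wts * b * phi0), sum(wts * cc * phi0)) -
    mean * w_bar

  act <- which(diag(P) > 0)
  beta <- numeric(3)
  beta[act] <- solve(P[act, act, drop = FALSE], s_cov[act]) / w_bar
  list(w_bar = w_bar, s = s_cov, beta = beta,
       delta = as.numeric(G %*% beta))
}
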