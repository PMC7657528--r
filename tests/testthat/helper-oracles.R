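# Independent oracles used across the suite: naive double-loop evaluations
# and Monte-Carlo references, kept free of the package's own fast paths.

# brute-force kernel U-statistic and plug-in variance
ku_brute <- function(k, e) {
  n <- length(e)
  t_n <- 0; v <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    t_n <- t_n + k[i, j] * e[i] * e[j]
    v <- v + k[i, j]^2 * e[i]^2 * e[j]^2
  }
  list(t_n = t_n / (n * (n - 1)), v_hat = 2 * v / (n^2 * (n - 1)^2))
}

# naive elementwise kernel evaluation
kernel_brute <- function(x, spec) {
  n <- nrow(x)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- x[i, ]; xj <- x[j, ]
    k[i, j] <- switch(spec$family,
      linear = sum(xi * xj) + spec$c,
      gaussian = exp(-sum((xi - xj)^2) / (2 * spec$sigma^2)),
      polynomial = (spec$alpha * sum(xi * xj) + spec$c)^spec$d)
  }
  k
}

# Monte-Carlo reference for P(max_m Z_m > q), Z ~ N(0, omega)
mvn_max_mc <- function(q, omega, ndraw = 200000, seed = 1) {
  set.seed(seed)
  l <- chol(omega + diag(1e-10, nrow(omega)))
  z <- matrix(rnorm(ndraw * nrow(omega)), ndraw) %*% l
  mean(apply(z, 1, max) > q)
}

# permutation p-value of the single-kernel standardized statistic, with the
# observed statistic included in the reference set
perm_pvalue <- function(k0, e, n_perm = 2000, seed = 1) {
  n <- length(e)
  q_of <- function(ee) {
    t_n <- as.numeric(crossprod(ee, k0 %*% ee))
    v <- 2 * as.numeric(crossprod(ee^2, (k0 * k0) %*% ee^2))
    t_n / sqrt(v)        # shared constants cancel in the comparison
  }
  q_obs <- q_of(e)
  set.seed(seed)
  em <- vapply(seq_len(n_perm), function(i) e[sample.int(n)],
               numeric(n))
  tq <- colSums(em * (k0 %*% em))
  vq <- 2 * colSums(em^2 * ((k0 * k0) %*% em^2))
  q_perm <- tq / sqrt(vq)
  (1 + sum(q_perm >= q_obs)) / (n_perm + 1)
}

# a few fixed well-conditioned 3x3 correlation matrices
repair_omega_for_test <- function(i) {
  oms <- list(
    matrix(c(1, .9, .8, .9, 1, .85, .8, .85, 1), 3),
    matrix(c(1, .3, .1, .3, 1, .5, .1, .5, 1), 3),
    matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3))
  oms[[i]]
}

# fast null dataset: centered iid normal residual vector
null_resid <- function(n) {
  e <- rnorm(n)
  e - mean(e)
}

# centered, zero-diagonal kernel matrices plus the cached products the fast
# simulation path expects
sim_kernels_with_products <- function(x, specs = kernel_bundle()) {
  k0 <- fcmsku:::sim_kernel_matrices(x, specs)
  m <- length(k0)
  prods <- list()
  if (m > 1) for (i in 1:(m - 1)) for (j in (i + 1):m)
    prods[[paste(i, j)]] <- k0[[i]] * k0[[j]]
  list(k0 = k0, prods = prods, norms = lapply(k0, function(a) a * a))
}

msku_pvalue_fast <- function(kp, e) {
  fcmsku:::sim_msku_pvalue(kp$k0, kp$prods, kp$norms, e)
}
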