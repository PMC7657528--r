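# Dependence-adjusted Fisher combination of the k marginal pathway p-values
# (one per phenotype) into a global p-value.
#
# Under independence T = sum_i -2 log p_i is chi-squared on 2k df.  Under
# dependence its null is moment-matched to a gamma distribution (Brown's
# method): mean mu = 2k, variance sigma^2 = 4k + 2 sum_{i<j} c(r_ij), with
# the pairwise covariance c(r) of (-2 log p_i, -2 log p_j) approximated by
# the Kost-McDermott cubic polynomial in the phenotype correlation r.

#' Correlation of covariate-adjusted phenotypes
#'
#' Pearson correlation between the OLS residuals of each phenotype column on
#' the covariates.  This is the dependence input to
#' \code{\link{brown_moments}}.
#'
#' @param phenotypes numeric n x k matrix.
#' @param covariates numeric covariate matrix or NULL.
#' @return k x k correlation matrix with unit diagonal.
#' @export
phenotype_correlation <- function(phenotypes, covariates = NULL) {
  y <- as.matrix(phenotypes)
  k <- ncol(y)
  if (nrow(y) <= k + NCOL(covariates) + 1)
    stop("too few samples to estimate the phenotype correlation")
  res <- apply(y, 2, function(col) {
    if (stats::var(col) == 0) stop("constant phenotype column")
    residualize(col, covariates)
  })
  r <- stats::cor(res)
  diag(r) <- 1
  structure((r + t(r)) / 2, method = "pearson-on-residuals")
}

# Kost-McDermott approximation to cov(-2 log p_i, -2 log p_j) at test
# correlation r, odd in r and clipped to the attainable range [-4, 4].
km_covariance <- function(r) {
  cv <- 3.263 * r + 0.710 * sign(r) * r^2 + 0.027 * r^3
  pmin(pmax(cv, -4), 4)
}

#' Moments of the Fisher statistic under dependent p-values
#'
#' Null mean and variance of \eqn{T = \sum_{i=1}^k -2 \log p_i}:
#' \eqn{\mu = 2k} and \eqn{\sigma^2 = 4k + 2 \sum_{i<j} \hat c(r_{ij})}
#' with \eqn{\hat c(r) = 3.263 r + 0.710\,\mathrm{sign}(r) r^2 + 0.027 r^3}
#' clipped to \eqn{[-4, 4]}.  With an identity correlation this reduces to
#' the independent Fisher case \eqn{\mu = 2k, \sigma^2 = 4k}.  The variance
#' is floored at \eqn{2k} so the matched gamma stays well defined under
#' pathological negative correlation.
#'
#' @param k number of phenotypes.
#' @param correlation k x k phenotype correlation matrix (identity if NULL).
#' @return list with \code{mu} and \code{sigma2}.
#' @export
brown_moments <- function(k, correlation = NULL) {
  if (k < 1) stop("k must be >= 1")
  mu <- 2 * k
  sigma2 <- 4 * k
  if (!is.null(correlation) && k > 1) {
    r <- as.matrix(correlation)
    if (!all(dim(r) == k)) stop("correlation must be k x k")
    if (any(abs(r) > 1 + 1e-8)) stop("correlation entries must be in [-1, 1]")
    off <- r[upper.tri(r)]
    sigma2 <- sigma2 + 2 * sum(km_covariance(off))
  }
  sigma2 <- max(sigma2, 2 * k)
  list(mu = mu, sigma2 = sigma2)
}

#' Combine marginal p-values across phenotypes (dependence-adjusted Fisher)
#'
#' Forms \eqn{T = \sum_i -2 \log p_i} and refers it to a gamma null with
#' shape \eqn{\mu^2/\sigma^2} and scale \eqn{\sigma^2/\mu} (equivalently a
#' scaled chi-squared), where \eqn{(\mu, \sigma^2)} come from
#' \code{\link{brown_moments}}.  With k = 1 the global p equals the marginal
#' p; with an identity correlation it equals the classical Fisher
#' \eqn{\chi^2_{2k}} p-value.
#'
#' @param pvalues k marginal p-values in (0, 1]; exact zeros are floored at
#'   the smallest positive double with a warning.
#' @param correlation k x k phenotype correlation matrix (identity if NULL),
#'   e.g. from \code{\link{phenotype_correlation}}.
#' @return list of class \code{fc_result}: \code{marginal_pvalues},
#'   \code{t_stat}, \code{mu}, \code{sigma2}, \code{shape}, \code{scale},
#'   \code{global_p}.
#' @examples
#' fc_combine(c(0.05, 0.05))                      # independent Fisher
#' r <- matrix(c(1, 0.7, 0.7, 1), 2)
#' fc_combine(c(0.05, 0.05), correlation = r)     # dependence-adjusted
#' @export
fc_combine <- function(pvalues, correlation = NULL) {
  p <- as.numeric(pvalues)
  k <- length(p)
  if (k < 1) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 floored at the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  t_stat <- sum(-2 * log(p))
  mom <- brown_moments(k, correlation)
  shape <- mom$mu^2 / mom$sigma2
  scale <- mom$sigma2 / mom$mu
  global_p <- stats::pgamma(t_stat, shape = shape, scale = scale,
                            lower.tail = FALSE)
  structure(list(marginal_pvalues = p, t_stat = t_stat, mu = mom$mu,
                 sigma2 = mom$sigma2, shape = shape, scale = scale,
                 global_p = global_p),
            class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  cat("Fisher combination of", length(x$marginal_pvalues),
      "marginal p-values\n")
  cat(sprintf("  T = %.4f; gamma null mean %.3f, variance %.3f\n",
              x$t_stat, x$mu, x$sigma2))
  cat(sprintf("  global p = %.4g\n", x$global_p))
  invisible(x)
}
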