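# The semi-supervised maximum kernel-based U-statistic (mSKU) test for one
# pathway x one quantitative phenotype.
#
# Per candidate kernel m the statistic is a degenerate second-order
# U-statistic of the centered kernel against products of phenotype
# residuals,
#   T_n = 1/(n(n-1)) sum_{i != j} Ktilde_ij e_i e_j,
# standardized by its plug-in variance to Q_m.  The test statistic is
# Q_max = max_m Q_m, referred to the upper tail of an equicoordinate
# multivariate normal with the estimated inter-kernel correlation.

.mvn_seed <- 20200911L

#' Per-SNP screening against an auxiliary label
#'
#' For each SNP, fits a single-predictor regression of the label on the
#' genotype (with intercept): logistic regression with a Wald test when the
#' label is binary, least squares with a t-test when it is quantitative.
#' SNPs with two-sided p-value below \code{alpha_m} are kept.  Screening is
#' meant to use an auxiliary label (e.g. disease status) distinct from the
#' phenotype being tested, so that the downstream test remains calibrated.
#'
#' @param genotypes \code{genotype_matrix} or 0/1/2 matrix restricted to the
#'   pathway.
#' @param label numeric vector of length n; treated as binary when it takes
#'   exactly the values 0/1.
#' @param alpha_m screening threshold in (0, 1].
#' @return list of class \code{screening_result}: \code{kept_snp_ids},
#'   \code{per_snp_pvalues} (named), \code{threshold}, \code{label_type},
#'   \code{fallback} (TRUE when no SNP passed and the full pathway is
#'   retained).
#' @export
screen_snps <- function(genotypes, label, alpha_m = 0.05) {
  x <- as_geno_values(genotypes)
  if (alpha_m <= 0 || alpha_m > 1) stop("alpha_m must be in (0, 1]")
  if (length(label) != nrow(x)) stop("label length must match sample count")
  snp_ids <- colnames(x)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(x)))
  binary <- all(label %in% c(0, 1)) && length(unique(label)) == 2
  pv <- vapply(seq_len(ncol(x)), function(j) {
    g <- as.numeric(x[, j])
    if (stats::var(g) == 0) return(1)          # monomorphic: never kept
    if (binary) {
      p <- tryCatch({
        fit <- suppressWarnings(
          stats::glm(label ~ g, family = stats::binomial()))
        if (!fit$converged) stop("no convergence")
        s <- summary(fit)$coefficients
        if (nrow(s) < 2 || !is.finite(s["g", 4])) stop("unstable fit")
        s["g", 4]
      }, error = function(e) NA_real_)
      if (is.na(p)) {           # separation etc.: score test at the null
        u <- sum(g * (label - mean(label)))
        v <- mean(label) * (1 - mean(label)) * sum((g - mean(g))^2)
        p <- if (v > 0) stats::pchisq(u^2 / v, 1, lower.tail = FALSE) else 1
      }
      p
    } else {
      n <- length(g)
      r <- stats::cor(g, label)
      if (!is.finite(r)) return(1)
      r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  }, numeric(1))
  names(pv) <- snp_ids
  kept <- snp_ids[pv < alpha_m]
  fallback <- length(kept) == 0
  if (fallback) kept <- snp_ids
  structure(list(kept_snp_ids = kept, per_snp_pvalues = pv,
                 threshold = alpha_m,
                 label_type = if (binary) "binary" else "quantitative",
                 fallback = fallback),
            class = "screening_result")
}

#' Residualize a phenotype on covariates
#'
#' Ordinary least-squares residuals of the phenotype on an intercept plus
#' the covariate columns.  The residuals are orthogonal to every design
#' column, which removes covariate effects before the kernel statistic.
#'
#' @param phenotype numeric vector of length n.
#' @param covariates numeric matrix with n rows, or NULL / zero columns for
#'   intercept-only centering.
#' @return numeric residual vector of length n.
#' @export
residualize <- function(phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(y - mean(y))
  z <- as.matrix(covariates)
  if (nrow(z) != n) stop("covariate rows must match phenotype length")
  design <- cbind(`(Intercept)` = 1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[-qrd$pivot[seq_len(qrd$rank)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(qrd, y))
}

#' Kernel U-statistic for one centered kernel
#'
#' Computes the degenerate second-order U-statistic
#' \deqn{T_n = \frac{1}{n(n-1)} \sum_{i \ne j} \tilde K_{ij} e_i e_j,}
#' its plug-in variance
#' \deqn{\hat V = \frac{2}{n^2 (n-1)^2} \sum_{i \ne j} \tilde K_{ij}^2
#'   e_i^2 e_j^2,}
#' and the standardized statistic \eqn{Q = T_n / \sqrt{\hat V}}, which is
#' asymptotically standard normal under no association.  Q is invariant to
#' positive rescaling of the kernel and of the residuals.
#'
#' @param k centered \code{kernel_matrix} (or symmetric matrix; it is
#'   centered first if an uncentered \code{kernel_matrix} is supplied).
#' @param residuals numeric residual vector (see \code{\link{residualize}}).
#' @return list of class \code{single_kernel_stat}: \code{t_n},
#'   \code{v_hat}, \code{q}, \code{spec}.
#' @export
ku_statistic <- function(k, residuals) {
  spec <- if (inherits(k, "kernel_matrix")) k$spec else NULL
  if (inherits(k, "kernel_matrix") && !isTRUE(k$centered)) k <- center_kernel(k)
  kv <- kernel_values(k)
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 4) stop("need n >= 4")
  if (nrow(kv) != n) stop("kernel dimension must match residual length")
  if (all(e == 0)) stop("residuals are identically zero")
  k0 <- kv; diag(k0) <- 0
  s1 <- as.numeric(crossprod(e, k0 %*% e))
  e2 <- e^2
  w <- as.numeric(crossprod(e2, (k0 * k0) %*% e2))
  t_n <- s1 / (n * (n - 1))
  v_hat <- 2 * w / (n^2 * (n - 1)^2)
  if (v_hat <= 0)
    stop("degenerate kernel statistic: zero plug-in variance")
  structure(list(t_n = t_n, v_hat = v_hat, q = t_n / sqrt(v_hat),
                 spec = spec),
            class = "single_kernel_stat")
}

#' Estimated correlation between kernel statistics
#'
#' Plug-in estimate of the null correlation between the standardized
#' statistics of each pair of candidate kernels,
#' \deqn{\hat\rho_{kl} = \frac{\sum_{i \ne j} \tilde K^{(k)}_{ij}
#'   \tilde K^{(l)}_{ij} e_i^2 e_j^2}{\sqrt{\sum_{i \ne j}
#'   (\tilde K^{(k)}_{ij})^2 e_i^2 e_j^2 \cdot \sum_{i \ne j}
#'   (\tilde K^{(l)}_{ij})^2 e_i^2 e_j^2}}.}
#' The result has unit diagonal and is projected to the nearest correlation
#' matrix when numerically indefinite.
#'
#' @param kernels list of centered \code{kernel_matrix} objects (uncentered
#'   ones are centered first).
#' @param residuals numeric residual vector.
#' @return M x M correlation matrix.
#' @export
kernel_correlation <- function(kernels, residuals) {
  e2 <- as.numeric(residuals)^2
  k0 <- lapply(kernels, function(k) {
    if (inherits(k, "kernel_matrix") && !isTRUE(k$centered))
      k <- center_kernel(k)
    kv <- kernel_values(k)
    diag(kv) <- 0
    kv
  })
  m <- length(k0)
  qf <- function(a, b) as.numeric(crossprod(e2, (a * b) %*% e2))
  norms <- vapply(k0, function(a) qf(a, a), numeric(1))
  if (any(norms <= 0)) stop("degenerate kernel: zero plug-in variance")
  omega <- diag(1, m)
  if (m > 1) {
    for (k in 1:(m - 1)) for (l in (k + 1):m) {
      omega[k, l] <- omega[l, k] <- qf(k0[[k]], k0[[l]]) /
        sqrt(norms[k] * norms[l])
    }
  }
  repair_correlation(omega)
}

# Clip eigenvalues at a small floor and rescale to unit diagonal.  The
# repair only fires when the smallest eigenvalue drops below `trigger`, so
# exactly singular but PSD matrices (e.g. duplicated kernels with rho = 1)
# pass through untouched when trigger <= 0.
repair_correlation <- function(omega, floor_frac = 1e-8, trigger = -1e-8) {
  omega <- (omega + t(omega)) / 2
  ev <- eigen(omega, symmetric = TRUE)
  if (min(ev$values) >= trigger) {
    diag(omega) <- 1
    return(omega)
  }
  vals <- pmax(ev$values, floor_frac * max(ev$values, 1))
  fixed <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(fixed))
  fixed <- fixed / outer(d, d)
  diag(fixed) <- 1
  (fixed + t(fixed)) / 2
}

#' Upper-tail p-value of the maximum standardized kernel statistic
#'
#' Under the null, \eqn{(Q_1, ..., Q_M)} converges to a mean-zero
#' multivariate normal with correlation \eqn{\Omega}; the p-value of the
#' observed maximum is the complement of the equicoordinate rectangle
#' probability \eqn{1 - P(Z \le q_{max} 1_M)}, computed with a fixed
#' integration seed so repeated calls agree to reported precision.
#'
#' @param q_max observed maximum standardized statistic.
#' @param omega M x M correlation matrix (repaired internally if needed).
#' @return p-value in [0, 1].
#' @export
max_statistic_pvalue <- function(q_max, omega) {
  omega <- as.matrix(omega)
  m <- nrow(omega)
  if (m == 1) return(stats::pnorm(q_max, lower.tail = FALSE))
  omega <- repair_correlation(omega)
  # deterministic quasi-Monte-Carlo integration: pin the RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(.mvn_seed)
  pr <- mvtnorm::pmvnorm(lower = rep(-Inf, m), upper = rep(q_max, m),
                         corr = omega,
                         algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                        maxpts = 100000))
  min(max(1 - as.numeric(pr), 0), 1)
}

# Core statistic path shared by msku_test and the simulation harness:
# takes centered kernel matrices (diagonal included) and a residual vector.
msku_core <- function(kc_list, residuals, specs = NULL) {
  stats_list <- vector("list", length(kc_list))
  keep <- logical(length(kc_list))
  for (m in seq_along(kc_list)) {
    st <- tryCatch(
      ku_statistic(structure(list(values = kernel_values(kc_list[[m]]),
                                  spec = if (!is.null(specs)) specs[[m]],
                                  centered = TRUE),
                             class = "kernel_matrix"),
                   residuals),
      error = function(e) NULL)
    if (!is.null(st)) { stats_list[[m]] <- st; keep[m] <- TRUE }
  }
  if (!any(keep)) stop("all candidate kernels are degenerate")
  if (!all(keep)) warning(sum(!keep), " degenerate kernel(s) dropped")
  stats_list <- stats_list[keep]
  kc_list <- kc_list[keep]
  q <- vapply(stats_list, `[[`, numeric(1), "q")
  omega <- kernel_correlation(kc_list, residuals)
  q_max <- max(q)
  list(per_kernel = stats_list, omega_hat = omega, q_max = q_max,
       p_value = max_statistic_pvalue(q_max, omega))
}

#' The mSKU test: one pathway, one quantitative phenotype
#'
#' Pipeline: restrict the genotype matrix to the pathway's SNPs, drop
#' monomorphic SNPs, optionally screen SNPs against an auxiliary label,
#' residualize the phenotype on the covariates, build each candidate kernel
#' (centered), compute the standardized kernel U-statistics
#' \eqn{Q_1, ..., Q_M}, their estimated correlation, and the upper-tail
#' p-value of \eqn{Q_{max}} under the multivariate-normal null.
#'
#' @param genotypes \code{genotype_matrix} or 0/1/2 matrix (all samples, any
#'   superset of the pathway's SNPs).
#' @param phenotype numeric vector of length n.
#' @param pathway_snp_ids character vector of SNP ids to test; NULL tests
#'   every column.
#' @param covariates numeric covariate matrix or NULL.
#' @param kernels list of \code{\link{kernel_spec}} objects, or a bundle
#'   string for \code{\link{kernel_bundle}}.
#' @param screening_label optional auxiliary label for
#'   \code{\link{screen_snps}}; when NULL no screening is performed.  The
#'   label must not be the phenotype under test.
#' @param alpha_m screening threshold.
#' @return list of class \code{msku_result}: \code{per_kernel},
#'   \code{omega_hat}, \code{q_max}, \code{p_value}, \code{n_used},
#'   \code{snps_in_pathway}, \code{snps_used}, \code{screening}
#'   (\code{screening_result} or NULL), \code{screen_fallback}.
#' @examples
#' g <- simulate_genotypes(n = 80, p = 30, seed = 7)
#' z <- simulate_covariates(80, seed = 8)
#' y <- simulate_phenotypes(z, h = 0, t = 1, rho = 0, seed = 9)[, 1]
#' msku_test(g, y, covariates = z)
#' @export
msku_test <- function(genotypes, phenotype, pathway_snp_ids = NULL,
                      covariates = NULL,
                      kernels = kernel_bundle(),
                      screening_label = NULL, alpha_m = 0.05) {
  if (is.character(kernels)) kernels <- kernel_bundle(kernels)
  x <- as_geno_values(genotypes)
  snp_ids <- colnames(x)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(x)))
  colnames(x) <- snp_ids
  if (!is.null(pathway_snp_ids)) {
    found <- intersect(pathway_snp_ids, snp_ids)
    if (!length(found))
      stop("none of the pathway's SNPs are present in the genotype matrix")
    x <- x[, found, drop = FALSE]
  }
  n_pathway <- ncol(x)
  # drop monomorphic SNPs: they carry no similarity information
  poly <- apply(x, 2, function(col) stats::var(col) > 0)
  if (!all(poly)) {
    message(sum(!poly), " monomorphic SNP(s) dropped from pathway")
    x <- x[, poly, drop = FALSE]
  }
  if (!ncol(x)) stop("no polymorphic SNPs left in pathway")
  screening <- NULL
  fallback <- FALSE
  if (!is.null(screening_label)) {
    screening <- screen_snps(x, screening_label, alpha_m)
    fallback <- screening$fallback
    x <- x[, screening$kept_snp_ids, drop = FALSE]
  }
  e <- residualize(phenotype, covariates)
  kc <- lapply(kernels, function(sp) center_kernel(kernel_matrix(x, sp)))
  core <- msku_core(kc, e, specs = lapply(kc, `[[`, "spec"))
  structure(c(core,
              list(n_used = length(e), snps_in_pathway = n_pathway,
                   snps_used = ncol(x), screening = screening,
                   screen_fallback = fallback)),
            class = "msku_result")
}

#' @export
print.msku_result <- function(x, ...) {
  q <- vapply(x$per_kernel, `[[`, numeric(1), "q")
  labs <- vapply(x$per_kernel, function(s)
    if (!is.null(s$spec)) format_kernel_spec(s$spec) else "kernel",
    character(1))
  cat("mSKU pathway test\n")
  cat("  n =", x$n_used, "; SNPs used:", x$snps_used, "of",
      x$snps_in_pathway, if (isTRUE(x$screen_fallback))
        "(screening fallback: none passed)" else "", "\n")
  for (i in seq_along(q))
    cat(sprintf("  Q[%s] = %.4f\n", labs[i], q[i]))
  cat(sprintf("  Q_max = %.4f, p = %.4g\n", x$q_max, x$p_value))
  invisible(x)
}
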