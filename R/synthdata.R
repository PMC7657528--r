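# Synthetic genotype / covariate / phenotype generator.
#
# Emulates the simulation design used throughout the package's validation:
# Hardy-Weinberg genotypes with AR(1) linkage disequilibrium, two baseline
# covariates, and t quantitative phenotypes with exchangeably correlated
# Gaussian errors and a configurable genetic effect h(.).

#' Construct a genotype matrix object
#'
#' Light container for an additive-coded (0/1/2 minor-allele count) genotype
#' matrix with SNP and sample identifiers.
#'
#' @param values integer matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1 or 2.
#' @param snp_ids character vector of unique SNP identifiers (default taken
#'   from column names, or generated as \code{snp1..snpP}).
#' @param sample_ids character vector of unique sample identifiers (default
#'   taken from row names, or generated as \code{s1..sN}).
#' @param mafs optional numeric vector of per-SNP minor allele frequencies in
#'   (0, 0.5].
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{values}, \code{snp_ids}, \code{sample_ids}, \code{mafs}.
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL,
                            mafs = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0L, 1L, 2L)))
    stop("genotype values must all be 0, 1 or 2")
  storage.mode(values) <- "integer"
  n <- nrow(values); p <- ncol(values)
  if (is.null(snp_ids)) snp_ids <- colnames(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  snp_ids <- as.character(snp_ids); sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != p || anyDuplicated(snp_ids))
    stop("snp_ids must be ", p, " unique strings")
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("sample_ids must be ", n, " unique strings")
  if (!is.null(mafs)) {
    if (length(mafs) != p || any(mafs <= 0 | mafs > 0.5))
      stop("mafs must have length ", p, " with values in (0, 0.5]")
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(list(values = values, snp_ids = snp_ids,
                 sample_ids = sample_ids, mafs = mafs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "SNPs\n")
  if (!is.null(x$mafs))
    cat("  MAF range:", format(range(x$mafs), digits = 3), "\n")
  invisible(x)
}

#' Coerce to a plain genotype matrix
#'
#' @param x a \code{genotype_matrix} or a numeric matrix of 0/1/2 values.
#' @return integer matrix of minor-allele counts.
#' @export
as_geno_values <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as genotypes")
}

#' Simulate Hardy-Weinberg genotypes with AR(1) linkage disequilibrium
#'
#' Each SNP's minor allele frequency is drawn uniformly from
#' \code{[maf_low, maf_high]}.  Alleles are generated by thresholding a
#' latent Gaussian AR(1) process (correlation \code{ld_r} between adjacent
#' SNPs) at the allele-frequency quantile, so each haplotype carries
#' Bernoulli(MAF) alleles with local LD; two independent haplotypes are
#' summed per sample, giving exact Hardy-Weinberg marginal genotype
#' frequencies \eqn{(1-q)^2, 2q(1-q), q^2}.
#'
#' @param n number of samples (>= 2).
#' @param p number of SNPs (>= 1).
#' @param maf_low,maf_high bounds of the uniform MAF distribution,
#'   \code{0 < maf_low <= maf_high <= 0.5}.
#' @param ld_r latent adjacent-SNP correlation in [0, 1).
#' @param seed optional integer seed; if supplied the draw is deterministic.
#' @return a \code{\link{genotype_matrix}} with the drawn \code{mafs}
#'   attached.
#' @export
simulate_genotypes <- function(n, p, maf_low = 0.05, maf_high = 0.5,
                               ld_r = 0.5, seed = NULL) {
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (ld_r < 0 || ld_r >= 1) stop("ld_r must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  mafs <- stats::runif(p, maf_low, maf_high)
  thr <- stats::qnorm(mafs)
  # two haplotypes per sample, latent AR(1) across SNPs
  hap <- function() {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (ld_r > 0 && p > 1) {
      s <- sqrt(1 - ld_r^2)
      for (j in 2:p) z[, j] <- ld_r * z[, j - 1L] + s * z[, j]
    }
    z < rep(thr, each = n)
  }
  x <- hap() + hap()
  storage.mode(x) <- "integer"
  genotype_matrix(x, mafs = mafs)
}

#' Simulate baseline covariates
#'
#' Two independent covariates: \code{Z1 ~ N(2, 1)} and
#' \code{Z2 ~ Bernoulli(0.6)}.
#'
#' @param n number of samples (>= 1).
#' @param seed optional integer seed.
#' @return numeric matrix with columns \code{Z1}, \code{Z2} and row names
#'   \code{s1..sN}.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (n < 1) stop("need n >= 1")
  if (!is.null(seed)) set.seed(seed)
  z <- cbind(Z1 = stats::rnorm(n, mean = 2, sd = 1),
             Z2 = as.numeric(stats::rbinom(n, 1, 0.6)))
  rownames(z) <- paste0("s", seq_len(n))
  z
}

#' Draw fixed coefficients for the many-SNP effect scenarios
#'
#' Selects a set \eqn{H_P} of 60 SNPs carrying main effects and a set
#' \eqn{H_Q} of 90 distinct SNP pairs carrying pairwise interactions, with
#' coefficients drawn independently from Uniform(0, 0.02).  Intended to be
#' drawn once per study and held fixed across simulation replicates.
#'
#' @param p number of SNPs available (>= 150).
#' @param seed optional integer seed.
#' @return list of class \code{scenario_pq_coefficients} with elements
#'   \code{hp_indices} (60), \code{hq_pairs} (90 x 2 matrix),
#'   \code{alpha_m} (60), \code{beta_mm} (90).
#' @export
make_scenario_pq_coefficients <- function(p, seed = NULL) {
  if (p < 150) stop("need p >= 150 to place 60 main effects and 90 pairs")
  if (!is.null(seed)) set.seed(seed)
  hp <- sort(sample.int(p, 60))
  # sample 90 distinct unordered pairs
  pairs <- matrix(0L, 0, 2)
  seen <- character(0)
  while (nrow(pairs) < 90) {
    cand <- matrix(sample.int(p, 2 * (90 - nrow(pairs)), replace = TRUE),
                   ncol = 2)
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    if (!nrow(cand)) next
    cand <- t(apply(cand, 1, sort))
    key <- paste(cand[, 1], cand[, 2])
    fresh <- !duplicated(key) & !(key %in% seen)
    cand <- cand[fresh, , drop = FALSE]
    seen <- c(seen, key[fresh])
    pairs <- rbind(pairs, cand)
  }
  structure(list(hp_indices = hp,
                 hq_pairs = pairs[seq_len(90), , drop = FALSE],
                 alpha_m = stats::runif(60, 0, 0.02),
                 beta_mm = stats::runif(90, 0, 0.02)),
            class = "scenario_pq_coefficients")
}

#' Genetic effect function h(X) under the named simulation scenarios
#'
#' \describe{
#'   \item{null}{\eqn{h = 0} for every sample.}
#'   \item{M}{\eqn{0.27 (x_5 - x_{10}) + \cos(x_{10}) e^{-x_{10}^2 / 5}}:
#'     a nonlinear effect of the tenth SNP plus opposite-direction main
#'     effects.}
#'   \item{N}{\eqn{0.37 x_5 + 0.62 x_{10} - 0.06 x_{15}}: three marginal
#'     linear effects.}
#'   \item{P, Q}{\eqn{b_P \sum_{m \in H_P} \alpha_m x_m +
#'     b_Q \sum_{(m,m') \in H_Q} \beta_{mm'} x_m x_{m'}}: 60 weak main
#'     effects plus 90 pairwise interactions, with \eqn{(b_P, b_Q) =
#'     (0.07, 2.3)} for P (interaction-dominated) and \eqn{(3.8, 0)} for Q
#'     (pure main effects).}
#' }
#' SNP indices are 1-based column positions.
#'
#' @param genotypes a \code{\link{genotype_matrix}} or 0/1/2 matrix.
#' @param scenario one of \code{"null"}, \code{"M"}, \code{"N"}, \code{"P"},
#'   \code{"Q"}.
#' @param coefficients a \code{\link{make_scenario_pq_coefficients}} result;
#'   required for scenarios P and Q.
#' @param b_p,b_q scale of the main-effect and interaction sums; defaults
#'   are the scenario's canonical values.
#' @return numeric vector of length n.
#' @export
scenario_h <- function(genotypes, scenario,
                       coefficients = NULL, b_p = NULL, b_q = NULL) {
  x <- as_geno_values(genotypes)
  n <- nrow(x); p <- ncol(x)
  scenario <- match.arg(scenario, c("null", "M", "N", "P", "Q"))
  if (scenario == "null") return(numeric(n))
  if (scenario == "M") {
    if (p < 10) stop("scenario M needs p >= 10")
    x10 <- unname(x[, 10])
    return(0.27 * (unname(x[, 5]) - x10) + cos(x10) * exp(-x10^2 / 5))
  }
  if (scenario == "N") {
    if (p < 15) stop("scenario N needs p >= 15")
    return(unname(0.37 * x[, 5] + 0.62 * x[, 10] - 0.06 * x[, 15]))
  }
  # scenarios P and Q
  if (is.null(coefficients))
    stop("scenarios P and Q require 'coefficients'")
  if (is.null(b_p)) b_p <- if (scenario == "P") 0.07 else 3.8
  if (is.null(b_q)) b_q <- if (scenario == "P") 2.3 else 0
  co <- coefficients
  if (max(co$hp_indices) > p || max(co$hq_pairs) > p)
    stop("coefficient SNP indices exceed the number of SNPs")
  main <- as.vector(x[, co$hp_indices, drop = FALSE] %*% co$alpha_m)
  inter <- as.vector((x[, co$hq_pairs[, 1], drop = FALSE] *
                      x[, co$hq_pairs[, 2], drop = FALSE]) %*% co$beta_mm)
  b_p * main + b_q * inter
}

#' Simulate correlated quantitative phenotypes
#'
#' Each of the t phenotypes follows
#' \deqn{Y_{ki} = 0.02 Z_{i1} + 0.6 Z_{i2} + h(X_i) + \epsilon_{ki}}
#' where per sample the t errors are multivariate normal with mean zero and
#' exchangeable covariance \code{error_sd^2 * ((1 - rho) I + rho J)}.
#'
#' @param covariates numeric matrix with columns \code{Z1}, \code{Z2} (extra
#'   columns are ignored for the mean but allowed), or NULL for no covariate
#'   contribution.
#' @param h numeric vector of genetic effects, length n (recycled scalar 0
#'   allowed).
#' @param t number of phenotypes (>= 1).
#' @param rho exchangeable error correlation in [0, 1).
#' @param error_sd residual standard deviation (> 0).
#' @param seed optional integer seed.
#' @return numeric n x t matrix with columns \code{Y1..Yt}.
#' @export
simulate_phenotypes <- function(covariates, h, t = 5, rho = 0.2,
                                error_sd = 1, seed = NULL) {
  if (t < 1) stop("need t >= 1")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (error_sd <= 0) stop("error_sd must be > 0")
  n <- if (!is.null(covariates)) nrow(covariates) else length(h)
  if (length(h) == 1) h <- rep(h, n)
  if (length(h) != n) stop("length of h must match the number of samples")
  if (!is.null(seed)) set.seed(seed)
  mu <- h
  if (!is.null(covariates)) {
    if (nrow(covariates) != n) stop("covariate rows must match length of h")
    mu <- mu + 0.02 * covariates[, "Z1"] + 0.6 * covariates[, "Z2"]
  }
  shared <- stats::rnorm(n)
  eps <- sqrt(rho) * shared +
    sqrt(1 - rho) * matrix(stats::rnorm(n * t), n, t)
  y <- mu + error_sd * eps
  colnames(y) <- paste0("Y", seq_len(t))
  rownames(y) <- if (!is.null(covariates) && !is.null(rownames(covariates)))
    rownames(covariates) else paste0("s", seq_len(n))
  y
}

#' Bundle the settings of a simulation study
#'
#' @param n,p,t sample, SNP and phenotype counts.
#' @param rho exchangeable phenotype-error correlation in [0, 1).
#' @param scenario effect scenario tag (see \code{\link{scenario_h}}).
#' @param maf_low,maf_high MAF range for \code{\link{simulate_genotypes}}.
#' @param ld_r adjacent-SNP latent correlation.
#' @param error_sd residual standard deviation.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param alpha_level nominal significance level.
#' @param seed master seed; replicate seeds are derived from it.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n = 200, p = 400, t = 5, rho = 0.2,
                              scenario = "null", maf_low = 0.05,
                              maf_high = 0.5, ld_r = 0.5, error_sd = 1,
                              n_replicates = 1000, alpha_level = 0.05,
                              seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (error_sd <= 0) stop("error_sd must be > 0")
  if (n_replicates < 1) stop("n_replicates must be a positive integer")
  scenario <- match.arg(scenario, c("null", "M", "N", "P", "Q"))
  structure(list(n = n, p = p, t = t, rho = rho, scenario = scenario,
                 maf_low = maf_low, maf_high = maf_high, ld_r = ld_r,
                 error_sd = error_sd, n_replicates = as.integer(n_replicates),
                 alpha_level = alpha_level, seed = as.integer(seed)),
            class = "simulation_config")
}
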