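# Candidate kernel construction over the SNP submatrix of a pathway.

#' Specify a kernel function
#'
#' @param family \code{"linear"} (\eqn{x^T y + c}), \code{"gaussian"}
#'   (\eqn{\exp(-\|x - y\|^2 / 2\sigma^2)}) or \code{"polynomial"}
#'   (\eqn{(\alpha x^T y + c)^d}).
#' @param c offset for linear / polynomial kernels (>= 0).
#' @param sigma Gaussian bandwidth: a positive number, or the string
#'   \code{"median"} to resolve it from the data by
#'   \code{\link{median_heuristic_bandwidth}}.
#' @param alpha polynomial scale (> 0).
#' @param d polynomial degree (integer >= 1).
#' @return list of class \code{kernel_spec}.
#' @export
kernel_spec <- function(family = c("linear", "gaussian", "polynomial"),
                        c = 0, sigma = "median", alpha = 1, d = 2L) {
  family <- match.arg(family)
  if (is.numeric(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (identical(family, "polynomial")) {
    if (alpha <= 0) stop("polynomial alpha must be > 0")
    if (c < 0) stop("polynomial c must be >= 0 for positive semidefiniteness")
    if (d < 1 || d != round(d)) stop("polynomial degree d must be >= 1")
  }
  structure(list(family = family, c = c, sigma = sigma, alpha = alpha,
                 d = as.integer(d)), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(format_kernel_spec(x), "\n")
  invisible(x)
}

format_kernel_spec <- function(spec) {
  switch(spec$family,
    linear = sprintf("linear(c=%g)", spec$c),
    gaussian = sprintf("gaussian(sigma=%s)",
                       if (is.numeric(spec$sigma)) format(spec$sigma)
                       else spec$sigma),
    polynomial = sprintf("polynomial(alpha=%g, c=%g, d=%d)",
                         spec$alpha, spec$c, spec$d))
}

#' Parse a kernel bundle description
#'
#' Comma-separated grammar: \code{linear[:c]},
#' \code{gaussian[:sigma|median]}, \code{poly:d[:alpha[:c]]}.  The default
#' bundle of M = 3 candidates is \code{"linear,gaussian:median,poly:2"}.
#'
#' @param text bundle description string.
#' @return list of \code{\link{kernel_spec}} objects.
#' @examples
#' kernel_bundle("linear,gaussian:median,poly:2")
#' @export
kernel_bundle <- function(text = "linear,gaussian:median,poly:2") {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty kernel bundle")
  lapply(parts, function(tok) {
    f <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
    head <- tolower(f[1])
    if (head == "linear") {
      kernel_spec("linear", c = if (length(f) > 1) as.numeric(f[2]) else 0)
    } else if (head == "gaussian") {
      s <- if (length(f) > 1) f[2] else "median"
      kernel_spec("gaussian",
                  sigma = if (identical(s, "median")) "median"
                          else as.numeric(s))
    } else if (head %in% c("poly", "polynomial")) {
      if (length(f) < 2) stop("poly kernel needs a degree: poly:d[:alpha[:c]]")
      kernel_spec("polynomial", d = as.integer(f[2]),
                  alpha = if (length(f) > 2) as.numeric(f[3]) else 1,
                  c = if (length(f) > 3) as.numeric(f[4]) else 1)
    } else stop("unknown kernel family: ", head)
  })
}

#' Median-heuristic Gaussian bandwidth
#'
#' Sets \eqn{\sigma^2} to the median of the squared pairwise Euclidean
#' distances between distinct rows, divided by 2, so the median pair has
#' kernel value \eqn{e^{-1/2}}.  Zero distances (duplicated rows) are
#' excluded from the median.
#'
#' @param x genotype submatrix (samples x SNPs) or \code{genotype_matrix}.
#' @return positive bandwidth \eqn{\sigma}.
#' @export
median_heuristic_bandwidth <- function(x) {
  x <- as_geno_values(x)
  if (nrow(x) < 2) stop("need at least two samples")
  d2 <- as.vector(stats::dist(x))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) stop("all rows identical: bandwidth undefined")
  sqrt(stats::median(d2) / 2)
}

#' Evaluate a kernel matrix over genotype rows
#'
#' @param x genotype submatrix (samples x SNPs) restricted to the pathway's
#'   SNPs, or a \code{genotype_matrix}.
#' @param spec a \code{\link{kernel_spec}}.
#' @return list of class \code{kernel_matrix}: \code{values} (exactly
#'   symmetric n x n), \code{spec} (with any \code{"median"} bandwidth
#'   resolved to its numeric value), \code{centered = FALSE}.
#' @export
kernel_matrix <- function(x, spec) {
  x <- as_geno_values(x)
  if (!is.numeric(x) && !is.integer(x)) stop("genotypes must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop("genotypes contain non-finite values")
  if (nrow(x) < 2) stop("need at least two samples")
  if (ncol(x) < 1) stop("empty SNP subset")
  storage.mode(x) <- "double"
  g <- tcrossprod(x)
  k <- switch(spec$family,
    linear = g + spec$c,
    gaussian = {
      sigma <- spec$sigma
      if (identical(sigma, "median")) sigma <- median_heuristic_bandwidth(x)
      spec$sigma <- sigma
      sq <- diag(g)
      d2 <- outer(sq, sq, "+") - 2 * g
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * sigma^2))
    },
    polynomial = (spec$alpha * g + spec$c)^spec$d)
  k <- (k + t(k)) / 2
  structure(list(values = k, spec = spec, centered = FALSE),
            class = "kernel_matrix")
}

#' Double-center a kernel matrix
#'
#' Applies the centering projection \eqn{\tilde K = H K H} with
#' \eqn{H = I - \frac{1}{n} 1 1^T}, so row and column sums of the result are
#' zero.  Centering is idempotent.
#'
#' @param k a \code{kernel_matrix} or a plain symmetric matrix.
#' @return a centered \code{kernel_matrix}.
#' @export
center_kernel <- function(k) {
  spec <- NULL
  if (inherits(k, "kernel_matrix")) {
    if (isTRUE(k$centered)) return(k)
    spec <- k$spec
    k <- k$values
  }
  rm_ <- rowMeans(k)
  gm <- mean(rm_)
  kc <- k - outer(rm_, rep(1, ncol(k))) - outer(rep(1, nrow(k)), rm_) + gm
  kc <- (kc + t(kc)) / 2
  structure(list(values = kc, spec = spec, centered = TRUE),
            class = "kernel_matrix")
}

kernel_values <- function(k) {
  if (inherits(k, "kernel_matrix")) k$values else k
}
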