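# I/O, pathway sets, the genome-wide runner and the simulation-study
# harness.

#' Read an additive-coded genotype table
#'
#' Supported formats: \code{"tsv"} — tab-separated, header row of SNP ids,
#' first column \code{sample_id}; entries must be 0, 1, 2 or NA.
#' \code{"plink"} — a PLINK .bed/.bim/.fam triple (pass the prefix or any of
#' the three file names); genotypes are decoded as minor-allele (A1) counts.
#' Missing genotypes are imputed to the SNP's rounded mean with a message
#' reporting the count.
#'
#' @param path file path (TSV) or PLINK prefix.
#' @param format \code{"tsv"} or \code{"plink"}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "plink") return(read_plink(path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!ncol(tab) >= 2) stop("genotype TSV needs sample_id plus SNP columns")
  sample_ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  ok <- is.na(vals) | vals %in% c("0", "1", "2", "NA", "")
  if (!all(ok))
    stop("invalid genotype token(s): ",
         paste(unique(vals[!ok])[1:min(3, sum(!ok))], collapse = ", "))
  x <- matrix(suppressWarnings(as.integer(vals)), nrow(vals), ncol(vals),
              dimnames = list(sample_ids, colnames(vals)))
  impute_missing_genotypes(x, sample_ids)
}

impute_missing_genotypes <- function(x, sample_ids) {
  n_miss <- sum(is.na(x))
  if (n_miss > 0) {
    message(n_miss, " missing genotype(s) imputed to rounded SNP means")
    for (j in which(colSums(is.na(x)) > 0)) {
      fill <- round(mean(x[, j], na.rm = TRUE))
      if (!is.finite(fill)) fill <- 0L
      x[is.na(x[, j]), j] <- as.integer(fill)
    }
  }
  genotype_matrix(x, sample_ids = sample_ids)
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes
       else genotype_matrix(genotypes)
  tab <- data.frame(sample_id = g$sample_ids, g$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample-keyed numeric table (phenotypes or covariates) as TSV
#'
#' @param values numeric matrix with row names as sample ids (generated as
#'   \code{s1..sN} when absent).
#' @param path output file.
#' @export
write_samples_tsv <- function(values, path) {
  v <- as.matrix(values)
  ids <- rownames(v)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(v)))
  tab <- data.frame(sample_id = ids, v, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-keyed numeric table (phenotypes or covariates)
#'
#' @param path TSV with header and a \code{sample_id} first column.
#' @return numeric matrix with sample ids as row names.
#' @export
read_samples_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in ", path)
  rownames(m) <- as.character(tab[[1]])
  m
}

# ---- PLINK .bed/.bim/.fam codec -------------------------------------------
# Minimal binary PLINK 1 support: SNP-major .bed with the standard 2-bit
# encoding (00 = hom A1, 10 = het, 11 = hom A2, 01 = missing); A1 is taken
# as the minor allele so the additive code counts A1 copies.

plink_paths <- function(prefix) {
  prefix <- sub("\\.(bed|bim|fam)$", "", prefix)
  list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
       fam = paste0(prefix, ".fam"))
}

#' Write genotypes as a PLINK .bed/.bim/.fam triple
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes
       else genotype_matrix(genotypes)
  pp <- plink_paths(prefix)
  n <- length(g$sample_ids); p <- length(g$snp_ids)
  utils::write.table(
    data.frame(fid = g$sample_ids, iid = g$sample_ids, pat = 0, mat = 0,
               sex = 0, pheno = -9),
    pp$fam, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(chrom = 1, id = g$snp_ids, cm = 0, pos = seq_len(p),
               a1 = "A", a2 = "B"),
    pp$bim, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  # genotype count -> 2-bit code (per-SNP, sample-packed 4 per byte)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)       # 11, 10, 00
  bytes_per_snp <- ceiling(n / 4)
  con <- file(pp$bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(p)) {
    codes <- c(code[as.character(g$values[, j])], rep(0L, pad))
    m <- matrix(codes, nrow = 4)
    packed <- m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ]
    writeBin(as.raw(packed), con)
  }
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam triple
#'
#' @param prefix path prefix (or any of the three file names).
#' @return a \code{\link{genotype_matrix}} of A1 (minor-allele) counts;
#'   missing genotypes are mean-imputed with a message.
#' @export
read_plink <- function(prefix) {
  pp <- plink_paths(prefix)
  if (!all(file.exists(pp$bed, pp$bim, pp$fam)))
    stop("incomplete PLINK triple at prefix ", prefix)
  fam <- utils::read.table(pp$fam, colClasses = "character")
  bim <- utils::read.table(pp$bim, colClasses = "character")
  sample_ids <- fam[[2]]; snp_ids <- bim[[2]]
  n <- length(sample_ids); p <- length(snp_ids)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(pp$bed, "raw", n = 3 + p * bytes_per_snp)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]),
                                    c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  body <- as.integer(raw[-(1:3)])
  if (length(body) != p * bytes_per_snp) stop("truncated .bed file")
  # unpack 4 x 2-bit codes per byte
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4 * bytes_per_snp, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  x <- matrix(NA_integer_, n, p, dimnames = list(sample_ids, snp_ids))
  x[codes == 0L] <- 2L     # hom A1
  x[codes == 2L] <- 1L     # het
  x[codes == 3L] <- 0L     # hom A2
  impute_missing_genotypes(x, sample_ids)
}

# ---- pathway sets ---------------------------------------------------------

#' Read pathway SNP sets from a GMT file
#'
#' Each line: set name, description, then the member SNP ids, tab-separated.
#' Duplicate members within a set are removed; sets with fewer than
#' \code{min_snps} members are dropped with a warning; duplicate set names
#' are an error.
#'
#' @param path GMT file.
#' @param min_snps minimum member count for a set to be kept (default 2).
#' @return named list of character vectors (class \code{pathway_set}).
#' @export
read_pathways <- function(path, min_snps = 2) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    stop("duplicate pathway names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f)
    unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- names_
  small <- lengths(sets) < min_snps
  if (any(small)) {
    warning(sum(small), " pathway(s) with < ", min_snps,
            " SNPs dropped: ", paste(names_[small], collapse = ", "))
    sets <- sets[!small]
  }
  if (!length(sets)) stop("no pathway with >= ", min_snps, " SNPs")
  structure(sets, class = "pathway_set")
}

# ---- genome-wide runner ---------------------------------------------------

#' Run FC-mSKU over every pathway
#'
#' For each pathway the mSKU test is run against each phenotype column, then
#' the marginal p-values are combined by the dependence-adjusted Fisher
#' method using the study-wide covariate-adjusted phenotype correlation.
#' Pathways with no SNP present in the genotype matrix are skipped with a
#' message.  Kernel matrices are built per pathway and released before the
#' next one, so memory scales with a single pathway.
#'
#' @param genotypes \code{\link{genotype_matrix}} (all SNPs).
#' @param phenotypes numeric n x t matrix.
#' @param covariates numeric covariate matrix or NULL.
#' @param pathways \code{\link{read_pathways}} result or named list of SNP
#'   id vectors.
#' @param kernels kernel bundle (list of specs or bundle string).
#' @param screening_label optional auxiliary screening label.
#' @param alpha_m screening threshold.
#' @param bh add a Benjamini-Hochberg adjusted column across pathways.
#' @return data.frame with one row per tested pathway: pathway id, n, SNP
#'   counts, per-phenotype p-values (\code{p_<name>}), \code{q_max_<name>},
#'   \code{global_p}, screening flag and optionally \code{global_p_bh}.
#' @export
run_study <- function(genotypes, phenotypes, covariates = NULL, pathways,
                      kernels = kernel_bundle(), screening_label = NULL,
                      alpha_m = 0.05, bh = FALSE) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes
       else genotype_matrix(genotypes)
  y <- as.matrix(phenotypes)
  t <- ncol(y)
  pheno_names <- colnames(y)
  if (is.null(pheno_names)) pheno_names <- paste0("Y", seq_len(t))
  if (is.character(kernels)) kernels <- kernel_bundle(kernels)
  pheno_cor <- if (t > 1) phenotype_correlation(y, covariates) else NULL
  rows <- list()
  for (pw in names(pathways)) {
    present <- intersect(pathways[[pw]], g$snp_ids)
    if (!length(present)) {
      message("pathway ", pw, " skipped: no SNP present")
      next
    }
    marg <- numeric(t); qmx <- numeric(t); used <- NA; fb <- FALSE
    for (k in seq_len(t)) {
      fit <- msku_test(g, y[, k], pathway_snp_ids = present,
                       covariates = covariates, kernels = kernels,
                       screening_label = screening_label, alpha_m = alpha_m)
      marg[k] <- fit$p_value; qmx[k] <- fit$q_max
      used <- fit$snps_used; fb <- fb || fit$screen_fallback
    }
    comb <- fc_combine(pmax(marg, .Machine$double.xmin), pheno_cor)
    row <- data.frame(pathway = pw, n = nrow(y),
                      snps_in_pathway = length(present), snps_used = used,
                      stringsAsFactors = FALSE)
    for (k in seq_len(t)) row[[paste0("p_", pheno_names[k])]] <- marg[k]
    for (k in seq_len(t)) row[[paste0("q_max_", pheno_names[k])]] <- qmx[k]
    row$global_p <- comb$global_p
    row$screen_fallback <- fb
    rows[[pw]] <- row
  }
  if (!length(rows)) stop("no testable pathway")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh) out$global_p_bh <- stats::p.adjust(out$global_p, "BH")
  out
}

# ---- simulation-study harness ---------------------------------------------

# Centered candidate kernel matrices for one simulated genotype block,
# sharing the single Gram-matrix GEMM across families.
sim_kernel_matrices <- function(x, specs) {
  storage.mode(x) <- "double"
  g <- tcrossprod(x)
  n <- nrow(g)
  sq <- diag(g)
  lapply(specs, function(sp) {
    k <- switch(sp$family,
      linear = g + sp$c,
      gaussian = {
        d2 <- sq - 2 * g          # column recycling: sq_i - 2 g_ij
        d2 <- d2 + rep(sq, each = n)
        d2[d2 < 0] <- 0
        pos <- d2[upper.tri(d2)]
        pos <- pos[pos > 0]
        sigma <- if (identical(sp$sigma, "median")) {
          if (!length(pos)) stop("all rows identical: bandwidth undefined")
          sqrt(stats::median(pos) / 2)
        } else sp$sigma
        exp(-d2 / (2 * sigma^2))
      },
      polynomial = (sp$alpha * g + sp$c)^sp$d)
    # double-centering without transposes (k is exactly symmetric here)
    rm_ <- rowMeans(k)
    kc <- k - rm_
    kc <- kc - rep(rm_, each = n)
    kc <- kc + mean(rm_)
    diag(kc) <- 0
    kc
  })
}

# Q statistics, inter-kernel correlation and max-test p-value from centered,
# zero-diagonal kernel matrices and a residual vector.
sim_msku_pvalue <- function(k0, prods, norms_mat, e) {
  n <- length(e)
  e2 <- e * e
  m <- length(k0)
  t_n <- vapply(k0, function(a)
    as.numeric(crossprod(e, a %*% e)) / (n * (n - 1)), numeric(1))
  norms <- vapply(seq_len(m), function(i)
    as.numeric(crossprod(e2, norms_mat[[i]] %*% e2)), numeric(1))
  v_hat <- 2 * norms / (n^2 * (n - 1)^2)
  if (any(v_hat <= 0)) stop("degenerate kernel statistic")
  q <- t_n / sqrt(v_hat)
  omega <- diag(1, m)
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      cross <- as.numeric(crossprod(e2, prods[[paste(i, j)]] %*% e2))
      omega[i, j] <- omega[j, i] <- cross / sqrt(norms[i] * norms[j])
    }
  }
  max_statistic_pvalue(max(q), repair_correlation(omega))
}

#' Monte-Carlo study of type I error or power
#'
#' Runs the full generative model for \code{n_replicates} independent
#' replicates: fresh genotypes, covariates and phenotypes per replicate,
#' the scenario's genetic effect h(.), the mSKU test of the whole simulated
#' SNP block (treated as one pathway) against each phenotype, and the
#' dependence-adjusted Fisher combination.  Reports the proportion of
#' global p-values below \code{alpha_level}.  For scenarios P and Q the
#' effect coefficients are drawn once from the master seed and held fixed
#' across replicates.  Replicate seeds are derived from the master seed so
#' the study is reproducible end to end.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param kernels kernel bundle (list of specs or bundle string).
#' @param progress print a progress message every 200 replicates.
#' @return list of class \code{simulation_report}: the config, empirical
#'   \code{rejection_rate}, its binomial \code{se}, \code{global_pvalues}
#'   (length B) and \code{marginal_pvalues} (B x t matrix).
#' @export
simulation_study <- function(config, kernels = kernel_bundle(),
                             progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.character(kernels)) kernels <- kernel_bundle(kernels)
  b <- config$n_replicates
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, b)
  coef_pq <- NULL
  if (config$scenario %in% c("P", "Q")) {
    set.seed(config$seed)
    coef_pq <- make_scenario_pq_coefficients(config$p)
  }
  t <- config$t
  global_p <- numeric(b)
  marginal_p <- matrix(NA_real_, b, t)
  for (r in seq_len(b)) {
    set.seed(rep_seeds[r])
    g <- simulate_genotypes(config$n, config$p, config$maf_low,
                            config$maf_high, config$ld_r)
    z <- simulate_covariates(config$n)
    h <- scenario_h(g, config$scenario, coefficients = coef_pq)
    y <- simulate_phenotypes(z, h, t = t, rho = config$rho,
                             error_sd = config$error_sd)
    k0 <- sim_kernel_matrices(g$values, kernels)
    m <- length(k0)
    norms_mat <- lapply(k0, function(a) a * a)
    prods <- list()
    if (m > 1) for (i in 1:(m - 1)) for (j in (i + 1):m)
      prods[[paste(i, j)]] <- k0[[i]] * k0[[j]]
    for (k in seq_len(t)) {
      e <- residualize(y[, k], z)
      marginal_p[r, k] <- sim_msku_pvalue(k0, prods, norms_mat, e)
    }
    pheno_cor <- if (t > 1) phenotype_correlation(y, z) else NULL
    global_p[r] <- fc_combine(pmax(marginal_p[r, ], .Machine$double.xmin),
                              pheno_cor)$global_p
    if (progress && r %% 200 == 0)
      message("replicate ", r, " / ", b)
  }
  rate <- mean(global_p < config$alpha_level)
  structure(list(config = config, rejection_rate = rate,
                 se = sqrt(rate * (1 - rate) / b),
                 n_replicates = b, global_pvalues = global_p,
                 marginal_pvalues = marginal_p),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "simulation_report: scenario %s, n=%d, p=%d, t=%d, rho=%.2f, B=%d\n",
    cf$scenario, cf$n, cf$p, cf$t, cf$rho, x$n_replicates))
  cat(sprintf("  rejection rate at %.3g: %.4f (SE %.4f)\n",
              cf$alpha_level, x$rejection_rate, x$se))
  invisible(x)
}
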