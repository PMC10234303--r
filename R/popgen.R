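#' Read haploid genotypes from a VCF
#'
#' Loads a population VCF with haploid GT calls (one allele per strain;
#' `"."` = missing). Any called allele index is kept, so multiallelic sites
#' are handled.
#'
#' @param path VCF file (plain or bgzipped).
#' @return object of class `snp_matrix`: list with `sites` (data frame
#'   `contig`, `pos`) and `geno` (integer matrix, sites x strains, `NA` for
#'   missing).
#' @export
read_haploid_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # haploid calls: take the first allele of any ploidy notation
  allele <- sub("[/|].*$", "", gt)
  allele[allele == "."] <- NA
  geno <- matrix(suppressWarnings(as.integer(allele)), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  sites <- data.frame(contig = vcfR::getCHROM(v),
                      pos = as.integer(vcfR::getPOS(v)))
  snp_matrix(sites, geno)
}

#' Construct a SNP matrix
#'
#' @param sites data frame with `contig`, `pos` (1-based).
#' @param geno integer matrix of allele indices (sites x strains), `NA`
#'   where the call is missing.
#' @return `snp_matrix` object.
#' @export
snp_matrix <- function(sites, geno) {
  stopifnot(nrow(sites) == nrow(geno))
  structure(list(sites = sites, geno = geno, n_strains = ncol(geno)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d site(s) x %d strain(s), %.1f%% missing\n",
              nrow(x$geno), x$n_strains, 100 * mean(is.na(x$geno))))
  invisible(x)
}

# harmonic numbers a_n = sum_{k=1}^{n-1} 1/k, a_1 = 0
.watterson_a <- function(n_max) {
  c(0, cumsum(1 / seq_len(max(n_max - 1, 1))))
}

#' Watterson's theta for one set of sites
#'
#' Missing-data form: each site contributes `1 / a_{n_i}` when it segregates
#' among its called alleles, where `n_i` is the site's own number of called
#' alleles; sites with fewer than two calls are skipped. Any site with more
#' than one distinct called allele counts as segregating.
#'
#' @param geno integer matrix (sites x strains) of allele indices, `NA` for
#'   missing calls. Zero rows give `theta = 0`.
#' @param L callable length in bp the sites were ascertained over.
#' @return list: `theta` (per bp), `n_segregating`, `mean_n` (mean called
#'   sample size over usable sites).
#' @export
theta_w <- function(geno, L) {
  if (L <= 0) stop("callable length must be positive")
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  if (nrow(geno) == 0L) {
    return(list(theta = 0, n_segregating = 0L, mean_n = NA_real_))
  }
  n_i <- rowSums(!is.na(geno))
  usable <- n_i >= 2
  seg <- logical(nrow(geno))
  for (i in which(usable)) {
    a <- geno[i, ]
    seg[i] <- length(unique(a[!is.na(a)])) > 1L
  }
  a_tab <- .watterson_a(max(n_i, 2))
  contrib <- sum(1 / a_tab[n_i[seg & usable]])
  list(theta = contrib / L,
       n_segregating = sum(seg & usable),
       mean_n = if (any(usable)) mean(n_i[usable]) else NA_real_)
}

#' Windowed Watterson's theta
#'
#' Applies [theta_w()] in the windows of a `WindowTable`. Windows whose
#' callable fraction falls below `min_callable` are reported as `NA`.
#'
#' @param snp `snp_matrix`.
#' @param windows `WindowTable` from [make_windows()].
#' @param min_callable minimum callable fraction for a window to yield a
#'   theta value (default 0.5).
#' @return the window table with `theta`, `n_segregating` and `mean_n`
#'   columns added (`ThetaWindows`).
#' @export
theta_windows <- function(snp, windows, min_callable = 0.5) {
  w <- windows
  w$theta <- NA_real_
  w$n_segregating <- NA_integer_
  w$mean_n <- NA_real_
  width <- w$end - w$start + 1
  ok <- w$callable_bp / width >= min_callable & w$callable_bp > 0
  # windows are fixed-width per construction; index sites by window id
  win_width <- w$end[1] - w$start[1] + 1
  site_key <- paste(snp$sites$contig, (snp$sites$pos - 1) %/% win_width)
  win_key <- paste(w$contig, (w$start - 1) %/% win_width)
  idx_by_win <- split(seq_len(nrow(snp$sites)), site_key)
  for (i in which(ok)) {
    idx <- idx_by_win[[win_key[i]]]
    res <- theta_w(snp$geno[idx, , drop = FALSE], w$callable_bp[i])
    w$theta[i] <- res$theta
    w$n_segregating[i] <- res$n_segregating
    w$mean_n[i] <- res$mean_n
  }
  w
}

#' Bayesian regression of diversity on predicted mutation rate
#'
#' Linear regression of windowed Watterson's theta on log10 predicted
#' mutation rate, with the conjugate normal-inverse-chi-squared posterior
#' sampled exactly (flat priors). Bayesian R-squared is computed per draw as
#' explained variance over explained-plus-residual variance. An optional
#' two-part (hurdle) variant models the probability that a window has
#' `theta > 0` separately with a logistic regression and fits the linear
#' model on the positive windows only.
#'
#' @param theta vector of per-window theta values.
#' @param log10_mu vector of per-window log10 predicted rates.
#' @param n_draws posterior draws (default 4000).
#' @param hurdle fit the two-part variant (default FALSE).
#' @return list with `slope`, `intercept`, `r2` ([posterior_summary]s),
#'   `n`, and for the hurdle variant `zero_model` (logistic coefficients)
#'   plus the positive-part estimates.
#' @export
diversity_regression <- function(theta, log10_mu, n_draws = 4000,
                                 hurdle = FALSE) {
  ok <- !is.na(theta) & !is.na(log10_mu)
  y <- theta[ok]
  x <- log10_mu[ok]
  if (length(y) < 100) stop("need at least 100 windows with theta and prediction")
  if (stats::var(x) == 0) stop("predictor has zero variance")

  fit_part <- function(y, x) {
    X <- cbind(1, x)
    n <- length(y)
    XtX_inv <- solve(crossprod(X))
    beta_hat <- drop(XtX_inv %*% crossprod(X, y))
    resid <- y - drop(X %*% beta_hat)
    df <- n - 2
    s2 <- sum(resid^2) / df
    sigma2 <- df * s2 / stats::rchisq(n_draws, df)
    L <- chol(XtX_inv)
    beta <- matrix(stats::rnorm(n_draws * 2), n_draws) %*% L *
      sqrt(sigma2) + matrix(beta_hat, n_draws, 2, byrow = TRUE)
    yhat_var <- beta[, 2]^2 * stats::var(x)
    r2 <- yhat_var / (yhat_var + sigma2)
    list(intercept = posterior_summary(beta[, 1]),
         slope = posterior_summary(beta[, 2]),
         r2 = posterior_summary(r2), n = n)
  }

  if (!hurdle) {
    return(fit_part(y, x))
  }
  pos <- y > 0
  zfit <- stats::glm(pos ~ x, family = stats::binomial())
  out <- fit_part(y[pos], x[pos])
  out$zero_model <- list(coef = stats::coef(zfit), vcov = stats::vcov(zfit))
  out$prop_positive <- mean(pos)
  out
}

#' Per-domain diversity medians and contrasts
#'
#' Median theta per stratum with bootstrap intervals, and bootstrap
#' differences of each stratum against euchromatin.
#'
#' @param tw `ThetaWindows` (from [theta_windows()]).
#' @param n_boot bootstrap replicates (default 2000).
#' @return list with `medians` (data frame per stratum) and `contrasts`
#'   (differences vs euchromatin; empty when only one stratum is present).
#' @export
domain_theta_contrast <- function(tw, n_boot = 2000) {
  ok <- !is.na(tw$theta)
  strata <- intersect(STRATA, unique(tw$stratum[ok]))
  boots <- lapply(strata, function(s) {
    v <- tw$theta[ok & tw$stratum == s]
    vapply(seq_len(n_boot), function(b) {
      stats::median(sample(v, length(v), replace = TRUE))
    }, numeric(1))
  })
  names(boots) <- strata
  medians <- do.call(rbind, lapply(strata, function(s) {
    v <- tw$theta[ok & tw$stratum == s]
    h <- hpdi(boots[[s]])
    data.frame(stratum = s, n = length(v), median = stats::median(v),
               lower = h[1], upper = h[2], row.names = NULL)
  }))
  contrasts <- NULL
  if ("euchromatin" %in% strata && length(strata) > 1) {
    others <- setdiff(strata, "euchromatin")
    contrasts <- do.call(rbind, lapply(others, function(s) {
      d <- boots[[s]] - boots[["euchromatin"]]
      h <- hpdi(d)
      data.frame(stratum = s, difference = stats::median(d),
                 lower = h[1], upper = h[2], row.names = NULL)
    }))
  }
  list(medians = medians, contrasts = contrasts)
}

#' Write a theta track as BED
#'
#' @param tw `ThetaWindows`.
#' @param path output path (BED-style, 0-based half-open, fourth column
#'   theta).
#' @export
write_theta_bed <- function(tw, path) {
  ok <- !is.na(tw$theta)
  utils::write.table(
    data.frame(tw$contig[ok], tw$start[ok] - 1L, tw$end[ok],
               signif(tw$theta[ok], 6)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}
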