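#' Highest posterior density interval
#'
#' Shortest contiguous interval containing a given mass of posterior draws.
#' Computed by sliding a window of `ceiling(mass * n)` draws over the sorted
#' sample and picking the narrowest.
#'
#' @param draws numeric vector of posterior draws (at least 100).
#' @param mass probability mass of the interval, in (0, 1). Default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hpdi(rnorm(4000))
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("`mass` must be a single number in (0, 1)")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("hpdi() needs at least 100 draws")
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) {
    return(c(lower = x[1L], upper = x[n]))
  }
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Summarise posterior draws
#'
#' @param draws numeric vector of draws.
#' @param mass HPD interval mass (default 0.95).
#' @return object of class `posterior_summary`: list with `draws`, `median`,
#'   `lower`, `upper` (HPD bounds) and `mass`.
#' @export
posterior_summary <- function(draws, mass = 0.95) {
  h <- hpdi(draws, mass)
  structure(
    list(draws = draws, median = stats::median(draws),
         lower = unname(h[1L]), upper = unname(h[2L]), mass = mass),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  cat(sprintf("%s [%s, %s] (median, %d%% HPDI; %d draws)\n",
              signif(x$median, digits), signif(x$lower, digits),
              signif(x$upper, digits), round(100 * x$mass),
              length(x$draws)))
  invisible(x)
}

# Split-Rhat (potential scale reduction) over a draws matrix with one column
# per chain. Chains are split in half so within-chain drift is detected.
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Poisson log-likelihood up to the constant term, with linear predictor
# eta = offset + X beta.
.pois_loglik <- function(y, eta) sum(y * eta - exp(eta))

#' Posterior sampling for a Poisson log-linear model
#'
#' MCMC backend used by all rate models in the package: a Poisson GLM with a
#' log link, known offset (log exposure) and independent normal priors on the
#' coefficients. Sampling uses random-walk Metropolis preconditioned with the
#' Fisher information at the penalised MLE, with step-scale adaptation during
#' warmup only, run as independent chains. Convergence is monitored with
#' split-Rhat.
#'
#' @param y integer vector of counts.
#' @param X design matrix (rows match `y`); include the intercept column.
#' @param offset log-exposure vector (recycled if length 1).
#' @param prior_sd prior standard deviations for the coefficients, recycled to
#'   `ncol(X)`. The rate-model convention is sd 10 on the intercept and sd 5
#'   on other effects.
#' @param chains,warmup,iter MCMC settings; defaults 4 chains of 1000 warmup
#'   and 3000 retained iterations.
#' @param method proposal scheme: joint preconditioned random walk
#'   (`"joint"`, efficient for a handful of coefficients), component-wise
#'   adaptive updates (`"gibbs"`, mixes better in higher dimension), or
#'   `"auto"` (joint up to 8 coefficients).
#' @param rhat_warn warn if any split-Rhat exceeds this (default 1.01).
#' @return list with `draws` (matrix, `chains * iter` rows, one column per
#'   coefficient), `rhat` (per coefficient), `accept` (mean acceptance rate)
#'   and the inputs needed for pointwise log-likelihoods.
#' @export
mcmc_poisson_glm <- function(y, X, offset = 0, prior_sd = 5,
                             chains = 4, warmup = 1000, iter = 3000,
                             method = c("auto", "joint", "gibbs"),
                             rhat_warn = 1.01) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must match length(y)")
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  offset <- rep_len(offset, n)
  if (any(!is.finite(offset))) stop("offsets must be finite (positive exposure)")
  prior_sd <- rep_len(prior_sd, p)

  log_post <- function(beta) {
    eta <- offset + drop(X %*% beta)
    .pois_loglik(y, eta) - 0.5 * sum((beta / prior_sd)^2)
  }

  # Penalised-MLE start and curvature for the proposal. With all-zero counts
  # the MLE is at -Inf; the prior then dominates, which is flagged, not fatal.
  all_zero <- sum(y) == 0
  if (all_zero) {
    warning("all counts are zero; posterior is dominated by the prior")
    beta0 <- rep(0, p)
    V <- diag(prior_sd^2, p)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, offset = offset, family = stats::poisson())
    )
    beta0 <- fit$coefficients
    beta0[!is.finite(beta0)] <- 0
    w <- fit$weights
    info <- crossprod(X * sqrt(pmax(w, 1e-12))) + diag(1 / prior_sd^2, p)
    V <- tryCatch(solve(info), error = function(e) diag(prior_sd^2, p))
  }
  L <- tryCatch(chol(V), error = function(e) diag(sqrt(diag(V)), p))
  if (method == "auto") method <- if (p > 8) "gibbs" else "joint"

  total <- warmup + iter
  keep <- vector("list", chains)
  acc_all <- numeric(chains)
  if (method == "gibbs") {
    sd0 <- sqrt(diag(V))
    for (ch in seq_len(chains)) {
      beta <- beta0 + stats::rnorm(p, 0, 0.1 * pmin(sd0, 1))
      eta <- offset + drop(X %*% beta)
      ll <- .pois_loglik(y, eta)
      scales <- 2.4 * sd0
      jscale <- 2.38 / sqrt(p)
      acc <- integer(p)
      jacc <- 0L
      n_acc <- 0L
      draws <- matrix(NA_real_, iter, p)
      for (s in seq_len(total)) {
        for (j in seq_len(p)) {
          delta <- stats::rnorm(1, 0, scales[j])
          eta_prop <- eta + X[, j] * delta
          ll_prop <- .pois_loglik(y, eta_prop)
          bj <- beta[j] + delta
          dprior <- (beta[j]^2 - bj^2) / (2 * prior_sd[j]^2)
          if (is.finite(ll_prop) &&
              log(stats::runif(1)) < ll_prop - ll + dprior) {
            beta[j] <- bj
            eta <- eta_prop
            ll <- ll_prop
            acc[j] <- acc[j] + 1L
            if (s > warmup) n_acc <- n_acc + 1L
          }
        }
        # one joint preconditioned move per sweep handles directions in
        # which the coordinates are strongly correlated
        prop <- beta + jscale * drop(stats::rnorm(p) %*% L)
        eta_prop <- offset + drop(X %*% prop)
        ll_prop <- .pois_loglik(y, eta_prop)
        dprior <- sum((beta^2 - prop^2) / (2 * prior_sd^2))
        if (is.finite(ll_prop) &&
            log(stats::runif(1)) < ll_prop - ll + dprior) {
          beta <- prop
          eta <- eta_prop
          ll <- ll_prop
          jacc <- jacc + 1L
        }
        if (s <= warmup && s %% 50L == 0L) {
          scales <- scales * exp(0.8 * (acc / 50 - 0.44))
          jscale <- jscale * exp(0.66 * (jacc / 50 - 0.234))
          acc <- integer(p)
          jacc <- 0L
        }
        if (s > warmup) draws[s - warmup, ] <- beta
      }
      keep[[ch]] <- draws
      acc_all[ch] <- n_acc / (iter * p)
    }
    return(.finish_glm_fit(keep, p, iter, chains, acc_all, rhat_warn,
                           y, X, offset, prior_sd))
  }
  for (ch in seq_len(chains)) {
    beta <- beta0 + drop(rnorm(p, 0, 0.1) %*% L)
    lp <- log_post(beta)
    scale <- 2.38 / sqrt(p)
    draws <- matrix(NA_real_, iter, p)
    n_acc <- 0L
    window_acc <- 0L
    for (s in seq_len(total)) {
      prop <- beta + scale * drop(rnorm(p) %*% L)
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        beta <- prop
        lp <- lp_prop
        window_acc <- window_acc + 1L
        if (s > warmup) n_acc <- n_acc + 1L
      }
      # Robbins-Monro style scale adaptation toward 0.234 acceptance,
      # warmup only so the retained chain is a valid Markov chain.
      if (s <= warmup && s %% 50L == 0L) {
        rate <- window_acc / 50
        scale <- scale * exp(0.66 * (rate - 0.234))
        window_acc <- 0L
      }
      if (s > warmup) draws[s - warmup, ] <- beta
    }
    keep[[ch]] <- draws
    acc_all[ch] <- n_acc / iter
  }

  .finish_glm_fit(keep, p, iter, chains, acc_all, rhat_warn,
                  y, X, offset, prior_sd)
}

.finish_glm_fit <- function(keep, p, iter, chains, acc_all, rhat_warn,
                            y, X, offset, prior_sd) {
  rhat <- vapply(seq_len(p), function(j) {
    split_rhat(vapply(keep, function(d) d[, j], numeric(iter)))
  }, numeric(1))
  if (any(rhat > rhat_warn)) {
    warning(sprintf("split-Rhat above %.3f for coefficient(s): %s",
                    rhat_warn,
                    paste(which(rhat > rhat_warn), collapse = ", ")))
  }
  draws <- do.call(rbind, keep)
  colnames(draws) <- colnames(X)
  list(draws = draws, rhat = rhat, accept = mean(acc_all),
       y = y, X = X, offset = offset, prior_sd = prior_sd)
}

# Pointwise log-likelihood matrix (draws x observations) for information
# criteria; draws are thinned to at most `max_draws` rows.
pointwise_loglik <- function(fit, max_draws = 1000) {
  d <- fit$draws
  idx <- unique(round(seq(1, nrow(d), length.out = min(max_draws, nrow(d)))))
  eta <- tcrossprod(d[idx, , drop = FALSE], fit$X) +
    matrix(fit$offset, length(idx), length(fit$y), byrow = TRUE)
  ll <- matrix(stats::dpois(rep(fit$y, each = length(idx)), exp(eta), log = TRUE),
               length(idx), length(fit$y))
  ll
}

# WAIC (widely applicable information criterion) from a pointwise
# log-likelihood matrix: elpd_hat = lpd - p_waic.
waic_elpd <- function(ll) {
  lpd <- sum(apply(ll, 2, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }))
  p_waic <- sum(apply(ll, 2, stats::var))
  lpd - p_waic
}

#' Adaptive Metropolis sampler for a user-supplied log-posterior
#'
#' Component-wise random-walk Metropolis with per-coordinate step adaptation
#' during warmup. Used for the small non-GLM posteriors in the package
#' (nuclei-count mitosis model).
#'
#' @param log_post function of the parameter vector returning the
#'   unnormalised log posterior.
#' @param init starting parameter vector.
#' @param chains,warmup,iter MCMC settings.
#' @return list with `draws` matrix and `rhat` per coordinate.
#' @export
mcmc_mh <- function(log_post, init, chains = 4, warmup = 1000, iter = 3000) {
  p <- length(init)
  total <- warmup + iter
  keep <- vector("list", chains)
  for (ch in seq_len(chains)) {
    theta <- init + stats::rnorm(p, 0, 0.1)
    lp <- log_post(theta)
    if (!is.finite(lp)) {
      theta <- init
      lp <- log_post(theta)
    }
    scales <- rep(0.5, p)
    acc <- integer(p)
    draws <- matrix(NA_real_, iter, p)
    for (s in seq_len(total)) {
      for (j in seq_len(p)) {
        prop <- theta
        prop[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc[j] <- acc[j] + 1L
        }
      }
      if (s <= warmup && s %% 50L == 0L) {
        scales <- scales * exp(0.8 * (acc / 50 - 0.44))
        acc <- integer(p)
      }
      if (s > warmup) draws[s - warmup, ] <- theta
    }
    keep[[ch]] <- draws
  }
  rhat <- vapply(seq_len(p), function(j) {
    split_rhat(vapply(keep, function(d) d[, j], numeric(iter)))
  }, numeric(1))
  list(draws = do.call(rbind, keep), rhat = rhat)
}
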