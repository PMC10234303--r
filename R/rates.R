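#' Experiment design for an MA rate analysis
#'
#' Bundles the quantities that convert a Poisson intercept into a mutation
#' rate: number of lines, number of transfers, posterior draws of the number
#' of mitoses per transfer, and callable-site totals.
#'
#' @param n_lines number of MA lines (e.g. 39).
#' @param t number of transfers (e.g. 40).
#' @param m_draws posterior draws of mitoses per transfer (a single number is
#'   treated as a point estimate, e.g. 25.375 so that `t * m` = 1015).
#' @param N named or unnamed vector of callable bases per stratum (bp).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(n_lines, t, m_draws, N = NULL) {
  stopifnot(n_lines >= 1, t >= 1, all(m_draws > 0))
  if (!is.null(N) && any(N <= 0)) stop("callable-site totals must be positive")
  structure(list(n_lines = n_lines, t = t, m_draws = m_draws, N = N),
            class = "experiment_design")
}

# Median of m, used where full propagation of mitosis uncertainty is not
# needed (its coefficient of variation is well under 2%).
.m_med <- function(design) stats::median(design$m_draws)

#' Fit the basic Poisson mutation-count model
#'
#' The core intercept-only model: per-line mutation counts
#' `y_i ~ Poisson(lambda_i)` with `log(lambda_i) = alpha + log(exposure_i)`
#' and a weakly regularising `N(0, 10)` prior on the intercept. Sampled with
#' four chains of 1000 warmup + 3000 retained iterations by default.
#'
#' @param counts per-line mutation counts (non-negative integers).
#' @param exposure per-line exposure multiplier (default 1); `exp(alpha)` is
#'   then the expected count per unit exposure.
#' @param prior_sd prior sd of the intercept (default 10).
#' @param chains,warmup,iter MCMC settings.
#' @return a [posterior_summary] of the intercept `alpha`, with the draws and
#'   the split-Rhat attached as attribute `rhat`.
#' @export
fit_poisson_rate <- function(counts, exposure = 1, prior_sd = 10,
                             chains = 4, warmup = 1000, iter = 3000) {
  exposure <- rep_len(exposure, length(counts))
  if (any(exposure <= 0)) stop("exposures must be positive")
  fit <- mcmc_poisson_glm(counts, matrix(1, length(counts), 1,
                                         dimnames = list(NULL, "alpha")),
                          offset = log(exposure), prior_sd = prior_sd,
                          chains = chains, warmup = warmup, iter = iter)
  out <- posterior_summary(fit$draws[, 1L])
  attr(out, "rhat") <- fit$rhat
  out
}

#' Convert a fitted intercept to a mutation rate
#'
#' Per-draw conversion `mu = exp(alpha) / (N * t * m)` (per bp) or
#' `mu = exp(alpha) / (t * m)` (per genome), pairing intercept draws with
#' resampled draws of the mitoses-per-transfer posterior so that uncertainty
#' in the number of mitoses propagates into the rate.
#'
#' @param alpha [posterior_summary] of the intercept from
#'   [fit_poisson_rate()] (per-line scale).
#' @param design [experiment_design].
#' @param N callable bases (bp); required for `per = "bp"`. Ignored for
#'   `per = "genome"`.
#' @param per `"bp"` or `"genome"`.
#' @return object of class `rate_estimate` (a [posterior_summary] with a
#'   `units` field).
#' @export
to_rate <- function(alpha, design, N = NULL, per = c("bp", "genome")) {
  per <- match.arg(per)
  a <- alpha$draws
  m <- design$m_draws
  if (length(m) == 1L) {
    m <- rep(m, length(a))
  } else if (length(m) != length(a)) {
    m <- sample(m, length(a), replace = TRUE)
  }
  denom <- design$t * m
  if (per == "bp") {
    if (is.null(N)) N <- design$N
    if (is.null(N) || length(N) != 1L) {
      stop("`N` (callable bp) is required for a per-bp rate")
    }
    denom <- denom * N
  }
  mu <- exp(a) / denom
  out <- posterior_summary(mu)
  out$units <- sprintf("mutations/%s/mitosis", per)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' @export
print.rate_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s [%s, %s] %s\n", signif(x$median, digits),
              signif(x$lower, digits), signif(x$upper, digits), x$units))
  invisible(x)
}

#' Posterior ratio of two rates
#'
#' Draw-wise ratio of two rate posteriors, with the two-sided decision rule:
#' the rates are flagged as different when 1 lies outside the ratio's 95%
#' HPD interval.
#'
#' @param a,b `rate_estimate` (or `posterior_summary`) objects with matching
#'   units.
#' @return [posterior_summary] of `a / b` with fields `different` (logical)
#'   and `units`.
#' @export
rate_ratio <- function(a, b) {
  ua <- if (!is.null(a$units)) a$units else ""
  ub <- if (!is.null(b$units)) b$units else ""
  if (ua != ub) stop(sprintf("unit mismatch: '%s' vs '%s'", ua, ub))
  x <- a$draws
  y <- b$draws
  if (length(x) != length(y)) y <- sample(y, length(x), replace = TRUE)
  out <- posterior_summary(x / y)
  out$different <- !(1 >= out$lower && 1 <= out$upper)
  out$units <- ""
  out
}

#' Estimate mitoses per transfer from nuclei counts
#'
#' Each transfer of an MA experiment passes through growth phases; in each
#' phase the number of nuclear doublings is `log2(final / initial)` nuclei.
#' Replicate counts carry lognormal measurement error, so observed log2
#' fold-changes are modelled as normal around the phase's true doubling
#' number with a shared noise sd. Mitoses per transfer `m` is the sum of the
#' per-phase doublings; priors are `N(10, 10)` truncated positive on each
#' doubling and half-normal(1) on the noise sd.
#'
#' @param nuclei data frame with columns `phase`, `initial`, `final`
#'   (replicate nuclei counts, >= 1).
#' @param t_transfers number of transfers in the experiment.
#' @param chains,warmup,iter MCMC settings.
#' @return list with `m` ([posterior_summary] of mitoses per transfer),
#'   `total` (posterior of `t * m`), `m_point` (plug-in sum of mean log2
#'   fold-changes), and `draws`.
#' @export
estimate_mitoses <- function(nuclei, t_transfers,
                             chains = 4, warmup = 1000, iter = 3000) {
  stopifnot(all(c("phase", "initial", "final") %in% names(nuclei)),
            nrow(nuclei) >= 1, all(nuclei$initial >= 1),
            all(nuclei$final >= 1), t_transfers >= 1)
  phases <- unique(nuclei$phase)
  r <- log2(nuclei$final / nuclei$initial)
  pid <- match(nuclei$phase, phases)
  for (k in seq_along(phases)) {
    if (all(r[pid == k] < 0)) {
      stop(sprintf("phase '%s': final < initial in all replicates (negative growth unsupported)",
                   phases[k]))
    }
  }
  P <- length(phases)

  log_post <- function(theta) {
    d <- theta[seq_len(P)]
    if (any(d < 0)) return(-Inf)
    tau <- exp(theta[P + 1L])
    sum(stats::dnorm(r, d[pid], tau, log = TRUE)) +
      sum(stats::dnorm(d, 10, 10, log = TRUE)) +
      stats::dnorm(tau, 0, 1, log = TRUE) + theta[P + 1L]  # half-normal + Jacobian
  }
  init <- c(pmax(tapply(r, pid, mean), 0.01), log(max(stats::sd(r), 0.05, na.rm = TRUE)))
  fit <- mcmc_mh(log_post, unname(init), chains = chains,
                 warmup = warmup, iter = iter)
  m_draws <- rowSums(fit$draws[, seq_len(P), drop = FALSE])
  list(m = posterior_summary(m_draws),
       total = posterior_summary(t_transfers * m_draws),
       m_point = sum(tapply(r, pid, mean)),
       draws = m_draws, rhat = fit$rhat)
}

# ---- windowed mutation-rate model --------------------------------------

.window_design_matrix <- function(windows, predictors, gc_mean, gc_sd) {
  gc_std <- (windows$gc_fraction - gc_mean) / gc_sd
  k9 <- as.numeric(windows$domain == "H3K9me3")
  k27 <- as.numeric(windows$domain == "H3K27me3")
  cen <- as.numeric(windows$centromeric)
  cols <- list(intercept = rep(1, nrow(windows)))
  for (p in predictors) {
    cols[[p]] <- switch(p,
      gc = gc_std, K9 = k9, K27 = k27, cen = cen,
      `gc:K9` = gc_std * k9, `gc:K27` = gc_std * k27,
      stop("unknown predictor: ", p))
  }
  do.call(cbind, cols)
}

#' Fit a windowed mutation-rate model with GC and chromatin predictors
#'
#' Poisson regression of per-window mutation counts (summed over lines) on
#' GC-content and chromatin-domain indicators, with offset
#' `log(callable_bp * n_lines * t * m)` so that `exp(X beta)` is a rate in
#' mutations/bp/mitosis. GC is standardised internally. The default predictor
#' set is GC, H3K9me3, H3K27me3, centromere and the GC-by-H3K9me3
#' interaction. Windows with no callable base are dropped. Identical
#' covariate rows are aggregated before sampling (exact for a Poisson
#' likelihood), and the aggregation is independent of the predictor set so
#' that models fitted to the same windows are comparable with
#' [model_weights()].
#'
#' @param window_counts integer vector of mutation counts per window, aligned
#'   with `windows`.
#' @param windows `WindowTable` from [make_windows()].
#' @param design [experiment_design()]; the posterior median of `m` enters
#'   the offset.
#' @param predictors character vector among `"gc"`, `"K9"`, `"K27"`,
#'   `"cen"`, `"gc:K9"`, `"gc:K27"`; the intercept is always included.
#' @param prior_sd prior sd: 10 for the intercept, 5 for the effects.
#' @param chains,warmup,iter MCMC settings.
#' @return object of class `rate_model`: coefficient draws, predictor names,
#'   GC standardisation constants, WAIC-style elpd and the aggregated data.
#' @export
fit_domain_gc_model <- function(window_counts, windows, design,
                                predictors = c("gc", "K9", "K27", "cen", "gc:K9"),
                                prior_sd = 5,
                                chains = 4, warmup = 1000, iter = 3000) {
  stopifnot(length(window_counts) == nrow(windows))
  keep <- windows$callable_bp > 0 & !is.na(windows$gc_fraction)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("dropping %d window(s) with no callable bases", n_drop))
  }
  w <- windows[keep, , drop = FALSE]
  y <- window_counts[keep]
  exposure <- w$callable_bp * design$n_lines * design$t * .m_med(design)

  # exact aggregation over identical covariate rows (always the full set)
  key <- paste(w$gc_fraction, w$domain, w$centromeric, sep = "|")
  grp <- match(key, unique(key))
  y_agg <- as.integer(rowsum(y, grp))
  e_agg <- as.numeric(rowsum(exposure, grp))
  first <- !duplicated(grp)
  w_agg <- w[first, c("gc_fraction", "domain", "centromeric")]

  gc_mean <- stats::weighted.mean(w$gc_fraction, w$callable_bp)
  gc_sd <- stats::sd(w$gc_fraction)
  if (gc_sd == 0) gc_sd <- 1
  X <- .window_design_matrix(w_agg, predictors, gc_mean, gc_sd)
  psd <- c(10, rep(prior_sd, length(predictors)))
  fit <- mcmc_poisson_glm(y_agg, X, offset = log(e_agg), prior_sd = psd,
                          chains = chains, warmup = warmup, iter = iter)
  ll <- pointwise_loglik(fit)
  structure(
    list(draws = fit$draws, predictors = predictors,
         gc_mean = gc_mean, gc_sd = gc_sd,
         elpd = waic_elpd(ll), rhat = fit$rhat,
         data = list(y = y_agg, exposure = e_agg, covariates = w_agg)),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, digits = 3, ...) {
  cat("Windowed Poisson mutation-rate model\n")
  cat("predictors:", paste(colnames(x$draws), collapse = ", "), "\n")
  for (j in seq_len(ncol(x$draws))) {
    h <- hpdi(x$draws[, j])
    cat(sprintf("  %-10s %8s [%s, %s]\n", colnames(x$draws)[j],
                signif(stats::median(x$draws[, j]), digits),
                signif(h[1], digits), signif(h[2], digits)))
  }
  invisible(x)
}

#' Posterior predicted log10 mutation rate per window
#'
#' @param model `rate_model` from [fit_domain_gc_model()].
#' @param windows `WindowTable`; windows with missing GC get `NA`.
#' @param summary `"median"` (default) for the posterior-median rate, or
#'   `"draws"` for the full draws matrix (windows in columns).
#' @return numeric vector of log10(mutations/bp/mitosis), or a draws matrix.
#' @export
predict_log10_mu <- function(model, windows, summary = c("median", "draws")) {
  summary <- match.arg(summary)
  ok <- !is.na(windows$gc_fraction)
  X <- .window_design_matrix(windows[ok, , drop = FALSE], model$predictors,
                             model$gc_mean, model$gc_sd)
  eta <- tcrossprod(model$draws, X)  # draws x windows, natural log rate
  if (summary == "draws") {
    out <- matrix(NA_real_, nrow(model$draws), nrow(windows))
    out[, ok] <- eta / log(10)
    return(out)
  }
  med <- apply(eta, 2, stats::median) / log(10)
  out <- rep(NA_real_, nrow(windows))
  out[ok] <- med
  out
}

#' Pseudo-BMA model weights
#'
#' Converts WAIC-style expected log predictive densities of competing
#' models, fitted to identical data rows, into weights proportional to
#' `exp(elpd_k - max(elpd))` (pseudo-Bayesian model averaging).
#'
#' @param models list of `rate_model` objects from [fit_domain_gc_model()].
#' @return numeric vector of weights summing to 1, ordered as the input,
#'   with the elpd values as attribute `elpd`.
#' @export
model_weights <- function(models) {
  stopifnot(length(models) >= 2)
  ref <- models[[1]]$data
  for (m in models[-1]) {
    if (!isTRUE(all.equal(m$data$y, ref$y)) ||
        !isTRUE(all.equal(m$data$exposure, ref$exposure))) {
      stop("models were not fitted to identical data rows")
    }
  }
  elpd <- vapply(models, function(m) m$elpd, numeric(1))
  w <- exp(elpd - max(elpd))
  w <- w / sum(w)
  attr(w, "elpd") <- elpd
  w
}
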