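#' The six strand-collapsed substitution classes
#'
#' Because the strand on which a mutation occurred is unknown, substitutions
#' are collapsed to base-pair changes, giving two transitions and four
#' transversions. The display order is fixed for all outputs.
#'
#' @export
SNM_CLASSES <- c("C:G>T:A", "A:T>G:C", "C:G>A:T",
                 "C:G>G:C", "A:T>C:G", "A:T>T:A")

SNM_TRANSITIONS <- c("C:G>T:A", "A:T>G:C")

#' Classify a single-nucleotide mutation
#'
#' Maps `ref -> alt` to one of the six base-pair substitution classes,
#' collapsing strands (so `G>A` is the same class as `C>T`).
#'
#' @param ref,alt reference and alternate bases (vectors over A/C/G/T).
#' @return character vector of classes (see [SNM_CLASSES]).
#' @examples
#' classify_snm("C", "T")  # "C:G>T:A"
#' classify_snm("G", "A")  # same class, complementary strand
#' @export
classify_snm <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("ref and alt must be single bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  key <- paste0(ref, alt)
  map <- c(CT = "C:G>T:A", AG = "A:T>G:C", CA = "C:G>A:T",
           CG = "C:G>G:C", AC = "A:T>C:G", AT = "A:T>T:A")
  unname(map[key])
}

#' Spectrum counts for a set of mutations
#'
#' Tallies the six substitution classes for the SNMs in an annotated
#' mutation table, together with the source base-pair composition needed for
#' frequency-corrected rates.
#'
#' @param annotated annotated mutation table (see [annotate_mutations()]).
#' @param composition data frame from [composition_table()].
#' @param domain restrict to a domain label (`"euchromatin"`, `"H3K9me3"`,
#'   `"H3K27me3"`) or `NULL` for genome-wide.
#' @return object of class `spectrum_counts`: list with `counts` (named
#'   vector over [SNM_CLASSES]), `at_pairs`, `cg_pairs`, `domain`.
#' @export
spectrum_counts <- function(annotated, composition, domain = NULL) {
  snms <- annotated[annotated$kind == "snm", , drop = FALSE]
  if (!is.null(domain)) {
    snms <- snms[snms$domain == domain, , drop = FALSE]
    rows <- if (domain == "H3K9me3") {
      composition$stratum %in% c("H3K9me3", "centromeric")
    } else composition$stratum == domain
  } else {
    rows <- rep(TRUE, nrow(composition))
  }
  cls <- classify_snm(snms$ref, snms$alt)
  counts <- table(factor(cls, levels = SNM_CLASSES))
  structure(
    list(counts = setNames(as.integer(counts), SNM_CLASSES),
         at_pairs = sum(composition$at_pairs[rows]),
         cg_pairs = sum(composition$cg_pairs[rows]),
         domain = if (is.null(domain)) "genome" else domain),
    class = "spectrum_counts"
  )
}

.source_pair <- function(classes) ifelse(grepl("^C:G", classes), "C:G", "A:T")

# Per-class Poisson rate draws with offset census * exposure; returns a
# draws matrix (one column per class).
.class_rate_draws <- function(counts, census, exposure = 1,
                              chains = 4, warmup = 1000, iter = 3000) {
  if (any(census <= 0 & counts > 0)) {
    stop("class with nonzero count but zero census")
  }
  draws <- matrix(NA_real_, chains * iter, length(counts))
  colnames(draws) <- names(counts)
  for (j in seq_along(counts)) {
    if (census[j] <= 0) next
    ps <- fit_poisson_rate(counts[j], exposure = census[j] * exposure,
                           chains = chains, warmup = warmup, iter = iter)
    draws[, j] <- exp(ps$draws)
  }
  draws
}

#' Frequency-corrected relative SNM rates
#'
#' Per-class Poisson rate posteriors with the source base-pair census as
#' exposure, renormalised draw-wise to sum to one across the six classes so
#' that the equal-rates expectation sits at 1/6.
#'
#' @param spec `spectrum_counts`.
#' @param chains,warmup,iter MCMC settings.
#' @return list with `summary` (data frame of class, count, median and HPD
#'   bounds of the normalised rate) and `draws` (normalised draws matrix).
#' @export
relative_rates <- function(spec, chains = 4, warmup = 1000, iter = 3000) {
  census <- ifelse(.source_pair(SNM_CLASSES) == "C:G",
                   spec$cg_pairs, spec$at_pairs)
  draws <- .class_rate_draws(spec$counts, census,
                             chains = chains, warmup = warmup, iter = iter)
  norm <- draws / rowSums(draws)
  summary <- data.frame(
    class = SNM_CLASSES, count = spec$counts,
    median = apply(norm, 2, stats::median),
    t(apply(norm, 2, hpdi)), row.names = NULL
  )
  list(summary = summary, draws = norm, raw_rate_draws = draws)
}

#' Transition/transversion rate ratio
#'
#' Posterior ratio of summed transition to summed transversion rates. The
#' default corrects for base-pair frequencies (rates per source pair); with
#' `corrected = FALSE` the raw count rates are used.
#'
#' @param spec `spectrum_counts`.
#' @param corrected frequency-correct the class rates (default TRUE).
#' @param chains,warmup,iter MCMC settings.
#' @return [posterior_summary] of the Ts/Tv ratio.
#' @export
ts_tv <- function(spec, corrected = TRUE,
                  chains = 4, warmup = 1000, iter = 3000) {
  is_ts <- SNM_CLASSES %in% SNM_TRANSITIONS
  if (sum(spec$counts[!is_ts]) == 0) {
    stop("no transversions observed; Ts/Tv posterior undefined")
  }
  census <- if (corrected) {
    ifelse(.source_pair(SNM_CLASSES) == "C:G", spec$cg_pairs, spec$at_pairs)
  } else rep(1, 6)
  draws <- .class_rate_draws(spec$counts, census,
                             chains = chains, warmup = warmup, iter = iter)
  posterior_summary(rowSums(draws[, is_ts]) / rowSums(draws[, !is_ts]))
}

#' Genome-wide trinucleotide mutability weights
#'
#' Relative per-class mutability (count / census, scaled to mean 1) used by
#' the trinucleotide-frequency correction of [domain_spectrum_ratio()].
#'
#' @param counts32 named vector of genome-wide mutation counts per
#'   trinucleotide class.
#' @param census32 matching census (positions per class).
#' @return named numeric vector of 32 weights.
#' @export
trinuc_weights <- function(counts32, census32) {
  w <- ifelse(census32 > 0, counts32 / census32, 0)
  w / mean(w[census32 > 0])
}

# middle base of the canonical representative
.focal_pair32 <- function(classes = trinuc_classes()) {
  mid <- substr(sub(":.*", "", classes), 2, 2)
  ifelse(mid %in% c("C", "G"), "C:G", "A:T")
}

#' Domain-versus-domain spectrum ratios
#'
#' Per-class ratio of frequency-corrected relative rates between two domains
#' (typically H3K9me3 over euchromatin). Under the nucleotide correction the
#' class exposure is the domain's source base-pair census; under the
#' trinucleotide correction it is the domain's trinucleotide census with the
#' matching focal pair, weighted by genome-wide per-class mutability (so the
#' correction acts only through the census/exposure terms). A class is
#' flagged different when 1 lies outside the ratio's 95% HPD interval;
#' classes with zero counts in both domains are returned as undefined.
#'
#' @param specA,specB `spectrum_counts` of the two domains (A / B).
#' @param correction `"nucleotide"` or `"trinucleotide"`.
#' @param censusA,censusB 32-class trinucleotide censuses of the two domains
#'   (required for the trinucleotide correction).
#' @param weights genome-wide mutability weights from [trinuc_weights()]
#'   (trinucleotide correction only; uniform weights if omitted).
#' @param chains,warmup,iter MCMC settings.
#' @return data frame per class: counts, ratio median, HPD bounds,
#'   `different`, `undefined`.
#' @export
domain_spectrum_ratio <- function(specA, specB,
                                  correction = c("nucleotide", "trinucleotide"),
                                  censusA = NULL, censusB = NULL,
                                  weights = NULL,
                                  chains = 4, warmup = 1000, iter = 3000) {
  correction <- match.arg(correction)
  src <- .source_pair(SNM_CLASSES)
  if (correction == "nucleotide") {
    expA <- ifelse(src == "C:G", specA$cg_pairs, specA$at_pairs)
    expB <- ifelse(src == "C:G", specB$cg_pairs, specB$at_pairs)
  } else {
    if (is.null(censusA) || is.null(censusB)) {
      stop("trinucleotide correction needs censusA and censusB")
    }
    if (is.null(weights)) weights <- setNames(rep(1, 32), trinuc_classes())
    focal <- .focal_pair32()
    wsum <- function(census) {
      vapply(src, function(p) sum(census[focal == p] * weights[focal == p]),
             numeric(1))
    }
    expA <- wsum(censusA)
    expB <- wsum(censusB)
  }
  dA <- .class_rate_draws(specA$counts, expA, chains = chains,
                          warmup = warmup, iter = iter)
  dB <- .class_rate_draws(specB$counts, expB, chains = chains,
                          warmup = warmup, iter = iter)
  out <- data.frame(class = SNM_CLASSES, count_a = specA$counts,
                    count_b = specB$counts, median = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    different = NA, undefined = FALSE)
  for (j in seq_len(6)) {
    if (specA$counts[j] == 0 && specB$counts[j] == 0) {
      out$undefined[j] <- TRUE
      next
    }
    r <- dA[, j] / dB[, j]
    h <- hpdi(r)
    out$median[j] <- stats::median(r)
    out$lower[j] <- h[1]
    out$upper[j] <- h[2]
    out$different[j] <- !(1 >= h[1] && 1 <= h[2])
  }
  out
}

#' Trinucleotide-class mutation-rate model
#'
#' Poisson model for mutation counts per trinucleotide class and stratum
#' with offset `log(census * n_lines * t * m)`: 32 class effects plus
#' additive H3K9me3, centromere and H3K27me3 effects, no class-by-domain
#' interactions. Reports draw-normalised per-class relative rates (so the
#' equal-rates line is 1/32) and the domain fold-changes.
#'
#' @param counts32 matrix 32 classes x strata (columns among
#'   euchromatin/H3K27me3/H3K9me3/centromeric) of mutation counts.
#' @param census32 matching trinucleotide census matrix.
#' @param design [experiment_design()].
#' @param chains,warmup,iter MCMC settings.
#' @return list with `classes` (data frame of per-class relative rates with
#'   HPD bounds), `folds` (posterior summaries of the H3K9me3, centromere
#'   and H3K27me3 fold-changes), `class_draws`, `fold_draws`.
#' @export
trinuc_model <- function(counts32, census32, design,
                         chains = 4, warmup = 1000, iter = 3000) {
  strata <- colnames(counts32)
  stopifnot(nrow(counts32) == 32, all(dim(counts32) == dim(census32)))
  cls <- rownames(counts32)
  long <- expand.grid(class = seq_len(32), stratum = seq_along(strata))
  y <- counts32[as.matrix(long)]
  census <- census32[as.matrix(long)]
  keep_class <- rowSums(census32) > 0
  if (!all(keep_class)) {
    warning(sprintf("dropping %d structurally empty class(es)",
                    sum(!keep_class)))
  }
  keep <- census > 0 & keep_class[long$class]
  long <- long[keep, ]
  y <- y[keep]
  exposure <- census[keep] * design$n_lines * design$t * .m_med(design)

  used <- which(keep_class)
  Xc <- matrix(0, nrow(long), length(used))
  Xc[cbind(seq_len(nrow(long)), match(long$class, used))] <- 1
  colnames(Xc) <- cls[used]
  s <- strata[long$stratum]
  Xd <- cbind(K9 = as.numeric(s %in% c("H3K9me3", "centromeric")),
              cen = as.numeric(s == "centromeric"),
              K27 = as.numeric(s == "H3K27me3"))
  Xd <- Xd[, colSums(Xd) > 0, drop = FALSE]
  X <- cbind(Xc, Xd)
  psd <- c(rep(10, ncol(Xc)), rep(5, ncol(Xd)))
  fit <- mcmc_poisson_glm(y, X, offset = log(exposure), prior_sd = psd,
                          chains = chains, warmup = warmup, iter = iter)

  class_draws <- exp(fit$draws[, seq_len(ncol(Xc)), drop = FALSE])
  class_draws <- class_draws / rowSums(class_draws)
  classes <- data.frame(
    class = cls[used],
    count = rowSums(counts32)[used],
    census = rowSums(census32)[used],
    median = apply(class_draws, 2, stats::median),
    t(apply(class_draws, 2, hpdi)), row.names = NULL
  )
  fold_draws <- exp(fit$draws[, ncol(Xc) + seq_len(ncol(Xd)), drop = FALSE])
  folds <- lapply(seq_len(ncol(Xd)), function(j) posterior_summary(fold_draws[, j]))
  names(folds) <- colnames(Xd)
  list(classes = classes, folds = folds,
       class_draws = class_draws, fold_draws = fold_draws, rhat = fit$rhat)
}

#' Flanking-base effects on trinucleotide mutation rates
#'
#' Measurement-error regression of log relative mutation rate per
#' trinucleotide class on indicators for the focal pair and the flanking
#' bases of the canonical representative:
#' `intercept + beta_b [focal C:G] + beta_5 [5' C:G] + beta_3 [3' C:G] +
#' beta_I5 [focal][5'] + beta_I3 [focal][3']`.
#' Each class's response sd is taken from its posterior sd (a known
#' measurement sd), making the coefficient posterior multivariate normal in
#' closed form; it is reported from exact draws. A coefficient is flagged
#' significant when 0 lies outside its 95% HPD interval.
#'
#' @param trinuc result of [trinuc_model()], or a list with `class_draws`
#'   and `classes`.
#' @param prior_sd prior sd on the coefficients (default 5).
#' @param n_draws posterior draws to generate (default 12000).
#' @param sd_floor lower bound applied to degenerate measurement sds.
#' @return list with `summary` (data frame per coefficient: median, HPD
#'   bounds, significant), `draws` and the design matrix used.
#' @export
flanking_effects <- function(trinuc, prior_sd = 5, n_draws = 12000,
                             sd_floor = 1e-3) {
  draws <- log(trinuc$class_draws)
  y <- colMeans(draws)
  s <- apply(draws, 2, stats::sd)
  if (any(s < sd_floor)) {
    message(sprintf("flooring %d degenerate measurement sd(s) at %g",
                    sum(s < sd_floor), sd_floor))
    s <- pmax(s, sd_floor)
  }
  cls <- trinuc$classes$class
  rep5 <- substr(cls, 1, 1)
  mid <- substr(cls, 2, 2)
  rep3 <- substr(cls, 3, 3)
  b <- as.numeric(mid %in% c("C", "G"))
  f5 <- as.numeric(rep5 %in% c("C", "G"))
  f3 <- as.numeric(rep3 %in% c("C", "G"))
  X <- cbind(intercept = 1, beta_b = b, beta_5 = f5, beta_3 = f3,
             beta_I5 = b * f5, beta_I3 = b * f3)
  # Gaussian likelihood with known sds + normal prior => exact MVN posterior
  W <- 1 / s^2
  prec <- crossprod(X * sqrt(W)) + diag(1 / prior_sd^2, ncol(X))
  Sigma <- solve(prec)
  mu <- drop(Sigma %*% crossprod(X, W * y))
  L <- chol(Sigma)
  bd <- matrix(stats::rnorm(n_draws * ncol(X)), n_draws) %*% L +
    matrix(mu, n_draws, ncol(X), byrow = TRUE)
  colnames(bd) <- colnames(X)
  summary <- data.frame(
    coefficient = colnames(X),
    median = apply(bd, 2, stats::median),
    t(apply(bd, 2, hpdi)), row.names = NULL
  )
  summary$significant <- !(summary$lower <= 0 & summary$upper >= 0)
  list(summary = summary, draws = bd, X = X, response = y, response_sd = s)
}
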