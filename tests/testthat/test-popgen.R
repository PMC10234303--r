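test_that("Watterson's theta handles missing data site by site", {
  # complete data, n = 4, S = 2, L = 200: theta = 2 / a4 / 200
  g <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L))
  res <- theta_w(g, 200)
  expect_equal(res$theta, 2 / (1 + 1 / 2 + 1 / 3) / 200, tolerance = 1e-12)
  expect_equal(res$n_segregating, 2L)

  # no segregating sites
  expect_equal(theta_w(matrix(0L, 5, 4), 100)$theta, 0)

  # knocking one segregating site down to n = 2 increases theta (a2 < a4)
  g2 <- g
  g2[1, c(2, 3)] <- NA
  expect_gt(theta_w(g2, 200)$theta, res$theta)

  # sites with fewer than 2 calls are skipped
  g3 <- rbind(c(0L, NA, NA, NA), c(0L, 1L, NA, NA))
  expect_equal(theta_w(g3, 100)$theta, 1 / 1 / 100)
  expect_error(theta_w(g, 0), "positive")
})

test_that("theta matches a brute-force oracle on random alignments", {
  set.seed(501)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    S <- sample(1:40, 1)
    geno <- matrix(rbinom(S * n, 1, runif(1, 0.05, 0.5)), S, n)
    if (rep > 25) {
      # with missingness in the second half of the cases
      geno[runif(length(geno)) < 0.3] <- NA
    }
    L <- sample(100:1000, 1)
    expect_equal(theta_w(geno, L)$theta, brute_theta(geno, L),
                 tolerance = 1e-12)
  }
})

test_that("windowed theta respects the callable threshold", {
  set.seed(502)
  s <- paste0(rand_dna(300), strrep("N", 150), rand_dna(150))
  ann <- make_test_ann(c(c1 = s))
  w <- make_windows(ann, 200)
  expect_equal(w$callable_bp, c(200, 100, 150))
  snp <- snp_matrix(data.frame(contig = "c1", pos = c(50L, 250L, 460L)),
                    matrix(c(0L, 1L, 0L, 1L,
                             0L, 1L, 1L, 1L,
                             0L, 0L, 1L, 0L), 3, 4, byrow = TRUE))
  tw <- theta_windows(snp, w, min_callable = 0.7)
  expect_false(is.na(tw$theta[1]))
  expect_true(is.na(tw$theta[2]))    # 100/200 callable < 0.7
  expect_equal(tw$n_segregating[3], 1L)
  tw2 <- theta_windows(snp, w, min_callable = 0.5)
  expect_false(any(is.na(tw2$theta)))
})

test_that("window predictions follow the fitted coefficients", {
  set.seed(503)
  cfg <- sim_config()
  sim <- simulate_genome(cfg)
  ma <- simulate_ma_experiment(sim, cfg)
  design <- experiment_design(cfg$n_lines, cfg$t, cfg$m)
  w <- ma$windows
  snm <- ma$mutations[ma$mutations$kind == "snm", ]
  wkey <- paste(w$contig, (w$start - 1) %/% 200)
  counts <- as.integer(table(factor(paste(snm$contig, (snm$pos - 1) %/% 200),
                                    levels = wkey)))
  model <- suppressWarnings(
    fit_domain_gc_model(counts, w, design, chains = fast$chains,
                        warmup = fast$warmup, iter = fast$iter))

  # identity: euchromatic window at the model's mean GC predicts the
  # intercept-implied rate
  fake <- data.frame(contig = "x", start = 1, end = 200,
                     gc_fraction = model$gc_mean,
                     domain = c("euchromatin", "H3K9me3"),
                     centromeric = FALSE, callable_bp = 200)
  pred <- predict_log10_mu(model, fake)
  expect_equal(pred[1], median(model$draws[, "intercept"]) / log(10),
               tolerance = 1e-6)
  # closed form: K9 window at the same GC differs by the K9 coefficient
  k9_diff <- median(model$draws[, "intercept"] + model$draws[, "K9"]) / log(10)
  expect_equal(pred[2], k9_diff, tolerance = 1e-6)

  # rank correlation between predicted and generating rates
  pred_all <- predict_log10_mu(model, w)
  truth <- ma$truth$log10_mu_windows
  expect_gt(cor(pred_all, truth, method = "spearman", use = "complete.obs"),
            0.95)
})

test_that("diversity regression recovers slope, R2 limits, and the null", {
  set.seed(504)
  x <- runif(5000, -9.5, -7.5)
  # noise-free linear data: slope exact, R2 -> 1
  y0 <- 0.0096 * x + 0.1
  r0 <- diversity_regression(y0 + rnorm(5000, 0, 1e-8), x)
  expect_equal(r0$slope$median, 0.0096, tolerance = 1e-3)
  expect_gt(r0$r2$median, 0.999)

  # realistic noise: slope HPDI covers the generating value
  y <- 0.0096 * x + 0.1 + rnorm(5000, 0, 0.01)
  r1 <- diversity_regression(y, x)
  expect_true(r1$slope$lower <= 0.0096 && 0.0096 <= r1$slope$upper)

  # predictor-independent response: slope ~ 0, R2 ~ 0
  y2 <- 0.02 + rnorm(5000, 0, 0.01)
  r2 <- diversity_regression(y2, x)
  expect_true(r2$slope$lower <= 0 && 0 <= r2$slope$upper)
  expect_lt(r2$r2$median, 0.01)

  expect_error(diversity_regression(y[1:50], x[1:50]), "100")
  expect_error(diversity_regression(y, rep(1, 5000)), "variance")

  # hurdle variant: same positive-part slope structure
  yz <- pmax(y + rnorm(5000, 0, 0.005) - 0.002, 0)
  rh <- diversity_regression(yz, x, hurdle = TRUE)
  expect_true(is.finite(rh$slope$median))
  expect_gte(rh$prop_positive, 0.5)
})

test_that("domain theta contrasts recover simulated differences", {
  set.seed(505)
  tw <- data.frame(
    stratum = rep(c("euchromatin", "H3K9me3"), c(3000, 800)),
    theta = c(rnorm(3000, 0.015, 0.004), rnorm(800, 0.031, 0.008))
  )
  dc <- domain_theta_contrast(tw)
  eu <- dc$medians[dc$medians$stratum == "euchromatin", ]
  expect_lt(abs(eu$median - 0.015), 0.002)
  k9 <- dc$contrasts[dc$contrasts$stratum == "H3K9me3", ]
  expect_true(k9$lower <= 0.016 && 0.016 <= k9$upper)

  # identical distributions: difference ~ 0
  tw2 <- tw
  tw2$theta <- rnorm(nrow(tw2), 0.02, 0.005)
  dc2 <- domain_theta_contrast(tw2)
  k9b <- dc2$contrasts[dc2$contrasts$stratum == "H3K9me3", ]
  expect_true(k9b$lower <= 0 && 0 <= k9b$upper)

  # single stratum: medians only
  dc3 <- domain_theta_contrast(tw[tw$stratum == "euchromatin", ])
  expect_null(dc3$contrasts)
  expect_equal(nrow(dc3$medians), 1L)
})

test_that("simulated populations give unbiased theta with and without missingness", {
  set.seed(506)
  cfg0 <- sim_config(contig_lengths = c(100000L), frac_k9 = 0, frac_k27 = 0,
                     frac_cen_of_k9 = 0, gc_slope = 0, gc_k9_slope = 0,
                     missing_rate = 0)
  sim <- simulate_genome(cfg0)
  w <- make_windows(sim$ann, 200)
  pop0 <- simulate_population(sim, cfg0, windows = w)
  tw0 <- theta_windows(pop0$snp, w)
  target <- mean(pop0$theta_target, na.rm = TRUE)
  m0 <- mean(tw0$theta, na.rm = TRUE)
  se0 <- sd(tw0$theta, na.rm = TRUE) / sqrt(sum(!is.na(tw0$theta)))
  expect_lt(abs(m0 - target), 3 * se0 + 1e-5)

  # i.i.d. missingness leaves the estimator unbiased
  cfg3 <- sim_config(contig_lengths = c(100000L), frac_k9 = 0, frac_k27 = 0,
                     frac_cen_of_k9 = 0, gc_slope = 0, gc_k9_slope = 0,
                     missing_rate = 0.3)
  pop3 <- simulate_population(sim, cfg3, windows = w)
  tw3 <- theta_windows(pop3$snp, w)
  m3 <- mean(tw3$theta, na.rm = TRUE)
  se3 <- sd(tw3$theta, na.rm = TRUE) / sqrt(sum(!is.na(tw3$theta)))
  expect_lt(abs(m3 - target), 3 * se3 + 1e-5)

  # two strains: every segregating site uses a2 = 1, so theta is the
  # segregating-site density
  cfg2 <- sim_config(contig_lengths = c(50000L), frac_k9 = 0, frac_k27 = 0,
                     frac_cen_of_k9 = 0, gc_slope = 0, gc_k9_slope = 0,
                     n_strains = 2L, missing_rate = 0)
  sim2 <- simulate_genome(cfg2, seed = 508)
  pop2 <- simulate_population(sim2, cfg2)
  w2 <- make_windows(sim2$ann, 200)
  tw2 <- theta_windows(pop2$snp, w2)
  expect_equal(sum(tw2$theta * tw2$callable_bp, na.rm = TRUE),
               nrow(pop2$snp$geno))
})

test_that("VCF round trip preserves haploid genotypes and missingness", {
  set.seed(507)
  sites <- data.frame(contig = rep("c1", 30), pos = sort(sample(1000, 30)))
  geno <- matrix(rbinom(30 * 8, 1, 0.3), 30, 8)
  geno[runif(length(geno)) < 0.2] <- NA
  colnames(geno) <- sprintf("s%d", 1:8)
  snp <- snp_matrix(sites, geno)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(snp, path)
  back <- read_haploid_vcf(path)
  expect_equal(back$sites$pos, sites$pos)
  expect_equal(unname(back$geno), unname(geno))
})
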