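test_that("SNM classification collapses strands into six classes", {
  expect_equal(classify_snm("C", "T"), "C:G>T:A")
  expect_equal(classify_snm("G", "A"), "C:G>T:A")
  expect_equal(classify_snm("A", "C"), "A:T>C:G")
  expect_error(classify_snm("C", "C"), "differ")
  expect_error(classify_snm("N", "A"), "bases")
  # strand involution over all 12 ordered base pairs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) {
    for (a in setdiff(names(comp), r)) {
      expect_equal(classify_snm(r, a), classify_snm(comp[[r]], comp[[a]]))
    }
  }
  expect_setequal(
    unique(vapply(list(c("C","T"), c("A","G"), c("C","A"), c("C","G"),
                       c("A","C"), c("A","T")),
                  function(p) classify_snm(p[1], p[2]), "")),
    SNM_CLASSES)
})

test_that("relative rates sit at 1/6 under symmetry and follow count proportions", {
  comp <- data.frame(stratum = STRATA, callable_bp = 4e5,
                     at_pairs = 2e5, cg_pairs = 2e5)
  mk_spec <- function(counts) {
    structure(list(counts = setNames(counts, SNM_CLASSES),
                   at_pairs = 8e5, cg_pairs = 8e5, domain = "genome"),
              class = "spectrum_counts")
  }
  set.seed(301)
  rr <- suppressWarnings(
    relative_rates(mk_spec(rep(40L, 6)), chains = fast$chains,
                   warmup = fast$warmup, iter = fast$iter))
  expect_equal(rr$summary$median, rep(1 / 6, 6), tolerance = 0.06)
  expect_equal(sum(rr$summary$median), 1, tolerance = 0.01)

  # frequency-correction identity: uniform composition -> count proportions
  cts <- c(120L, 60L, 30L, 30L, 30L, 30L)
  rr2 <- suppressWarnings(
    relative_rates(mk_spec(cts), chains = fast$chains,
                   warmup = fast$warmup, iter = fast$iter))
  expect_equal(rr2$summary$median, cts / sum(cts), tolerance = 0.05)

  # one dominant class
  rr3 <- suppressWarnings(
    relative_rates(mk_spec(c(200L, 1L, 0L, 0L, 1L, 0L)),
                   chains = fast$chains, warmup = fast$warmup,
                   iter = fast$iter))
  expect_gt(rr3$summary$median[1], 0.9)
  expect_error(relative_rates(structure(list(
    counts = setNames(c(1L, rep(0L, 5)), SNM_CLASSES),
    at_pairs = 10, cg_pairs = 0, domain = "genome"),
    class = "spectrum_counts")), "zero census")
})

test_that("Ts/Tv behaves under symmetry, count doubling, and zero transversions", {
  mk_spec <- function(counts, at = 5e5, cg = 5e5) {
    structure(list(counts = setNames(counts, SNM_CLASSES),
                   at_pairs = at, cg_pairs = cg, domain = "genome"),
              class = "spectrum_counts")
  }
  set.seed(302)
  eq <- mk_spec(c(60L, 60L, 30L, 30L, 30L, 30L))
  r1 <- suppressWarnings(
    ts_tv(eq, chains = fast$chains, warmup = fast$warmup, iter = fast$iter))
  expect_equal(r1$median, 1, tolerance = 0.06)

  dbl <- mk_spec(2L * c(60L, 60L, 30L, 30L, 30L, 30L))
  r2 <- suppressWarnings(
    ts_tv(dbl, chains = fast$chains, warmup = fast$warmup, iter = fast$iter))
  expect_equal(r2$median, r1$median, tolerance = 0.06)
  expect_lt(diff(hpdi(r2$draws)), diff(hpdi(r1$draws)))

  expect_error(ts_tv(mk_spec(c(10L, 10L, 0L, 0L, 0L, 0L))), "transversions")
})

test_that("domain spectrum ratios flag simulated enrichment and respect censuses", {
  set.seed(303)
  mk_spec <- function(counts, at, cg) {
    structure(list(counts = setNames(counts, SNM_CLASSES),
                   at_pairs = at, cg_pairs = cg, domain = "x"),
              class = "spectrum_counts")
  }
  # identical spectra and compositions: no class flagged
  s <- mk_spec(c(50L, 50L, 25L, 25L, 25L, 25L), 4e5, 4e5)
  same <- suppressWarnings(
    domain_spectrum_ratio(s, s, chains = fast$chains,
                          warmup = fast$warmup, iter = fast$iter))
  expect_false(any(same$different, na.rm = TRUE))
  expect_equal(same$median, rep(1, 6), tolerance = 0.2)

  # C:G>G:C enriched 3x in domain A: that class flagged, others mostly not
  n_rep <- 10L
  hit <- 0L
  false_flags <- 0L
  for (i in seq_len(n_rep)) {
    base <- c(60, 60, 30, 30, 30, 30)
    a <- rpois(6, base * c(1, 1, 1, 3, 1, 1))
    b <- rpois(6, base)
    ra <- suppressWarnings(
      domain_spectrum_ratio(mk_spec(as.integer(a), 4e5, 4e5),
                            mk_spec(as.integer(b), 4e5, 4e5),
                            chains = fast$chains, warmup = fast$warmup,
                            iter = fast$iter))
    if (isTRUE(ra$different[4])) hit <- hit + 1L
    false_flags <- false_flags + sum(ra$different[-4], na.rm = TRUE)
  }
  expect_gte(hit, 9L)
  expect_lte(false_flags, 5L)

  # correction switch acts only through census terms (closed-form check):
  # scaling one domain's C:G exposure by k multiplies C:G-class ratios by ~1/k
  cens <- setNames(rep(1000, 32), trinuc_classes())
  focal_cg <- grepl("^[ACGT]C", sub(":.*", "", trinuc_classes()))
  censB <- cens
  censB[focal_cg] <- 500  # domain B has half the C:G trinucleotide census
  set.seed(304)
  r_nuc <- suppressWarnings(
    domain_spectrum_ratio(mk_spec(c(50L, 50L, 25L, 25L, 25L, 25L), 1e5, 1e5),
                          mk_spec(c(50L, 50L, 25L, 25L, 25L, 25L), 1e5, 1e5),
                          chains = fast$chains, warmup = fast$warmup,
                          iter = fast$iter))
  r_tri <- suppressWarnings(
    domain_spectrum_ratio(mk_spec(c(50L, 50L, 25L, 25L, 25L, 25L), 1e5, 1e5),
                          mk_spec(c(50L, 50L, 25L, 25L, 25L, 25L), 1e5, 1e5),
                          correction = "trinucleotide",
                          censusA = cens, censusB = censB,
                          chains = fast$chains, warmup = fast$warmup,
                          iter = fast$iter))
  is_cg_class <- grepl("^C:G", SNM_CLASSES)
  expect_equal(r_tri$median[is_cg_class] / r_nuc$median[is_cg_class],
               rep(0.5, 3), tolerance = 0.08)
  expect_equal(r_tri$median[!is_cg_class] / r_nuc$median[!is_cg_class],
               rep(1, 3), tolerance = 0.08)

  # both-zero class is undefined
  z <- mk_spec(c(50L, 50L, 25L, 0L, 25L, 25L), 4e5, 4e5)
  rz <- suppressWarnings(
    domain_spectrum_ratio(z, z, chains = fast$chains,
                          warmup = fast$warmup, iter = fast$iter))
  expect_true(rz$undefined[4])
})

test_that("trinucleotide model recovers a K9 fold and ranks a hot class first", {
  set.seed(305)
  cls <- trinuc_classes()
  census <- matrix(3000L, 32, 4, dimnames = list(cls, STRATA))
  design <- experiment_design(39, 40, 25.375)
  expos <- 39 * 40 * 25.375
  base_rate <- 20 / (expos * 3000)   # ~20 expected counts per euchromatin cell
  k9_fold <- 8
  lam <- outer(rep(base_rate * expos * 3000, 32),
               c(euchromatin = 1, H3K27me3 = 1, H3K9me3 = k9_fold,
                 centromeric = k9_fold))
  counts <- matrix(rpois(128, lam), 32, 4, dimnames = dimnames(census))
  tm <- suppressWarnings(
    trinuc_model(counts, census, design, chains = fast$chains,
                 warmup = fast$warmup, iter = fast$iter))
  expect_true(tm$folds$K9$lower <= k9_fold && k9_fold <= tm$folds$K9$upper)
  # flat simulation: relative-rate HPDIs of extreme classes overlap
  i_max <- which.max(tm$classes$median)
  i_min <- which.min(tm$classes$median)
  expect_gt(tm$classes$upper[i_min], tm$classes$lower[i_max] * 0.8)

  # one hot class (TCT:AGA at 5x) ranks first
  hot <- which(cls == "TCT:AGA")
  lam2 <- lam
  lam2[hot, ] <- lam2[hot, ] * 5
  counts2 <- matrix(rpois(128, lam2), 32, 4, dimnames = dimnames(census))
  tm2 <- suppressWarnings(
    trinuc_model(counts2, census, design, chains = fast$chains,
                 warmup = fast$warmup, iter = fast$iter))
  expect_equal(tm2$classes$class[which.max(tm2$classes$median)], "TCT:AGA")
})

test_that("trinucleotide model nests independent per-class Poisson fits", {
  set.seed(306)
  cls <- trinuc_classes()
  census <- matrix(0L, 32, 4, dimnames = list(cls, STRATA))
  census[, "euchromatin"] <- 5000L
  counts <- matrix(0L, 32, 4, dimnames = list(cls, STRATA))
  counts[, "euchromatin"] <- rpois(32, 20)
  design <- experiment_design(39, 40, 25.375)
  tm <- suppressWarnings(
    trinuc_model(counts, census, design, chains = fast$chains,
                 warmup = fast$warmup, iter = fast$iter))
  # with a single stratum there are no domain effects and per-class
  # normalised rates follow the independent count proportions
  expect_equal(length(tm$folds), 0L)
  expect_equal(tm$classes$median,
               unname(counts[, "euchromatin"] / sum(counts[, "euchromatin"])),
               tolerance = 0.12)
})

test_that("flanking-base regression recovers coefficients and widens with noise", {
  cls <- trinuc_classes()
  rep5 <- substr(cls, 1, 1)
  f5 <- as.numeric(rep5 %in% c("C", "G"))
  make_fake <- function(y, sd) {
    draws <- sapply(seq_along(y), function(j) rnorm(2000, y[j], sd[j]))
    list(class_draws = exp(draws),
         classes = data.frame(class = cls))
  }
  set.seed(307)
  # beta_5 = -0.5, everything else 0
  n_rep <- 100L
  cover5 <- 0L
  other_names <- c("beta_b", "beta_3", "beta_I5", "beta_I3")
  others0 <- 0L
  for (i in seq_len(n_rep)) {
    y <- -3 + (-0.5) * f5 + rnorm(32, 0, 0.1)
    fit <- flanking_effects(make_fake(y, rep(0.1, 32)))
    s <- fit$summary
    if (s$lower[s$coefficient == "beta_5"] <= -0.5 &&
        -0.5 <= s$upper[s$coefficient == "beta_5"]) cover5 <- cover5 + 1L
    others0 <- others0 + sum(!s$significant[s$coefficient %in% other_names])
  }
  expect_gte(cover5, 90L)
  expect_gte(others0 / (4 * n_rep), 0.9)

  # all responses equal: every effect ~ 0
  fit0 <- flanking_effects(make_fake(rep(-2, 32), rep(0.05, 32)))
  expect_true(all(abs(fit0$summary$median[-1]) < 0.05))

  # inflating measurement sd widens every coefficient interval
  y <- -3 + 0.4 * f5 + rnorm(32, 0, 0.1)
  f_small <- flanking_effects(make_fake(y, rep(0.05, 32)))
  f_big <- flanking_effects(make_fake(y, rep(0.5, 32)))
  w_small <- f_small$summary$upper - f_small$summary$lower
  w_big <- f_big$summary$upper - f_big$summary$lower
  expect_true(all(w_big > w_small))
})

test_that("the simulated spectrum pipeline recovers the generating class rates", {
  set.seed(308)
  cfg <- sim_config()
  sim <- simulate_genome(cfg)
  ma <- simulate_ma_experiment(sim, cfg)
  am <- annotate_mutations(ma$mutations, sim$ann, homopolymers = ma$catalog)
  comp <- composition_table(sim$ann)
  spec <- spectrum_counts(am, comp, "euchromatin")
  rr <- suppressWarnings(
    relative_rates(spec, chains = fast$chains, warmup = fast$warmup,
                   iter = fast$iter))
  truth <- cfg$spectrum[, "euchromatin"]
  covered <- sum(rr$summary$lower <= truth & truth <= rr$summary$upper)
  expect_gte(covered, 5L)
  tt <- suppressWarnings(
    ts_tv(spec, chains = fast$chains, warmup = fast$warmup,
          iter = fast$iter))
  r_truth <- sum(truth[1:2]) / sum(truth[3:6])
  expect_true(tt$lower <= r_truth && r_truth <= tt$upper)
})
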