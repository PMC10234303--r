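make_indel_fixture <- function() {
  set.seed(401)
  base <- rand_dna(2000)
  # plant: A7 run at 501-507, (ACA)x5 at 1001-1015, unique elsewhere;
  # explicit non-matching boundary bases keep the runs maximal as planted
  s <- paste0(substr(base, 1, 499), "C", "AAAAAAA", "G",
              substr(base, 510, 999), "G", strrep("ACA", 5), "T",
              substr(base, 1018, 2000))
  ann <- make_test_ann(c(c1 = s))
  list(ann = ann, catalog = find_homopolymers(ann),
       micro = detect_microsatellites(ann))
}

test_that("indels are classified into exactly one repeat category", {
  fx <- make_indel_fixture()
  muts <- data.frame(
    line_id = "L1", contig = "c1",
    pos = c(503L, 1004L, 1700L, 504L, 504L),
    ref = NA, alt = NA,
    kind = c("deletion", "deletion", "deletion", "insertion", "insertion"),
    length = c(1L, 3L, 200L, 1L, 1L),
    seq = c(NA, NA, NA, "A", "C")
  )
  am <- annotate_mutations(muts, fx$ann, homopolymers = fx$catalog)
  rec <- classify_indels(am, fx$catalog, microsats = fx$micro)
  expect_equal(rec$category,
               c("homopolymer", "microsatellite", "nonrepeat",
                 "homopolymer", "nonrepeat"))
  expect_equal(rec$polymer_length[1], 7L)
  expect_equal(rec$polymer_type[1], "A:T")
  # partition: every record got exactly one category
  expect_equal(sum(table(rec$category)), nrow(rec))
  expect_false(any(is.na(rec$category)))
})

test_that("microsatellite detection finds tandem motifs but not homopolymers", {
  fx <- make_indel_fixture()
  hit <- fx$micro[fx$micro$start <= 1002 & fx$micro$end >= 1012, ]
  expect_gte(nrow(hit), 1L)
  # no single-base motifs
  expect_false(any(vapply(strsplit(fx$micro$motif, ""),
                          function(x) length(unique(x)) == 1L, logical(1))))
})

test_that("deletion/insertion rates and ratio behave under simulated ratios", {
  design <- experiment_design(20, 40, 25.375)
  mk <- function(n_del, n_ins, cat = "nonrepeat") {
    data.frame(line_id = sample(sprintf("L%02d", 1:20), n_del + n_ins,
                                replace = TRUE),
               contig = "c1", pos = 1L,
               kind = c(rep("deletion", n_del), rep("insertion", n_ins)),
               length = c(pmax(1, round(rlnorm(n_del, 4.5, 2))),
                          1 + rgeom(n_ins, 1 / 27)),
               category = cat, stratum = "euchromatin")
  }
  set.seed(402)
  # identical counts: ratio ~ 1
  eq <- mk(60, 60)
  r_eq <- suppressWarnings(
    indel_rate_table(eq, design, line_ids = sprintf("L%02d", 1:20),
                     chains = fast$chains, warmup = fast$warmup,
                     iter = fast$iter))
  expect_equal(r_eq$ratio$median, 1, tolerance = 0.15)
  expect_false(r_eq$ratio$different)

  # 3:1 deletion bias: ratio HPDI covers 3; net change is negative
  # (deletions are long, insertions short)
  tri <- mk(90, 30)
  r_tri <- suppressWarnings(
    indel_rate_table(tri, design, line_ids = sprintf("L%02d", 1:20),
                     chains = fast$chains, warmup = fast$warmup,
                     iter = fast$iter))
  expect_true(r_tri$ratio$lower <= 3 && 3 <= r_tri$ratio$upper)
  expect_lt(r_tri$net_bp, 0)
  expect_gt(r_tri$mean_lengths[["deletion"]], r_tri$mean_lengths[["insertion"]])
  expect_error(indel_rate_table(eq, design, subset = "repeats_only"),
               "no records")
})

test_that("homopolymer model recovers the type ratio and length slope", {
  design <- experiment_design(39, 40, 25.375)
  exposure <- 39 * 40 * 25.375
  set.seed(403)
  # synthetic catalog: realistic length decay, A:T more common
  lens <- 5:12
  cat_at <- data.frame(type = "A:T", length = rep(lens, round(600 * 0.6^(lens - 5))))
  cat_cg <- data.frame(type = "C:G", length = rep(lens, round(350 * 0.6^(lens - 5))))
  catalog <- rbind(
    data.frame(contig = "c1", start = 1L, end = 1L, base = "A",
               type = cat_at$type, length = cat_at$length, stratum = "euchromatin"),
    data.frame(contig = "c1", start = 1L, end = 1L, base = "C",
               type = cat_cg$type, length = cat_cg$length, stratum = "euchromatin"))
  rate_at <- 3.6e-7   # per locus per mitosis, desk scale
  slope <- 0.25
  ratio_true <- 2.2
  sim_records <- function() {
    lam <- ifelse(catalog$type == "A:T", rate_at, rate_at / ratio_true) *
      exp(slope * (catalog$length - 5)) * exposure
    n <- rpois(nrow(catalog), lam)
    idx <- rep(seq_len(nrow(catalog)), n)
    data.frame(line_id = "L01", contig = "c1", pos = 1L, kind = "deletion",
               length = 1L, category = "homopolymer",
               polymer_type = catalog$type[idx],
               polymer_length = catalog$length[idx])
  }
  rec <- sim_records()
  fit <- suppressWarnings(
    homopolymer_model(rec, catalog, design, chains = fast$chains,
                      warmup = fast$warmup, iter = fast$iter))
  expect_true(fit$ratio$lower <= ratio_true && ratio_true <= fit$ratio$upper)
  expect_true(fit$length_slope$lower <= slope && slope <= fit$length_slope$upper)
  expect_gt(fit$rate_at$median, fit$rate_cg$median)

  # null type effect: ratio HPDI includes 1
  ratio_true <- 1
  set.seed(404)
  rec0 <- sim_records()
  fit0 <- suppressWarnings(
    homopolymer_model(rec0, catalog, design, chains = fast$chains,
                      warmup = fast$warmup, iter = fast$iter))
  expect_true(fit0$ratio$lower <= 1 && 1 <= fit0$ratio$upper)

  # offset identity: doubling the locus census halves per-locus rates
  catalog2 <- rbind(catalog, catalog)
  set.seed(405)
  fit_a <- suppressWarnings(
    homopolymer_model(rec, catalog, design, chains = fast$chains,
                      warmup = fast$warmup, iter = fast$iter))
  set.seed(405)
  fit_b <- suppressWarnings(
    homopolymer_model(rec, catalog2, design, chains = fast$chains,
                      warmup = fast$warmup, iter = fast$iter))
  expect_equal(fit_b$rate_at$median, fit_a$rate_at$median / 2, tolerance = 0.03)
  expect_equal(fit_b$rate_cg$median, fit_a$rate_cg$median / 2, tolerance = 0.03)
})

test_that("per-domain indel rates flag only simulated enrichments", {
  set.seed(406)
  design <- experiment_design(20, 40, 25.375)
  comp <- data.frame(stratum = STRATA,
                     callable_bp = c(6e5, 1e5, 1.5e5, 5e4),
                     at_pairs = 0, cg_pairs = 0)
  exposure <- 20 * 40 * 25.375
  mk_records <- function(del_rates, ins_rate = 2e-10) {
    rows <- list()
    for (i in seq_along(STRATA)) {
      nd <- rpois(1, del_rates[i] * comp$callable_bp[i] * exposure)
      ni <- rpois(1, ins_rate * comp$callable_bp[i] * exposure)
      if (nd + ni == 0) next
      rows[[i]] <- data.frame(
        line_id = "L01", contig = "c1", pos = 1L,
        kind = c(rep("deletion", nd), rep("insertion", ni)),
        length = 1L, category = "nonrepeat", stratum = STRATA[i])
    }
    do.call(rbind, rows)
  }
  # deletions elevated 8x in H3K9me3 only
  rec <- mk_records(c(2e-10, 2e-10, 1.6e-9, 2e-10))
  out <- suppressWarnings(
    domain_indel_rates(rec, design, comp, chains = fast$chains,
                       warmup = fast$warmup, iter = fast$iter))
  del_k9 <- out[out$kind == "deletion" & out$subset == "all" &
                out$stratum == "H3K9me3", ]
  ins_k9 <- out[out$kind == "insertion" & out$stratum == "H3K9me3", ]
  expect_true(del_k9$different)
  expect_false(isTRUE(ins_k9$different))

  # uniform rates at informative counts: flagged comparisons stay near the
  # nominal 5% error rate (small-count discreteness keeps this approximate)
  flagged <- 0L
  total <- 0L
  for (r in 1:10) {
    rec_u <- mk_records(rep(2e-8, 4), ins_rate = 2e-8)
    out_u <- suppressWarnings(
      domain_indel_rates(rec_u, design, comp, chains = fast$chains,
                         warmup = fast$warmup, iter = fast$iter))
    flagged <- flagged + sum(out_u$different, na.rm = TRUE)
    total <- total + sum(!is.na(out_u$different))
  }
  expect_lte(flagged / total, 0.1)
})
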