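#' Published headline counts of the MA experiment
#'
#' The printed totals of the experiment the package models: 1322 mutations
#' (1077 SNMs, 134 insertions, 97 deletions, 9 complex events, 5
#' translocations) over 39 lines, 40 transfers of 25.375 mitoses (1015 in
#' total), on a 41,108,926 bp genome of which 98.7% of sites were callable.
#'
#' @param total,snm,insertion,deletion,complex,translocation mutation counts
#'   by type.
#' @param n_lines,t,tm lines, transfers and total mitoses per line.
#' @param genome_bp,called_frac genome size and callable fraction.
#' @return validated list of class `printed_counts`.
#' @export
printed_counts <- function(total = 1322, snm = 1077, insertion = 134,
                           deletion = 97, complex = 9, translocation = 5,
                           n_lines = 39, t = 40, tm = 1015,
                           genome_bp = 41108926, called_frac = 0.987) {
  if (snm + insertion + deletion + complex + translocation != total) {
    stop("component counts do not sum to the total")
  }
  structure(list(total = total, snm = snm, insertion = insertion,
                 deletion = deletion, complex = complex,
                 translocation = translocation, n_lines = n_lines, t = t,
                 tm = tm, genome_bp = genome_bp, called_frac = called_frac),
            class = "printed_counts")
}

#' Round-robin split of a total count over lines
#'
#' The intercept-only Poisson likelihood depends only on the total and the
#' total exposure, so how a published total is split across lines is
#' bookkeeping; the round-robin split keeps the per-line counts integral
#' and as even as possible.
#'
#' @param total total count.
#' @param n number of lines.
#' @return integer vector of length `n` summing to `total`.
#' @export
split_counts <- function(total, n) {
  q <- total %/% n
  r <- total %% n
  c(rep(q + 1L, r), rep(q, n - r))
}

#' Reproduce the headline mutation rates from printed counts
#'
#' Recomputes the five headline rate statements from published totals alone:
#' the SNM rate per bp, the total mutation rate per genome, the
#' translocation rate per genome, the complex-mutation rate per bp, and the
#' SNM over complex-mutation rate ratio, each as a posterior median with
#' 95% HPD interval from the intercept-only Poisson model with the counts
#' split evenly across lines.
#'
#' @param counts [printed_counts()].
#' @param seed RNG seed for the MCMC.
#' @param chains,warmup,iter MCMC settings.
#' @return data frame: `quantity`, `median`, `lower`, `upper`, `units`.
#' @export
reproduce_printed <- function(counts = printed_counts(), seed = NULL,
                              chains = 4, warmup = 1000, iter = 3000) {
  if (!is.null(seed)) set.seed(seed)
  design <- experiment_design(counts$n_lines, counts$t,
                              m_draws = counts$tm / counts$t)
  N <- counts$genome_bp * counts$called_frac
  fit <- function(x) {
    fit_poisson_rate(split_counts(x, counts$n_lines),
                     chains = chains, warmup = warmup, iter = iter)
  }
  snm_alpha <- fit(counts$snm)
  complex_alpha <- fit(counts$complex)
  snm_rate <- to_rate(snm_alpha, design, N = N, per = "bp")
  complex_rate <- to_rate(complex_alpha, design, N = N, per = "bp")
  total_rate <- to_rate(fit(counts$total), design, per = "genome")
  transloc_rate <- to_rate(fit(counts$translocation), design, per = "genome")
  ratio <- rate_ratio(snm_rate, complex_rate)
  row <- function(q, ps, units) {
    data.frame(quantity = q, median = ps$median, lower = ps$lower,
               upper = ps$upper, units = units)
  }
  out <- rbind(
    row("snm_rate", snm_rate, "mutations/bp/mitosis"),
    row("total_rate", total_rate, "mutations/genome/mitosis"),
    row("translocation_rate", transloc_rate, "mutations/genome/mitosis"),
    row("complex_rate", complex_rate, "mutations/bp/mitosis"),
    row("snm_complex_ratio", ratio, "")
  )
  rownames(out) <- NULL
  out
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a genome, an MA mutation table, nuclei counts and a population
#' sample under one configuration, then runs annotation, the windowed
#' rate model, the SNM spectrum, the indel analyses and the diversity
#' regression, writing a single JSON summary (plus the generated inputs)
#' into a run directory.
#'
#' @param cfg [sim_config()].
#' @param seed RNG seed; recorded in the summary.
#' @param out_dir run directory (`NULL` for no files).
#' @param chains,warmup,iter MCMC settings passed to every fit.
#' @return list with the fitted objects and the `summary` list.
#' @export
run_all <- function(cfg = sim_config(), seed = 1, out_dir = NULL,
                    chains = 4, warmup = 1000, iter = 3000) {
  set.seed(seed)
  sim <- simulate_genome(cfg)
  ma <- simulate_ma_experiment(sim, cfg)
  design <- experiment_design(cfg$n_lines, cfg$t, m_draws = cfg$m,
                              N = sum(composition_table(sim$ann)$callable_bp))
  ann_muts <- annotate_mutations(ma$mutations, sim$ann,
                                 homopolymers = ma$catalog)
  windows <- ma$windows
  snm <- ann_muts[ann_muts$kind == "snm", , drop = FALSE]
  win_width <- windows$end[1] - windows$start[1] + 1
  wkey <- paste(windows$contig, (windows$start - 1) %/% win_width)
  counts <- as.integer(table(factor(paste(snm$contig, (snm$pos - 1) %/% win_width),
                                    levels = wkey)))
  model <- fit_domain_gc_model(counts, windows, design,
                               chains = chains, warmup = warmup, iter = iter)

  comp <- composition_table(sim$ann)
  spec_eu <- spectrum_counts(ann_muts, comp, "euchromatin")
  spec_k9 <- spectrum_counts(ann_muts, comp, "H3K9me3")
  rel_eu <- relative_rates(spec_eu, chains = chains, warmup = warmup, iter = iter)
  tstv_eu <- ts_tv(spec_eu, chains = chains, warmup = warmup, iter = iter)
  tstv_k9 <- ts_tv(spec_k9, chains = chains, warmup = warmup, iter = iter)

  indels <- classify_indels(ann_muts, ma$catalog,
                            microsats = detect_microsatellites(sim$ann))
  hp <- homopolymer_model(indels, ma$catalog, design,
                          chains = chains, warmup = warmup, iter = iter)

  pop <- simulate_population(sim, cfg, windows = windows)
  tw <- theta_windows(pop$snp, windows)
  pred <- predict_log10_mu(model, windows)
  reg <- diversity_regression(tw$theta, pred)

  summary <- list(
    seed = seed,
    n_mutations = nrow(ma$mutations),
    n_snms = nrow(snm),
    model_coefficients = lapply(seq_len(ncol(model$draws)), function(j) {
      h <- hpdi(model$draws[, j])
      list(name = colnames(model$draws)[j],
           median = stats::median(model$draws[, j]),
           lower = unname(h[1]), upper = unname(h[2]))
    }),
    ts_tv = list(euchromatin = tstv_eu$median, H3K9me3 = tstv_k9$median),
    homopolymer_ratio = hp$ratio$median,
    theta_slope = reg$slope$median,
    theta_r2 = reg$r2$median
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(sim, out_dir)
    write_mutations(ma$mutations, file.path(out_dir, "mutations.tsv"))
    write_vcf(pop$snp, file.path(out_dir, "population.vcf"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = model, spectrum = list(eu = rel_eu, ts_tv_eu = tstv_eu,
                                      ts_tv_k9 = tstv_k9),
       homopolymer = hp, regression = reg, summary = summary,
       mutations = ann_muts, windows = windows)
}
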