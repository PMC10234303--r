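#' Configuration for the synthetic MA study
#'
#' Defaults emulate the structure of a filamentous-fungus MA experiment at
#' desk scale: a 2 Mb genome over 4 contigs standing in for a 41 Mb genome,
#' low-GC H3K9me3/centromeric blocks inside high-GC euchromatin, 39 lines
#' propagated for 40 transfers of 25.375 mitoses each, per-bp SNM rates
#' scaled up by `rate_scale` (default 20, the genome-size ratio) so the
#' expected mutation yield per line (~30) matches a real experiment, and a
#' natural population of 57 strains whose windowed diversity is proportional
#' to the local mutation rate. Rate parameters are expressed exactly as the
#' windowed model estimates them: a euchromatic base rate at the reference
#' GC, multiplicative domain folds (10x H3K9me3, 1.4x H3K27me3, a further
#' 1.3x inside centromeres), a log-linear GC slope, and a GC-by-H3K9me3
#' interaction.
#'
#' @param ... overrides for any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    contig_lengths = rep(500000L, 4),
    frac_k9 = 0.15, frac_k27 = 0.10, frac_cen_of_k9 = 0.25,
    gc_targets = c(euchromatin = 0.54, H3K9me3 = 0.38, H3K27me3 = 0.50),
    # experiment
    n_lines = 39L, t = 40L, m = 25.375,
    # SNM rate structure (per bp per mitosis, model parameterisation)
    rate_scale = 20,
    snm_base_rate = 2.46e-10,   # euchromatin at the reference GC
    fold_k9 = 10, fold_k27 = 1.4, fold_cen = 1.3,
    gc_slope = -5, gc_k9_slope = 3, gc_center = 0.5,
    # 6-class spectrum weights per stratum (frequency-corrected scale,
    # each column sums to 1; transitions first two rows)
    spectrum = cbind(
      euchromatin = c(0.28, 0.32, 0.10, 0.10, 0.10, 0.10),
      H3K27me3    = c(0.28, 0.32, 0.10, 0.10, 0.10, 0.10),
      H3K9me3     = c(0.24, 0.24, 0.107, 0.20, 0.107, 0.106),
      centromeric = c(0.24, 0.24, 0.107, 0.20, 0.107, 0.106)
    ),
    # homopolymers: planting density and per-locus slippage rates
    hp_at_per_mb = 500, hp_cg_per_mb = 300,
    hp_len_geom_p = 0.5, hp_min_len = 5L, hp_max_len = 15L,
    hp_rate_at = 1.79e-8, hp_rate_cg = 8.15e-9,  # per locus per mitosis
    hp_length_slope = 0.25,                      # shared log slope per bp
    p_ins_repeat = 0.67,
    # non-repeat indels (per genome per mitosis; not genome-size scaled)
    del_rate = 7.5e-4, ins_rate = 2.5e-4,
    ins_len_mean = 27, del_meanlog = 4.5, del_sdlog = 2.0,
    # other event classes (per genome per mitosis)
    complex_rate = 2.27e-4, transloc_rate = 1.19e-4,
    # population sample
    n_strains = 57L, missing_rate = 0.2,
    theta_slope = 0.0096, theta_eu = 0.015,
    # nuclei-count data for the mitosis estimate
    phase_doublings = c(tube = 13.4, plate = 12.0),
    nuclei_reps = 6L, nuclei_initial = 20, nuclei_cv = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    if (frac_k9 + frac_k27 > 0.8) stop("infeasible domain fractions")
    stopifnot(frac_k9 >= 0, frac_k27 >= 0, frac_cen_of_k9 >= 0,
              frac_cen_of_k9 <= 1, all(gc_targets >= 0 & gc_targets <= 1),
              snm_base_rate >= 0, rate_scale > 0)
  })
  structure(cfg, class = "sim_config")
}

.rand_seq <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a chromatin-annotated genome
#'
#' Each contig carries a central H3K9me3 block (with a centromeric core) and
#' a separate H3K27me3 block; the remainder is euchromatin. Base composition
#' is drawn per domain from the configured GC targets (bimodal: the
#' heterochromatic blocks are GC-poor), and homopolymer tracts are planted
#' at the configured densities on top of naturally occurring runs.
#'
#' @param cfg [sim_config()].
#' @param seed RNG seed (optional).
#' @return list with `ann` (a `genome_annotation`) and `truth` (the
#'   generating layout).
#' @export
simulate_genome <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- character(length(cfg$contig_lengths))
  k9 <- k27 <- cen <- list()
  for (i in seq_along(cfg$contig_lengths)) {
    L <- cfg$contig_lengths[i]
    s <- .rand_seq(L, cfg$gc_targets[["euchromatin"]])
    # central H3K9me3 block with centromeric core
    lk9 <- round(cfg$frac_k9 * L)
    k9_start <- round((L - lk9) / 2)
    if (lk9 > 0) {
      s[(k9_start + 1):(k9_start + lk9)] <-
        .rand_seq(lk9, cfg$gc_targets[["H3K9me3"]])
      k9[[i]] <- c(i, k9_start, k9_start + lk9)
      lcen <- round(cfg$frac_cen_of_k9 * lk9)
      if (lcen > 0) {
        cen_start <- k9_start + round((lk9 - lcen) / 2)
        cen[[i]] <- c(i, cen_start, cen_start + lcen)
      }
    }
    # H3K27me3 block near the contig start
    lk27 <- round(cfg$frac_k27 * L)
    if (lk27 > 0) {
      k27_start <- round(0.05 * L)
      s[(k27_start + 1):(k27_start + lk27)] <-
        .rand_seq(lk27, cfg$gc_targets[["H3K27me3"]])
      k27[[i]] <- c(i, k27_start, k27_start + lk27)
    }
    # plant homopolymer tracts
    for (ty in c("at", "cg")) {
      dens <- if (ty == "at") cfg$hp_at_per_mb else cfg$hp_cg_per_mb
      n_tracts <- stats::rpois(1, dens * L / 1e6)
      if (n_tracts == 0) next
      lens <- pmin(cfg$hp_min_len + stats::rgeom(n_tracts, cfg$hp_len_geom_p),
                   cfg$hp_max_len)
      starts <- sample.int(L - cfg$hp_max_len - 1L, n_tracts)
      bases <- sample(if (ty == "at") c("A", "T") else c("C", "G"),
                      n_tracts, replace = TRUE)
      for (j in seq_len(n_tracts)) {
        s[starts[j]:(starts[j] + lens[j] - 1L)] <- bases[j]
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- paste0("contig_", seq_along(seqs))
  to_gr <- function(lst) {
    if (length(lst) == 0) return(NULL)
    m <- do.call(rbind, lst)
    GenomicRanges::GRanges(names(seqs)[m[, 1]],
                           IRanges::IRanges(m[, 2] + 1, m[, 3]))
  }
  ann <- load_annotation(Biostrings::DNAStringSet(seqs),
                         k9_bed = to_gr(k9), k27_bed = to_gr(k27),
                         cen_bed = to_gr(cen))
  list(ann = ann, truth = list(config = cfg, contigs = names(seqs)))
}

#' Write a simulated genome to FASTA + BED files
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed). Writes `genome.fasta`,
#'   `h3k9me3.bed`, `h3k27me3.bed`, `centromeres.bed` (0-based half-open).
#' @return the directory, invisibly.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim$ann
  Biostrings::writeXStringSet(ann$seq, file.path(dir, "genome.fasta"))
  dom <- ann$domains
  .write_bed(dom[S4Vectors::mcols(dom)$label == "H3K9me3"],
             file.path(dir, "h3k9me3.bed"))
  .write_bed(dom[S4Vectors::mcols(dom)$label == "H3K27me3"],
             file.path(dir, "h3k27me3.bed"))
  .write_bed(ann$cen, file.path(dir, "centromeres.bed"))
  invisible(dir)
}

# True per-window log10 mutation rate under the generator's model
# parameterisation (mutations/bp/mitosis).
true_log10_mu <- function(windows, cfg) {
  base <- log(cfg$snm_base_rate * cfg$rate_scale)
  k9 <- windows$domain == "H3K9me3"
  k27 <- windows$domain == "H3K27me3"
  cen <- windows$centromeric
  gc <- windows$gc_fraction - cfg$gc_center
  eta <- base + log(cfg$fold_k9) * k9 + log(cfg$fold_k27) * k27 +
    log(cfg$fold_cen) * cen + cfg$gc_slope * gc + cfg$gc_k9_slope * gc * k9
  eta / log(10)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# alt allele for a ref base under a strand-collapsed class like "C:G>T:A"
.alt_for_class <- function(ref, class) {
  src <- substr(class, 1, 1)          # pyrimidine-side source base (C or A)
  dst <- substr(class, 5, 5)
  ifelse(ref == src, dst, .complement[dst])
}

#' Simulate an MA-line mutation table
#'
#' Places SNMs window-by-window under the generator's rate model (Poisson
#' counts with domain folds, GC slope and GC-by-H3K9me3 interaction),
#' drawing each mutation's class from the stratum's spectrum weighted by the
#' source-pair census, slippage indels on the homopolymer catalog with
#' type- and length-dependent per-locus rates, non-repeat indels, complex
#' events and translocations at per-genome rates, each assigned to a random
#' line. Every generating parameter is returned in the `truth` sidecar.
#'
#' @param sim result of [simulate_genome()] (or a list with `ann`).
#' @param cfg [sim_config()].
#' @param seed RNG seed (optional).
#' @return list with `mutations` (data frame: `line_id`, `contig`, `pos`,
#'   `ref`, `alt`, `kind`, `length`, `seq`), `truth`, and the reusable
#'   `windows` and `catalog` tables.
#' @export
simulate_ma_experiment <- function(sim, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ann <- sim$ann
  windows <- make_windows(ann, 200)
  catalog <- find_homopolymers(ann, cfg$hp_min_len)
  comp <- composition_table(ann)
  exposure <- cfg$n_lines * cfg$t * cfg$m
  lines <- sprintf("L%02d", seq_len(cfg$n_lines))
  rows <- list()

  ## --- SNMs ------------------------------------------------------------
  mu_w <- 10^true_log10_mu(windows, cfg)
  e_w <- mu_w * windows$callable_bp * exposure
  n_w <- stats::rpois(length(e_w), e_w)
  pair_frac <- setNames(comp$cg_pairs / pmax(comp$callable_bp, 1), comp$stratum)
  src <- .source_pair(SNM_CLASSES)
  for (i in which(n_w > 0)) {
    st <- windows$stratum[i]
    fcg <- pair_frac[[st]]
    wts <- cfg$spectrum[, st] * ifelse(src == "C:G", fcg, 1 - fcg)
    code <- ann$codes[[windows$contig[i]]]
    span <- windows$start[i]:windows$end[i]
    for (k in seq_len(n_w[i])) {
      cls <- sample(SNM_CLASSES, 1, prob = wts)
      want <- if (.source_pair(cls) == "C:G") c(2L, 3L) else c(1L, 4L)
      cand <- span[!is.na(code[span]) & code[span] %in% want]
      if (length(cand) == 0L) cand <- span[!is.na(code[span])]
      if (length(cand) == 0L) next
      pos <- if (length(cand) == 1L) cand else sample(cand, 1)
      ref <- c("A", "C", "G", "T")[code[pos]]
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = sample(lines, 1), contig = windows$contig[i], pos = pos,
        ref = ref, alt = unname(.alt_for_class(ref, cls)), kind = "snm",
        length = 1L, seq = NA_character_)
    }
  }

  ## --- homopolymer slippage indels --------------------------------------
  if (nrow(catalog) > 0) {
    base_rate <- ifelse(catalog$type == "A:T", cfg$hp_rate_at, cfg$hp_rate_cg)
    lam <- base_rate * cfg$rate_scale *
      exp(cfg$hp_length_slope * (catalog$length - cfg$hp_min_len)) * exposure
    n_ev <- stats::rpois(nrow(catalog), lam)
    for (i in which(n_ev > 0)) {
      for (k in seq_len(n_ev[i])) {
        ins <- stats::runif(1) < cfg$p_ins_repeat
        pos <- sample(catalog$start[i]:(catalog$end[i] - 1L), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = sample(lines, 1), contig = catalog$contig[i], pos = pos,
          ref = catalog$base[i], alt = NA_character_,
          kind = if (ins) "insertion" else "deletion", length = 1L,
          seq = if (ins) catalog$base[i] else NA_character_)
      }
    }
  }

  ## --- non-repeat indels, complex events, translocations ----------------
  genome_len <- sum(as.numeric(GenomeInfoDb::seqlengths(ann$seqinfo)))
  contigs <- names(ann$seq)
  clen <- GenomeInfoDb::seqlengths(ann$seqinfo)
  rand_pos <- function() {
    ct <- sample(contigs, 1, prob = clen)
    list(contig = ct, pos = sample.int(clen[[ct]] - 50L, 1))
  }
  in_run <- function(contig, pos) {
    any(catalog$contig == contig & catalog$start <= pos & catalog$end >= pos)
  }
  place_simple <- function(kind, rate, len_fun) {
    n <- stats::rpois(1, rate * exposure)
    for (k in seq_len(n)) {
      for (try in 1:20) {
        p <- rand_pos()
        if (!in_run(p$contig, p$pos)) break
      }
      len <- len_fun()
      if (kind == "deletion") {
        len <- min(len, clen[[p$contig]] - p$pos + 1L)  # stay on the contig
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        line_id = sample(lines, 1), contig = p$contig, pos = p$pos,
        ref = NA_character_, alt = NA_character_, kind = kind,
        length = len, seq = NA_character_)
    }
  }
  place_simple("deletion", cfg$del_rate, function() {
    max(1L, round(stats::rlnorm(1, cfg$del_meanlog, cfg$del_sdlog)))
  })
  place_simple("insertion", cfg$ins_rate, function() {
    1L + stats::rgeom(1, 1 / cfg$ins_len_mean)
  })
  place_simple("complex", cfg$complex_rate, function() 2L)
  place_simple("translocation", cfg$transloc_rate, function() 316L)

  mutations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line_id = character(), contig = character(), pos = integer(),
               ref = character(), alt = character(), kind = character(),
               length = integer(), seq = character())
  rownames(mutations) <- NULL
  truth <- list(
    config = cfg, exposure = exposure, lines = lines,
    expected_snms = sum(e_w), genome_len = genome_len,
    log10_mu_windows = true_log10_mu(windows, cfg)
  )
  list(mutations = mutations, truth = truth, windows = windows,
       catalog = catalog)
}

#' Simulate population SNP genotypes tied to the local mutation rate
#'
#' Places segregating sites window-by-window so that the expected windowed
#' Watterson's theta follows `slope * log10(mu) + intercept` (clamped at
#' zero), with mutant counts drawn from the neutral site-frequency spectrum
#' (so subsampling under missingness leaves the estimator unbiased) and
#' i.i.d. per-call missingness.
#'
#' @param sim result of [simulate_genome()].
#' @param cfg [sim_config()]; `theta_slope` and `theta_eu` define the
#'   diversity-rate coupling (the intercept is anchored so a euchromatic
#'   window at the base rate has theta `theta_eu`).
#' @param windows `WindowTable`; computed if `NULL`.
#' @param log10_mu per-window log10 rate driving diversity; defaults to the
#'   generator's true rates.
#' @param seed RNG seed (optional).
#' @return list with `snp` (`snp_matrix`), `theta_target` per window, and
#'   `intercept`.
#' @export
simulate_population <- function(sim, cfg = sim_config(), windows = NULL,
                                log10_mu = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ann <- sim$ann
  if (is.null(windows)) windows <- make_windows(ann, 200)
  if (is.null(log10_mu)) log10_mu <- true_log10_mu(windows, cfg)
  intercept <- cfg$theta_eu -
    cfg$theta_slope * log10(cfg$snm_base_rate * cfg$rate_scale)
  target <- cfg$theta_slope * log10_mu + intercept
  clamped <- sum(target < 0, na.rm = TRUE)
  if (clamped > 0) {
    message(sprintf("%d window(s) with negative implied theta clamped to 0",
                    clamped))
  }
  target <- pmax(target, 0)
  n <- cfg$n_strains
  a_n <- sum(1 / seq_len(n - 1))
  sfs_p <- (1 / seq_len(n - 1)) / a_n
  sites <- list()
  genos <- list()
  for (i in seq_len(nrow(windows))) {
    if (is.na(target[i]) || target[i] == 0 || windows$callable_bp[i] == 0) next
    q <- min(target[i] * a_n, 0.9)
    S <- stats::rbinom(1, windows$callable_bp[i], q)
    if (S == 0) next
    pos <- sort(sample(windows$start[i]:windows$end[i], S))
    k <- sample.int(n - 1, S, replace = TRUE, prob = sfs_p)
    g <- matrix(0L, S, n)
    for (s in seq_len(S)) g[s, sample.int(n, k[s])] <- 1L
    sites[[length(sites) + 1L]] <- data.frame(contig = windows$contig[i],
                                              pos = pos)
    genos[[length(genos) + 1L]] <- g
  }
  if (length(sites) == 0L) {
    snp <- snp_matrix(data.frame(contig = character(), pos = integer()),
                      matrix(integer(), 0, n))
  } else {
    geno <- do.call(rbind, genos)
    if (cfg$missing_rate > 0) {
      geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
    }
    colnames(geno) <- sprintf("strain_%02d", seq_len(n))
    snp <- snp_matrix(do.call(rbind, sites), geno)
  }
  list(snp = snp, theta_target = target, intercept = intercept)
}

#' Write haploid genotypes as a minimal VCF
#'
#' @param snp `snp_matrix` (0/1 alleles).
#' @param path output file.
#' @export
write_vcf <- function(snp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(snp$geno)), collapse = "\t")),
             con)
  if (nrow(snp$geno) > 0) {
    gt <- snp$geno
    gt_chr <- matrix(as.character(gt), nrow(gt))
    gt_chr[is.na(gt)] <- "."
    lines <- paste(snp$sites$contig, snp$sites$pos, ".", "A", "T", ".",
                   "PASS", ".", "GT",
                   apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Simulate nuclei counts for the mitosis estimate
#'
#' Generates replicate (initial, final) nuclei counts per transfer phase
#' whose true log2 fold-changes sum to the configured number of mitoses per
#' transfer, with lognormal count noise at the configured CV.
#'
#' @param cfg [sim_config()]; uses `phase_doublings`, `nuclei_reps`,
#'   `nuclei_initial`, `nuclei_cv`.
#' @param seed RNG seed (optional).
#' @return data frame with `phase`, `initial`, `final`.
#' @export
simulate_nuclei_counts <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + cfg$nuclei_cv^2))
  out <- list()
  for (p in names(cfg$phase_doublings)) {
    d <- cfg$phase_doublings[[p]]
    ini <- cfg$nuclei_initial * stats::rlnorm(cfg$nuclei_reps, 0, sdlog)
    fin <- cfg$nuclei_initial * 2^d * stats::rlnorm(cfg$nuclei_reps, 0, sdlog)
    out[[p]] <- data.frame(phase = p, initial = pmax(1, round(ini)),
                           final = pmax(1, round(fin)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
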