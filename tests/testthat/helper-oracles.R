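# Independent oracles and small fixture builders used across the suite.

# 1-D grid integration of the intercept-only Poisson posterior:
# y ~ Poisson(exp(alpha) * exposure), alpha ~ N(0, prior_sd).
# Returns posterior median and HPD interval for alpha, independently of the
# package's sampler.
grid_alpha_posterior <- function(y_total, exposure_total, prior_sd = 10,
                                 lo = -40, hi = 10, n_grid = 400000) {
  grid <- seq(lo, hi, length.out = n_grid)
  logp <- y_total * grid - exposure_total * exp(grid) +
    stats::dnorm(grid, 0, prior_sd, log = TRUE)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  cdf <- cumsum(p)
  median <- grid[which.min(abs(cdf - 0.5))]
  # HPD via density threshold
  ord <- order(p, decreasing = TRUE)
  inc <- ord[cumsum(p[ord]) <= 0.95]
  list(median = median,
       lower = min(grid[inc]), upper = max(grid[inc]))
}

# Brute-force Watterson's theta with per-site sample sizes: direct per-site
# loop written independently of theta_w().
brute_theta <- function(geno, L) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  tot <- 0
  for (i in seq_len(nrow(geno))) {
    called <- geno[i, !is.na(geno[i, ])]
    n <- length(called)
    if (n < 2) next
    if (length(unique(called)) > 1) {
      tot <- tot + 1 / sum(1 / seq_len(n - 1))
    }
  }
  tot / L
}

# Brute-force collapsed 3-mer tally of a sequence string (dictionary method).
brute_trinuc_tally <- function(s) {
  rc1 <- function(x) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  out <- setNames(integer(32), trinuc_classes())
  n <- nchar(s)
  if (n < 3) return(out)
  for (i in 1:(n - 2)) {
    tri <- substr(s, i, i + 2)
    if (grepl("N", tri)) next
    rep <- if (substr(tri, 2, 2) %in% c("A", "C")) tri else rc1(tri)
    cls <- paste0(rep, ":", rc1(rep))
    out[cls] <- out[cls] + 1L
  }
  out
}

# Build a genome_annotation from raw strings and interval vectors
# (1-based closed coordinates), via on-disk FASTA/BED so the readers are
# exercised too.
make_test_ann <- function(seqs, k9 = NULL, k27 = NULL, cen = NULL,
                          on_disk = FALSE) {
  to_gr <- function(iv) {
    if (is.null(iv)) return(NULL)
    GenomicRanges::GRanges(iv$contig, IRanges::IRanges(iv$start, iv$end))
  }
  if (!on_disk) {
    return(load_annotation(Biostrings::DNAStringSet(seqs),
                           k9_bed = to_gr(k9), k27_bed = to_gr(k27),
                           cen_bed = to_gr(cen)))
  }
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  bed <- function(iv, name) {
    if (is.null(iv)) return(NULL)
    path <- file.path(dir, name)
    write.table(data.frame(iv$contig, iv$start - 1L, iv$end), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
  }
  load_annotation(fa, k9_bed = bed(k9, "k9.bed"), k27_bed = bed(k27, "k27.bed"),
                  cen_bed = bed(cen, "cen.bed"))
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Small MCMC settings for tests where full-length chains are unnecessary.
fast <- list(chains = 2, warmup = 400, iter = 1200)
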