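#' Detect simple microsatellites
#'
#' Tandem repeats of a 2-6 bp motif with at least `min_copies` copies, found
#' with a maximal regex scan. Motifs that are themselves a single repeated
#' base are excluded (those are homopolymers).
#'
#' @param ann `genome_annotation`.
#' @param min_copies minimum number of tandem copies (default 3).
#' @return data frame: `contig`, `start`, `end`, `motif`, `copies`.
#' @export
detect_microsatellites <- function(ann, min_copies = 3) {
  res <- list()
  pat <- sprintf("([ACGT]{2,6})\\1{%d,}", min_copies - 1L)
  for (contig in names(ann$seq)) {
    s <- as.character(ann$seq[[contig]])
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    cs <- attr(m, "capture.start")[, 1]
    cl <- attr(m, "capture.length")[, 1]
    motif <- substr(rep(s, length(starts)), cs, cs + cl - 1L)
    single <- vapply(strsplit(motif, ""), function(x) length(unique(x)) == 1L,
                     logical(1))
    keep <- !single
    if (!any(keep)) next
    res[[contig]] <- data.frame(
      contig = contig, start = starts[keep],
      end = starts[keep] + lens[keep] - 1L,
      motif = motif[keep], copies = (lens[keep] %/% cl[keep]),
      row.names = NULL
    )
  }
  if (length(res) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), motif = character(),
                      copies = integer()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify insertions and deletions by repeat context
#'
#' Assigns each indel exactly one category: `homopolymer` when the affected
#' interval lies within a catalog run (insertions additionally require the
#' inserted sequence to consist of the run base), `microsatellite` when it
#' overlaps a tandem-repeat locus, `other_repeat` when it overlaps a
#' user-supplied repeat track, otherwise `nonrepeat`.
#'
#' @param annotated annotated mutation table ([annotate_mutations()]); only
#'   insertion/deletion records are used.
#' @param homopolymers catalog from [find_homopolymers()].
#' @param microsats optional data frame from [detect_microsatellites()].
#' @param other_repeats optional `GRanges` of additional repeat intervals.
#' @return data frame of indel records with `category`, `polymer_type`,
#'   `polymer_length` columns.
#' @export
classify_indels <- function(annotated, homopolymers, microsats = NULL,
                            other_repeats = NULL) {
  rec <- annotated[annotated$kind %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(rec) == 0L) {
    rec$category <- character(0)
    return(rec)
  }
  homo <- rec$homopolymer
  # insertions must insert the run base to count as homopolymer slippage
  if (!is.null(rec$seq)) {
    ins <- rec$kind == "insertion" & homo & !is.na(rec$seq) & nzchar(rec$seq)
    if (any(ins)) {
      ok <- vapply(which(ins), function(i) {
        chars <- unique(strsplit(toupper(rec$seq[i]), "")[[1]])
        identical(chars, rec$polymer_base[i])
      }, logical(1))
      homo[which(ins)[!ok]] <- FALSE
    }
  }
  span_end <- ifelse(rec$kind == "deletion", rec$pos + rec$length - 1L, rec$pos)
  in_track <- function(track) {
    if (is.null(track) || (is.data.frame(track) && nrow(track) == 0L)) {
      return(rep(FALSE, nrow(rec)))
    }
    tg <- if (inherits(track, "GRanges")) track else {
      GenomicRanges::GRanges(track$contig, IRanges::IRanges(track$start, track$end))
    }
    mg <- GenomicRanges::GRanges(rec$contig, IRanges::IRanges(rec$pos, span_end))
    IRanges::overlapsAny(mg, tg)
  }
  micro <- in_track(microsats)
  other <- in_track(other_repeats)
  rec$category <- ifelse(homo, "homopolymer",
                  ifelse(micro, "microsatellite",
                  ifelse(other, "other_repeat", "nonrepeat")))
  rec$polymer_type[rec$category != "homopolymer"] <- NA_character_
  rec$polymer_length[rec$category != "homopolymer"] <- NA_integer_
  rec
}

.per_line_counts <- function(ids, design, line_ids = NULL) {
  if (is.null(line_ids)) {
    line_ids <- unique(ids)
    extra <- design$n_lines - length(line_ids)
    if (extra < 0) stop("more line ids than design$n_lines")
    tab <- table(factor(ids, levels = line_ids))
    return(c(as.integer(tab), integer(extra)))
  }
  as.integer(table(factor(ids, levels = line_ids)))
}

#' Deletion and insertion rates and their ratio
#'
#' Per-genome per-mitosis Poisson rate posteriors for deletions and
#' insertions over a repeat-context subset, plus the deletion/insertion rate
#' ratio, mean lengths, and the net base-pair change.
#'
#' @param records classified indels from [classify_indels()].
#' @param design [experiment_design()].
#' @param subset `"all"`, `"excl_repeats"` (nonrepeat records only) or
#'   `"repeats_only"`.
#' @param line_ids optional full vector of line identifiers (so lines with
#'   zero indels contribute zeros).
#' @param chains,warmup,iter MCMC settings.
#' @return list with `deletion` and `insertion` (`rate_estimate`s), `ratio`
#'   (deletion / insertion posterior), `counts`, `mean_lengths`, `net_bp`.
#' @export
indel_rate_table <- function(records, design,
                             subset = c("all", "excl_repeats", "repeats_only"),
                             line_ids = NULL,
                             chains = 4, warmup = 1000, iter = 3000) {
  subset <- match.arg(subset)
  sel <- switch(subset,
    all = rep(TRUE, nrow(records)),
    excl_repeats = records$category == "nonrepeat",
    repeats_only = records$category != "nonrepeat")
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0L) stop("subset '", subset, "' contains no records")
  out <- list(subset = subset)
  flagged <- character(0)
  for (kind in c("deletion", "insertion")) {
    k <- r[r$kind == kind, , drop = FALSE]
    counts <- .per_line_counts(k$line_id, design, line_ids)
    if (sum(counts) == 0L) flagged <- c(flagged, kind)
    alpha <- suppressWarnings(
      fit_poisson_rate(counts, chains = chains, warmup = warmup, iter = iter))
    out[[kind]] <- to_rate(alpha, design, per = "genome")
  }
  out$prior_dominated <- flagged
  out$ratio <- rate_ratio(out$deletion, out$insertion)
  del <- r[r$kind == "deletion", , drop = FALSE]
  ins <- r[r$kind == "insertion", , drop = FALSE]
  out$counts <- c(deletion = nrow(del), insertion = nrow(ins))
  out$mean_lengths <- c(deletion = mean(del$length), insertion = mean(ins$length))
  out$net_bp <- sum(ins$length) - sum(del$length)
  out
}

#' Homopolymer slippage-rate model
#'
#' Poisson regression of homopolymer mutation counts per (type, length)
#' stratum with offset `log(locus count * n_lines * t * m)`. Predictors: an
#' A:T-vs-C:G type indicator and a single shared length slope (no
#' interaction: length has the same effect for both types). Lengths above
#' `max_len` are pooled.
#'
#' @param records classified indels ([classify_indels()]); only
#'   `homopolymer` category records are used.
#' @param catalog homopolymer catalog from [find_homopolymers()].
#' @param design [experiment_design()].
#' @param max_len pooling cap for the length stratification (default 15).
#' @param chains,warmup,iter MCMC settings.
#' @return list with `rate_at`, `rate_cg` (census-weighted per-locus
#'   per-mitosis `rate_estimate`s), `ratio` (A:T over C:G), `length_slope`
#'   (posterior of the per-bp log slope) and the fitted draws.
#' @export
homopolymer_model <- function(records, catalog, design, max_len = 15,
                              chains = 4, warmup = 1000, iter = 3000) {
  h <- records[records$category == "homopolymer", , drop = FALSE]
  if (nrow(h) == 0L) stop("no homopolymer-category records")
  min_len <- min(catalog$length)
  cap <- function(x) pmin(x, max_len)
  strata <- expand.grid(type = c("A:T", "C:G"),
                        length = min_len:max_len, stringsAsFactors = FALSE)
  loci <- mapply(function(ty, le) {
    if (le == max_len) sum(catalog$type == ty & cap(catalog$length) == le)
    else sum(catalog$type == ty & catalog$length == le)
  }, strata$type, strata$length)
  y <- mapply(function(ty, le) {
    if (le == max_len) sum(h$polymer_type == ty & cap(h$polymer_length) == le)
    else sum(h$polymer_type == ty & h$polymer_length == le)
  }, strata$type, strata$length)
  keep <- loci > 0
  strata <- strata[keep, ]
  loci <- loci[keep]
  y <- as.integer(y[keep])
  exposure <- loci * design$n_lines * design$t * .m_med(design)
  X <- cbind(intercept = 1,
             type_at = as.numeric(strata$type == "A:T"),
             length = strata$length - min_len)
  fit <- mcmc_poisson_glm(y, X, offset = log(exposure),
                          prior_sd = c(10, 5, 5),
                          chains = chains, warmup = warmup, iter = iter)
  d <- fit$draws
  # census-weighted marginal per-locus rate for each type
  marg <- function(type) {
    sel <- strata$type == type
    eta <- d[, "intercept"] +
      d[, "type_at"] * as.numeric(type == "A:T") +
      outer(d[, "length"], strata$length[sel] - min_len)
    drop(exp(eta) %*% loci[sel]) / sum(loci[sel])
  }
  rate <- function(x) {
    ps <- posterior_summary(x)
    ps$units <- "mutations/locus/mitosis"
    class(ps) <- c("rate_estimate", class(ps))
    ps
  }
  out <- list(
    rate_at = rate(marg("A:T")), rate_cg = rate(marg("C:G")),
    length_slope = posterior_summary(d[, "length"]),
    draws = d, strata = cbind(strata, loci = loci, count = y),
    rhat = fit$rhat
  )
  out$ratio <- rate_ratio(out$rate_at, out$rate_cg)
  out
}

#' Per-domain deletion and insertion rates
#'
#' Per-bp per-mitosis rates of deletions and insertions in each stratum
#' (euchromatin, H3K27me3, H3K9me3 excluding centromeres, centromeric), with
#' posterior ratios against euchromatin. Deletions are reported both overall
#' and excluding repeats.
#'
#' @param records classified indels.
#' @param design [experiment_design()].
#' @param composition [composition_table()] (per-stratum callable bp).
#' @param chains,warmup,iter MCMC settings.
#' @return data frame per (kind, subset, stratum): count, rate median and
#'   HPD, ratio vs euchromatin with `different`/`undefined` flags.
#' @export
domain_indel_rates <- function(records, design, composition,
                               chains = 4, warmup = 1000, iter = 3000) {
  combos <- list(
    list(kind = "deletion", subset = "all"),
    list(kind = "deletion", subset = "excl_repeats"),
    list(kind = "insertion", subset = "all")
  )
  bp <- setNames(composition$callable_bp, composition$stratum)
  rows <- list()
  for (cb in combos) {
    r <- records[records$kind == cb$kind, , drop = FALSE]
    if (cb$subset == "excl_repeats") r <- r[r$category == "nonrepeat", , drop = FALSE]
    ests <- list()
    for (s in STRATA) {
      count <- sum(r$stratum == s, na.rm = TRUE)
      alpha <- suppressWarnings(fit_poisson_rate(
        count, exposure = bp[[s]] * design$n_lines * design$t * .m_med(design),
        chains = chains, warmup = warmup, iter = iter))
      mu <- posterior_summary(exp(alpha$draws))
      mu$units <- "mutations/bp/mitosis"
      class(mu) <- c("rate_estimate", class(mu))
      ests[[s]] <- list(count = count, mu = mu)
    }
    for (s in STRATA) {
      ratio <- if (s == "euchromatin") NULL else {
        rate_ratio(ests[[s]]$mu, ests[["euchromatin"]]$mu)
      }
      undefined <- ests[[s]]$count == 0 && ests[["euchromatin"]]$count == 0
      rows[[length(rows) + 1L]] <- data.frame(
        kind = cb$kind, subset = cb$subset, stratum = s,
        count = ests[[s]]$count,
        rate = ests[[s]]$mu$median,
        rate_lower = ests[[s]]$mu$lower, rate_upper = ests[[s]]$mu$upper,
        ratio_vs_eu = if (is.null(ratio)) NA_real_ else ratio$median,
        ratio_lower = if (is.null(ratio)) NA_real_ else ratio$lower,
        ratio_upper = if (is.null(ratio)) NA_real_ else ratio$upper,
        different = if (is.null(ratio) || undefined) NA else ratio$different,
        undefined = undefined
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
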