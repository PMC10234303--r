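#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels Seqinfo
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

DOMAIN_LABELS <- c("euchromatin", "H3K9me3", "H3K27me3")

#' The four disjoint genome strata
#'
#' Strata used for composition tables and rate models: euchromatin,
#' H3K27me3, H3K9me3 (excluding centromeres) and centromeric. Centromeres
#' are an overlay on H3K9me3, carved out as their own stratum so the
#' additive centromere effect can be estimated on top of the H3K9me3
#' effect.
#' @export
STRATA <- c("euchromatin", "H3K27me3", "H3K9me3", "centromeric")

.base_code <- function(chars) {
  # A=1, C=2, G=3, T=4, N/other = NA
  match(chars, c("A", "C", "G", "T"))
}

# Integer base codes per contig, computed once at load time.
.codes_from_seq <- function(seqs) {
  lapply(as.character(seqs), function(s) {
    .base_code(strsplit(s, "", fixed = TRUE)[[1]])
  })
}

#' Read a BED3 file of domain intervals
#'
#' Native BED convention (0-based, half-open) converted to the 1-based closed
#' convention used internally. Only the first three columns are used.
#'
#' @param path BED file path.
#' @param seqinfo optional `Seqinfo` to validate contigs and bounds against.
#' @return `GRanges`
#' @export
read_bed <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GRanges(seqinfo = seqinfo))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3L) {
      stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields", i, path))
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop(sprintf("malformed BED line %d in '%s': bad coordinates", i, path))
    }
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- as.numeric(vapply(parts, `[`, "", 2L))
  end0 <- as.numeric(vapply(parts, `[`, "", 3L))
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (!is.null(seqinfo)) {
    missing <- setdiff(unique(chrom), seqlevels(seqinfo))
    if (length(missing) > 0L) {
      stop(sprintf("BED file '%s' refers to contig(s) absent from the genome: %s",
                   path, paste(missing, collapse = ", ")))
    }
    GenomeInfoDb::seqlevels(gr) <- seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
    too_far <- end(gr) > seqlengths(seqinfo)[as.character(seqnames(gr))]
    if (any(too_far)) {
      stop(sprintf("BED file '%s': interval(s) extend past contig end", path))
    }
  }
  reduce(sort(gr))
}

.write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Load a genome with its chromatin-domain annotation
#'
#' Reads the genome FASTA and three BED interval sets (H3K9me3, H3K27me3 and
#' centromeres) and builds the domain partition: H3K9me3 and H3K27me3
#' intervals with euchromatin as their complement, tiling every contig
#' without overlap. Overlaps between the two input marks are resolved with
#' H3K9me3 priority (H3K27me3 truncated). Centromeres are a boolean overlay,
#' forced to lie inside H3K9me3 (the H3K9me3 set is extended by union if
#' needed, with a warning).
#'
#' @param fasta path to the genome FASTA, or a `DNAStringSet`.
#' @param k9_bed,k27_bed,cen_bed BED3 paths (or `GRanges`) for H3K9me3,
#'   H3K27me3 and centromeric intervals. `NULL` means none.
#' @return object of class `genome_annotation`: list with elements `seq`
#'   (`DNAStringSet`), `seqinfo`, `domains` (labelled `GRanges` tiling the
#'   genome), `cen` (`GRanges` overlay), `strata` (disjoint `GRanges` over
#'   the four strata euchromatin / H3K27me3 / H3K9me3 / centromeric) and
#'   cached integer base codes.
#' @export
load_annotation <- function(fasta, k9_bed = NULL, k27_bed = NULL,
                            cen_bed = NULL) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in FASTA")
  if (any(Biostrings::width(seqs) == 0L)) stop("zero-length contig in FASTA")
  chars <- Biostrings::uniqueLetters(seqs)
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(setdiff(chars, c("A", "C", "G", "T", "N")), collapse = ", "))
  }
  si <- Seqinfo(names(seqs), Biostrings::width(seqs))

  as_gr <- function(x) {
    if (is.null(x)) return(GRanges(seqinfo = si))
    if (inherits(x, "GRanges")) {
      GenomeInfoDb::seqlevels(x) <- seqlevels(si)
      GenomeInfoDb::seqinfo(x) <- si
      return(reduce(sort(x)))
    }
    read_bed(x, si)
  }
  k9 <- as_gr(k9_bed)
  k27 <- as_gr(k27_bed)
  cen <- as_gr(cen_bed)

  outside <- length(setdiff(cen, k9)) > 0 && sum(width(setdiff(cen, k9))) > 0
  if (outside) {
    warning("centromeric intervals extend outside H3K9me3; extending H3K9me3 by union")
  }
  k9 <- reduce(union(k9, cen))
  k27 <- setdiff(k27, k9)   # H3K9me3 priority on overlap
  genome_gr <- GRanges(seqlevels(si), IRanges(1, seqlengths(si)), seqinfo = si)
  eu <- setdiff(genome_gr, union(k9, k27))

  lab <- function(gr, label) {
    if (length(gr)) mcols(gr)$label <- label
    gr
  }
  domains <- sort(c(lab(eu, "euchromatin"), lab(k9, "H3K9me3"),
                    lab(k27, "H3K27me3")))

  k9_ex_cen <- setdiff(k9, cen)
  st <- function(gr, s) {
    if (length(gr)) mcols(gr)$stratum <- s
    gr
  }
  strata <- sort(c(st(eu, "euchromatin"), st(k27, "H3K27me3"),
                   st(k9_ex_cen, "H3K9me3"), st(cen, "centromeric")))

  stopifnot(sum(width(domains)) == sum(as.numeric(seqlengths(si))))

  structure(
    list(seq = seqs, seqinfo = si, domains = domains, cen = cen,
         strata = strata, codes = .codes_from_seq(seqs)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  bp <- tapply(width(x$strata), mcols(x$strata)$stratum, sum)
  cat(sprintf("genome_annotation: %d contig(s), %s bp\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)), big.mark = ",")))
  for (s in STRATA) {
    cat(sprintf("  %-12s %s bp\n", s,
                format(ifelse(is.na(bp[s]), 0, bp[s]), big.mark = ",")))
  }
  invisible(x)
}

# Per-contig integer stratum vector (index into STRATA).
.stratum_vector <- function(ann, contig) {
  len <- seqlengths(ann$seqinfo)[[contig]]
  v <- integer(len)
  gr <- ann$strata[seqnames(ann$strata) == contig]
  idx <- match(mcols(gr)$stratum, STRATA)
  for (i in seq_along(gr)) {
    v[start(gr)[i]:end(gr)[i]] <- idx[i]
  }
  v
}

# ---- trinucleotide classes ---------------------------------------------

.trinuc_table <- local({
  bases <- c("A", "C", "G", "T")
  tri <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  tri <- sort(tri)  # lexicographic: index = 16*(b1-1) + 4*(b2-1) + (b3-1) + 1
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  rcs <- vapply(tri, rc, "")
  # representative: the strand whose focal (middle) base is A or C
  canon <- ifelse(substr(tri, 2, 2) %in% c("A", "C"), tri, rcs)
  classes <- sort(unique(canon))
  list(tri = tri, rc = rcs, canon = canon,
       class_names = paste0(classes, ":", vapply(classes, rc, "")),
       class_index = match(canon, classes))
})

#' Canonical trinucleotide classes
#'
#' The 64 trinucleotides collapse with their reverse complements into 32
#' classes (the strand of a mutation is unknown). The class representative
#' is the strand whose focal base is A or C, displayed as
#' `"REP:REVCOMP"`, e.g. `"TCT:AGA"` or `"GAT:ATC"`.
#'
#' @return character vector of the 32 class names.
#' @export
trinuc_classes <- function() .trinuc_table$class_names

#' Collapse a trinucleotide to its canonical class
#'
#' @param tri character vector of trinucleotides over A/C/G/T.
#' @return class names (`"MIN:REVCOMP"`); `NA` for trinucleotides containing
#'   other letters.
#' @export
trinuc_class <- function(tri) {
  i <- match(toupper(tri), .trinuc_table$tri)
  .trinuc_table$class_names[.trinuc_table$class_index[i]]
}

#' Trinucleotide census by stratum
#'
#' Counts, for every interior position of every contig, the canonical class
#' of the trinucleotide centred there, stratified by the stratum of the
#' focal (middle) base. Positions whose trinucleotide contains N are
#' skipped.
#'
#' @param ann `genome_annotation`.
#' @return integer matrix, 32 rows (classes) by 4 strata columns.
#' @export
trinucleotide_census <- function(ann) {
  out <- matrix(0L, 32L, length(STRATA),
                dimnames = list(trinuc_classes(), STRATA))
  for (contig in names(ann$seq)) {
    code <- ann$codes[[contig]]
    n <- length(code)
    if (n < 3L) next
    b1 <- code[1:(n - 2)]
    b2 <- code[2:(n - 1)]
    b3 <- code[3:n]
    tri_idx <- 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3   # NA if any N
    st <- .stratum_vector(ann, contig)[2:(n - 1)]
    ok <- !is.na(tri_idx) & st > 0L
    cls <- .trinuc_table$class_index[tri_idx[ok]]
    tab <- tapply(rep(1L, sum(ok)), list(factor(cls, 1:32), factor(st[ok], 1:4)), sum)
    tab[is.na(tab)] <- 0L
    out <- out + tab
  }
  out
}

#' Base-pair composition by stratum
#'
#' @param ann `genome_annotation`.
#' @return data frame with one row per stratum: `callable_bp` (non-N),
#'   `at_pairs`, `cg_pairs` and `gc_fraction`.
#' @export
composition_table <- function(ann) {
  at <- cg <- setNames(numeric(length(STRATA)), STRATA)
  for (contig in names(ann$seq)) {
    code <- ann$codes[[contig]]
    st <- .stratum_vector(ann, contig)
    ok <- !is.na(code)
    is_gc <- code %in% c(2L, 3L)
    for (k in seq_along(STRATA)) {
      sel <- st == k & ok
      cg[k] <- cg[k] + sum(is_gc & sel)
      at[k] <- at[k] + sum(sel) - sum(is_gc & sel)
    }
  }
  data.frame(stratum = STRATA, callable_bp = at + cg,
             at_pairs = at, cg_pairs = cg,
             gc_fraction = ifelse(at + cg > 0, cg / (at + cg), NA_real_),
             row.names = NULL)
}

#' Homopolymer catalog
#'
#' Maximal runs of a single base of at least `min_len` bp. Runs containing N
#' never qualify; runs never overlap by construction.
#'
#' @param ann `genome_annotation`.
#' @param min_len minimum run length (default 5, the usual minimum for
#'   slippage-prone homopolymers; must be >= 2).
#' @return data frame: `contig`, `start`, `end` (1-based closed), `base`,
#'   `type` (`"A:T"` or `"C:G"`), `length`, `stratum` (of the run start).
#' @export
find_homopolymers <- function(ann, min_len = 5) {
  if (min_len < 2) stop("min_len must be >= 2")
  res <- list()
  for (contig in names(ann$seq)) {
    code <- ann$codes[[contig]]
    r <- rle(ifelse(is.na(code), 0L, code))
    keep <- r$lengths >= min_len & r$values > 0L
    if (!any(keep)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    st <- .stratum_vector(ann, contig)
    res[[contig]] <- data.frame(
      contig = contig,
      start = starts[keep], end = ends[keep],
      base = c("A", "C", "G", "T")[r$values[keep]],
      type = ifelse(r$values[keep] %in% c(1L, 4L), "A:T", "C:G"),
      length = r$lengths[keep],
      stratum = STRATA[st[starts[keep]]],
      row.names = NULL
    )
  }
  if (length(res) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), base = character(), type = character(),
                      length = integer(), stratum = character()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tile the genome into fixed-width windows
#'
#' Windows are non-overlapping and fixed-width except for the final window of
#' each contig. GC fraction is computed over non-N bases; `callable_bp` is the
#' number of non-N bases. The domain label is assigned by majority base
#' overlap with ties broken toward the rarer label (H3K9me3 over H3K27me3
#' over euchromatin); the centromeric flag is set when at least half of the
#' window is centromeric.
#'
#' @param ann `genome_annotation`.
#' @param width window width in bp (>= 50; default 200).
#' @return data frame (`WindowTable`): `contig`, `start`, `end`,
#'   `gc_fraction` (NA if no callable base), `domain`, `centromeric`,
#'   `stratum`, `callable_bp`.
#' @export
make_windows <- function(ann, width = 200) {
  if (width < 50) stop("window width must be >= 50")
  res <- list()
  for (contig in names(ann$seq)) {
    code <- ann$codes[[contig]]
    n <- length(code)
    starts <- seq.int(1L, n, by = width)
    ends <- pmin(starts + width - 1L, n)
    cuts <- c(0L, ends)

    wsum <- function(x) diff(cumsum(c(0, x))[cuts + 1L])
    callable <- wsum(!is.na(code))
    gc <- wsum(!is.na(code) & code %in% c(2L, 3L))
    st <- .stratum_vector(ann, contig)
    cnt <- vapply(1:4, function(k) wsum(st == k), numeric(length(starts)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
    # majority over the 3 labels; centromeric bases count as H3K9me3
    lab_cnt <- cbind(euchromatin = cnt[, 1], H3K9me3 = cnt[, 3] + cnt[, 4],
                     H3K27me3 = cnt[, 2])
    pref <- c("H3K9me3", "H3K27me3", "euchromatin")
    domain <- apply(lab_cnt, 1, function(x) {
      pref[which.max(x[pref])]  # which.max takes the first, i.e. rarer, label
    })
    res[[contig]] <- data.frame(
      contig = contig, start = starts, end = ends,
      gc_fraction = ifelse(callable > 0, gc / callable, NA_real_),
      domain = domain,
      centromeric = cnt[, 4] >= (ends - starts + 1) / 2,
      callable_bp = callable,
      row.names = NULL
    )
  }
  out <- do.call(rbind, res)
  out$stratum <- ifelse(out$centromeric, "centromeric",
                 ifelse(out$domain == "H3K9me3", "H3K9me3",
                 ifelse(out$domain == "H3K27me3", "H3K27me3", "euchromatin")))
  rownames(out) <- NULL
  out
}

#' Annotate mutation records with their genomic context
#'
#' Joins a mutation table to the domain partition, the trinucleotide class of
#' the mutated base (SNMs), the homopolymer run containing the record
#' (indels) and the GC fraction of the enclosing window.
#'
#' @param mutations data frame with columns `line_id`, `contig`, `pos`
#'   (1-based), `ref`, `alt`, `kind` (one of `snm`, `insertion`, `deletion`,
#'   `translocation`, `complex`) and `length` (bp; 1 for SNMs).
#' @param ann `genome_annotation`.
#' @param homopolymers optional precomputed catalog from
#'   [find_homopolymers()]; computed on the fly if missing.
#' @param window_width width used for the window GC column (default 200).
#' @return the input with columns `domain`, `centromeric`, `stratum`,
#'   `trinuc_class`, `homopolymer` (logical), `polymer_type`,
#'   `polymer_length`, `window_gc` added.
#' @export
annotate_mutations <- function(mutations, ann, homopolymers = NULL,
                               window_width = 200) {
  m <- as.data.frame(mutations)
  needed <- c("line_id", "contig", "pos", "kind")
  if (!all(needed %in% names(m))) {
    stop("mutation table must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(m$contig %in% names(ann$seq))) {
    stop("mutation record(s) on contig(s) absent from the genome")
  }
  lens <- seqlengths(ann$seqinfo)[m$contig]
  if (any(m$pos < 1 | m$pos > lens)) stop("mutation position(s) outside contig")
  if (is.null(m$length)) m$length <- 1L

  # reference-allele check for SNMs
  is_snm <- m$kind == "snm"
  if (any(is_snm)) {
    genome_base <- vapply(which(is_snm), function(i) {
      c("A", "C", "G", "T", "N")[min(ann$codes[[m$contig[i]]][m$pos[i]], 5, na.rm = TRUE)]
    }, "")
    genome_base[is.na(genome_base)] <- "N"
    bad <- toupper(m$ref[is_snm]) != genome_base
    if (any(bad)) {
      idx <- which(is_snm)[bad]
      stop("SNM reference allele mismatches genome at record(s): ",
           paste(sprintf("%s:%d (%s!=%s)", m$contig[idx], m$pos[idx],
                         m$ref[idx], genome_base[bad]), collapse = "; "))
    }
  }

  gr <- GRanges(m$contig, IRanges(m$pos, m$pos), seqinfo = ann$seqinfo)
  ov <- findOverlaps(gr, ann$strata, select = "first")
  m$stratum <- mcols(ann$strata)$stratum[ov]
  m$centromeric <- m$stratum == "centromeric"
  m$domain <- ifelse(m$centromeric, "H3K9me3", m$stratum)

  m$trinuc_class <- NA_character_
  if (any(is_snm)) {
    m$trinuc_class[is_snm] <- vapply(which(is_snm), function(i) {
      code <- ann$codes[[m$contig[i]]]
      p <- m$pos[i]
      if (p < 2L || p > length(code) - 1L) return(NA_character_)
      tri <- code[(p - 1):(p + 1)]
      if (anyNA(tri)) return(NA_character_)
      .trinuc_table$class_names[
        .trinuc_table$class_index[16L * (tri[1] - 1L) + 4L * (tri[2] - 1L) + tri[3]]]
    }, "")
  }

  if (is.null(homopolymers)) homopolymers <- find_homopolymers(ann)
  m$homopolymer <- FALSE
  m$polymer_type <- NA_character_
  m$polymer_length <- NA_integer_
  m$polymer_base <- NA_character_
  is_indel <- m$kind %in% c("insertion", "deletion")
  if (any(is_indel) && nrow(homopolymers) > 0L) {
    span_end <- ifelse(m$kind == "deletion", m$pos + m$length - 1L, m$pos)
    mg <- GRanges(m$contig[is_indel],
                  IRanges(m$pos[is_indel], span_end[is_indel]),
                  seqinfo = ann$seqinfo)
    hg <- GRanges(homopolymers$contig,
                  IRanges(homopolymers$start, homopolymers$end),
                  seqinfo = ann$seqinfo)
    hit <- findOverlaps(mg, hg, type = "within", select = "first")
    rows <- which(is_indel)[!is.na(hit)]
    hidx <- hit[!is.na(hit)]
    m$homopolymer[rows] <- TRUE
    m$polymer_type[rows] <- homopolymers$type[hidx]
    m$polymer_length[rows] <- homopolymers$length[hidx]
    m$polymer_base[rows] <- homopolymers$base[hidx]
  }

  win_idx <- (m$pos - 1L) %/% window_width
  m$window_gc <- vapply(seq_len(nrow(m)), function(i) {
    code <- ann$codes[[m$contig[i]]]
    a <- win_idx[i] * window_width + 1L
    b <- min(a + window_width - 1L, length(code))
    w <- code[a:b]
    w <- w[!is.na(w)]
    if (length(w) == 0L) return(NA_real_)
    mean(w %in% c(2L, 3L))
  }, numeric(1))
  m
}
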