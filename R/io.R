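#' Read a mutation table
#'
#' Accepts either the package's TSV layout (columns `line_id`, `contig`,
#' `pos`, `ref`, `alt`, `kind`, `length`, optional `seq`) or a VCF, in which
#' case the record kind is inferred from the REF/ALT lengths (equal length 1
#' = SNM, longer ALT = insertion, longer REF = deletion) and the line
#' identifier is taken from the sample column with a non-reference call.
#'
#' @param path TSV or VCF file.
#' @return mutation data frame.
#' @export
read_mutations <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ref <- vcfR::getREF(v)
    alt <- vcfR::getALT(v)
    kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snm",
            ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
    len <- ifelse(kind == "snm", 1L, abs(nchar(alt) - nchar(ref)))
    gt <- vcfR::extract.gt(v, element = "GT")
    line <- apply(gt, 1, function(g) {
      i <- which(!is.na(g) & g != "0" & g != "0/0" & g != "0|0")
      if (length(i)) colnames(gt)[i[1]] else NA_character_
    })
    out <- data.frame(line_id = line, contig = vcfR::getCHROM(v),
                      pos = as.integer(vcfR::getPOS(v)),
                      ref = ref, alt = alt, kind = kind, length = len,
                      seq = ifelse(kind == "insertion", substring(alt, 2),
                                   NA_character_))
    # indel VCF convention anchors on the base before the event
    out$pos[out$kind != "snm"] <- out$pos[out$kind != "snm"] + 1L
    out$ref[out$kind != "snm"] <- NA_character_
    out$alt[out$kind != "snm"] <- NA_character_
    return(out)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a mutation table as TSV
#'
#' @param mutations mutation data frame.
#' @param path output file.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a composition table as TSV
#'
#' @param composition data frame from [composition_table()].
#' @param path output file.
#' @export
write_composition <- function(composition, path) {
  utils::write.table(composition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
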