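#' Read a VCF file with DP/RO/AO per-sample counts into a variant table
#'
#' Parses a VCF (the freebayes output dialect: per-sample FORMAT fields
#' `DP`, `RO`, `AO`) via \pkg{vcfR} and returns the package's internal
#' [variant_table()]. Multiallelic records and non-SNP records (REF or ALT
#' longer than one base) are excluded, since all downstream analyses operate
#' on biallelic SNPs only. Samples with a missing genotype at a site are
#' recorded as `NA`, never as zero counts.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param required_fields FORMAT fields that must be present in every
#'   record; absence is a fatal error naming the missing field.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, required_fields = c("DP", "RO", "AO")) {
  if (!file.exists(path)) stop_hk("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE]
  if (nrow(fix) == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(variant_table(data.frame(contig = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0)),
                         dp = empty, ro = empty, ao = empty))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_drop <- sum(!keep)
  if (n_drop) hk_log("read_vcf: excluding %d multiallelic/non-SNP records",
                     n_drop)
  sites <- data.frame(contig = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  # sortedness contract: positions non-decreasing within each contig
  if (any(unlist(tapply(sites$pos, factor(sites$contig,
                                          unique(sites$contig)),
                        function(p) diff(p) < 0))))
    stop_hk("unsorted VCF: positions decrease within a contig in %s", path)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop_hk("VCF has no sample columns with FORMAT data: %s", path)
  fmt <- gt[keep, "FORMAT", drop = TRUE]
  for (f in required_fields) {
    present <- vapply(strsplit(fmt, ":", fixed = TRUE),
                      function(x) f %in% x, logical(1))
    if (!all(present))
      stop_hk("required FORMAT field '%s' absent from %d record(s) in %s",
              f, sum(!present), path)
  }
  grab <- function(f) {
    m <- vcfR::extract.gt(v, element = f, as.numeric = TRUE)
    m[keep, , drop = FALSE]
  }
  dp <- grab("DP"); ro <- grab("RO"); ao <- grab("AO")
  variant_table(sites, dp = dp, ro = ro, ao = ao)
}

#' Write a variant table as VCF v4.2 with DP/RO/AO FORMAT fields
#'
#' @param table a [variant_table()].
#' @param path output path.
#' @param contig_lengths optional named vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, contig_lengths = NULL) {
  stopifnot(inherits(table, "variant_table"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=heterokaryon",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
           "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
           "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", table$samples),
                      collapse = "\t"))
  fmt1 <- function(dp, ro, ao) {
    out <- sprintf("%d:%d:%d", as.integer(dp), as.integer(ro),
                   as.integer(ao))
    out[is.na(dp) | is.na(ro) | is.na(ao)] <- "."
    out
  }
  cols <- lapply(seq_along(table$samples), function(j)
    fmt1(table$dp[, j], table$ro[, j], table$ao[, j]))
  body <- do.call(paste, c(list(table$sites$contig, table$sites$pos, ".",
                                table$sites$ref, table$sites$alt, ".",
                                "PASS", ".", "DP:RO:AO"),
                           cols, sep = "\t"))
  writeLines(c(hdr, if (nrow(table$sites)) body), path)
  invisible(path)
}

#' Read repeat annotation intervals from a BED file
#'
#' Intervals are 0-based half-open, per the BED convention. Overlapping or
#' book-ended intervals on the same contig are merged.
#'
#' @param path path to a BED file with at least 3 columns.
#' @return A data.frame with columns `contig`, `start`, `end` (0-based,
#'   half-open), merged and sorted; class `repeat_intervals`.
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) stop_hk("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(repeat_intervals(NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop_hk("BED line %d has fewer than 3 columns",
            which(ncols < 3L)[1])
  df <- data.frame(contig = vapply(parts, `[`, "", 1L),
                   start = as.numeric(vapply(parts, `[`, "", 2L)),
                   end = as.numeric(vapply(parts, `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad))
    stop_hk("BED line %d: start must be < end", bad[1])
  repeat_intervals(df)
}

# normalise + merge a contig/start/end frame into the canonical interval set
repeat_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0))
    class(out) <- c("repeat_intervals", "data.frame")
    return(out)
  }
  merged <- lapply(split(df, df$contig), function(d) {
    # IRanges is 1-based closed; shift BED [s,e) to [s+1, e]
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(contig = d$contig[1],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_intervals", "data.frame")
  out
}

#' Write repeat intervals to BED
#'
#' @param repeats a `repeat_intervals` data.frame (contig, start, end;
#'   0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(repeats, path) {
  utils::write.table(repeats[, c("contig", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Test which 1-based site positions fall inside repeat intervals
#'
#' A 1-based position `p` lies in a 0-based half-open interval `[s, e)`
#' iff `s <= p - 1 < e`.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based).
#' @param repeats a `repeat_intervals` data.frame.
#' @return Logical vector along the rows of `sites`.
#' @export
sites_in_repeats <- function(sites, repeats) {
  if (nrow(repeats) == 0L || nrow(sites) == 0L)
    return(rep(FALSE, nrow(sites)))
  out <- rep(FALSE, nrow(sites))
  for (ctg in unique(sites$contig)) {
    ri <- repeats[repeats$contig == ctg, , drop = FALSE]
    if (!nrow(ri)) next
    si <- which(sites$contig == ctg)
    p0 <- sites$pos[si] - 1                    # to 0-based
    idx <- findInterval(p0, ri$start)          # intervals sorted, disjoint
    hit <- idx > 0 & p0 < ri$end[pmax(idx, 1L)]
    out[si] <- hit
  }
  out
}

#' Read / write nucleus MAT-identity assignments
#'
#' Two-column tab-separated table: `nucleus_id`, `mat` (values `MAT-1` or
#' `MAT-2`). MAT identity is determined upstream (e.g. by PCR genotyping)
#' and kept in a sidecar rather than in VCF headers.
#'
#' @param path file path.
#' @return `read_mat_table`: data.frame with columns `nucleus_id`, `mat`.
#' @export
read_mat_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("nucleus_id", "mat"),
                          colClasses = "character")
  bad <- setdiff(unique(df$mat), c("MAT-1", "MAT-2"))
  if (length(bad))
    stop_hk("invalid MAT labels: %s", paste(bad, collapse = ", "))
  df
}

#' @rdname read_mat_table
#' @param mat data.frame with columns `nucleus_id`, `mat`.
#' @export
write_mat_table <- function(mat, path) {
  utils::write.table(mat[, c("nucleus_id", "mat")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write rDNA copies as plain FASTA
#'
#' @param copies named character vector of sequences over \{A,C,G,T\}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdna_fasta <- function(copies, path) {
  ds <- Biostrings::DNAStringSet(copies)
  Biostrings::writeXStringSet(ds, path)
  invisible(path)
}
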