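#' Construct a diploid biallelic variant matrix
#'
#' Genotypes are stored as alternate-allele dosage (0, 1, 2, or `NA` for
#' missing) in an `N x P` integer matrix over strictly increasing 1-based
#' reference positions on a single segment.
#'
#' @param sample_ids character vector, length `N >= 2`.
#' @param positions strictly increasing integer vector of 1-based positions.
#' @param geno `N x P` integer matrix of alt-allele dosages (`NA` = missing).
#' @param segment_length reference segment length in bp.
#' @return object of class `variant_matrix`.
#' @export
variant_matrix <- function(sample_ids, positions, geno, segment_length) {
  stopifnot(length(sample_ids) >= 2L, !anyDuplicated(sample_ids))
  positions <- as.integer(positions)
  if (length(positions) && (any(diff(positions) <= 0L)))
    stop("variant_matrix: positions must be strictly increasing")
  if (length(positions) && (positions[1L] < 1L ||
      positions[length(positions)] > segment_length))
    stop("variant_matrix: positions outside [1, segment_length]")
  geno <- matrix(as.integer(geno), nrow = length(sample_ids),
                 dimnames = list(sample_ids, positions))
  if (ncol(geno) != length(positions))
    stop("variant_matrix: geno must have one column per position")
  if (any(!is.na(geno) & !(geno %in% 0:2)))
    stop("variant_matrix: genotypes must be dosages 0/1/2 or NA")
  structure(list(sample_ids = sample_ids, positions = positions,
                 geno = geno, segment_length = as.integer(segment_length)),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d samples x %d sites on %d bp segment (%.3f missing)\n",
              length(x$sample_ids), length(x$positions), x$segment_length,
              mean(is.na(x$geno))))
  invisible(x)
}

#' Read a minimal biallelic-SNP VCF
#'
#' Parses a single-contig, GT-only VCF v4.2 dialect.  Sites that are not
#' biallelic SNPs, or whose FILTER is neither `PASS` nor `.`, are dropped and
#' tallied in the returned drop-log.  `./.` (or any `.`-containing call)
#' becomes missing; the phase separator `|` is treated as `/`.
#'
#' @param path VCF text file.
#' @return list with elements `matrix` ([variant_matrix()]) and `drop_log`
#'   (named integer vector: `not_biallelic`, `not_snp`, `filter_fail`).
#' @export
read_vcf_biallelic <- function(path) {
  if (!file.exists(path)) stop("read_vcf_biallelic: no such file: ", path)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (!length(hdr_i)) stop("read_vcf_biallelic: missing #CHROM header line")
  hdr <- strsplit(lines[hdr_i[1L]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stop("read_vcf_biallelic: no sample columns")
  samples <- hdr[-(1:9)]
  seg_len <- NA_integer_
  contig <- grep("^##contig=", lines, value = TRUE)
  if (length(contig) == 1L) {
    m <- regmatches(contig, regexec("length=([0-9]+)", contig))[[1]]
    if (length(m) == 2L) seg_len <- as.integer(m[2])
  }
  body <- lines[-seq_len(hdr_i[1L])]
  body <- body[nzchar(body)]
  drop_log <- c(not_biallelic = 0L, not_snp = 0L, filter_fail = 0L)
  pos <- integer(0)
  rows <- list()
  chroms <- character(0)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    chroms <- union(chroms, f[1])
    if (length(chroms) > 1L)
      stop("read_vcf_biallelic: more than one contig is unsupported")
    alt <- f[5]; ref <- f[4]; filt <- f[7]
    if (grepl(",", alt, fixed = TRUE)) {
      drop_log["not_biallelic"] <- drop_log["not_biallelic"] + 1L; next
    }
    if (nchar(ref) != 1L || nchar(alt) != 1L ||
        !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES)) {
      drop_log["not_snp"] <- drop_log["not_snp"] + 1L; next
    }
    if (!(filt %in% c("PASS", "."))) {
      drop_log["filter_fail"] <- drop_log["filter_fail"] + 1L; next
    }
    gt_idx <- match("GT", strsplit(f[9], ":", fixed = TRUE)[[1]])
    if (is.na(gt_idx)) stop("read_vcf_biallelic: FORMAT lacks GT at POS ", f[2])
    calls <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1), gt_idx)
    calls <- gsub("|", "/", calls, fixed = TRUE)
    dos <- rep(NA_integer_, length(calls))
    ok <- !grepl(".", calls, fixed = TRUE)
    dos[ok] <- vapply(strsplit(calls[ok], "/", fixed = TRUE),
                      function(a) sum(as.integer(a)), integer(1))
    pos <- c(pos, as.integer(f[2]))
    rows[[length(rows) + 1L]] <- dos
  }
  geno <- if (length(rows)) do.call(cbind, rows) else
    matrix(integer(0), nrow = length(samples))
  if (is.na(seg_len)) seg_len <- if (length(pos)) max(pos) else 1L
  o <- order(pos)
  vm <- variant_matrix(samples, pos[o], geno[, o, drop = FALSE], seg_len)
  cp_log("info", "read_vcf_biallelic: kept %d site(s), dropped %d (%s)",
         length(pos), sum(drop_log),
         paste(names(drop_log), drop_log, sep = "=", collapse = ", "))
  list(matrix = vm, drop_log = drop_log)
}

#' Write a variant matrix as minimal VCF v4.2
#'
#' The matrix stores dosages only, so placeholder `REF=A`, `ALT=G` bases are
#' written; genotypes are emitted unphased with FILTER `PASS`.
#'
#' @param vm [variant_matrix()].
#' @param path output file.
#' @param contig contig name.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vm, path, contig = "seg1") {
  stopifnot(inherits(vm, "variant_matrix"))
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(vm$positions), function(j) {
    calls <- ifelse(is.na(vm$geno[, j]), "./.", gt[vm$geno[, j] + 1L])
    paste(c(contig, vm$positions[j], ".", "A", "G", ".", "PASS", ".", "GT",
            calls), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig, vm$segment_length),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vm$sample_ids), collapse = "\t"),
               body), path)
  invisible(path)
}
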