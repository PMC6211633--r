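#' Construct an allele sequence record
#'
#' An `allele_sequence` bundles a named DNA sequence with its gene label
#' (`B1`/`B2` parental, `B3` chimeric, or `other`), a free-text region label,
#' and exon/intron feature annotation in 0-based half-open sequence
#' coordinates.
#'
#' @param id sequence identifier (non-empty).
#' @param sequence DNA string over `A,C,G,T,N` plus `-` when aligned.
#' @param gene_label one of `"B1"`, `"B2"`, `"B3"`, `"other"`.
#' @param region_label free text, e.g. `"Australia"`; `""` when unknown.
#' @param features `data.frame` with columns `kind` (`"exon"`/`"intron"`),
#'   `start`, `end` (0-based half-open, within the sequence, non-overlapping).
#' @return object of class `allele_sequence`.
#' @export
allele_sequence <- function(id, sequence, gene_label = "other",
                            region_label = "", features = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("allele_sequence: empty sequence for record '", id, "'")
  if (grepl("[^ACGTN-]", sequence))
    stop("allele_sequence: invalid characters in sequence '", id, "'")
  gene_label <- match.arg(gene_label, c("B1", "B2", "B3", "other"))
  if (is.null(features))
    features <- data.frame(kind = character(), start = integer(), end = integer())
  stopifnot(all(c("kind", "start", "end") %in% names(features)))
  len <- nchar(sequence)
  if (nrow(features)) {
    stopifnot(all(features$kind %in% c("exon", "intron")),
              all(features$start >= 0), all(features$end <= len),
              all(features$start < features$end))
    o <- order(features$start)
    features <- features[o, , drop = FALSE]
    if (nrow(features) > 1L &&
        any(features$start[-1L] < features$end[-nrow(features)]))
      stop("allele_sequence: overlapping features in '", id, "'")
  }
  structure(list(id = id, gene_label = gene_label,
                 region_label = region_label, sequence = sequence,
                 features = features),
            class = "allele_sequence")
}

#' @export
print.allele_sequence <- function(x, ...) {
  cat(sprintf("<allele_sequence> %s [%s%s] %d bp, %d feature(s)\n",
              x$id, x$gene_label,
              if (nzchar(x$region_label)) paste0(", ", x$region_label) else "",
              nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

# intron span of an allele_sequence, or NULL
intron_span <- function(allele) {
  f <- allele$features
  f <- f[f$kind == "intron", , drop = FALSE]
  if (!nrow(f)) return(NULL)
  c(f$start[1L], f$end[1L])
}

#' Read allele sequences from FASTA
#'
#' Headers of the form `id|gene|region` populate `gene_label` and
#' `region_label`; bare headers yield `gene_label = "other"` and an empty
#' region.  Records are returned in file order.
#'
#' @param path FASTA file.
#' @return list of [allele_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  seqs <- unname(as.character(set))
  out <- vector("list", length(set))
  ids <- character(length(set))
  for (i in seq_along(set)) {
    hdr <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    id <- trimws(hdr[1])
    if (!nzchar(id)) stop("read_fasta: record ", i, " has an empty id")
    gene <- if (length(hdr) >= 2 && hdr[2] %in% c("B1", "B2", "B3")) hdr[2] else "other"
    region <- if (length(hdr) >= 3) hdr[3] else ""
    if (!nzchar(seqs[i]))
      stop("read_fasta: record '", id, "' has an empty sequence")
    ids[i] <- id
    out[[i]] <- allele_sequence(id, toupper(seqs[i]), gene, region)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("read_fasta: duplicate id(s): ", paste(unique(dup), collapse = ", "))
  out
}

#' Write allele sequences to FASTA
#'
#' Inverse of [read_fasta()] for the fields the FASTA header can carry
#' (id, gene label, region).  Feature annotation is not serialised; the
#' synthetic-data writers emit it as separate truth tables.
#'
#' @param alleles list of [allele_sequence()] (or plain named character vector).
#' @param path output file.
#' @param width line-wrap width in bases.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(alleles, path, width = 60L) {
  if (is.character(alleles)) {
    stopifnot(!is.null(names(alleles)))
    alleles <- mapply(allele_sequence, names(alleles), alleles, SIMPLIFY = FALSE)
  }
  hdr <- vapply(alleles, function(a) {
    if (a$gene_label == "other" && !nzchar(a$region_label)) a$id
    else paste(a$id, a$gene_label, a$region_label, sep = "|")
  }, character(1))
  set <- Biostrings::DNAStringSet(vapply(alleles, `[[`, character(1), "sequence"))
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
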