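#' Construct a PCR primer pair
#'
#' Both primers are written 5'->3'; the reverse primer anneals to the forward
#' strand as its reverse complement, per PCR convention.
#'
#' @param name assay name.
#' @param forward,reverse primer sequences (length >= 12, alphabet `ACGT`).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  for (p in c(forward, reverse)) {
    if (nchar(p) < 12L) stop("primer_pair: primers must be >= 12 nt")
    if (grepl("[^ACGT]", p)) stop("primer_pair: primer alphabet is ACGT")
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' Find primer annealing sites on a template
#'
#' Reports all occurrences of the primer on the forward strand and of its
#' reverse complement on the reverse strand with at most `max_mismatch`
#' mismatches, requiring the three 3'-terminal primer bases to match exactly
#' (the polymerase-extension anchor).  Positions are 0-based coordinates of
#' the primer's 5' end on the forward strand (so the rightmost footprint
#' base for reverse-strand hits).
#'
#' @param template DNA string.
#' @param primer DNA string.
#' @param max_mismatch maximum non-anchor mismatches (default 0).
#' @return data.frame with columns `position`, `strand` (`"+"`/`"-"`),
#'   `mismatches`; empty when the primer is longer than the template.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0L)
  lt <- nchar(template); lp <- nchar(primer)
  empty <- data.frame(position = integer(), strand = character(),
                      mismatches = integer())
  if (lp > lt) return(empty)
  tch <- seq_chars(template)
  starts0 <- 0:(lt - lp)
  scan <- function(pat, anchor_cols) {
    pch <- seq_chars(pat)
    idx <- outer(starts0, seq_len(lp), `+`)  # 1-based template indices
    mm <- matrix(tch[idx] != rep(pch, each = length(starts0)),
                 nrow = length(starts0))
    ok <- rowSums(mm) <= max_mismatch &
      rowSums(mm[, anchor_cols, drop = FALSE]) == 0L
    list(start0 = starts0[ok], mism = rowSums(mm)[ok])
  }
  f <- scan(primer, (lp - 2L):lp)
  r <- scan(revcomp(primer), 1:3)
  out <- rbind(
    data.frame(position = f$start0, strand = rep("+", length(f$start0)),
               mismatches = f$mism),
    data.frame(position = r$start0 + lp - 1L,
               strand = rep("-", length(r$start0)), mismatches = r$mism))
  out[order(out$position), , drop = FALSE]
}

#' Predict the PCR product of a primer pair on a template
#'
#' A product is called present iff a forward-strand hit of the forward primer
#' lies 5' of a reverse-strand hit of the reverse primer within `max_len`;
#' the product spans from the forward primer's 5' end to the reverse
#' primer's 5' end inclusive.  When several pairings exist the shortest
#' (then leftmost) product is returned — the dominant band of a PCR.
#'
#' @param template DNA string.
#' @param pair [primer_pair()].
#' @param max_len maximum amplifiable product length in bp (default 5000).
#' @param max_mismatch passed to [find_primer_sites()].
#' @param template_id optional template label carried into the call.
#' @return object of class `amplicon_call`: `template_id`, `product`
#'   (logical), and when present `product_length` and `product_sequence`.
#' @export
predict_amplicon <- function(template, pair, max_len = 5000L,
                             max_mismatch = 0L, template_id = "") {
  stopifnot(max_len > 0L)
  fwd <- find_primer_sites(template, pair$forward, max_mismatch)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- find_primer_sites(template, pair$reverse, max_mismatch)
  rev <- rev[rev$strand == "-", , drop = FALSE]
  absent <- structure(list(template_id = template_id, product = FALSE,
                           product_length = NA_integer_,
                           product_sequence = NA_character_),
                      class = "amplicon_call")
  if (!nrow(fwd) || !nrow(rev)) return(absent)
  min_span <- max(nchar(pair$forward), nchar(pair$reverse))
  best <- NULL
  for (f in fwd$position) for (r in rev$position) {
    len <- r - f + 1L
    if (len >= min_span && len <= max_len &&
        (is.null(best) || len < best$len ||
         (len == best$len && f < best$f)))
      best <- list(f = f, r = r, len = len)
  }
  if (is.null(best)) return(absent)
  structure(list(template_id = template_id, product = TRUE,
                 product_length = best$len,
                 product_sequence = substr(template, best$f + 1L, best$r + 1L)),
            class = "amplicon_call")
}

#' @export
print.amplicon_call <- function(x, ...) {
  if (x$product)
    cat(sprintf("<amplicon_call> %s: %d bp product\n", x$template_id,
                x$product_length))
  else cat(sprintf("<amplicon_call> %s: absent\n", x$template_id))
  invisible(x)
}

#' Expected screening products of a chimera pool
#'
#' Convenience lookup used to name alleles from amplicon sequences: runs the
#' screening pair over every named chimera and returns the product sequences.
#'
#' @param chimera_pool result of [build_chimera_pool()].
#' @param primers result of [design_diagnostic_primers()].
#' @return named character vector of screening product sequences.
#' @export
screening_products <- function(chimera_pool, primers) {
  vapply(chimera_pool, function(ch) {
    ac <- predict_amplicon(ch$sequence, primers$screening)
    if (!ac$product) stop("screening_products: no product on allele ", ch$id)
    ac$product_sequence
  }, character(1))
}

#' Classify a diploid sample by in-silico PCR
#'
#' Each haplotype template is screened with the chimera-diagnostic pair
#' (B2-forward + B1-reverse): a haplotype carries the chimeric gene iff that
#' pair amplifies on it.  Genotype classes: `B3/B3` (both haplotypes),
#' `B3/par` (one), `par/par` (none, but both parental pairs amplify),
#' `unknown` otherwise (absent or contradictory evidence).  The reciprocal
#' pair (B1-forward + B2-reverse) is always run and reported in the
#' evidence; it is expected absent on correctly formed loci.
#'
#' The real assay sees the two haplotypes pooled in one reaction; screening
#' per haplotype keeps the classifier exact while the per-pair evidence
#' table reproduces what the pooled band pattern would show.
#'
#' @param templates character vector of exactly two haplotype templates.
#' @param primers named list of [primer_pair()] with elements `screening`,
#'   `parental_b1`, `parental_b2`, `reciprocal`
#'   (see [design_diagnostic_primers()]).
#' @param sample_id sample label.
#' @param max_len,max_mismatch passed to [predict_amplicon()].
#' @param allele_refs optional named character of known screening-product
#'   sequences (see [screening_products()]); exact matches name the allele
#'   calls.
#' @return object of class `genotype_record`: `sample_id`,
#'   `genotype_class`, `allele_calls`, `evidence` (data.frame of all
#'   amplicon calls).
#' @export
classify_genotype <- function(templates, primers, sample_id = "",
                              max_len = 5000L, max_mismatch = 0L,
                              allele_refs = NULL) {
  stopifnot(length(templates) == 2L,
            all(c("screening", "parental_b1", "parental_b2", "reciprocal")
                %in% names(primers)))
  ev <- list()
  calls <- list()
  for (h in 1:2) for (pr in names(primers)) {
    ac <- predict_amplicon(templates[h], primers[[pr]], max_len, max_mismatch,
                           template_id = sprintf("%s/hap%d", sample_id, h))
    calls[[paste(h, pr)]] <- ac
    ev[[length(ev) + 1L]] <- data.frame(haplotype = h, pair = pr,
                                        product = ac$product,
                                        product_length = ac$product_length)
  }
  evidence <- do.call(rbind, ev)
  b3 <- vapply(1:2, function(h) calls[[paste(h, "screening")]]$product, logical(1))
  par_b1 <- any(vapply(1:2, function(h) calls[[paste(h, "parental_b1")]]$product,
                       logical(1)))
  par_b2 <- any(vapply(1:2, function(h) calls[[paste(h, "parental_b2")]]$product,
                       logical(1)))
  cls <- if (sum(b3) == 2L) "B3/B3"
         else if (sum(b3) == 1L) "B3/par"
         else if (par_b1 && par_b2) "par/par"
         else "unknown"
  allele_calls <- character(0)
  if (!is.null(allele_refs)) {
    for (h in which(b3)) {
      hit <- names(allele_refs)[match(calls[[paste(h, "screening")]]$product_sequence,
                                      allele_refs)]
      if (length(hit) == 1L && !is.na(hit)) allele_calls <- c(allele_calls, hit)
    }
  }
  structure(list(sample_id = sample_id, genotype_class = cls,
                 allele_calls = allele_calls, evidence = evidence),
            class = "genotype_record")
}

#' @export
print.genotype_record <- function(x, ...) {
  cat(sprintf("<genotype_record> %s: %s%s\n", x$sample_id, x$genotype_class,
              if (length(x$allele_calls))
                paste0(" [", paste(x$allele_calls, collapse = "/"), "]") else ""))
  invisible(x)
}

#' Screen a whole simulated population
#'
#' Runs [classify_genotype()] over every sample's haplotype templates and
#' returns a tidy table alongside the raw records.
#'
#' @param templates named list of two-haplotype character vectors
#'   (see [simulate_population()]).
#' @param primers as in [classify_genotype()].
#' @param metadata optional data.frame with `sample_id` and `region`, joined
#'   into the result.
#' @param ... passed to [classify_genotype()].
#' @return data.frame with `sample_id`, `genotype_class`, `allele_1`,
#'   `allele_2` (and `region` when metadata given); attribute `records`
#'   holds the full `genotype_record` list.
#' @export
screen_population <- function(templates, primers, metadata = NULL, ...) {
  recs <- lapply(names(templates), function(sid)
    classify_genotype(templates[[sid]], primers, sample_id = sid, ...))
  tab <- data.frame(
    sample_id = vapply(recs, `[[`, character(1), "sample_id"),
    genotype_class = vapply(recs, `[[`, character(1), "genotype_class"),
    allele_1 = vapply(recs, function(r)
      if (length(r$allele_calls) >= 1L) r$allele_calls[1] else NA_character_,
      character(1)),
    allele_2 = vapply(recs, function(r)
      if (length(r$allele_calls) >= 2L) r$allele_calls[2] else NA_character_,
      character(1)))
  if (!is.null(metadata))
    tab <- merge(tab, metadata[, c("sample_id", "region")], by = "sample_id",
                 sort = FALSE)
  attr(tab, "records") <- recs
  tab
}
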