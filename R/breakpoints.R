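# Crossover-interval mapping of chimeric alleles against aligned parents.
# Coordinates are 0-based alignment columns internally; TSV reports are
# 1-based inclusive.

#' Informative-site map of a chimera against its aligned parents
#'
#' Informative columns are exactly those where both parental bases are
#' unambiguous (`A/C/G/T`), non-gap and different.  At each, the chimera is
#' scored `matches_B1`, `matches_B2` or `neither`; columns where the chimera
#' carries a gap or `N` are excluded and counted in the skip-log.
#'
#' @param aligned_b1,aligned_b2,aligned_chimera equal-length aligned
#'   sequences (strings or [allele_sequence()]).
#' @return object of class `informative_site_map`: `alignment_length`,
#'   `sites` (data.frame: `column` 0-based, `b1_base`, `b2_base`, `state`),
#'   `skip_log` (columns masked by chimera gap/N).
#' @export
informative_sites <- function(aligned_b1, aligned_b2, aligned_chimera) {
  pick <- function(x) if (inherits(x, "allele_sequence")) x$sequence else x
  s1 <- pick(aligned_b1); s2 <- pick(aligned_b2); sc <- pick(aligned_chimera)
  if (length(unique(nchar(c(s1, s2, sc)))) != 1L)
    stop("informative_sites: sequences must be aligned to equal length")
  c1 <- seq_chars(s1); c2 <- seq_chars(s2); cc <- seq_chars(sc)
  unamb <- function(x) x %in% DNA_BASES
  cand <- which(unamb(c1) & unamb(c2) & c1 != c2)
  masked <- cand[!unamb(cc[cand])]
  keep <- setdiff(cand, masked)
  state <- ifelse(cc[keep] == c1[keep], "matches_B1",
                  ifelse(cc[keep] == c2[keep], "matches_B2", "neither"))
  structure(list(alignment_length = nchar(s1),
                 sites = data.frame(column = keep - 1L, b1_base = c1[keep],
                                    b2_base = c2[keep], state = state),
                 skip_log = length(masked)),
            class = "informative_site_map")
}

#' Map the crossover interval of a chimeric allele
#'
#' Scans informative-site states 5'->3' under the 5'-B2 / 3'-B1 chimera
#' geometry.  `neither` states (e.g. post-formation mutations) are ignored
#' for switch counting but tallied.  With a single B2->B1 switch the
#' breakpoint is bounded by the interval (last `matches_B2` column, first
#' `matches_B1` column); the unobservable crossover position lies strictly
#' between informative sites, so an interval — never a point — is reported.
#' Zero switches give a degenerate call at the alignment start (all B1) or
#' end (all B2).  More than one switch flags the allele as a gene-conversion
#' / multiple-crossover candidate (`complex_flag`), reporting the first
#' interval of the run segmentation (which is the minimal-switch
#' segmentation once `neither` columns are dropped).
#'
#' @param site_map result of [informative_sites()].
#' @param allele_id label carried into the result.
#' @return object of class `crossover_interval`: `allele_id`, `left`,
#'   `right` (0-based columns; `-1` / `alignment_length` for degenerate
#'   boundaries), `n_switches`, `complex_flag`, `degenerate` (`NA`,
#'   `"start"` or `"end"`), `n_neither`.
#' @export
map_crossover <- function(site_map, allele_id = "") {
  stopifnot(inherits(site_map, "informative_site_map"))
  st <- site_map$sites
  if (!nrow(st)) stop("map_crossover: no informative sites (no information)")
  informative <- st[st$state != "neither", , drop = FALSE]
  n_neither <- sum(st$state == "neither")
  if (!nrow(informative))
    stop("map_crossover: all informative columns are 'neither' (no information)")
  s <- informative$state
  cols <- informative$column
  switches <- which(s[-1L] != s[-length(s)])
  n_sw <- length(switches)
  res <- list(allele_id = allele_id, left = NA_integer_, right = NA_integer_,
              n_switches = n_sw, complex_flag = FALSE, degenerate = NA_character_,
              n_neither = n_neither)
  if (n_sw == 0L) {
    if (s[1L] == "matches_B1") {        # indistinguishable from B1
      res$left <- -1L; res$right <- cols[1L]; res$degenerate <- "start"
    } else {                            # indistinguishable from B2
      res$left <- cols[length(cols)]; res$right <- site_map$alignment_length
      res$degenerate <- "end"
    }
  } else if (n_sw == 1L && s[1L] == "matches_B2") {
    res$left <- cols[switches[1L]]
    res$right <- cols[switches[1L] + 1L]
  } else {
    # reversed orientation or multiple switches: first interval of the
    # segmentation, flagged complex
    res$complex_flag <- TRUE
    res$left <- cols[switches[1L]]
    res$right <- cols[switches[1L] + 1L]
  }
  structure(res, class = "crossover_interval")
}

#' @export
print.crossover_interval <- function(x, ...) {
  cat(sprintf("<crossover_interval> %s: (%d, %d]%s%s, %d switch(es)\n",
              x$allele_id, x$left, x$right,
              if (x$complex_flag) " COMPLEX" else "",
              if (!is.na(x$degenerate)) paste0(" degenerate-", x$degenerate) else "",
              x$n_switches))
  invisible(x)
}

#' Check recovery of planted crossover positions
#'
#' For each synthetic chimera (carrying its planted breakpoint and parent
#' ids), maps the crossover interval against the true parents and tests
#' whether the planted position `p` satisfies `left < p <= right`.
#' Degenerate and complex calls are excluded from the containment
#' denominator: the former carry no positional information, the latter are
#' flagged as multi-crossover candidates rather than forced into one
#' interval.
#'
#' @param chimeras list of chimeras from [make_chimera()] /
#'   [build_chimera_pool()].
#' @param pools parental pools the chimeras were built from.
#' @return data.frame (`allele`, `true_pos`, `left`, `right`, `complex`,
#'   `degenerate`, `eligible`, `contained`) with attribute
#'   `containment_rate` (over eligible calls).
#' @export
recover_planted_breakpoints <- function(chimeras, pools) {
  by_id <- function(pool) setNames(pool, vapply(pool, `[[`, character(1), "id"))
  b1s <- by_id(pools$b1); b2s <- by_id(pools$b2)
  rows <- lapply(chimeras, function(ch) {
    p <- attr(ch, "breakpoint")
    stopifnot(!is.null(p))
    sm <- informative_sites(b1s[[attr(ch, "b1_parent")]],
                            b2s[[attr(ch, "b2_parent")]], ch)
    ci <- map_crossover(sm, allele_id = ch$id)
    eligible <- !ci$complex_flag && is.na(ci$degenerate)
    data.frame(allele = ch$id, true_pos = p, left = ci$left, right = ci$right,
               complex = ci$complex_flag, degenerate = !is.na(ci$degenerate),
               eligible = eligible,
               contained = eligible && ci$left < p && p <= ci$right)
  })
  out <- do.call(rbind, rows)
  attr(out, "containment_rate") <-
    if (any(out$eligible)) mean(out$contained[out$eligible]) else NA_real_
  out
}

#' Cluster chimeras into named allele variants
#'
#' Variants are equivalence classes under exact full-sequence identity
#' (coding plus intron).  Variant names `v1, v2, ...` are assigned in order
#' of first appearance after lexicographic sort of the representative
#' sequences, making the naming deterministic; mapping onto any published
#' labels is a user-supplied lookup.  Chimeras without intron annotation
#' are excluded with a warning.
#'
#' @param chimeras list of chimeric [allele_sequence()] with intron features.
#' @param aligned_b1,aligned_b2 optional parental reference sequences on the
#'   chimera coordinate frame; when given, each variant's crossover interval
#'   is mapped from its representative.
#' @return data.frame (`variant_name`, `representative_id`, `n_members`,
#'   `member_ids` comma-joined, `intron_length`, `left`, `right`) with
#'   attribute `intron_diff`: pairwise SNP-difference matrix between variant
#'   introns (`NA` when lengths differ).
#' @export
type_alleles <- function(chimeras, aligned_b1 = NULL, aligned_b2 = NULL) {
  stopifnot(length(chimeras) >= 1L)
  has_intron <- vapply(chimeras, function(ch) !is.null(intron_span(ch)), logical(1))
  if (any(!has_intron)) {
    warning("type_alleles: excluding ", sum(!has_intron),
            " chimera(s) without intron annotation")
    chimeras <- chimeras[has_intron]
  }
  if (!length(chimeras)) stop("type_alleles: no annotated chimeras left")
  seqs <- vapply(chimeras, `[[`, character(1), "sequence")
  ids <- vapply(chimeras, `[[`, character(1), "id")
  uniq <- sort(unique(seqs))
  variant_of <- match(seqs, uniq)
  introns <- character(length(uniq))
  rows <- lapply(seq_along(uniq), function(v) {
    members <- which(variant_of == v)
    rep_i <- members[1L]
    sp <- intron_span(chimeras[[rep_i]])
    introns[v] <<- substr(uniq[v], sp[1] + 1L, sp[2])
    left <- right <- NA_integer_
    if (!is.null(aligned_b1) && !is.null(aligned_b2)) {
      ci <- map_crossover(informative_sites(aligned_b1, aligned_b2,
                                            chimeras[[rep_i]]),
                          allele_id = ids[rep_i])
      left <- ci$left; right <- ci$right
    }
    data.frame(variant_name = sprintf("v%d", v),
               representative_id = ids[rep_i],
               n_members = length(members),
               member_ids = paste(ids[members], collapse = ","),
               intron_length = nchar(introns[v]),
               left = left, right = right)
  })
  out <- do.call(rbind, rows)
  nv <- length(uniq)
  diffm <- matrix(NA_integer_, nv, nv,
                  dimnames = list(out$variant_name, out$variant_name))
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    if (nchar(introns[i]) == nchar(introns[j]))
      diffm[i, j] <- sum(seq_chars(introns[i]) != seq_chars(introns[j]))
  }
  attr(out, "intron_diff") <- diffm
  out
}
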