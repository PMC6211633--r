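# Distance-based gene-tree construction, monophyly assessment with column
# bootstrap, and the divergence-rate feasibility calculation.  A
# neighbor-joining / p-distance surrogate stands in for model-based tree
# inference: the object reproduced is the monophyly question, not any
# model-fit statistic.

.aln_strings <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "allele_sequence")))
    x <- setNames(vapply(x, `[[`, character(1), "sequence"),
                  vapply(x, `[[`, character(1), "id"))
  stopifnot(is.character(x), !is.null(names(x)), !anyDuplicated(names(x)))
  if (length(unique(nchar(x))) != 1L)
    stop("sequences must be aligned to equal length")
  x
}

# integer-coded alignment matrix; NA for gaps/ambiguity
.aln_codes <- function(aln) {
  M <- do.call(rbind, lapply(aln, function(s) match(seq_chars(s), DNA_BASES)))
  rownames(M) <- names(aln)
  M
}

.pdist_codes <- function(M) {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    valid <- !is.na(M[i, ]) & !is.na(M[j, ])
    den <- sum(valid)
    if (den == 0L) return(NULL)
    d[i, j] <- d[j, i] <- sum(M[i, valid] != M[j, valid]) / den
  }
  d
}

#' Pairwise p-distances with pairwise deletion
#'
#' `d[i, j]` = differing unambiguous columns / columns where both sequences
#' are unambiguous non-gap bases.  Errors when a pair has no comparable
#' column.
#'
#' @param alignment named character vector of equal-length aligned sequences,
#'   or a list of [allele_sequence()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment) {
  aln <- .aln_strings(alignment)
  stopifnot(length(aln) >= 2L)
  d <- .pdist_codes(.aln_codes(aln))
  if (is.null(d)) stop("p_distance: a pair has no comparable columns")
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a distance matrix.  Negative
#' branch lengths are clamped to 0; ties in the Q criterion are broken by
#' the lexicographically smallest pair of node labels (internal nodes
#' inherit their smallest descendant leaf label), making the output
#' deterministic.
#'
#' @param d symmetric distance matrix with row/col names (`>= 3` taxa).
#' @return unrooted `ape` `phylo` tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, !is.null(rownames(d)),
            isTRUE(all.equal(d, t(d))), all(is.finite(d)))
  quote_lab <- function(lab)
    if (grepl("[](),:;'\"\t []", lab))
      paste0("'", gsub("'", "''", lab, fixed = TRUE), "'") else lab
  frag <- vapply(rownames(d), quote_lab, character(1))
  repl <- rownames(d)
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    cand <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij)
      paste(sort(c(repl[ij[1]], repl[ij[2]])), collapse = "\001"))
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], max(vi, 0),
                       frag[j], max(vj, 0))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    repl <- c(repl[keep], min(repl[c(i, j)]))
    rownames(d2) <- colnames(d2) <- repl
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1], max(v1, 0),
                 frag[2], max(v2, 0), frag[3], max(v3, 0))
  ape::read.tree(text = nwk)
}

#' Test whether a leaf set is monophyletic on an unrooted tree
#'
#' TRUE iff removing some edge bipartitions the leaves into exactly
#' (`leafset`, complement).  Singleton leaf sets are monophyletic by
#' definition.
#'
#' @param tree `phylo` object.
#' @param leafset character vector, non-empty proper subset of the leaves.
#' @return logical scalar.
#' @export
is_monophyletic <- function(tree, leafset) {
  tips <- tree$tip.label
  stopifnot(length(leafset) >= 1L, all(leafset %in% tips),
            length(leafset) < length(tips))
  if (length(leafset) == 1L) return(TRUE)
  target <- sort(leafset)
  ntip <- length(tips)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  desc[seq_len(ntip)] <- as.list(tips)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (k in seq_len(nrow(edges))) {
    clade <- sort(desc[[edges[k, 2]]])
    if (identical(clade, target) ||
        identical(sort(setdiff(tips, clade)), target)) return(TRUE)
  }
  FALSE
}

#' Bootstrap support for monophyly of a leaf set
#'
#' Resamples alignment columns with replacement; each replicate recomputes
#' [p_distance()], [nj_tree()] and [is_monophyletic()].  Support is the
#' fraction of retained replicates in which the leaf set is monophyletic.
#' Replicates in which some pair has no comparable column are discarded and
#' logged.  Fully seeded and reproducible; resampling is by column index,
#' so the result is invariant to leaf order.
#'
#' @param alignment as in [p_distance()].
#' @param leafset leaf labels whose clade status is assessed.
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @return support in `[0, 1]`, with attributes `n_retained` and
#'   `n_discarded`.
#' @export
monophyly_bootstrap <- function(alignment, leafset, replicates = 1000L,
                                seed = 1L) {
  stopifnot(replicates >= 1L)
  aln <- .aln_strings(alignment)
  M <- .aln_codes(aln)
  L <- ncol(M)
  with_seed(seed, {
    mono <- logical(0)
    discarded <- 0L
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      d <- .pdist_codes(M[, cols, drop = FALSE])
      if (is.null(d)) { discarded <- discarded + 1L; next }
      mono <- c(mono, is_monophyletic(nj_tree(d), leafset))
    }
    if (!length(mono))
      stop("monophyly_bootstrap: every replicate had an incomparable pair")
    cp_log("info", "monophyly_bootstrap: seed=%d, %d/%d replicates retained",
           seed, length(mono), replicates)
    structure(mean(mono), n_retained = length(mono), n_discarded = discarded)
  })
}

#' Divergence-rate feasibility of recent allelic diversity
#'
#' Asks what substitution rate would be needed to accumulate an observed
#' pairwise divergence `d_obs` within `T_years`, and how many fold that
#' exceeds a baseline divergence rate (quoted in percent per million years
#' and interpreted as a pairwise-divergence accumulation rate).
#'
#' @param d_obs observed pairwise divergence (substitutions/site, `>= 0`).
#' @param T_years time window in years (`> 0`).
#' @param baseline_pct_per_myr baseline rate(s), percent divergence per
#'   million years; a scalar or a `(lo, hi)` range (default `c(1.5, 2.5)`,
#'   the conventional fast mitochondrial clock).
#' @return object of class `rate_feasibility`: `d_obs`, `T_years`,
#'   `baseline_lo`, `baseline_hi`, `required_rate` (per site per year),
#'   `fold_lo`, `fold_hi` (required/baseline; `fold_hi` uses the lower
#'   baseline).
#' @export
rate_feasibility <- function(d_obs, T_years,
                             baseline_pct_per_myr = c(1.5, 2.5)) {
  stopifnot(d_obs >= 0, T_years > 0, length(baseline_pct_per_myr) %in% 1:2,
            all(baseline_pct_per_myr > 0))
  lo <- min(baseline_pct_per_myr); hi <- max(baseline_pct_per_myr)
  required <- d_obs / T_years
  rate_of <- function(pct) pct / 100 / 1e6  # per site per year
  structure(list(d_obs = d_obs, T_years = T_years,
                 baseline_lo = lo, baseline_hi = hi,
                 required_rate = required,
                 fold_lo = required / rate_of(hi),
                 fold_hi = required / rate_of(lo)),
            class = "rate_feasibility")
}

#' @export
print.rate_feasibility <- function(x, ...) {
  cat(sprintf(
    "<rate_feasibility> d=%.4g over %g yr -> %.3g /site/yr; %.0f-%.0f x the %.2g-%.2g%%/Myr baseline\n",
    x$d_obs, x$T_years, x$required_rate, x$fold_lo, x$fold_hi,
    x$baseline_lo, x$baseline_hi))
  invisible(x)
}
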