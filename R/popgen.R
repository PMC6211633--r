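# Frequency tabulation and the from-scratch sliding-window pi / Tajima's D
# sweep scan.

#' Filter samples to a target species
#'
#' Individuals whose (mitochondrial-barcode-derived) species label differs
#' from the target are excluded, as in a field-survey screen.
#'
#' @param metadata data.frame with a `species_label` column.
#' @param target_species label to keep.
#' @return list with `kept` (filtered data.frame) and `counts` (named
#'   integer vector over every observed label).
#' @export
species_filter <- function(metadata, target_species) {
  stopifnot("species_label" %in% names(metadata))
  counts <- table(metadata$species_label)
  kept <- metadata[metadata$species_label == target_species, , drop = FALSE]
  cp_log("info", "species_filter: kept %d/%d records (%s)", nrow(kept),
         nrow(metadata), target_species)
  list(kept = kept, counts = setNames(as.integer(counts), names(counts)))
}

#' Genotype-class frequency table
#'
#' Counts and percentages of the three locus genotype classes per group,
#' plus the carriage percentage (individuals with at least one chimeric
#' allele).  Percentages are recomputed from counts over classified
#' individuals; `unknown` records are tallied separately.
#'
#' @param records data.frame with `genotype_class` and (for regional
#'   grouping) `region`.
#' @param group_by `"region"` or `"global"`.
#' @return data.frame, one row per group: `group`, `n`, `n_B3B3`,
#'   `n_B3par`, `n_parpar`, `n_unknown`, `pct_B3B3`, `pct_B3par`,
#'   `pct_parpar`, `carriage_pct`.
#' @export
genotype_frequency_table <- function(records, group_by = c("region", "global")) {
  group_by <- match.arg(group_by)
  stopifnot("genotype_class" %in% names(records))
  grp <- if (group_by == "region") records$region else rep("global", nrow(records))
  rows <- lapply(split(records, grp), function(d) {
    cls <- d$genotype_class
    n_hom <- sum(cls == "B3/B3"); n_het <- sum(cls == "B3/par")
    n_par <- sum(cls == "par/par"); n_unk <- sum(cls == "unknown")
    n <- n_hom + n_het + n_par
    data.frame(group = d$region[1] %||% "global", n = n,
               n_B3B3 = n_hom, n_B3par = n_het, n_parpar = n_par,
               n_unknown = n_unk,
               pct_B3B3 = 100 * n_hom / n, pct_B3par = 100 * n_het / n,
               pct_parpar = 100 * n_par / n,
               carriage_pct = 100 * (n_hom + n_het) / n)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (group_by == "global") out$group <- "global"
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Chimeric-allele frequency table
#'
#' Each individual contributes 0, 1 or 2 named chimeric alleles
#' (homozygote and heterozygote alleles summed); counts and percentages are
#' reported per group over sequenced alleles.
#'
#' @param records data.frame with `allele_1`, `allele_2` (NA when absent)
#'   and `region`.
#' @param group_by `"region"` or `"global"`.
#' @return data.frame: `group`, `allele`, `count`, `n_alleles`, `pct`.
#' @export
allele_frequency_table <- function(records, group_by = c("region", "global")) {
  group_by <- match.arg(group_by)
  stopifnot(all(c("allele_1", "allele_2") %in% names(records)))
  grp <- if (group_by == "region") records$region else rep("global", nrow(records))
  rows <- lapply(split(records, grp), function(d) {
    calls <- c(d$allele_1, d$allele_2)
    calls <- calls[!is.na(calls)]
    if (!length(calls)) return(NULL)
    tab <- table(calls)
    data.frame(group = if (group_by == "region") d$region[1] else "global",
               allele = names(tab), count = as.integer(tab),
               n_alleles = length(calls),
               pct = 100 * as.integer(tab) / length(calls))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-site heterozygosity (mean pairwise difference)
#'
#' The unbiased per-site mean pairwise difference among `n` haplotypes with
#' `j` derived copies: `2 j (n - j) / (n (n - 1))`.  Vectorised over `j`.
#'
#' @param j derived-allele count(s), `0 <= j <= n`.
#' @param n number of haplotypes (`>= 2`).
#' @return numeric vector.
#' @export
site_diversity <- function(j, n) {
  stopifnot(n >= 2L, all(j >= 0), all(j <= n))
  2 * j * (n - j) / (n * (n - 1))
}

# Tajima's D normalising constants for n haplotypes
tajima_constants <- function(n) {
  stopifnot(n >= 4L)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Sliding-window nucleotide diversity and Tajima's D
#'
#' Windows of `window_bp` advancing by `step_bp` tile `[1, segment_length]`;
#' a final partial window is retained with its true span as the pi
#' denominator and flagged.  Sites with any missing genotype are dropped
#' first (and logged) so the haplotype number `n = 2N` is constant, as the
#' Tajima constants require.  Per window: `S` = segregating sites; `pi` =
#' sum of per-site heterozygosities divided by the window span in bp;
#' Tajima's `D = (theta_pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with
#' `theta_pi` the un-normalised sum of per-site mean pairwise differences.
#' `D` is `NA` (undefined, never 0) when `S = 0` or the variance term
#' vanishes.
#'
#' @param vm [variant_matrix()] with `N >= 2` diploids (`2N >= 4`).
#' @param window_bp,step_bp window size and step in bp.
#' @return data.frame of class `window_stats`: `start`, `end` (1-based
#'   inclusive), `span`, `S`, `theta_pi`, `pi`, `tajima_d`, `partial`;
#'   attribute `n_dropped_missing` logs the missingness filter.
#' @export
sweep_scan <- function(vm, window_bp = 2500L, step_bp = 1250L) {
  stopifnot(inherits(vm, "variant_matrix"), window_bp > 0L, step_bp > 0L)
  n <- 2L * length(vm$sample_ids)
  if (n < 4L) stop("sweep_scan: Tajima's D requires at least 4 haplotypes")
  complete <- !apply(is.na(vm$geno), 2L, any)
  n_drop <- sum(!complete)
  pos <- vm$positions[complete]
  j <- colSums(vm$geno[, complete, drop = FALSE])
  seg <- j > 0L & j < n
  hets <- site_diversity(j, n)
  konst <- tajima_constants(n)
  L <- vm$segment_length
  starts <- seq.int(1L, L, by = step_bp)
  rows <- lapply(starts, function(s) {
    e_full <- s + window_bp - 1L
    e <- min(e_full, L)
    idx <- which(pos >= s & pos <= e)
    S <- sum(seg[idx])
    theta_pi <- sum(hets[idx])
    span <- e - s + 1L
    d <- NA_real_
    if (S > 0L) {
      v <- konst$e1 * S + konst$e2 * S * (S - 1)
      if (v > 0) d <- (theta_pi - S / konst$a1) / sqrt(v)
    }
    data.frame(start = s, end = e, span = span, S = S, theta_pi = theta_pi,
               pi = theta_pi / span, tajima_d = d, partial = e_full > L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_stats", class(out))
  attr(out, "n_dropped_missing") <- n_drop
  attr(out, "n_haplotypes") <- n
  cp_log("info", "sweep_scan: %d windows, %d site(s) dropped for missingness",
         nrow(out), n_drop)
  out
}

#' Summarise a sweep scan
#'
#' Minimum and mean pi and Tajima's D (means over defined windows only;
#' argmin ties broken by the leftmost window).  Means are reported both over
#' all windows and excluding the partial final window, since conventions
#' differ.
#'
#' @param ws result of [sweep_scan()].
#' @return list: `min_pi_window`, `min_d_window` (single-row data.frames or
#'   `NULL`), `mean_pi`, `mean_d`, `mean_pi_full_windows`,
#'   `mean_d_full_windows`, `n_windows`, `n_d_defined`.
#' @export
sweep_report <- function(ws) {
  stopifnot(nrow(ws) >= 1L)
  d_def <- !is.na(ws$tajima_d)
  full <- !ws$partial
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  list(min_pi_window = ws[which.min(ws$pi), , drop = FALSE],
       min_d_window = if (any(d_def))
         ws[d_def, , drop = FALSE][which.min(ws$tajima_d[d_def]), , drop = FALSE]
       else NULL,
       mean_pi = mean(ws$pi),
       mean_d = mean_or_na(ws$tajima_d[d_def]),
       mean_pi_full_windows = mean_or_na(ws$pi[full]),
       mean_d_full_windows = mean_or_na(ws$tajima_d[d_def & full]),
       n_windows = nrow(ws), n_d_defined = sum(d_def))
}

#' Plot pi and Tajima's D along the segment
#'
#' Two stacked base-graphics panels against window midpoint, with the
#' segment-wide mean pi as a dashed reference line.
#'
#' @param ws result of [sweep_scan()].
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @return invisibly, `ws`.
#' @export
plot_sweep <- function(ws, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  mid <- (ws$start + ws$end) / 2
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(mid, ws$pi, type = "l", xlab = "position (bp)",
                 ylab = expression(pi))
  graphics::abline(h = mean(ws$pi), lty = 2, col = "red")
  graphics::plot(mid, ws$tajima_d, type = "l", xlab = "position (bp)",
                 ylab = "Tajima's D")
  graphics::abline(h = 0, lty = 3)
  invisible(ws)
}
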