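# Independent oracles: deliberately naive implementations that share no code
# with the package internals they check.

options(chimerapop.log_level = "warn")

# Brute-force windowed pi / Tajima's D: reconstructs the haplotype column at
# every site and enumerates all haplotype pairs.
oracle_window_stats <- function(vm, window_bp = 2500, step_bp = 1250) {
  geno <- vm$geno
  complete <- colSums(is.na(geno)) == 0
  geno <- geno[, complete, drop = FALSE]
  pos <- vm$positions[complete]
  N <- nrow(geno)
  n <- 2 * N
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  starts <- seq(1, vm$segment_length, by = step_bp)
  out <- lapply(starts, function(s) {
    e_full <- s + window_bp - 1
    e <- min(e_full, vm$segment_length)
    idx <- which(pos >= s & pos <= e)
    S <- 0
    theta_pi <- 0
    for (jj in idx) {
      k <- sum(geno[, jj])
      hap <- c(rep(1, k), rep(0, n - k))
      diffs <- 0
      for (a in 1:(n - 1)) for (b in (a + 1):n)
        diffs <- diffs + (hap[a] != hap[b])
      theta_pi <- theta_pi + diffs / choose(n, 2)
      if (k > 0 && k < n) S <- S + 1
    }
    d <- NA_real_
    if (S > 0) {
      v <- e1 * S + e2 * S * (S - 1)
      if (v > 0) d <- (theta_pi - S / a1) / sqrt(v)
    }
    data.frame(start = s, end = e, S = S, pi = theta_pi / (e - s + 1),
               tajima_d = d)
  })
  do.call(rbind, out)
}

# random small variant matrix for oracle-equivalence tests
random_variant_matrix <- function(seed, max_N = 10, max_P = 50,
                                  segment_length = 10000) {
  set.seed(seed)
  N <- sample(2:max_N, 1)
  P <- sample(5:max_P, 1)
  pos <- sort(sample(segment_length, P))
  geno <- matrix(sample(0:2, N * P, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15)), nrow = N)
  variant_matrix(sprintf("T%02d", 1:N), pos, geno, segment_length)
}

# Exhaustive monophyly check: remove each edge of the tree graph and test the
# resulting leaf bipartition by breadth-first traversal.
oracle_monophyletic <- function(tree, leafset) {
  tips <- tree$tip.label
  if (length(leafset) == 1) return(TRUE)
  edges <- tree$edge
  nodes <- sort(unique(as.vector(edges)))
  for (k in seq_len(nrow(edges))) {
    adj <- edges[-k, , drop = FALSE]
    comp <- c(edges[k, 2])
    repeat {
      nb <- unique(c(adj[adj[, 1] %in% comp, 2], adj[adj[, 2] %in% comp, 1]))
      new <- setdiff(nb, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    side <- tips[comp[comp <= length(tips)]]
    if (setequal(side, leafset) || setequal(setdiff(tips, side), leafset))
      return(TRUE)
  }
  FALSE
}

# naive FASTA line-joiner (independent of Biostrings)
oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ends <- c(hdr[-1] - 1, length(lines))
  setNames(
    vapply(seq_along(hdr), function(i)
      paste(lines[(hdr[i] + 1):ends[i]], collapse = ""), character(1)),
    sub("^>", "", lines[hdr]))
}
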