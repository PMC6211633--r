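test_that("informative_sites enumerates parent-discriminating columns", {
  sm <- informative_sites("ACGTACGTACGT", "ACGAACGAACGA", "ACGAACGTACGT")
  expect_equal(sm$sites$column, c(3L, 7L, 11L))
  expect_equal(sm$sites$state, c("matches_B2", "matches_B1", "matches_B1"))
  expect_equal(sm$skip_log, 0L)
  # identical parents -> no informative sites
  expect_equal(nrow(informative_sites("ACGT", "ACGT", "ACGT")$sites), 0L)
  # chimera N at an informative column -> masked and logged
  sm2 <- informative_sites("ACGTACGTACGT", "ACGAACGAACGA", "ACGNACGTACGT")
  expect_equal(sm2$sites$column, c(7L, 11L))
  expect_equal(sm2$skip_log, 1L)
  expect_error(informative_sites("ACGT", "ACG", "ACGT"), "equal length")
})

test_that("map_crossover bounds the breakpoint and counts switches", {
  sm <- informative_sites("ACGTACGTACGT", "ACGAACGAACGA", "ACGAACGTACGT")
  ci <- map_crossover(sm, "toy")
  expect_equal(c(ci$left, ci$right), c(3L, 7L))
  expect_equal(ci$n_switches, 1L)
  expect_false(ci$complex_flag)
  # all matches_B1: degenerate at start (chimera indistinguishable from B1)
  ci2 <- map_crossover(informative_sites("ACGTACGTACGT", "ACGAACGAACGA",
                                         "ACGTACGTACGT"))
  expect_equal(ci2$degenerate, "start")
  expect_false(ci2$complex_flag)
  # all matches_B2: degenerate at end
  ci3 <- map_crossover(informative_sites("ACGTACGTACGT", "ACGAACGAACGA",
                                         "ACGAACGAACGA"))
  expect_equal(ci3$degenerate, "end")
  # states (B2, B1, B2, B1) runs -> 3 switches, complex
  b1 <- "ATATATATATATATAT"; b2 <- "GCGCGCGCGCGCGCGC"
  ch <- paste0(substr(b2, 1, 4), substr(b1, 5, 8), substr(b2, 9, 12),
               substr(b1, 13, 16))
  ci4 <- map_crossover(informative_sites(b1, b2, ch))
  expect_equal(ci4$n_switches, 3L)
  expect_true(ci4$complex_flag)
  expect_error(map_crossover(informative_sites("ACGT", "ACGT", "ACGT")),
               "no informative")
})

test_that("map_crossover ignores non-informative columns and 'neither' states", {
  b1 <- "AAAATTTT"; b2 <- "CCCCGGGG"
  ch <- paste0("CCCC", "TTTT")
  ci <- map_crossover(informative_sites(b1, b2, ch))
  # interleave identical (non-informative) columns: interval columns shift
  # deterministically but the bounded informative sites are the same ones
  ins <- function(s) paste(strsplit(s, "")[[1]], collapse = "X")
  ci2 <- map_crossover(informative_sites(chartr("X", "A", ins(b1)),
                                         chartr("X", "A", ins(b2)),
                                         chartr("X", "A", ins(ch))))
  expect_equal(ci2$n_switches, ci$n_switches)
  expect_equal(ci2$left, 2L * ci$left)      # column c maps to 2c
  expect_equal(ci2$right, 2L * ci$right)
  # a post-formation mutation matching neither parent is logged, not counted
  # as a switch: col 5 has b1 = T, b2 = G, chimera = C
  ch_nei <- paste0("CCCC", "T", "C", "TT")
  ci3 <- map_crossover(informative_sites(b1, b2, ch_nei))
  expect_equal(ci3$n_neither, 1L)
  expect_equal(ci3$n_switches, 1L)
  expect_false(ci3$complex_flag)
})

test_that("planted breakpoints are contained in noise-free intervals", {
  cfg <- simulation_config(seed = 29)
  pools <- sample_parental_alleles(cfg)
  set.seed(77)
  chims <- lapply(1:200, function(i) {
    b1 <- pools$b1[[sample.int(length(pools$b1), 1)]]
    b2 <- pools$b2[[sample.int(length(pools$b2), 1)]]
    make_chimera(b2, b1, sample(130:1100, 1), sprintf("c%03d", i))
  })
  rec <- recover_planted_breakpoints(chims, pools)
  expect_equal(attr(rec, "containment_rate"), 1)
  expect_true(all(rec$eligible))
})

test_that("zero 5' divergence yields a degenerate call excluded from the rate", {
  b1 <- allele_sequence("b1", paste0(strrep("A", 50), strrep("T", 50)), "B1")
  b2 <- allele_sequence("b2", paste0(strrep("A", 50), strrep("G", 50)), "B2")
  ch <- make_chimera(b2, b1, 25, "deg")  # no informative site 5' of 25
  rec <- recover_planted_breakpoints(list(ch), list(b1 = list(b1), b2 = list(b2)))
  expect_true(rec$degenerate)
  expect_false(rec$eligible)
  expect_true(is.na(attr(rec, "containment_rate")))
})

test_that("containment stays high under post-formation mutation", {
  cfg <- simulation_config(seed = 37)
  pools <- sample_parental_alleles(cfg)
  for (seed in 1:20) {
    set.seed(3000 + seed)
    chims <- lapply(1:50, function(i) {
      b1 <- pools$b1[[sample.int(length(pools$b1), 1)]]
      b2 <- pools$b2[[sample.int(length(pools$b2), 1)]]
      ch <- make_chimera(b2, b1, sample(130:1100, 1), sprintf("m%03d", i))
      chars <- strsplit(ch$sequence, "")[[1]]
      idx <- which(runif(length(chars)) < 0.01)
      for (k in idx)
        chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1)
      mut <- allele_sequence(ch$id, paste(chars, collapse = ""), "B3",
                             features = ch$features)
      attributes(mut)[c("breakpoint", "b1_parent", "b2_parent")] <-
        attributes(ch)[c("breakpoint", "b1_parent", "b2_parent")]
      mut
    })
    rec <- recover_planted_breakpoints(chims, pools)
    expect_gte(attr(rec, "containment_rate"), 0.95)
  }
})

test_that("type_alleles partitions by exact sequence identity", {
  cfg <- simulation_config(seed = 41)
  pool <- build_chimera_pool(cfg, sample_parental_alleles(cfg))
  # 10 copies of one sequence -> one variant with 10 members
  copies <- lapply(1:10, function(i)
    allele_sequence(sprintf("cp%d", i), pool$v1$sequence, "B3",
                    features = pool$v1$features))
  tt <- type_alleles(copies)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$n_members, 10L)
  # 8 planted variants in a mixed pool -> 8 classes matching planted labels
  mixed <- unlist(lapply(names(pool), function(v)
    lapply(1:3, function(k)
      allele_sequence(sprintf("%s_copy%d", v, k), pool[[v]]$sequence, "B3",
                      features = pool[[v]]$features))), recursive = FALSE)
  set.seed(1); mixed <- mixed[sample(length(mixed))]
  tt2 <- type_alleles(mixed)
  expect_equal(nrow(tt2), 8L)
  expect_true(all(tt2$n_members == 3L))
  for (i in seq_len(nrow(tt2))) {
    planted <- sub("_copy[0-9]+$", "", strsplit(tt2$member_ids[i], ",")[[1]])
    expect_length(unique(planted), 1L)  # members share one planted label
  }
  # partition is an equivalence relation: every chimera in exactly one class
  all_members <- unlist(strsplit(tt2$member_ids, ","))
  expect_setequal(all_members, vapply(mixed, `[[`, character(1), "id"))
  expect_equal(sum(tt2$n_members), length(mixed))
})

test_that("variant intron differences are reported pairwise", {
  base <- strrep("ACGT", 150)
  intron_ft <- data.frame(kind = "intron", start = 300L, end = 500L)
  a <- allele_sequence("a", base, "B3", features = intron_ft)
  bs <- strsplit(base, "")[[1]]
  bs[c(351, 402)] <- c("T", "A")  # two SNPs inside the intron
  b <- allele_sequence("b", paste(bs, collapse = ""), "B3", features = intron_ft)
  tt <- type_alleles(list(a, b))
  expect_equal(nrow(tt), 2L)
  diffm <- attr(tt, "intron_diff")
  expect_equal(unname(diffm[1, 2]), 2L)
  # unannotated chimera is excluded with a warning
  expect_warning(type_alleles(list(a, allele_sequence("c", base, "B3"))),
                 "without intron")
})
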