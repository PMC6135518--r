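mk_aln <- function(targets, nontargets) {
  data.frame(
    id = c(sprintf("T%02d", seq_along(targets)),
           sprintf("N%02d", seq_along(nontargets))),
    bases = c(targets, nontargets),
    group = c(rep("target", length(targets)),
              rep("non-target", length(nontargets))),
    stringsAsFactors = FALSE)
}

test_that("column profiles count bases and gaps per group", {
  aln <- mk_aln(c("AAC", "AGC", "A-C"), c("TAC"))
  pr <- profile_alignment(aln)
  expect_equal(unname(pr$target_counts[, 1]), c(3, 0, 0, 0, 0))
  expect_equal(unname(pr$target_counts["A", 2]), 1)
  expect_equal(unname(pr$target_counts["G", 2]), 1)
  expect_equal(unname(pr$target_counts["gap", 2]), 1)
  expect_equal(unname(pr$nontarget_counts["T", 1]), 1)
  expect_equal(sum(pr$target_counts[, 1]), pr$n_target)
})

test_that("profile preconditions: groups present, equal lengths", {
  expect_error(profile_alignment(mk_aln(c("AAA"), character())),
               "at least one")
  bad <- mk_aln(c("AAA", "AA"), c("AAA"))
  expect_error(profile_alignment(bad), "ragged")
  bad2 <- mk_aln(c("AAA"), c("AAA")); bad2$group <- c("x", "y")
  expect_error(profile_alignment(bad2), "group labels")
})

test_that("window consensus keeps bases above the frequency floor", {
  # 10 targets: column 1 all A; column 2 six C, four T
  targets <- c(rep("AC", 6), rep("AT", 4))
  pr <- profile_alignment(mk_aln(targets, "GG"))
  expect_equal(consensus_window(pr, 1, 2, min_base_freq = 0.05), "AY")

  # 21 targets: {A:20, G:1} -> G at 1/21 < 0.10 is dropped
  pr2 <- profile_alignment(mk_aln(c(rep("A", 20), "G"), "C"))
  expect_equal(consensus_window(pr2, 1, 1, min_base_freq = 0.10), "A")

  # all four bases above threshold -> N
  pr3 <- profile_alignment(mk_aln(c("A", "C", "G", "T"), "A"))
  expect_equal(consensus_window(pr3, 1, 1, min_base_freq = 0.05), "N")
})

test_that("gap-majority columns disqualify a window", {
  pr <- profile_alignment(mk_aln(c("A-A", "A-A", "ACA"), "AAA"))
  expect_error(consensus_window(pr, 1, 3), "gap-majority")
  expect_equal(consensus_window(pr, 1, 1), "A")
})

test_that("scoring classifies full non-target mismatches as vertebrate universal", {
  # targets invariant; all non-targets differ at the 3'-terminal column
  targets <- rep(strrep("A", 20), 5)
  nontargets <- rep(paste0(strrep("A", 19), "C"), 3)
  sc <- score_window(profile_alignment(mk_aln(targets, nontargets)),
                     1, 20, orientation = "forward")
  expect_equal(sc$specificity_class, "vertebrate universal")
  expect_equal(sc$full_offsets[[1]], 0)
  expect_equal(sc$target_coverage, 1)
  expect_equal(sc$degeneracy, 1)

  # no non-target mismatch anywhere -> universal
  sc2 <- score_window(profile_alignment(mk_aln(targets, targets[1:2])),
                      1, 20, orientation = "forward")
  expect_equal(sc2$specificity_class, "universal")
  expect_equal(sc2$n_full, 0L)
})

test_that("a 3'-proximal mismatch outranks the same mismatch at the 5' side", {
  base <- strrep("G", 20)
  nt_at <- function(pos) {
    ch <- strsplit(base, "", fixed = TRUE)[[1]]; ch[pos] <- "C"
    paste(ch, collapse = "")
  }
  pr_close <- profile_alignment(mk_aln(rep(base, 4), rep(nt_at(20), 3)))
  pr_far <- profile_alignment(mk_aln(rep(base, 4), rep(nt_at(10), 3)))
  s_close <- score_window(pr_close, 1, 20, "forward")$score
  s_far <- score_window(pr_far, 1, 20, "forward")$score
  expect_gt(s_close, s_far)
  # reverse orientation flips which edge is 3'
  r_close <- score_window(pr_close, 1, 20, "reverse")$score
  expect_lt(r_close, s_close)
})

test_that("score is monotonically non-increasing in degeneracy, all else equal", {
  # same mismatch structure, growing number of 2-fold columns
  mk <- function(n_deg) {
    t1 <- strsplit(strrep("A", 20), "", fixed = TRUE)[[1]]
    t2 <- t1
    if (n_deg > 0) t2[seq_len(n_deg)] <- "G"
    targets <- c(rep(paste(t1, collapse = ""), 2),
                 rep(paste(t2, collapse = ""), 2))
    profile_alignment(mk_aln(targets, strrep("T", 20)))
  }
  scores <- vapply(0:4, function(k) score_window(mk(k), 1, 20,
                                                 "forward")$score, 0)
  expect_true(all(diff(scores) <= 0))
})

test_that("scan recovers an implanted discriminative window as the top hit", {
  pars <- study_params(sites = list(list(start = 101, length = 22,
                                         orientation = "forward",
                                         mismatch_offsets = c(0, 2, 5))))
  ma <- make_alignment(pars, seed = 31)
  cand <- scan_priming_sites(ma$aln)
  expect_equal(cand$start[1], 101)
  expect_equal(cand$end[1], 122)
  expect_equal(cand$orientation[1], "forward")
  expect_equal(cand$specificity_class[1], "vertebrate universal")
})

test_that("identical target and non-target groups yield no vertebrate-universal site", {
  seqs <- vapply(1:6, function(i) mutate_sequence(random_dna(80, seed = 5),
                                                  0.02, seed = i), "")
  cand <- scan_priming_sites(mk_aln(seqs, seqs[1:3]), min_len = 20,
                             max_len = 22, min_coverage = 0.5)
  expect_true(nrow(cand) > 0)
  expect_true(all(cand$specificity_class == "universal"))
})

test_that("a degeneracy cap of 1 returns only invariant windows", {
  targets <- c(strrep("A", 30), paste0(strrep("A", 15), strrep("C", 15)))
  cand <- scan_priming_sites(mk_aln(rep(targets, 2), strrep("T", 30)),
                             min_len = 10, max_len = 10, max_degeneracy = 1,
                             min_coverage = 0.4)
  expect_true(all(cand$degeneracy == 1))
})

test_that("short alignments are rejected", {
  expect_error(scan_priming_sites(mk_aln(rep("ACGT", 3), "ACGT")),
               "shorter than")
})

test_that("every reported candidate satisfies its coverage by direct recount", {
  ma <- make_alignment(seed = 17)
  cand <- head(scan_priming_sites(ma$aln), 10)
  tseqs <- ma$aln$bases[ma$aln$group == "target"]
  for (i in seq_len(nrow(cand))) {
    win_cons <- strsplit(cand$consensus[i], "", fixed = TRUE)[[1]]
    ok <- vapply(tseqs, function(s) {
      sch <- strsplit(substr(s, cand$start[i], cand$end[i]), "",
                      fixed = TRUE)[[1]]
      all(mapply(oracle_char_match, win_cons, sch))
    }, TRUE)
    expect_equal(mean(ok), cand$target_coverage[i])
    expect_gte(mean(ok), 0.90)
  }
})

test_that("candidate pairing maps windows to reference coordinates", {
  # ungapped alignment: 700 columns, windows at known reference positions
  ref <- random_dna(700, seed = 8)
  aln <- mk_aln(rep(ref, 2), mutate_sequence(ref, 0.2, seed = 9))
  cand <- rbind(
    data.frame(start = 1L, end = 22L, orientation = "forward",
               consensus = substr(ref, 1, 22), stringsAsFactors = FALSE),
    data.frame(start = 222L, end = 244L, orientation = "reverse",
               consensus = substr(ref, 222, 244), stringsAsFactors = FALSE),
    data.frame(start = 642L, end = 664L, orientation = "reverse",
               consensus = substr(ref, 642, 664), stringsAsFactors = FALSE))
  pairs_ <- pair_candidates(cand, aln, "T01", length_bounds = c(100, 800))
  expect_equal(sort(pairs_$amplicon_bp), c(244L, 664L))
  expect_equal(pairs_$reverse_seq[pairs_$amplicon_bp == 244],
               iupac_revcomp(substr(ref, 222, 244)))
  # a reverse candidate overlapping the forward window is an error when
  # explicitly requested alone
  bad <- cand[c(1, 2), ]; bad$start[2] <- 10L; bad$end[2] <- 32L
  expect_error(pair_candidates(bad, aln, "T01"), "not downstream")
  # amplicon length always covers both primers
  expect_true(all(pairs_$amplicon_bp >=
                    nchar(pairs_$forward_seq) + nchar(pairs_$reverse_seq)))
})

test_that("windows mapping onto reference gaps are rejected", {
  aln <- mk_aln(c("AC-GTACGTACGTACGTACGTACGTACGTACGT",
                  "ACCGTACGTACGTACGTACGTACGTACGTACGT"),
                "ACCGTACGTACGTACGTACGTACGTACGTACGT")
  cand <- rbind(
    data.frame(start = 1L, end = 5L, orientation = "forward",
               consensus = "ACCGT", stringsAsFactors = FALSE),
    data.frame(start = 20L, end = 25L, orientation = "reverse",
               consensus = "CGTACG", stringsAsFactors = FALSE))
  expect_error(pair_candidates(cand, aln, "T01", length_bounds = c(5, 50)),
               "gap")
})
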