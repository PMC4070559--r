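hits_from <- function(windows) {
  data.frame(read_id = sprintf("r%d", seq_along(windows)),
             status = rep("SEGMENTED", length(windows)),
             window = windows, stringsAsFactors = FALSE)
}

test_that("count_windows sorts and counts with deterministic ties", {
  tab <- count_windows(hits_from(c("W1", "W2", "W1", "W1")))
  expect_identical(tab$seed_window, c("W1", "W2"))
  expect_identical(tab$read_count, c(3L, 1L))
  expect_identical(total_segmented(tab), 4L)
  # equal counts fall back to lexicographic window order
  tie <- count_windows(hits_from(c("B", "A", "B", "A")))
  expect_identical(tie$seed_window, c("A", "B"))
  empty <- count_windows(hits_from(character(0)))
  expect_equal(nrow(empty), 0L)
  expect_identical(total_segmented(empty), 0L)
})

test_that("window_distance splits edits into substitution/indel/homopolymer", {
  expect_identical(window_distance("ACGT", "ACGA"),
                   c(substitutions = 1L, plain_indels = 0L,
                     homopolymer_indels = 0L))
  # deleted A flanked by A in the other sequence: homopolymer-type
  expect_identical(window_distance("AAAG", "AAG"),
                   c(substitutions = 0L, plain_indels = 0L,
                     homopolymer_indels = 1L))
  expect_identical(window_distance("ACGT", "ACGT"),
                   c(substitutions = 0L, plain_indels = 0L,
                     homopolymer_indels = 0L))
  # deletion not flanked by an equal base: plain indel
  expect_identical(window_distance("ACGT", "AGT"),
                   c(substitutions = 0L, plain_indels = 1L,
                     homopolymer_indels = 0L))
})

test_that("window_distance totals match Levenshtein and are symmetric", {
  set.seed(17)
  for (i in 1:200) {
    a <- rand_dna(sample(3:12, 1))
    b <- rand_dna(sample(3:12, 1))
    c_ <- rand_dna(sample(3:12, 1))
    dab <- window_distance(a, b); dba <- window_distance(b, a)
    expect_identical(dab, dba)
    expect_equal(sum(dab), as.integer(adist(a, b)))
    # triangle inequality on the total edit count
    expect_lte(sum(dab), sum(window_distance(a, c_)) +
                 sum(window_distance(c_, b)))
  }
})

test_that("zero-tolerance clustering is the identity", {
  tab <- count_windows(hits_from(c("ACGTACGT", "ACGTACGA", "ACGTACGT")))
  out <- cluster_windows(tab, cluster_params())
  expect_identical(out$seed_window, tab$seed_window)
  expect_identical(out$read_count, tab$read_count)
  expect_identical(total_segmented(out), total_segmented(tab))
})

test_that("greedy merge-to-seed follows the worked examples", {
  # A(100) absorbs B(3) at 1 substitution
  winA <- strrep("A", 10); winB <- paste0(strrep("A", 9), "C")
  tab <- count_windows(hits_from(c(rep(winA, 100), rep(winB, 3))))
  out <- cluster_windows(tab, cluster_params(max_subst = 1))
  expect_equal(nrow(out), 1L)
  expect_identical(out$seed_window, winA)
  expect_identical(out$read_count, 103L)
  # C is 1 sub from B but 2 from A: compared to seed A only, stays separate
  winC <- paste0(strrep("A", 8), "CC")
  tab3 <- count_windows(hits_from(c(rep(winA, 100), rep(winB, 5), rep(winC, 4))))
  out3 <- cluster_windows(tab3, cluster_params(max_subst = 1))
  expect_equal(nrow(out3), 2L)
  expect_identical(out3$seed_window, c(winA, winC))
  expect_identical(out3$read_count, c(105L, 4L))
  # read conservation in all cases
  expect_identical(sum(out3$read_count), total_segmented(tab3))
})

test_that("manual pairs merge unconditionally; absent windows warn", {
  winA <- "AAAACCCC"; winB <- "GGGGTTTT"
  tab <- count_windows(hits_from(c(rep(winA, 5), rep(winB, 2))))
  out <- cluster_windows(tab, cluster_params(manual_pairs = list(c(winA, winB))))
  expect_equal(nrow(out), 1L)
  expect_identical(out$read_count, 7L)
  expect_identical(out$seed_window, winA)   # most abundant member
  expect_warning(cluster_windows(tab,
                                 cluster_params(manual_pairs = list(c(winA, "TTTTTTTT")))),
                 "absent")
})

test_that("read counts are conserved under random clustering settings", {
  set.seed(29)
  for (i in 1:10) {
    wins <- replicate(40, rand_dna(8))
    hits <- hits_from(sample(wins, 200, replace = TRUE))
    tab <- count_windows(hits)
    prm <- cluster_params(max_subst = sample(0:2, 1),
                          max_indel = sample(0:1, 1),
                          max_homo = sample(0:1, 1))
    out <- cluster_windows(tab, prm)
    expect_identical(sum(out$read_count), 200L)
    expect_identical(total_segmented(out), 200L)
    # member windows are preserved as a set
    expect_setequal(unlist(lapply(out$member_windows, names)),
                    unlist(lapply(tab$member_windows, names)))
  }
})

test_that("clone selection applies top_n, min_reads and followed windows", {
  wins <- sprintf("W%02d", 1:25)
  counts <- seq(250, 10, by = -10)
  hits <- hits_from(rep(wins, counts))
  tab <- count_windows(hits)
  sel <- select_clones(tab, cluster_params(top_n = 20, min_reads = 10))
  expect_equal(nrow(sel), 20L)
  # a clone below min_reads is excluded
  tab9 <- count_windows(hits_from(c(rep("BIG", 50), rep("SMALL", 9))))
  sel9 <- select_clones(tab9, cluster_params())
  expect_identical(sel9$seed_window, "BIG")
  # followed windows come back regardless of rank and count, flagged
  self <- select_clones(tab9, cluster_params(followed_windows = "SMALL"))
  expect_identical(self$seed_window, c("BIG", "SMALL"))
  expect_identical(self$followed, c(FALSE, TRUE))
  expect_identical(total_segmented(self), total_segmented(tab9))
})
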