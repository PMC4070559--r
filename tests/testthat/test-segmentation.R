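mini_db <- function() {
  germline_db("MINI", c(V1 = "AAAACCCC"), c(J1 = "GGGGTTTT"),
              seed = seed_pattern("####"), w = 4L)
}

test_that("best_gene_alignment trims gene ends at the junction", {
  sc <- alignment_scoring()
  res <- best_gene_alignment("AAAACCTAGGGGTTTT", c(V1 = "AAAACCCC"),
                             side = "end_of_V", scoring = sc)
  # oracle: best over (e, q) of the reference matrix
  H <- oracle_end_matrix("AAAACCTAGGGGTTTT", "AAAACCCC", sc)
  expect_equal(res$score, max(H))
  expect_identical(res$pos, 5L)        # 0-based end of "AAAACC"
  expect_identical(res$deletions, 2L)
  # a gene occurring intact scores 2 * its length with no deletions
  full <- best_gene_alignment("AAAACCTAGGGGTTTT", c(J1 = "GGGGTTTT"),
                              side = "start_of_J", scoring = sc)
  expect_identical(full$deletions, 0L)
  expect_equal(full$score, 16)
  expect_identical(full$pos, 8L)
  expect_error(best_gene_alignment("ACGT", setNames(character(0), character(0))),
               "empty gene list")
})

test_that("segment_sequence recovers the worked V/N/J decomposition", {
  db <- mini_db()
  seg <- segment_sequence("AAAACCTAGGGGTTTT", db)
  expect_true(seg$segmented)
  expect_identical(seg$v_name, "V1")
  expect_identical(seg$v_del, 2L)
  expect_identical(seg$n_region, "TA")
  expect_identical(seg$j_del, 0L)
  expect_identical(seg$v_end, 5L)
  expect_identical(seg$j_start, 8L)
  expect_identical(format_designation(seg), "V1 -2/TA/0 J1")
  expect_identical(reconstruct_from_designation(seg, db), "AAAACCTAGGGGTTTT")
  # exact V + J concatenation: no deletions, empty N
  seg0 <- segment_sequence("AAAACCCCGGGGTTTT", db)
  expect_identical(seg0$v_del, 0L)
  expect_identical(seg0$n_region, "")
  expect_identical(seg0$j_del, 0L)
  expect_identical(format_designation(seg0), "V1 0//0 J1")
  # hopeless sequence fails segmentation but is reported as such
  expect_false(segment_sequence(strrep("CA", 10), db)$segmented)
})

test_that("designations print in the compact field notation", {
  mk <- function(v, vd, n, jd, j) {
    list(segmented = TRUE, v_name = v, v_del = vd, n_region = n,
         j_del = jd, j_name = j)
  }
  expect_identical(format_designation(mk("TRGV5*01", 5L, "CC", 0L, "TRGJ1*02")),
                   "TRGV5*01 -5/CC/0 TRGJ1*02")
  expect_identical(format_designation(mk("TRGV10*02", 5L, "AGAC", 3L, "TRGJP1*01")),
                   "TRGV10*02 -5/AGAC/-3 TRGJP1*01")
  expect_identical(format_designation(mk("TRGV10*02", 4L, "", 0L, "TRGJP1*01")),
                   "TRGV10*02 -4//0 TRGJP1*01")
})

test_that("reconstruction validates genes and deletion bounds", {
  db <- mini_db()
  seg <- list(segmented = TRUE, v_name = "V1", v_del = 0L, n_region = "",
              j_del = 0L, j_name = "J1")
  expect_identical(reconstruct_from_designation(seg, db), "AAAACCCCGGGGTTTT")
  seg$v_del <- 9L
  expect_error(reconstruct_from_designation(seg, db), "exceeds")
  seg$v_del <- 0L; seg$v_name <- "nope"
  expect_error(reconstruct_from_designation(seg, db), "unknown V")
})

test_that("the DP designation score equals brute-force enumeration", {
  sc <- alignment_scoring()
  set.seed(41)
  n_instances <- 0L
  while (n_instances < 200L) {
    db <- germline_db("RND",
                      setNames(replicate(2, rand_dna(sample(5:9, 1))),
                               c("Va", "Vb")),
                      setNames(replicate(2, rand_dna(sample(5:8, 1))),
                               c("Ja", "Jb")),
                      seed = seed_pattern("####"), w = 4L)
    seqs <- replicate(10, rand_dna(sample(8:15, 1)))
    for (s in seqs) {
      seg <- segment_sequence(s, db, scoring = sc, min_score = -1e9)
      expect_true(seg$segmented)
      expect_equal(seg$score, oracle_segment_score(s, db, sc))
      expect_lt(seg$v_end, seg$j_start)
      expect_equal(nchar(seg$n_region), seg$j_start - seg$v_end - 1L)
      n_instances <- n_instances + 1L
    }
  }
  expect_gte(n_instances, 200L)
})

test_that("error-free simulated clones round-trip through designation", {
  db <- trg_db()
  clones <- simulate_clones(db, 25, rng_seed = 19L)
  for (cl in clones) {
    seg <- segment_sequence(cl$full_sequence, db)
    expect_true(seg$segmented)
    # designation equivalence class: the reconstruction must match exactly
    expect_identical(reconstruct_from_designation(seg, db), cl$full_sequence)
    expect_identical(seg$v_name, cl$v_name)
    expect_identical(seg$j_name, cl$j_name)
  }
})

test_that("VDJ loci get a D assignment with round-trip consistency", {
  set.seed(55)
  db <- make_synthetic_germline(n_v = 3, n_j = 2, n_d = 2, locus = "TRB",
                                d_len_range = c(25L, 35L), rng_seed = 23L)
  expect_equal(db$w, 60L)
  clones <- simulate_clones(db, 8, del_range = c(0L, 4L),
                            n_len_range = c(0L, 6L), rng_seed = 27L)
  n_with_d <- 0L
  for (cl in clones) {
    seg <- segment_sequence(cl$full_sequence, db)
    expect_true(seg$segmented)
    expect_identical(reconstruct_from_designation(seg, db), cl$full_sequence)
    if (!is.null(seg$d_name)) {
      n_with_d <- n_with_d + 1L
      expect_match(format_designation(seg), " TRBD[0-9]+\\*01 ")
    }
  }
  # with 25-35 bp D genes and small trims, D should usually be recovered
  expect_gte(n_with_d, 6L)
})
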