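mk_matches <- function(starts, ends, seq_id = "s1") {
  tibble::tibble(ref_id = seq_id, ref_start = as.integer(starts),
                 ref_end = as.integer(ends), qry_id = "q",
                 qry_start = 0L, qry_end = 1L,
                 length = as.integer(ends - starts), strand = "+")
}

test_that("interval merging unions overlapping and adjacent intervals", {
  lens <- c(s1 = 1000L)
  expect_identical(nrow(merge_to_intervals(mk_matches(integer(0), integer(0)),
                                           lens)), 0L)
  iv <- merge_to_intervals(mk_matches(c(0, 25), c(50, 100)), lens)
  expect_identical(as.data.frame(iv),
                   data.frame(seq_id = "s1", start = 0L, end = 100L))
  iv2 <- merge_to_intervals(mk_matches(c(0, 50), c(50, 60)), lens)
  expect_identical(as.data.frame(iv2),
                   data.frame(seq_id = "s1", start = 0L, end = 60L))
  expect_error(merge_to_intervals(mk_matches(990, 1010), lens), "bounds")
})

test_that("coverage percentages follow from merged intervals", {
  lens <- c(s1 = 1000L)
  expect_identical(mums_percentage(merge_to_intervals(mk_matches(integer(0),
                                                                 integer(0)),
                                                      lens), lens)$percent, 0)
  p <- mums_percentage(merge_to_intervals(mk_matches(c(0, 25), c(50, 100)),
                                          lens), lens)
  expect_equal(p$percent, 10)
  expect_equal(p$covered_bp, 100)
  expect_error(mums_percentage(tibble::tibble(), c(s1 = 0L)), "zero length")
})

test_that("a repeat-free genome self-aligned covers itself fully", {
  set.seed(90)
  g <- c(chr1 = random_dna(400))
  m <- filter_one_to_one(find_mums(g, g, min_length = 20))
  p <- mums_percentage(merge_to_intervals(m, g), g)
  expect_equal(p$percent, 100)
})

test_that("merged coverage equals a bitmap oracle on random match piles", {
  set.seed(321)
  for (i in 1:25) {
    lens <- c(s1 = sample(200:2000, 1), s2 = sample(200:2000, 1))
    n <- sample(1:60, 1)
    sid <- sample(names(lens), n, replace = TRUE)
    st <- floor(runif(n) * (lens[sid] - 30))
    en <- st + sample(1:30, n, replace = TRUE)
    m <- tibble::tibble(ref_id = sid, ref_start = as.integer(st),
                        ref_end = as.integer(en), qry_id = "q",
                        qry_start = 0L, qry_end = 1L,
                        length = as.integer(en - st), strand = "+")
    iv <- merge_to_intervals(m, lens)
    expect_identical(sum(iv$end - iv$start),
                     as.integer(bitmap_covered_bp(m, as.list(lens))))
    # disjointness and order within each sequence
    for (sq in unique(iv$seq_id)) {
      s <- iv[iv$seq_id == sq, ]
      if (nrow(s) > 1) {
        expect_true(all(s$start[-1] > s$end[-nrow(s)]))
      }
    }
  }
})

test_that("cumulative pair percentage is the union, not the sum", {
  lens <- c(s1 = 1000L)
  a <- tibble::tibble(seq_id = "s1", start = 0L, end = 100L)
  b <- tibble::tibble(seq_id = "s1", start = 500L, end = 550L)
  expect_equal(cumulative_pair_percentage(a, b, lens), 15)
  expect_equal(cumulative_pair_percentage(a, a, lens), 10)
  # heavy overlap: union < sum
  c2 <- tibble::tibble(seq_id = "s1", start = 50L, end = 150L)
  expect_lt(cumulative_pair_percentage(a, c2, lens), 20)
})

test_that("pair matrix satisfies symmetry and dominance invariants", {
  set.seed(17)
  lens <- c(s1 = 3000L, s2 = 2000L)
  ivs <- lapply(1:4, function(i) {
    n <- sample(3:25, 1)
    sid <- sample(names(lens), n, replace = TRUE)
    st <- floor(runif(n) * (lens[sid] - 50))
    m <- tibble::tibble(ref_id = sid, ref_start = as.integer(st),
                        ref_end = as.integer(st + sample(5:50, n, TRUE)),
                        qry_id = "q", qry_start = 0L, qry_end = 1L,
                        length = 1L, strand = "+")
    merge_to_intervals(m, lens)
  })
  names(ivs) <- paste0("sp", 1:4)
  pm <- pair_coverage_matrix(ivs, lens)
  v <- pm$values
  expect_equal(v, t(v))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      expect_gte(v[i, j] + 1e-9, max(v[i, i], v[j, j]))
      expect_lte(v[i, j], min(100, v[i, i] + v[j, j]) + 1e-9)
    }
  }
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  pm2 <- pair_coverage_matrix(ivs[perm], lens)
  expect_equal(pm2$values, v[perm, perm])
  expect_identical(rank_pairs(pm)[1, ], rank_pairs(pm2)[1, ])
})

test_that("monotonicity: adding matches never decreases coverage", {
  set.seed(23)
  lens <- c(s1 = 2000L)
  st <- sample(0:1950, 40)
  m <- tibble::tibble(ref_id = "s1", ref_start = as.integer(st),
                      ref_end = as.integer(st + 20), qry_id = "q",
                      qry_start = 0L, qry_end = 1L, length = 20L,
                      strand = "+")
  p_small <- mums_percentage(merge_to_intervals(m[1:10, ], lens), lens)$percent
  p_big <- mums_percentage(merge_to_intervals(m, lens), lens)$percent
  expect_gte(p_big, p_small)
})

test_that("rank_pairs sorts by percent with lexicographic tie-break", {
  sp <- c("d", "b", "a", "c")
  v <- matrix(10, 4, 4, dimnames = list(sp, sp))
  v[1, 2] <- v[2, 1] <- 40
  v[3, 4] <- v[4, 3] <- 40
  v[1, 3] <- v[3, 1] <- 25
  v[1, 4] <- v[4, 1] <- 25
  v[2, 3] <- v[3, 2] <- 25
  v[2, 4] <- v[4, 2] <- 25
  diag(v) <- c(9, 9, 9, 9)
  pm <- structure(list(species = sp, values = v, singles = diag(v),
                       sum_percent = outer(diag(v), diag(v), "+"),
                       target_bp = 1000), class = "pair_coverage")
  rp <- rank_pairs(pm)
  # full sort oracle
  expect_identical(rp$percent, sort(rp$percent, decreasing = TRUE))
  expect_identical(rp[1, ]$species_i, "a")   # a+c ties b+d at 40; a < b
  expect_identical(rp[1, ]$species_j, "c")
  expect_identical(nrow(rp), 6L)
  single <- structure(list(species = "x", values = matrix(1, 1, 1),
                           singles = 1, sum_percent = matrix(2, 1, 1),
                           target_bp = 10), class = "pair_coverage")
  expect_error(rank_pairs(single), "fewer than 2")
})
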