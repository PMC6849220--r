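test_that("reverse_complement is correct and involutive", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_identical(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGU"), "outside")
  set.seed(2)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1), alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("identical repeat-free sequences give one full-length MUM", {
  m <- find_mums(c(r1 = "GATTACACAT"), c(q1 = "GATTACACAT"), min_length = 5)
  expect_identical(nrow(m), 1L)
  expect_identical(m$ref_start, 0L)
  expect_identical(m$length, 10L)
  expect_identical(m$strand, "+")
})

test_that("sequences with no shared substring give no matches", {
  m <- find_mums(c(r1 = "AAAAAAAAAA"), c(q1 = "CCCCCCCCCC"), min_length = 4)
  expect_identical(nrow(m), 0L)
  n <- find_mums_naive(c(r1 = "AAAAAAAAAA"), c(q1 = "CCCCCCCCCC"),
                       min_length = 4)
  expect_identical(nrow(n), 0L)
})

test_that("uniqueness is enforced against repeated target substrings", {
  # "ACGT" occurs twice in the target, so no MUM of exactly that string;
  # the length-5 maximal matches TACGT (+) and ACGTA (-) are unique in both
  # sequences and are the full result (verified by the brute-force oracle)
  a <- find_mums(c(r1 = "ACGTACGT"), c(q1 = "TACGTT"), min_length = 4)
  b <- find_mums_naive(c(r1 = "ACGTACGT"), c(q1 = "TACGTT"), min_length = 4)
  expect_same_matches(a, b)
  expect_identical(sort(a$length), c(5L, 5L))
  expect_false(any(a$length == 4L))
})

test_that("engine equals the brute-force oracle on random genome pairs", {
  set.seed(421)
  for (i in 1:40) {
    gc <- runif(1, 0.3, 0.7)
    t <- setNames(random_dna(sample(50:800, 1), gc), "r1")
    q <- setNames(random_dna(sample(50:800, 1), gc), "q1")
    if (i %% 2 == 0) {
      seg <- substr(t[[1]], 5, 5 + sample(10:40, 1))
      q[[1]] <- paste0(q[[1]], seg)
    }
    ml <- sample(c(5L, 10L, 20L), 1)
    un <- sample(c("both", "reference_only"), 1)
    expect_same_matches(
      find_mums(t, q, min_length = ml, uniqueness = un),
      find_mums_naive(t, q, min_length = ml, uniqueness = un)
    )
  }
})

test_that("matches satisfy their string-equality invariant", {
  set.seed(77)
  t <- c(tA = random_dna(400), tB = random_dna(300))
  q <- c(qA = paste0(random_dna(100), substr(t[["tA"]], 21, 90), random_dna(100)))
  m <- find_mums(t, q, min_length = 10)
  expect_gt(nrow(m), 0)
  expect_false(any(duplicated(m)))
  for (r in seq_len(nrow(m))) {
    ts <- substr(t[[m$ref_id[r]]], m$ref_start[r] + 1, m$ref_end[r])
    qs <- substr(q[[m$qry_id[r]]], m$qry_start[r] + 1, m$qry_end[r])
    if (m$strand[r] == "-") qs <- reverse_complement(qs)
    expect_identical(ts, qs)
    expect_false(grepl("N", ts, fixed = TRUE))
  }
})

test_that("strand symmetry: reverse-complementing the candidate flips strands", {
  set.seed(13)
  t <- c(r1 = random_dna(600))
  q <- c(q1 = paste0(random_dna(50), substr(t[[1]], 101, 200), random_dna(50)))
  a <- find_mums(t, q, min_length = 8)
  qr <- setNames(reverse_complement(q), names(q))
  s <- find_mums(t, qr, min_length = 8)
  flipped <- dplyr::mutate(s,
    strand = ifelse(strand == "+", "-", "+"),
    new_start = qry_len - qry_end,
    qry_end = qry_len - qry_start,
    qry_start = new_start) |>
    dplyr::select(-new_start) |>
    dplyr::arrange(ref_id, ref_start, qry_id, qry_start, strand)
  expect_same_matches(a, flipped[, names(a)])
})

test_that("matches never include N or cross record boundaries", {
  t <- c(r1 = "ACGTACTGANACGTACTGA")   # repeated 9-mer split by N
  q <- c(q1 = "ACGTACTGA")
  m <- find_mums(t, q, min_length = 4)
  n <- find_mums_naive(t, q, min_length = 4)
  expect_same_matches(m, n)
  # two-record target: the shared string occurs once per record -> not unique
  t2 <- c(a = "GATTACACAT", b = "GATTACACAT")
  expect_identical(nrow(find_mums(t2, c(q1 = "GATTACACAT"),
                                  min_length = 5)), 0L)
})

test_that("the naive oracle refuses oversized inputs", {
  g <- c(r1 = strrep("A", 15000))
  q <- c(q1 = strrep("C", 15000))
  expect_error(find_mums_naive(g, q, min_length = 10), "guard")
})

test_that("match tables round-trip through the PAF-like TSV", {
  set.seed(3)
  t <- c(r1 = random_dna(300))
  q <- c(q1 = paste0(substr(t[[1]], 11, 60), random_dna(60)))
  m <- find_mums(t, q, min_length = 8)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matches(m, tf)
  expect_identical(as.data.frame(read_matches(tf)), as.data.frame(m))
})

test_that("min_length below 2 is rejected", {
  expect_error(find_mums(c(r = "ACGT"), c(q = "ACGT"), min_length = 1), ">= 2")
})
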