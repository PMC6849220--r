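# Shared test fixtures and independent oracles, all built in code.

random_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  p <- if (length(alphabet) == 4) {
    c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  } else {
    NULL
  }
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

random_genome <- function(n_records = 1, min_len = 50, max_len = 500,
                          gc = 0.5, prefix = "s") {
  lens <- sample(min_len:max_len, n_records, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1), gc = gc)
  setNames(seqs, paste0(prefix, seq_len(n_records)))
}

# random match tables for the one-to-one filter; coordinates deliberately
# packed into a small range so axis overlaps and crossings are common
random_matches <- function(n, ref_ids = c("r1", "r2"), qry_ids = c("q1", "q2"),
                           span = 150L) {
  tibble::tibble(
    ref_id = sample(ref_ids, n, replace = TRUE),
    qry_id = sample(qry_ids, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    ref_start = sample(0:span, n, replace = TRUE),
    qry_start = sample(0:span, n, replace = TRUE),
    length = sample(5:40, n, replace = TRUE)
  ) |>
    dplyr::mutate(ref_end = ref_start + length, qry_end = qry_start + length,
                  ref_len = span + 100L, qry_len = span + 100L)
}

# feasibility predicate for one-to-one subsets: pairwise non-overlap on both
# axes, and same-group pairs consistently ordered (non-crossing)
one_to_one_feasible <- function(m) {
  n <- nrow(m)
  if (n < 2) return(TRUE)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (m$ref_id[i] == m$ref_id[j] &&
          m$ref_start[i] < m$ref_end[j] && m$ref_end[i] > m$ref_start[j]) {
        return(FALSE)
      }
      if (m$qry_id[i] == m$qry_id[j] &&
          m$qry_start[i] < m$qry_end[j] && m$qry_end[i] > m$qry_start[j]) {
        return(FALSE)
      }
      if (m$ref_id[i] == m$ref_id[j] && m$qry_id[i] == m$qry_id[j] &&
          m$strand[i] == m$strand[j]) {
        rb <- m$ref_start[i] < m$ref_start[j]
        qb <- m$qry_start[i] < m$qry_start[j]
        crossed <- if (m$strand[i] == "+") rb != qb else rb == qb
        if (crossed) return(FALSE)
      }
    }
  }
  TRUE
}

# exhaustive optimum over all one-to-one-feasible subsets (full enumeration)
brute_one_to_one_weight <- function(m) {
  n <- nrow(m)
  stopifnot(n <= 14)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2L^(0:(n - 1))) > 0)
    if (length(idx) == 0) next
    if (one_to_one_feasible(m[idx, , drop = FALSE])) {
      best <- max(best, sum(m$length[idx]))
    }
  }
  as.integer(best)
}

# bitmap coverage oracle: mark covered positions explicitly
bitmap_covered_bp <- function(matches, lens) {
  total <- 0L
  for (sid in names(lens)) {
    bm <- logical(lens[[sid]])
    mm <- matches[matches$ref_id == sid, , drop = FALSE]
    for (r in seq_len(nrow(mm))) {
      if (mm$ref_end[r] > mm$ref_start[r]) {
        bm[(mm$ref_start[r] + 1):mm$ref_end[r]] <- TRUE
      }
    }
    total <- total + sum(bm)
  }
  total
}

match_df <- function(x) {
  d <- as.data.frame(x)[, c("ref_id", "ref_start", "ref_end", "qry_id",
                            "qry_start", "qry_end", "length", "strand")]
  rownames(d) <- NULL
  d
}

expect_same_matches <- function(a, b) {
  expect_identical(match_df(a), match_df(b))
}

# small scenario used by pipeline tests (fast: ~45 kb ancestor)
small_scenario_config <- function(seed = 1L) {
  scenario_config(ancestor_length = 45000L, n_chromosomes = 2L, seed = seed)
}
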