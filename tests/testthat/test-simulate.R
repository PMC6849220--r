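test_that("ancestor simulation is seed-reproducible with near-equal records", {
  g1 <- simulate_ancestor(1000, n_chromosomes = 3, gc = 0.5, seed = 1)
  g2 <- simulate_ancestor(1000, n_chromosomes = 3, gc = 0.5, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- simulate_ancestor(10, n_chromosomes = 3, gc = 0.5, seed = 2)
  expect_identical(unname(Biostrings::width(g3)), c(4L, 3L, 3L))
  expect_error(simulate_ancestor(100, gc = 1.2), "gc")
})

test_that("simulated GC content concentrates around the requested fraction", {
  g <- simulate_ancestor(1e5, gc = 0.99, seed = 3)
  s <- as.character(g)[[1]]
  gc_obs <- nchar(gsub("[AT]", "", s)) / nchar(s)
  expect_lt(abs(gc_obs - 0.99), 0.01)
})

test_that("evolution with zero rates is the identity", {
  g <- simulate_ancestor(2000, seed = 4)
  e <- evolve_genome(g, sub_rate = 0, indel_rate = 0, n_inversions = 0,
                     seed = 5)
  expect_identical(as.character(e), as.character(g))
})

test_that("substitution counts match the binomial model", {
  n <- 1e5
  g <- simulate_ancestor(n, seed = 6)
  rate <- 0.1
  e <- evolve_genome(g, sub_rate = rate, seed = 7)
  a <- strsplit(as.character(g)[[1]], "")[[1]]
  b <- strsplit(as.character(e)[[1]], "")[[1]]
  diff <- sum(a != b)
  # every hit site changes base, so E[diff] = n * rate
  expect_lt(abs(diff - n * rate), 3 * sqrt(n * rate * (1 - rate)))
})

test_that("an inversion reverse-complements one segment in place", {
  g <- simulate_ancestor(20000, seed = 8)
  e <- evolve_genome(g, sub_rate = 0, n_inversions = 1, seed = 9)
  a <- strsplit(as.character(g)[[1]], "")[[1]]
  b <- strsplit(as.character(e)[[1]], "")[[1]]
  expect_identical(length(a), length(b))
  d <- which(a != b)
  expect_gt(length(d), 0)
  lo <- min(d); hi <- max(d)
  seg_in <- paste(a[lo:hi], collapse = "")
  seg_out <- paste(b[lo:hi], collapse = "")
  # the changed region need not start exactly at the segment edge (ends of a
  # segment can be revcomp-fixed points), so test the spanned window
  expect_identical(reverse_complement(seg_in), seg_out)
  # outside the inverted window nothing changed
  expect_identical(a[-(lo:hi)], b[-(lo:hi)])
})

test_that("read simulation respects count, placement and error model", {
  g <- c(chr1 = random_dna(10000))
  r <- simulate_reads(g, depth = 10, read_length = 100, seed = 10)
  expect_identical(nrow(r), 1000L)
  expect_true(all(nchar(r$seq) == 100))
  # error-free reads are exact forward substrings
  set.seed(11)
  for (i in sample(nrow(r), 25)) {
    expect_true(grepl(r$seq[i], g[[1]], fixed = TRUE))
  }
  # 1% error rate within 3 sd over 1e5 sampled bases
  r2 <- simulate_reads(g, depth = 10, read_length = 100, error_rate = 0.01,
                       seed = 10)
  mism <- sum(strsplit(paste(r$seq, collapse = ""), "")[[1]] !=
                strsplit(paste(r2$seq, collapse = ""), "")[[1]])
  expect_lt(abs(mism - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
  expect_error(simulate_reads(g, depth = 1, read_length = 20000), "shortest")
})

test_that("scenarios are reproducible and carry the declared structure", {
  cfg <- small_scenario_config(seed = 21L)
  s1 <- make_scenario(cfg)
  s2 <- make_scenario(cfg)
  expect_identical(as.character(s1$target), as.character(s2$target))
  expect_identical(lapply(s1$candidates, as.character),
                   lapply(s2$candidates, as.character))
  expect_identical(s1$true_pair, sort(c("prog_a", "prog_b")))
  expect_identical(names(s1$candidates), names(cfg$panel))
  expect_true(all(startsWith(names(s1$target),
                             c(rep("subgenomeA_", 2), rep("subgenomeB_", 2)))))
  expect_error(make_scenario(scenario_config(progenitors = c("prog_a", "nope"))),
               "not in panel")
})

test_that("with no post-hybrid divergence the target is the progenitor concat", {
  cfg <- scenario_config(ancestor_length = 8000L, n_chromosomes = 1L,
                         panel = c(p1 = 0.05, p2 = 0.05),
                         progenitors = c("p1", "p2"),
                         post_hybrid_divergence = 0, indel_rate = 0,
                         n_inversions = 0L, seed = 33L)
  sc <- make_scenario(cfg)
  expect_identical(unname(as.character(sc$target)),
                   unname(c(as.character(sc$candidates$p1),
                            as.character(sc$candidates$p2))))
  # each progenitor covers its own half (plus weak cross-subgenome homology);
  # together they cover essentially the whole target
  rep <- run_ancestry(sc$target, sc$candidates)
  expect_true(all(rep$singles$percent > 45 & rep$singles$percent < 85))
  expect_gt(rep$winner$percent, 95)
})
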