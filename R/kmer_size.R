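# Genome-size estimation from the k-mer spectrum of a read set.
#
# The estimator is G = (N * (L - K + 1) - B) / D, where N is the number of
# reads, L the read length, K the k-mer length, B the number of k-mer
# instances in low-frequency bins (occurrence below `cutoff`, attributed to
# sequencing error), and D the sequencing depth read off the spectrum as the
# modal multiplicity at or above the cutoff. K-mers are counted as read (no
# canonical strand collapsing) so the window count N*(L-K+1) and the instance
# total agree exactly; windows containing N are skipped.

reads_to_seqs <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("seq" %in% names(reads))
    return(as.character(reads$seq))
  }
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads)) return(reads)
  abort("reads must be a tibble with a seq column, a character vector, or a DNAStringSet")
}

#' Count k-mers of a read set into a multiplicity histogram
#'
#' Every k-length window of every read is counted as read (forward
#' orientation, no strand collapsing); windows containing `N` are skipped.
#'
#' @param reads Read tibble ([read_reads()] / [simulate_reads()]), character
#'   vector, or `DNAStringSet`.
#' @param k K-mer length (>= 2).
#' @return A `kmer_histogram`: tibble with columns `multiplicity` and `count`
#'   (distinct k-mers observed at that multiplicity), with attributes `k` and
#'   `total_kmers` (total counted instances).
#' @export
count_kmers <- function(reads, k) {
  if (!is.numeric(k) || k < 2) abort("k must be an integer >= 2")
  k <- as.integer(k)
  seqs <- reads_to_seqs(reads)
  lens <- nchar(seqs)
  if (length(seqs) == 0 || all(lens < k)) {
    abort(paste0("no k-mers: every read is shorter than k = ", k))
  }
  max_off <- max(lens) - k + 1L
  chunks <- vector("list", max_off)
  for (off in seq_len(max_off)) {
    sel <- lens >= off + k - 1L
    chunks[[off]] <- substr(seqs[sel], off, off + k - 1L)
  }
  kmers <- unlist(chunks, use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0) {
    abort("no k-mers: every window contains N")
  }
  hist <- tibble(kmer = kmers) |>
    count(.data$kmer, name = "multiplicity") |>
    count(.data$multiplicity, name = "count") |>
    arrange(.data$multiplicity)
  structure(as_tibble(hist), k = k,
            total_kmers = sum(as.numeric(hist$multiplicity) * hist$count),
            class = c("kmer_histogram", class(hist)))
}

as_kmer_histogram <- function(x, k = NA_integer_) {
  stopifnot(is.data.frame(x), all(c("multiplicity", "count") %in% names(x)))
  x <- as_tibble(x[order(x$multiplicity), c("multiplicity", "count")])
  structure(x, k = k,
            total_kmers = sum(as.numeric(x$multiplicity) * x$count),
            class = unique(c("kmer_histogram", class(x))))
}

#' Sequencing depth from a k-mer histogram
#'
#' The modal multiplicity of the spectrum at or above `cutoff` (bins below the
#' cutoff are treated as sequencing-error k-mers); ties break toward the
#' smaller multiplicity.
#'
#' @param hist A `kmer_histogram` (or tibble with `multiplicity`, `count`).
#' @param cutoff Low-frequency threshold (default 4: occurrences below 4 are
#'   the error zone).
#' @return Integer depth `D`.
#' @export
estimate_depth <- function(hist, cutoff = 4L) {
  h <- hist[hist$multiplicity >= cutoff & hist$count > 0, , drop = FALSE]
  if (nrow(h) == 0) {
    abort("spectrum entirely low-frequency: no multiplicity at or above cutoff")
  }
  h <- h[order(h$multiplicity), , drop = FALSE]
  as.integer(h$multiplicity[which.max(h$count)])
}

#' Low-frequency (error) k-mer mass
#'
#' Total k-mer instances in bins with multiplicity below `cutoff`:
#' `sum(m * count[m])` over `m < cutoff`. The alternative reading of the
#' error term as distinct k-mers is available via `mode = "distinct"` but
#' warned against, since the term is subtracted from an instance total.
#'
#' @inheritParams estimate_depth
#' @param mode `"instances"` (default) or `"distinct"`.
#' @return Numeric B.
#' @export
error_kmer_mass <- function(hist, cutoff = 4L, mode = c("instances", "distinct")) {
  mode <- match.arg(mode)
  h <- hist[hist$multiplicity < cutoff, , drop = FALSE]
  if (nrow(h) == 0) return(0)
  if (mode == "distinct") {
    warn("error_kmer_mass(mode = 'distinct') is inconsistent with the instance total the estimator subtracts from")
    return(sum(as.numeric(h$count)))
  }
  sum(as.numeric(h$multiplicity) * h$count)
}

#' Genome size from the k-mer formula
#'
#' `G = (N * (L - K + 1) - B) / D`.
#'
#' @param N Number of reads.
#' @param L Read length (bases); for mixed lengths use the mean.
#' @param K K-mer length (`K < L`).
#' @param B Low-frequency k-mer instance mass ([error_kmer_mass()]).
#' @param D Sequencing depth ([estimate_depth()]).
#' @return Genome size in bases (double; round for an integer base count).
#' @examples
#' estimate_genome_size(N = 1000, L = 100, K = 21, B = 0, D = 10) # 8000
#' @export
estimate_genome_size <- function(N, L, K, B, D) {
  if (D < 1) abort("depth D must be >= 1")
  if (L <= K) abort("read length L must exceed k-mer length K")
  if (N < 1) abort("need at least one read")
  num <- N * (L - K + 1) - B
  if (num <= 0) abort("low-frequency mass exceeds k-mer total")
  num / D
}

#' Estimate genome size from a read set
#'
#' Chains [count_kmers()], [estimate_depth()], [error_kmer_mass()] and
#' [estimate_genome_size()].
#'
#' @param reads Read tibble, character vector or `DNAStringSet`.
#' @param k K-mer length (default 21).
#' @param cutoff Low-frequency threshold (default 4).
#' @param b_mode Error-mass mode, see [error_kmer_mass()].
#' @return A `genome_size_estimate`: list with `N`, `L`, `K`, `B`, `D`, `G`,
#'   `G_bases` (rounded), `cutoff` and the `histogram`.
#' @export
genome_size_from_reads <- function(reads, k = 21L, cutoff = 4L,
                                   b_mode = c("instances", "distinct")) {
  b_mode <- match.arg(b_mode)
  seqs <- reads_to_seqs(reads)
  hist <- count_kmers(seqs, k)
  N <- length(seqs)
  L <- mean(nchar(seqs))
  D <- estimate_depth(hist, cutoff)
  B <- error_kmer_mass(hist, cutoff, b_mode)
  G <- estimate_genome_size(N, L, k, B, D)
  structure(list(N = N, L = L, K = as.integer(k), B = B, D = D, G = G,
                 G_bases = round(G), cutoff = as.integer(cutoff),
                 histogram = hist),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat("k-mer genome size estimate\n")
  cat(sprintf("  N = %d reads, L = %.1f bp, K = %d, cutoff = %d\n",
              x$N, x$L, x$K, x$cutoff))
  cat(sprintf("  B = %.0f error k-mer instances, D = %d (spectrum peak)\n",
              x$B, x$D))
  cat(sprintf("  G = %.0f bases\n", x$G))
  invisible(x)
}

#' Write a k-mer histogram as two-column TSV
#' @param hist A `kmer_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  write.table(hist[, c("multiplicity", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
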