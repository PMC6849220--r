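# Coverage statistics on the target genome: per-candidate MUM coverage
# percentage and the cumulative (union) percentage for every candidate pair.
# Interval arithmetic is delegated to IRanges; all coordinates in results are
# 0-based half-open.

target_lengths <- function(target) {
  if (is.numeric(target) && !is.null(names(target))) {
    return(setNames(as.integer(target), names(target)))
  }
  g <- as_genome(target)
  setNames(Biostrings::width(g), names(g))
}

#' Merge match footprints into disjoint covered intervals
#'
#' Per target sequence, the union of `[ref_start, ref_end)` over all matches,
#' merged (adjacent intervals coalesce) and sorted.
#'
#' @param matches A match tibble ([find_mums()] / [filter_one_to_one()]).
#' @param target The target genome, or a named integer vector of its record
#'   lengths.
#' @return A tibble with columns `seq_id`, `start`, `end` (0-based half-open),
#'   disjoint and sorted within each `seq_id`.
#' @export
merge_to_intervals <- function(matches, target) {
  lens <- target_lengths(target)
  if (nrow(matches) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer()))
  }
  if (!all(matches$ref_id %in% names(lens))) {
    abort("matches refer to sequences absent from the target")
  }
  if (any(matches$ref_start < 0) ||
      any(matches$ref_end > lens[matches$ref_id])) {
    abort("match interval out of target sequence bounds")
  }
  out <- matches |>
    group_by(.data$ref_id) |>
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$ref_start + 1L,
                                             end = d$ref_end))
      tibble(start = BiocGenerics::start(ir) - 1L,
             end = BiocGenerics::end(ir))
    }) |>
    ungroup() |>
    rename(seq_id = "ref_id") |>
    arrange(match(.data$seq_id, names(lens)), .data$start)
  out
}

covered_bp <- function(intervals) {
  if (nrow(intervals) == 0) return(0L)
  sum(intervals$end - intervals$start)
}

#' Per-candidate coverage percentage of the target
#'
#' `percent = 100 * covered_bp / target_bp`, full precision.
#'
#' @param intervals Interval tibble from [merge_to_intervals()].
#' @param target Target genome or named record lengths.
#' @param species Candidate label for the report row.
#' @return One-row tibble: `species`, `covered_bp`, `target_bp`, `percent`.
#' @export
mums_percentage <- function(intervals, target, species = NA_character_) {
  lens <- target_lengths(target)
  total <- sum(as.numeric(lens))
  if (total == 0) abort("target has zero length")
  cov <- covered_bp(intervals)
  tibble(species = species, covered_bp = as.numeric(cov),
         target_bp = total, percent = 100 * cov / total)
}

#' Cumulative pair coverage percentage
#'
#' Percent of the target covered by the union of two candidates' interval
#' sets. This is the cumulative alignment statistic used to rank candidate
#' pairs: union, not sum, so a shared ancestral region is counted once and
#' the value can never exceed 100.
#'
#' @param intervals_a,intervals_b Interval tibbles on the same target.
#' @param target Target genome or named record lengths.
#' @return A single numeric percentage.
#' @export
cumulative_pair_percentage <- function(intervals_a, intervals_b, target) {
  both <- bind_rows(
    intervals_a[, c("seq_id", "start", "end")],
    intervals_b[, c("seq_id", "start", "end")]
  )
  if (nrow(both) > 0) {
    names(both) <- c("ref_id", "ref_start", "ref_end")
    both <- merge_to_intervals(both, target)
  }
  mums_percentage(both, target)$percent
}

#' Pairwise cumulative coverage matrix over a candidate panel
#'
#' Symmetric matrix of cumulative (union) coverage percentages for every
#' candidate pair; the diagonal holds single-candidate percentages. The sum
#' of the two single percentages is also reported per pair for transparency.
#'
#' @param interval_sets Named list of interval tibbles, one per candidate.
#' @param target Target genome or named record lengths.
#' @return A `pair_coverage` object: list with `species`, `values` (matrix of
#'   percentages), `singles`, `sum_percent` matrix and `target_bp`.
#' @export
pair_coverage_matrix <- function(interval_sets, target) {
  if (is.null(names(interval_sets)) || any(names(interval_sets) == "")) {
    abort("interval_sets must be a named list (one candidate per element)")
  }
  sp <- names(interval_sets)
  singles <- vapply(interval_sets, function(iv) {
    mums_percentage(iv, target)$percent
  }, numeric(1))
  k <- length(sp)
  vals <- matrix(NA_real_, k, k, dimnames = list(sp, sp))
  diag(vals) <- singles
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- cumulative_pair_percentage(interval_sets[[i]], interval_sets[[j]],
                                        target)
        vals[i, j] <- p
        vals[j, i] <- p
      }
    }
  }
  structure(list(species = sp, values = vals, singles = singles,
                 sum_percent = outer(singles, singles, "+"),
                 target_bp = sum(as.numeric(target_lengths(target)))),
            class = "pair_coverage")
}

#' Rank candidate pairs by cumulative coverage
#'
#' All unordered off-diagonal pairs, sorted by percentage descending; ties
#' break lexicographically by species names. The first row is the nominated
#' progenitor pair.
#'
#' @param matrix A `pair_coverage` object.
#' @return A tibble `species_i`, `species_j`, `percent`, sorted.
#' @export
rank_pairs <- function(matrix) {
  stopifnot(inherits(matrix, "pair_coverage"))
  sp <- matrix$species
  if (length(sp) < 2) abort("fewer than 2 candidates")
  idx <- which(upper.tri(matrix$values), arr.ind = TRUE)
  out <- tibble(
    species_i = pmin(sp[idx[, 1]], sp[idx[, 2]]),
    species_j = pmax(sp[idx[, 1]], sp[idx[, 2]]),
    percent = matrix$values[idx]
  )
  out |> arrange(desc(.data$percent), .data$species_i, .data$species_j)
}

#' @export
print.pair_coverage <- function(x, ...) {
  cat("Pairwise cumulative coverage of target (", x$target_bp, " bp) over ",
      length(x$species), " candidates\n", sep = "")
  print(round(x$values, 2))
  invisible(x)
}

#' Write a pair-coverage matrix as TSV (two-decimal percentages)
#'
#' @param matrix A `pair_coverage` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pair_coverage"))
  df <- data.frame(species = matrix$species,
                   format(round(matrix$values, 2), nsmall = 2, trim = TRUE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
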