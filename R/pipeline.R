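# End-to-end orchestration: MUMs -> one-to-one filter -> coverage ->
# pairwise cumulative matrix -> ranked progenitor nomination, and the k-mer
# genome-size chain. Reports are deterministic (no timestamps) so identical
# inputs give byte-identical output files.

#' Run the full ancestry analysis
#'
#' For every candidate: find MUMs against the target, reduce them to a
#' one-to-one subset (unless `use_raw_mums`), and merge the retained match
#' footprints into covered intervals. Then build the pairwise cumulative
#' coverage matrix and rank candidate pairs; the top pair is the nominated
#' progenitor pair. A candidate with zero matches contributes a 0% row.
#'
#' @param target Target genome ([as_genome()] accepted forms) or FASTA path.
#' @param candidates Named list of genomes (or FASTA paths); at least one.
#'   With fewer than two candidates the pair ranking is skipped with a
#'   warning and singles are still reported.
#' @param min_length,uniqueness MUM parameters ([find_mums()]).
#' @param use_raw_mums If `TRUE`, coverage is computed from raw MUMs rather
#'   than the one-to-one filtered set.
#' @param out_dir Optional directory; when given, writes per-candidate match
#'   TSVs, the coverage matrix TSV and a JSON report.
#' @return An `ancestry_report`: list with `singles` (per-candidate coverage
#'   tibble), `matrix` (`pair_coverage` or `NULL`), `pairs` (ranked tibble or
#'   `NULL`), `winner` (named list or `NULL`), `params`.
#' @export
run_ancestry <- function(target, candidates, min_length = 20L,
                         uniqueness = c("both", "reference_only"),
                         use_raw_mums = FALSE, out_dir = NULL) {
  uniqueness <- match.arg(uniqueness)
  if (is.character(target) && length(target) == 1 && file.exists(target)) {
    target <- read_genome(target)
  }
  target <- as_genome(target)
  if (length(candidates) == 0) abort("no candidates supplied")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    abort("candidates must be a named list")
  }
  candidates <- lapply(candidates, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      x <- read_genome(x)
    }
    as_genome(x)
  })
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  stage <- function(name, candidate_name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed for candidate '",
                   candidate_name, "': ", conditionMessage(e)))
    })
  }

  interval_sets <- vector("list", length(candidates))
  names(interval_sets) <- names(candidates)
  singles <- vector("list", length(candidates))
  for (nm in names(candidates)) {
    raw <- stage("mums", nm, find_mums(target, candidates[[nm]],
                                       min_length = min_length,
                                       uniqueness = uniqueness))
    kept <- if (use_raw_mums) raw else
      stage("filter", nm, filter_one_to_one(raw))
    iv <- stage("coverage", nm, merge_to_intervals(kept, target))
    interval_sets[[nm]] <- iv
    singles[[nm]] <- mums_percentage(iv, target, species = nm) |>
      mutate(n_matches_raw = nrow(raw), n_matches_kept = nrow(kept))
    if (!is.null(out_dir)) {
      write_matches(kept, file.path(out_dir, paste0("matches_", nm, ".tsv")))
    }
  }
  singles <- bind_rows(singles)

  mat <- NULL; pairs <- NULL; winner <- NULL
  if (length(candidates) >= 2) {
    mat <- pair_coverage_matrix(interval_sets, target)
    pairs <- rank_pairs(mat)
    winner <- list(species_i = pairs$species_i[1],
                   species_j = pairs$species_j[1],
                   percent = pairs$percent[1])
  } else {
    warn("fewer than 2 candidates: pair ranking skipped")
  }

  report <- structure(
    list(singles = singles, matrix = mat, pairs = pairs, winner = winner,
         intervals = interval_sets,
         params = list(min_length = as.integer(min_length),
                       uniqueness = uniqueness,
                       use_raw_mums = use_raw_mums,
                       target_bp = genome_length(target),
                       n_candidates = length(candidates),
                       tool = paste0("allomum ",
                                     as.character(utils::packageVersion("allomum"))))),
    class = "ancestry_report")
  if (!is.null(out_dir)) {
    if (!is.null(mat)) {
      write_coverage_matrix(mat, file.path(out_dir, "coverage_matrix.tsv"))
    }
    write_ancestry_report(report, file.path(out_dir, "ancestry_report.json"))
  }
  report
}

#' Write an ancestry report as deterministic JSON
#'
#' @param report An `ancestry_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_report <- function(report, path) {
  stopifnot(inherits(report, "ancestry_report"))
  payload <- list(
    params = report$params,
    singles = report$singles,
    pairs = report$pairs,
    winner = report$winner
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.ancestry_report <- function(x, ...) {
  cat("Ancestry analysis over", x$params$n_candidates, "candidates; target",
      x$params$target_bp, "bp\n")
  print(x$singles)
  if (!is.null(x$winner)) {
    cat(sprintf("Nominated progenitor pair: %s + %s (%.2f%% cumulative)\n",
                x$winner$species_i, x$winner$species_j, x$winner$percent))
  }
  invisible(x)
}

#' Run the k-mer genome-size estimate
#'
#' Wrapper around [genome_size_from_reads()] that optionally writes the
#' histogram TSV and estimate JSON.
#'
#' @param reads Read tibble, character vector, `DNAStringSet`, or FASTQ/FASTA
#'   path.
#' @param k,cutoff,b_mode See [genome_size_from_reads()].
#' @param out_dir Optional output directory.
#' @return A `genome_size_estimate`.
#' @export
run_gsize <- function(reads, k = 21L, cutoff = 4L,
                      b_mode = c("instances", "distinct"), out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  est <- genome_size_from_reads(reads, k = k, cutoff = cutoff,
                                b_mode = match.arg(b_mode))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_kmer_histogram(est$histogram,
                         file.path(out_dir, "kmer_histogram.tsv"))
    jsonlite::write_json(est[c("N", "L", "K", "B", "D", "G", "G_bases",
                               "cutoff")],
                         file.path(out_dir, "genome_size.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  est
}
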