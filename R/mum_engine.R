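# Maximal unique match (MUM) detection between a target and a candidate
# genome, on both candidate strands.
#
# A MUM is an exact match of at least `min_length` bases that is maximal
# (extendable in neither direction) and unique: the matched string occurs
# exactly once in the target and — with uniqueness = "both" — exactly once in
# the candidate, counting both candidate strands. The engine builds one
# generalized suffix array over target + candidate + candidate reverse
# complement, with a unique sentinel code at every record boundary and every N
# so matches can never cross either.

#' Reverse complement of a nucleotide string
#'
#' Watson–Crick complement, reversed; `N` maps to `N`. Vectorized.
#'
#' @param seq Character vector over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    abort("reverse_complement: characters outside {A,C,G,T,N}")
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

# Map a genome to integer codes A=1 C=2 G=3 T=4; each N gets a fresh negative
# code from `counter` so it matches nothing, not even another N.
encode_genome <- function(seqs, counter) {
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    v <- lut[utf8ToInt(seqs[[i]])]
    ns <- which(v == 0L)
    if (length(ns) > 0) {
      v[ns] <- counter$take(length(ns))
    }
    out[[i]] <- v
  }
  out
}

new_neg_counter <- function() {
  env <- new.env()
  env$next_id <- -1L
  env$take <- function(k) {
    ids <- seq.int(env$next_id, by = -1L, length.out = k)
    env$next_id <- env$next_id - k
    ids
  }
  env
}

empty_matches <- function() {
  tibble(ref_id = character(), ref_len = integer(), ref_start = integer(),
         ref_end = integer(), qry_id = character(), qry_len = integer(),
         qry_start = integer(), qry_end = integer(), length = integer(),
         strand = character())
}

# order matches by target record order, then coordinates
arrange_matches <- function(m, ref_levels = NULL, qry_levels = NULL) {
  ref_key <- if (is.null(ref_levels)) m$ref_id else
    match(m$ref_id, ref_levels)
  qry_key <- if (is.null(qry_levels)) m$qry_id else
    match(m$qry_id, qry_levels)
  m[order(ref_key, m$ref_start, qry_key, m$qry_start, m$strand), , drop = FALSE]
}

#' Find maximal unique matches between two genomes
#'
#' Exact matches of at least `min_length` bases, extendable in neither
#' direction, whose matched string occurs exactly once in the target and
#' (for `uniqueness = "both"`, the default) exactly once in the candidate
#' counting both candidate strands. Minus-strand matches report `qry_start`
#' on the candidate's forward strand (leftmost matched base). The result is
#' deterministic: rows are sorted by (`ref_id`, `ref_start`, `qry_id`,
#' `qry_start`), record ids in input record order.
#'
#' @param target,candidate Genomes ([as_genome()]).
#' @param min_length Minimum match length in bases (default 20, minimum 2).
#' @param uniqueness `"both"` (unique in target and candidate) or
#'   `"reference_only"` (unique in the target only).
#' @return A tibble with columns `ref_id`, `ref_len`, `ref_start`, `ref_end`,
#'   `qry_id`, `qry_len`, `qry_start`, `qry_end`, `length`, `strand`
#'   (0-based half-open coordinates).
#' @examples
#' find_mums(c(r1 = "GATTACACAT"), c(q1 = "GATTACACAT"), min_length = 5)
#' @export
find_mums <- function(target, candidate, min_length = 20L,
                      uniqueness = c("both", "reference_only")) {
  uniqueness <- match.arg(uniqueness)
  target <- as_genome(target)
  candidate <- as_genome(candidate)
  if (!is.numeric(min_length) || min_length < 2) {
    abort("min_length must be an integer >= 2")
  }
  min_length <- as.integer(min_length)

  t_seq <- as.character(target)
  c_seq <- as.character(candidate)
  cr_seq <- reverse_complement(c_seq)

  counter <- new_neg_counter()
  enc_t <- encode_genome(t_seq, counter)
  enc_cf <- encode_genome(c_seq, counter)
  enc_cr <- encode_genome(cr_seq, counter)

  blocks <- list()
  offsets_t <- integer(length(enc_t))
  pos <- 0L
  for (i in seq_along(enc_t)) {
    offsets_t[i] <- pos
    blocks[[length(blocks) + 1L]] <- enc_t[[i]]
    blocks[[length(blocks) + 1L]] <- counter$take(1L)
    pos <- pos + length(enc_t[[i]]) + 1L
  }
  t_len <- pos
  offsets_cf <- integer(length(enc_cf))
  for (i in seq_along(enc_cf)) {
    offsets_cf[i] <- pos
    blocks[[length(blocks) + 1L]] <- enc_cf[[i]]
    blocks[[length(blocks) + 1L]] <- counter$take(1L)
    pos <- pos + length(enc_cf[[i]]) + 1L
  }
  offsets_cr <- integer(length(enc_cr))
  for (i in seq_along(enc_cr)) {
    offsets_cr[i] <- pos
    blocks[[length(blocks) + 1L]] <- enc_cr[[i]]
    blocks[[length(blocks) + 1L]] <- counter$take(1L)
    pos <- pos + length(enc_cr[[i]]) + 1L
  }
  text <- unlist(blocks, use.names = FALSE)

  hits <- .mum_core(text, t_len, min_length, uniqueness == "both")
  if (nrow(hits) == 0) return(empty_matches())

  t_widths <- Biostrings::width(target)
  c_widths <- Biostrings::width(candidate)

  ref_idx <- findInterval(hits$tpos, offsets_t)
  ref_start <- hits$tpos - offsets_t[ref_idx]

  is_fwd <- hits$cpos < offsets_cr[1]
  qry_idx <- integer(nrow(hits))
  qry_start <- integer(nrow(hits))
  qry_idx[is_fwd] <- findInterval(hits$cpos[is_fwd], offsets_cf)
  qry_start[is_fwd] <- hits$cpos[is_fwd] - offsets_cf[qry_idx[is_fwd]]
  if (any(!is_fwd)) {
    ri <- findInterval(hits$cpos[!is_fwd], offsets_cr)
    rel <- hits$cpos[!is_fwd] - offsets_cr[ri]
    qry_idx[!is_fwd] <- ri
    # leftmost matched base on the forward strand
    qry_start[!is_fwd] <- c_widths[ri] - rel - hits$len[!is_fwd]
  }

  m <- tibble(
    ref_id = names(target)[ref_idx],
    ref_len = t_widths[ref_idx],
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_start + hits$len),
    qry_id = names(candidate)[qry_idx],
    qry_len = c_widths[qry_idx],
    qry_start = as.integer(qry_start),
    qry_end = as.integer(qry_start + hits$len),
    length = as.integer(hits$len),
    strand = ifelse(is_fwd, "+", "-")
  )
  m <- arrange_matches(m, names(target), names(candidate))
  as_tibble(m)
}

#' Brute-force MUM enumeration (test oracle)
#'
#' Same contract as [find_mums()], computed by exhaustive run-length
#' enumeration over all record pairs and both strands, with explicit
#' occurrence counting for the uniqueness check. Kept in the package
#' permanently as the independent reference for the suffix-array engine;
#' refuses inputs whose combined length exceeds `guard` bases.
#'
#' @inheritParams find_mums
#' @param guard Maximum combined genome length (default 20000 bases).
#' @return As [find_mums()].
#' @export
find_mums_naive <- function(target, candidate, min_length = 20L,
                            uniqueness = c("both", "reference_only"),
                            guard = 20000L) {
  uniqueness <- match.arg(uniqueness)
  target <- as_genome(target)
  candidate <- as_genome(candidate)
  if (!is.numeric(min_length) || min_length < 2) {
    abort("min_length must be an integer >= 2")
  }
  total <- genome_length(target) + genome_length(candidate)
  if (total > guard) {
    abort(paste0("find_mums_naive: combined length ", total,
                 " exceeds guard bound ", guard))
  }
  t_seq <- as.character(target)
  c_seq <- as.character(candidate)
  cr_seq <- reverse_complement(c_seq)

  # occurrence counting (overlaps included) on sentinel-joined texts
  t_text <- paste(t_seq, collapse = "#")
  c_text <- paste(c(c_seq, cr_seq), collapse = "#")
  count_occ <- function(pat, text) {
    hits <- gregexpr(paste0("(?=", pat, ")"), text, perl = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }

  to_int <- function(s, n_code) {
    v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    v[is.na(v)] <- n_code
    v
  }

  acc <- list(ref_id = character(0), ref_len = integer(0),
              ref_start = integer(0), qry_id = character(0),
              qry_len = integer(0), qry_start = integer(0),
              length = integer(0), strand = character(0))
  for (ti in seq_along(t_seq)) {
    tv <- to_int(t_seq[[ti]], -1L)
    n <- length(tv)
    for (ci in seq_along(c_seq)) {
      for (strand in c("+", "-")) {
        cs <- if (strand == "+") c_seq[[ci]] else cr_seq[[ci]]
        cv <- to_int(cs, -2L)
        m <- length(cv)
        if (n < min_length || m < min_length) next
        # row-by-row run-length DP along diagonals; run[j] = length of the
        # equality run ending at (row i, column j)
        ends_i <- integer(0); ends_j <- integer(0); ends_l <- integer(0)
        prev <- integer(m)
        for (i in seq_len(n)) {
          e <- as.integer(tv[i] == cv)
          cur <- e
          if (m > 1) cur[2:m] <- (prev[1:(m - 1)] + 1L) * e[2:m]
          # a run ending at (i-1, j) is maximal unless it extends to (i, j+1)
          if (i > 1) {
            cand <- which(prev >= min_length)
            if (length(cand) > 0) {
              extends <- cand < m & c(cur[-1], 0L)[cand] == prev[cand] + 1L
              keep <- cand[!extends]
              if (length(keep) > 0) {
                ends_i <- c(ends_i, rep(i - 1L, length(keep)))
                ends_j <- c(ends_j, keep)
                ends_l <- c(ends_l, prev[keep])
              }
            }
          }
          prev <- cur
        }
        fin <- which(prev >= min_length)
        if (length(fin) > 0) {
          ends_i <- c(ends_i, rep(n, length(fin)))
          ends_j <- c(ends_j, fin)
          ends_l <- c(ends_l, prev[fin])
        }
        if (length(ends_i) == 0) next
        for (e in seq_along(ends_i)) {
          i <- ends_i[e]; j <- ends_j[e]
          l <- ends_l[e]
          ts0 <- i - l      # 0-based start on target
          cs0 <- j - l      # 0-based start on this strand's sequence
          s <- substr(t_seq[[ti]], ts0 + 1, ts0 + l)
          if (count_occ(s, t_text) != 1L) next
          if (uniqueness == "both" && count_occ(s, c_text) != 1L) next
          qstart <- if (strand == "+") cs0 else nchar(c_seq[[ci]]) - cs0 - l
          acc$ref_id <- c(acc$ref_id, names(t_seq)[ti])
          acc$ref_len <- c(acc$ref_len, n)
          acc$ref_start <- c(acc$ref_start, as.integer(ts0))
          acc$qry_id <- c(acc$qry_id, names(c_seq)[ci])
          acc$qry_len <- c(acc$qry_len, nchar(c_seq[[ci]]))
          acc$qry_start <- c(acc$qry_start, as.integer(qstart))
          acc$length <- c(acc$length, as.integer(l))
          acc$strand <- c(acc$strand, strand)
        }
      }
    }
  }
  if (length(acc$ref_id) == 0) return(empty_matches())
  m <- tibble(ref_id = acc$ref_id, ref_len = acc$ref_len,
              ref_start = acc$ref_start, ref_end = acc$ref_start + acc$length,
              qry_id = acc$qry_id, qry_len = acc$qry_len,
              qry_start = acc$qry_start, qry_end = acc$qry_start + acc$length,
              length = acc$length, strand = acc$strand)
  as_tibble(arrange_matches(m, names(t_seq), names(c_seq)))
}

#' Write / read a match table as PAF-like TSV
#'
#' Columns: `qry_id`, `qry_len`, `qry_start`, `qry_end`, `strand`, `ref_id`,
#' `ref_len`, `ref_start`, `ref_end`, `match_length`; 0-based half-open
#' coordinates.
#'
#' @param matches A match tibble from [find_mums()].
#' @param path Output (input) path.
#' @return `path` invisibly; `read_matches()` returns a match tibble.
#' @export
write_matches <- function(matches, path) {
  out <- matches[, c("qry_id", "qry_len", "qry_start", "qry_end", "strand",
                     "ref_id", "ref_len", "ref_start", "ref_end", "length")]
  names(out)[names(out) == "length"] <- "match_length"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("qry_id", "qry_len", "qry_start", "qry_end", "strand",
            "ref_id", "ref_len", "ref_start", "ref_end", "match_length")
  if (!all(need %in% names(raw))) {
    abort(paste0("not a match TSV (missing columns): ", path))
  }
  tibble(ref_id = as.character(raw$ref_id), ref_len = as.integer(raw$ref_len),
         ref_start = as.integer(raw$ref_start), ref_end = as.integer(raw$ref_end),
         qry_id = as.character(raw$qry_id), qry_len = as.integer(raw$qry_len),
         qry_start = as.integer(raw$qry_start), qry_end = as.integer(raw$qry_end),
         length = as.integer(raw$match_length), strand = as.character(raw$strand))
}
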