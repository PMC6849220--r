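# One-to-one filtering of a raw MUM set: no retained match may overlap
# another retained match on the target axis or on the candidate axis, and
# matches sharing (ref_id, qry_id, strand) must be mutually collinear
# (consistently ordered, non-crossing). Weight is matched bases.
#
# Small inputs (<= exact_limit matches) are solved exactly by branch-and-bound
# over the pairwise conflict graph; larger inputs use per-group maximum-weight
# collinear chaining followed by greedy cross-chain overlap resolution in
# descending chain weight. Both paths are deterministic.

match_canonical_order <- function(m) {
  order(m$ref_id, m$ref_start, m$qry_id, m$qry_start, m$strand)
}

# pairwise conflict matrix: overlap on either axis, or same-group crossing
conflict_matrix <- function(m) {
  n <- nrow(m)
  same_ref <- outer(m$ref_id, m$ref_id, "==")
  same_qry <- outer(m$qry_id, m$qry_id, "==")
  ov_ref <- same_ref &
    outer(m$ref_start, m$ref_end, "<") & outer(m$ref_end, m$ref_start, ">")
  ov_qry <- same_qry &
    outer(m$qry_start, m$qry_end, "<") & outer(m$qry_end, m$qry_start, ">")
  same_grp <- same_ref & same_qry & outer(m$strand, m$strand, "==")
  ref_before <- outer(m$ref_start, m$ref_start, "<")
  qry_before <- outer(m$qry_start, m$qry_start, "<")
  plus <- m$strand == "+"
  cross <- same_grp & !ov_ref & !ov_qry &
    ((outer(plus, plus, "&") & (ref_before != qry_before)) |
     (outer(!plus, !plus, "&") & (ref_before == qry_before)))
  conf <- ov_ref | ov_qry | cross
  diag(conf) <- FALSE
  conf
}

# exact maximum-weight one-to-one-feasible subset (branch and bound);
# m must be in canonical order. Ties resolve toward retaining the earliest
# matches in canonical order.
exact_one_to_one <- function(m) {
  n <- nrow(m)
  w <- as.numeric(m$length)
  conf <- conflict_matrix(m)
  suffix <- rev(cumsum(rev(w)))
  best <- new.env()
  best$w <- -1
  best$sel <- integer(0)
  recurse <- function(i, sel, cur, blocked) {
    if (i > n) {
      if (cur > best$w) {
        best$w <- cur
        best$sel <- sel
      }
      return(invisible(NULL))
    }
    if (cur + suffix[i] <= best$w) return(invisible(NULL))
    if (!blocked[i]) {
      recurse(i + 1L, c(sel, i), cur + w[i], blocked | conf[i, ])
    }
    recurse(i + 1L, sel, cur, blocked)
    invisible(NULL)
  }
  recurse(1L, integer(0), 0, rep(FALSE, n))
  m[sort(best$sel), , drop = FALSE]
}

# greedy heuristic: best chain per (ref_id, qry_id, strand) group, then keep
# chain matches in descending chain weight unless they overlap kept intervals
heuristic_one_to_one <- function(m) {
  groups <- split(seq_len(nrow(m)),
                  paste(m$ref_id, m$qry_id, m$strand, sep = "\r"),
                  drop = TRUE)
  chains <- lapply(groups, function(idx) {
    g <- m[idx, , drop = FALSE]
    ch <- chain_group(g)
    ch
  })
  wts <- vapply(chains, function(ch) attr(ch, "weight"), numeric(1))
  key <- vapply(chains, function(ch) {
    paste(ch$ref_id[1], ch$qry_id[1], ch$strand[1],
          sprintf("%012d", ch$ref_start[1]))
  }, character(1))
  ord <- order(-wts, key)
  kept <- m[0, , drop = FALSE]
  for (ci in ord) {
    ch <- chains[[ci]]
    for (r in seq_len(nrow(ch))) {
      row <- ch[r, , drop = FALSE]
      same_r <- kept$ref_id == row$ref_id
      same_q <- kept$qry_id == row$qry_id
      clash <- any(same_r & kept$ref_start < row$ref_end &
                     kept$ref_end > row$ref_start) ||
               any(same_q & kept$qry_start < row$qry_end &
                     kept$qry_end > row$qry_start)
      if (!clash) kept <- bind_rows(kept, row)
    }
  }
  kept[match_canonical_order(kept), , drop = FALSE]
}

#' Reduce a raw MUM set to a one-to-one consistent subset
#'
#' Returns a subset of `matches` in which no retained match overlaps another
#' on the target axis or on the candidate axis, and matches of one
#' (`ref_id`, `qry_id`, `strand`) group are mutually collinear. The retained
#' subset maximizes total matched bases exactly for inputs of up to
#' `exact_limit` matches (branch-and-bound over the conflict graph); larger
#' inputs are resolved by per-group maximum-weight collinear chaining followed
#' by greedy cross-chain overlap resolution in descending chain weight.
#' Deterministic, idempotent.
#'
#' @param matches A match tibble ([find_mums()]).
#' @param exact_limit Largest input size solved exactly (default 20).
#' @return A match tibble (subset of the input rows, canonical order).
#' @export
filter_one_to_one <- function(matches, exact_limit = 20L) {
  stopifnot(is.data.frame(matches))
  for (col in c("pair", "target", "candidate")) {
    if (col %in% names(matches) && length(unique(matches[[col]])) > 1) {
      abort("filter_one_to_one: matches from more than one genome pair")
    }
  }
  if (nrow(matches) == 0) return(as_tibble(matches))
  m <- matches[match_canonical_order(matches), , drop = FALSE]
  out <- if (nrow(m) <= exact_limit) exact_one_to_one(m) else
    heuristic_one_to_one(m)
  as_tibble(out)
}

#' Maximum-weight collinear chain of one match group
#'
#' All matches must share `ref_id`, `qry_id` and `strand`. Returns the chain
#' (ordered subset, strictly increasing on the reference axis; query axis
#' increasing for `+`, decreasing for `-`; no overlap on either axis) that
#' maximizes total matched bases. Among equal-weight optima the chain whose
#' first match has the smallest `ref_start` (then `qry_start`) is returned.
#'
#' @param matches Match tibble rows sharing `ref_id`, `qry_id`, `strand`.
#' @return The chained match tibble, in chain order, with the total matched
#'   bases in `attr(, "weight")`.
#' @export
chain_group <- function(matches) {
  stopifnot(is.data.frame(matches), nrow(matches) > 0)
  if (length(unique(matches$ref_id)) > 1 || length(unique(matches$qry_id)) > 1 ||
      length(unique(matches$strand)) > 1) {
    abort("chain_group: matches must share ref_id, qry_id and strand")
  }
  g <- matches[order(matches$ref_start, matches$qry_start), , drop = FALSE]
  sel <- .chain_core(g$ref_start, g$ref_end, g$qry_start, g$qry_end,
                     as.numeric(g$length), g$strand[1] == "-")
  out <- g[sel, , drop = FALSE]
  attr(out, "weight") <- sum(out$length)
  out
}
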