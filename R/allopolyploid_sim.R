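# Synthetic allotetraploid scenario generator.
#
# A random ancestor genome is evolved along independent lineages (a star
# phylogeny) to produce a candidate panel at controlled divergences; the
# target is built by concatenating the two designated progenitor lineages'
# genomes, each further evolved after hybridization. Ground truth (the true
# progenitor pair) is carried alongside, which is what makes the whole
# ancestry pipeline testable without any external data.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

#' Simulate a random ancestor genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split into `n_chromosomes` records of
#' near-equal length (earlier records take the remainder bases).
#'
#' @param length Total genome length in bases.
#' @param n_chromosomes Number of records.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed (bit-reproducible); `NULL` uses the current RNG
#'   state.
#' @return A genome (`DNAStringSet`) with records `chr1..chrK`.
#' @export
simulate_ancestor <- function(length, n_chromosomes = 1L, gc = 0.5,
                              seed = NULL) {
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  if (length < n_chromosomes || n_chromosomes < 1) {
    abort("need length >= n_chromosomes >= 1")
  }
  length <- as.integer(length)
  n_chromosomes <- as.integer(n_chromosomes)
  with_seed_if(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    base_len <- length %/% n_chromosomes
    extra <- length %% n_chromosomes
    lens <- rep(base_len, n_chromosomes) + c(rep(1L, extra),
                                             rep(0L, n_chromosomes - extra))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- vapply(seq_len(n_chromosomes), function(i) {
      paste(bases[starts[i]:ends[i]], collapse = "")
    }, character(1))
    as_genome(setNames(seqs, paste0("chr", seq_len(n_chromosomes))))
  })
}

# mutate a single record's character vector: substitutions then indels
mutate_record <- function(chars, sub_rate, indel_rate, indel_max) {
  n <- length(chars)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit) > 0) {
      alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                      "A", "C", "G"), nrow = 4, byrow = TRUE,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pick <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- alt[cbind(match(chars[hit], rownames(alt)), pick)]
    }
  }
  if (indel_rate > 0) {
    n_events <- rbinom(1L, n, indel_rate)
    if (n_events > 0) {
      pos <- sort(sample.int(n, n_events), decreasing = TRUE)
      sizes <- sample.int(indel_max, n_events, replace = TRUE)
      is_ins <- runif(n_events) < 0.5
      for (e in seq_len(n_events)) {
        p <- pos[e]
        if (is_ins[e]) {
          ins <- sample(c("A", "C", "G", "T"), sizes[e], replace = TRUE)
          chars <- append(chars, ins, after = p)
        } else {
          del_end <- min(p + sizes[e] - 1L, base::length(chars))
          chars <- chars[-(p:del_end)]
        }
      }
    }
  }
  chars
}

#' Evolve a genome along one lineage
#'
#' Applies, in order: `n_inversions` random non-overlapping segment
#' inversions (segment reverse-complemented in place), substitutions (each
#' site mutated to a different base with probability `sub_rate`), and indels
#' (binomially thinned events, length uniform on `[1, indel_max]`, insertion
#' and deletion equiprobable). Inversion segment lengths are drawn uniformly
#' between 500 and 5000 bases, capped at the record length.
#'
#' @param genome A genome ([as_genome()]).
#' @param sub_rate Substitutions per site in `[0, 1)`.
#' @param indel_rate Indel events per site in `[0, 1)`.
#' @param indel_max Maximum indel length (bases, >= 1).
#' @param n_inversions Number of inversions across the genome.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The evolved genome (`DNAStringSet`, same record ids).
#' @export
evolve_genome <- function(genome, sub_rate, indel_rate = 0, indel_max = 1L,
                          n_inversions = 0L, seed = NULL) {
  genome <- as_genome(genome)
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    abort("rates must be in [0, 1)")
  }
  if (indel_max < 1) abort("indel_max must be >= 1")
  seqs <- as.character(genome)
  with_seed_if(seed, {
    chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    widths <- vapply(chars, base::length, integer(1))
    if (n_inversions > 0) {
      taken <- lapply(chars, function(x) integer(0))
      for (v in seq_len(n_inversions)) {
        rec <- sample.int(base::length(chars), 1L, prob = widths)
        w <- widths[rec]
        size <- min(w, sample(500:5000, 1L))
        for (try in 1:50) {
          s0 <- sample.int(w - size + 1L, 1L)
          span <- s0:(s0 + size - 1L)
          if (!any(span %in% taken[[rec]])) {
            seg <- paste(chars[[rec]][span], collapse = "")
            inv <- strsplit(reverse_complement(seg), "", fixed = TRUE)[[1]]
            chars[[rec]][span] <- inv
            taken[[rec]] <- c(taken[[rec]], span)
            break
          }
        }
      }
    }
    chars <- lapply(chars, mutate_record, sub_rate = sub_rate,
                    indel_rate = indel_rate, indel_max = as.integer(indel_max))
    out <- vapply(chars, paste, character(1), collapse = "")
    as_genome(setNames(out, names(genome)))
  })
}

#' Default synthetic allotetraploid scenario configuration
#'
#' The desk-scale study conditions: a 200 kb ancestor in 2 chromosomes at
#' GC 0.36, a panel of six lineages with divergences spanning 0.03-0.20
#' substitutions/site (both progenitors at 0.05; the nearest non-progenitor
#' decoy at 1.5x that), post-hybridization divergence 0.02 per subgenome,
#' light indels, and two inversions per lineage.
#'
#' @param ancestor_length,n_chromosomes,gc Ancestor genome parameters.
#' @param panel Named numeric vector: candidate name -> divergence
#'   (substitutions/site from the ancestor), all in `[0, 0.5)`.
#' @param progenitors Two distinct panel names contributing the subgenomes.
#' @param post_hybrid_divergence Substitutions/site applied to each subgenome
#'   after hybridization.
#' @param indel_rate,indel_max,n_inversions Lineage evolution parameters.
#' @param seed Integer master seed.
#' @return A named list understood by [make_scenario()].
#' @export
scenario_config <- function(ancestor_length = 200000L, n_chromosomes = 2L,
                            gc = 0.36,
                            panel = c(prog_a = 0.05, prog_b = 0.05,
                                      sister = 0.03, near_decoy = 0.075,
                                      mid_decoy = 0.12, far_decoy = 0.20),
                            progenitors = c("prog_a", "prog_b"),
                            post_hybrid_divergence = 0.02,
                            indel_rate = 5e-4, indel_max = 10L,
                            n_inversions = 2L, seed = 1L) {
  cfg <- list(ancestor_length = as.integer(ancestor_length),
              n_chromosomes = as.integer(n_chromosomes), gc = gc,
              panel = panel, progenitors = progenitors,
              post_hybrid_divergence = post_hybrid_divergence,
              indel_rate = indel_rate, indel_max = as.integer(indel_max),
              n_inversions = as.integer(n_inversions), seed = as.integer(seed))
  if (is.null(names(cfg$panel)) || anyDuplicated(names(cfg$panel))) {
    abort("panel must be a named vector with unique candidate names")
  }
  if (any(cfg$panel < 0 | cfg$panel >= 0.5)) {
    abort("panel divergences must be in [0, 0.5)")
  }
  if (length(cfg$progenitors) != 2 || anyDuplicated(cfg$progenitors)) {
    abort("progenitors must be two distinct names")
  }
  if (!all(cfg$progenitors %in% names(cfg$panel))) {
    abort("progenitor name not in panel")
  }
  cfg
}

#' Build a synthetic allotetraploid scenario with known truth
#'
#' Simulates the ancestor, evolves every panel lineage to its divergence,
#' builds the allotetraploid target as the concatenation of the two
#' progenitor lineages' genomes each further evolved by
#' `post_hybrid_divergence` (records renamed `subgenomeA_*` / `subgenomeB_*`),
#' and returns the candidates (the panel genomes, without the post-hybrid
#' mutations) plus the true pair. Bit-reproducible for a fixed config.
#'
#' @param cfg A configuration from [scenario_config()].
#' @return A list: `target` (genome), `candidates` (named list of genomes),
#'   `true_pair` (character 2-vector), `config`.
#' @export
make_scenario <- function(cfg = scenario_config()) {
  cfg <- do.call(scenario_config, cfg)   # re-validate
  n_lineages <- length(cfg$panel)
  seeds <- withr::with_seed(cfg$seed, {
    sample.int(.Machine$integer.max - 1L, 2L * n_lineages + 3L)
  })
  ancestor <- simulate_ancestor(cfg$ancestor_length, cfg$n_chromosomes,
                                cfg$gc, seed = seeds[1])
  candidates <- vector("list", n_lineages)
  names(candidates) <- names(cfg$panel)
  for (i in seq_len(n_lineages)) {
    candidates[[i]] <- evolve_genome(ancestor, sub_rate = cfg$panel[[i]],
                                     indel_rate = cfg$indel_rate,
                                     indel_max = cfg$indel_max,
                                     n_inversions = cfg$n_inversions,
                                     seed = seeds[1 + i])
  }
  sub_labels <- c("subgenomeA", "subgenomeB")
  subgenomes <- vector("list", 2)
  for (s in 1:2) {
    prog <- candidates[[cfg$progenitors[s]]]
    evolved <- evolve_genome(prog, sub_rate = cfg$post_hybrid_divergence,
                             indel_rate = cfg$indel_rate,
                             indel_max = cfg$indel_max,
                             n_inversions = cfg$n_inversions,
                             seed = seeds[1 + n_lineages + s])
    seqs <- as.character(evolved)
    names(seqs) <- paste0(sub_labels[s], "_", names(seqs))
    subgenomes[[s]] <- seqs
  }
  target <- as_genome(c(subgenomes[[1]], subgenomes[[2]]))
  list(target = target, candidates = candidates,
       true_pair = sort(cfg$progenitors), config = cfg)
}

#' Simulate uniform single-end shotgun reads
#'
#' `round(depth * genome_length / read_length)` reads placed uniformly on the
#' forward strand (records weighted by the number of valid start positions);
#' each base is flipped to a random different base with probability
#' `error_rate`. Quality strings are constant `"I"`.
#'
#' @param genome A genome ([as_genome()]).
#' @param depth Fold coverage (> 0).
#' @param read_length Read length in bases (must fit the shortest record).
#' @param error_rate Per-base error probability.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A read tibble (`id`, `seq`, `qual`).
#' @export
simulate_reads <- function(genome, depth, read_length = 100L, error_rate = 0,
                           seed = NULL) {
  genome <- as_genome(genome)
  widths <- Biostrings::width(genome)
  if (depth <= 0) abort("depth must be > 0")
  if (read_length > min(widths)) {
    abort("read_length exceeds the shortest genome record")
  }
  read_length <- as.integer(read_length)
  total <- sum(as.numeric(widths))
  n_reads <- as.integer(round(depth * total / read_length))
  seqs <- as.character(genome)
  with_seed_if(seed, {
    slots <- widths - read_length + 1L
    rec <- sample.int(length(seqs), n_reads, replace = TRUE, prob = slots)
    start <- floor(runif(n_reads) * slots[rec]) + 1L
    out <- character(n_reads)
    for (ri in seq_along(seqs)) {
      sel <- rec == ri
      if (any(sel)) {
        out[sel] <- substring(seqs[ri], start[sel],
                              start[sel] + read_length - 1L)
      }
    }
    if (error_rate > 0) {
      n_err <- rbinom(1L, n_reads * read_length, error_rate)
      if (n_err > 0) {
        flat <- sample.int(n_reads * read_length, n_err)
        r_idx <- ((flat - 1L) %/% read_length) + 1L
        p_idx <- ((flat - 1L) %% read_length) + 1L
        cur <- substr(out[r_idx], p_idx, p_idx)
        alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                        "A", "C", "G"), nrow = 4, byrow = TRUE,
                      dimnames = list(c("A", "C", "G", "T"), NULL))
        new <- alt[cbind(match(cur, rownames(alt)),
                         sample.int(3L, n_err, replace = TRUE))]
        for (e in seq_len(n_err)) {
          substr(out[r_idx[e]], p_idx[e], p_idx[e]) <- new[e]
        }
      }
    }
    tibble(id = sprintf("read%07d", seq_len(n_reads)), seq = out,
           qual = strrep("I", read_length))
  })
}
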