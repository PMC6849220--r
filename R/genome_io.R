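# Sequence I/O and the in-memory genome model.
#
# A "genome" is a named Biostrings::DNAStringSet (record ids as names, optional
# free-text descriptions in an attribute); every derived result in the package
# is a tibble. Coordinates are 0-based half-open throughout.

VALID_BASES <- c("A", "C", "G", "T", "N")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Coerce to a validated genome
#'
#' Accepts a named character vector or a `DNAStringSet` and returns a
#' validated `DNAStringSet`: non-empty records, unique ids, alphabet
#' `{A,C,G,T,N}` (uppercase).
#'
#' @param x Named character vector of sequences, or a `DNAStringSet`.
#' @return A `DNAStringSet` with unique names.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- names(x)
    x <- seqs
  }
  if (!is.character(x)) {
    abort("a genome must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(x)) || any(names(x) == "") || anyNA(names(x))) {
    abort("every genome record needs a non-empty id")
  }
  if (anyDuplicated(names(x))) {
    dup <- unique(names(x)[duplicated(names(x))])
    abort(paste0("duplicate record id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(nchar(x) == 0L)) abort("genome records must have non-empty sequences")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(paste0("record(s) with characters outside {A,C,G,T,N}: ",
                 paste(names(x)[bad], collapse = ", "),
                 " (use read_genome() to normalize raw input)"))
  }
  Biostrings::DNAStringSet(x)
}

#' Total genome length in bases
#' @param genome A genome ([as_genome()]).
#' @return Integer total length.
#' @export
genome_length <- function(genome) {
  genome <- as_genome(genome)
  sum(Biostrings::width(genome))
}

# Uppercase, map U->T, collapse IUPAC ambiguity codes (and any other residual
# character) to N with one warning; error when any record is >50% invalid.
normalize_sequences <- function(seqs, ids) {
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  n_invalid <- nchar(gsub(paste0("[ACGTN", paste(IUPAC_AMBIG, collapse = ""), "]"),
                          "", seqs))
  frac_invalid <- n_invalid / nchar(seqs)
  if (any(nchar(seqs) > 0 & frac_invalid > 0.5)) {
    bad <- ids[nchar(seqs) > 0 & frac_invalid > 0.5]
    abort(paste0("record(s) do not look like nucleotide sequences ",
                 "(>50% invalid characters): ", paste(bad, collapse = ", ")))
  }
  n_mapped <- nchar(gsub("[ACGTN]", "", seqs))
  if (sum(n_mapped) > 0) {
    warn(paste0(sum(n_mapped), " non-ACGTN character(s) mapped to N across ",
                sum(n_mapped > 0), " record(s)"))
    seqs <- vapply(seqs, function(s) {
      gsub("[^ACGTN]", "N", s)
    }, character(1), USE.NAMES = FALSE)
  }
  seqs
}

#' Read a FASTA genome
#'
#' Parses a (possibly multi-line, CRLF-tolerant) FASTA file into a genome.
#' Sequences are normalized: lowercase is uppercased, `U` becomes `T`, and any
#' other IUPAC/unknown character collapses to `N` with a warning. A record
#' with more than 50% invalid characters, a duplicate id, or an empty file is
#' an error.
#'
#' @param path Path to a FASTA file (transparently gunzipped if `.gz`).
#' @return A `DNAStringSet`; record descriptions (text after the first
#'   whitespace in the header) are kept in `attr(, "descriptions")`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("cannot parse FASTA '", path,
                                                   "': ", conditionMessage(e))))
  if (length(raw) == 0) abort(paste0("no sequences in ", path))
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate record id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  seqs <- gsub("[ \r]", "", as.character(raw))
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  seqs <- normalize_sequences(seqs, ids)
  g <- as_genome(setNames(seqs, ids))
  attr(g, "descriptions") <- setNames(desc, ids)
  g
}

#' Write a genome as FASTA
#'
#' @param genome A genome ([as_genome()]).
#' @param path Output path.
#' @param line_width Sequence line wrap width (positive integer).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, line_width = 60L) {
  genome <- as_genome(genome)
  if (!is.numeric(line_width) || line_width < 1) {
    abort("line_width must be a positive integer")
  }
  desc <- attr(genome, "descriptions")
  if (!is.null(desc)) {
    has <- !is.na(desc[names(genome)]) & desc[names(genome)] != ""
    names(genome)[has] <- paste(names(genome)[has], desc[names(genome)][has])
  }
  tryCatch(Biostrings::writeXStringSet(genome, path, width = as.integer(line_width)),
           error = function(e) abort(paste0("cannot write FASTA '", path, "': ",
                                            conditionMessage(e))))
  invisible(path)
}

#' Read sequencing reads (FASTQ or FASTA)
#'
#' The format is auto-detected from the first non-empty character (`@` FASTQ,
#' `>` FASTA). FASTA input yields reads without quality strings. Sequences are
#' normalized as in [read_genome()].
#'
#' @param path Path to a FASTQ/FASTA file.
#' @return A tibble with columns `id`, `seq`, and `qual` (`NA` for FASTA).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- file(path, "r")
  on.exit(close(con))
  first <- ""
  while (length(line <- readLines(con, n = 1L)) == 1L) {
    if (nzchar(trimws(line))) {
      first <- substr(trimws(line), 1, 1)
      break
    }
  }
  if (first == ">") {
    g <- read_genome(path)
    return(tibble(id = names(g), seq = unname(as.character(g)),
                  qual = NA_character_))
  }
  if (first != "@") abort(paste0("cannot detect FASTQ/FASTA format of ", path))
  lines <- c(line, readLines(con))
  lines <- sub("\r$", "", lines)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4 != 0) {
    abort(paste0("truncated FASTQ record at end of ", path))
  }
  i <- seq(1, length(lines), by = 4)
  ids <- sub("\\s.*$", "", sub("^@", "", lines[i]))
  seqs <- normalize_sequences(lines[i + 1], ids)
  quals <- lines[i + 3]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    abort(paste0("FASTQ record(s) with mismatched sequence/quality lengths: ",
                 paste(head(ids[bad], 5), collapse = ", ")))
  }
  tibble(id = ids, seq = seqs, qual = quals)
}

#' Write reads as FASTQ (or FASTA when no qualities are present)
#'
#' @param reads Tibble with columns `id`, `seq`, and optionally `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  has_qual <- "qual" %in% names(reads) && !anyNA(reads$qual)
  if (has_qual) {
    if (any(nchar(reads$seq) != nchar(reads$qual))) {
      abort("sequence/quality length mismatch")
    }
    out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  } else {
    out <- as.vector(rbind(paste0(">", reads$id), reads$seq))
  }
  writeLines(out, path)
  invisible(path)
}
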