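#' @importFrom methods as is
NULL

.ALPHABETS <- list(
  nucleotide = c("A", "C", "G", "T", "N"),
  protein    = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*"),
  ss3        = c("H", "E", "C")
)

#' Build a set of sequence records
#'
#' Records are kept as a plain data.frame with columns \code{id},
#' \code{desc} and \code{seq}; the declared alphabet is carried as an
#' attribute and enforced (case-insensitive input, stored upper case).
#'
#' @param id character vector of identifiers (no whitespace, non-empty).
#' @param seq character vector of sequences.
#' @param desc optional descriptions (the remainder of a FASTA header).
#' @param alphabet one of \code{"nucleotide"}, \code{"protein"}, \code{"ss3"}.
#' @return data.frame of class \code{seq_records}.
#' @export
seq_records <- function(id, seq, desc = "", alphabet = "nucleotide") {
  alphabet <- match.arg(alphabet, names(.ALPHABETS))
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("id and seq must have equal length")
  desc <- rep_len(as.character(desc), length(id))
  if (length(id)) {
    if (any(!nzchar(id)) || any(grepl("\\s", id)))
      stop("sequence ids must be non-empty and contain no whitespace")
    if (anyDuplicated(id))
      stop("duplicate sequence id: ", id[duplicated(id)][1])
    if (any(!nzchar(seq)))
      stop("empty sequence for id: ", id[!nzchar(seq)][1])
    bad <- grepl(sprintf("[^%s]", paste(.ALPHABETS[[alphabet]], collapse = "")),
                 seq, fixed = FALSE)
    # '*' needs escaping inside a class only when first; build class safely
    if (alphabet == "protein") {
      bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", seq)
    }
    if (any(bad))
      stop(sprintf("sequence '%s' contains characters outside the %s alphabet",
                   id[bad][1], alphabet))
  }
  out <- data.frame(id = id, desc = desc, seq = seq,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file into sequence records
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @param alphabet declared alphabet, enforced on read.
#' @return \code{\link{seq_records}} in file order; empty file gives zero rows.
#' @export
read_fasta <- function(path, alphabet = "nucleotide") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(seq_records(character(), character(), alphabet = alphabet))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seq_records(ids, as.character(set), descs, alphabet = alphabet)
}

#' Write sequence records to FASTA
#'
#' @param records \code{\link{seq_records}}.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste(records$id[i], records$desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param seq character vector of nucleotide strings (A/C/G/T/N).
#' @return reverse-complemented strings.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Translate a CDS nucleotide sequence
#'
#' Standard genetic code. A single terminal stop codon is trimmed from the
#' protein string; an internal stop does not abort the translation but is
#' flagged so callers can treat the model as broken.
#'
#' @param seq one nucleotide string, length a multiple of 3.
#' @return list with \code{protein} (string, terminal stop trimmed) and
#'   \code{internal_stop} (logical).
#' @export
translate_cds <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0)
    stop("CDS length ", nchar(seq), " is not a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                           if.fuzzy.codon = "X"))
  n <- nchar(aa)
  trimmed <- if (n > 0 && substr(aa, n, n) == "*") substr(aa, 1, n - 1) else aa
  list(protein = trimmed,
       internal_stop = grepl("*", trimmed, fixed = TRUE))
}

#' GC fraction of nucleotide strings, ignoring ambiguous bases
#'
#' N bases are excluded from both numerator and denominator, the common
#' convention for assembly statistics.
#'
#' @param seq character vector of nucleotide strings.
#' @return numeric vector of GC fractions (NA where no unambiguous base).
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    freq <- Biostrings::alphabetFrequency(Biostrings::DNAString(toupper(s)))
    acgt <- sum(freq[c("A", "C", "G", "T")])
    if (acgt == 0) return(NA_real_)
    sum(freq[c("G", "C")]) / acgt
  }, numeric(1), USE.NAMES = FALSE)
}
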