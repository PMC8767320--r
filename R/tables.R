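.HIT_COLS <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

#' Write a TSV with a commented header line
#'
#' All tabular pipeline outputs share this shape: a single header line
#' starting with \code{#} naming the columns, then tab-separated rows.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsvc <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsvc}}
#'
#' @param path input path.
#' @param col_names expected column names; if NULL they are taken from the
#'   commented header.
#' @return data.frame.
#' @export
read_tsvc <- function(path, col_names = NULL) {
  first <- readLines(path, n = 1L)
  header <- NULL
  if (length(first) && startsWith(first, "#"))
    header <- strsplit(sub("^#\\s*", "", first), "\t")[[1L]]
  if (is.null(col_names)) col_names <- header
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE,
                          col.names = col_names, quote = "")
  df
}

#' Read a 12-column tabular homology hit table
#'
#' The de-facto tabular alignment format: query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject start/end,
#' e-value, bitscore. Accepts files with or without a commented header.
#'
#' @param path TSV path.
#' @return data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- .HIT_COLS
    return(hit_table(out))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("hit table ", path, ": line ", which(nf != 12L)[1L],
         " has ", nf[nf != 12L][1L], " fields (expected 12)")
  m <- do.call(rbind, parts)
  out <- data.frame(
    query = m[, 1L], subject = m[, 2L],
    pct_identity = as.numeric(m[, 3L]), aln_len = as.integer(m[, 4L]),
    mismatches = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$evalue) | is.na(out$pct_identity))
  if (length(bad))
    stop("hit table ", path, ": line ", bad[1L], " is malformed")
  hit_table(out)
}

#' Validate a hit table
#'
#' @param df data.frame with the 12 standard columns.
#' @return the validated data.frame.
#' @export
hit_table <- function(df) {
  miss <- setdiff(.HIT_COLS, names(df))
  if (length(miss)) stop("hit table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$evalue < 0)) stop("hit table: negative e-value")
    if (any(df$pct_identity < 0 | df$pct_identity > 100))
      stop("hit table: pct_identity outside [0, 100]")
  }
  df[.HIT_COLS]
}

#' Write a 12-column hit table
#' @param hits hit table data.frame.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  write_tsvc(hit_table(hits), path)
}

#' Read a predictor score table (protein_id, tool, probability)
#' @param path TSV path.
#' @return data.frame; probabilities validated to [0, 1].
#' @export
read_scores <- function(path) {
  df <- read_tsvc(path, c("protein_id", "tool", "probability"))
  df$probability <- as.numeric(df$probability)
  if (any(is.na(df$probability) | df$probability < 0 | df$probability > 1))
    stop("score table ", path, ": probabilities must lie in [0, 1]")
  df
}

#' Read a TMD interval table (protein_id, start, end, source)
#' @param path TSV path.
#' @return data.frame of predicted transmembrane segments.
#' @export
read_tmd <- function(path) {
  df <- read_tsvc(path, c("protein_id", "start", "end", "source"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 1L | df$end < df$start))
    stop("TMD table ", path, ": intervals must satisfy 1 <= start <= end")
  df
}

#' Read a transcript-read alignment table
#'
#' Columns: read_id, gene_tag, aln_start, aln_end (genomic span of the
#' alignment), polya_boundary (genomic coordinate where the read meets the
#' oligo-dT primer) and full_length (0/1 as classified by the read
#' preprocessor).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_reads <- function(path) {
  df <- read_tsvc(path, c("read_id", "gene_tag", "aln_start", "aln_end",
                          "polya_boundary", "full_length"))
  for (cn in c("aln_start", "aln_end", "polya_boundary"))
    df[[cn]] <- as.integer(df[[cn]])
  df$full_length <- as.logical(as.integer(df$full_length))
  df
}
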