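#' Gene model feature table
#'
#' Gene models are held as a long-format data.frame with one row per
#' feature interval: columns \code{locus_tag}, \code{contig}, \code{strand}
#' (\code{+}/\code{-}), \code{type} (\code{exon}, \code{CDS},
#' \code{five_prime_UTR}, \code{three_prime_UTR}), \code{start}, \code{end}
#' (1-based, closed, GFF3 convention) and an optional logical
#' \code{complete} column (default TRUE) marking models whose CDS must be a
#' multiple of 3.
#'
#' Invariants enforced: exons per model are sorted and separated by gaps of
#' at least 1 bp (introns have positive length); CDS and UTR bases are a
#' subset of exon bases; complete models have CDS length divisible by 3.
#'
#' @param features data.frame as described above.
#' @param validate run the invariant checks.
#' @return the feature table with class \code{gene_models}.
#' @export
gene_models <- function(features, validate = TRUE) {
  need <- c("locus_tag", "contig", "strand", "type", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!"complete" %in% names(features))
    features$complete <- rep(TRUE, nrow(features))
  features <- features[order(features$locus_tag, features$start,
                             features$end), , drop = FALSE]
  rownames(features) <- NULL
  class(features) <- c("gene_models", "data.frame")
  if (validate) validate_gene_models(features)
  features
}

#' @rdname gene_models
#' @param models a \code{gene_models} table.
#' @export
validate_gene_models <- function(models) {
  if (any(models$start < 1L) || any(models$end < models$start))
    stop("intervals must satisfy 1 <= start <= end")
  if (!all(models$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad_type <- setdiff(unique(models$type),
                      c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
  if (length(bad_type))
    stop("unknown feature type(s): ", paste(bad_type, collapse = ", "))
  for (tag in unique(models$locus_tag)) {
    m <- models[models$locus_tag == tag, ]
    if (length(unique(m$contig)) > 1L || length(unique(m$strand)) > 1L)
      stop("model ", tag, " spans multiple contigs or strands")
    ex <- m[m$type == "exon", ]
    if (!nrow(ex)) stop("model ", tag, " has no exons")
    if (nrow(ex) > 1L) {
      gaps <- ex$start[-1L] - ex$end[-nrow(ex)] - 1L
      if (any(gaps < 1L))
        stop("model ", tag, " has overlapping or abutting exons")
    }
    exr <- IRanges::IRanges(ex$start, ex$end)
    sub <- m[m$type != "exon", ]
    if (nrow(sub)) {
      subr <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
      if (sum(IRanges::width(IRanges::setdiff(subr, exr))) > 0L)
        stop("model ", tag, ": CDS/UTR bases fall outside exons")
    }
    cds <- m[m$type == "CDS", ]
    if (nrow(cds) && all(m$complete)) {
      if (sum(cds$end - cds$start + 1L) %% 3L != 0L)
        stop("model ", tag, ": complete CDS length not a multiple of 3")
    }
  }
  invisible(models)
}

#' Per-model genomic spans
#'
#' @param models \code{gene_models}.
#' @return data.frame with one row per locus_tag: contig, strand, start, end
#'   (first to last exon base) and cds_len.
#' @export
model_spans <- function(models) {
  ex <- models[models$type == "exon", ]
  cds <- models[models$type == "CDS", ]
  cds_len <- tapply(cds$end - cds$start + 1L, cds$locus_tag, sum)
  tags <- unique(models$locus_tag)
  out <- data.frame(
    locus_tag = tags,
    contig = ex$contig[match(tags, ex$locus_tag)],
    strand = ex$strand[match(tags, ex$locus_tag)],
    start = as.integer(tapply(ex$start, ex$locus_tag, min)[tags]),
    end = as.integer(tapply(ex$end, ex$locus_tag, max)[tags]),
    cds_len = as.integer(ifelse(is.na(cds_len[tags]), 0L, cds_len[tags])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Intron intervals implied by exon gaps
#'
#' @param models \code{gene_models}.
#' @return data.frame locus_tag, contig, strand, start, end for every gap
#'   between consecutive exons.
#' @export
model_introns <- function(models) {
  ex <- models[models$type == "exon", ]
  res <- lapply(split(ex, ex$locus_tag), function(m) {
    if (nrow(m) < 2L) return(NULL)
    data.frame(locus_tag = m$locus_tag[1L], contig = m$contig[1L],
               strand = m$strand[1L],
               start = m$end[-nrow(m)] + 1L, end = m$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(locus_tag = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# For models carrying no explicit UTR features, exon bases flanking the CDS
# span become UTRs: upstream of the CDS in transcript orientation ->
# five_prime_UTR, downstream -> three_prime_UTR.
.infer_utrs <- function(features) {
  out <- list(features)
  for (tag in unique(features$locus_tag)) {
    m <- features[features$locus_tag == tag, ]
    if (any(m$type %in% c("five_prime_UTR", "three_prime_UTR"))) next
    cds <- m[m$type == "CDS", ]
    ex <- m[m$type == "exon", ]
    if (!nrow(cds) || !nrow(ex)) next
    lo <- min(cds$start); hi <- max(cds$end)
    left <- ex[ex$start < lo, ]
    right <- ex[ex$end > hi, ]
    mk <- function(df, clip_lo, clip_hi, type) {
      if (!nrow(df)) return(NULL)
      data.frame(locus_tag = tag, contig = df$contig[1L],
                 strand = df$strand[1L], type = type,
                 start = pmax(df$start, clip_lo),
                 end = pmin(df$end, clip_hi),
                 complete = all(m$complete), stringsAsFactors = FALSE)
    }
    plus <- m$strand[1L] == "+"
    out[[length(out) + 1L]] <- mk(left, 1L, lo - 1L,
                                  if (plus) "five_prime_UTR"
                                  else "three_prime_UTR")
    out[[length(out) + 1L]] <- mk(right, hi + 1L, .Machine$integer.max,
                                  if (plus) "three_prime_UTR"
                                  else "five_prime_UTR")
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features linked
#' by ID/Parent; one model per mRNA, identified by the mRNA ID. Models
#' without explicit UTR features get UTRs inferred from exon bases outside
#' the CDS span (set \code{infer_utrs = FALSE} to keep them as-is).
#'
#' @param path GFF3 file.
#' @param infer_utrs infer missing UTRs from exon minus CDS.
#' @return \code{gene_models} table.
#' @export
read_gff3 <- function(path, infer_utrs = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna <- df[df$type == "mRNA", ]
  known <- c(df$ID[!is.na(df$ID)])
  feats <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR"), ]
  orphan <- setdiff(unique(feats$Parent), known)
  orphan <- orphan[!is.na(orphan)]
  if (length(orphan))
    stop("orphan Parent reference(s) in ", path, ": ",
         paste(orphan, collapse = ", "))
  feats <- feats[feats$Parent %in% mrna$ID, ]
  out <- data.frame(
    locus_tag = feats$Parent,
    contig = as.character(feats$seqnames),
    strand = as.character(feats$strand),
    type = as.character(feats$type),
    start = feats$start,
    end = feats$end,
    stringsAsFactors = FALSE
  )
  if ("complete" %in% names(feats)) {
    out$complete <- !(feats$complete %in% "false")
  } else {
    out$complete <- TRUE
  }
  if (infer_utrs) out <- .infer_utrs(out)
  tryCatch(gene_models(out),
           error = function(e) stop("GFF3 validation error in ", path, ": ",
                                    conditionMessage(e)))
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and sub-features with ID/Parent links and the
#' \code{##gff-version 3} pragma.
#'
#' @param models \code{gene_models}.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  spans <- model_spans(models)
  lines <- character(0)
  esc <- function(x) gsub("([;=&,])", "", x)
  for (i in seq_len(nrow(spans))) {
    tag <- spans$locus_tag[i]
    g <- sprintf("%s\tmxpipe\tgene\t%d\t%d\t.\t%s\t.\tID=%s.gene",
                 spans$contig[i], spans$start[i], spans$end[i],
                 spans$strand[i], esc(tag))
    m <- sprintf("%s\tmxpipe\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s.gene",
                 spans$contig[i], spans$start[i], spans$end[i],
                 spans$strand[i], esc(tag), esc(tag))
    feats <- models[models$locus_tag == tag, ]
    incomplete <- !all(feats$complete)
    phase <- ifelse(feats$type == "CDS", "0", ".")
    f <- sprintf("%s\tmxpipe\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s%s",
                 feats$contig, feats$type, feats$start, feats$end,
                 feats$strand, phase, esc(tag),
                 if (incomplete) ";complete=false" else "")
    lines <- c(lines, g, m, f)
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

.as_genome <- function(genome) {
  if (inherits(genome, "seq_records") || is.data.frame(genome))
    stats::setNames(genome$seq, genome$id)
  else if (is.character(genome) &&
           (length(genome) == 0L || !is.null(names(genome))))
    genome
  else stop("genome must be seq_records or a named character vector")
}

#' Extract spliced CDS sequences
#'
#' CDS pieces are concatenated in ascending genomic order and
#' reverse-complemented for minus-strand models. Terminal stop codons are
#' part of the CDS by convention here.
#'
#' @param genome \code{\link{seq_records}} (nucleotide) or named character.
#' @param models \code{gene_models}.
#' @param tags optionally restrict to these locus tags.
#' @return \code{seq_records} (nucleotide), one record per model, in
#'   \code{tags} order.
#' @export
extract_cds <- function(genome, models, tags = NULL) {
  contigs <- .as_genome(genome)
  cds <- models[models$type == "CDS", ]
  if (is.null(tags)) tags <- unique(cds$locus_tag)
  cds_by_tag <- split(cds, cds$locus_tag)
  strands <- character(length(tags))
  seqs <- vapply(seq_along(tags), function(i) {
    tag <- tags[i]
    m <- cds_by_tag[[tag]]
    if (is.null(m)) stop("model ", tag, " has no CDS")
    ctg <- m$contig[1L]
    if (!ctg %in% names(contigs))
      stop("model ", tag, " references unknown contig ", ctg)
    clen <- nchar(contigs[[ctg]])
    if (any(m$start < 1L) || any(m$end > clen))
      stop("CDS interval of ", tag, " outside bounds of contig ", ctg)
    strands[i] <<- m$strand[1L]
    paste(substring(contigs[[ctg]], m$start, m$end), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  minus <- which(strands == "-")
  if (length(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  seq_records(tags, seqs, alphabet = "nucleotide")
}

#' Extract and translate all CDSs
#'
#' @inheritParams extract_cds
#' @return \code{seq_records} (protein); records with internal stops carry
#'   \code{desc = "internal_stop"}.
#' @export
extract_proteins <- function(genome, models, tags = NULL) {
  nt <- extract_cds(genome, models, tags)
  tr <- lapply(nt$seq, translate_cds)
  seq_records(nt$id,
              vapply(tr, `[[`, character(1), "protein"),
              ifelse(vapply(tr, `[[`, logical(1), "internal_stop"),
                     "internal_stop", ""),
              alphabet = "protein")
}

#' Extract UTR sequences in transcript orientation
#'
#' @inheritParams extract_cds
#' @param kind \code{"three_prime"} or \code{"five_prime"}.
#' @return data.frame gene_tag, kind, seq, length, introns (introns located
#'   within the UTR span), one row per model that has such a UTR. Sequence
#'   is 5'->3' of the transcript.
#' @export
extract_utrs <- function(genome, models, kind = c("three_prime",
                                                  "five_prime")) {
  kind <- match.arg(kind)
  type <- if (kind == "three_prime") "three_prime_UTR" else "five_prime_UTR"
  contigs <- .as_genome(genome)
  utr <- models[models$type == type, ]
  introns <- model_introns(models)
  tags <- unique(utr$locus_tag)
  rows <- lapply(tags, function(tag) {
    m <- utr[utr$locus_tag == tag, ]
    ctg <- m$contig[1L]
    s <- paste(substring(contigs[[ctg]], m$start, m$end), collapse = "")
    if (m$strand[1L] == "-") s <- revcomp(s)
    ints <- introns[introns$locus_tag == tag, ]
    n_int <- if (nrow(ints))
      sum(ints$start >= min(m$start) & ints$end <= max(m$end)) else 0L
    data.frame(gene_tag = tag, kind = kind, seq = s, length = nchar(s),
               introns = n_int, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_tag = character(), kind = character(),
                      seq = character(), length = integer(),
                      introns = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
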