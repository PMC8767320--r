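.check_origin <- function(seqs, origin) {
  if (!length(seqs)) return(stats::setNames(character(0), character(0)))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop(origin, " sequences must be named by tag")
  if (anyDuplicated(names(seqs)))
    stop("duplicate tag within ", origin, " origin: ",
         names(seqs)[duplicated(names(seqs))][1L])
  toupper(seqs)
}

#' Exact sequence clustering across two annotation versions
#'
#' Two sequences co-cluster iff they have equal length and 100% identity
#' (the \code{-s 1 -c 1} regime of greedy length-sorted clustering). Old
#' tags that share a cluster with at least one new sequence are
#' "transferred". Results are independent of input order.
#'
#' @param old_seqs named character vector of CDS sequences (old assembly).
#' @param new_seqs named character vector of CDS sequences (new assembly).
#' @return list: \code{transferred} (old tags), \code{matches} (named list,
#'   old tag -> matching new tags), \code{duplicated} (old tags matching
#'   more than one new copy), \code{clusters} (data.frame cluster, origin,
#'   tag).
#' @export
cluster_exact <- function(old_seqs, new_seqs) {
  old_seqs <- .check_origin(old_seqs, "old")
  new_seqs <- .check_origin(new_seqs, "new")
  all_seq <- c(old_seqs, new_seqs)
  origin <- rep(c("old", "new"), c(length(old_seqs), length(new_seqs)))
  key <- match(all_seq, unique(all_seq))
  clusters <- data.frame(cluster = key, origin = origin,
                         tag = c(names(old_seqs), names(new_seqs)),
                         stringsAsFactors = FALSE)
  matches <- lapply(stats::setNames(names(old_seqs), names(old_seqs)),
                    function(tag) {
    names(new_seqs)[new_seqs == old_seqs[[tag]]]
  })
  matches <- matches[lengths(matches) > 0L]
  list(transferred = names(matches),
       matches = matches,
       duplicated = names(matches)[lengths(matches) > 1L],
       clusters = clusters[order(clusters$cluster, clusters$origin,
                                 clusters$tag), ])
}

#' Global alignment identity
#'
#' Identity of a global alignment under match +1, mismatch 0, gap open -2,
#' gap extend -1; identity = matches / alignment length (gaps included).
#'
#' @param a,b nucleotide or protein strings.
#' @param type \code{"nucleotide"} or \code{"protein"}.
#' @return identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b, type = "nucleotide") {
  if (a == b) return(1.0)
  if (type == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                    baseOnly = FALSE)
    xs <- Biostrings::DNAString(a); ys <- Biostrings::DNAString(b)
  } else {
    letters <- Biostrings::AA_ALPHABET
    mat <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
    diag(mat) <- 1
    xs <- Biostrings::AAString(a); ys <- Biostrings::AAString(b)
  }
  aln <- Biostrings::pairwiseAlignment(xs, ys, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Near-identity clustering across two annotation versions
#'
#' Co-cluster iff equal length and global identity at least
#' \code{identity} (the \code{-c 0.95 -s 1} regime). Equal length is a hard
#' rule, so only same-length pairs are ever aligned.
#'
#' @inheritParams cluster_exact
#' @param identity minimum identity fraction.
#' @param type sequence type for the aligner.
#' @return same shape as \code{\link{cluster_exact}} (without
#'   \code{clusters}).
#' @export
cluster_near <- function(old_seqs, new_seqs, identity = 0.95,
                         type = "nucleotide") {
  old_seqs <- .check_origin(old_seqs, "old")
  new_seqs <- .check_origin(new_seqs, "new")
  new_by_len <- split(names(new_seqs), nchar(new_seqs))
  matches <- list()
  for (tag in names(old_seqs)) {
    cand <- new_by_len[[as.character(nchar(old_seqs[[tag]]))]]
    if (is.null(cand)) next
    hit <- cand[vapply(cand, function(nt)
      seq_identity(old_seqs[[tag]], new_seqs[[nt]], type) >= identity,
      logical(1))]
    if (length(hit)) matches[[tag]] <- hit
  }
  list(transferred = names(matches), matches = matches,
       duplicated = names(matches)[lengths(matches) > 1L])
}

#' Detect fusion and split events between mapped model sets
#'
#' Both model sets must be on the same (new) coordinate system; old models
#' enter as mapper output. A new model whose CDS overlaps the CDS of two or
#' more old models on the same strand, covering at least half of each old
#' CDS, is a fusion of those old genes; symmetrically, two or more new
#' models each absorbing at least half of their own CDS length from a
#' single old model constitute a split. A model may participate in at most
#' one event; conflicting assignments raise an error.
#'
#' @param old_models \code{gene_models} mapped onto the new assembly.
#' @param new_models \code{gene_models} on the new assembly.
#' @param min_frac minimum overlap fraction of the absorbed partner's CDS.
#' @return list of events; each event is a list with \code{type}
#'   ("fusion"/"split"), \code{old_tags}, \code{new_tags} (ordered by
#'   plus-strand coordinate).
#' @export
detect_fusion_split <- function(old_models, new_models, min_frac = 0.5) {
  ospan <- model_spans(old_models)
  nspan <- model_spans(new_models)
  ocds <- old_models[old_models$type == "CDS", ]
  ncds <- new_models[new_models$type == "CDS", ]
  pairs <- list()
  for (ctg in intersect(unique(ocds$contig), unique(ncds$contig))) {
    for (str in c("+", "-")) {
      o <- ocds[ocds$contig == ctg & ocds$strand == str, ]
      n <- ncds[ncds$contig == ctg & ncds$strand == str, ]
      if (!nrow(o) || !nrow(n)) next
      oir <- IRanges::IRanges(o$start, o$end)
      nir <- IRanges::IRanges(n$start, n$end)
      ov <- IRanges::findOverlaps(oir, nir)
      if (!length(ov)) next
      w <- IRanges::width(IRanges::pintersect(oir[S4Vectors::queryHits(ov)],
                                              nir[S4Vectors::subjectHits(ov)]))
      df <- data.frame(old_tag = o$locus_tag[S4Vectors::queryHits(ov)],
                       new_tag = n$locus_tag[S4Vectors::subjectHits(ov)],
                       w = w, stringsAsFactors = FALSE)
      pairs[[length(pairs) + 1L]] <- df
    }
  }
  if (!length(pairs)) return(list())
  ov <- do.call(rbind, pairs)
  ov <- stats::aggregate(w ~ old_tag + new_tag, data = ov, FUN = sum)
  ov$old_len <- ospan$cds_len[match(ov$old_tag, ospan$locus_tag)]
  ov$new_len <- nspan$cds_len[match(ov$new_tag, nspan$locus_tag)]
  ov$covers_old <- ov$w >= min_frac * ov$old_len
  ov$covers_new <- ov$w >= min_frac * ov$new_len
  events <- list()
  used_old <- character(0)
  used_new <- character(0)
  claim <- function(tags, used, what) {
    clash <- intersect(tags, used)
    if (length(clash))
      stop("model(s) in more than one fusion/split event: ",
           paste(clash, collapse = ", "))
    c(used, tags)
  }
  # fusions: one new model absorbing >= 2 old models
  for (nt in unique(ov$new_tag)) {
    olds <- ov$old_tag[ov$new_tag == nt & ov$covers_old]
    if (length(olds) >= 2L) {
      used_old <- claim(olds, used_old, "old")
      used_new <- claim(nt, used_new, "new")
      events[[length(events) + 1L]] <-
        list(type = "fusion", old_tags = sort(olds), new_tags = nt)
    }
  }
  # splits: >= 2 new models each drawn from one old model
  for (ot in setdiff(unique(ov$old_tag), used_old)) {
    news <- ov$new_tag[ov$old_tag == ot & ov$covers_new]
    news <- setdiff(news, used_new)
    if (length(news) >= 2L) {
      used_old <- claim(ot, used_old, "old")
      used_new <- claim(news, used_new, "new")
      ord <- order(nspan$start[match(news, nspan$locus_tag)])
      events[[length(events) + 1L]] <-
        list(type = "split", old_tags = ot, new_tags = news[ord])
    }
  }
  events
}

.tag_number <- function(tags, prefix) {
  num <- sub(paste0("^", prefix, "_"), "", tags)
  if (any(!grepl("^[0-9]+$", num)))
    stop("locus tag(s) not matching '", prefix, "_<number>': ",
         paste(tags[!grepl("^[0-9]+$", num)], collapse = ", "))
  as.integer(num)
}

#' Locus-tag names for fusion and split events
#'
#' A fusion of PREFIX_a and PREFIX_b (numbers sorted ascending) is named
#' PREFIX_afub; a split of PREFIX_n into k parts is named PREFIX_np1 ..
#' PREFIX_npk, parts numbered in plus-strand coordinate order. Input order
#' of the fused tags does not matter.
#'
#' @param events event list from \code{\link{detect_fusion_split}}.
#' @param prefix locus-tag prefix; inferred from the first event if NULL.
#' @return the events, each with a \code{new_names} character vector added.
#' @export
assign_locus_tags <- function(events, prefix = NULL) {
  if (!length(events)) return(events)
  if (is.null(prefix))
    prefix <- sub("_[0-9]+$", "", events[[1L]]$old_tags[1L])
  lapply(events, function(ev) {
    nums <- sort(.tag_number(ev$old_tags, prefix))
    if (ev$type == "fusion") {
      ev$new_names <- paste0(prefix, "_", nums[1L],
                             paste0("fu", nums[-1L], collapse = ""))
    } else {
      k <- length(ev$new_tags)
      ev$new_names <- paste0(prefix, "_", nums[1L], "p", seq_len(k))
    }
    ev
  })
}

#' Stage-wise annotation transfer
#'
#' Iterates the supplied candidate stages in order. At each stage the still
#' unresolved old tags are tested against that stage's candidate CDS set by
#' exact clustering (the first \code{n_exact_stages} stages) or
#' near-identity clustering (later stages); resolved tags leave the pool
#' and are never revisited. Old tags participating in a supplied
#' fusion/split event are classified as fused/split; the remainder fails.
#'
#' @param old_seqs named character vector of old CDS sequences.
#' @param stage_candidates named, ordered list; each element a named
#'   character vector of candidate new CDS sequences for that stage.
#' @param events optional event list from \code{\link{detect_fusion_split}}
#'   (run \code{\link{assign_locus_tags}} first to name the products).
#' @param near_identity identity threshold for the near stages.
#' @param n_exact_stages how many leading stages use exact clustering.
#' @param type sequence type for the near-identity aligner.
#' @return data.frame (transfer records): old_tag, outcome, stage, new_tags
#'   (";"-separated).
#' @export
run_transfer <- function(old_seqs, stage_candidates, events = NULL,
                         near_identity = 0.95, n_exact_stages = 2L,
                         type = "nucleotide") {
  old_seqs <- .check_origin(old_seqs, "old")
  pool <- names(old_seqs)
  records <- list()
  push <- function(tags, outcome, stage, new_tags) {
    records[[length(records) + 1L]] <<- data.frame(
      old_tag = tags, outcome = outcome, stage = stage,
      new_tags = new_tags, stringsAsFactors = FALSE)
  }
  for (i in seq_along(stage_candidates)) {
    if (!length(pool)) break
    stage <- names(stage_candidates)[i]
    if (is.null(stage) || !nzchar(stage)) stage <- paste0("stage", i)
    cand <- stage_candidates[[i]]
    res <- if (i <= n_exact_stages)
      cluster_exact(old_seqs[pool], cand)
    else
      cluster_near(old_seqs[pool], cand, identity = near_identity,
                   type = type)
    if (length(res$transferred))
      push(res$transferred, "transferred", stage,
           vapply(res$matches[res$transferred], paste, character(1),
                  collapse = ";"))
    pool <- setdiff(pool, res$transferred)
  }
  if (!is.null(events)) {
    for (ev in events) {
      hit <- intersect(ev$old_tags, pool)
      if (!length(hit)) next
      nm <- if (!is.null(ev$new_names)) ev$new_names else ev$new_tags
      out <- if (ev$type == "fusion") "fused" else "split"
      push(hit, out, "event", paste(nm, collapse = ";"))
      pool <- setdiff(pool, hit)
    }
  }
  if (length(pool)) push(pool, "failed", "none", "")
  out <- do.call(rbind, records)
  if (is.null(out))
    out <- data.frame(old_tag = character(), outcome = character(),
                      stage = character(), new_tags = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise transfer records
#'
#' Counts per outcome and per stage, plus resulting-model counts for fusion
#' and split events. Enforces conservation: every old tag appears exactly
#' once and the outcome counts sum to the number of old tags.
#'
#' @param records data.frame from \code{\link{run_transfer}}.
#' @return list: by_outcome (named counts), by_stage, n_old,
#'   fused_models (distinct fusion products), split_models (total split
#'   parts).
#' @export
transfer_summary <- function(records) {
  if (anyDuplicated(records$old_tag))
    stop("conservation violation: old tag appears more than once: ",
         records$old_tag[duplicated(records$old_tag)][1L])
  outcomes <- c("transferred", "fused", "split", "failed", "contaminant",
                "opposite_strand_conflict", "duplicate_collapsed",
                "poor_isoform")
  by_outcome <- vapply(outcomes, function(o) sum(records$outcome == o),
                       integer(1))
  if (sum(by_outcome) != nrow(records))
    stop("conservation violation: unknown outcome present")
  fused <- records[records$outcome == "fused", ]
  split <- records[records$outcome == "split", ]
  list(
    by_outcome = by_outcome,
    by_stage = table(records$stage),
    n_old = nrow(records),
    fused_models = length(unique(fused$new_tags)),
    split_models = length(unlist(strsplit(unique(split$new_tags), ";",
                                          fixed = TRUE)))
  )
}
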