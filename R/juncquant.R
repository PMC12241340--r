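#' Build the junction k-mer index
#'
#' Each retained collision class contributes exactly one k-mer (its full
#' 31-nt junction) plus the reverse complement. If reverse-complement
#' folding makes a k-mer shared between two classes, the classes are merged
#' (a read carrying that k-mer cannot distinguish them) and the merge is
#' reported with a message.
#'
#' @param ref A [build_junction_reference()] result.
#' @param k k-mer length; must equal the junction length (default 31).
#' @return A `kmer_index`: list with `k`, `class_ids` (per index key),
#'   `kmers` (index keys), `pdict` (a Biostrings PDict over the keys),
#'   `classes` (the possibly merged class table) and `merged`
#'   (data.frame of RC-folding merges, possibly empty).
#' @export
build_kmer_index <- function(ref, k = 31L) {
  stopifnot(inherits(ref, "junction_reference"))
  jl <- nchar(ref$classes$junction)
  if (length(jl) && any(jl != k))
    stop("junction length (", paste(unique(jl), collapse = ","),
         ") does not match the index k-mer length (", k,
         "): reference/index mismatch")
  cls <- ref$classes
  fwd <- cls$junction
  rc <- if (length(fwd)) revcomp(fwd) else character(0)

  class_id <- cls$class_id
  merged <- data.frame(kept = character(0), merged = character(0))
  if (length(fwd)) {
    # RC-folding: canonical form = lexicographic min(fwd, rc)
    canon <- pmin(fwd, rc)
    if (anyDuplicated(canon)) {
      keep_of <- class_id[!duplicated(canon)][match(canon, canon[!duplicated(canon)])]
      merged <- data.frame(kept = keep_of[keep_of != class_id],
                           merged = class_id[keep_of != class_id],
                           stringsAsFactors = FALSE)
      message("RC-folding merged ", nrow(merged), " collision class(es): ",
              paste(merged$merged, "->", merged$kept, collapse = "; "))
      class_id <- keep_of
    }
  }
  kmers <- c(fwd, rc)
  ids <- c(class_id, class_id)
  dup <- duplicated(kmers)            # palindromic junction: rc == fwd
  kmers <- kmers[!dup]; ids <- ids[!dup]
  pdict <- if (length(kmers))
    Biostrings::PDict(Biostrings::DNAStringSet(kmers)) else NULL
  cls$class_id <- class_id
  structure(list(k = as.integer(k), kmers = kmers, class_ids = ids,
                 pdict = pdict, classes = cls,
                 class_levels = unique(class_id),
                 merged = merged),
            class = "kmer_index")
}

#' Assign read pairs to junction classes and the linear transcriptome
#'
#' A fragment is junction-assigned iff either mate contains one of the
#' junction 31-mers as an exact substring (every length-k window, both
#' strands via the RC keys) — exact matching of the full 31-mer implies at
#' least 15 nt overlap on one side of the backsplice and 16 nt on the other.
#' Fragments hitting two or more classes are counted `ambiguous` (reported,
#' not fractionally split). Fragments with no junction hit are tested for
#' linear origin: a fragment is `linear_assigned` iff either mate, or its
#' reverse complement, occurs as an exact substring of any linear
#' transcript. The remainder is `unassigned`. Each fragment is counted
#' exactly once, and junction evidence takes priority over linear.
#'
#' @param reads A `read_set`.
#' @param jidx A [build_kmer_index()] result.
#' @param linear_ref A `transcript_set` of linear transcripts (or `NULL` to
#'   skip linear assignment).
#' @return A `sample_counts`: list with `sample_id`, `junction_counts`
#'   (named integer vector over collision classes), `linear_assigned`,
#'   `ambiguous`, `unassigned`, `fragments`.
#' @export
assign_reads <- function(reads, jidx, linear_ref = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(jidx, "kmer_index"))
  n <- length(reads$read1)
  classes <- jidx$class_levels
  jc <- structure(integer(length(classes)), names = classes)
  if (n == 0L)
    return(new_sample_counts(reads$sample_id, jc, 0L, 0L, 0L, 0L))

  w1 <- nchar(reads$read1); w2 <- nchar(reads$read2)
  if (any(pmax(w1, w2) < jidx$k))
    warning(sum(pmax(w1, w2) < jidx$k),
            " fragment(s) with both mates shorter than k = ", jidx$k,
            " cannot be junction-assigned")

  hit_classes <- vector("list", n)
  if (!is.null(jidx$pdict)) {
    for (mate in list(reads$read1, reads$read2)) {
      ok <- nchar(mate) >= jidx$k
      if (!any(ok)) next
      subj <- Biostrings::DNAStringSet(mate[ok])
      hits <- Biostrings::vwhichPDict(jidx$pdict, subj)
      idx_ok <- which(ok)
      nonempty <- which(lengths(hits) > 0L)
      for (i in nonempty) {
        fi <- idx_ok[i]
        hit_classes[[fi]] <- c(hit_classes[[fi]], jidx$class_ids[hits[[i]]])
      }
    }
  }
  ncls <- vapply(hit_classes, function(h) length(unique(h)), integer(1))
  uniq <- which(ncls == 1L)
  if (length(uniq)) {
    tb <- table(factor(vapply(hit_classes[uniq], `[[`, character(1), 1L),
                       levels = classes))
    jc[] <- as.integer(tb)
  }
  ambiguous <- sum(ncls >= 2L)
  rest <- which(ncls == 0L)

  linear_assigned <- 0L
  if (length(rest) && !is.null(linear_ref) && length(linear_ref)) {
    lin <- as_transcript_set(linear_ref)
    subj <- Biostrings::DNAStringSet(c(as.character(lin), revcomp(lin)))
    m1 <- substring_in_any(reads$read1[rest], subj)
    m2 <- substring_in_any(reads$read2[rest], subj)
    linear_assigned <- sum(m1 | m2)
  }
  unassigned <- length(rest) - linear_assigned
  new_sample_counts(reads$sample_id, jc, linear_assigned,
                    as.integer(ambiguous), as.integer(unassigned), n)
}

# TRUE per query iff the query occurs as an exact substring of any subject.
# Constant-width query batches go through a PDict; mixed widths are batched
# by width.
substring_in_any <- function(queries, subjects) {
  out <- logical(length(queries))
  if (!length(queries)) return(out)
  queries <- unname(queries)
  for (w in unique(nchar(queries))) {
    sel <- nchar(queries) == w
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries[sel]))
    cnt <- Biostrings::vcountPDict(pd, subjects, collapse = 1)
    out[sel] <- cnt > 0L
  }
  out
}

new_sample_counts <- function(sample_id, junction_counts, linear_assigned,
                              ambiguous, unassigned, fragments) {
  structure(list(sample_id = sample_id, junction_counts = junction_counts,
                 linear_assigned = as.integer(linear_assigned),
                 ambiguous = as.integer(ambiguous),
                 unassigned = as.integer(unassigned),
                 fragments = as.integer(fragments)),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("sample_counts [", x$sample_id, "]: ", x$fragments, " fragments; ",
      sum(x$junction_counts), " junction, ", x$linear_assigned, " linear, ",
      x$ambiguous, " ambiguous, ", x$unassigned, " unassigned\n", sep = "")
  invisible(x)
}

#' Naive reference counter (test oracle)
#'
#' Same assignment rule as [assign_reads()], implemented as a plain
#' O(fragments x junctions) substring scan in base R with no shared
#' machinery beyond the collision-class table. Intended for small inputs
#' (<= 1e4 fragments).
#'
#' @inheritParams assign_reads
#' @param ref A `junction_reference` (the index is derived internally with
#'   the same RC-folding rule).
#' @return A `sample_counts`.
#' @export
brute_force_assign <- function(reads, ref, linear_ref = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(ref, "junction_reference"))
  cls <- ref$classes
  fwd <- cls$junction
  rc <- if (length(fwd)) revcomp(fwd) else character(0)
  class_id <- cls$class_id
  if (length(fwd)) {                  # RC-folding, as in the index
    canon <- pmin(fwd, rc)
    class_id <- class_id[!duplicated(canon)][match(canon, canon[!duplicated(canon)])]
  }
  classes <- unique(class_id)
  n <- length(reads$read1)
  jc <- structure(integer(length(classes)), names = classes)
  if (n == 0L)
    return(new_sample_counts(reads$sample_id, jc, 0L, 0L, 0L, 0L))

  hit <- vector("list", n)
  for (j in seq_along(fwd)) {
    m <- grepl(fwd[j], reads$read1, fixed = TRUE) |
         grepl(fwd[j], reads$read2, fixed = TRUE) |
         grepl(rc[j], reads$read1, fixed = TRUE) |
         grepl(rc[j], reads$read2, fixed = TRUE)
    for (i in which(m)) hit[[i]] <- union(hit[[i]], class_id[j])
  }
  nh <- lengths(hit)
  one <- which(nh == 1L)
  if (length(one)) {
    tb <- table(factor(unlist(hit[one]), levels = classes))
    jc[] <- as.integer(tb)
  }
  ambiguous <- sum(nh >= 2L)
  rest <- which(nh == 0L)
  linear_assigned <- 0L
  if (length(rest) && !is.null(linear_ref) && length(linear_ref)) {
    lin <- as.character(as_transcript_set(linear_ref))
    q <- rbind(reads$read1[rest], reads$read2[rest],
               revcomp(reads$read1[rest]), revcomp(reads$read2[rest]))
    is_lin <- vapply(seq_along(rest), function(i)
      any(vapply(lin, function(t)
        any(vapply(q[, i], grepl, logical(1), x = t, fixed = TRUE)),
        logical(1))),
      logical(1))
    linear_assigned <- sum(is_lin)
  }
  unassigned <- length(rest) - linear_assigned
  new_sample_counts(reads$sample_id, jc, linear_assigned,
                    as.integer(ambiguous), as.integer(unassigned), n)
}

#' Write junction counts and an assignment summary
#'
#' @param sc A `sample_counts`.
#' @param counts_path Output TSV (`class_id`, `count`).
#' @param summary_path Optional JSON path for the assignment summary.
#' @return `counts_path`, invisibly.
#' @export
write_sample_counts <- function(sc, counts_path, summary_path = NULL) {
  stopifnot(inherits(sc, "sample_counts"))
  write.table(data.frame(class_id = names(sc$junction_counts),
                         count = as.integer(sc$junction_counts)),
              counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(
      list(sample_id = sc$sample_id, fragments = sc$fragments,
           junction = sum(sc$junction_counts),
           linear_assigned = sc$linear_assigned,
           ambiguous = sc$ambiguous, unassigned = sc$unassigned),
      summary_path, auto_unbox = TRUE)
  invisible(counts_path)
}
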