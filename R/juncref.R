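#' Read a transcript FASTA file
#'
#' Reads circRNA or linear transcript sequences. Sequences are uppercased,
#' multi-line records are concatenated and input order is preserved. The
#' record id is the first whitespace-delimited token of the header
#' (circBank- and GENCODE-style headers both follow this convention).
#'
#' @param path Path to a FASTA file.
#' @return A `transcript_set`: named character vector of uppercase DNA
#'   sequences (names are transcript ids).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa_circ_0000001", "acgtacgtacgt"), fa)
#' read_transcript_fasta(fa)
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  if (length(ss) == 0L) warning("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  structure(seqs, class = c("transcript_set", "character"))
}

as_transcript_set <- function(x) {
  if (inherits(x, "transcript_set")) return(x)
  stopifnot(is.character(x), !is.null(names(x)))
  if (anyDuplicated(names(x)))
    stop("duplicate transcript id(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  structure(toupper(x), class = c("transcript_set", "character"))
}

#' Build the backsplice-junction pseudo-reference
#'
#' For each circRNA transcript the backsplice junction is reconstructed by
#' ligating the last `suffix_len` bases of the sequence to its first
#' `prefix_len` bases (defaults 15 + 16 = 31 nt, one k-mer at k = 31).
#' Transcripts shorter than `max(suffix_len, prefix_len)` are skipped
#' (`too_short`); transcripts with an ambiguous base (N) inside the junction
#' window are skipped (`ambiguous_base`). Transcripts between 16 and 30 nt
#' are retained: suffix and prefix then overlap in the middle but the
#' construction is still well defined, and such records are flagged in the
#' skip report. Identical junction strings are merged into a single
#' *collision class* — such circRNAs are experimentally indistinguishable at
#' the junction and counting them separately would double-count reads.
#'
#' @param tx A `transcript_set` (see [read_transcript_fasta()]) or a named
#'   character vector of circRNA sequences.
#' @param suffix_len Number of bases taken from the transcript 3' end.
#' @param prefix_len Number of bases taken from the transcript 5' start.
#' @return A `junction_reference`: list with
#'   \describe{
#'     \item{records}{data.frame (`circ_id`, `junction`, `class_id`), one row
#'       per retained circRNA; coordinates 1-based inclusive.}
#'     \item{classes}{data.frame (`class_id`, `junction`, `members`), one row
#'       per distinct junction string; `members` is a comma-separated id list
#'       and `class_id` is the first member in input order.}
#'     \item{skipped}{data.frame (`circ_id`, `reason`).}
#'     \item{suffix_len,prefix_len}{the construction parameters.}
#'   }
#' @export
build_junction_reference <- function(tx, suffix_len = 15L, prefix_len = 16L) {
  tx <- as_transcript_set(tx)
  stopifnot(suffix_len >= 1L, prefix_len >= 1L)
  ids <- names(tx)
  L <- nchar(tx)
  min_len <- max(suffix_len, prefix_len)

  junction <- rep(NA_character_, length(tx))
  reason <- rep(NA_character_, length(tx))

  ok <- L >= min_len
  reason[!ok] <- "too_short"
  if (any(ok)) {
    suf <- substr(tx[ok], L[ok] - suffix_len + 1L, L[ok])
    pre <- substr(tx[ok], 1L, prefix_len)
    j <- paste0(suf, pre)
    amb <- grepl("[^ACGT]", j)
    junction[ok][!amb] <- j[!amb]
    reason[ok][amb] <- "ambiguous_base"
  }

  keep <- !is.na(junction)
  skipped <- data.frame(circ_id = ids[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)

  rec_ids <- ids[keep]
  rec_junc <- junction[keep]
  # collision classes: first member (input order) names the class
  first_idx <- !duplicated(rec_junc)
  class_of <- rec_ids[first_idx][match(rec_junc, rec_junc[first_idx])]
  records <- data.frame(circ_id = rec_ids, junction = rec_junc,
                        class_id = class_of, stringsAsFactors = FALSE)
  classes <- data.frame(
    class_id = rec_ids[first_idx],
    junction = rec_junc[first_idx],
    members = vapply(rec_junc[first_idx], function(j)
      paste(rec_ids[rec_junc == j], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(records = records, classes = classes, skipped = skipped,
                 suffix_len = suffix_len, prefix_len = prefix_len),
            class = "junction_reference")
}

#' @export
print.junction_reference <- function(x, ...) {
  cat("junction_reference:", nrow(x$records), "circRNAs in",
      nrow(x$classes), "collision classes;", nrow(x$skipped), "skipped\n")
  cat("junction = last", x$suffix_len, "nt + first", x$prefix_len,
      "nt (", x$suffix_len + x$prefix_len, "nt )\n")
  invisible(x)
}

#' Write junction sequences as FASTA
#'
#' One record per collision class, headers `class_id|junction|<length>`.
#'
#' @param ref A `junction_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "junction_reference"))
  ss <- Biostrings::DNAStringSet(ref$classes$junction)
  names(ss) <- paste(ref$classes$class_id, "junction",
                     nchar(ref$classes$junction), sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the skip report
#'
#' @param ref A `junction_reference`.
#' @param path Output TSV path (columns `circ_id`, `reason`).
#' @return `path`, invisibly.
#' @export
write_skip_report <- function(ref, path) {
  stopifnot(inherits(ref, "junction_reference"))
  write.table(ref$skipped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
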