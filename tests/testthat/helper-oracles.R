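# Independent oracles and tiny constructors shared across tests.
# These deliberately avoid the package's own code paths.

# naive junction slicing: last s bases then first p bases, by strsplit
naive_junction <- function(seq, s = 15, p = 16) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  paste(c(ch[(L - s + 1):L], ch[1:p]), collapse = "")
}

# base-R reverse complement, independent of Biostrings
naive_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                              collapse = "")

make_read_set <- function(read1, read2, sample_id = "s", treated = FALSE) {
  structure(list(read1 = read1, read2 = read2, sample_id = sample_id,
                 treated = treated), class = "read_set")
}

counts_equal <- function(a, b) {
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$linear_assigned, b$linear_assigned)
  expect_identical(a$ambiguous, b$ambiguous)
  expect_identical(a$unassigned, b$unassigned)
  expect_identical(a$junction_counts[sort(names(a$junction_counts))],
                   b$junction_counts[sort(names(b$junction_counts))])
}
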