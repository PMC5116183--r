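# Shared fixture builders.  All synthetic data is generated in code with
# fixed seeds; nothing is read from disk except files the tests write.

fixture_fasta <- function(lines, path = withr::local_tempfile(
                            fileext = ".fasta",
                            .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# A hand-built mapping object for tests that probe single operations
# without running the full assignment search.
manual_mapping <- function(sequence, slots, positions, id = "manual",
                           extras_pos = integer(0)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  stopifnot(all(chars[positions] == "C"), all(chars[extras_pos] == "C"))
  assignment <- stats::setNames(as.list(as.integer(positions)),
                                as.character(slots))
  extras <- if (length(extras_pos)) {
    csabref:::extras_frame(sort(c(positions, extras_pos)),
                           positions, slots)
  } else {
    data.frame(label = character(0), position = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, assignment = assignment,
         extras = extras, anchor_used = NA_integer_, anchor_hit = NULL,
         score = NA_real_, csh_violations = NA_integer_),
    class = "array_mapping"
  )
}

# The C/X pattern actually present between the outermost assigned slots,
# computed directly from the sequence (the independent route for the
# notation round-trip check).
sequence_pattern <- function(mapping) {
  pos <- unlist(mapping$assignment)
  span <- substring(mapping$sequence, min(pos), max(pos))
  gsub("[^C]", "X", span)
}
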