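#' Construct a mature-peptide record
#'
#' A `peptide_record` holds one mature peptide sequence together with the
#' ternary propeptide flags used as phylogenetic characters (present /
#' absent / unknown) and optional free-text metadata.
#'
#' @param id Unique identifier (non-empty character scalar, no whitespace).
#' @param sequence Amino-acid sequence; the 20 standard residues plus the
#'   ambiguity codes X, B, Z and U are accepted.  A terminal `*` (stop) is
#'   stripped; an interior `*` or any other character is an error.
#' @param description Free-text description.
#' @param has_n_propeptide,has_c_propeptide One of `"present"`, `"absent"`,
#'   `"unknown"`.
#' @param taxon_group Optional taxon label (e.g. `"Hexapoda"`).
#'
#' @return An object of class `peptide_record`.
#' @export
#' @examples
#' peptide_record("sapA", "ATCDLLSGTGINHSACAAHCLLRGNRGGYCNGKGVCVCRN")
peptide_record <- function(id, sequence, description = "",
                           has_n_propeptide = "unknown",
                           has_c_propeptide = "unknown",
                           taxon_group = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("[[:space:]]", id)) {
    stop("record id must not contain whitespace: ", id)
  }
  sequence <- normalize_sequence(sequence, id = id)
  has_n_propeptide <- match.arg(has_n_propeptide,
                                c("unknown", "present", "absent"))
  has_c_propeptide <- match.arg(has_c_propeptide,
                                c("unknown", "present", "absent"))
  structure(
    list(
      id = id,
      description = description,
      sequence = sequence,
      has_n_propeptide = has_n_propeptide,
      has_c_propeptide = has_c_propeptide,
      taxon_group = taxon_group
    ),
    class = "peptide_record"
  )
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("<peptide_record> %s (%d aa, %d Cys)\n",
              x$id, nchar(x$sequence),
              length(gregexpr("C", x$sequence, fixed = TRUE)[[1]][
                gregexpr("C", x$sequence, fixed = TRUE)[[1]] > 0])))
  invisible(x)
}

## Uppercase, strip one terminal '*', and validate the residue alphabet.
## Reports the 1-based offset of the first illegal character.
normalize_sequence <- function(sequence, id = "<sequence>") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  s <- sub("\\*$", "", s)
  if (!nzchar(s)) stop("record ", id, ": sequence is empty")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_LEGAL)
  if (length(bad)) {
    stop(sprintf("record %s: illegal residue '%s' at offset %d",
                 id, chars[bad[1]], bad[1]))
  }
  s
}

#' Read mature peptides from a FASTA file
#'
#' Sequences are uppercased and a single terminal `*` is removed.  The
#' header token up to the first whitespace becomes the record id; the
#' remainder becomes the description.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A list of [peptide_record] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE, whole.header = TRUE)
  if (!length(fa)) stop("no FASTA records in ", path)
  recs <- lapply(fa, function(entry) {
    header <- attr(entry, "name")
    id <- sub("[[:space:]].*$", "", header)
    desc <- sub("^[^[:space:]]+[[:space:]]*", "", header)
    peptide_record(id, as.character(entry), description = desc)
  })
  names(recs) <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(names(recs))) {
    stop("duplicate record id(s): ",
         paste(unique(names(recs)[duplicated(names(recs))]), collapse = ", "))
  }
  recs
}

#' Write records to a FASTA file
#'
#' @param records List of [peptide_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  seqinr::write.fasta(
    sequences = lapply(records, `[[`, "sequence"),
    names = headers, file.out = path, as.string = TRUE, nbchar = 60
  )
  invisible(path)
}

#' Attach propeptide presence flags from a sidecar table
#'
#' The table is tab-separated with columns `id`, `n_propeptide`,
#' `c_propeptide`; values are `1` (present), `0` (absent) or `-`
#' (missing/unknown).  Records not listed keep their current flags; table
#' ids with no matching record raise a warning but are not fatal.
#'
#' @param path Path to the tab-separated table (header row required).
#' @param records List of [peptide_record] objects.
#' @return The updated list of records.
#' @export
read_propeptide_table <- function(path, records) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  needed <- c("id", "n_propeptide", "c_propeptide")
  if (!all(needed %in% names(tab))) {
    stop("propeptide table must have columns: ",
         paste(needed, collapse = ", "))
  }
  decode <- function(v, id) {
    switch(v,
           "1" = "present",
           "0" = "absent",
           "-" = "unknown",
           stop("propeptide table: illegal value '", v, "' for id ", id))
  }
  ids <- vapply(records, `[[`, character(1), "id")
  for (i in seq_len(nrow(tab))) {
    j <- match(tab$id[i], ids)
    if (is.na(j)) {
      warning("propeptide table id not found among records: ", tab$id[i])
      next
    }
    records[[j]]$has_n_propeptide <- decode(tab$n_propeptide[i], tab$id[i])
    records[[j]]$has_c_propeptide <- decode(tab$c_propeptide[i], tab$id[i])
  }
  records
}

#' Write a propeptide sidecar table
#'
#' Inverse of [read_propeptide_table()]: one row per record with flags
#' encoded as `1` / `0` / `-`.
#'
#' @param records List of [peptide_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_propeptide_table <- function(records, path) {
  enc <- function(v) switch(v, present = "1", absent = "0", unknown = "-")
  tab <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    n_propeptide = vapply(records, function(r) enc(r$has_n_propeptide),
                          character(1)),
    c_propeptide = vapply(records, function(r) enc(r$has_c_propeptide),
                          character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the per-record annotation table
#'
#' One tab-separated row per record, in input order, with the reference
#' array assignment, box/spacer notation, family label, bond description,
#' γ-core span, toxin-heuristic flag and n-loop length.
#'
#' @param annotations A data frame as produced by [annotate_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  cols <- c("id", "n_cysteines", "slots", "notation", "family",
            "bonds", "gamma_core", "kcxn", "n_loop", "toxin_heuristic")
  stopifnot(all(cols %in% names(annotations)))
  utils::write.table(annotations[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
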