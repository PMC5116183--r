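#' The AdDLP-relative indel coding scheme
#'
#' Insertions/deletions relative to the AdDLP-like ancestor are coded for
#' six areas of the anchored alignment.  The reference lengths are those
#' of AdDLP: (1) 3 residues upstream of C2; (2) 17 gap spaces between C2
#' and C3; (3) 3 residues between C3 and C4 (standard for the CSH motif);
#' (4) 11 gap spaces between C6 and C8; (5) 1 residue between C8 and C9
#' (standard for the motif); (6) 9 residues after C9.  An observed value
#' below the reference codes 0, equal codes 1, above codes 2.
#'
#' @return A named integer vector of the six reference lengths.
#' @export
indel_code_scheme <- function() {
  c(area1 = 3L, area2 = 17L, area3 = 3L, area4 = 11L, area5 = 1L,
    area6 = 9L)
}

#' Apply the `<`/`=`/`>` indel coding rule to one length
#'
#' @param x Observed length (residues or gap spaces); `NA` codes `-`.
#' @param ref Reference length.
#' @return `"0"`, `"1"`, `"2"` or `"-"`.
#' @export
indel_code <- function(x, ref) {
  if (is.na(x)) return("-")
  c("0", "1", "2")[sign(x - ref) + 2L]
}

#' Code the six AdDLP-relative indel characters for one record
#'
#' Areas 1, 3, 5 and 6 are coded from the record's own residue counts
#' (upstream of C2; between C3/C4; between C8/C9; after C9); areas 2 and 4
#' are coded from gap spaces in the anchored alignment (between C2/C3 and
#' C6/C8), mirroring how the reference lengths are stated.  Any area
#' touching an unassigned slot is coded `-` (missing).
#'
#' @param mapping The record's [map_to_reference()] result.
#' @param alignment The [build_anchored_alignment()] containing the record.
#' @param id Record identifier.
#' @param scheme Reference lengths, see [indel_code_scheme()].
#' @return Character vector of six codes over \{0, 1, 2, -\}.
#' @export
code_indels <- function(mapping, alignment, id = mapping$id,
                        scheme = indel_code_scheme()) {
  if (!id %in% alignment$ids) stop("record not in alignment: ", id)
  p <- function(s) slot_position(mapping, s)
  n <- nchar(mapping$sequence)

  a1 <- if (is.na(p(2L))) NA_integer_ else p(2L) - 1L
  a2 <- if (is.na(p(2L)) || is.na(p(3L))) NA_integer_ else
    gap_spaces(alignment, id, "C2_C3")
  a3 <- if (is.na(p(3L)) || is.na(p(4L))) NA_integer_ else p(4L) - p(3L) - 1L
  a4 <- if (is.na(p(6L)) || is.na(p(8L))) NA_integer_ else
    gap_spaces(alignment, id, "C6_C8")
  a5 <- if (is.na(p(8L)) || is.na(p(9L))) NA_integer_ else p(9L) - p(8L) - 1L
  a6 <- if (is.na(p(9L))) NA_integer_ else n - p(9L)

  obs <- c(a1, a2, a3, a4, a5, a6)
  vapply(seq_len(6L), function(i) indel_code(obs[i], scheme[[i]]),
         character(1))
}

#' Code propeptide presence as phylogenetic characters
#'
#' N- and C-terminal propeptides are coded present = 1, absent = 0, and
#' missing/unknown = `-`.
#'
#' @param record A [peptide_record].
#' @return Character vector of two codes (N-terminal, C-terminal).
#' @export
code_propeptides <- function(record) {
  enc <- function(v) switch(v, present = "1", absent = "0", unknown = "-")
  c(enc(record$has_n_propeptide), enc(record$has_c_propeptide))
}

#' Assemble the partitioned character matrix
#'
#' Columns are ordered protein (the gapped alignment), then the six indel
#' codes, then the two propeptide codes, with the partition spans
#' recorded.
#'
#' @param alignment An [build_anchored_alignment()] result.
#' @param indel_codes Named list (by record id) of six-code vectors from
#'   [code_indels()].
#' @param pro_codes Named list (by record id) of two-code vectors from
#'   [code_propeptides()].
#' @return An object of class `character_matrix` with fields `taxa`,
#'   `protein`, `indel`, `pro` and `spans`.
#' @export
build_matrix <- function(alignment, indel_codes, pro_codes) {
  taxa <- alignment$ids
  missing_codes <- setdiff(taxa, intersect(names(indel_codes),
                                           names(pro_codes)))
  if (length(missing_codes)) {
    stop("codes missing for aligned record(s): ",
         paste(missing_codes, collapse = ", "))
  }
  indel <- do.call(rbind, lapply(taxa, function(id) {
    v <- indel_codes[[id]]
    if (length(v) != 6L || !all(v %in% c("0", "1", "2", "-"))) {
      stop("invalid indel codes for ", id)
    }
    v
  }))
  pro <- do.call(rbind, lapply(taxa, function(id) {
    v <- pro_codes[[id]]
    if (length(v) != 2L || !all(v %in% c("0", "1", "-"))) {
      stop("invalid propeptide codes for ", id)
    }
    v
  }))
  rownames(indel) <- taxa
  rownames(pro) <- taxa
  L <- alignment$width
  if (length(unique(nchar(alignment$rows))) != 1L) {
    stop("alignment rows differ in length")
  }
  structure(
    list(taxa = taxa, protein = alignment$rows, indel = indel, pro = pro,
         spans = list(protein = c(1L, L), indel = c(L + 1L, L + 6L),
                      pro = c(L + 7L, L + 8L))),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d taxa, %d characters (protein %d-%d, indel %d-%d, pro %d-%d)\n",
              length(x$taxa), x$spans$pro[2L],
              x$spans$protein[1L], x$spans$protein[2L],
              x$spans$indel[1L], x$spans$indel[2L],
              x$spans$pro[1L], x$spans$pro[2L]))
  invisible(x)
}
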