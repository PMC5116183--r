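#' Build a cysteine-anchored multiple alignment
#'
#' Every reference slot that is occupied by at least one record receives
#' its own anchor column, shared by all records; the blocks between
#' anchors are sized to the widest occupant.  Within a block, each
#' record's residues are left-justified against the block's leading
#' anchor; the stretch upstream of a record's first assigned slot is
#' right-justified against that first anchor, so records lacking early
#' slots (e.g. CSH-only peptides) carry gaps through the missing anchor
#' columns.  Gap placement is therefore fully deterministic and ungapping
#' any row returns the original sequence.
#'
#' @param mappings List of [map_to_reference()] results.  Entries that are
#'   `NULL` (failed mappings) are dropped with a warning.
#' @param records Optional list of [peptide_record]s (unused; accepted for
#'   symmetry with the rest of the pipeline since mappings carry their
#'   sequences).
#' @return An object of class `anchored_alignment` with fields `ids`,
#'   `rows` (named character vector of gapped sequences), `width`,
#'   `anchor_columns` (named integer vector, slot -> column) and
#'   `mappings`.
#' @export
build_anchored_alignment <- function(mappings, records = NULL) {
  failed <- vapply(mappings, is.null, logical(1))
  if (any(failed)) {
    warning(sum(failed), " record(s) without a valid mapping excluded ",
            "from the alignment")
    mappings <- mappings[!failed]
  }
  if (!length(mappings)) stop("no mappable records: cannot build alignment")

  for (m in mappings) {
    pos <- unlist(m$assignment)
    if (is.unsorted(pos[order(as.integer(names(m$assignment)))],
                    strictly = TRUE)) {
      stop("inconsistent mapping for ", m$id,
           ": residue order violates slot order")
    }
  }

  anchors <- sort(unique(unlist(lapply(mappings, function(m)
    as.integer(names(m$assignment))))))

  ## Block k (k = 0..10) holds residues between anchor k and anchor k+1.
  alloc <- lapply(mappings, block_allocation)
  widths <- integer(11L)
  for (al in alloc) widths <- pmax(widths, al)

  ## Column layout: block 0, [C1], block 1, [C2], ..., [C10], block 10.
  block_start <- integer(11L)   # first column of each block (1-based)
  anchor_col <- stats::setNames(rep(NA_integer_, 10L), as.character(1:10))
  col <- 1L
  for (kk in 0:10) {
    block_start[kk + 1L] <- col
    col <- col + widths[kk + 1L]
    if (kk < 10L && (kk + 1L) %in% anchors) {
      anchor_col[[as.character(kk + 1L)]] <- col
      col <- col + 1L
    }
  }
  width <- col - 1L

  rows <- vapply(seq_along(mappings), function(i) {
    lay_out_row(mappings[[i]], alloc[[i]], block_start, anchor_col, widths,
                width)
  }, character(1))
  ids <- vapply(mappings, `[[`, character(1), "id")
  names(rows) <- ids
  names(mappings) <- ids

  structure(
    list(ids = ids, rows = rows, width = width,
         anchor_columns = anchor_col[!is.na(anchor_col)],
         mappings = mappings),
    class = "anchored_alignment"
  )
}

## Residues each record contributes to the 11 inter-anchor blocks:
## the flank before the first assigned slot goes to the block ending at
## that slot; the segment between consecutive assigned slots a < b goes to
## the block just after a; the tail goes to the block just after the last
## slot.
block_allocation <- function(mapping) {
  slots <- sort(as.integer(names(mapping$assignment)))
  pos <- vapply(as.character(slots), function(s) mapping$assignment[[s]],
                integer(1))
  n <- nchar(mapping$sequence)
  al <- integer(11L)
  al[slots[1L]] <- pos[1L] - 1L                       # flank -> block s1-1
  if (length(slots) > 1L) {
    for (i in seq_len(length(slots) - 1L)) {
      al[slots[i] + 1L] <- pos[i + 1L] - pos[i] - 1L  # segment -> block a
    }
  }
  al[slots[length(slots)] + 1L] <- n - pos[length(pos)]  # tail -> block sN
  al
}

lay_out_row <- function(mapping, al, block_start, anchor_col, widths, width) {
  chars <- strsplit(mapping$sequence, "", fixed = TRUE)[[1]]
  row <- rep("-", width)
  slots <- sort(as.integer(names(mapping$assignment)))
  pos <- vapply(as.character(slots), function(s) mapping$assignment[[s]],
                integer(1))

  ## anchored cysteines
  for (i in seq_along(slots)) {
    row[anchor_col[[as.character(slots[i])]]] <- chars[pos[i]]
  }
  ## flank: right-justified in the block before the first anchor
  f <- pos[1L] - 1L
  if (f > 0L) {
    blk <- slots[1L]   # block index s1-1 -> widths[blk], start block_start[blk]
    end <- block_start[blk] + widths[blk] - 1L
    row[(end - f + 1L):end] <- chars[seq_len(f)]
  }
  ## segments: left-justified in the block after their leading anchor
  if (length(slots) > 1L) {
    for (i in seq_len(length(slots) - 1L)) {
      len <- pos[i + 1L] - pos[i] - 1L
      if (len > 0L) {
        ## block k (0-based) starts at block_start[k + 1]; here k = slots[i]
        st <- block_start[slots[i] + 1L]
        row[st:(st + len - 1L)] <- chars[(pos[i] + 1L):(pos[i + 1L] - 1L)]
      }
    }
  }
  ## tail: left-justified after the last anchor
  tail_len <- length(chars) - pos[length(pos)]
  if (tail_len > 0L) {
    st <- block_start[slots[length(slots)] + 1L]
    row[st:(st + tail_len - 1L)] <- chars[(pos[length(pos)] + 1L):length(chars)]
  }
  paste(row, collapse = "")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("<anchored_alignment> %d records x %d columns; anchors: %s\n",
              length(x$ids), x$width,
              paste(names(x$anchor_columns), collapse = ",")))
  invisible(x)
}

## Named column ranges of the six reporting regions (bounds are anchor
## columns; counts are taken strictly between them).
region_bounds <- function(alignment, region) {
  ac <- alignment$anchor_columns
  col <- function(s) {
    if (!as.character(s) %in% names(ac)) {
      stop("region anchor C", s, " absent from alignment")
    }
    ac[[as.character(s)]]
  }
  switch(region,
         flank_before_C2 = c(0L, col(2L)),
         C2_C3 = c(col(2L), col(3L)),
         C3_C4 = c(col(3L), col(4L)),
         C6_C8 = c(col(6L), col(8L)),
         C8_C9 = c(col(8L), col(9L)),
         after_C9 = c(col(9L), alignment$width + 1L),
         stop("unknown region: ", region))
}

#' Count gap columns in a region of one alignment row
#'
#' Regions are named `flank_before_C2`, `C2_C3`, `C3_C4`, `C6_C8`,
#' `C8_C9` and `after_C9`; gaps are counted strictly between the bounding
#' anchor columns (or between the sequence edge and the anchor for the
#' two flank regions).
#'
#' @param alignment An [build_anchored_alignment()] result.
#' @param id Record identifier.
#' @param region Region name.
#' @return Integer gap count.
#' @export
gap_spaces <- function(alignment, id, region) {
  if (!id %in% alignment$ids) stop("record not in alignment: ", id)
  b <- region_bounds(alignment, region)
  lo <- b[1L] + 1L
  hi <- b[2L] - 1L
  if (hi < lo) return(0L)
  seg <- substring(alignment$rows[[id]], lo, hi)
  lengths(regmatches(seg, gregexpr("-", seg, fixed = TRUE)))
}

#' Export an anchored alignment
#'
#' @param alignment An [build_anchored_alignment()] result.
#' @param path Output path.
#' @param format `"fasta"` (gapped FASTA) or `"nexus"` (a PAUP-style
#'   protein DATA block).
#' @return `path`, invisibly.
#' @export
export_alignment <- function(alignment, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (!length(alignment$ids)) stop("empty alignment")
  if (format == "fasta") {
    seqinr::write.fasta(as.list(alignment$rows), names = alignment$ids,
                        file.out = path, as.string = TRUE, nbchar = 60)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con, sep = "\n")
    w("#NEXUS")
    w("BEGIN DATA;")
    w("    DIMENSIONS NTAX=%d NCHAR=%d;", length(alignment$ids),
      alignment$width)
    w("    FORMAT DATATYPE=PROTEIN GAP=- MISSING=?;")
    w("    MATRIX")
    for (id in alignment$ids) {
      w("    %s  %s", nexus_label(id), alignment$rows[[id]])
    }
    w("    ;")
    w("END;")
  }
  invisible(path)
}

## NEXUS token quoting: wrap labels containing punctuation or whitespace
## in single quotes (embedded quotes doubled) rather than mangling them.
nexus_label <- function(id) {
  if (grepl("[^A-Za-z0-9_.]", id)) {
    paste0("'", gsub("'", "''", id), "'")
  } else {
    id
  }
}
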