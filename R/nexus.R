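#' Write a partitioned NEXUS file (protein + indel + propeptide)
#'
#' Emits a single mixed-datatype DATA block (protein span, then six indel
#' characters over states 0/1/2, then two propeptide characters over 0/1)
#' followed by a sets/charset section and, optionally, a MrBayes command
#' block with the analysis settings used for such matrices: invgamma
#' rates and a mixed amino-acid model prior on the protein partition,
#' gamma rates on the indel and propeptide partitions, and variable
#' per-partition rates.  MCMC length and chain temperature are emitted
#' only as comments; the file never launches an analysis.
#'
#' The matrix-wide FORMAT line declares `GAP=- MISSING=?`; a header
#' comment records that `-` in the indel/propeptide spans denotes
#' missing/unknown data (those spans have no alignment gaps), preserving
#' the visible `-` coding while keeping the file parseable.
#'
#' @param matrix A [build_matrix()] result.
#' @param path Output path.
#' @param include_mrbayes_block Emit the `BEGIN mrbayes;` block
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_nexus <- function(matrix, path, include_mrbayes_block = TRUE) {
  stopifnot(inherits(matrix, "character_matrix"))
  L <- matrix$spans$protein[2L]
  nchar_total <- matrix$spans$pro[2L]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")

  w("#NEXUS")
  w("[ protein alignment with AdDLP-relative indel and propeptide characters ]")
  w("[ '-' in the standard-data spans (%d-%d) denotes missing/unknown data ]",
    L + 1L, nchar_total)
  w("BEGIN DATA;")
  w("    DIMENSIONS NTAX=%d NCHAR=%d;", length(matrix$taxa), nchar_total)
  w("    FORMAT DATATYPE=MIXED(PROTEIN:1-%d,STANDARD:%d-%d) GAP=- MISSING=? INTERLEAVE=NO;",
    L, L + 1L, nchar_total)
  w("    MATRIX")
  for (id in matrix$taxa) {
    w("    %s  %s%s%s", nexus_label(id), matrix$protein[[id]],
      paste(matrix$indel[id, ], collapse = ""),
      paste(matrix$pro[id, ], collapse = ""))
  }
  w("    ;")
  w("END;")
  w("")
  w("BEGIN sets;")
  w("    charset protein = 1-%d;", L)
  w("    charset indel = %d-%d;", matrix$spans$indel[1L],
    matrix$spans$indel[2L])
  w("    charset pro = %d-%d;", matrix$spans$pro[1L], matrix$spans$pro[2L])
  w("END;")
  if (include_mrbayes_block) {
    w("")
    w("BEGIN mrbayes;")
    w("    charset protein = 1-%d;", L)
    w("    charset indel = %d-%d;", matrix$spans$indel[1L],
      matrix$spans$indel[2L])
    w("    charset pro = %d-%d;", matrix$spans$pro[1L], matrix$spans$pro[2L])
    w("    partition bymodule = 3: protein, indel, pro;")
    w("    set partition = bymodule;")
    w("    lset applyto=(1) rates=invgamma;")
    w("    prset applyto=(1) aamodelpr=mixed;")
    w("    lset applyto=(2,3) rates=gamma;")
    w("    prset applyto=(all) ratepr=variable;")
    w("    [ mcmc ngen=2000000 temp=0.5; ]")
    w("END;")
  }
  invisible(path)
}

#' Parse back a NEXUS file written by [write_nexus()]
#'
#' A minimal reader for the mixed-datatype DATA block this package emits
#' (general-purpose NEXUS readers do not support mixed datatypes); used
#' to verify write/parse round trips.
#'
#' @param path Path to a NEXUS file.
#' @return A list with `taxa`, `protein`, `indel`, `pro` and `spans`,
#'   comparable to a [build_matrix()] result.
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fmt <- grep("DATATYPE=MIXED", lines, value = TRUE)
  if (!length(fmt)) stop("not a mixed-datatype NEXUS matrix: ", path)
  spans <- regmatches(fmt, gregexpr("[0-9]+-[0-9]+", fmt))[[1]]
  protein_span <- as.integer(strsplit(spans[1L], "-", fixed = TRUE)[[1]])
  standard_span <- as.integer(strsplit(spans[2L], "-", fixed = TRUE)[[1]])

  start <- grep("^\\s*MATRIX\\s*$", lines)[1L]
  stop_at <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > start)[1L]
  rows <- lines[(start + 1L):(stop_at - 1L)]
  rows <- rows[nzchar(trimws(rows))]
  taxa <- character(0)
  protein <- character(0)
  indel <- NULL
  pro <- NULL
  for (row in rows) {
    row <- trimws(row)
    if (startsWith(row, "'")) {
      m <- regmatches(row, regexpr("^'([^']|'')*'", row))
      label <- gsub("''", "'", substring(m, 2L, nchar(m) - 1L))
      chars <- trimws(substring(row, nchar(m) + 1L))
    } else {
      label <- sub("\\s.*$", "", row)
      chars <- trimws(sub("^\\S+\\s+", "", row))
    }
    L <- protein_span[2L]
    taxa <- c(taxa, label)
    protein <- c(protein, substring(chars, 1L, L))
    codes <- strsplit(substring(chars, L + 1L), "", fixed = TRUE)[[1]]
    indel <- rbind(indel, codes[1:6])
    pro <- rbind(pro, codes[7:8])
  }
  names(protein) <- taxa
  rownames(indel) <- taxa
  rownames(pro) <- taxa
  list(taxa = taxa, protein = protein, indel = indel, pro = pro,
       spans = list(protein = protein_span,
                    indel = c(standard_span[1L], standard_span[1L] + 5L),
                    pro = c(standard_span[1L] + 6L, standard_span[2L])))
}
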