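#' Locate every cysteine in a peptide
#'
#' Only the literal residue `C` counts; ambiguity codes (X, B, Z) and
#' selenocysteine (U) are never treated as cysteine.
#'
#' @param record A [peptide_record].
#' @return An object of class `cysteine_profile` with fields `positions`
#'   (1-based, strictly increasing) and `count`.
#' @export
cysteine_profile <- function(record) {
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  pos <- which(chars == "C")
  structure(list(positions = pos, count = length(pos)),
            class = "cysteine_profile")
}

#' Scan for γ-core candidates (GXC / CXG)
#'
#' The γ-core of cysteine-containing defense peptides is an 8-16 residue
#' motif generally containing GXC (or its mirror CXG).  Every occurrence
#' of the tripattern is reported; choosing among candidates is left to the
#' array mapper.  The reported span is the window of up to 16 residues
#' centred on the tripattern and clipped to the sequence; windows clipped
#' below 8 residues are kept but flagged `truncated`.
#'
#' @param record A [peptide_record].
#' @param profile Optional precomputed [cysteine_profile()].
#' @return A list of `gamma_core_hit` objects, sorted by `core_cys`
#'   (the 1-based position of the motif cysteine).  Each hit has fields
#'   `span` (c(start, end)), `core_cys`, `orientation` ("GXC"/"CXG"),
#'   `kcxn` (TRUE when the residues from core_cys - 1 read K, C, x, N)
#'   and `truncated`.
#' @export
find_gamma_core <- function(record, profile = cysteine_profile(record)) {
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    orientation <- NULL
    if (chars[i] == "G" && chars[i + 2L] == "C") {
      orientation <- "GXC"
      core <- i + 2L
    } else if (chars[i] == "C" && chars[i + 2L] == "G") {
      orientation <- "CXG"
      core <- i
    }
    if (is.null(orientation)) next
    center <- i + 1L
    start <- max(1L, center - 7L)
    end <- min(n, center + 8L)
    kcxn <- core > 1L && core + 2L <= n &&
      chars[core - 1L] == "K" && chars[core] == "C" && chars[core + 2L] == "N"
    hits[[length(hits) + 1L]] <- structure(
      list(span = c(start, end), core_cys = core, orientation = orientation,
           kcxn = kcxn, truncated = (end - start + 1L) < 8L),
      class = "gamma_core_hit"
    )
  }
  hits[order(vapply(hits, `[[`, integer(1), "core_cys"))]
}

#' Length of the n-loop (residues between slots C2 and C3)
#'
#' The n-loop of insect-type defensins varies between 4 and 16 residues;
#' short n-loops co-occur with channel-toxin activity.
#'
#' @param mapping An [map_to_reference()] result.
#' @return Integer count of residues strictly between the residues
#'   assigned to C2 and C3, or `NA` when either slot is unassigned.
#' @export
n_loop_length <- function(mapping) {
  p2 <- mapping$assignment[["2"]]
  p3 <- mapping$assignment[["3"]]
  if (is.null(p2) || is.null(p3)) return(NA_integer_)
  p3 - p2 - 1L
}

#' Check the canonical CSH spacing
#'
#' The cysteine-stabilised helix motif has exactly three residues between
#' C3 and C4 and exactly one residue between C8 and C9.
#'
#' @param mapping An [map_to_reference()] result with slots 3, 4, 8 and 9
#'   assigned; anything else is an error (not a CSH-bearing mapping).
#' @return `TRUE` iff both spacings are canonical.
#' @export
csh_spacing_ok <- function(mapping) {
  a <- mapping$assignment
  need <- c("3", "4", "8", "9")
  if (!all(need %in% names(a))) {
    stop("not a CSH mapping: slot(s) ",
         paste(setdiff(need, names(a)), collapse = ", "), " unassigned")
  }
  (a[["4"]] - a[["3"]] - 1L) == 3L && (a[["9"]] - a[["8"]] - 1L) == 1L
}
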