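#' Render the box/spacer notation of an array mapping
#'
#' Occupied reference slots are drawn as filled boxes `[Cn]`, unoccupied
#' interior slots as empty boxes `[-n]`.  Between two consecutive occupied
#' slots the spacer token gives run lengths of non-cysteine residues as
#' decimal digits and extra (unslotted) cysteines as a literal `C`: a
#' region reading `CXXCC` is written `2C`, `CCXXCC` is `C2C`, `CXXCXC` is
#' `2C1`, and two adjacent slot cysteines yield `0`.  Flanking residues
#' (including terminal extra cysteines) are rendered with the same token
#' grammar before the first and after the last box.
#'
#' @param mapping An [map_to_reference()] result.
#' @return An object of class `notation_string` with fields `string`,
#'   `tokens` (named by slot pair, e.g. `"2_3"`), `flank_left` and
#'   `flank_right`.
#' @export
encode_notation <- function(mapping) {
  chars <- strsplit(mapping$sequence, "", fixed = TRUE)[[1]]
  slots <- sort(as.integer(names(mapping$assignment)))
  pos <- vapply(as.character(slots), function(s) mapping$assignment[[s]],
                integer(1))

  token_of <- function(region_chars) {
    if (!length(region_chars)) return("0")
    out <- character(0)
    run <- 0L
    for (ch in region_chars) {
      if (ch == "C") {
        if (run > 0L) out <- c(out, as.character(run))
        out <- c(out, "C")
        run <- 0L
      } else {
        run <- run + 1L
      }
    }
    if (run > 0L) out <- c(out, as.character(run))
    if (!length(out)) "0" else paste(out, collapse = "")
  }

  flank_left <- if (pos[1L] > 1L) token_of(chars[seq_len(pos[1L] - 1L)]) else ""
  if (flank_left == "0") flank_left <- ""
  nlast <- length(chars)
  flank_right <- if (pos[length(pos)] < nlast) {
    token_of(chars[(pos[length(pos)] + 1L):nlast])
  } else ""
  if (flank_right == "0") flank_right <- ""

  tokens <- character(0)
  pieces <- c(flank_left, sprintf("[C%d]", slots[1L]))
  if (length(slots) > 1L) {
    for (i in seq_len(length(slots) - 1L)) {
      a <- slots[i]; b <- slots[i + 1L]
      region <- if (pos[i + 1L] - pos[i] > 1L) {
        chars[(pos[i] + 1L):(pos[i + 1L] - 1L)]
      } else character(0)
      tok <- token_of(region)
      tokens[sprintf("%d_%d", a, b)] <- tok
      empties <- if (b - a > 1L) sprintf("[-%d]", (a + 1L):(b - 1L)) else
        character(0)
      pieces <- c(pieces, tok, empties, sprintf("[C%d]", b))
    }
  }
  pieces <- c(pieces, flank_right)
  structure(
    list(string = paste(pieces, collapse = ""), tokens = tokens,
         flank_left = flank_left, flank_right = flank_right),
    class = "notation_string"
  )
}

#' @export
print.notation_string <- function(x, ...) {
  cat(x$string, "\n")
  invisible(x)
}

#' @export
as.character.notation_string <- function(x, ...) x$string

#' Expand a spacer token back to its C/X pattern
#'
#' Exact inverse of the spacer-token grammar of [encode_notation()] for
#' the region between two boxed cysteines; the result is bracketed by the
#' two slot cysteines themselves.
#'
#' @param token A spacer token (digits and `C` only).
#' @return The C/X pattern text, e.g. `decode_notation("2C")` is
#'   `"CXXCC"`.
#' @export
decode_notation <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  if (grepl("[^0-9C]", token)) {
    stop("illegal character in notation token: ", token)
  }
  paste0("C", expand_token(token), "C")
}

## digits -> runs of X, literal C kept; "0" expands to "".
expand_token <- function(token) {
  if (!nzchar(token)) return("")
  parts <- regmatches(token, gregexpr("[0-9]+|C", token))[[1]]
  paste(vapply(parts, function(p) {
    if (p == "C") "C" else strrep("X", as.integer(p))
  }, character(1)), collapse = "")
}

#' Reconstruct the C/X pattern spanned by a notation string
#'
#' Expands a full [encode_notation()] result between its outermost boxes:
#' filled boxes become `C`, empty boxes vanish, and spacer tokens expand
#' per [decode_notation()].  Used to verify that notation encoding is
#' lossless at the C/X level.
#'
#' @param notation A `notation_string`.
#' @return C/X pattern text from the first to the last assigned slot.
#' @export
notation_to_pattern <- function(notation) {
  s <- notation$string
  if (nzchar(notation$flank_left)) {
    s <- substring(s, nchar(notation$flank_left) + 1L)
  }
  if (nzchar(notation$flank_right)) {
    s <- substring(s, 1L, nchar(s) - nchar(notation$flank_right))
  }
  parts <- regmatches(s, gregexpr("\\[C[0-9]+\\]|\\[-[0-9]+\\]|[0-9C]+", s))[[1]]
  paste(vapply(parts, function(p) {
    if (startsWith(p, "[C")) "C"
    else if (startsWith(p, "[-")) ""
    else expand_token(p)
  }, character(1)), collapse = "")
}
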