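#' Classify the cysteine-spacing family of a mapping
#'
#' A family label is assigned only when the occupied slot set matches a
#' template exactly.  The drosomycin/plant and long-chain scorpion-toxin
#' templates share the slot set \{1,2,3,4,6,8,9,10\} and are separated by
#' the length of the C9-C10 extension: long-chain toxins carry a long
#' C-terminal extension, drosomycin and plant defensins do not.
#' Mollusk defensins and myticins have nearly identical spacing and are
#' deliberately not distinguished (both report `mollusk_nematode_8`).
#'
#' @param mapping An [map_to_reference()] result.
#' @param long_extension_threshold Residues between C9 and C10 above which
#'   the shared 8-cysteine slot set is called `longchain_toxin` rather
#'   than `drosomycin_plant` (default 10).
#' @return An object of class `family_label` with fields `label` and
#'   `note`.
#' @export
classify_family <- function(mapping, long_extension_threshold = 10L) {
  stopifnot(long_extension_threshold > 0L)
  slots <- sort(as.integer(names(mapping$assignment)))
  templates <- family_templates()
  matches <- Filter(function(tpl) setequal(slots, tpl$slots), templates)

  if (length(matches) == 0L) {
    nearest <- nearest_template(mapping, templates)
    return(family_label("unassigned",
                        sprintf("no exact slot-set match; nearest template: %s",
                                nearest)))
  }

  labels <- vapply(matches, `[[`, character(1), "label")
  if (all(sort(labels) == c("drosomycin_plant", "longchain_toxin"))) {
    ext <- slot_position(mapping, 10L) - slot_position(mapping, 9L) - 1L
    if (ext > long_extension_threshold) {
      return(family_label("longchain_toxin",
                          sprintf("C9-C10 extension of %d residues (> %d)",
                                  ext, long_extension_threshold)))
    }
    return(family_label("drosomycin_plant",
                        sprintf("C9-C10 extension of %d residues (<= %d)",
                                ext, long_extension_threshold)))
  }

  label <- labels[[1L]]
  note <- switch(
    label,
    mollusk_nematode_8 =
      "myticins and mollusk defensins share this spacing and are not distinguished",
    mytilin_type = "mollusk/nematode 8-cysteine spacing with the GXC aligned to C7",
    ""
  )
  family_label(label, note)
}

family_label <- function(label, note = "") {
  structure(list(label = label, note = note), class = "family_label")
}

#' @export
print.family_label <- function(x, ...) {
  cat(sprintf("<family_label> %s%s\n", x$label,
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

## Template with the smallest deviation from this assignment (slot-set
## mismatch counts 2 per slot, spacings outside the canonical range count
## 1 per residue) -- used only for the confidence note.
nearest_template <- function(mapping, templates = family_templates()) {
  slots <- sort(as.integer(names(mapping$assignment)))
  devs <- vapply(templates, function(tpl) {
    dev <- 2 * length(c(setdiff(slots, tpl$slots), setdiff(tpl$slots, slots)))
    for (rn in names(tpl$regions)) {
      ab <- as.integer(strsplit(rn, "_", fixed = TRUE)[[1]])
      pa <- slot_position(mapping, ab[1L])
      pb <- slot_position(mapping, ab[2L])
      if (is.na(pa) || is.na(pb)) next
      sp <- pb - pa - 1L
      rng <- tpl$regions[[rn]]
      dev <- dev + max(0, rng[1L] - sp, sp - rng[2L])
    }
    dev
  }, numeric(1))
  names(templates)[which.min(devs)]
}

#' Infer disulfide bonds from the family template
#'
#' Bond inference is homology-based only: the family template contributes
#' its bond list with status `inferred`; assigned slots left unpaired and
#' all extra cysteines are reported with status `unknown` (extras are
#' paired with each other when exactly two are present, mirroring how a
#' theromacin-like extra pair is described).  Experimentally verified
#' bonds supplied by the user upgrade matching pairs to `verified`.
#'
#' @param mapping An [map_to_reference()] result.
#' @param family A [classify_family()] result.
#' @param verified Optional list of integer pairs `c(i, j)` of reference
#'   slots whose bond is experimentally verified.
#' @return An object of class `bond_set`: a data frame `bonds` with
#'   columns `a`, `b`, `status`, plus `unpaired` (labels of cysteines
#'   with no partner).
#' @export
infer_bonds <- function(mapping, family, verified = NULL) {
  slots <- sort(as.integer(names(mapping$assignment)))
  templates <- family_templates()
  tpl_bonds <- if (family$label %in% names(templates)) {
    templates[[family$label]]$bonds
  } else {
    list()
  }

  a <- character(0); b <- character(0); status <- character(0)
  bonded_slots <- integer(0)
  for (bd in tpl_bonds) {
    if (!all(bd %in% slots)) {
      stop("template/assignment mismatch: bond C", bd[1L], "-C", bd[2L],
           " references an unassigned slot")
    }
    st <- "inferred"
    if (!is.null(verified) &&
        any(vapply(verified, function(v) all(sort(v) == bd), logical(1)))) {
      st <- "verified"
    }
    a <- c(a, sprintf("C%d", bd[1L]))
    b <- c(b, sprintf("C%d", bd[2L]))
    status <- c(status, st)
    bonded_slots <- c(bonded_slots, bd)
  }

  unpaired <- sprintf("C%d", setdiff(slots, bonded_slots))
  extras <- mapping$extras$label
  if (length(extras) == 2L) {
    a <- c(a, extras[1L]); b <- c(b, extras[2L])
    status <- c(status, "unknown")
  } else {
    unpaired <- c(unpaired, extras)
  }

  structure(
    list(bonds = data.frame(a = a, b = b, status = status,
                            stringsAsFactors = FALSE),
         unpaired = unpaired),
    class = "bond_set"
  )
}

#' Render a bond set as descriptive text
#'
#' Experimentally verified bonds are written bare (`C2–C6`); bonds
#' inferred from homology, bonds of unknown status and unpaired cysteines
#' are grouped in parentheses.  The fold bonds are listed in the
#' conventional order C2–C6, C3–C8, C4–C9 first, then the remaining slot
#' pairs by first slot, then extra-cysteine pairs and unpaired cysteines.
#'
#' @param bondset An [infer_bonds()] result.
#' @return A single character string (empty for an empty bond set).
#' @export
describe_bonds <- function(bondset) {
  bonds <- bondset$bonds
  if (nrow(bonds)) {
    bonds <- bonds[order(bond_rank(bonds$a, bonds$b)), , drop = FALSE]
  }
  fmt <- function(rows) sprintf("%s–%s", rows$a, rows$b)
  verified <- fmt(bonds[bonds$status == "verified", , drop = FALSE])
  grouped <- c(fmt(bonds[bonds$status != "verified", , drop = FALSE]),
               bondset$unpaired)
  parts <- character(0)
  if (length(verified)) parts <- c(parts, paste(verified, collapse = ", "))
  if (length(grouped)) {
    parts <- c(parts, paste0("(", paste(grouped, collapse = ", "), ")"))
  }
  paste(parts, collapse = ", ")
}

## Fold bonds first in the order the array is read (C2-C6, C3-C8, C4-C9),
## then remaining slot pairs by first slot, then extra-cysteine entries.
bond_rank <- function(a, b) {
  key <- paste(a, b)
  core <- match(key, c("C2 C6", "C3 C8", "C4 C9"))
  slot_a <- suppressWarnings(as.integer(sub("^C([0-9]+)$", "\\1", a)))
  ifelse(!is.na(core), core,
         ifelse(!is.na(slot_a), 10L + slot_a, 100L))
}

#' Heuristic channel-toxin flag (KCXN in the γ-core plus a short n-loop)
#'
#' Defensin-fold peptides carrying the motif K-C-x-N around the slot-6
#' cysteine of the γ-core are likely to act as channel toxins when the
#' n-loop is short enough to avoid steric hindrance.  This is a sequence
#' heuristic only, never an activity claim.
#'
#' @param mapping An [map_to_reference()] result.
#' @param gamma_hit The γ-core hit anchored at slot 6 (defaults to the
#'   hit used by the mapper).
#' @param short_nloop_threshold Maximum n-loop length considered "short"
#'   (default 6 residues).
#' @return `TRUE`/`FALSE`; `FALSE` whenever slot 6 is unanchored or the
#'   n-loop length is undefined.
#' @export
toxin_flag <- function(mapping, gamma_hit = mapping$anchor_hit,
                       short_nloop_threshold = 6L) {
  stopifnot(short_nloop_threshold > 0L)
  p6 <- slot_position(mapping, 6L)
  if (is.na(p6) || is.null(gamma_hit)) return(FALSE)
  if (gamma_hit$core_cys != p6) return(FALSE)
  nl <- n_loop_length(mapping)
  isTRUE(gamma_hit$kcxn) && !is.na(nl) && nl <= short_nloop_threshold
}
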