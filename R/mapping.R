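#' Assign observed cysteines to reference slots C1-C10
#'
#' Performs an exhaustive, deterministic search over all order-preserving
#' assignments of the observed cysteines to the ten reference slots
#' (allowing up to two unslotted "extra" cysteines) and returns the
#' assignment maximising a fixed score:
#'
#' * +8 when a γ-core cysteine is anchored at slot 6 (or slot 7 under the
#'   mytilin exception, see below);
#' * +4 for each canonical CSH spacing (exactly 3 residues between C3/C4,
#'   exactly 1 between C8/C9);
#' * +3 when the occupied slot set matches a family template exactly;
#' * -1 per residue of deviation from the closest template's canonical
#'   region-length ranges (plus 2 per slot of slot-set mismatch);
#' * -2 per extra (unslotted) cysteine.
#'
#' Ties are broken by preferring an exact template match, then minimal
#' template deviation, then the leftmost (lexicographically smallest)
#' slot assignment.
#'
#' Mytilin exception: mytilins align their GXC with C7 of the reference
#' array instead of C6.  Whenever a γ-core is present, the slot-7
#' anchoring is also evaluated, and it replaces the slot-6 result only
#' when it is an exact, deviation-free template fit with intact CSH
#' spacings, anchors a γ-core cysteine at slot 7, and strictly outscores
#' the slot-6 reading.
#'
#' @param record A [peptide_record].
#' @param profile Optional precomputed [cysteine_profile()].
#' @param gamma_hits Optional precomputed [find_gamma_core()] result.
#' @param mytilin_exception Allow γ-core anchoring at slot 7 (default TRUE).
#' @return An object of class `array_mapping` with fields `id`,
#'   `sequence`, `assignment` (named list, slot -> 1-based residue
#'   position), `extras` (data frame with `label`, `position`),
#'   `anchor_used` (6, 7 or NA), `score`, and `csh_violations`.
#' @export
map_to_reference <- function(record, profile = cysteine_profile(record),
                             gamma_hits = find_gamma_core(record, profile),
                             mytilin_exception = TRUE) {
  k <- profile$count
  if (k < 2L) {
    stop("record ", record$id, ": not a candidate CS-αβ sequence ",
         "(fewer than 2 cysteines)")
  }
  if (k > 12L) {
    stop("record ", record$id, ": ", k, " cysteines exceeds the modeled ",
         "superfamily envelope (<= 12); map manually or split the sequence")
  }
  gamma_pos <- vapply(gamma_hits, `[[`, integer(1), "core_cys")

  pass6 <- best_assignment(profile$positions, gamma_pos, anchor_slot = 6L)
  best <- pass6
  anchor_slot <- 6L
  if (mytilin_exception && length(gamma_pos)) {
    pass7 <- best_assignment(profile$positions, gamma_pos, anchor_slot = 7L)
    p7 <- pass7$positions[match(7L, pass7$slots)]
    if (pass7$csh_violations == 0L && pass7$tmatch && pass7$devmin == 0 &&
        !is.na(p7) && p7 %in% gamma_pos && pass7$score > pass6$score) {
      best <- pass7
      anchor_slot <- 7L
    }
  }

  assignment <- as.list(best$positions)
  names(assignment) <- as.character(best$slots)
  extras <- extras_frame(profile$positions, best$positions, best$slots)

  anchor_used <- NA_integer_
  anchor_hit <- NULL
  for (s in c(anchor_slot, setdiff(c(6L, 7L), anchor_slot))) {
    p <- assignment[[as.character(s)]]
    if (!is.null(p) && p %in% gamma_pos) {
      anchor_used <- s
      anchor_hit <- gamma_hits[[match(p, gamma_pos)]]
      break
    }
  }

  structure(
    list(
      id = record$id,
      sequence = record$sequence,
      assignment = assignment,
      extras = extras,
      anchor_used = anchor_used,
      anchor_hit = anchor_hit,
      score = best$score,
      csh_violations = best$csh_violations
    ),
    class = "array_mapping"
  )
}

#' Residue position assigned to a reference slot
#'
#' @param mapping An `array_mapping`.
#' @param slot Slot number 1-10.
#' @return 1-based residue position, or `NA` when unassigned.
#' @export
slot_position <- function(mapping, slot) {
  p <- mapping$assignment[[as.character(slot)]]
  if (is.null(p)) NA_integer_ else p
}

#' @export
print.array_mapping <- function(x, ...) {
  cat(sprintf("<array_mapping> %s: slots {%s}", x$id,
              paste(names(x$assignment), collapse = ",")))
  if (nrow(x$extras)) {
    cat(" + extras", paste(x$extras$label, collapse = ","))
  }
  cat("\n")
  invisible(x)
}

## Exhaustive vectorised search over (extras choice) x (slot subset).
## Enumeration order is deterministic: extras count ascending, extras
## combination in combn order, slot subsets in combn order; this order is
## the final tie-break ("leftmost" slot sets come first in combn order).
best_assignment <- function(positions, gamma_pos, anchor_slot) {
  k <- length(positions)
  templates <- family_templates()
  cum <- upper.tri(matrix(1L, 10L, 10L), diag = TRUE) * 1L

  best <- NULL
  for (e in max(0L, k - 10L):min(2L, k - 2L)) {
    m <- k - e
    if (m < 2L || m > 10L) next
    extra_sets <- if (e == 0L) matrix(integer(0), nrow = 0L, ncol = 1L) else
      utils::combn(k, e)
    for (ec in seq_len(ncol(extra_sets))) {
      keep <- if (e == 0L) seq_len(k) else setdiff(seq_len(k), extra_sets[, ec])
      p <- positions[keep]
      subsets <- utils::combn(10L, m)
      sc <- score_subsets(p, subsets, gamma_pos, templates, anchor_slot, cum)
      sc$score <- sc$score - 2 * e
      ord <- order(-sc$score, -sc$tmatch, sc$devmin, seq_along(sc$score))
      j <- ord[1L]
      cand <- list(
        slots = subsets[, j], positions = p, score = sc$score[j],
        tmatch = sc$tmatch[j], devmin = sc$devmin[j],
        csh_violations = sc$viol[j]
      )
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$tmatch > best$tmatch) ||
          (cand$score == best$score && cand$tmatch == best$tmatch &&
           cand$devmin < best$devmin)) {
        best <- cand
      }
    }
  }
  best
}

## Vectorised scoring of all m-subsets of slots for fixed slotted positions.
score_subsets <- function(p, subsets, gamma_pos, templates, anchor_slot, cum) {
  m <- nrow(subsets)
  C <- ncol(subsets)
  M <- matrix(FALSE, C, 10L)
  M[cbind(rep(seq_len(C), each = m), as.vector(subsets))] <- TRUE
  idx <- (M * 1L) %*% cum              # idx[c, a] = rank of slot a in subset c
  P <- matrix(p[pmax(idx, 1L)], C, 10L)
  P[!M] <- NA_integer_

  spacing <- function(a, b) P[, b] - P[, a] - 1L

  bonus <- ifelse(M[, anchor_slot] & P[, anchor_slot] %in% gamma_pos, 8, 0)
  sp34 <- spacing(3L, 4L)
  sp89 <- spacing(8L, 9L)
  b34 <- ifelse(!is.na(sp34) & sp34 == 3L, 4, 0)
  b89 <- ifelse(!is.na(sp89) & sp89 == 1L, 4, 0)
  viol <- ifelse(is.na(sp34) | sp34 != 3L, 1L, 0L) +
    ifelse(is.na(sp89) | sp89 != 1L, 1L, 0L)

  tbest <- rep(-Inf, C)
  devmin <- rep(Inf, C)
  tmatch <- rep(FALSE, C)
  for (tpl in templates) {
    sT <- as.numeric(seq_len(10L) %in% tpl$slots)
    inter <- as.vector((M * 1L) %*% sT)
    dev <- 2 * (sum(sT) + m - 2 * inter)
    for (rn in names(tpl$regions)) {
      ab <- as.integer(strsplit(rn, "_", fixed = TRUE)[[1]])
      sp <- spacing(ab[1L], ab[2L])
      lo <- tpl$regions[[rn]][1L]
      hi <- tpl$regions[[rn]][2L]
      d <- pmax(0, lo - sp, sp - hi)
      d[is.na(d)] <- 0
      dev <- dev + d
    }
    eq <- (sum(sT) == m) & inter == m   # slot sets identical
    tsc <- 3 * eq - dev
    tbest <- pmax(tbest, tsc)
    devmin <- pmin(devmin, dev)
    tmatch <- tmatch | eq
  }

  list(score = bonus + b34 + b89 + tbest,
       tmatch = tmatch, devmin = devmin, viol = viol)
}

## Label cysteines left out of the slot assignment: C^i/j^ between assigned
## slots i and j, C^/s^ before the first assigned slot, C^s/^ after the last.
extras_frame <- function(all_pos, slotted_pos, slots) {
  extra_pos <- setdiff(all_pos, slotted_pos)
  if (!length(extra_pos)) {
    return(data.frame(label = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  }
  labels <- vapply(extra_pos, function(q) {
    before <- slots[slotted_pos < q]
    after <- slots[slotted_pos > q]
    if (!length(before)) {
      sprintf("C^/%d^", min(after))
    } else if (!length(after)) {
      sprintf("C^%d/^", max(before))
    } else {
      sprintf("C^%d/%d^", max(before), min(after))
    }
  }, character(1))
  data.frame(label = labels, position = extra_pos, stringsAsFactors = FALSE)
}
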