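#' Generate synthetic CS-αβ-like peptides for a family template
#'
#' Builds peptides whose cysteines sit exactly at template-implied
#' positions: region lengths between consecutive occupied slots are drawn
#' uniformly from the template's canonical ranges (the CSH spacings are
#' fixed at 3 and 1), all non-cysteine positions are drawn uniformly from
#' the 19 non-cysteine standard residues, and a γ-core is planted as
#' G-x-C ending at the slot-6 cysteine (slot 7 for the mytilin-type
#' template; the CSH-only template has no slot-6 cysteine and carries no
#' planted γ-core, matching its AdDLP-like archetype).  Generation is
#' bit-for-bit reproducible for a given (family, n, seed).
#'
#' @param family One of [family_template_names()].
#' @param n Number of records (>= 1).
#' @param seed Integer seed; all randomness is local to this call.
#' @param regions Named list overriding region length ranges, e.g.
#'   `list("2_3" = c(4, 4))` to force an n-loop of 4.
#' @param flank_range,tail_range Ranges for residues before the first /
#'   after the last occupied slot.
#' @param plant_gamma Plant the γ-core tripattern (default: whenever the
#'   template has a γ-core slot).
#' @param plant_kcxn Additionally plant K before and N two after the
#'   γ-core cysteine (the channel-toxin heuristic motif).
#' @param extras Number of extra cysteines substituted at random
#'   unprotected positions (default 0).
#' @param prop_n,prop_c Propeptide flags for all records (`"present"`,
#'   `"absent"`, `"unknown"`, or `"random"`).
#' @return List of [peptide_record]s; each carries attributes `family`
#'   (the generating label) and `protected` (positions [perturb()] must
#'   not touch).
#' @export
generate_family <- function(family, n, seed, regions = NULL,
                            flank_range = c(1, 6), tail_range = c(0, 6),
                            plant_gamma = NULL, plant_kcxn = FALSE,
                            extras = 0L,
                            prop_n = "unknown", prop_c = "unknown") {
  templates <- family_templates()
  if (!family %in% names(templates)) {
    stop("unknown template '", family, "'; valid templates: ",
         paste(names(templates), collapse = ", "))
  }
  stopifnot(n >= 1L)
  tpl <- templates[[family]]
  ranges <- tpl$regions
  for (rn in names(regions)) {
    if (!rn %in% names(ranges)) {
      stop("region ", rn, " is not part of the ", family, " template")
    }
    ranges[[rn]] <- regions[[rn]]
  }
  if (any(vapply(ranges, min, numeric(1)) < 0) || min(flank_range) < 0 ||
      min(tail_range) < 0) {
    stop("region ranges must be non-negative")
  }
  if (is.null(plant_gamma)) plant_gamma <- !is.na(tpl$gamma_slot)
  if (plant_gamma && is.na(tpl$gamma_slot)) {
    stop("template ", family, " has no γ-core slot to plant into")
  }

  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      build_synthetic(tpl, ranges, flank_range, tail_range, plant_gamma,
                      plant_kcxn, extras, prop_n, prop_c,
                      id = sprintf("%s_%03d", family, i))
    })
  })
}

rand_len <- function(range) {
  lo <- as.integer(range[1L]); hi <- as.integer(range[2L])
  if (hi < lo) stop("infeasible region range: ", lo, "-", hi)
  if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

rand_flag <- function(v) {
  if (identical(v, "random")) {
    sample(c("present", "absent", "unknown"), 1L)
  } else v
}

build_synthetic <- function(tpl, ranges, flank_range, tail_range,
                            plant_gamma, plant_kcxn, extras, prop_n, prop_c,
                            id) {
  slots <- tpl$slots
  flank <- rand_len(flank_range)
  seg <- vapply(seq_len(length(slots) - 1L), function(i) {
    rn <- sprintf("%d_%d", slots[i], slots[i + 1L])
    rand_len(ranges[[rn]])
  }, integer(1))
  tail_len <- rand_len(tail_range)

  total <- flank + length(slots) + sum(seg) + tail_len
  chars <- sample(AA_NONCYS, total, replace = TRUE)
  pos <- flank + 1L + cumsum(c(0L, seg + 1L))   # cysteine positions
  chars[pos] <- "C"

  protected <- pos
  if (plant_gamma) {
    g_at <- pos[match(tpl$gamma_slot, slots)]
    chars[g_at - 2L] <- "G"
    protected <- c(protected, g_at - 2L)
    if (plant_kcxn) {
      chars[g_at - 1L] <- "K"
      chars[g_at + 2L] <- "N"
      protected <- c(protected, g_at - 1L, g_at + 2L)
    }
  }
  if (extras > 0L) {
    free <- setdiff(seq_len(total), protected)
    extra_at <- sort(sample(free, extras))
    chars[extra_at] <- "C"
  }

  rec <- peptide_record(
    id, paste(chars, collapse = ""),
    description = paste("synthetic", tpl$label),
    has_n_propeptide = rand_flag(prop_n),
    has_c_propeptide = rand_flag(prop_c)
  )
  attr(rec, "family") <- tpl$label
  attr(rec, "protected") <- sort(unique(protected))
  rec
}

#' Randomly substitute non-anchor residues
#'
#' Each position that is neither a cysteine nor a planted γ-core anchor
#' is substituted independently with the given probability, always to a
#' different non-cysteine residue (so no cysteines are created or
#' destroyed and the planted motifs survive).
#'
#' @param records List of [peptide_record]s (typically from
#'   [generate_family()]).
#' @param rate Per-position substitution probability in \[0, 1\].
#' @param seed Integer seed; randomness is local to this call.
#' @return The perturbed records (attributes preserved).
#' @export
perturb <- function(records, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  withr::with_seed(seed, {
    lapply(records, function(rec) {
      chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
      protected <- union(which(chars == "C"),
                         attr(rec, "protected") %||% integer(0))
      free <- setdiff(seq_along(chars), protected)
      hit <- free[stats::runif(length(free)) < rate]
      for (i in hit) {
        chars[i] <- sample(setdiff(AA_NONCYS, chars[i]), 1L)
      }
      out <- rec
      out$sequence <- paste(chars, collapse = "")
      out
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
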