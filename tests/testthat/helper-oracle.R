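# Independent brute-force slot-assignment oracle.
#
# Re-implements the published scoring with plain nested loops and scalar
# arithmetic (no shared search code with csabref::map_to_reference, which
# uses a vectorised enumeration).  Both routes share only the family
# template table, which is part of the score's definition.

oracle_score_one <- function(p, slots, n_extras, gamma_pos, anchor_slot,
                             templates) {
  pos_of <- function(s) {
    i <- match(s, slots)
    if (is.na(i)) NA_integer_ else p[i]
  }
  spacing <- function(a, b) {
    pa <- pos_of(a); pb <- pos_of(b)
    if (is.na(pa) || is.na(pb)) NA_integer_ else pb - pa - 1L
  }
  bonus <- 0
  pa <- pos_of(anchor_slot)
  if (!is.na(pa) && pa %in% gamma_pos) bonus <- 8
  sp34 <- spacing(3L, 4L)
  sp89 <- spacing(8L, 9L)
  b34 <- if (!is.na(sp34) && sp34 == 3L) 4 else 0
  b89 <- if (!is.na(sp89) && sp89 == 1L) 4 else 0
  viol <- (is.na(sp34) || sp34 != 3L) + (is.na(sp89) || sp89 != 1L)

  tbest <- -Inf; devmin <- Inf; tmatch <- FALSE
  for (tpl in templates) {
    dev <- 2 * length(c(setdiff(slots, tpl$slots),
                        setdiff(tpl$slots, slots)))
    for (rn in names(tpl$regions)) {
      ab <- as.integer(strsplit(rn, "_", fixed = TRUE)[[1]])
      sp <- spacing(ab[1L], ab[2L])
      if (is.na(sp)) next
      rng <- tpl$regions[[rn]]
      dev <- dev + max(0, rng[1L] - sp, sp - rng[2L])
    }
    eq <- setequal(slots, tpl$slots)
    tbest <- max(tbest, 3 * eq - dev)
    devmin <- min(devmin, dev)
    tmatch <- tmatch || eq
  }
  list(score = bonus + b34 + b89 + tbest - 2 * n_extras,
       tmatch = tmatch, devmin = devmin, viol = viol)
}

oracle_best <- function(positions, gamma_pos, anchor_slot) {
  k <- length(positions)
  templates <- csabref:::family_templates()
  best <- NULL
  for (e in max(0L, k - 10L):min(2L, k - 2L)) {
    m <- k - e
    if (m < 2L || m > 10L) next
    extra_sets <- if (e == 0L) list(integer(0)) else
      asplit(utils::combn(k, e), 2L)
    for (ex in extra_sets) {
      p <- positions[setdiff(seq_len(k), ex)]
      subsets <- utils::combn(10L, m)
      for (j in seq_len(ncol(subsets))) {
        sc <- oracle_score_one(p, subsets[, j], e, gamma_pos, anchor_slot,
                               templates)
        cand <- list(slots = subsets[, j], positions = p,
                     score = sc$score, tmatch = sc$tmatch,
                     devmin = sc$devmin, viol = sc$viol)
        if (is.null(best) ||
            cand$score > best$score ||
            (cand$score == best$score && cand$tmatch > best$tmatch) ||
            (cand$score == best$score && cand$tmatch == best$tmatch &&
             cand$devmin < best$devmin)) {
          best <- cand
        }
      }
    }
  }
  best
}

oracle_map <- function(record, mytilin_exception = TRUE) {
  profile <- cysteine_profile(record)
  gamma_pos <- vapply(find_gamma_core(record, profile), `[[`, integer(1),
                      "core_cys")
  pass6 <- oracle_best(profile$positions, gamma_pos, 6L)
  best <- pass6
  if (mytilin_exception && length(gamma_pos)) {
    pass7 <- oracle_best(profile$positions, gamma_pos, 7L)
    p7 <- pass7$positions[match(7L, pass7$slots)]
    if (pass7$viol == 0L && pass7$tmatch && pass7$devmin == 0 &&
        !is.na(p7) && p7 %in% gamma_pos && pass7$score > pass6$score) {
      best <- pass7
    }
  }
  stats::setNames(as.list(best$positions), as.character(best$slots))
}
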