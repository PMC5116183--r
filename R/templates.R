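## Family templates for the CS-αβ superfamily.
##
## Each template fixes the set of occupied reference slots, the canonical
## range of residues between consecutive occupied slots, where the γ-core
## cysteine sits (slot 6, or slot 7 for the mytilin-type spacing), and the
## homology-inferred disulfide pairing.  The CSH spacings (3 residues
## between C3/C4, 1 between C8/C9) are fixed; the remaining ranges are the
## package's reading of the family envelopes (e.g. insect n-loop 4-16,
## long-chain toxins with a long C9-C10 extension) and are shared by the
## synthetic generator and the slot-assignment score.

family_templates <- function() {
  tpl <- function(label, slots, regions, gamma_slot, bonds) {
    list(label = label, slots = slots, regions = regions,
         gamma_slot = gamma_slot, bonds = bonds)
  }
  csh <- list("3_4" = c(3, 3), "8_9" = c(1, 1))
  list(
    csh_only = tpl(
      "csh_only", c(3L, 4L, 8L, 9L),
      c(csh, list("4_8" = c(6, 14))),
      NA_integer_,
      list(c(3L, 8L), c(4L, 9L))
    ),
    insect_type = tpl(
      "insect_type", c(2L, 3L, 4L, 6L, 8L, 9L),
      c(csh, list("2_3" = c(4, 16), "4_6" = c(4, 12), "6_8" = c(3, 10))),
      6L,
      list(c(2L, 6L), c(3L, 8L), c(4L, 9L))
    ),
    asabf_6cys = tpl(
      "asabf_6cys", c(3L, 4L, 5L, 6L, 8L, 9L),
      c(csh, list("4_5" = c(4, 12), "5_6" = c(2, 4), "6_8" = c(3, 10))),
      6L,
      list(c(3L, 8L), c(4L, 9L))
    ),
    mollusk_nematode_8 = tpl(
      "mollusk_nematode_8", c(2L, 3L, 4L, 5L, 6L, 8L, 9L, 10L),
      c(csh, list("2_3" = c(4, 18), "4_5" = c(4, 12), "5_6" = c(2, 4),
                  "6_8" = c(3, 10), "9_10" = c(0, 6))),
      6L,
      list(c(2L, 6L), c(3L, 8L), c(4L, 9L), c(5L, 10L))
    ),
    mytilin_type = tpl(
      "mytilin_type", c(2L, 3L, 4L, 5L, 7L, 8L, 9L, 10L),
      c(csh, list("2_3" = c(4, 18), "4_5" = c(4, 12), "5_7" = c(6, 10),
                  "7_8" = c(2, 6), "9_10" = c(0, 6))),
      7L,
      list(c(2L, 7L), c(3L, 8L), c(4L, 9L), c(5L, 10L))
    ),
    drosomycin_plant = tpl(
      "drosomycin_plant", c(1L, 2L, 3L, 4L, 6L, 8L, 9L, 10L),
      c(csh, list("1_2" = c(1, 6), "2_3" = c(4, 16), "4_6" = c(4, 12),
                  "6_8" = c(3, 10), "9_10" = c(0, 8))),
      6L,
      list(c(2L, 6L), c(3L, 8L), c(4L, 9L), c(1L, 10L))
    ),
    longchain_toxin = tpl(
      "longchain_toxin", c(1L, 2L, 3L, 4L, 6L, 8L, 9L, 10L),
      c(csh, list("1_2" = c(1, 6), "2_3" = c(4, 16), "4_6" = c(4, 12),
                  "6_8" = c(3, 10), "9_10" = c(12, 30))),
      6L,
      list(c(2L, 6L), c(3L, 8L), c(4L, 9L), c(1L, 10L))
    ),
    macin_8 = tpl(
      "macin_8", c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L),
      c(csh, list("1_2" = c(1, 6), "2_3" = c(4, 18), "4_6" = c(4, 12),
                  "6_7" = c(2, 6), "7_8" = c(2, 8))),
      6L,
      list(c(2L, 6L), c(3L, 8L), c(4L, 9L), c(1L, 7L))
    ),
    macin_10 = tpl(
      "macin_10", 1:10,
      c(csh, list("1_2" = c(1, 6), "2_3" = c(4, 18), "4_5" = c(4, 12),
                  "5_6" = c(2, 4), "6_7" = c(2, 6), "7_8" = c(2, 8),
                  "9_10" = c(0, 8))),
      6L,
      list(c(2L, 6L), c(3L, 8L), c(4L, 9L), c(1L, 7L), c(5L, 10L))
    )
  )
}

#' Names of the built-in family templates
#'
#' @return Character vector of template labels accepted by
#'   [generate_family()] and reported by [classify_family()].
#' @export
family_template_names <- function() {
  names(family_templates())
}
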