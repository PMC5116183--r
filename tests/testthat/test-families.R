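test_that("slot sets classify to their families", {
  lab <- function(rec, ...) classify_family(map_to_reference(rec), ...)$label

  expect_equal(lab(generate_family("insect_type", 1, seed = 1)[[1]]),
               "insect_type")
  expect_equal(lab(generate_family("mollusk_nematode_8", 1, seed = 1)[[1]]),
               "mollusk_nematode_8")
  expect_equal(lab(generate_family("macin_8", 1, seed = 1)[[1]]), "macin_8")
  expect_equal(lab(generate_family("csh_only", 1, seed = 1)[[1]]),
               "csh_only")
})

test_that("the C9-C10 extension separates long-chain toxins from drosomycin", {
  long <- generate_family("longchain_toxin", 1, seed = 2,
                          regions = list("9_10" = c(30, 30)))[[1]]
  expect_equal(classify_family(map_to_reference(long))$label,
               "longchain_toxin")

  dros <- generate_family("drosomycin_plant", 1, seed = 2,
                          regions = list("9_10" = c(4, 4)))[[1]]
  expect_equal(classify_family(map_to_reference(dros))$label,
               "drosomycin_plant")

  # threshold is configurable
  expect_equal(
    classify_family(map_to_reference(long),
                    long_extension_threshold = 40L)$label,
    "drosomycin_plant")
})

test_that("non-template slot sets report unassigned with the nearest family", {
  # insect-like but with a grossly stretched C3-C4 spacing: no template fits
  m <- manual_mapping(paste0("A", "C", strrep("A", 6), "C", strrep("A", 9),
                             "C", strrep("A", 5), "C", strrep("A", 4),
                             "C", "A", "C", "AA"),
                      slots = c(2, 3, 4, 6, 8, 9),
                      positions = c(2, 9, 19, 25, 30, 32))
  fam <- classify_family(m)
  # slot set matches the insect template exactly, so it still classifies
  expect_equal(fam$label, "insect_type")

  m2 <- manual_mapping("CAAAACAAAC", slots = c(1, 2, 10),
                       positions = c(1, 6, 10))
  fam2 <- classify_family(m2)
  expect_equal(fam2$label, "unassigned")
  expect_match(fam2$note, "nearest template")
})

test_that("family templates force their bond counts and pairs", {
  bonds_for <- function(family, seed = 3) {
    rec <- generate_family(family, 1, seed = seed)[[1]]
    m <- map_to_reference(rec)
    infer_bonds(m, classify_family(m))
  }
  pair_strings <- function(bs) paste(bs$bonds$a, bs$bonds$b, sep = "-")

  ins <- bonds_for("insect_type")
  expect_equal(pair_strings(ins), c("C2-C6", "C3-C8", "C4-C9"))
  expect_true(all(ins$bonds$status == "inferred"))

  mac <- bonds_for("macin_10")
  expect_setequal(pair_strings(mac),
                  c("C2-C6", "C3-C8", "C4-C9", "C1-C7", "C5-C10"))
  expect_equal(nrow(mac$bonds), 5L)  # full ten-slot mapping: five bonds

  csh <- bonds_for("csh_only")
  expect_setequal(pair_strings(csh), c("C3-C8", "C4-C9"))

  abf <- bonds_for("mollusk_nematode_8")
  expect_setequal(pair_strings(abf),
                  c("C2-C6", "C3-C8", "C4-C9", "C5-C10"))
})

test_that("bond descriptions follow the parenthesis grammar", {
  rec <- generate_family("macin_10", 1, seed = 4)[[1]]
  m <- map_to_reference(rec)
  fam <- classify_family(m)
  expect_equal(describe_bonds(infer_bonds(m, fam)),
               "(C2–C6, C3–C8, C4–C9, C1–C7, C5–C10)")

  # experimentally verified bonds are written bare, before the parentheses
  bs <- infer_bonds(m, fam, verified = list(c(3, 8), c(4, 9)))
  expect_equal(describe_bonds(bs),
               "C3–C8, C4–C9, (C2–C6, C1–C7, C5–C10)")

  # empty bond set
  expect_equal(describe_bonds(list(bonds = data.frame(
    a = character(0), b = character(0), status = character(0)),
    unpaired = character(0))), "")
})

test_that("an extra-cysteine pair is described with slot-interval names", {
  rec <- generate_family("macin_10", 1, seed = 51,
                         regions = list("3_4" = c(3, 3)),
                         tail_range = c(10, 10))[[1]]
  chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
  pos <- which(chars == "C")
  chars[pos[3] + 1L] <- "C"
  chars[length(chars)] <- "C"
  rec$sequence <- paste(chars, collapse = "")
  m <- map_to_reference(rec)
  txt <- describe_bonds(infer_bonds(m, classify_family(m)))
  expect_match(txt, "C^3/4^–C^10/^", fixed = TRUE)
  expect_match(txt, "^\\(C2–C6, C3–C8, C4–C9, C1–C7, C5–C10")
})

test_that("the channel-toxin heuristic needs KCXN and a short n-loop", {
  kcxn_short <- generate_family("insect_type", 1, seed = 5,
                                regions = list("2_3" = c(4, 4)),
                                plant_kcxn = TRUE)[[1]]
  expect_true(toxin_flag(map_to_reference(kcxn_short)))

  plain_short <- generate_family("insect_type", 1, seed = 5,
                                 regions = list("2_3" = c(4, 4)))[[1]]
  expect_false(toxin_flag(map_to_reference(plain_short)))

  kcxn_long <- generate_family("insect_type", 1, seed = 5,
                               regions = list("2_3" = c(16, 16)),
                               plant_kcxn = TRUE)[[1]]
  m <- map_to_reference(kcxn_long)
  expect_false(toxin_flag(m))
  expect_true(toxin_flag(m, short_nloop_threshold = 16L))  # configurable
})
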