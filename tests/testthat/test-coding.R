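coded_fixture <- function(records) {
  mappings <- lapply(records, map_to_reference)
  aln <- build_anchored_alignment(mappings)
  indel <- lapply(aln$mappings, code_indels, alignment = aln)
  pro <- lapply(records, code_propeptides)
  names(pro) <- vapply(records, `[[`, "", "id")
  build_matrix(aln, indel, pro)
}

test_that("indel codes follow the ancestral-reference rule per area", {
  recs <- list(
    generate_family("insect_type", 1, seed = 15,
                    flank_range = c(3, 3))[[1]],     # area 1: 3 aa -> 1
    generate_family("insect_type", 1, seed = 16,
                    tail_range = c(12, 12))[[1]]     # area 6: 12 aa -> 2
  )
  recs[[1]]$id <- "flank3"
  recs[[2]]$id <- "tail12"
  mappings <- lapply(recs, map_to_reference)
  aln <- build_anchored_alignment(mappings)
  codes <- lapply(aln$mappings, code_indels, alignment = aln)
  expect_equal(codes[["flank3"]][1], "1")
  expect_equal(codes[["tail12"]][6], "2")
  # area 3: both records have the canonical 3 residues between C3 and C4
  expect_equal(codes[["flank3"]][3], "1")
  # area 5: canonical single residue between C8 and C9
  expect_equal(codes[["flank3"]][5], "1")
})

test_that("areas touching unassigned slots are coded missing", {
  addlp <- generate_family("csh_only", 1, seed = 17)[[1]]
  insect <- generate_family("insect_type", 1, seed = 17)[[1]]
  mat_recs <- list(addlp, insect)
  mappings <- lapply(mat_recs, map_to_reference)
  aln <- build_anchored_alignment(mappings)
  codes <- code_indels(mappings[[1]], aln)
  # CSH-only peptides lack C2 and C6: areas 1, 2 and 4 are missing
  expect_equal(codes[c(1, 2, 4)], c("-", "-", "-"))
  expect_false(any(codes[c(3, 5, 6)] == "-"))
  expect_error(code_indels(mappings[[1]], aln, id = "ghost"),
               "not in alignment")
})

test_that("propeptide flags code as 1 / 0 / -", {
  expect_equal(code_propeptides(peptide_record("a", "AC", has_n_propeptide =
    "present", has_c_propeptide = "absent")), c("1", "0"))
  expect_equal(code_propeptides(peptide_record("a", "AC")), c("-", "-"))
  expect_equal(code_propeptides(peptide_record("a", "AC", has_n_propeptide =
    "absent", has_c_propeptide = "present")), c("0", "1"))
})

test_that("matrix columns are protein, then six indel, then two pro", {
  recs <- generate_family("insect_type", 2, seed = 18)
  mat <- coded_fixture(recs)
  L <- mat$spans$protein[2]
  expect_equal(mat$spans$indel, c(L + 1L, L + 6L))
  expect_equal(mat$spans$pro, c(L + 7L, L + 8L))

  # single taxon is valid
  mat1 <- coded_fixture(generate_family("macin_8", 1, seed = 18))
  expect_length(mat1$taxa, 1L)

  # missing codes are an error
  aln <- build_anchored_alignment(lapply(recs, map_to_reference))
  expect_error(build_matrix(aln, list(), list()), "codes missing")
})

test_that("NEXUS output carries the partition and MrBayes settings", {
  recs <- generate_family("insect_type", 2, seed = 19,
                          prop_n = "present", prop_c = "absent")
  mat <- coded_fixture(recs)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(mat, path)
  txt <- readLines(path)
  expect_match(txt[grep("DATATYPE", txt)], "MIXED\\(PROTEIN:1-")
  expect_true(any(grepl("rates=invgamma", txt)))
  expect_true(any(grepl("aamodelpr=mixed", txt)))
  expect_true(any(grepl("ratepr=variable", txt)))
  expect_true(any(grepl("partition", txt)))

  write_nexus(mat, path, include_mrbayes_block = FALSE)
  expect_false(any(grepl("mrbayes", readLines(path), ignore.case = TRUE)))
})

test_that("written NEXUS parses back to the identical matrix", {
  recs <- c(generate_family("insect_type", 2, seed = 20),
            generate_family("csh_only", 1, seed = 20))
  mat <- coded_fixture(recs)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(mat, path)
  back <- read_nexus_matrix(path)
  expect_equal(back$taxa, unname(mat$taxa))
  expect_equal(back$protein, mat$protein)
  expect_equal(unname(back$indel), unname(mat$indel))
  expect_equal(unname(back$pro), unname(mat$pro))
  expect_equal(back$spans, mat$spans)
})

test_that("taxon labels needing quotes survive the NEXUS round trip", {
  recs <- generate_family("insect_type", 2, seed = 22)
  recs[[1]]$id <- "Genus species-1"
  mat <- coded_fixture(recs)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(mat, path)
  expect_equal(read_nexus_matrix(path)$taxa[1], "Genus species-1")
})
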