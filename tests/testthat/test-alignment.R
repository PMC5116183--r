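align_fixtures <- function(records) {
  build_anchored_alignment(lapply(records, map_to_reference))
}

test_that("identical sequences align without gaps", {
  rec <- generate_family("insect_type", 1, seed = 7)[[1]]
  rec2 <- rec
  rec2$id <- "copy"
  aln <- align_fixtures(list(rec, rec2))
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  expect_equal(aln$width, nchar(rec$sequence))
})

test_that("n-loop length differences become gap columns in the C2-C3 region", {
  short <- generate_family("insect_type", 1, seed = 8,
                           regions = list("2_3" = c(4, 4)))[[1]]
  long <- generate_family("insect_type", 1, seed = 9,
                          regions = list("2_3" = c(16, 16)))[[1]]
  long$id <- "long"
  aln <- align_fixtures(list(short, long))
  expect_equal(gap_spaces(aln, short$id, "C2_C3"), 12L)  # 16 - 4
  expect_equal(gap_spaces(aln, "long", "C2_C3"), 0L)
})

test_that("records missing early slots carry gaps through those anchors", {
  addlp <- generate_family("csh_only", 1, seed = 10)[[1]]
  insect <- generate_family("insect_type", 1, seed = 10)[[1]]
  aln <- align_fixtures(list(addlp, insect))
  c2 <- aln$anchor_columns[["2"]]
  expect_equal(substring(aln$rows[[addlp$id]], c2, c2), "-")
  expect_equal(substring(aln$rows[[insect$id]], c2, c2), "C")
})

test_that("anchored slots share one column and rows ungap to their input", {
  recs <- c(generate_family("insect_type", 2, seed = 11),
            generate_family("macin_10", 2, seed = 11),
            generate_family("csh_only", 2, seed = 11),
            generate_family("mollusk_nematode_8", 2, seed = 11))
  mappings <- lapply(recs, map_to_reference)
  aln <- build_anchored_alignment(mappings)
  expect_equal(length(unique(nchar(aln$rows))), 1L)
  for (i in seq_along(recs)) {
    row <- aln$rows[[recs[[i]]$id]]
    expect_equal(gsub("-", "", row, fixed = TRUE), recs[[i]]$sequence)
    for (s in names(mappings[[i]]$assignment)) {
      col <- aln$anchor_columns[[s]]
      expect_equal(substring(row, col, col), "C")
    }
  }
})

test_that("gap counts equal region width minus placed residues", {
  recs <- c(generate_family("insect_type", 3, seed = 12),
            generate_family("drosomycin_plant", 2, seed = 12))
  aln <- align_fixtures(recs)
  regions <- c("flank_before_C2", "C2_C3", "C3_C4", "C6_C8", "C8_C9",
               "after_C9")
  bounds <- lapply(regions, csabref:::region_bounds, alignment = aln)
  for (id in aln$ids) {
    for (i in seq_along(regions)) {
      lo <- bounds[[i]][1] + 1L
      hi <- bounds[[i]][2] - 1L
      seg <- strsplit(substring(aln$rows[[id]], lo, hi), "")[[1]]
      expect_equal(gap_spaces(aln, id, regions[i]), sum(seg == "-"))
      expect_equal(gap_spaces(aln, id, regions[i]) + sum(seg != "-"),
                   hi - lo + 1L)
    }
  }
  expect_error(gap_spaces(aln, aln$ids[1], "C4_C5"), "unknown region")
  expect_error(gap_spaces(aln, "ghost", "C2_C3"), "not in alignment")
})

test_that("failed mappings are dropped with a warning, not an error", {
  recs <- generate_family("insect_type", 2, seed = 13)
  mappings <- c(lapply(recs, map_to_reference), list(NULL))
  expect_warning(aln <- build_anchored_alignment(mappings), "excluded")
  expect_length(aln$ids, 2L)
  expect_error(suppressWarnings(build_anchored_alignment(list(NULL))),
               "no mappable")
})

test_that("alignment exports round-trip through standard parsers", {
  recs <- generate_family("mollusk_nematode_8", 2, seed = 14)
  aln <- align_fixtures(recs)

  fa <- withr::local_tempfile(fileext = ".fasta")
  export_alignment(aln, fa, format = "fasta")
  back <- seqinr::read.fasta(fa, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  expect_equal(unname(vapply(back, as.character, "")),
               unname(aln$rows))

  nx <- withr::local_tempfile(fileext = ".nex")
  export_alignment(aln, nx, format = "nexus")
  lines <- readLines(nx)
  expect_match(lines[grep("DIMENSIONS", lines)],
               sprintf("NTAX=2 NCHAR=%d", aln$width))
  parsed <- ape::read.nexus.data(nx)
  expect_equal(names(parsed), unname(aln$ids))
  expect_equal(toupper(paste(parsed[[1]], collapse = "")),
               unname(aln$rows[[1]]))
})
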