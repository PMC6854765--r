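archs <- apo_architectures()

test_that("the packaged architectures follow the printed gene models", {
  expect_equal(archs[["ApoA-IV"]]$introns, 2L)
  expect_equal(archs[["ApoA-IV"]]$exons, 3L)
  expect_equal(archs[["ApoC-IV"]]$introns, 2L)
  expect_equal(archs[["ApoE"]]$introns, 3L)
  for (nm in c("ApoA-I", "ApoA-II", "ApoA-V", "ApoC-I", "ApoC-II",
               "ApoC-III", "ApoE")) {
    expect_equal(archs[[nm]]$introns, 3L, label = nm)
    expect_equal(archs[[nm]]$exons, 4L, label = nm)
  }
  # one 33-codon common block everywhere
  for (a in archs) expect_equal(sum(a$units == 33L), 1L, label = a$name)
})

test_that("identity diff is empty and the documented scenario edges are reproduced", {
  expect_equal(nrow(architecture_diff(archs[["ApoA-I"]], archs[["ApoA-I"]])), 0L)

  # primordial gene -> ApoA-IV: first intron lost, 3 x 22 and 1 x 11 duplicated
  d <- architecture_diff(archs[["Ancestral"]], archs[["ApoA-IV"]])
  expect_equal(d$count[d$kind == "duplicate_unit" & d$size == 22], 3L)
  expect_equal(d$count[d$kind == "duplicate_unit" & d$size == 11], 1L)
  expect_equal(d$count[d$kind == "lose_intron"], 1L)
  expect_equal(nrow(d), 3L)

  # primordial gene -> ApoA-I: unchanged lineage
  expect_equal(nrow(architecture_diff(archs[["Ancestral"]], archs[["ApoA-I"]])), 0L)

  # ApoA-I -> ApoE: one 22- and one 11-codon duplication (2 unit events)
  d2 <- architecture_diff(archs[["ApoA-I"]], archs[["ApoE"]])
  expect_equal(event_count(d2), 2L)
  expect_setequal(d2$kind, "duplicate_unit")
  expect_setequal(d2$size, c(22L, 11L))

  # ApoA-IV -> ApoA-V: one 11-codon duplication, intron regained
  d3 <- architecture_diff(archs[["ApoA-IV"]], archs[["ApoA-V"]])
  expect_equal(d3$count[d3$kind == "duplicate_unit" & d3$size == 11], 1L)
  expect_equal(d3$count[d3$kind == "gain_intron"], 1L)
  expect_equal(nrow(d3), 2L)

  # ApoA-IV lineage -> ApoA-II/ApoC ancestor: eleven 11-codon deletions
  d4 <- architecture_diff(archs[["ApoA-IV"]], archs[["ApoA-II"]])
  expect_equal(d4$count[d4$kind == "delete_unit" & d4$size == 11], 11L)

  # ApoC ancestor -> ApoC-II deletes one 22-repeat, -> ApoC-I two
  d_c2 <- architecture_diff(archs[["ApoC-ancestral"]], archs[["ApoC-II"]])
  d_c1 <- architecture_diff(archs[["ApoC-ancestral"]], archs[["ApoC-I"]])
  del22 <- function(d) {
    x <- d$count[d$kind == "delete_unit" & d$size == 22]
    if (length(x)) x else 0L
  }
  expect_equal(del22(d_c2), 1L)
  expect_equal(del22(d_c1), 2L)
  expect_equal(del22(d_c1) - del22(d_c2), 1L)
  # the shared teleost-era 11-codon duplication appears on both paths
  expect_equal(d_c1$count[d_c1$kind == "duplicate_unit" & d_c1$size == 11], 1L)
  expect_equal(d_c2$count[d_c2$kind == "duplicate_unit" & d_c2$size == 11], 1L)

  # ApoC ancestor -> ApoC-III deletes, -> ApoC-IV duplicates an 11-codon unit
  d_c3 <- architecture_diff(archs[["ApoC-ancestral"]], archs[["ApoC-III"]])
  expect_equal(d_c3$count[d_c3$kind == "delete_unit" & d_c3$size == 11], 1L)
  d_c4 <- architecture_diff(archs[["ApoC-ancestral"]], archs[["ApoC-IV"]])
  expect_equal(d_c4$count[d_c4$kind == "duplicate_unit" & d_c4$size == 11], 1L)
  expect_equal(d_c4$count[d_c4$kind == "lose_intron"], 1L)
})

random_arch <- function(name) {
  repeat_architecture(name, introns <- sample(0:4, 1), introns + 1,
                      c(33L, sample(c(22L, 11L), sample(0:12, 1),
                                    replace = TRUE)))
}

test_that("event_count equals the multiset symmetric difference (oracle)", {
  set.seed(41)
  for (k in 1:30) {
    a <- random_arch("a")
    b <- random_arch("b")
    oracle <- sum(abs(sum(a$units == 33) - sum(b$units == 33)),
                  abs(sum(a$units == 22) - sum(b$units == 22)),
                  abs(sum(a$units == 11) - sum(b$units == 11)),
                  abs(a$introns - b$introns))
    expect_equal(event_count(architecture_diff(a, b)), oracle)
  }
})

test_that("diff is antisymmetric and satisfies the triangle inequality", {
  set.seed(43)
  for (k in 1:20) {
    a <- random_arch("a"); b <- random_arch("b"); c <- random_arch("c")
    dab <- architecture_diff(a, b)
    dba <- architecture_diff(b, a)
    expect_equal(event_count(dab), event_count(dba))
    swap <- c(duplicate_unit = "delete_unit", delete_unit = "duplicate_unit",
              gain_intron = "lose_intron", lose_intron = "gain_intron")
    key <- function(d) sort(paste(d$kind, d$size, d$count))
    expect_equal(key(dba),
                 key(transform(dab, kind = unname(swap[kind]))))
    expect_lte(event_count(architecture_diff(a, c)),
               event_count(dab) + event_count(architecture_diff(b, c)))
  }
})

test_that("architecture files round-trip and invalid models are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_architectures(archs, path)
  back <- read_architectures(path)
  expect_equal(names(back), names(archs))
  for (nm in names(archs)) expect_equal(back[[nm]], archs[[nm]])

  expect_error(repeat_architecture("bad", 3, 3, c(33L)),
               "exons == introns \\+ 1")
  expect_error(repeat_architecture("bad", 3, 4, c(33L, 44L)),
               "must be 33, 22 or 11")
  expect_warning(repeat_architecture("odd", 3, 4, c(33L, 33L, 11L)),
                 "33-codon blocks")
})
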