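# short canonical protein and its CDS under one-codon-per-aa reverse
# translation; used to build hand-checkable translation cases
CANON <- "MKVLITAE"
CDS <- "ATGAAAGTTCTTATTACTGCTGAATAA"
PREFIX <- substr(CDS, 1, 12)

test_that("translation anchors on the CDS prefix and stops at the first stop", {
  # alternative mRNA = UTRs around the canonical CDS -> identical protein
  pair <- isoform_pair("g", CANON, PREFIX,
                       alternative_mrna = paste0("GGGC", CDS, "TTTT"))
  res <- translate_alternative(pair)
  expect_equal(res$status, "ok")
  expect_equal(res$protein, CANON)

  # anchor absent -> start_not_found, no translation attempted
  pair2 <- isoform_pair("g", CANON, PREFIX,
                        alternative_mrna = "GGGCCCTTTAAACCCGGGTTTAAACCC")
  expect_equal(translate_alternative(pair2)$status, "start_not_found")

  expect_error(translate_alternative(
    isoform_pair("g", CANON, PREFIX, alternative_mrna = "ACGTQ")),
    "non-nucleotide")
})

test_that("a 1-nt deletion downstream of the anchor frameshifts to a hand-computed stop", {
  # delete nt 13 of the CDS (just past the 12-nt anchor), add a 3' tail
  # holding the first shifted-frame stop; hand translation:
  # ATG AAA GTT CTT | TTA CTG CTG AAT AAC TAA -> MKVL + LLLNN, stop
  shifted <- paste0(substr(CDS, 1, 12), substr(CDS, 14, nchar(CDS)), "CTAAG")
  res <- translate_alternative(isoform_pair("g", CANON, PREFIX,
                                            alternative_mrna = shifted))
  expect_equal(res$protein, "MKVLLLLNN")
})

test_that("the four-category cascade matches its defining examples", {
  long_canon <- paste0("M", paste(rep("ACDEFGHIKL", 100), collapse = ""))
  long_canon <- substr(long_canon, 1, 1000)

  # identical proteins -> category 4, functional
  c4 <- classify_as_impact(isoform_pair("g4", CANON, PREFIX,
                                        alternative_protein = CANON))
  expect_equal(c4$category, 4L)
  expect_equal(c4$rollup, "functional")

  # canonical 300 aa, alternative truncated to 50 aa: 16.7% < 20% -> category 2
  canon300 <- substr(long_canon, 1, 300)
  c2 <- classify_as_impact(isoform_pair("g2", canon300, PREFIX,
                                        alternative_protein = substr(canon300, 1, 50)))
  expect_equal(c2$category, 2L)
  expect_equal(c2$rollup, "deleterious")
  expect_lt(c2$stop_position_fraction, 0.2)

  # 28-residue internal deletion out of 1,000 -> < 10% indels, category 3
  alt_del <- paste0(substr(long_canon, 1, 399), substr(long_canon, 428, 1000))
  c3 <- classify_as_impact(isoform_pair("g3", long_canon, PREFIX,
                                        alternative_protein = alt_del))
  expect_equal(c3$category, 3L)
  expect_equal(c3$reason, "small_indels")
  expect_lt(c3$indel_fraction, 0.1)

  # 600-aa proteins identical on the first 520 aa, divergent tail -> category 3
  withr::local_seed(22)
  canon600 <- paste0("M", paste(sample(c("A", "C", "D", "E", "F"), 599,
                                       replace = TRUE), collapse = ""))
  tail80 <- paste(sample(c("K", "R", "H", "W", "Y"), 80, replace = TRUE),
                  collapse = "")
  alt600 <- paste0(substr(canon600, 1, 520), tail80)
  c3b <- classify_as_impact(isoform_pair("g3b", canon600, PREFIX,
                                         alternative_protein = alt600))
  expect_equal(c3b$category, 3L)

  # a 40% truncation matches no rule -> deleterious, major_disruption
  cMaj <- classify_as_impact(isoform_pair(
    "gm", long_canon, PREFIX,
    alternative_protein = substr(long_canon, 1, 400)))
  expect_equal(cMaj$category, 2L)
  expect_equal(cMaj$reason, "major_disruption")
  expect_equal(cMaj$rollup, "deleterious")

  expect_error(isoform_pair("gX", CANON, PREFIX), "need alternative")
})

test_that("category 4 (exact equality) has priority over category 3", {
  # identical sequences also satisfy every category-3 rule; the cascade
  # must report 4
  canon <- paste(rep("MKVLITAE", 80), collapse = "")
  call <- classify_as_impact(isoform_pair("g", canon, PREFIX,
                                          alternative_protein = canon))
  expect_equal(call$category, 4L)
})

# minimal synthetic impact call for the cross-tab test
impact_call_for_test <- function(gene, category) {
  data.frame(gene_id = gene, category = category, label = "x",
             rollup = if (category <= 2L) "deleterious" else "functional",
             reason = "x", identity_fraction = NA_real_,
             indel_fraction = NA_real_, aligned_length = NA_real_,
             stop_position_fraction = NA_real_, stringsAsFactors = FALSE)
}

test_that("impact cross-tabulation reproduces a known mixture", {
  calls <- do.call(rbind, list(
    impact_call_for_test("g1", 1L), impact_call_for_test("g2", 2L),
    impact_call_for_test("g3", 3L), impact_call_for_test("g4", 4L),
    impact_call_for_test("g5", 4L)))
  contrast <- data.frame(
    gene_id = paste0("g", 1:5), kind = "iqr_contrast",
    direction = c("higher_in_WS", "higher_in_WS", "higher_in_CS",
                  "higher_in_CS", "higher_in_WS"),
    iq_r_cs = 0, iq_r_ws = 0, med_r_cs = 0, med_r_ws = 0,
    stringsAsFactors = FALSE)
  tab <- impact_table(calls, contrast)
  expect_equal(tab$counts["higher_in_WS", "no_protein"], 1L)
  expect_equal(tab$counts["higher_in_WS", "non_functional"], 1L)
  expect_equal(tab$counts["higher_in_WS", "identical"], 1L)
  expect_equal(tab$counts["higher_in_CS", "potentially_functional"], 1L)
  expect_equal(tab$counts["higher_in_CS", "identical"], 1L)
  expect_equal(tab$counts["higher_in_CS", "total_functional"], 2L)
  expect_equal(tab$counts["higher_in_WS", "total_deleterious"], 2L)
  expect_equal(unname(tab$percent["higher_in_CS", "total_functional"]), 100)

  empty <- impact_table(calls, contrast[0, ])
  expect_true(all(empty$counts == 0L))
})

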