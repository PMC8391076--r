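test_that("residue abundance pools over the whole dataset", {
  ab <- residue_abundance(seq_records("a", "FFGG"))
  expect_equal(ab$fraction[ab$residue == "F"], 0.5)
  expect_equal(ab$fraction[ab$residue == "G"], 0.5)
  ab2 <- residue_abundance(seq_records(c("a", "b"), c("K", "D")))
  expect_equal(ab2$fraction[ab2$residue == "K"], 0.5)
  expect_equal(ab2$fraction[ab2$residue == "D"], 0.5)
})

test_that("abundance fractions sum to one and honour the residue order", {
  set.seed(7)
  rec <- seq_records(paste0("s", 1:5),
                     replicate(5, random_seq(200, 0.1, 0.1)))
  ab <- residue_abundance(rec)
  expect_equal(sum(ab$fraction), 1, tolerance = 1e-9)
  # order-promoting residues first, charged last
  present <- ab$residue
  expect_true(which(present == "F") < which(present == "A"))
  expect_identical(utils::tail(present[present %in% c("D", "E", "K", "R")], 1),
                   utils::tail(present, 1))
  # explicit order selects and orders, padding absent residues with zero
  ab3 <- residue_abundance(seq_records("a", "KK"),
                           residue_order = c("W", "K"))
  expect_identical(ab3$residue, c("W", "K"))
  expect_equal(ab3$fraction, c(0, 1))
})

test_that("FG-motif density counts exact FG dipeptides per residue", {
  expect_equal(fg_motif_density(c("FGFG", "GF", "AFGAFGAA")),
               c(0.5, 0, 0.25))
  # substring-count oracle on a random sequence
  set.seed(9)
  s <- random_seq(400, 0.05, 0.05)
  n_fg <- length(gregexpr("(?=FG)", s, perl = TRUE)[[1]])
  if (gregexpr("(?=FG)", s, perl = TRUE)[[1]][1] == -1) n_fg <- 0
  expect_equal(fg_motif_density(s), n_fg / 400)
})

test_that("disorder fraction uses merged regions over full-protein length", {
  rec <- seq_records("p1", strrep("G", 100))
  expect_equal(disorder_fraction(rec, region_annotations("p1", 1, 30)), 0.30)
  none <- data.frame(seq_id = character(), start = integer(),
                     end = integer(), evidence = character())
  expect_equal(disorder_fraction(rec, none), 0)
  rec40 <- seq_records("p1", strrep("G", 40))
  ann <- data.frame(seq_id = c("p1", "p1"), start = c(1L, 5L),
                    end = c(10L, 20L), evidence = "")
  expect_equal(disorder_fraction(rec40, ann), 0.5)
  expect_error(disorder_fraction(rec40, region_annotations("p1", 30, 50)),
               "exceeds")
})

test_that("FG-Nup candidacy uses strict inequalities on both filters", {
  mk <- function(disorder, fg_per_aa, len = 100) {
    body <- c(rep("FG", round(fg_per_aa * len)),
              rep("A", len - 2 * round(fg_per_aa * len)))
    rec <- seq_records("p", paste(body, collapse = ""))
    ann <- region_annotations("p", 1, round(disorder * len))
    list(rec = rec, ann = ann)
  }
  x <- mk(0.5, 0.2)
  expect_true(is_fg_nup_candidate(x$rec, x$ann))
  x <- mk(0.30, 0.2)   # exactly at the disorder threshold
  expect_false(is_fg_nup_candidate(x$rec, x$ann))
  x <- mk(0.5, 0.15)   # exactly at the FG threshold
  expect_false(is_fg_nup_candidate(x$rec, x$ann))
})

test_that("LCR-covered percentage matches hand counts on the example", {
  rec <- worked_example()
  expect_equal(lcr_covered_percentage(rec, "POSITIVE", 2), 100 * 8 / 17)
  expect_equal(lcr_covered_percentage(rec, "NEGATIVE", 2), 100 * 7 / 17)
  expect_equal(lcr_covered_percentage(rec, "POSITIVE", 40), 0)
})

test_that("coverage is non-increasing in min_length and signs share <= 100%", {
  set.seed(21)
  for (rep in 1:20) {
    rec <- seq_records("r", random_seq(sample(30:200, 1), 0.2, 0.2))
    pos <- vapply(c(1, 2, 5, 10, 20), function(ml)
      lcr_covered_percentage(rec, "POSITIVE", ml), numeric(1))
    expect_true(all(diff(pos) <= 1e-12))
    tot <- lcr_covered_percentage(rec, "POSITIVE", 1) +
      lcr_covered_percentage(rec, "NEGATIVE", 1)
    expect_lte(tot, 100 + 1e-12)
  }
})

test_that("top-k ranking is by length with start-position tie-break", {
  lcrs <- data.frame(seq_id = "x", sign = "POSITIVE",
                     start = c(40L, 1L, 10L), end = c(44L, 9L, 18L),
                     length = c(5L, 9L, 9L), charge_count = 2L,
                     charge_content = 0.4)
  top <- top_k_lcrs(lcrs, "POSITIVE", 3)
  expect_identical(top$length, c(9L, 9L, 5L))
  expect_identical(top$start, c(1L, 10L, 40L))
  expect_identical(nrow(top_k_lcrs(lcrs[1, ], "POSITIVE", 3)), 1L)
  expect_identical(nrow(top_k_lcrs(lcrs, "NEGATIVE", 3)), 0L)
})

test_that("rank gaps and ratios follow their definitions", {
  rs <- rank_gap_and_ratio(c(127, 20, 15))
  expect_equal(rs$gap_12, 107)
  expect_equal(rs$ratio_12, 6.35)
  expect_equal(rs$gap_23, 5)
  expect_equal(rs$ratio_23, 4 / 3)
  rs2 <- rank_gap_and_ratio(c(10, 10))
  expect_equal(rs2$gap_12, 0)
  expect_equal(rs2$ratio_12, 1)
  expect_true(is.na(rs2$gap_23))
  rs1 <- rank_gap_and_ratio(127)
  expect_true(all(is.na(unlist(rs1))))
  expect_error(rank_gap_and_ratio(c(5, 9)), "non-increasing")
})

test_that("lpLCR flagging distinguishes DETECT and LONGEST modes", {
  long_lcr <- data.frame(seq_id = "x", sign = "POSITIVE", start = 1L,
                         end = 250L, length = 250L, charge_count = 5L,
                         charge_content = 0.02)
  short_lcr <- scan_lcrs(worked_example())
  expect_identical(flag_lplcr(long_lcr, "detect")$length, 250L)
  expect_null(flag_lplcr(filter_lcrs(short_lcr, 2), "detect"))
  # LONGEST mode returns the top-ranked positive LCR unconditionally
  expect_identical(flag_lplcr(filter_lcrs(short_lcr, 2), "longest")$length,
                   8L)
  # optional charge-content cap
  expect_null(flag_lplcr(long_lcr, "detect", max_content = 0.01))
  expect_identical(flag_lplcr(long_lcr, "detect", max_content = 0.02)$length,
                   250L)
})

test_that("per-protein summaries assemble the expected metrics", {
  s <- protein_charge_summary(worked_example())
  expect_equal(s$longest_pos_len, 8)
  expect_equal(s$longest_pos_content, 0.5)
  expect_equal(s$longest_neg_len, 7)
  expect_true(is.na(s$second_pos_len))
  expect_equal(s$covered_pos_pct, 100 * 8 / 17)
  expect_false(s$lplcr_flag)
  expect_true(is.na(s$disorder_fraction))
})
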