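test_that("residue charge classification follows the K/R, D/E convention", {
  expect_identical(classify_residue(c("K", "R")), rep("POSITIVE", 2))
  expect_identical(classify_residue(c("D", "E")), rep("NEGATIVE", 2))
  # histidine and ambiguity codes are neutral
  expect_identical(classify_residue(c("G", "H", "X", "U")),
                   rep("NEUTRAL", 4))
  expect_error(classify_residue("1"), "single letters")
  expect_error(classify_residue("KK"), "single letters")
})

test_that("charge profiles agree with direct letter counting", {
  p <- charge_profile("KKDD")
  expect_identical(p$n_positive, 2L)
  expect_identical(p$n_negative, 2L)
  expect_equal(p$f_plus, 0.5)
  p0 <- charge_profile("GGGG")
  expect_identical(unique(p0$signs), "NEUTRAL")
  expect_equal(p0$f_plus, 0)

  set.seed(41)
  s <- random_seq(500, 0.15, 0.2)
  ch <- strsplit(s, "")[[1]]
  p <- charge_profile(s)
  expect_identical(p$n_positive, sum(ch %in% c("K", "R")))
  expect_identical(p$n_negative, sum(ch %in% c("D", "E")))
  expect_identical(length(p$signs), 500L)
})

test_that("the scanner reproduces the 8/4 positive, 7/3 negative example", {
  lcrs <- scan_lcrs(worked_example())
  expect_identical(nrow(lcrs), 2L)
  expect_identical(lcrs$sign, c("POSITIVE", "NEGATIVE"))
  expect_identical(lcrs$start, c(1L, 10L))
  expect_identical(lcrs$end, c(8L, 16L))
  expect_identical(lcrs$length, c(8L, 7L))
  expect_identical(lcrs$charge_count, c(4L, 3L))
  expect_equal(lcrs$charge_content, c(4 / 8, 3 / 7))
})

test_that("degenerate sequences scan correctly", {
  expect_identical(nrow(scan_lcrs(seq_records("x", "GGGG"))), 0L)
  kd <- scan_lcrs(seq_records("x", "KD"))
  expect_identical(kd$length, c(1L, 1L))
  expect_identical(kd$sign, c("POSITIVE", "NEGATIVE"))
  # a terminal run with no flanking opposite charge still yields an LCR
  term <- scan_lcrs(seq_records("x", "GGKGG"))
  expect_identical(nrow(term), 1L)
  expect_identical(c(term$start, term$end), c(3L, 3L))
})

test_that("the extended span convention runs up to the next opposite charge", {
  lcrs <- scan_lcrs(worked_example(), extend_to_opposite = TRUE)
  # positive region continues through position 9; terminal negative region
  # extends to the sequence end
  expect_identical(lcrs$end, c(9L, 17L))
  expect_identical(lcrs$charge_count, c(4L, 3L))
})

test_that("length filtering is strictly greater-than", {
  lcrs <- data.frame(seq_id = "x", sign = "POSITIVE", start = 1:4, end = 1:4,
                     length = c(1L, 2L, 3L, 8L), charge_count = 1L,
                     charge_content = 1)
  expect_identical(filter_lcrs(lcrs, 2)$length, c(3L, 8L))
  expect_identical(nrow(filter_lcrs(lcrs[lcrs$length == 1, ], 1)), 0L)
  expect_identical(nrow(filter_lcrs(scan_lcrs(worked_example()), 40)), 0L)
})

test_that("scanner matches the brute-force enumerator on random sequences", {
  set.seed(101)
  for (rep in 1:300) {
    len <- sample(1:300, 1)
    p_pos <- stats::runif(1)
    p_neg <- stats::runif(1, 0, 1 - p_pos)
    s <- random_seq(len, p_pos, p_neg)
    got <- scan_lcrs(seq_records("r", s))
    want <- brute_force_lcrs(s)
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  }
})

test_that("scan output satisfies conservation, alternation and disjointness", {
  set.seed(202)
  for (rep in 1:100) {
    s <- random_seq(sample(5:250, 1), stats::runif(1, 0, 0.4),
                    stats::runif(1, 0, 0.4))
    lcrs <- scan_lcrs(seq_records("r", s))
    prof <- charge_profile(s)
    # conservation: charge counts sum to the profile totals pre-filter
    expect_identical(sum(lcrs$charge_count[lcrs$sign == "POSITIVE"]),
                     prof$n_positive)
    expect_identical(sum(lcrs$charge_count[lcrs$sign == "NEGATIVE"]),
                     prof$n_negative)
    if (nrow(lcrs) >= 2) {
      # alternation and disjoint, ordered spans
      expect_true(all(lcrs$sign[-1] != lcrs$sign[-nrow(lcrs)]))
      expect_true(all(lcrs$start[-1] > lcrs$end[-nrow(lcrs)]))
      # residues strictly between consecutive spans are all neutral
      for (i in seq_len(nrow(lcrs) - 1)) {
        gap <- seq(lcrs$end[i] + 1, lcrs$start[i + 1] - 1)
        gap <- gap[gap >= lcrs$end[i] + 1 & gap <= lcrs$start[i + 1] - 1]
        if (length(gap))
          expect_true(all(prof$signs[gap] == "NEUTRAL"))
      }
    }
  }
})

test_that("reversing a sequence preserves (sign, length, count) multisets", {
  set.seed(303)
  for (rep in 1:50) {
    s <- random_seq(sample(2:200, 1), 0.2, 0.2)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    a <- scan_lcrs(seq_records("f", s))
    b <- scan_lcrs(seq_records("r", rev_s))
    key <- function(d) sort(paste(d$sign, d$length, d$charge_count))
    expect_identical(key(a), key(b))
  }
})

test_that("inserting a neutral residue inside an LCR lengthens it by one", {
  set.seed(404)
  for (rep in 1:25) {
    s <- random_seq(sample(20:100, 1), 0.25, 0.25)
    lcrs <- scan_lcrs(seq_records("x", s))
    wide <- lcrs[lcrs$length >= 2, ]
    if (nrow(wide) == 0) next
    pick <- wide[sample(nrow(wide), 1), ]
    at <- pick$start + 1L  # strictly inside the span
    s2 <- paste0(substr(s, 1, at - 1), "G", substr(s, at, nchar(s)))
    lcrs2 <- scan_lcrs(seq_records("x", s2))
    hit <- lcrs2[lcrs2$start == pick$start & lcrs2$sign == pick$sign, ]
    expect_identical(hit$length, pick$length + 1L)
    expect_identical(hit$charge_count, pick$charge_count)
  }
})
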