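# read simulation, assignment, methylation calling, conversion
# correction

test_that("fully methylated, fully converted reads carry C at every CpG offset", {
  panel <- subset_panel(fixture_panel(), "cg19761273")
  b <- simulate_reads(panel, c(cg19761273 = 1.0), n_fragments = 50,
                      conversion_rate = 1, seq_error_rate = 0, seed = 1)
  calls <- quantify_reads(b, panel, min_reads = 10)
  cpg <- calls[calls$type %in% c("target", "cpg"), ]
  expect_true(all(cpg$t_count == 0))
  expect_true(all(cpg$raw_beta == 1))
  ctrl <- calls[calls$type == "control", ]
  expect_true(all(ctrl$c_count == 0))  # full conversion
})

test_that("simulated C fraction honours the binomial oracle", {
  panel <- subset_panel(fixture_panel(), "cg06493994")
  b <- simulate_reads(panel, c(cg06493994 = 0.7), n_fragments = 1000,
                      conversion_rate = 1, seq_error_rate = 0, seed = 5)
  calls <- quantify_reads(b, panel, min_reads = 1000)
  tg <- calls[calls$type == "target", ]
  ci <- binom_ci99(tg$coverage, 0.7)
  expect_gte(tg$raw_beta, ci[1])
  expect_lte(tg$raw_beta, ci[2])
  # control offsets measure the conversion rate
  b2 <- simulate_reads(panel, c(cg06493994 = 0.5), n_fragments = 1000,
                       conversion_rate = 0.95, seq_error_rate = 0,
                       seed = 6)
  calls2 <- quantify_reads(b2, panel, min_reads = 1000)
  ctrl <- calls2[calls2$type == "control", ]
  n_ctrl <- sum(ctrl$c_count + ctrl$t_count)
  ci2 <- binom_ci99(n_ctrl, 0.95)
  expect_gte(ctrl$conversion_rate[1], ci2[1])
  expect_lte(ctrl$conversion_rate[1], ci2[2])
})

test_that("error-free reads assign perfectly; noisy reads assign >= 99%", {
  panel <- fixture_panel()
  tb <- stats::setNames(rep(0.5, 16), names(panel))
  b0 <- simulate_reads(panel, tb, n_fragments = 40, seed = 2)
  a0 <- assign_reads(b0, panel)
  expect_equal(a0$marker, b0$true_marker)
  # 1% substitution error, 10,000 reads over the 16-marker panel
  b1 <- simulate_reads(panel, tb, n_fragments = 313,
                       seq_error_rate = 0.01, seed = 3)
  a1 <- assign_reads(b1, panel)
  correct <- mean(!is.na(a1$marker) & a1$marker == b1$true_marker)
  expect_gte(correct, 0.99)
})

test_that("foreign sequence reads land in the unassigned bin", {
  panel <- fixture_panel()
  set.seed(8)
  junk <- data.frame(
    read_id = sprintf("junk%02d", 1:20), mate = 1L,
    sequence = vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), ""),
    quality = strrep("I", 120), stringsAsFactors = FALSE)
  a <- assign_reads(junk, panel)
  expect_true(all(is.na(a$marker)))
  expect_equal(nrow(assign_reads(junk[0, ], panel)), 0)
})

test_that("methylation calling counts, thresholds and flags behave", {
  amp <- fixture_panel()[["cg19761273"]]
  mk_assign <- function(n_c, n_t) {
    ref <- amp$reference_seq
    seq_c <- chartr("Y", "C", ref)
    seq_t <- chartr("Y", "T", ref)
    data.frame(
      read_id = sprintf("r%06d", seq_len(n_c + n_t)), mate = 1L,
      marker = amp$cpg_id,
      tmpl_seq = c(rep(seq_c, n_c), rep(seq_t, n_t)), tmpl_start = 1L,
      identity = 1, stringsAsFactors = FALSE)
  }
  calls <- call_methylation(mk_assign(700, 300), amp, min_reads = 1000)
  tg <- calls[calls$type == "target", ]
  expect_equal(tg$raw_beta, 0.7)
  expect_equal(tg$coverage, 1000)
  expect_true(tg$pass_coverage)
  # boundary: 999 reads fail the 1000-read floor
  calls999 <- call_methylation(mk_assign(699, 300), amp,
                               min_reads = 1000)
  expect_false(calls999$pass_coverage[calls999$type == "target"])
  expect_equal(calls999$coverage[calls999$type == "target"], 999)
  # no reads: undefined beta, flagged row
  calls0 <- call_methylation(mk_assign(1, 0)[0, ], amp)
  expect_true(all(is.na(calls0$raw_beta)))
  expect_true(all(!calls0$pass_coverage))
  # counting conservation
  expect_equal(calls$c_count + calls$t_count + calls$other_count,
               rep(1000, nrow(calls)))
})

test_that("overlapping mate bases are counted once (first mate wins)", {
  amp <- fixture_panel()[["cg27544190"]]  # 106 bp < 150 bp reads
  panel <- subset_panel(fixture_panel(), "cg27544190")
  b <- simulate_reads(panel, c(cg27544190 = 0.4), n_fragments = 200,
                      seed = 4)
  calls <- quantify_reads(b, panel, min_reads = 100)
  # both mates span the whole amplicon; each fragment contributes one
  # observation per offset, not two
  expect_true(all(calls$coverage + calls$other_count == 200))
})

test_that("conversion rate pools controls and refuses empty input", {
  expect_equal(conversion_rate(data.frame(c_count = 0, t_count = 50)), 1)
  expect_equal(conversion_rate(data.frame(c_count = c(1, 1),
                                          t_count = c(49, 49))), 0.98)
  expect_error(conversion_rate(data.frame(c_count = 0, t_count = 0)),
               "no conversion controls")
})

test_that("conversion correction inverts the conversion process", {
  expect_equal(correct_conversion(0.5, 1.0), 0.5)
  expect_equal(correct_conversion(0.01, 0.99), 0)
  # forward oracle: raw = m + (1 - m)(1 - c) with m = 0.5, c = 0.96
  m <- 0.5; c <- 0.96
  raw <- m + (1 - m) * (1 - c)
  expect_equal(raw, 0.52)
  expect_equal(correct_conversion(raw, c), m, tolerance = 1e-12)
  expect_error(correct_conversion(0.5, 0.5), "assay failure")
  # monotone non-decreasing in raw_beta for fixed rate
  g <- correct_conversion(seq(0, 1, by = 0.01), 0.97)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
})

test_that("FASTQ round trip preserves sequences and pairing", {
  panel <- subset_panel(fixture_panel(), "cg04084157")
  b <- simulate_reads(panel, c(cg04084157 = 0.3), n_fragments = 25,
                      seed = 12)
  r1 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(b, r1, r2)
  back <- read_fastq(r1, r2)
  expect_equal(nrow(back), nrow(b))
  expect_setequal(back$read_id, b$read_id)
  expect_equal(back$sequence[order(back$read_id, back$mate)],
               b$sequence[order(b$read_id, b$mate)])
})

test_that("quantification round trip recovers the true beta after correction", {
  panel <- subset_panel(fixture_panel(), c("cg22736354", "cg01511567"))
  tb <- c(cg22736354 = 0.3, cg01511567 = 0.8)
  b <- simulate_reads(panel, tb, n_fragments = 1200,
                      conversion_rate = 0.97, seed = 13)
  calls <- quantify_reads(b, panel, min_reads = 1000)
  got <- target_betas(calls)
  for (mk in names(tb)) {
    cov <- calls$coverage[calls$type == "target" & calls$marker == mk]
    p_obs <- tb[[mk]] + (1 - tb[[mk]]) * 0.03
    ci <- binom_ci99(cov, p_obs)
    corrected_ci <- correct_conversion(ci, 0.97)
    expect_gte(got[[mk]], corrected_ci[1])
    expect_lte(got[[mk]], corrected_ci[2])
  }
})

test_that("replicate averaging respects the coverage filter", {
  panel <- subset_panel(fixture_panel(), "cg20692569")
  tb <- c(cg20692569 = 0.6)
  good1 <- quantify_reads(simulate_reads(panel, tb, 1100, seed = 1),
                          panel, min_reads = 1000)
  good2 <- quantify_reads(simulate_reads(panel, tb, 1100, seed = 2),
                          panel, min_reads = 1000)
  low <- quantify_reads(simulate_reads(panel, tb, 200, seed = 3),
                        panel, min_reads = 1000)
  expect_warning(avg <- average_replicates(list(good1, good2, low)),
                 "failed coverage")
  manual <- mean(c(target_betas(good1), target_betas(good2)))
  expect_equal(unname(avg), manual)
  expect_warning(all_fail <- average_replicates(list(low, low)),
                 "failed coverage")
  expect_true(is.na(all_fail))
})
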