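make_record <- function(acc, values, desc = "test index") {
  # values named in AAindex file order
  c(paste("H", acc), paste("D", desc),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste(values[1:10], collapse = "   "),
    paste(values[11:20], collapse = "   "),
    "//")
}

test_that("AAindex parsing handles multiple records, NA values and re-keying", {
  vals1 <- as.character(1:20)
  vals2 <- as.character(21:40)
  idx <- parse_aaindex(c(make_record("TEST000101", vals1),
                         make_record("TEST000102", vals2)))
  expect_length(idx, 2)
  expect_equal(names(idx), c("TEST000101", "TEST000102"))
  # file order starts A R N D ...; alphabetical re-keying puts C (5th) third
  expect_equal(idx[["TEST000101"]]$values[["C"]], 5)
  expect_equal(idx[["TEST000101"]]$values[["V"]], 20)

  vals_na <- vals1; vals_na[3] <- "NA"
  idxna <- parse_aaindex(make_record("TEST000103", vals_na))
  expect_true(is.na(idxna[[1]]$values[["N"]]))
  expect_equal(sum(!is.na(idxna[[1]]$values)), 19)
})

test_that("malformed records are skipped with a warning, not fatally", {
  lines <- c(make_record("GOOD000101", as.character(1:20)),
             c("H BADRECORD1", "D truncated", "//"))
  expect_warning(idx <- parse_aaindex(lines), "malformed")
  expect_length(idx, 1)
  expect_equal(attr(idx, "n_skipped"), 1)
})

test_that("parse then re-serialise preserves all 20 values exactly", {
  ax <- scm_fixture("aaindex")
  back <- parse_aaindex(format_aaindex(ax))
  for (a in names(ax))
    expect_equal(back[[a]]$values, ax[[a]]$values)
})

test_that("the packaged property indices carry the expected values", {
  ax <- scm_fixture("aaindex")
  expect_equal(names(ax),
               c("BLAS910101", "PUNT030101", "WOLR810101"))
  expect_equal(ax$BLAS910101$values[["A"]], 0.616)
  expect_equal(ax$BLAS910101$values[["F"]], 1.000)
  expect_equal(ax$BLAS910101$values[["R"]], 0.000)
  expect_equal(ax$PUNT030101$values[["D"]], 0.37)
  expect_equal(ax$WOLR810101$values[["R"]], -19.92)
  expect_equal(ax$WOLR810101$values[["P"]], -3.68)  # imputed; see file notes
})

test_that("correlation with an index is sign-symmetric and self-correlation is 1", {
  rc <- scm_fixture("reference_card")
  ps <- setNames(rc$propensity, rc$aa)
  self <- correlate_index(ps, setNames(ps, names(ps)))
  expect_equal(self$r, 1)
  ax <- scm_fixture("aaindex")
  r1 <- correlate_index(ps, ax$BLAS910101)
  neg <- ax$BLAS910101
  neg$values <- -neg$values
  expect_equal(correlate_index(ps, neg)$r, -r1$r)
  expect_equal(r1$n_used, 20)
})

test_that("correlate_index rejects indices with too few usable pairs", {
  ps <- setNames(scm_fixture("reference_card")$propensity,
                 scm_fixture("reference_card")$aa)
  sparse <- list(accession = "SPARSE", description = "",
                 values = setNames(c(1, 2, rep(NA, 18)), AA_ALPHABET))
  expect_error(correlate_index(ps, sparse), "fewer than 3")
})

test_that("scanning ranks indices by |r| and decomposes into single calls", {
  rc <- scm_fixture("reference_card")
  ps <- setNames(rc$propensity, rc$aa)
  ax <- scm_fixture("aaindex")
  rep <- scan_indices(ps, ax)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$accession[1], "BLAS910101")   # largest |r|
  expect_true(all(rep$informative))
  expect_true(all(diff(abs(rep$r)) <= 0))
  for (i in seq_len(nrow(rep)))
    expect_equal(rep$r[i], correlate_index(ps, ax[[rep$accession[i]]])$r)
  # an unattainable cutoff leaves nothing informative
  expect_true(all(!scan_indices(ps, ax, cutoff = 1.1)$informative))
})

test_that("composition-difference correlation matches stats::cor and guards degeneracy", {
  rc <- scm_fixture("reference_card")
  ps <- setNames(rc$propensity, rc$aa)
  pos <- setNames(rc$comp_pos_pct, rc$aa)
  neg <- setNames(rc$comp_neg_pct, rc$aa)
  r <- composition_difference_correlation(ps, pos, neg)
  expect_equal(r, stats::cor(rc$propensity, rc$comp_pos_pct - rc$comp_neg_pct),
               tolerance = 1e-12)
  expect_error(composition_difference_correlation(ps, pos, pos),
               "zero variance")
})

test_that("external-scale correlation honours exclusion and log scale", {
  rcst <- scm_fixture("rate_constants")
  rc <- scm_fixture("reference_card")
  ps <- setNames(rc$propensity, rc$aa)
  rates <- setNames(rcst$rate_constant, rcst$aa)
  full <- correlate_external(ps, rates, log10_values = TRUE)
  expect_equal(full$n_used, 20)
  sub <- correlate_external(ps, rates, exclude = c("A", "P", "G"),
                            log10_values = TRUE)
  expect_equal(sub$n_used, 17)
  expect_true(abs(sub$r) <= 1 && abs(full$r) <= 1)
})
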