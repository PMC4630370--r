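test_that("protein ratios are geometric means of peptide ratios", {
  expect_equal(protein_ratio(2), 2)
  expect_equal(protein_ratio(c(2, 8)), 4)
  for (r in c(0.1, 0.7, 3, 42)) {
    expect_equal(protein_ratio(c(r, 1 / r)), 1, tolerance = 1e-12)
  }
  expect_error(protein_ratio(numeric()), "no peptide ratios")
  expect_error(protein_ratio(c(1, -2)), "positive")
})

test_that("signed fold change uses the reciprocal sign convention", {
  expect_equal(signed_fold_change(1), 1)
  expect_equal(signed_fold_change(0.25), -4)
  expect_equal(signed_fold_change(1 / 4.2), -4.2)
  expect_error(signed_fold_change(-1), "positive")
  # round trip on (0, Inf); |FC| >= 1 always
  r <- exp(runif(50, -3, 3))
  fc <- signed_fold_change(r)
  expect_true(all(abs(fc) >= 1))
  expect_equal(ratio_from_signed(fc), r, tolerance = 1e-12)
})

test_that("normalisation centres each time point at median ratio 1", {
  expect_equal(unname(normalize_ratios(cbind(x = c(2, 2, 2)))[, 1]), c(1, 1, 1))
  expect_equal(unname(normalize_ratios(cbind(x = c(1, 2, 4)))[, 1]), c(0.5, 1, 2))
  set.seed(11)
  for (i in 1:50) {
    col <- exp(rnorm(sample(5:40, 1)))
    norm <- normalize_ratios(cbind(col))
    expect_equal(median(norm), 1, tolerance = 1e-12)
  }
})

test_that("thresholds follow |median| + z*SD on the log2 scale", {
  # degenerate population: SD 0 -> tau 1
  thr0 <- compute_thresholds(cbind(t1 = rep(0, 10)))
  expect_equal(thr0$tau, 1)
  # large Gaussian population: tau ~ 2^(1.6449 * sigma)
  set.seed(99)
  lg <- cbind(t1 = rnorm(10000, 0, 1))
  thr <- compute_thresholds(lg, p_level = 0.1)
  expect_equal(attr(thr, "z"), qnorm(0.95), tolerance = 1e-6)
  expect_equal(thr$tau, 2^1.6449, tolerance = 0.02 * 2^1.6449)
  expect_error(compute_thresholds(cbind(c(1, 2))), "at least 3")
})

test_that("differential calls replay the published fold-change table", {
  tabs <- cigb552_tables()
  diff <- tabs$differential
  called <- call_differential(diff, attr(diff, "thresholds"))
  # spot checks against the printed calls
  row <- function(g) called[called$gene == g, ]
  expect_equal(unlist(row("MCM6")[, paste0("sig_", TIMEPOINTS)], use.names = FALSE),
               c(TRUE, FALSE, FALSE))   # -4.2 / -1.1 / -2
  expect_equal(unlist(row("SUCLG2")[, paste0("sig_", TIMEPOINTS)], use.names = FALSE),
               c(FALSE, FALSE, TRUE))   # -2.4 at 2 h below 2.6; -2.4 meets 2.4
  expect_equal(unlist(row("CCBL2")[, paste0("sig_", TIMEPOINTS)], use.names = FALSE),
               c(FALSE, TRUE, FALSE))   # OFF at 2 h
  expect_equal(unlist(row("ARVCF")[, paste0("sig_", TIMEPOINTS)], use.names = FALSE),
               c(TRUE, TRUE, TRUE))     # ON at every time point
  # every published per-cell call is reproduced
  for (tp in TIMEPOINTS) {
    expect_equal(called[[paste0("sig_", tp)]], diff[[paste0("sig_", tp)]],
                 info = tp)
  }
  # all 72 proteins significant in at least one time point
  any_sig <- rowSums(called[, paste0("sig_", TIMEPOINTS)]) > 0
  expect_equal(sum(any_sig), 72L)
})

test_that("trend grouping discretises trajectories and respects pigeonhole", {
  tabs <- cigb552_tables()
  called <- call_differential(tabs$differential, attr(tabs$differential, "thresholds"))
  trends <- cluster_trends(called)
  expect_true(nrow(trends) <= nrow(called))
  expect_equal(sum(trends$n), nrow(called))
  mcm6 <- trends$pattern[grepl("Q14566", trends$proteins)]
  expect_equal(mcm6, "down/none/none")
  arvcf <- trends$pattern[grepl("O00192", trends$proteins)]
  expect_equal(arvcf, "ON/ON/ON")
  # identical patterns land in one group: GAK and RPS7 are down at all times
  gak_grp <- trends[grepl("O14976", trends$proteins), ]
  expect_true(grepl("P62081", gak_grp$proteins))
})

test_that("peptide aggregation handles ON/OFF detection states", {
  tpl <- reporter_templates()
  fits <- list(
    fit_reporter_ratios(gen_reporter_spectrum(c(1, 2, 1, 0.5), tpl), tpl),
    fit_reporter_ratios(gen_reporter_spectrum(c(1, 8, 1, 0.5), tpl), tpl),
    fit_reporter_ratios(gen_reporter_spectrum(c(0, 1, 1, 1), tpl), tpl),  # ON
    fit_reporter_ratios(gen_reporter_spectrum(c(1, 1, 0, 1), tpl), tpl)   # OFF at 2 h
  )
  pt <- peptide_ratio_table(fits, c("pepA1", "pepA2", "pepB1", "pepC1"))
  pm <- c(pepA1 = "A", pepA2 = "A", pepB1 = "B", pepC1 = "C")
  q <- protein_quant(pt, pm, min_gof = 0.8)
  a <- q[q$accession == "A", ]
  expect_equal(a$ratio_40min, 4, tolerance = 1e-6)    # geomean(2, 8)
  expect_equal(a$n_peptides, 2L)
  expect_equal(q[q$accession == "B", "status_40min"], "ON")
  expect_equal(q[q$accession == "C", "status_2h"], "OFF")
  expect_equal(q[q$accession == "C", "status_5h"], "normal")
  expect_error(protein_quant(pt, pm, min_gof = 1.1), "min_gof")
  expect_error(protein_quant(pt, pm[1:3]), "not in the peptide->protein map")
})
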