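test_that("paired t-test matches the definitional oracle and is antisymmetric", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, mean = 0.3)
    got <- paired_t_test(a, b)
    ref <- oracle_paired_t(a, b)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
    rev <- paired_t_test(b, a)
    expect_equal(rev$t, -got$t, tolerance = 1e-12)
    expect_equal(rev$p, got$p, tolerance = 1e-12)
  }
})

test_that("degenerate paired inputs are flagged, not mis-tested", {
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 3))       # all differences 0
  expect_true(r$undefined)
  expect_true(is.na(r$p))
  r2 <- paired_t_test(c(1, 2, 3), c(2, 3, 4))      # constant nonzero diff
  expect_true(r2$undefined)
  expect_error(paired_t_test(1, 2), ">= 2 pairs")
  expect_error(paired_t_test(c(1, NA), c(1, 2)), "finite")
})

test_that("signed fold change follows the -1/r convention", {
  expect_equal(fold_change(10, 20), 2)
  expect_equal(fold_change(20, 10), -2)
  expect_equal(fold_change(7, 7), 1)
  expect_true(is.na(fold_change(0, 0)))
  expect_error(fold_change(-1, 2), ">= 0")
  # |fc| == max(r, 1/r) identity on random positive means
  set.seed(11)
  a <- rexp(200) + 0.01
  b <- rexp(200) + 0.01
  expect_equal(abs(fold_change(a, b)), pmax(b / a, a / b), tolerance = 1e-12)
})

test_that("DE calling applies strict thresholds and is monotone in them", {
  res <- data.frame(feature_id = c("f1", "f2", "f3", "f4", "f5"),
                    p = c(0.04, 0.04, 0.2, NA, 0.05),
                    fc = c(1.2, 1.05, 2.0, 3.0, 1.2))
  out <- call_de(res, 0.05, 1.1)
  expect_identical(out$is_de, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$direction[1], "up")
  s <- attr(out, "summary")
  expect_identical(s$n_de, s$n_up + s$n_down)

  # tightening thresholds never adds calls
  set.seed(5)
  rnd <- data.frame(feature_id = sprintf("f%03d", 1:200),
                    p = runif(200), fc = ifelse(runif(200) > 0.5, 1, -1) *
                      (1 + rexp(200)))
  loose <- call_de(rnd, 0.1, 1.1)
  tight <- call_de(rnd, 0.05, 1.5)
  expect_true(all(which(tight$is_de) %in% which(loose$is_de)))
  expect_error(call_de(rnd, 0.05, 0.9), "fc_thresh")
})

test_that("zero-noise planted effects are recovered exactly by run_diffexp", {
  planted <- rbind(
    data.frame(feature = c("mir-0001", "mir-0002"), condition = "shA", fc = 2),
    data.frame(feature = "mir-0003", condition = "shA", fc = 0.5))
  m <- zero_noise_matrix(planted_fc = planted)
  nm <- normalize_spikein(m)
  de <- run_diffexp(nm, paired_design(nm$meta, "crxnrl", "shA"),
                    p_thresh = 0.05, fc_thresh = 1.1)
  expect_equal(de$fc[de$feature_id == "mir-0001"], 2)
  expect_equal(de$fc[de$feature_id == "mir-0003"], -2)
  # planted features have zero-variance log differences -> undefined p -> the
  # strict caller never calls them at zero noise, and unplanted features sit
  # at fc exactly 1
  expect_true(all(is.na(de$p)))
  expect_equal(de$fc[de$feature_id == "mir-0004"], 1)
})

test_that("exchanging conditions negates fold changes and preserves p-values", {
  cfg <- sim_config(n_mirnas = 40, conditions = c("a", "b"), noise_cv = 0.1,
                    seed = 13)
  nm <- global_normalize(normalize_spikein(simulate_ncounter(cfg)))
  fwd <- run_diffexp(nm, paired_design(nm$meta, "a", "b"))
  bwd <- run_diffexp(nm, paired_design(nm$meta, "b", "a"))
  expect_equal(bwd$fc, -fwd$fc, tolerance = 1e-12)
  expect_equal(bwd$p, fwd$p, tolerance = 1e-12)
  expect_identical(attr(fwd, "summary")$n_up, attr(bwd, "summary")$n_down)
})

test_that("design construction validates pairing and sample membership", {
  meta <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                     condition = rep(c("a", "b"), each = 3),
                     timepoint = rep(c("t1", "t2", "t3"), 2))
  d <- paired_design(meta, "a", "b")
  expect_identical(nrow(d$pairs), 3L)
  expect_error(paired_design(meta, "a", "zz"), "not present")
  expect_error(paired_design(meta[c(1, 4), ], "a", "b"), ">= 2 shared")

  mat <- matrix(rexp(12) + 1, 2, 6,
                dimnames = list(c("g1", "g2"), meta$sample_id))
  d2 <- d
  d2$pairs$sample_b[1] <- "missing_sample"
  expect_error(run_diffexp(mat, d2), "missing_sample")
})

test_that("a noisy planted run reproduces its frozen golden summary", {
  planted <- rbind(
    data.frame(feature = sprintf("mir-%04d", 1:10), condition = "b", fc = 1.5),
    data.frame(feature = sprintf("mir-%04d", 11:20), condition = "b",
               fc = 1 / 1.5))
  cfg <- sim_config(n_mirnas = 200, conditions = c("a", "b"),
                    timepoints = c("15h", "24h", "48h"), noise_cv = 0.1,
                    sample_cv = 0.05, planted_fc = planted, seed = 11)
  nm <- global_normalize(normalize_spikein(simulate_ncounter(cfg)))
  de <- run_diffexp(nm, paired_design(nm$meta, "a", "b"), 0.05, 1.1)
  truth <- de$feature_id %in% planted$feature
  s <- attr(de, "summary")
  # frozen golden values recorded at fixture creation (seed 11)
  expect_identical(s$n_de, 19L)
  expect_identical(s$n_up, 4L)
  expect_identical(s$n_down, 15L)
  expect_equal(sum(de$is_de & truth) / sum(truth), 9 / 20)
  expect_equal(sum(!de$is_de & !truth) / sum(!truth), 170 / 180)
})

test_that("fold-change method and BH options behave as documented", {
  mat <- matrix(c(10, 20, 12, 22, 8, 18,
                  40, 10, 44, 12, 36, 9), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"),
                                c("a1", "b1", "a2", "b2", "a3", "b3")))
  meta <- data.frame(sample_id = colnames(mat),
                     condition = rep(c("a", "b"), 3),
                     timepoint = rep(c("t1", "t2", "t3"), each = 2))
  d <- paired_design(meta, "a", "b")
  rom <- run_diffexp(mat, d, fc_method = "ratio_of_means")
  mor <- run_diffexp(mat, d, fc_method = "mean_of_ratios")
  expect_equal(rom$fc[rom$feature_id == "g1"], mean(c(20, 22, 18)) / mean(c(10, 12, 8)))
  expect_equal(mor$fc[mor$feature_id == "g1"], mean(c(20 / 10, 22 / 12, 18 / 8)))
  # BH adjustment can only reduce the number of calls
  raw <- run_diffexp(mat, d, adjust = "none")
  bh <- run_diffexp(mat, d, adjust = "BH")
  expect_lte(attr(bh, "summary")$n_de, attr(raw, "summary")$n_de)
  expect_true(all(bh$p >= raw$p))
})
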