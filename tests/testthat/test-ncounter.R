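test_that("spike-in fit reproduces an exact line and rejects degenerate input", {
  concs <- c(32, 8, 2, 0.5)
  fit <- fit_spikein_response(10 * concs + 5, concs)
  expect_equal(fit$slope, 10)
  expect_equal(fit$B, 325)   # fitted signal at the POS_B concentration
  expect_equal(fit$r2, 1)

  expect_error(fit_spikein_response(rep(100, 4), concs), "degenerate")
  expect_error(fit_spikein_response(c(1, 2), c(32, 8)), "3 distinct")
  expect_error(fit_spikein_response(5 - 2 * concs, concs), "slope")
})

test_that("spike-in fit matches the normal-equations oracle on noisy data", {
  set.seed(42)
  concs <- c(32, 8, 2, 0.5)
  for (i in 1:100) {
    counts <- 20 + runif(1, 2, 30) * concs + rnorm(4, sd = 5)
    if (any(counts <= 0)) next
    fit <- fit_spikein_response(counts, concs)
    ref <- oracle_ls(concs, counts, 32)
    expect_equal(fit$slope, ref$slope, tolerance = 1e-10)
    expect_equal(fit$B, ref$at, tolerance = 1e-10)
  }
})

test_that("log-space fit variant recovers a power-law response", {
  concs <- c(32, 8, 2, 0.5)
  counts <- 12 * concs^0.9
  fit <- fit_spikein_response(counts, concs, log_space = TRUE)
  expect_equal(fit$slope, 0.9, tolerance = 1e-10)    # log-log slope
  expect_equal(fit$B, 12 * 32^0.9, tolerance = 1e-8)
})

test_that("normalization applies Ei = (Ri - B)/slope with clipping", {
  counts <- matrix(c(325L, 335L, 300L, 500L,
                     325L, 345L, 280L, 700L), ncol = 2,
                   dimnames = list(c("m1", "m2", "m3", "m4"), c("s1", "s2")))
  spikes <- matrix(as.integer(10 * c(32, 8, 2, 0.5) + 5), ncol = 2,
                   nrow = 4, dimnames = list(paste0("POS_", LETTERS[2:5]),
                                             c("s1", "s2")))
  m <- count_matrix(rbind(counts, spikes),
                    data.frame(sample_id = c("s1", "s2"),
                               condition = c("a", "b"),
                               timepoint = c("t1", "t1")),
                    spike_concs = c(POS_B = 32, POS_C = 8, POS_D = 2,
                                    POS_E = 0.5))
  nm <- normalize_spikein(m)
  expect_equal(nm$values["m1", "s1"], 0)            # R = B
  expect_equal(nm$values["m2", "s1"], 1)            # R = B + slope
  expect_equal(nm$values["m3", "s1"], 0)            # negative clipped
  expect_equal(nm$values["m4", "s1"], (500 - 325) / 10)
  expect_false(any(rownames(nm$values) %in% rownames(spikes)))
  expect_equal(nm$log2_values, log2(nm$values + 1))

  # per-sample affine map preserves within-sample rank order (above clipping)
  keep <- c("m1", "m2", "m4")
  expect_identical(order(nm$values[keep, "s2"]), order(counts[keep, "s2"]))
  # clipping monotonicity: raising a raw count never lowers its normalized value
  counts2 <- counts; counts2["m3", "s1"] <- 400L
  m2 <- count_matrix(rbind(counts2, spikes), m$meta, m$spike_concs)
  nm2 <- normalize_spikein(m2)
  expect_gte(nm2$values["m3", "s1"], nm$values["m3", "s1"])

  expect_error(normalize_spikein(m, fits = list(s1 = fit_spikein_response(
    spikes[, 1], c(32, 8, 2, 0.5)))), "missing spike-in fit")
})

test_that("global normalization equalizes sample means and is idempotent", {
  # hand-computable case: sample means 10 and 20 -> factors 1.5 and 0.75
  nm <- structure(list(
    values = matrix(c(5, 15, 10, 30), 2,
                    dimnames = list(c("f1", "f2"), c("s1", "s2"))),
    meta = data.frame(sample_id = c("s1", "s2"), condition = c("a", "b"),
                      timepoint = "t1"),
    pseudocount = 1), class = "normalized_matrix")
  nm$log2_values <- log2(nm$values + 1)
  g <- global_normalize(nm)
  expect_equal(unname(g$scale_factors), c(1.5, 0.75))
  expect_equal(unname(colMeans(g$values)), c(15, 15))
  expect_equal(mean(g$values), mean(nm$values))     # grand mean preserved
  expect_equal(global_normalize(g)$values, g$values) # idempotent
  # within-sample ratios of nonzero values preserved
  expect_equal(g$values["f2", "s1"] / g$values["f1", "s1"],
               nm$values["f2", "s1"] / nm$values["f1", "s1"])

  # defining property on random matrices
  set.seed(1)
  for (i in 1:20) {
    v <- matrix(rexp(40, 0.1), 8, 5,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
    x <- structure(list(values = v, log2_values = log2(v + 1),
                        meta = NULL, pseudocount = 1),
                   class = "normalized_matrix")
    gx <- global_normalize(x)
    expect_lt(max(abs(colMeans(gx$values) - mean(v))), 1e-12)
  }

  nm$values[, "s1"] <- 0
  expect_error(global_normalize(nm), "all-zero")
})

test_that("pipeline closure: zero-noise run is recovered up to one global scalar", {
  # per-sample hybridization efficiencies vary; probe-level noise is zero.
  # A large slope keeps integer rounding negligible relative to the signal.
  cfg <- sim_config(n_mirnas = 12, noise_cv = 0, sample_cv = 0.15,
                    hyb_slope = 1000, conditions = c("crxnrl", "shA"),
                    baseline_abund = rep(c(50, 120, 300), 4), seed = 5)
  m <- simulate_ncounter(cfg)
  g <- global_normalize(normalize_spikein(m))
  truth <- attr(m, "truth")$abundance
  ratio <- g$values / truth
  expect_lt(diff(range(ratio)), 1e-4)  # one scalar for the whole run
})

test_that("counts round-trip through CSV and the minimal RCC dialect", {
  m <- zero_noise_matrix(n_mirnas = 6)
  tdir <- withr::local_tempdir()
  cpath <- file.path(tdir, "counts.csv")
  mpath <- file.path(tdir, "meta.csv")
  write_counts(m, cpath, mpath)
  m2 <- read_counts(cpath, mpath, format = "csv", spike_concs = m$spike_concs)
  expect_identical(m2$counts, m$counts)
  expect_identical(m2$meta$condition, m$meta$condition)

  rdir <- file.path(tdir, "rcc")
  write_rcc(m, rdir)
  m3 <- read_counts(rdir, mpath, format = "rcc", spike_concs = m$spike_concs)
  expect_identical(m3$counts[, colnames(m$counts)], m$counts)
})

test_that("count matrix validation names the offending cell or sample", {
  counts <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), condition = "c",
                     timepoint = "t")
  bad <- counts; bad["b", "s2"] <- -1L
  expect_error(count_matrix(bad, meta), "feature 'b', sample 's2'")
  dup <- counts; rownames(dup) <- c("a", "a")
  expect_error(count_matrix(dup, meta), "duplicate feature")
  meta2 <- meta; meta2$condition[2] <- NA
  expect_error(count_matrix(counts, meta2), "s2")
  expect_error(count_matrix(counts, meta[1, ]), "match")

  tdir <- withr::local_tempdir()
  f <- file.path(tdir, "bad.rcc")
  writeLines(c("<CodeSummary>", "Name,Count", "x,1,2", "</CodeSummary>"), f)
  expect_error(read_counts(f, meta, format = "rcc"), "Name,Count")
})
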