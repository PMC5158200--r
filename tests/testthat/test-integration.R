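test_that("set overlap computes intersections and direction concordance", {
  a <- feature_set("shPias2_50",
                   c(sprintf("mir-x%02d", 1:33), "hsa-miR-654-3p",
                     "hsa-miR-760"),
                   direction = setNames(
                     c(rep("up", 14), rep("down", 21)),
                     c(sprintf("mir-x%02d", 1:33), "hsa-miR-654-3p",
                       "hsa-miR-760")))
  b <- feature_set("shPias2_49",
                   c(sprintf("mir-y%02d", 1:15), "hsa-miR-654-3p",
                     "hsa-miR-760"),
                   direction = setNames(
                     c(rep("up", 4), rep("down", 13)),
                     c(sprintf("mir-y%02d", 1:15), "hsa-miR-654-3p",
                       "hsa-miR-760")))
  ov <- set_overlap(a, b)
  expect_identical(sort(ov$intersection),
                   sort(c("hsa-miR-654-3p", "hsa-miR-760")))
  expect_identical(ov$n, 2L)
  expect_identical(ov$concordant, 2L)   # both downregulated in both sets
  expect_identical(ov$discordant, 0L)

  expect_identical(set_overlap(feature_set("p", c("a", "b")),
                               feature_set("q", c("c")))$n, 0L)
  sub <- feature_set("s", c("a", "b"))
  sup <- feature_set("S", c("a", "b", "c"))
  expect_identical(sort(set_overlap(sub, sup)$intersection), c("a", "b"))
  # commutative, bounded by the smaller set
  expect_identical(set_overlap(a, b)$n, set_overlap(b, a)$n)
  expect_lte(ov$n, min(length(a$members), length(b$members)))
})

test_that("miRNA-target intersection finds exactly the DE predicted targets", {
  tmap <- list("hsa-miR-760" = c("HIST1H2AE", "HIST1H2BJ", "HIST2H2AB", "X"))
  de_m <- feature_set("mirnas", "hsa-miR-760",
                      direction = c("hsa-miR-760" = "down"))
  de_g <- feature_set("genes",
                      c("HIST1H2AE", "HIST1H2BJ", "HIST2H2AB", "OTHER"),
                      direction = setNames(rep("down", 4),
                                           c("HIST1H2AE", "HIST1H2BJ",
                                             "HIST2H2AB", "OTHER")))
  got <- target_intersect(de_m, tmap, de_g)
  expect_identical(nrow(got), 3L)
  expect_identical(sort(got$gene), c("HIST1H2AE", "HIST1H2BJ", "HIST2H2AB"))
  # miRNA down + target down is not consistent with direct repression relief
  expect_true(all(!got$repression_consistent))

  expect_identical(nrow(target_intersect(de_m, list(), de_g)), 0L)

  # randomized instances match a brute-force triple loop
  set.seed(14)
  for (i in 1:20) {
    mirnas <- sprintf("m%d", 1:4)
    genes <- sprintf("g%d", 1:8)
    tm <- lapply(setNames(mirnas, mirnas),
                 function(m) sample(genes, sample(0:5, 1)))
    dm <- feature_set("m", sample(mirnas, sample(1:4, 1)))
    dg <- feature_set("g", sample(genes, sample(1:8, 1)))
    got <- target_intersect(dm, tm, dg)
    brute <- 0L
    for (m in dm$members) for (g in dg$members)
      if (m %in% names(tm) && g %in% tm[[m]]) brute <- brute + 1L
    expect_identical(nrow(got), brute)
    expect_lte(nrow(got), sum(lengths(tm)))
  }
})

test_that("family enrichment reports the printed percentage convention", {
  # 20 histone genes in a 10000-gene universe: 7 of 320 draws is surprising
  fam <- data.frame(
    gene = c(sprintf("HIST%02d", 1:20), sprintf("g%04d", 1:9980)),
    family = rep(c("histone", "other"), c(20, 9980)))
  de <- feature_set("de", c(sprintf("HIST%02d", 1:7),
                            sprintf("g%04d", 1:313)))
  enr <- family_enrichment(de, fam, "histone")
  expect_identical(enr$k, 7L)
  expect_identical(enr$n, 320L)
  expect_identical(enr$percent, 2.19)   # 7/320, rounded half-up to 2 dp
  expect_equal(enr$p, 1.742359e-06, tolerance = 1e-6)

  none <- family_enrichment(feature_set("de", sprintf("g%04d", 1:10)),
                            fam, "histone")
  expect_identical(none$k, 0L)
  expect_identical(none$percent, 0)
  expect_equal(none$p, 1)
  expect_error(family_enrichment(de, fam, "kinase"), "absent")
  expect_error(family_enrichment(de, fam, "histone", background = 10),
               "smaller")
})

test_that("hypergeometric p matches exhaustive enumeration and is monotone in k", {
  set.seed(15)
  for (i in 1:30) {
    bg <- sample(6:12, 1)
    K <- sample(2:(bg - 2), 1)
    n <- sample(2:(bg - 1), 1)
    k <- sample(0:min(K, n), 1)
    fam <- data.frame(gene = as.character(1:bg),
                      family = rep(c("f", "o"), c(K, bg - K)))
    # any DE list of size n with exactly k family members gives the same p
    de <- feature_set("de", as.character(c(seq_len(k),
                                           K + seq_len(n - k))))
    enr <- family_enrichment(de, fam, "f")
    expect_equal(enr$p, oracle_hyper(k, K, bg, n), tolerance = 1e-10)
  }
  # p decreases as k rises at fixed (background, family, n)
  fam <- data.frame(gene = as.character(1:100),
                    family = rep(c("f", "o"), c(10, 90)))
  ps <- sapply(0:5, function(k) {
    de <- feature_set("de", as.character(c(seq_len(k), 10 + seq_len(20 - k))))
    family_enrichment(de, fam, "f")$p
  })
  expect_true(all(diff(ps) < 0))
})

test_that("R-squared matches the covariance-formula oracle", {
  x <- 1:10
  expect_equal(r_squared(x, 2 * x + 1), 1)
  set.seed(16)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(length(x))
    expect_equal(r_squared(x, y), oracle_r2(x, y), tolerance = 1e-12)
    expect_equal(r_squared(x, y), r_squared(y, x), tolerance = 1e-15)
  }
  expect_warning(out <- r_squared(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(out))
  expect_error(r_squared(1:2, 1:2), ">= 3")
})

test_that("target map and family annotation TSV readers validate their input", {
  tdir <- withr::local_tempdir()
  tm_path <- file.path(tdir, "tmap.tsv")
  writeLines(c("mirna\tgene", "miR-1\tGENE1", "miR-1\tGENE2", "miR-2\tGENE1"),
             tm_path)
  tm <- read_target_map(tm_path)
  expect_identical(tm[["miR-1"]], c("GENE1", "GENE2"))
  fam_path <- file.path(tdir, "fam.tsv")
  writeLines(c("gene\tfamily", "GENE1\thistone"), fam_path)
  expect_identical(read_family_annotation(fam_path)$family, "histone")
  writeLines(c("a\tb", "x\ty"), tm_path)
  expect_error(read_target_map(tm_path), "mirna")
})
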