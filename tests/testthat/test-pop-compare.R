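test_that("Fisher two-sided p-values match enumeration and fisher.test", {
  # (5,0,0,5): only the two extreme tables of the 6 with margins (5,5;5,5)
  # are as improbable as observed: p = 2 * C(5,5)C(5,0)/C(10,5) = 2/252
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252,
               tolerance = 1e-12)
  # modal symmetric table
  expect_equal(fisher_exact_two_sided(2, 3, 2, 3), 1.0)
  # row-swap symmetry
  set.seed(15)
  for (i in 1:20) {
    x <- sample(0:12, 4, replace = TRUE)
    expect_equal(fisher_exact_two_sided(x[1], x[2], x[3], x[4]),
                 fisher_exact_two_sided(x[3], x[4], x[1], x[2]),
                 tolerance = 1e-12)
  }
  # full enumeration oracle on all tables with row sums <= 12
  dev <- 0
  for (r1 in 0:12) for (r2 in 0:12) {
    n <- r1 + r2
    if (n == 0) next
    for (c1 in 0:n) {
      lo <- max(0, c1 - r2); hi <- min(r1, c1)
      for (a in lo:hi) {
        b <- r1 - a; cc <- c1 - a; d <- r2 - cc
        dev <- max(dev, abs(fisher_exact_two_sided(a, b, cc, d) -
                              fisher_oracle(a, b, cc, d)))
      }
    }
  }
  expect_lt(dev, 1e-12)
  # spot-check against stats::fisher.test on larger random tables
  set.seed(16)
  for (i in 1:50) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x) == 0) next
    ft <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact_two_sided(x[1], x[2], x[3], x[4]), ft,
                 tolerance = 1e-10)
  }
})

test_that("BH q-values match the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(17)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in p-rank
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("odds ratios follow the Haldane-Anscombe convention", {
  expect_equal(odds_ratio(10, 10, 5, 15), 3.0)
  expect_equal(odds_ratio(5, 5, 5, 5), 1.0)
  expect_equal(odds_ratio(5, 0, 0, 5), (5.5 * 5.5) / (0.5 * 0.5))  # 121
  set.seed(18)
  for (i in 1:20) {
    x <- sample(1:30, 4, replace = TRUE)  # no zero cells
    expect_equal(odds_ratio(x[1], x[2], x[3], x[4]) *
                   odds_ratio(x[2], x[1], x[4], x[3]), 1.0,
                 tolerance = 1e-12)
  }
})

test_that("absence tables count cohort-wise, male-only on chrY", {
  meta_case <- tibble::tibble(sample = sprintf("c%02d", 1:10), cohort = "case",
                              sex = rep(c("male", "female"), 5))
  meta_ctrl <- tibble::tibble(sample = sprintf("k%02d", 1:10),
                              cohort = "ctrl",
                              sex = rep(c("male", "female"), 5))
  pres_case <- matrix(TRUE, 10, 2, dimnames = list(meta_case$sample,
                                                   c("g1", "gY")))
  pres_case[1:3, "g1"] <- FALSE
  pres_ctrl <- matrix(TRUE, 10, 2, dimnames = list(meta_ctrl$sample,
                                                   c("g1", "gY")))
  mc <- make_pav_matrix(pres_case, meta_case, seqnames = c("chr1", "chrY"))
  mk <- make_pav_matrix(pres_ctrl, meta_ctrl, seqnames = c("chr1", "chrY"))
  expect_equal(unname(absence_table(mc, mk, "g1")), c(3L, 7L, 0L, 10L))
  # chrY gene counted over the 5 males per cohort only
  expect_equal(unname(absence_table(mc, mk, "gY")), c(0L, 5L, 0L, 5L))
  expect_error(absence_table(mc, mk, "nope"), "missing")
  # identical matrices give equal frequencies
  k <- absence_table(mc, mc, "g1")
  expect_equal(k[["a"]] / (k[["a"]] + k[["b"]]),
               k[["c"]] / (k[["c"]] + k[["d"]]))
})

test_that("cohort comparison flags reproduce the BH step-up rejection set", {
  set.seed(19)
  n <- 40L
  meta_a <- tibble::tibble(sample = sprintf("a%02d", 1:n), cohort = "a",
                           sex = "male")
  meta_b <- tibble::tibble(sample = sprintf("b%02d", 1:n), cohort = "b",
                           sex = "male")
  gene_ids <- sprintf("g%02d", 1:12)
  pa <- matrix(runif(n * 12) > c(rep(0.7, n * 3), rep(0.05, n * 9)), n, 12,
               dimnames = list(meta_a$sample, gene_ids))
  pb <- matrix(runif(n * 12) > 0.05, n, 12,
               dimnames = list(meta_b$sample, gene_ids))
  cmp <- compare_cohorts(make_pav_matrix(pa, meta_a),
                         make_pav_matrix(pb, meta_b))
  expect_s3_class(cmp, "pav_comparison")
  expect_equal(nrow(cmp), 12L)
  expect_equal(cmp$a + cmp$b, rep(n, 12L))
  # flags = BH step-up rejection set at alpha
  expect_identical(cmp$flagged, bh_oracle(cmp$p) < 0.05)
  # sorted by q then gene
  expect_true(all(diff(cmp$q) >= -1e-12))
  # empty gene intersection
  cmp0 <- compare_cohorts(make_pav_matrix(pa, meta_a),
                          make_pav_matrix(pb, meta_b), genes = character(0))
  expect_equal(nrow(cmp0), 0L)
  expect_s3_class(glance(cmp), "tbl_df")
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("HAG/LAG splits top-ranked distributed genes at 50% coverage", {
  meta <- tibble::tibble(sample = sprintf("s%02d", 1:10), cohort = "a",
                         sex = "male")
  gene_ids <- c("hag1", "lag1", "rare", "core1")
  pres <- matrix(TRUE, 10, 4, dimnames = list(meta$sample, gene_ids))
  pres[1:9, "hag1"] <- FALSE
  pres[1:6, "lag1"] <- FALSE
  pres[1, "rare"] <- FALSE
  m <- make_pav_matrix(pres, meta)
  # coverage patterns: absences at 0.1 for hag1, 0.7 for lag1, 0.6 for rare
  cov_of <- function(g, v) {
    i <- m$calls$gene_id == g & !m$calls$present
    m$calls$coverage[i] <<- v
  }
  cov_of("hag1", 0.1); cov_of("lag1", 0.7); cov_of("rare", 0.6)
  res <- hag_lag(m, top_n = 2L)
  expect_equal(res$gene_id, c("hag1", "lag1"))
  expect_equal(res$category, c("HAG", "LAG"))
  # fewer distributed genes than top_n: all ranked, none invented
  res_all <- hag_lag(m, top_n = 20L)
  expect_equal(nrow(res_all), 3L)
  expect_false("core1" %in% res_all$gene_id)
})

test_that("phenotype association needs a contrast and skips chrY for sex", {
  meta <- tibble::tibble(sample = sprintf("s%02d", 1:20), cohort = "a",
                         sex = rep(c("male", "female"), 10),
                         lauren = rep(c("intestinal", "diffuse"), each = 10),
                         grade = "G2")
  set.seed(20)
  pres <- matrix(runif(20 * 4) > 0.2, 20, 4,
                 dimnames = list(meta$sample, c("g1", "g2", "g3", "gY")))
  pres[meta$sex == "female", "gY"] <- FALSE
  m <- make_pav_matrix(pres, meta,
                       seqnames = c("chr1", "chr1", "chr2", "chrY"))
  expect_error(phenotype_association(m, "grade"), "fewer than two levels")
  expect_error(phenotype_association(m, "missing_col"), "not in sample")
  res <- phenotype_association(m, "lauren")
  expect_equal(nrow(res), 4L)
  res_sex <- phenotype_association(m, "sex")
  expect_false("gY" %in% res_sex$gene_id)
  expect_equal(nrow(res_sex), 3L)
})

test_that("Fisher tests keep their type-I level on null presence data", {
  # discrete exact tests are conservative: P(p <= a) <= a at every level
  set.seed(22)
  n <- 30L; n_genes <- 15L; n_sims <- 60L
  pvals <- numeric(0)
  meta_a <- tibble::tibble(sample = sprintf("a%02d", 1:n), cohort = "a",
                           sex = "male")
  meta_b <- tibble::tibble(sample = sprintf("b%02d", 1:n), cohort = "b",
                           sex = "male")
  ids <- sprintf("g%02d", seq_len(n_genes))
  for (s in seq_len(n_sims)) {
    pa <- matrix(runif(n * n_genes) > 0.3, n, n_genes,
                 dimnames = list(meta_a$sample, ids))
    pb <- matrix(runif(n * n_genes) > 0.3, n, n_genes,
                 dimnames = list(meta_b$sample, ids))
    cmp <- compare_cohorts(make_pav_matrix(pa, meta_a),
                           make_pav_matrix(pb, meta_b))
    pvals <- c(pvals, cmp$p)
  }
  m <- length(pvals)
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / m))
  }
})
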