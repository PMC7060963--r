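make_design <- function(n1 = 5, n2 = 5, g = c("A", "B")) {
  data.frame(sample = paste0("s", seq_len(n1 + n2)),
             group = rep(g, c(n1, n2)))
}

test_that("size factors: identical columns, scaling, hand example", {
  m <- matrix(c(4, 9), 1, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(4 / 6, 9 / 6), tolerance = 1e-12)
  m2 <- matrix(rpois(50, 20) + 1, 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  m2[, ] <- m2[, 1]                          # identical columns
  expect_equal(unname(size_factors(m2)), rep(1, 5) * size_factors(m2)[[1]])
  expect_true(all(size_factors(m2) == size_factors(m2)[1]))
  # scaling equivariance within one matrix: a sample that is an exact
  # 3-fold scaled copy of another gets a 3-fold size factor, and the two
  # samples' normalized counts coincide
  set.seed(3)
  m3 <- matrix(rpois(300, 50) + 1, 60, 5,
               dimnames = list(paste0("g", 1:60), paste0("s", 1:5)))
  m4 <- cbind(m3, s6 = m3[, 2] * 3)
  sf4 <- size_factors(m4)
  expect_equal(unname(sf4["s6"]), unname(sf4["s2"]) * 3, tolerance = 1e-12)
  z <- normalize_counts(m4, sf4)
  expect_equal(z[, "s6"], z[, "s2"], ignore_attr = TRUE)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "size factors undefined")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  set.seed(14)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 10), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  suppressMessages(ref <- DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(size_factors(m), ref, tolerance = 1e-10)
})

test_that("log2 fold change of median-normalized means", {
  d <- make_design()
  m <- matrix(100L, 20, 10, dimnames = list(paste0("g", 1:20), d$sample))
  cm <- count_matrix(m, d)
  expect_equal(unname(log2fc_median_norm(cm, contrast = c("B", "A"))),
               rep(0, 20))
  m2 <- m; m2[, d$group == "B"] <- 400L
  expect_equal(unname(log2fc_median_norm(m2, setNames(d$group, d$sample),
                                         c("B", "A"), sf = rep(1, 10))),
               rep(log2(401 / 101), 20))
  expect_error(log2fc_median_norm(cm, contrast = c("C", "A")), "no samples")
})

test_that("planted CRISPLD1-like effect is estimated near 1.6 at depth", {
  # CH vs NF with 5 vs 4 samples, baseline mean 200, dispersion 0.05
  d <- make_design(4, 5, c("NF", "CH"))
  pe <- matrix(1.6, 1, 1, dimnames = list(NULL, "CH"))
  est <- replicate(60, {
    p <- count_sim_params(400, d, dispersion = 0.05, mu0 = 200,
                          planted_effects = pe)
    cm <- gen_counts(p, seed = sample.int(1e6, 1))
    log2fc_median_norm(cm, contrast = c("CH", "NF"))[["GENE00001"]]
  })
  expect_lt(abs(mean(est) - 1.6), 0.15)
})

test_that("NB LRT matches brute-force likelihood maximization on one gene", {
  y <- matrix(c(0, 1, 50, 60), 1, dimnames = list("g", paste0("s", 1:4)))
  g <- setNames(c("A", "A", "B", "B"), colnames(y))
  alpha <- 0.1
  p <- nb_lrt_test(y, g, c("B", "A"), sf = rep(1, 4), alpha = alpha)
  ll <- function(mu, yy) sum(dnbinom(yy, mu = mu, size = 1 / alpha, log = TRUE))
  l0 <- optimize(function(m) ll(m, c(0, 1, 50, 60)), c(1e-6, 200),
                 maximum = TRUE)$objective
  l1 <- optimize(function(m) ll(m, c(0, 1)), c(1e-6, 200),
                 maximum = TRUE)$objective +
    optimize(function(m) ll(m, c(50, 60)), c(1e-6, 200),
             maximum = TRUE)$objective
  expect_equal(unname(p), pchisq(2 * (l1 - l0), 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("all-zero genes get p = 1 and are dropped from DE tables", {
  d <- make_design(3, 3)
  m <- matrix(rpois(60, 30), 10, 6, dimnames = list(paste0("g", 1:10), d$sample))
  m[4, ] <- 0L
  g <- setNames(d$group, d$sample)
  p <- nb_lrt_test(m, g, c("B", "A"), sf = rep(1, 6))
  expect_equal(unname(p["g4"]), 1)
  dt <- de_table(count_matrix(m, d), contrast = c("B", "A"))
  expect_false("g4" %in% dt$gene_id)
  expect_equal(attr(dt, "n_dropped"), 1L)
})

test_that("NB LRT null p-values are approximately uniform", {
  d <- make_design()
  p0 <- count_sim_params(2000, d, dispersion = 0.05, mu0 = 200,
                         size_factor_range = c(0.7, 1.4))
  cm <- gen_counts(p0, seed = 1)
  pv <- nb_lrt_test(cm, contrast = c("B", "A"))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.013), 0.013)
  set.seed(30)
  for (i in 1:20) {
    p <- runif(sample(2:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # ties share the adjusted value
  p <- c(0.01, 0.01, 0.5)
  expect_equal(bh_adjust(p)[1], bh_adjust(p)[2])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG filtering applies both thresholds with direction labels", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(1.2, 0.8, -1.5),
                    q_value = c(0.01, 0.01, 0.2))
  out <- filter_degs(tab, 1, 0.05)
  expect_equal(out$gene_id, "a")
  expect_equal(out$direction, "up")
  expect_equal(nrow(filter_degs(tab[0, ], 1, 0.05)), 0)
  # the looser in-vitro setting keeps the sub-unit fold change too
  out2 <- filter_degs(tab, 0.5, 0.05)
  expect_setequal(out2$gene_id, c("a", "b"))
  expect_error(filter_degs(tab, 0, 0.05), "thresholds")
})

test_that("realized FDR stays controlled and planted genes are found", {
  d <- make_design()
  planted <- sprintf("GENE%05d", 1:100)
  res <- t(replicate(20, {
    pe <- matrix(2, 100, 1, dimnames = list(NULL, "B"))
    p <- count_sim_params(2000, d, dispersion = 0.05, mu0 = 200,
                          planted_effects = pe)
    cm <- gen_counts(p, seed = sample.int(1e6, 1))
    dg <- filter_degs(de_table(cm, contrast = c("B", "A")), 1, 0.05)
    c(fdr = if (nrow(dg) == 0) 0 else mean(!(dg$gene_id %in% planted)),
      power = mean(planted %in% dg$gene_id))
  }))
  expect_lte(mean(res[, "fdr"]), 0.10)
  expect_gte(mean(res[, "power"]), 0.90)
})

test_that("count matrices round-trip through TSV", {
  d <- make_design(2, 2)
  m <- matrix(rpois(20, 40), 5, 4,
              dimnames = list(paste0("g", 1:5), d$sample))
  cm <- count_matrix(m, d)
  cf <- withr::local_tempfile(fileext = ".tsv")
  df <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, cf, df)
  back <- read_counts(cf, df)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$design$group, cm$design$group)
})

test_that("NB generator moments match mean and overdispersion targets", {
  # Var / mean of NB at mu = 100, alpha = 0.1 is 1 + alpha mu = 11
  d <- data.frame(sample = paste0("s", 1:100), group = rep("A", 100))
  p <- count_sim_params(1000, d, dispersion = 0.1, mu0 = 100,
                        size_factor_range = c(1, 1))
  cm <- gen_counts(p, seed = 9)
  x <- as.vector(cm$counts)                   # 1e5 draws
  expect_equal(mean(x), 100, tolerance = 0.01)
  expect_equal(var(x) / mean(x), 11, tolerance = 0.1)
  # alpha = 0 limit is Poisson: variance equals mean
  p0 <- count_sim_params(1000, d, dispersion = 0, mu0 = 100,
                         size_factor_range = c(1, 1))
  x0 <- as.vector(gen_counts(p0, seed = 9)$counts)
  expect_equal(var(x0) / mean(x0), 1, tolerance = 0.05)
  expect_true(all(x0 == round(x0)) && all(x0 >= 0))
  # planted log2FC = 2 at large mu: ratio of normalized group means ~ 4
  d2 <- make_design()
  pe <- matrix(2, 1, 1, dimnames = list(NULL, "B"))
  p2 <- count_sim_params(500, d2, dispersion = 0.02, mu0 = 500,
                         size_factor_range = c(1, 1), planted_effects = pe)
  cm2 <- gen_counts(p2, seed = 10)
  z <- cm2$counts[1, ]
  g <- cm2$design$group
  expect_equal(mean(z[g == "B"]) / mean(z[g == "A"]), 4, tolerance = 0.15)
})
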