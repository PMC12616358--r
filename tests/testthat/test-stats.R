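test_that("LN mean follows the log-normal MLE formula", {
  expect_equal(lnMean(rep(7, 10)), 7)                  # s^2 = 0
  expect_equal(lnMean(c(1, exp(2))), exp(1.5))         # m = 1, s^2 = 1 (1/n)
  expect_equal(lnMean(42), 42)                         # degenerate n = 1
  expect_error(lnMean(c(1, 0)), class = "clonequant_data_error")
  expect_error(lnMean(numeric(0)), class = "clonequant_data_error")
})

test_that("percentile sizes use linear interpolation and are monotone", {
  expect_equal(percentileSize(1:100, 50), 50.5)
  expect_equal(percentileSize(rep(3, 9), 90), 3)
  set.seed(1)
  x <- rlnorm(57, 5, 2)
  qs <- vapply(c(50, 60, 70, 80, 90), function(q) percentileSize(x, q),
               numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("relative metric divides by the median across inert vectors", {
  expect_equal(relativeMetric(2.3, c(1.0, 1.1, 1.2, 1.3)), 2)
  expect_equal(relativeMetric(1.15, c(1.0, 1.1, 1.2, 1.3)), 1)
  expect_equal(relativeMetric(3, 1.5), 2)  # single inert vector
  expect_error(relativeMetric(1, numeric(0)),
               class = "clonequant_data_error")
})

test_that("gene aggregation weights sgRNAs by sampled tumor counts", {
  expect_equal(aggregateGene(c(2, 1), c(300, 100)), 1.75)
  expect_equal(aggregateGene(c(2, 1), c(100, 100)), 1.5)
  expect_equal(aggregateGene(5, 10), 5)
  expect_equal(aggregateGene(c(2, NA), c(100, 100)), 2)  # NA sgRNA dropped
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
})

test_that("burden and number use a strict >500-cell cutoff and titer scaling", {
  ts <- makeTumorSet(list(m1 = list(A = c(600, 400, 1000))), titer = 1)
  bn <- burdenAndNumber(ts, titer_adjust = FALSE)
  expect_equal(bn$tumor_number, 2)
  expect_equal(bn$burden, 1600)
  ts2 <- makeTumorSet(list(m1 = list(A = c(500, 501))), titer = 1)
  bn2 <- burdenAndNumber(ts2, titer_adjust = FALSE)
  expect_equal(bn2$tumor_number, 1)   # exactly 500 excluded
  ts3 <- makeTumorSet(list(m1 = list(A = c(600, 400, 1000))), titer = 2)
  bn3 <- burdenAndNumber(ts3)
  expect_equal(bn3$tumor_number, 1)
  expect_equal(bn3$burden, 800)
})

test_that("empirical p-values follow the two-sided tail convention", {
  t_rep <- c(rep(2, 9900), rep(0.5, 100))
  expect_equal(clonequant:::.empiricalP(t_rep, 1), 0.02)
  # all replicates above baseline: floored at 2/B
  expect_equal(clonequant:::.empiricalP(rep(2, 1000), 1), 2 / 1000)
  # ties at the baseline split equally
  expect_equal(clonequant:::.empiricalP(c(rep(1, 10), rep(2, 10)), 1), 0.5)
})

test_that("degenerate cohorts give a point-mass bootstrap (CI = [1, 1])", {
  ts <- makeTumorSet(list(m1 = list(AAAACCCC = rep(100, 20),
                                    CCCCAAAA = rep(100, 20),
                                    GGGGTTTT = rep(100, 20),
                                    TTTTGGGG = rep(100, 20)),
                          m2 = list(AAAACCCC = rep(100, 20),
                                    CCCCAAAA = rep(100, 20),
                                    GGGGTTTT = rep(100, 20),
                                    TTTTGGGG = rep(100, 20))))
  vec <- statsVectors("GeneA")
  plan <- flatPlan(ts, 20L)
  stat <- function(x) {
    rs <- relativeStats(x, plan, vec, "c1")
    setNames(rs$estimate, rs$gene)
  }
  br <- nestedBootstrap(ts, stat, B = 50L, seed = 9)
  et <- suppressWarnings(effectTable(br))
  expect_true(all(et$ci_lo == 1 & et$ci_hi == 1))
  expect_true(all(br@point == 1))
})

test_that("bootstrap results are deterministic in the seed", {
  set.seed(30)
  ts <- makeTumorSet(list(
    m1 = list(AAAACCCC = rlnorm(40, 5, 1), CCCCAAAA = rlnorm(40, 5, 1),
              GGGGTTTT = rlnorm(40, 5, 1), TTTTGGGG = rlnorm(50, 5.5, 1)),
    m2 = list(AAAACCCC = rlnorm(60, 5, 1), CCCCAAAA = rlnorm(30, 5, 1),
              GGGGTTTT = rlnorm(40, 5, 1), TTTTGGGG = rlnorm(40, 5.5, 1)),
    m3 = list(AAAACCCC = rlnorm(50, 5, 1), CCCCAAAA = rlnorm(50, 5, 1),
              GGGGTTTT = rlnorm(40, 5, 1), TTTTGGGG = rlnorm(30, 5.5, 1))))
  vec <- statsVectors("GeneA")
  plan <- flatPlan(ts, 30L)
  b1 <- bootstrapRelativeLNMean(ts, plan, vec, "c1", B = 200L, seed = 4)
  b2 <- bootstrapRelativeLNMean(ts, plan, vec, "c1", B = 200L, seed = 4)
  expect_identical(replicates(b1), replicates(b2))
  expect_identical(effectTable(b1), effectTable(b2))
  b3 <- bootstrapRelativeLNMean(ts, plan, vec, "c1", B = 200L, seed = 5)
  expect_false(identical(replicates(b1), replicates(b3)))
})

test_that("compiled bootstrap matches the R statistic exactly at the point", {
  set.seed(12)
  sizes <- lapply(1:4, function(m)
    list(AAAACCCC = rlnorm(30 + 5 * m, 5, 1.5),
         CCCCAAAA = rlnorm(40, 5, 1.5),
         GGGGTTTT = rlnorm(35, 5, 1.5),
         TTTTGGGG = rlnorm(45, 5.4, 1.5),
         AAAAGGGG = rlnorm(25, 4.8, 1.5)))
  names(sizes) <- paste0("m", 1:4)
  ts <- makeTumorSet(sizes)
  vec <- statsVectors(c("GeneA", "GeneB"))
  plan <- flatPlan(ts, 25L)
  rs <- relativeStats(ts, plan, vec, "c1")
  br <- bootstrapRelativeLNMean(ts, plan, vec, "c1", B = 10L, seed = 1)
  expect_equal(unname(br@point[rs$gene]), rs$estimate, tolerance = 1e-12)
  # and the replicate distribution agrees with the generic R bootstrap
  stat <- function(x) {
    r <- relativeStats(x, plan, vec, "c1")
    setNames(r$estimate, r$gene)
  }
  brR <- nestedBootstrap(ts, stat, B = 300L, seed = 2)
  brC <- bootstrapRelativeLNMean(ts, plan, vec, "c1", B = 300L, seed = 2)
  mR <- colMeans(replicates(brR)[, rs$gene], na.rm = TRUE)
  mC <- colMeans(replicates(brC)[, rs$gene], na.rm = TRUE)
  expect_equal(mR, mC, tolerance = 0.15)
})

test_that("age contrast pairs replicates and reduces to q = p for one gene", {
  repY <- matrix(rnorm(100, 1.2, 0.1), ncol = 1,
                 dimnames = list(NULL, "GeneA"))
  repA <- matrix(rnorm(100, 1.0, 0.1), ncol = 1,
                 dimnames = list(NULL, "GeneA"))
  brY <- new("BootstrapResult", replicates = repY,
             point = c(GeneA = 1.2), baseline = 1, B = 100L, seed = 1L)
  brA <- new("BootstrapResult", replicates = repA,
             point = c(GeneA = 1.0), baseline = 1, B = 100L, seed = 1L)
  ct <- contrastAge(brY, brA)
  expect_equal(ct$estimate, 0.2)
  expect_identical(ct$q, ct$p)
  expect_equal(replicates(brY) - replicates(brA),
               matrix(repY - repA, ncol = 1, dimnames = list(NULL, "GeneA")))
})

test_that("scoreRGM is zero when aged is an exact copy of young", {
  set.seed(21)
  sizes <- lapply(1:3, function(m)
    list(AAAACCCC = round(rlnorm(80, 7, 1)) + 1,
         CCCCAAAA = round(rlnorm(80, 7, 1)) + 1,
         GGGGTTTT = round(rlnorm(80, 7, 1)) + 1,
         TTTTGGGG = round(rlnorm(60, 7.5, 1)) + 1))
  names(sizes) <- paste0("m", 1:3)
  young <- makeTumorSet(sizes)
  aged <- makeTumorSet(sizes)
  vec <- statsVectors("GeneA")
  res <- scoreRGM(young, aged, vec, "GeneA")
  expect_equal(res$R, 1, tolerance = 1e-3)
  expect_equal(res$score, 0, tolerance = 1e-9)
})

test_that("uniform size scaling cancels in scoreRGM (R tracks the scale)", {
  set.seed(22)
  sizes <- lapply(1:3, function(m)
    list(AAAACCCC = round(rlnorm(150, 7, 1)) + 1,
         CCCCAAAA = round(rlnorm(150, 7, 1)) + 1,
         GGGGTTTT = round(rlnorm(150, 7, 1)) + 1,
         TTTTGGGG = round(rlnorm(120, 7.5, 1)) + 1))
  names(sizes) <- paste0("m", 1:3)
  young <- makeTumorSet(sizes)
  half <- lapply(sizes, function(g) lapply(g, function(x) x * 0.5))
  aged <- makeTumorSet(half)
  vec <- statsVectors("GeneA")
  r_grid <- fitReductionFactor(young, aged, vec, method = "grid")
  expect_equal(r_grid, 0.5, tolerance = 0.05)
  res <- scoreRGM(young, aged, vec, "GeneA", R = r_grid)
  expect_equal(res$score, 0, tolerance = 0.1)
})

test_that("scoreRGM negates under a consistent young/aged label swap", {
  set.seed(23)
  sizes_y <- lapply(1:3, function(m)
    list(AAAACCCC = round(rlnorm(100, 7, 1)) + 1,
         CCCCAAAA = round(rlnorm(100, 7, 1)) + 1,
         GGGGTTTT = round(rlnorm(100, 7, 1)) + 1,
         TTTTGGGG = round(rlnorm(90, 7.8, 1)) + 1))
  sizes_a <- lapply(1:3, function(m)
    list(AAAACCCC = round(rlnorm(70, 6.6, 1)) + 1,
         CCCCAAAA = round(rlnorm(70, 6.6, 1)) + 1,
         GGGGTTTT = round(rlnorm(70, 6.6, 1)) + 1,
         TTTTGGGG = round(rlnorm(55, 6.9, 1)) + 1))
  names(sizes_y) <- paste0("y", 1:3)
  names(sizes_a) <- paste0("a", 1:3)
  young <- makeTumorSet(sizes_y)
  aged <- makeTumorSet(sizes_a)
  vec <- statsVectors("GeneA")
  L <- 500
  R <- fitReductionFactor(young, aged, vec, L = L)
  fwd <- scoreRGM(young, aged, vec, "GeneA", L = L, R = R)
  # swapped labels with the matched cutoff pair (L/R in the new aged cohort,
  # reduction 1/R): selects identical tumor sets, so the score negates
  bwd <- scoreRGM(aged, young, vec, "GeneA", L = L / R, R = 1 / R)
  expect_equal(bwd$score, -fwd$score, tolerance = 1e-9)
  expect_identical(bwd$N_L, fwd$N_LR)
  expect_identical(bwd$N_LR, fwd$N_L)
})

test_that("bisection-fitted R agrees with the grid-search oracle", {
  set.seed(24)
  for (rep in 1:5) {
    mu <- runif(1, 6.5, 7.5)
    shrink <- runif(1, 0.3, 0.9)
    sy <- lapply(1:3, function(m)
      list(AAAACCCC = round(rlnorm(120, mu, 1)) + 1,
           CCCCAAAA = round(rlnorm(120, mu, 1)) + 1,
           GGGGTTTT = round(rlnorm(120, mu, 1)) + 1))
    sa <- lapply(sy, function(g) lapply(g, function(x)
      round(x * shrink) + 1))
    names(sy) <- paste0("y", 1:3)
    names(sa) <- paste0("a", 1:3)
    young <- makeTumorSet(sy)
    aged <- makeTumorSet(sa)
    vec <- statsVectors(character(0))
    rg <- fitReductionFactor(young, aged, vec, method = "bisect")
    rgrid <- fitReductionFactor(young, aged, vec, method = "grid")
    expect_lt(abs(rg - rgrid), 0.011)
  }
})

test_that("ECDF comparison selects titer-scaled top tumors and runs the K-S test", {
  set.seed(25)
  y <- list(s1 = rlnorm(500, 6, 1), s2 = rlnorm(500, 6, 1))
  res <- ecdfCompare(y, y, n_young = 100, titer_ratio = 1)
  expect_equal(res$D, 0)
  expect_equal(res$n_aged, 100L)
  # threefold titer ratio scales the aged selection threefold
  a <- list(s1 = rlnorm(2000, 6, 1), s2 = rlnorm(2000, 6, 1))
  res3 <- ecdfCompare(y, a, n_young = 100, titer_ratio = 3)
  expect_equal(res3$n_aged, 300L)
  expect_true(all(lengths(res3$aged_selected) == 300L))
  # a downward shift is detected
  a_small <- lapply(a, function(x) x * 0.3)
  res_shift <- ecdfCompare(y, a_small, n_young = 300, titer_ratio = 3)
  expect_lt(res_shift$p, 1e-6)
  ks_oracle <- suppressWarnings(ks.test(unlist(res_shift$young_selected),
                                        unlist(res_shift$aged_selected),
                                        exact = FALSE))
  expect_equal(res_shift$D, unname(ks_oracle$statistic))
})

test_that("LN mean and percentiles are scale-equivariant, relative metrics invariant", {
  set.seed(26)
  for (i in 1:10) {
    x <- rlnorm(40, 6, 1.3)
    c0 <- runif(1, 0.1, 10)
    expect_equal(lnMean(c0 * x), c0 * lnMean(x))
    expect_equal(percentileSize(c0 * x, 70), c0 * percentileSize(x, 70))
  }
  sizes <- lapply(1:3, function(m)
    list(AAAACCCC = rlnorm(50, 6, 1), CCCCAAAA = rlnorm(50, 6, 1),
         GGGGTTTT = rlnorm(50, 6, 1), TTTTGGGG = rlnorm(50, 6.5, 1)))
  names(sizes) <- paste0("m", 1:3)
  ts <- makeTumorSet(sizes)
  scaled <- lapply(sizes, function(g) lapply(g, function(x) 3.7 * x))
  ts2 <- makeTumorSet(scaled)
  vec <- statsVectors("GeneA")
  plan <- flatPlan(ts, 40L)
  r1 <- relativeStats(ts, plan, vec, "c1")
  set.seed(26)  # makeTumorSet draws barcodes; stats ignore them
  r2 <- relativeStats(ts2, plan, vec, "c1")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
})
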