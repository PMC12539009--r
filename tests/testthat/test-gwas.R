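test_that("marker filtering applies MAF, missingness and polymorphism rules", {
  set.seed(61)
  n <- 100
  mono <- rep(2, n)
  lowMaf <- c(rep(2, 98), 0, 0)          # MAF 0.02 -> discarded
  atMaf <- c(rep(2, 97), 0, 0, 0)        # MAF 0.03 -> retained (boundary)
  miss6 <- c(sample(c(0, 2), 94, TRUE), rep(NA, 6))   # 6% missing
  miss5 <- c(sample(c(0, 2), 95, TRUE), rep(NA, 5))   # 5% -> retained
  keep <- sample(c(0, 2), n, TRUE)
  d <- cbind(mono = mono, lowMaf = lowMaf, atMaf = atMaf, miss6 = miss6,
             miss5 = miss5, keep = keep)
  rownames(d) <- sprintf("cv%03d", 1:n)
  p <- makePanel(d)
  f <- filterMarkers(p)
  expect_setequal(markers(f), c("atMaf", "miss5", "keep"))
  rep_ <- attr(f, "report")
  expect_equal(rep_$monomorphic, 1)
  expect_equal(rep_$lowMaf, 1)
  expect_equal(rep_$highMissing, 1)
  expect_error(filterMarkers(makePanel(cbind(m = mono))), "empty-panel")
})

test_that("mean imputation preserves observed column means", {
  d <- cbind(a = c(0, 2, NA), b = c(0, 1, 2))
  rownames(d) <- c("x", "y", "z")
  p <- makePanel(d)
  imp <- imputeMissing(p)
  expect_equal(doses(imp)["z", "a"], 1)         # mean of {0, 2}
  expect_equal(attr(imp, "nImputed"), 1)
  p2 <- makePanel(cbind(b = c(0, 1, 2)))
  expect_identical(doses(imputeMissing(p2)), doses(p2))   # identity w/o NA
  expect_equal(colMeans(doses(imp)), colMeans(doses(p), na.rm = TRUE))
})

test_that("marker PCA matches an SVD oracle and detects planted structure", {
  set.seed(62)
  base <- matrix(sample(c(0, 2), 50 * 40, TRUE), 50, 40)
  rownames(base) <- sprintf("cv%03d", 1:50)
  p <- makePanel(base)
  pc <- pcaMarkers(p, k = 3)
  Xc <- scale(base, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  for (j in 1:3) {
    a <- pc$scores[, j]; b <- sv$u[, j] * sv$d[j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # rank-1 matrix: PC1 carries all variance
  r1 <- outer(c(rep(0, 25), rep(2, 25)), rep(1, 10))
  rownames(r1) <- sprintf("cv%03d", 1:50)
  pc1 <- pcaMarkers(makePanel(r1), k = 1)
  expect_equal(pc1$varExplained[1], 1, tolerance = 1e-12)
  expect_error(pcaMarkers(makePanel(r1), k = 3), "rank")
})

test_that("single-marker scan recovers exact effects and calibrates under the null", {
  set.seed(63)
  n <- 200; m <- 2000
  d <- matrix(sample(c(0, 2), n * m, TRUE), n, m)
  rownames(d) <- sprintf("cv%03d", 1:n)
  p <- makePanel(d)
  # exact linear phenotype, no noise
  y <- setNames(-0.02 * d[, 7], rownames(d))
  res <- singleMarkerScan(y, p)
  expect_equal(res$effect[7], -0.02, tolerance = 1e-10)
  expect_lt(res$p[7], 1e-100)
  # null phenotype: type-I error within 3 binomial SEs at 0.05 and 0.01
  y0 <- setNames(rnorm(n), rownames(d))
  res0 <- singleMarkerScan(y0, p)
  for (a in c(0.05, 0.01)) {
    fr <- mean(res0$p < a, na.rm = TRUE)
    se <- sqrt(a * (1 - a) / m)
    expect_lt(abs(fr - a), 3 * se + 1e-12)
  }
  expect_true(all(res0$p > 0 & res0$p <= 1, na.rm = TRUE))
})

test_that("PC covariates attenuate structure-confounded effects", {
  set.seed(64)
  n <- 200
  grp <- rep(0:1, each = n / 2)
  confounded <- 2 * grp                    # dose equals group indicator
  # strongly group-divergent background markers, so the leading PC is a
  # near-exact image of the population split
  backgr <- matrix(0, n, 200)
  colnames(backgr) <- sprintf("bg%03d", 1:200)
  backgr[grp == 0, ] <- 2 * rbinom(sum(grp == 0) * 200, 1, 0.1)
  backgr[grp == 1, ] <- 2 * rbinom(sum(grp == 1) * 200, 1, 0.9)
  d <- cbind(conf = confounded, backgr)
  rownames(d) <- sprintf("cv%03d", 1:n)
  p <- makePanel(d)
  y <- setNames(0.5 * grp + rnorm(n, 0, 0.1), rownames(d))
  naive <- singleMarkerScan(y, p)
  pcs <- pcaMarkers(imputeMissing(p), k = 3)$scores
  adj <- singleMarkerScan(y, p, covariates = pcs)
  effN <- naive$effect[naive$marker == "conf"]
  effA <- adj$effect[adj$marker == "conf"]
  expect_lt(abs(effA), abs(effN))
  # a marker perfectly collinear with covariates is flagged
  coll <- singleMarkerScan(y, p, covariates = cbind(confounded))
  expect_true(coll$collinear[coll$marker == "conf"])
  expect_true(is.na(coll$p[coll$marker == "conf"]))
})

test_that("multilocus scan selects planted loci and stays empty under the null", {
  set.seed(65)
  n <- 300
  cs <- causalSpec(data.frame(chrom = c("1A", "6B"), pos = c(10e6, 90e6),
                              favAllele = c("G", "T"), effect = c(25, 25),
                              nSpec = "all", maf = c(0.3, 0.3),
                              favIsMinor = FALSE))
  g <- simulateGenotypes(n, 500, causal = cs, seed = 66, missingRate = 0,
                         structureSd = 0.2)
  D <- doses(imputeMissing(g))
  # strong single-locus phenotype (>= 20% variance)
  y1 <- setNames(-0.05 * D[, "QTN_1A_10.0"] + rnorm(n, 0, 0.06), rownames(D))
  r1 <- multilocusScan(y1, g)
  sel1 <- attr(r1, "pseudoQtn")
  expect_length(sel1, 1)
  block1 <- c("QTN_1A_10.0", grep("^LD_1A", markers(g), value = TRUE))
  expect_true(sel1 %in% block1)
  expect_true(r1$marker[which.min(r1$p)] %in% block1 | sel1 %in% block1)
  # two independent loci on different chromosomes: both found
  y2 <- setNames(-0.04 * D[, "QTN_1A_10.0"] - 0.04 * D[, "QTN_6B_90.0"] +
                   rnorm(n, 0, 0.06), rownames(D))
  r2 <- multilocusScan(y2, g)
  sel2 <- attr(r2, "pseudoQtn")
  block2 <- c("QTN_6B_90.0", grep("^LD_6B", markers(g), value = TRUE))
  expect_true(any(sel2 %in% block1) && any(sel2 %in% block2))
  expect_lte(length(sel2), 4)
  # effects negative on the favourable dose
  expect_lt(r2$effect[r2$marker == sel2[1]], 0)
})

test_that("null phenotypes rarely admit any pseudo-QTN", {
  set.seed(67)
  n <- 200; m <- 400
  d <- matrix(sample(c(0, 2), n * m, TRUE), n, m)
  rownames(d) <- sprintf("cv%03d", 1:n)
  p <- makePanel(d)
  hits <- 0
  for (i in 1:100) {
    y <- setNames(rnorm(n), rownames(d))
    r <- multilocusScan(y, p, maxIter = 3)
    if (length(attr(r, "pseudoQtn")) > 0) hits <- hits + 1
  }
  expect_lte(hits, 5)   # >= 95% of null scans select nothing
})

test_that("multiple-testing control matches the step-up definition", {
  mt <- multipleTesting(rep(0.5, 20), alpha = 0.05)
  expect_equal(mt$bonferroniThreshold, 0.0025)
  expect_false(any(multipleTesting(rep(1, 10))$fdrSignificant))
  expect_false(any(multipleTesting(rep(1, 10))$bonferroniSignificant))
  # brute-force BH step-up oracle on random vectors
  set.seed(68)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    pv <- runif(m)^sample(1:3, 1)
    mt <- multipleTesting(pv, alpha = 0.05)
    srt <- sort(pv)
    kmax <- suppressWarnings(max(which(srt <= 0.05 * seq_len(m) / m)))
    bruteFlags <- if (is.finite(kmax)) pv <= srt[kmax] else rep(FALSE, m)
    expect_identical(mt$fdrSignificant, bruteFlags)
    bruteAdj <- rev(cummin(rev(sort(pv) * m / seq_len(m))))[rank(pv,
                                                            ties.method = "first")]
    expect_equal(mt$pAdj, pmin(bruteAdj, 1), tolerance = 1e-12)
  }
  expect_error(multipleTesting(numeric(0)), "argument error")
})

test_that("PVE formula and its agreement with single-locus regression R2", {
  expect_equal(pve(1, 0.5, 2), 25)
  expect_equal(pve(1, 0, 2), 0)
  expect_error(pve(1, 0.5, 0), "positive")
  expect_error(pve(1, 0.7, 1), "maf")
  # heterozygous (Hardy-Weinberg) doses: PVE tracks the regression R2
  set.seed(69)
  n <- 5000
  dose <- rbinom(n, 2, 0.3)
  y <- -0.5 * dose + rnorm(n, 0, 1)
  fit <- lm(y ~ dose)
  r2 <- summary(fit)$r.squared * 100
  est <- pve(coef(fit)[2], min(mean(dose) / 2, 1 - mean(dose) / 2), var(y))
  expect_lt(abs(est - r2), 2)
})

test_that("Manhattan table is chromosome-ordered with strictly increasing positions", {
  res <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                    p = c(0.5, 0.5, 0.5, 0.5))
  map <- data.frame(marker = c("m3", "m1", "m4", "m2"),
                    chrom = c("2B", "1A", "2B", "1A"),
                    pos = c(50, 10, 20, 40))
  tab <- manhattanTable(res, map)
  expect_identical(tab$marker, c("m1", "m2", "m4", "m3"))
  expect_true(all(diff(tab$cumPos) > 0))
  expect_equal(tab$negLog10P, rep(-log10(0.5), 4))
  expect_error(manhattanTable(data.frame(marker = "zz", p = 0.5), map),
               "mapping error")
})
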