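# two clean multilocus patterns over 8 block markers, nA + nB cultivars
twoPatternPanel <- function(nA = 10, nB = 10, flip = 0, seed = 1) {
  nm <- 8
  d <- rbind(matrix(0, nA, nm), matrix(2, nB, nm))
  if (flip > 0) {
    set.seed(seed)
    idx <- which(matrix(runif(length(d)) < flip, nrow(d)))
    d[idx] <- 2 - d[idx]
  }
  rownames(d) <- sprintf("cv%03d", seq_len(nA + nB))
  makePanel(d, pos = seq_len(nm) * 1e6)
}

test_that("LD r2 is symmetric, relabelling-invariant and near 1/n under independence", {
  set.seed(71)
  a <- sample(c(0, 2), 221, TRUE)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 2 - a), 1)                     # allele flip
  b <- sample(c(0, 2), 221, TRUE)
  expect_equal(ldR2(a, b), ldR2(b, a))
  expect_error(ldR2(a, rep(2, 221)), "monomorphic")
  expect_error(ldR2(a[1:5], b[1:5]), "cultivars")
  r2s <- replicate(1000, ldR2(sample(c(0, 2), 221, TRUE),
                              sample(c(0, 2), 221, TRUE)))
  expect_lt(mean(r2s), 0.02)                          # null expectation ~ 1/n
})

test_that("block collection follows the contiguous-run rule", {
  # correlated chain: neighbours with focal-r2 ~ [0.9, 0.8, 0.6] rightwards
  set.seed(72)
  n <- 400
  focal <- sample(c(0, 2), n, TRUE)
  copyWith <- function(x, s) ifelse(runif(n) < s, x, sample(c(0, 2), n, TRUE))
  d <- cbind(m1 = focal,
             m2 = copyWith(focal, sqrt(0.9)),
             m3 = copyWith(focal, sqrt(0.8)),
             m4 = copyWith(focal, sqrt(0.4)),
             m5 = copyWith(focal, sqrt(0.95)))  # beyond the break: unreachable
  rownames(d) <- sprintf("cv%03d", 1:n)
  p <- makePanel(d, pos = (1:5) * 1e6)
  bl <- collectBlock("m1", p, r2Min = 0.7)
  expect_true(all(c("m1", "m2", "m3") %in% bl$members))
  expect_false("m4" %in% bl$members)
  expect_false("m5" %in% bl$members)   # extension stopped at first failure
  # gap-tolerant variant may reach past the break
  blSkip <- collectBlock("m1", p, r2Min = 0.7, maxSkip = 1)
  expect_true("m5" %in% blSkip$members)
  # all neighbours below threshold: singleton block at the focal position
  ind <- cbind(f = focal, x = sample(c(0, 2), n, TRUE),
               y = sample(c(0, 2), n, TRUE))
  rownames(ind) <- rownames(d)
  pi <- makePanel(ind, pos = c(2e6, 1e6, 3e6))
  bls <- collectBlock("f", pi)
  expect_identical(bls$members, "f")
  expect_equal(bls$spanMbp, c(2, 2))
  # symmetric layout gives symmetric membership
  dSym <- cbind(l1 = copyWith(focal, sqrt(0.9)), c0 = focal,
                r1 = copyWith(focal, sqrt(0.9)))
  rownames(dSym) <- rownames(d)
  pSym <- makePanel(dSym, pos = c(1e6, 2e6, 3e6))
  expect_setequal(collectBlock("c0", pSym)$members, c("l1", "c0", "r1"))
  expect_error(collectBlock("f", makePanel(cbind(f = rep(2, n)),
                                           pos = 1e6)), "monomorphic")
})

test_that("k-means haplotype calling recovers planted patterns deterministically", {
  p <- twoPatternPanel(10, 10)
  bl <- list(members = markers(p), spanMbp = c(1, 8))
  cl <- clusterHaplotypes(p, bl, focal = "M01", seed = 3)
  truth <- rep(1:2, each = 10)
  expect_equal(adjustedRand(cl@assignments, truth), 1)
  expect_length(cl@sizes, 2)
  # minority below the membership rule is absorbed
  pm <- twoPatternPanel(12, 3)
  clm <- clusterHaplotypes(pm, list(members = markers(pm), spanMbp = c(1, 8)),
                           focal = "M01", seed = 3)
  expect_length(clm@sizes, 1)
  expect_equal(clm@sizes, 15L)
  # determinism under a fixed seed
  cl2 <- clusterHaplotypes(p, bl, focal = "M01", seed = 3)
  expect_identical(cl@assignments, cl2@assignments)
  expect_error(clusterHaplotypes(twoPatternPanel(2, 2), bl, focal = "M01"),
               "infeasible")
  # noisy planted structure still recovered well (k capped at the planted
  # number of haplotypes; free k legitimately sub-splits noisy groups)
  pn <- twoPatternPanel(40, 40, flip = 0.1, seed = 9)
  cln <- clusterHaplotypes(pn, list(members = markers(pn), spanMbp = c(1, 8)),
                           focal = "M01", kMax = 2, seed = 3)
  expect_gte(adjustedRand(cln@assignments, rep(1:2, each = 40)), 0.8)
})

test_that("haplotype codes follow the M/m + base + variant grammar", {
  # major-G cluster vs minor-A cluster at the focal marker
  d <- rbind(matrix(c(2, 2), 12, 2, byrow = TRUE),
             matrix(c(0, 0), 6, 2, byrow = TRUE))
  rownames(d) <- sprintf("cv%03d", 1:18)
  p <- makePanel(d, ref = "A", alt = "G", pos = c(1e6, 2e6))
  cl <- clusterHaplotypes(p, list(members = markers(p), spanMbp = c(1, 2)),
                          focal = "M01", seed = 5)
  cl <- nameHaplotypes(cl, p)
  expect_setequal(cl@codes, c("MG", "mA"))
  expect_equal(cl@sizes[cl@codes == "MG"], 12L)
  # two clusters sharing the major base: the smaller gets the 'v' suffix
  d2 <- rbind(matrix(c(2, 2, 2), 120, 3, byrow = TRUE),
              matrix(c(2, 0, 0), 40, 3, byrow = TRUE),
              matrix(c(0, 2, 0), 30, 3, byrow = TRUE))
  rownames(d2) <- sprintf("cv%03d", 1:190)
  p2 <- makePanel(d2, ref = "C", alt = "G", pos = (1:3) * 1e6)
  cl2 <- clusterHaplotypes(p2, list(members = markers(p2), spanMbp = c(1, 3)),
                           focal = "M01", kMax = 3, seed = 5)
  cl2 <- nameHaplotypes(cl2, p2)
  expect_setequal(cl2@codes, c("MG", "MGv", "mC"))
  szs <- setNames(cl2@sizes, cl2@codes)
  expect_gt(szs[["MG"]], szs[["MGv"]])
  # single cluster, major T
  d3 <- matrix(c(rep(2, 18), 0, 0), 20, 1)
  rownames(d3) <- sprintf("cv%03d", 1:20)
  p3 <- makePanel(d3, ref = "A", alt = "T", pos = 1e6)
  cl3 <- clusterHaplotypes(p3, list(members = "M01", spanMbp = c(1, 1)),
                           focal = "M01", kMax = 1, seed = 5)
  cl3 <- nameHaplotypes(cl3, p3)
  expect_identical(cl3@codes, "MT")
  # grammar on all emitted codes
  allCodes <- c(cl@codes, cl2@codes, cl3@codes)
  expect_true(all(grepl("^[Mm][ACGT]v?$", allCodes)))
})

test_that("favourable clusters sit significantly below the locus mean", {
  p <- twoPatternPanel(30, 30)
  cl <- clusterHaplotypes(p, list(members = markers(p), spanMbp = c(1, 8)),
                          focal = "M01", seed = 7)
  eff <- setNames(c(rnorm(30, -0.05, 0.01), rnorm(30, 0.05, 0.01)),
                  cultivars(p))
  cl <- favourableClusters(cl, eff)
  lowCluster <- cl@assignments[["cv001"]]
  expect_true(cl@favourable[lowCluster])
  expect_false(cl@favourable[-lowCluster])
})

test_that("effect tests pick the branch the data support", {
  set.seed(73)
  # two groups, equal variance, strong separation -> Student branch
  v <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  g <- rep(c("A", "B"), each = 50)
  out <- haplotypeEffectTest(v, g)
  expect_identical(out$test, "Student t")
  expect_lte(out$p, 0.001)
  expect_identical(unname(out$letters), c("a", "b"))
  # 10-fold variance ratio -> Welch branch
  v2 <- c(rnorm(60, 0, 0.1), rnorm(60, 0.5, 1.0))
  out2 <- haplotypeEffectTest(v2, g2 <- rep(c("A", "B"), each = 60))
  expect_identical(out2$test, "Welch t")
  # three homogeneous groups -> ANOVA/Tukey; heterogeneous -> Kruskal
  v3 <- c(rnorm(40, 0, .2), rnorm(40, 1, .2), rnorm(40, 2, .2))
  g3 <- rep(c("A", "B", "C"), each = 40)
  out3 <- haplotypeEffectTest(v3, g3)
  expect_identical(out3$test, "ANOVA + Tukey HSD")
  expect_length(unique(out3$letters), 3)
  v4 <- c(rnorm(40, 0, .1), rnorm(40, 0, 1.5), rnorm(40, 3, .1))
  out4 <- haplotypeEffectTest(v4, g3)
  expect_identical(out4$test, "Kruskal-Wallis + pairwise Wilcoxon")
  expect_error(haplotypeEffectTest(v3, rep("A", 120)), "two groups")
})

test_that("null group differences are declared at honest rates", {
  set.seed(74)
  fp <- 0
  for (i in 1:100) {
    v <- rnorm(60)
    g <- rep(c("A", "B", "C"), each = 20)
    if (haplotypeEffectTest(v, g)$p < 0.05) fp <- fp + 1
  }
  expect_lte(fp, 10)   # p > 0.05 in >= 90% of null simulations
})

test_that("stacking classes combine per-locus flags in fixed order", {
  mkCall <- function(fav, n = 30) {
    asg <- setNames(rep(1:2, length.out = n), sprintf("cv%03d", 1:n))
    new("HaplotypeCall", focal = "f", members = "f", spanMbp = c(1, 1),
        assignments = asg, codes = c("MG", "mA"), sizes = c(15L, 15L),
        favourable = fav, majorAllele = "G", minorAllele = "A",
        flags = character(0))
  }
  # cluster 1 favourable at locus 1 only: odd cultivars are F-U-U
  calls <- list(mkCall(c(TRUE, FALSE)), mkCall(c(FALSE, FALSE)),
                mkCall(c(FALSE, FALSE)))
  st <- stackingClasses(calls)
  lab <- setNames(st$classes$label, st$classes$cultivar)
  expect_identical(unname(lab["cv001"]), "F-U-U")
  expect_identical(unname(lab["cv002"]), "U-U-U")
  callsF <- list(mkCall(c(TRUE, FALSE)), mkCall(c(TRUE, FALSE)),
                 mkCall(c(TRUE, FALSE)))
  stF <- stackingClasses(callsF)
  expect_identical(unname(setNames(stF$classes$label,
                                   stF$classes$cultivar)["cv001"]), "F-F-F")
  expect_error(stackingClasses(calls[1:2]), "three")
})

test_that("carrier fraction counts cultivars favourable at every locus", {
  asg <- setNames(c(1L, 1L, 1L, 2L), paste0("cv", 1:4))
  call1 <- new("HaplotypeCall", focal = "a", members = "a", spanMbp = c(1, 1),
               assignments = asg, codes = c("MG", "mA"), sizes = c(3L, 1L),
               favourable = c(TRUE, FALSE), majorAllele = "G",
               minorAllele = "A", flags = character(0))
  expect_equal(carrierFraction(paste0("cv", 1:4), list(call1)), 75)
  call2 <- call1; call2@favourable <- c(FALSE, FALSE)
  expect_equal(carrierFraction(paste0("cv", 1:4), list(call1, call2)), 0)
  expect_equal(carrierFraction(paste0("cv", 1:3), list(call1)), 100)
  expect_error(carrierFraction(character(0), list(call1)), "empty")
})

test_that("allele-frequency trends by decade detect a planted ramp", {
  set.seed(75)
  decs <- paste0(seq(1970, 2010, 10), "s")
  nPer <- 60
  freq <- seq(0.1, 0.5, length.out = 5)
  d <- unlist(lapply(freq, function(f) 2 * rbinom(nPer, 1, f)))
  dm <- cbind(mk = d)
  rownames(dm) <- sprintf("cv%03d", seq_along(d))
  info <- data.frame(cultivar = rownames(dm),
                     decade = rep(decs, each = nPer), origin = "Germany")
  p <- makePanel(dm, ref = "A", alt = "G", info = info)
  tr <- alleleFrequencyTrend(p, "mk", allele = "G")
  expect_equal(nrow(tr$table), 5)
  expect_gt(tr$trend$tau, 0)
  expect_lt(tr$trend$p, 0.05)
  # inbred doses {0,0,2,2} -> frequency 0.5
  dm2 <- cbind(mk = c(0, 0, 2, 2))
  rownames(dm2) <- paste0("cv", 1:4)
  p2 <- makePanel(dm2, ref = "A", alt = "G",
                  info = data.frame(cultivar = paste0("cv", 1:4),
                                    decade = "1990s"))
  tr2 <- alleleFrequencyTrend(p2, "mk", allele = "G")
  expect_equal(tr2$table$frequency, 0.5)
  expect_null(tr2$trend)                      # single decade: no trend test
  # ref-allele frequency is the complement
  expect_equal(alleleFrequencyTrend(p2, "mk", allele = "A")$table$frequency,
               0.5)
})
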