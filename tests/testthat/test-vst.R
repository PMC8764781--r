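test_that("estimation gene and cell selection respect their contracts", {
    set.seed(40)
    sm <- data.frame(gene = sprintf("g%d", 1:60),
                     mean = runif(60, 0.5, 5), gmean = runif(60, 0.3, 3))
    sm$variance <- sm$mean * 2
    expect_setequal(selectEstimationGenes(sm, 2000), sm$gene)
    sm$variance[1:10] <- sm$mean[1:10] * 0.5  # no excess variance
    expect_false(any(sm$gene[1:10] %in% selectEstimationGenes(sm, 2000)))
    m <- simulateCounts(simulationSpec(rep(2, 10), n_cells = 50, seed = 41))
    expect_identical(counts(selectEstimationCells(m, 100)), counts(m))
    s1 <- selectEstimationCells(m, 20, seed = 7)
    s2 <- selectEstimationCells(m, 20, seed = 7)
    expect_identical(cellIDs(s1), cellIDs(s2))
    expect_equal(ncol(s1), 20)
})

test_that("density-dependent gene sampling over-represents sparse abundance regimes", {
    set.seed(42)
    # abundance mass concentrated low, thin high tail
    gm <- c(10^runif(900, -2, -1), 10^runif(100, 0.5, 1))
    sm <- data.frame(gene = sprintf("g%d", 1:1000), mean = gm * 1.1,
                     gmean = gm, variance = gm * 3)
    picked <- selectEstimationGenes(sm, 200, seed = 43)
    # high-tail share among picks well above its 10% population share
    expect_gt(mean(picked %in% sm$gene[901:1000]), 0.2)
})

test_that("v2 regularization applies exclusion rules and the analytic intercept", {
    set.seed(44)
    means <- c(transcriptome_means(800, seed = 44), 0.0005)
    spec <- simulationSpec(means, theta = 10, n_cells = 1500, seed = 45)
    m <- simulateCounts(spec)
    fit <- vst(m, mode = "v2", seed = 46)
    pt <- parameterTable(fit$params)
    sm <- fit$gene_attributes
    excl <- sm$mean < 0.001 | sm$variance <= sm$mean
    expect_true(all(pt$flag[excl] == "poisson_fixed"))
    expect_true(all(is.infinite(pt$theta[excl])))
    # analytic Poisson intercept ln(sum x) - ln(sum n)
    tot <- Matrix::rowSums(counts(m))
    expect_equal(pt$intercept[excl & sm$mean > 0],
                 unname(log(tot[excl & sm$mean > 0]) - log(sum(depths(m)))))
    # v2 slope column is constant at ln(10)
    expect_true(all(pt$slope == log(10)))
    expect_error(regularizeParameters(
        fitDispersionModels(m, genes = geneSummaries(m)$gene[1:5]),
        geneSummaries(m), depths(m)), "usable fits")
})

test_that("a flat true theta yields a flat regularized curve; v1 frees the slope", {
    set.seed(47)
    means <- 10^runif(300, -1, 1.3)
    m <- simulateCounts(simulationSpec(means, theta = 10, n_cells = 2000,
                                       seed = 48))
    f2 <- vst(m, mode = "v2", seed = 49)
    th <- parameterTable(f2$params)$theta
    fin <- is.finite(th)
    expect_lt(max(th[fin]) / min(th[fin]), 1.5)
    f1 <- vst(m, mode = "v1", seed = 49)
    p1 <- parameterTable(f1$params)
    expect_gt(length(unique(p1$slope)), 1)  # v1 slope varies by gene
    expect_equal(median(p1$slope), log(10), tolerance = 0.25)
})

test_that("fixed-theta models expose the NB-to-Poisson limit and theta-free intercepts", {
    set.seed(50)
    m <- simulateCounts(simulationSpec(10^runif(100, -1, 1), theta = 1,
                                       n_cells = 500, seed = 51))
    pInf <- fixedThetaModel(m, Inf)
    p10 <- fixedThetaModel(m, 10)
    p100 <- fixedThetaModel(m, 100)
    expect_identical(p10@intercept, p100@intercept)
    # theta = Inf: residuals are classical Poisson Pearson residuals
    r <- pearsonResiduals(m, pInf, min_variance = "none")
    n <- depths(m)
    mu <- exp(outer(pInf@slope, log10(n)) + pInf@intercept)
    expect_equal(r@residuals, (as.matrix(counts(m)) - mu) / sqrt(mu),
                 ignore_attr = TRUE)
    # misspecified large theta on overdispersed data: variance rises with mean
    rv <- residualVariance(pearsonResiduals(m, p100))
    sm <- geneSummaries(m)
    hi <- sm$mean > 1
    expect_gt(cor(sm$mean[hi], rv[hi], method = "spearman"), 0.5)
})

test_that("Pearson residuals follow the closed formula with clamp and clip", {
    # two genes, two cells; depths 12 and 6
    x <- rbind(g = c(10, 0), h = c(2, 6))
    colnames(x) <- c("a", "b")
    m <- CountMatrix(x)
    n <- depths(m)
    mk <- function(b0_at_4) new("ModelParameters",
        gene_ids = c("g", "h"), mean = rowMeans(x), gmean = rowMeans(x),
        intercept = c(b0_at_4, log(3) - log(n[1])),
        slope = rep(log(10), 2), theta = c(4, Inf),
        flag = rep("estimated", 2), mode = "v2",
        theta_curve = data.frame(log10_gmean = numeric(0),
                                 log_theta = numeric(0)),
        n0 = 9, bandwidth = NA_real_)
    # gene g in cell a: mu = 4, theta = 4, x = 10 -> Z = 6 / sqrt(8)
    params <- mk(log(4) - log(n[1]))
    r <- pearsonResiduals(m, params, min_variance = "none")
    expect_equal(unname(r@residuals["g", "a"]), 6 / sqrt(8))
    # x = 0 gives a negative residual
    expect_lt(r@residuals["g", "b"], 0)
    # theta = Inf row is the classical Poisson residual (sigma = sqrt(mu))
    mu_h <- 3 / n[1] * n
    expect_equal(unname(r@residuals["h", ]),
                 unname((x["h", ] - mu_h) / sqrt(mu_h)))
    # clipping bounds the residuals at +/- sqrt(C)
    rc <- pearsonResiduals(m, params, min_variance = "none", clip = "sqrt_n")
    expect_lte(max(abs(rc@residuals)), sqrt(2))
})

test_that("the minimum-variance clamp caps single-UMI residuals at 5", {
    # one gene with a single detected UMI among many zeros, plus sparse
    # overdispersed genes that keep the dataset nzmedian at 1
    set.seed(52)
    x <- rbind(rare = c(1, rep(0, 199)),
               nb1 = rnbinom(200, mu = 0.4, size = 0.3),
               nb2 = rnbinom(200, mu = 0.5, size = 0.3),
               nb3 = rnbinom(200, mu = 0.6, size = 0.3),
               ballast = rep(1, 200))  # keeps every depth positive
    colnames(x) <- sprintf("c%d", 1:200)
    m <- CountMatrix(x)
    expect_equal(attr(geneSummaries(m), "nzmedian_dataset"), 1)
    fit <- fitDispersionModels(m, model = "offset")
    params <- regularizeParameters(fit, geneSummaries(m), depths(m),
                                   mode = "v2", min_fits = 1,
                                   bandwidth = 0.5)
    r <- pearsonResiduals(m, params, min_variance = "auto")
    expect_equal(r@min_sd, 0.2)
    expect_lte(max(r@residuals["rare", ]), 5)
    # without the clamp the single-UMI residual explodes
    r0 <- pearsonResiduals(m, params, min_variance = "none")
    expect_gt(max(r0@residuals["rare", ]), 5)
})

test_that("residual variance follows the C-1 sample formula", {
    z <- rbind(c(1, -1), c(2, 2))
    expect_equal(residualVariance(z), c(2, 0))
    expect_error(residualVariance(matrix(1, 2, 1)), "at least 2")
    set.seed(53)
    zz <- matrix(rnorm(300), 30)
    expect_equal(residualVariance(zz), apply(zz, 1, var))
})

test_that("residual variance is about 1 when the fitted model is the truth", {
    set.seed(54)
    spec <- simulationSpec(10^runif(250, -1, 1), theta = 10, n_cells = 3000,
                           seed = 55)
    m <- simulateCounts(spec)
    p <- renormalizeIntercepts(vst(m, seed = 56)$params)
    m2 <- simulateFromModel(p, depths(m), seed = 57)
    rv <- residualVariance(pearsonResiduals(m2, p))
    expect_gt(median(rv), 0.9)
    expect_lt(median(rv), 1.1)
})

test_that("variable-gene ranking is by variance with gmean then id tie-breaks", {
    v <- c(g1 = 2, g2 = 5, g3 = 2, g4 = 1)
    gm <- c(1, 1, 3, 1)
    expect_equal(selectVariableGenes(v, 4, gmean = gm),
                 c("g2", "g3", "g1", "g4"))
    expect_equal(selectVariableGenes(v, 2, gmean = gm), c("g2", "g3"))
    expect_error(selectVariableGenes(v, 9), "exceeds")
})

test_that("corrected counts invert the model: identity, floor and depth scaling", {
    # equal-depth input is reproduced exactly (pure algebra: the same
    # clamped sigma is used in both directions, for any parameter set)
    m <- equal_depth_counts(300, 250, 1500, seed = 58)
    p <- fixedThetaModel(m, 5)
    cc <- correctedCounts(m, p, n0 = 1500)
    expect_identical(as.matrix(counts(cc)), as.matrix(counts(m)))
    # floor against the direct formula oracle at a different n0
    idx <- match(geneIDs(m), p@gene_ids)
    r <- pearsonResiduals(m, p)
    n0 <- 900
    mu0 <- exp(p@intercept[idx] + p@slope[idx] * log10(n0))
    s0 <- sqrt(pmax(mu0 + mu0^2 / p@theta[idx],
                    (attr(geneSummaries(m), "nzmedian_dataset") / 5)^2))
    oracle <- pmax(floor(r@residuals * s0 + mu0 + 1e-6), 0)
    cc0 <- correctedCounts(m, p, n0 = n0)
    expect_equal(as.matrix(counts(cc0)), oracle, ignore_attr = TRUE)
    expect_error(correctedCounts(m, p, n0 = -5), "positive")
})

test_that("halving the depth of a depth-proportional gene doubles its corrected count", {
    # cells at half the reference depth with x = 5 correct to ~10; a
    # ballast gene pins every column sum to the intended depth exactly
    set.seed(60)
    depth <- c(rep(1000, 100), rep(500, 100))
    x <- rbind(g1 = rpois(200, 0.005 * depth), g2 = rpois(200, 0.02 * depth),
               g3 = rpois(200, 0.01 * depth))
    x <- rbind(x, ballast = depth - colSums(x))
    m <- CountMatrix(x)
    p <- fixedThetaModel(m, Inf)
    cc <- correctedCounts(m, p, n0 = 1000, min_variance = "none")
    half <- depths(m) == 500
    with5 <- which(x["g3", ] == 5 & half)
    expect_gt(length(with5), 0)
    corrected <- as.matrix(counts(cc))["g3", with5]
    # oracle: y = floor(2 mu_c + (5 - mu_c) sqrt(2)) with mu_c near 5
    expect_true(all(abs(corrected - 10) <= 3))
})

test_that("the v2 predictor parameterization is bit-comparable to an ln-offset", {
    n <- c(137, 5000, 81234)
    expect_equal(log(10) * log10(n), log(n), tolerance = 1e-15)
    b0 <- -7.3
    expect_equal(exp(b0 + log(10) * log10(n)), exp(b0 + log(n)),
                 tolerance = 1e-12)
})
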