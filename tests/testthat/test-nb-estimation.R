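test_that("NB log-likelihood matches direct pmf evaluation and its Poisson limit", {
    # theta = Inf is the Poisson log pmf
    expect_equal(nbLogLik(2, 2, Inf), log(2 * exp(-2)))
    # direct log-gamma evaluation of the NB pmf on a 5-point example
    x <- c(0, 1, 5, 2, 9); mu <- c(1, 2, 4, 3, 6); th <- 2.5
    direct <- sum(lgamma(x + th) - lgamma(th) - lgamma(x + 1) +
                  th * log(th / (th + mu)) + x * log(mu / (th + mu)))
    expect_equal(nbLogLik(x, mu, th), direct, tolerance = 1e-12)
    # large theta approaches the Poisson likelihood per observation
    expect_lt(abs(nbLogLik(x, mu, 1e8) - nbLogLik(x, mu, Inf)) / length(x),
              1e-4)
    expect_error(nbLogLik(1, -1, 2), "positive")
})

test_that("genes without excess variance are excluded with Poisson parameters", {
    f <- estimateThetaOffset(c(3, 3, 3, 3), rep(100, 4))
    expect_identical(f$theta, Inf)
    expect_identical(f$excluded_reason, "var_le_mean")
    expect_equal(f$intercept, log(12 / 400))
    f0 <- estimateThetaOffset(rep(0, 4), rep(100, 4))
    expect_identical(f0$excluded_reason, "all_zero")
})

test_that("theta estimation recovers truth and agrees with MASS at scale", {
    skip_if_not_installed("MASS")
    set.seed(30)
    n <- rep(4000, 5000)
    x <- rnbinom(5000, mu = 10, size = 5)
    f <- estimateThetaOffset(x, n)
    expect_true(f$converged)
    expect_gt(f$theta, 4.5); expect_lt(f$theta, 5.5)
    # independent ML oracle (equal depths: fitted mean is the sample mean)
    ref <- as.numeric(MASS::theta.ml(x, rep(mean(x), 5000), limit = 50))
    expect_equal(f$theta, ref, tolerance = 1e-4)
    # with heterogeneous depths, agree with MASS::glm.nb
    set.seed(31)
    nh <- round(rlnorm(3000, log(2000), 0.4))
    xh <- rnbinom(3000, mu = 0.004 * nh, size = 3)
    fh <- estimateThetaOffset(xh, nh)
    gh <- suppressWarnings(MASS::glm.nb(xh ~ 1 + offset(log(nh))))
    expect_equal(fh$theta, gh$theta, tolerance = 1e-3)
    expect_equal(fh$intercept, unname(coef(gh)), tolerance = 1e-5)
})

test_that("theta estimate maximizes the profile likelihood (grid oracle)", {
    set.seed(32)
    for (rep in 1:5) {
        x <- rnbinom(150, mu = runif(1, 2, 8), size = runif(1, 0.5, 8))
        if (var(x) <= mean(x)) next
        n <- rep(1000, 150)
        f <- estimateThetaOffset(x, n)
        # equal depths: profile intercept is log(mean(x)/1000) for any theta
        mu <- rep(mean(x), 150)
        grid <- seq(-6, 10, by = 1e-3)
        ll <- vapply(grid, function(lt) nbLogLik(x, mu, exp(lt)), numeric(1))
        expect_equal(log(f$theta), grid[which.max(ll)], tolerance = 2e-3)
    }
})

test_that("the alternating optimizer never decreases the likelihood", {
    set.seed(33)
    n <- round(rlnorm(800, log(3000), 0.35))
    x <- rnbinom(800, mu = 0.003 * n, size = 2)
    f <- estimateThetaOffset(x, n, trace = TRUE)
    tr <- attr(f, "loglik_trace")
    expect_gt(length(tr), 1)
    expect_true(all(diff(tr) >= -1e-8))
})

test_that("free-slope model recovers ln(10) and honors the offset identity", {
    set.seed(34)
    n <- round(rlnorm(4000, log(3000), 0.5))
    x <- rnbinom(4000, mu = 0.005 * n, size = 4)  # slope exactly ln(10)
    f <- fitNBFreeSlope(x, n)
    expect_true(f$converged)
    expect_equal(f$slope, log(10), tolerance = 0.08)
    expect_equal(f$theta, 4, tolerance = 0.6)
    # constant depths: slope unidentifiable
    fd <- fitNBFreeSlope(x, rep(3000, 4000))
    expect_false(fd$converged)
    fp <- fitNBFreeSlope(x, rep(3000, 4000), degenerate = "pin")
    expect_true(fp$converged)
    expect_equal(fp$slope, log(10))
    # algebraic identity: offset fit and slope-pinned fit coincide
    fo <- estimateThetaOffset(x, rep(3000, 4000))
    expect_equal(fp$theta, fo$theta)
    expect_equal(fp$intercept, fo$intercept)
})

test_that("matrix-level fitting reproduces per-gene fits with summaries", {
    set.seed(35)
    spec <- simulationSpec(c(a = 8, b = 0.5, zero = 1e-6), theta = 3,
                           n_cells = 300, seed = 35)
    m0 <- simulateCounts(spec)
    # ballast row guarantees positive depths in every cell
    m <- CountMatrix(rbind(as.matrix(counts(m0)),
                           ballast = rep(1, 300)))
    tab <- fitDispersionModels(m, model = "offset")
    expect_equal(tab$gene, c("a", "b", "zero", "ballast"))
    i <- 1
    ref <- estimateThetaOffset(as.matrix(counts(m))[i, ], depths(m))
    expect_equal(tab$theta[i], ref$theta)
    expect_equal(tab$intercept[i], ref$intercept)
    expect_error(fitDispersionModels(m, genes = "nope"), "unknown gene")
})

test_that("theta estimates are biased down at low means and rescued by upsampling", {
    set.seed(36)
    means <- 10^seq(-2.2, 0.8, length.out = 120)
    sp <- simulationSpec(means, theta = 10, n_cells = 2500, seed = 36)
    f <- fitDispersionModels(simulateCounts(sp), model = "offset")
    bin <- cut(means, c(0.005, 0.1, 1, 10))
    med <- tapply(ifelse(is.finite(f$theta), f$theta, NA), bin, median,
                  na.rm = TRUE)
    # monotone median ordering across abundance bins, low bins biased down
    expect_true(all(diff(med) > 0))
    expect_lt(med[1], 8)
    up <- simulateCounts(upsampleMeans(sp, 500))
    fu <- fitDispersionModels(up, model = "offset")
    medu <- tapply(fu$theta, bin, median, na.rm = TRUE)
    expect_true(all(abs(medu - 10) / 10 < 0.2))
})
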