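test_that("simulation specs validate their fields", {
    expect_error(simulationSpec(c(1, -1), n_cells = 10), "positive")
    expect_error(simulationSpec(1, theta = 0, n_cells = 10), "theta")
    expect_error(simulationSpec(1, n_cells = 10,
                                depth_model = list(type = "bogus")),
                 "depth_model")
    expect_error(simulationSpec(rep(1, 3), n_cells = 4,
                                group_labels = c("a", "b"),
                                fold_changes = c(1, 2, 3)),
                 "one entry per cell")
})

test_that("simulated counts reproduce NB/Poisson moments and are seed-stable", {
    # Poisson moments
    sp <- simulationSpec(rep(4, 20), theta = Inf, n_cells = 5000,
                         depth_model = list(type = "equal", depth = 80),
                         seed = 70)
    m <- simulateCounts(sp)
    x <- as.vector(as.matrix(counts(m)))
    expect_equal(mean(x), 4, tolerance = 0.01)
    expect_equal(var(x) / mean(x), 1, tolerance = 0.02)
    # NB variance mu + mu^2 / theta
    sp2 <- simulationSpec(rep(4, 20), theta = 2, n_cells = 5000,
                          depth_model = list(type = "equal", depth = 80),
                          seed = 71)
    x2 <- as.vector(as.matrix(counts(simulateCounts(sp2))))
    expect_equal(var(x2), 4 + 16 / 2, tolerance = 0.03 * 12)
    # bit-reproducible under the spec seed
    expect_identical(counts(simulateCounts(sp2)),
                     counts(simulateCounts(sp2)))
})

test_that("unit fold changes are distribution-identical to an ungrouped spec", {
    means <- 10^runif(50, -1, 1)
    spA <- simulationSpec(means, theta = 5, n_cells = 4000, seed = 72,
                          group_labels = rep(c("a", "b"), 2000),
                          fold_changes = rep(1, 50))
    spB <- simulationSpec(means, theta = 5, n_cells = 4000, seed = 73)
    sA <- geneSummaries(simulateCounts(spA))
    sB <- geneSummaries(simulateCounts(spB))
    expect_equal(sA$mean, sB$mean, tolerance = 0.08)
    expect_equal(mean(sA$variance / sB$variance), 1, tolerance = 0.1)
})

test_that("binomial thinning preserves Poisson structure and expected totals", {
    sp <- simulationSpec(rep(2, 100), theta = Inf, n_cells = 5000, seed = 74)
    m <- simulateCounts(sp)
    expect_identical(counts(thinCounts(m, 1)), counts(m))
    total <- sum(counts(m))
    th <- thinCounts(m, 0.2, seed = 75)
    # binomial concentration around 20% of the original total
    expect_lt(abs(sum(counts(th)) - 0.2 * total), 4 * sqrt(0.16 * total))
    # thinning a Poisson(4) matrix by p gives Poisson(0.8) moments
    spP <- simulationSpec(rep(4, 50), theta = Inf, n_cells = 4000,
                          depth_model = list(type = "equal", depth = 200),
                          seed = 76)
    tp <- thinCounts(simulateCounts(spP), 0.2, seed = 77)
    xv <- as.vector(as.matrix(counts(tp)))
    expect_equal(mean(xv), 0.8, tolerance = 0.02)
    expect_equal(var(xv) / mean(xv), 1, tolerance = 0.03)
    expect_error(thinCounts(m, 0), "0, 1")
    expect_error(thinCounts(m, c(0.2, 0.3)), "per_cell")
})

test_that("depth-targeted downsampling lands every surviving cell in the band", {
    set.seed(78)
    sp <- simulationSpec(rep(5, 400), theta = 10, n_cells = 800,
                         depth_model = list(type = "lognormal",
                                            meanlog = log(5000),
                                            sdlog = 0.3),
                         seed = 78)
    m <- simulateCounts(sp)
    ds <- downsampleToDepth(m, target = 1000, tolerance = 100, seed = 79)
    expect_true(all(depths(ds) >= 900 & depths(ds) <= 1100))
    expect_gt(ncol(ds), 0)
    # all cells already near target: thinning rate ~ 1, nearly all retained
    me <- equal_depth_counts(50, 100, 1000, seed = 80)
    dse <- downsampleToDepth(me, 1000, tolerance = 100, seed = 81)
    expect_gt(ncol(dse) / ncol(me), 0.9)
    expect_error(downsampleToDepth(me, 1e6), "99%")
})

test_that("downsampling depth masks overdispersion in the GoF test", {
    # NB theta = 10 genes at high depth are detected; the same matrix
    # downsampled 20-fold loses most of that power
    p <- 10^seq(-4, -1.5, length.out = 250); p <- p / sum(p) * 0.5
    sp <- simulationSpec(p * 20000, theta = 10, n_cells = 400,
                         depth_model = list(type = "equal", depth = 20000),
                         seed = 82)
    m <- simulateCounts(sp)
    full <- mean(poissonGofTest(m, seed = 83)$overdispersed)
    low <- downsampleToDepth(m, 1000, tolerance = 200, seed = 84)
    shallow <- mean(poissonGofTest(low, seed = 85)$overdispersed)
    expect_gt(full, shallow)
})

test_that("metacell pooling conserves counts and respects labels", {
    m <- simulateCounts(simulationSpec(rep(1, 30), theta = 5, n_cells = 60,
                                       seed = 86))
    # every cell its own label: identity up to column names
    own <- poolMetacells(m, cellIDs(m))
    expect_equal(unname(as.matrix(counts(own))[, cellIDs(m)]),
                 unname(as.matrix(counts(m))))
    # one label: single column of row sums
    one <- poolMetacells(m, rep("mc", 60))
    expect_equal(as.vector(as.matrix(counts(one))),
                 unname(Matrix::rowSums(counts(m))))
    # conservation under an arbitrary labeling
    lab <- kmeans_metacell_labels(m, 5)
    pooled <- poolMetacells(m, lab)
    expect_identical(sum(counts(pooled)), sum(counts(m)))
    expect_identical(ncol(pooled), length(unique(lab)))
    expect_error(poolMetacells(m, c("a", "b")), "one entry per cell")
})

test_that("thinning commutes with pooling in distribution", {
    sp <- simulationSpec(rep(3, 80), theta = 8, n_cells = 600, seed = 87)
    m <- simulateCounts(sp)
    lab <- rep(1:60, each = 10)
    a <- poolMetacells(thinCounts(m, 0.3, seed = 88), lab)
    b <- thinCounts(poolMetacells(m, lab), 0.3, seed = 89)
    expect_equal(sum(counts(a)) / sum(counts(b)), 1, tolerance = 0.01)
    expect_equal(mean(Matrix::rowMeans(counts(a))),
                 mean(Matrix::rowMeans(counts(b))), tolerance = 0.01)
})

test_that("mean upsampling scales the spec and nothing else", {
    sp <- simulationSpec(c(0.01, 2), theta = 3, n_cells = 10, seed = 90)
    expect_identical(upsampleMeans(sp, 1)@gene_means, sp@gene_means)
    up <- upsampleMeans(sp, 500)
    expect_equal(unname(up@gene_means), c(5, 1000))
    expect_identical(up@theta, sp@theta)
    expect_identical(up@seed, sp@seed)
})
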