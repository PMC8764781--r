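# Shared fixture builders. Everything is generated in code; no files.

# Small dense CountMatrix with explicit entries.
toy_counts <- function() {
    m <- matrix(c(4, 0, 0,
                  0, 1, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
    CountMatrix(m)
}

# Equal-depth matrix: every column is a multinomial draw with the same
# total, so depths are exactly equal (needed for exact-identity checks).
equal_depth_counts <- function(n_genes, n_cells, depth, seed = 1) {
    set.seed(seed)
    p <- 10^rnorm(n_genes, -1.3, 0.9)
    x <- vapply(seq_len(n_cells),
                function(i) rmultinom(1, depth, p)[, 1],
                integer(n_genes))
    rownames(x) <- sprintf("g%d", seq_len(n_genes))
    CountMatrix(x)
}

# Realistic sparse transcriptome abundance profile (dataset nzmedian 1).
transcriptome_means <- function(n_genes, seed = 1, meanlog10 = -1.8,
                                sdlog10 = 1.0) {
    set.seed(seed)
    10^rnorm(n_genes, meanlog10, sdlog10)
}

# Crude metacell labeler for pooling tests: k-means on log1p counts.
kmeans_metacell_labels <- function(object, k, seed = 1) {
    set.seed(seed)
    emb <- t(as.matrix(log1p(counts(object))))
    stats::kmeans(emb, centers = k, nstart = 2)$cluster
}
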