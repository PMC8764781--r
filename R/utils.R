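# Internal numeric helpers shared across modules.

# Row variances of a sparse matrix, divisor n-1. Counts are small integers,
# so the E[x^2] - E[x]^2 form is numerically safe here.
.row_vars_sparse <- function(x) {
    n <- ncol(x)
    if (n < 2) return(rep(NA_real_, nrow(x)))
    m <- Matrix::rowMeans(x)
    m2 <- Matrix::rowMeans(x^2)
    pmax((m2 - m^2) * n / (n - 1), 0)
}

.row_vars_dense <- function(x) {
    n <- ncol(x)
    m <- rowMeans(x)
    pmax(rowSums((x - m)^2) / (n - 1), 0)
}

# Median of the non-zero entries of each row of a dgCMatrix; 0 for rows
# without non-zero entries.
.row_nz_median <- function(x) {
    out <- numeric(nrow(x))
    if (length(x@x)) {
        ri <- x@i + 1L
        keep <- x@x > 0
        med <- tapply(x@x[keep], ri[keep], median)
        out[as.integer(names(med))] <- as.numeric(med)
    }
    out
}

# Dataset-wide median of all non-zero entries (0 if the matrix is all zero).
.nz_median_dataset <- function(x) {
    v <- x@x[x@x > 0]
    if (length(v)) median(v) else 0
}

# Nadaraya-Watson kernel regression with a Gaussian kernel. Evaluation
# points are clamped to the support of the training covariate so that genes
# outside the fitted abundance range receive the boundary value rather than
# a 0/0 weight ratio.
.ksmooth_gauss <- function(x, y, xout, bw) {
    stopifnot(length(x) == length(y), bw > 0)
    xq <- pmin(pmax(xout, min(x)), max(x))
    out <- numeric(length(xq))
    block <- 4000L
    for (s in seq(1L, length(xq), by = block)) {
        idx <- s:min(s + block - 1L, length(xq))
        w <- exp(-0.5 * (outer(xq[idx], x, "-") / bw)^2)
        out[idx] <- as.vector(w %*% y) / rowSums(w)
    }
    out
}

# Inverse-density sampling weights on a 1-d covariate: Gaussian KDE with
# Silverman's bandwidth, floored at a small fraction of the maximum density
# so isolated points cannot receive unbounded weight.
.inverse_density_weights <- function(v) {
    if (length(v) < 2 || sd(v) == 0)
        return(rep(1, length(v)))
    d <- density(v, bw = "nrd0")
    dens <- approx(d$x, d$y, xout = v, rule = 2)$y
    dens <- pmax(dens, 1e-8 * max(dens))
    1 / dens
}

# Robust local center and scale: median and MAD of y within covariate
# bins of the given width, with global fallbacks for sparse or
# degenerate bins. Used to flag outliers without letting the outliers
# themselves shift the reference curve (a kernel mean would be dragged
# toward them) or inflate the scale.
.local_median_mad <- function(x, y, width) {
    g_med <- median(y)
    g_mad <- stats::mad(y)
    if (!is.finite(g_mad) || g_mad == 0) g_mad <- max(sd(y), 1e-8)
    breaks <- seq(min(x) - 1e-9, max(x) + width, by = width)
    bin <- findInterval(x, breaks)
    center <- rep(g_med, length(y))
    scale <- rep(g_mad, length(y))
    for (b in unique(bin)) {
        i <- bin == b
        if (sum(i) >= 5) {
            center[i] <- median(y[i])
            s <- stats::mad(y[i])
            if (is.finite(s) && s > 0) scale[i] <- s
        }
    }
    list(center = center, scale = scale)
}

# Derive k reproducible sub-seeds from one top-level seed (or draw from the
# current stream when seed is NULL).
.sub_seeds <- function(seed, k) {
    if (!is.null(seed)) set.seed(seed)
    sample.int(.Machine$integer.max - 1L, k)
}
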