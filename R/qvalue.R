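#' Storey q-values
#'
#' False discovery rate q-values with the proportion of true nulls
#' \eqn{\pi_0} estimated by Storey's smoother method: \eqn{\hat\pi_0(\lambda)
#' = \#\{p > \lambda\} / (m(1-\lambda))} is computed over a lambda grid and
#' a cubic smoothing spline is evaluated at the largest lambda. The q-value
#' of a p-value is the minimum estimated FDR over all rejection thresholds
#' at least as large, so q-values are monotone in p and bounded by 1.
#'
#' With fewer than 100 p-values the smoother is unstable, and \eqn{\pi_0}
#' falls back to 1, in which case the q-values equal Benjamini-Hochberg
#' adjusted p-values. The same happens when the smoother returns a
#' non-finite or non-positive estimate.
#'
#' @param p p-values in [0, 1].
#' @param lambda grid for the \eqn{\pi_0} smoother.
#' @param pi0 optional fixed \eqn{\pi_0} overriding estimation (set 1 to
#'   obtain BH-adjusted p-values).
#' @return q-values in the order of \code{p}.
#' @references Storey & Tibshirani (2003) PNAS 100:9440-9445.
#' @export
storeyQValues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
    if (length(p) == 0) return(numeric(0))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (is.null(pi0)) {
        pi0 <- if (m < 100) 1 else .estimate_pi0_smoother(p, lambda)
    }
    pi0 <- min(max(pi0, 0), 1)
    if (pi0 <= 0) pi0 <- 1 / m  # degenerate: every test non-null
    o <- order(p)
    qo <- pi0 * m * p[o] / seq_len(m)
    qo <- rev(cummin(rev(qo)))
    q <- numeric(m)
    q[o] <- pmin(qo, 1)
    q
}

.estimate_pi0_smoother <- function(p, lambda) {
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- tryCatch(smooth.spline(lambda, pi0l, df = 3),
                    error = function(e) NULL)
    if (is.null(fit)) return(1)
    est <- predict(fit, x = max(lambda))$y
    if (!is.finite(est) || est <= 0) 1 else min(est, 1)
}
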