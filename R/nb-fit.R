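#' Negative binomial log-likelihood (mean-dispersion parameterization)
#'
#' Evaluates \eqn{\sum_c \log NB(x_c; \mu_c, \theta)} where the NB variance
#' is \eqn{\mu + \mu^2/\theta}. \code{theta = Inf} evaluates the Poisson
#' log-likelihood, the exact limit of the NB as overdispersion vanishes.
#'
#' @param x non-negative integer counts.
#' @param mu positive means, recycled against \code{x}.
#' @param theta positive scalar inverse overdispersion, or \code{Inf}.
#' @return the summed log-likelihood.
#' @export
nbLogLik <- function(x, mu, theta) {
    if (any(mu <= 0)) stop("mu must be positive")
    if (length(theta) != 1 || theta <= 0)
        stop("theta must be a positive scalar (Inf allowed)")
    if (is.infinite(theta))
        sum(dpois(x, lambda = mu, log = TRUE))
    else
        sum(dnbinom(x, size = theta, mu = mu, log = TRUE))
}

# Newton iterations for the offset-model intercept given theta:
# score  = sum (x - mu) theta / (theta + mu),  mu = exp(b0) n
# info   = sum theta mu (theta + x) / (theta + mu)^2
.nb_intercept_newton <- function(x, n, theta, b0) {
    for (i in 1:50) {
        mu <- exp(b0) * n
        s <- sum((x - mu) * theta / (theta + mu))
        info <- sum(theta * mu * (theta + x) / (theta + mu)^2)
        if (info <= 0) break
        step <- s / info
        b0 <- b0 + step
        if (abs(step) < 1e-12) break
    }
    b0
}

# First and second derivative of the NB log-likelihood in log(theta),
# holding mu fixed.
.nb_ltheta_grad <- function(x, mu, theta) {
    g <- sum(digamma(x + theta) - digamma(theta) + log(theta) + 1 -
             log(theta + mu) - (x + theta) / (theta + mu))
    h <- sum(trigamma(x + theta) - trigamma(theta) + 1 / theta -
             2 / (theta + mu) + (x + theta) / (theta + mu)^2)
    c(grad = theta * g, hess = theta^2 * h + theta * g)
}

#' Per-gene NB fit with library-size offset
#'
#' Maximum-likelihood estimation of the gene-level model
#' \eqn{x_c \sim NB(\mu_c, \theta)}, \eqn{\ln\mu_c = \beta_0 + \ln n_c}:
#' the inverse overdispersion \eqn{\theta} and the intercept are estimated
#' jointly by alternating a closed-form-like Newton update of the intercept
#' with damped Newton steps on \eqn{\ln\theta} along the profile
#' likelihood. Step halving enforces a non-decreasing likelihood.
#'
#' Genes whose sample variance does not exceed the sample mean carry no
#' evidence of overdispersion: they are not fitted, and are returned with
#' \eqn{\theta = \infty} and the analytic Poisson intercept
#' \eqn{\ln(\sum x / \sum n)}. \eqn{\theta} is initialized by method of
#' moments on depth-normalized counts (counts rescaled to the median
#' depth), floored at \code{theta_min}, and estimates reaching
#' \code{theta_max} are reported as \code{Inf} (numerically Poisson).
#'
#' @param x per-cell counts of one gene.
#' @param depths per-cell total UMI, positive.
#' @param tol relative convergence tolerance on \eqn{\ln\theta}.
#' @param max_iter maximum number of alternating iterations.
#' @param theta_min,theta_max clamp for the \eqn{\theta} estimate.
#' @param trace when \code{TRUE} attach the per-iteration log-likelihood
#'   path as attribute \code{"loglik_trace"}.
#' @return list with \code{theta}, \code{intercept}, \code{slope} (the
#'   \eqn{\ln(10)} constant of the offset parameterization),
#'   \code{converged}, \code{excluded_reason} (\code{"none"},
#'   \code{"var_le_mean"} or \code{"all_zero"}), \code{loglik} and
#'   \code{iterations}.
#' @seealso \code{\link{fitNBFreeSlope}}, \code{\link{fitDispersionModels}}
#' @export
estimateThetaOffset <- function(x, depths, tol = 1e-6, max_iter = 100,
                                theta_min = 1e-4, theta_max = 1e7,
                                trace = FALSE) {
    if (any(depths <= 0)) stop("depths must be positive")
    if (length(x) != length(depths))
        stop("x and depths must have the same length")
    done <- function(theta, intercept, converged, reason, ll = NA_real_,
                     it = 0L, path = NULL) {
        out <- list(theta = theta, intercept = intercept, slope = log(10),
                    converged = converged, excluded_reason = reason,
                    loglik = ll, iterations = it)
        if (trace && !is.null(path)) attr(out, "loglik_trace") <- path
        out
    }
    if (sum(x) == 0)
        return(done(Inf, -Inf, TRUE, "all_zero"))
    m <- mean(x); v <- var(x)
    b0_pois <- log(sum(x) / sum(depths))
    if (v <= m)
        return(done(Inf, b0_pois, TRUE, "var_le_mean",
                    nbLogLik(x, exp(b0_pois) * depths, Inf)))

    # method-of-moments start on the depth-normalized scale
    xs <- x * median(depths) / depths
    mb <- mean(xs); s2 <- var(xs)
    theta <- if (is.finite(s2) && s2 > mb) mb^2 / (s2 - mb) else 1
    if (!is.finite(theta) || theta <= 0) theta <- 1
    theta <- min(max(theta, theta_min), theta_max)

    b0 <- b0_pois
    path <- numeric(0)
    ll <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
        it <- it + 1L
        b0 <- .nb_intercept_newton(x, depths, theta, b0)
        mu <- exp(b0) * depths
        ll <- nbLogLik(x, mu, theta)
        if (trace) path <- c(path, ll)

        d <- .nb_ltheta_grad(x, mu, theta)
        delta <- if (is.finite(d["hess"]) && d["hess"] < 0)
            -d["grad"] / d["hess"] else sign(d["grad"])
        delta <- max(min(delta, 2), -2)  # trust region on log(theta)
        # halve until the likelihood does not decrease
        for (h in 1:30) {
            theta_new <- exp(log(theta) + delta)
            if (theta_new >= theta_max)
                return(done(Inf, b0_pois, TRUE, "none",
                            nbLogLik(x, exp(b0_pois) * depths, Inf), it,
                            path))
            theta_new <- max(theta_new, theta_min)
            ll_new <- nbLogLik(x, mu, theta_new)
            if (ll_new >= ll - 1e-10) break
            delta <- delta / 2
        }
        conv <- abs(delta) < tol * (1 + abs(log(theta)))
        theta <- theta_new
        ll <- ll_new
        if (conv) { converged <- TRUE; break }
    }
    b0 <- .nb_intercept_newton(x, depths, theta, b0)
    ll <- nbLogLik(x, exp(b0) * depths, theta)
    if (trace) path <- c(path, ll)
    done(theta, b0, converged, "none", ll, it, path)
}

#' Per-gene NB fit with a free depth slope
#'
#' Maximum-likelihood fit of \eqn{\ln\mu_c = \beta_0 + \beta_1 \log_{10}
#' n_c} jointly with \eqn{\theta}: iteratively reweighted least squares for
#' the coefficients given \eqn{\theta}, alternated with the same damped
#' Newton \eqn{\ln\theta} update used by \code{\link{estimateThetaOffset}}.
#' This is the free-slope model underlying the v1 regularization; fixing
#' \eqn{\beta_1 = \ln(10)} makes it algebraically identical to the offset
#' model, since \eqn{\ln(10) \log_{10} n = \ln n}.
#'
#' When all depths are equal the slope is unidentifiable; by default the
#' fit is reported as not converged, or with \code{degenerate = "pin"} the
#' slope is pinned to \eqn{\ln(10)} and the offset model is fitted.
#'
#' @inheritParams estimateThetaOffset
#' @param degenerate behavior under constant depths: \code{"unconverged"}
#'   or \code{"pin"}.
#' @return list as in \code{\link{estimateThetaOffset}}, with \code{slope}
#'   the fitted \eqn{\log_{10}}-depth coefficient.
#' @export
fitNBFreeSlope <- function(x, depths, tol = 1e-6, max_iter = 100,
                           theta_min = 1e-4, theta_max = 1e7,
                           degenerate = c("unconverged", "pin")) {
    degenerate <- match.arg(degenerate)
    if (any(depths <= 0)) stop("depths must be positive")
    if (sum(x) == 0)
        return(list(theta = Inf, intercept = -Inf, slope = NA_real_,
                    converged = TRUE, excluded_reason = "all_zero",
                    loglik = NA_real_, iterations = 0L))
    l10 <- log10(depths)
    if (sd(l10) == 0) {
        fit <- estimateThetaOffset(x, depths, tol, max_iter, theta_min,
                                   theta_max)
        if (degenerate == "unconverged") {
            fit$converged <- FALSE
            fit$slope <- NA_real_
        }
        return(fit)
    }
    m <- mean(x); v <- var(x)
    b0_pois <- log(sum(x) / sum(depths))
    if (v <= m)
        return(list(theta = Inf, intercept = b0_pois, slope = log(10),
                    converged = TRUE, excluded_reason = "var_le_mean",
                    loglik = nbLogLik(x, exp(b0_pois) * depths, Inf),
                    iterations = 0L))

    X <- cbind(1, l10)
    beta <- c(b0_pois, log(10))
    xs <- x * median(depths) / depths
    mb <- mean(xs); s2 <- var(xs)
    theta <- if (is.finite(s2) && s2 > mb) mb^2 / (s2 - mb) else 1
    if (!is.finite(theta) || theta <= 0) theta <- 1
    theta <- min(max(theta, theta_min), theta_max)

    ll <- -Inf; converged <- FALSE; it <- 0L
    while (it < max_iter) {
        it <- it + 1L
        # IRLS for (beta0, beta1) given theta
        for (k in 1:50) {
            eta <- drop(X %*% beta)
            mu <- pmin(exp(eta), 1e12)
            w <- mu * theta / (theta + mu)
            z <- eta + (x - mu) / mu
            beta_new <- tryCatch(
                solve(crossprod(X, w * X), crossprod(X, w * z)),
                error = function(e) NULL)
            if (is.null(beta_new)) break
            step <- max(abs(beta_new - beta))
            beta <- drop(beta_new)
            if (step < 1e-10) break
        }
        mu <- exp(drop(X %*% beta))
        ll <- nbLogLik(x, mu, theta)
        d <- .nb_ltheta_grad(x, mu, theta)
        delta <- if (is.finite(d["hess"]) && d["hess"] < 0)
            -d["grad"] / d["hess"] else sign(d["grad"])
        delta <- max(min(delta, 2), -2)
        for (h in 1:30) {
            theta_new <- exp(log(theta) + delta)
            if (theta_new >= theta_max) {
                theta_new <- Inf
                break
            }
            theta_new <- max(theta_new, theta_min)
            if (nbLogLik(x, mu, theta_new) >= ll - 1e-10) break
            delta <- delta / 2
        }
        if (is.infinite(theta_new))
            return(list(theta = Inf, intercept = b0_pois, slope = log(10),
                        converged = TRUE, excluded_reason = "none",
                        loglik = nbLogLik(x, exp(b0_pois) * depths, Inf),
                        iterations = it))
        conv <- abs(delta) < tol * (1 + abs(log(theta)))
        theta <- theta_new
        if (conv) { converged <- TRUE; break }
    }
    mu <- exp(drop(X %*% beta))
    list(theta = theta, intercept = unname(beta[1]),
         slope = unname(beta[2]), converged = converged,
         excluded_reason = "none", loglik = nbLogLik(x, mu, theta),
         iterations = it)
}

#' Fit gene-level dispersion models across a count matrix
#'
#' Applies \code{\link{estimateThetaOffset}} (\code{model = "offset"}) or
#' \code{\link{fitNBFreeSlope}} (\code{model = "free_slope"}) to every
#' requested gene and collects the results with per-gene summary
#' statistics.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param genes optional gene identifiers to fit (default all genes).
#' @param model \code{"offset"} or \code{"free_slope"}.
#' @param ... passed to the per-gene fitting function.
#' @return data.frame with columns \code{gene}, \code{mean}, \code{gmean},
#'   \code{variance}, \code{theta}, \code{intercept}, \code{slope},
#'   \code{converged}, \code{excluded_reason}.
#' @export
fitDispersionModels <- function(object, genes = NULL,
                                model = c("offset", "free_slope"), ...) {
    stopifnot(is(object, "CountMatrix"))
    model <- match.arg(model)
    if (is.null(genes)) genes <- geneIDs(object)
    idx <- match(genes, geneIDs(object))
    if (anyNA(idx)) stop("unknown gene identifiers: ",
                         paste(head(genes[is.na(idx)]), collapse = ", "))
    n <- depths(object)
    xs <- as.matrix(object@counts[idx, , drop = FALSE])
    sm <- geneSummaries(object[idx, ])
    fitfun <- if (model == "offset") estimateThetaOffset else fitNBFreeSlope
    fits <- lapply(seq_along(idx), function(i) fitfun(xs[i, ], n, ...))
    data.frame(
        gene = genes,
        mean = sm$mean, gmean = sm$gmean, variance = sm$variance,
        theta = vapply(fits, `[[`, numeric(1), "theta"),
        intercept = vapply(fits, `[[`, numeric(1), "intercept"),
        slope = vapply(fits, `[[`, numeric(1), "slope"),
        converged = vapply(fits, `[[`, logical(1), "converged"),
        excluded_reason = vapply(fits, `[[`, character(1),
                                 "excluded_reason"),
        row.names = NULL)
}
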