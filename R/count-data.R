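#' Quality-control filtering of cells
#'
#' Retains cells whose total UMI count lies inside an empirical quantile
#' band of the depth distribution (default the 5 to 95% quantiles) and
#' whose fraction of counts assigned to mitochondrial genes does not exceed
#' a threshold (default 15%). Mitochondrial genes are identified by a
#' case-insensitive identifier prefix. The gene set is never changed.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param umi_quantiles length-2 numeric in [0, 1]: lower and upper depth
#'   quantiles (inclusive band, linear-interpolation quantiles).
#' @param mito_fraction_max maximum tolerated mitochondrial count fraction.
#' @param mito_gene_prefix identifier prefix marking mitochondrial genes.
#' @param depth_first apply the depth-quantile filter before the
#'   mitochondrial filter (default); when \code{FALSE} the quantiles are
#'   computed on the cells surviving the mitochondrial filter.
#' @return the filtered \linkS4class{CountMatrix}.
#' @examples
#' m <- CountMatrix(matrix(rpois(600, 5), nrow = 6,
#'                  dimnames = list(c(paste0("g", 1:5), "MT-CO1"), NULL)))
#' dim(qcFilterCells(m))
#' @export
qcFilterCells <- function(object, umi_quantiles = c(0.05, 0.95),
                          mito_fraction_max = 0.15,
                          mito_gene_prefix = "MT-",
                          depth_first = TRUE) {
    stopifnot(is(object, "CountMatrix"))
    q <- umi_quantiles
    if (length(q) != 2 || q[1] < 0 || q[2] > 1 || q[1] >= q[2])
        stop("umi_quantiles must satisfy 0 <= q_lo < q_hi <= 1")

    depth_keep <- function(m) {
        n <- depths(m)
        band <- quantile(n, q, type = 7, names = FALSE)
        n >= band[1] & n <= band[2]
    }
    mito_keep <- function(m) {
        mito <- grepl(paste0("^", mito_gene_prefix), geneIDs(m),
                      ignore.case = TRUE)
        n <- depths(m)
        frac <- if (any(mito))
            Matrix::colSums(m@counts[mito, , drop = FALSE]) / pmax(n, 1)
        else rep(0, ncol(m))
        frac <= mito_fraction_max
    }
    out <- object
    steps <- if (depth_first) list(depth_keep, mito_keep)
             else list(mito_keep, depth_keep)
    for (f in steps) {
        keep <- f(out)
        if (!any(keep))
            stop("qcFilterCells removed all cells")
        out <- out[, keep]
    }
    out
}

#' Per-gene summary statistics
#'
#' Computes, for every gene: the arithmetic mean UMI/cell, the geometric
#' mean abundance \eqn{\exp(\mathrm{mean}(\log(x+1))) - 1} (robust to
#' outlier counts; zero for all-zero genes), the sample variance, the
#' median of the non-zero counts (0 when the gene is never detected), and
#' the detection rate. The dataset-wide median of all non-zero entries is
#' attached as attribute \code{"nzmedian_dataset"}; it drives the
#' minimum-variance clamp of \code{\link{pearsonResiduals}}.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @return data.frame with columns \code{gene}, \code{mean}, \code{gmean},
#'   \code{variance}, \code{nzmedian}, \code{detection_rate} and attribute
#'   \code{nzmedian_dataset}.
#' @export
geneSummaries <- function(object) {
    stopifnot(is(object, "CountMatrix"))
    x <- object@counts
    nC <- ncol(x)
    out <- data.frame(
        gene = geneIDs(object),
        mean = Matrix::rowMeans(x),
        gmean = expm1(Matrix::rowMeans(log1p(x))),
        variance = if (nC >= 2) .row_vars_sparse(x) else rep(0, nrow(x)),
        nzmedian = .row_nz_median(x),
        detection_rate = Matrix::rowSums(x > 0) / max(nC, 1),
        row.names = NULL)
    attr(out, "nzmedian_dataset") <- .nz_median_dataset(x)
    out
}
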