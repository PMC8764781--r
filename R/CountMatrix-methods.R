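#' Construct a CountMatrix
#'
#' Coerces a dense or sparse matrix of UMI counts into a validated
#' \linkS4class{CountMatrix}. Gene and cell identifiers default to the
#' dimnames of \code{counts}; generic identifiers are generated when the
#' input is unnamed.
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (base matrix or any \pkg{Matrix} sparse matrix).
#' @param gene_ids,cell_ids optional identifier vectors overriding the
#'   dimnames of \code{counts}.
#' @return a \linkS4class{CountMatrix}.
#' @examples
#' m <- CountMatrix(matrix(c(4, 0, 0, 0, 1, 0), nrow = 3))
#' depths(m)
#' @export
CountMatrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
    x <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (is.null(gene_ids))
        gene_ids <- rownames(x)
    if (is.null(cell_ids))
        cell_ids <- colnames(x)
    if (is.null(gene_ids) && nrow(x) > 0)
        gene_ids <- sprintf("gene%d", seq_len(nrow(x)))
    if (is.null(cell_ids) && ncol(x) > 0)
        cell_ids <- sprintf("cell%d", seq_len(ncol(x)))
    if (length(gene_ids) != nrow(x))
        stop("gene_ids length (", length(gene_ids),
             ") does not match number of rows (", nrow(x), ")")
    if (length(cell_ids) != ncol(x))
        stop("cell_ids length (", length(cell_ids),
             ") does not match number of columns (", ncol(x), ")")
    dimnames(x) <- list(as.character(gene_ids), as.character(cell_ids))
    new("CountMatrix", counts = drop0(x))
}

#' @describeIn CountMatrix access the sparse count matrix.
#' @param object a \code{CountMatrix}.
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' @rdname depths
#' @export
setMethod("depths", "CountMatrix", function(object)
    Matrix::colSums(object@counts))

#' @rdname geneIDs
#' @export
setMethod("geneIDs", "CountMatrix", function(object)
    rownames(object@counts))

#' @rdname geneIDs
#' @export
setMethod("geneIDs", "ModelParameters", function(object) object@gene_ids)

#' @rdname cellIDs
#' @export
setMethod("cellIDs", "CountMatrix", function(object)
    colnames(object@counts))

#' @export
setMethod("dim", "CountMatrix", function(x) dim(x@counts))

#' @export
setMethod("dimnames", "CountMatrix", function(x) dimnames(x@counts))

#' Subset a CountMatrix by genes and/or cells
#'
#' @param x a \code{CountMatrix}.
#' @param i,j gene and cell indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{CountMatrix}.
#' @export
setMethod("[", "CountMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@counts))
    if (missing(j)) j <- seq_len(ncol(x@counts))
    new("CountMatrix", counts = x@counts[i, j, drop = FALSE])
})

setMethod("show", "CountMatrix", function(object) {
    d <- dim(object@counts)
    n <- depths(object)
    cat("CountMatrix:", d[1], "genes x", d[2], "cells\n")
    if (d[2] > 0)
        cat(sprintf("  depth (UMI/cell): median %.0f, range [%.0f, %.0f]\n",
                    median(n), min(n), max(n)))
    nz <- length(object@counts@x)
    cat(sprintf("  nonzero entries: %d (%.1f%% dense)\n", nz,
                if (prod(d) > 0) 100 * nz / prod(d) else 0))
})

setMethod("show", "ModelParameters", function(object) {
    cat("ModelParameters (mode:", object@mode, ")\n")
    cat("  genes:", length(object@gene_ids), "\n")
    tab <- table(object@flag)
    cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
    fin <- is.finite(object@theta)
    if (any(fin))
        cat(sprintf("  theta: median %.3g over %d finite genes (%d at Inf)\n",
                    median(object@theta[fin]), sum(fin), sum(!fin)))
    cat(sprintf("  n0 (reference depth): %.0f\n", object@n0))
})

setMethod("show", "ResidualMatrix", function(object) {
    d <- dim(object@residuals)
    cat("ResidualMatrix:", d[1], "genes x", d[2], "cells\n")
    cat(sprintf("  residual variance: median %.3f\n",
                median(object@residual_variance)))
    if (all(is.finite(object@clip_range)))
        cat(sprintf("  clipped to [%.3g, %.3g]\n",
                    object@clip_range[1], object@clip_range[2]))
    if (object@min_sd > 0)
        cat(sprintf("  minimum standard deviation: %.3g\n", object@min_sd))
})

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec:", length(object@gene_means), "genes x",
        object@n_cells, "cells\n")
    th <- unique(object@theta)
    cat("  theta:", if (length(th) == 1) format(th) else
        sprintf("per-gene (range %.3g-%.3g)", min(object@theta),
                max(object@theta)), "\n")
    cat("  depth model:", object@depth_model$type, "\n")
    if (length(object@group_labels))
        cat("  planted groups:", nlevels(object@group_labels), "\n")
})

#' @rdname residualVariance
#' @export
setMethod("residualVariance", "ResidualMatrix",
          function(object) object@residual_variance)

#' @rdname residualVariance
#' @export
setMethod("residualVariance", "matrix", function(object) {
    if (ncol(object) < 2)
        stop("residual variance requires at least 2 cells")
    .row_vars_dense(object)
})

#' @rdname parameterTable
#' @export
setMethod("parameterTable", "ModelParameters", function(object)
    data.frame(gene = object@gene_ids, mean = object@mean,
               gmean = object@gmean, intercept = object@intercept,
               slope = object@slope, theta = object@theta,
               flag = object@flag, row.names = NULL))
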