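#' @importFrom BiocGenerics counts
NULL

#' Per-cell sequencing depths
#'
#' Total UMI count per cell, \eqn{n_c = \sum_g x_{gc}}; used as the
#' library-size offset in all GLM fits.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @return numeric vector named by cell identifier.
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))

#' Gene identifiers
#' @param object a \linkS4class{CountMatrix} or \linkS4class{ModelParameters}.
#' @return character vector of gene identifiers.
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' Cell identifiers
#' @param object a \linkS4class{CountMatrix}.
#' @return character vector of cell identifiers.
#' @export
setGeneric("cellIDs", function(object) standardGeneric("cellIDs"))

#' Per-gene residual variance
#'
#' Sample variance of each gene's Pearson residuals,
#' \eqn{\frac{1}{C-1}\sum_c (Z_{gc} - \bar Z_g)^2} with \eqn{\bar Z_g} the
#' arithmetic mean residual of the gene. Under a correctly specified model
#' this is approximately 1; genes whose biological variation is not captured
#' by the error model have larger values, which is the basis of variable
#' gene selection.
#'
#' @param object a \linkS4class{ResidualMatrix} (returns the stored values)
#'   or a plain genes x cells residual matrix (computes them).
#' @return numeric vector named by gene.
#' @export
setGeneric("residualVariance",
           function(object) standardGeneric("residualVariance"))

#' Model parameter table
#'
#' @param object a \linkS4class{ModelParameters}.
#' @return data.frame with one row per gene: gene, mean, gmean, intercept,
#'   slope, theta, flag.
#' @export
setGeneric("parameterTable",
           function(object) standardGeneric("parameterTable"))
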