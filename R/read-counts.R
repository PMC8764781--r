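#' Read a UMI count matrix from disk
#'
#' Reads either a 10x-style Matrix Market directory (\code{matrix.mtx} plus
#' \code{features.tsv}/\code{genes.tsv} and \code{barcodes.tsv}, optionally
#' gzipped) or a dense TSV with gene identifiers in the first column and one
#' column per cell. Entries must be non-negative integers; anything else is
#' rejected.
#'
#' @param path directory containing the Matrix Market triplet, a path to a
#'   \code{.mtx} file whose sibling id files live in the same directory, or
#'   a dense TSV file.
#' @param format \code{"auto"} (default; inferred from \code{path}),
#'   \code{"mtx"}, or \code{"tsv"}.
#' @return a \linkS4class{CountMatrix}.
#' @seealso \code{\link{writeCounts}}
#' @export
readCounts <- function(path, format = c("auto", "mtx", "tsv")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "auto") {
        format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path))
            "mtx" else "tsv"
    }
    if (format == "mtx") .read_mtx(path) else .read_tsv(path)
}

.find_sibling <- function(dir, stems) {
    for (stem in stems)
        for (ext in c("", ".gz")) {
            f <- file.path(dir, paste0(stem, ext))
            if (file.exists(f)) return(f)
        }
    stop("no file named ", paste(stems, collapse = " or "), " found in ", dir)
}

.read_mtx <- function(path) {
    if (dir.exists(path)) {
        dir <- path
        mtx <- .find_sibling(dir, c("matrix.mtx", "counts.mtx"))
    } else {
        dir <- dirname(path)
        mtx <- path
    }
    m <- tryCatch(readMM(mtx), error = function(e)
        stop("malformed Matrix Market file ", mtx, ": ",
             conditionMessage(e), call. = FALSE))
    feat <- read.delim(.find_sibling(dir, c("features.tsv", "genes.tsv")),
                       header = FALSE, stringsAsFactors = FALSE)
    barc <- read.delim(.find_sibling(dir, "barcodes.tsv"), header = FALSE,
                       stringsAsFactors = FALSE)
    if (nrow(feat) != nrow(m))
        stop("features file lists ", nrow(feat), " genes but matrix has ",
             nrow(m), " rows")
    if (nrow(barc) != ncol(m))
        stop("barcodes file lists ", nrow(barc), " cells but matrix has ",
             ncol(m), " columns")
    CountMatrix(m, gene_ids = feat[[1]], cell_ids = barc[[1]])
}

.read_tsv <- function(path) {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (ncol(tab) < 1) stop("malformed TSV ", path, ": no columns")
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m))
        stop("malformed TSV ", path, ": non-numeric count columns")
    CountMatrix(m, gene_ids = ids, cell_ids = colnames(m))
}

#' Write a CountMatrix as a Matrix Market triplet
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' into \code{dir}, the layout understood by \code{\link{readCounts}}.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCounts <- function(object, dir) {
    stopifnot(is(object, "CountMatrix"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeMM(object@counts, file.path(dir, "matrix.mtx"))
    writeLines(geneIDs(object), file.path(dir, "features.tsv"))
    writeLines(cellIDs(object), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}
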