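## Unbiased mean structure: ensemble-averaged distance matrix, classical
## scaling back-projection into Cartesian space, chirality fixed against the
## first conformer. Averaging distances over conformers avoids biasing the
## mean toward any reference structure chosen for superposition.

#' Ensemble-averaged inter-atomic distance matrix
#'
#' Entry `(i, j)` is the mean over conformers of the Euclidean distance
#' between selected atoms `i` and `j`. The matrix is symmetric with a zero
#' diagonal; being an average of metric matrices it is in general
#' non-Euclidean (its Gram spectrum can have negative tail eigenvalues).
#'
#' @param e an [NMREnsemble-class]
#' @param sel an [AtomSelection-class] (or anything [atomSelection()] accepts)
#' @param chain chain identifier, defaulting to the first chain.
#' @return `k x k` numeric matrix (Angstrom) with atom labels as dimnames
#' @export
averageDistanceMatrix <- function(e, sel, chain = NULL) {
    sc <- selectCoords(e, sel, chain = chain)
    m <- dim(sc$xyz)[3]
    k <- dim(sc$xyz)[1]
    D <- matrix(0, k, k)
    for (j in seq_len(m))
        D <- D + as.matrix(stats::dist(sc$xyz[, , j]))
    D <- D / m
    lab <- paste0(sc$atoms$resSeq, ".", sc$atoms$name)
    dimnames(D) <- list(lab, lab)
    D
}

#' Back-project a distance matrix into 3-D coordinates
#'
#' Classical scaling (metric MDS): the distance matrix is converted to a
#' double-centred Gram matrix, eigendecomposed, and the top three
#' eigenvectors scaled by the square roots of their eigenvalues give the
#' embedding. For a matrix of exact 3-D distances this recovers the point
#' set up to isometry and reflection; for an ensemble-averaged matrix the
#' tail of the spectrum may go negative, which is reported, not an error.
#' A third eigenvalue that is substantially negative indicates geometry that
#' cannot be embedded in 3-D and is an error; an (essentially) planar point
#' set embeds with a near-zero third eigenvalue.
#'
#' @param D symmetric distance matrix with zero diagonal (Angstrom)
#' @return object of class `MeanStructure`: list with `coords` (`n x 3`,
#'   centred at the origin), `eigenvalues` (full descending spectrum) and
#'   `chiralityFlipped` (set by [unbiasedMean()]; `NA` here because a
#'   distance matrix carries no chirality).
#' @export
backProject <- function(D) {
    D <- as.matrix(D)
    stopifnot(nrow(D) == ncol(D))
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
    if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
    n <- nrow(D)
    if (n < 4L) stop("need at least 4 points to embed in 3-D")
    mds <- stats::cmdscale(D, k = 3L, eig = TRUE)
    ev <- sort(mds$eig, decreasing = TRUE)
    scale0 <- max(abs(ev))
    if (ev[2] <= 1e-9 * scale0)
        stop("degenerate geometry: fewer than 2 positive Gram eigenvalues")
    if (ev[3] < -1e-6 * scale0)
        stop("degenerate geometry: third Gram eigenvalue is negative (",
             format(ev[3]), ")")
    X <- mds$points
    if (ncol(X) < 3L)                       # planar input: cmdscale drops axes
        X <- cbind(X, matrix(0, n, 3L - ncol(X)))
    X <- sweep(X, 2, colMeans(X))
    rownames(X) <- rownames(D)
    structure(list(coords = X, eigenvalues = ev, chiralityFlipped = NA),
              class = "MeanStructure")
}

#' @export
print.MeanStructure <- function(x, ...) {
    cat("MeanStructure:", nrow(x$coords), "atoms\n")
    cat("  top eigenvalues:",
        paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", "), "\n")
    cat("  chirality flipped:", x$chiralityFlipped, "\n")
    invisible(x)
}

#' Unbiased mean structure of an ensemble
#'
#' Composes [averageDistanceMatrix()] and [backProject()]. Classical scaling
#' is blind to chirality, so the mirror image with the lower Kabsch RMSD to
#' the first conformer is chosen (deterministic). Because the distance
#' matrix is invariant under conformer reordering, the mean coordinates are
#' reproducible to numerical precision regardless of model order.
#'
#' @inheritParams averageDistanceMatrix
#' @return a `MeanStructure` (see [backProject()]); `chiralityFlipped`
#'   records whether the mirror image was taken.
#' @export
unbiasedMean <- function(e, sel, chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    if (nModels(e) < 2L)
        stop("unbiased mean requires at least 2 conformers")
    D <- averageDistanceMatrix(e, sel, chain = chain)
    ms <- backProject(D)
    ref <- selectCoords(e, sel, chain = chain)$xyz[, , 1]
    mirror <- ms$coords %*% diag(c(-1, 1, 1))
    r1 <- kabsch(ms$coords, ref)$rmsd
    r2 <- kabsch(mirror, ref)$rmsd
    if (r2 < r1) {
        ms$coords <- mirror
        ms$chiralityFlipped <- TRUE
    } else {
        ms$chiralityFlipped <- FALSE
    }
    ms
}
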