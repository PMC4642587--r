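## Rigid-body superposition by the Kabsch SVD construction.

#' Optimal rigid superposition of two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally weighted) RMSD between `X %*% t(R) + t` and `Y`, i.e. maps
#' `X` onto `Y`. The rotation is guaranteed proper (`det(R) = +1`); a
#' reflection is never returned, so mirror-image point sets superpose with a
#' non-zero residual.
#'
#' @param X,Y `n x 3` coordinate matrices (Angstrom), matched row order,
#'   `n >= 3`.
#' @param weights optional non-negative weights of length `n`.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, weighted root-mean-square residual).
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' kabsch(X, X %*% t(R) + 5)$rmsd   # ~0
#' @export
kabsch <- function(X, Y, weights = NULL) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    stopifnot(ncol(X) == 3L, ncol(Y) == 3L, nrow(X) == nrow(Y),
              nrow(X) >= 3L)
    n <- nrow(X)
    w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
    stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
    w <- w / sum(w)
    cx <- colSums(X * w); cy <- colSums(Y * w)
    Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
    sv <- svd(crossprod(Xc * w, Yc))
    if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
        stop("degenerate (collinear) point set: superposition undefined")
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    fitted <- Xc %*% t(R)
    msd <- sum(w * rowSums((fitted - Yc)^2))
    list(rotation = R,
         translation = as.numeric(cy - R %*% cx),
         rmsd = sqrt(max(msd, 0)))
}

## Apply a kabsch() result to coordinates.
.applyTransform <- function(X, tr) {
    sweep(as.matrix(X) %*% t(tr$rotation), 2, -tr$translation)
}

## Plain RMSD between matched coordinate sets (no superposition).
.rawRmsd <- function(X, Y) sqrt(mean(rowSums((X - Y)^2)))
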