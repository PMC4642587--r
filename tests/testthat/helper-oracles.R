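# Independent oracles used to cross-check the package implementations.
# These deliberately do not reuse any package internals.

# --- brute-force rigid superposition via quaternion search ---------------
# Minimise RMSD over rotations parameterised by unit quaternions: coarse
# 4-D grid followed by Nelder-Mead polish. Translation handled by
# centroid alignment.
quatToRot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

bruteForceRmsd <- function(X, Y) {
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    obj <- function(q) {
        if (sum(q^2) < 1e-8) return(Inf)
        R <- quatToRot(q)
        sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
    }
    g <- seq(-1, 1, length.out = 7)
    best <- NULL
    for (w in g) for (x in g) for (y in g) for (z in g) {
        q <- c(w, x, y, z)
        if (sum(q^2) < 1e-6) next
        v <- obj(q)
        if (is.null(best) || v < best$value) best <- list(par = q, value = v)
    }
    opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    opt$value
}

# --- independent 15N relaxation rate formulas ----------------------------
# Farrow-style formulation: spectral density without the 2/5 prefactor,
# dipolar constant d2 = dd^2/10 and CSA constant c2 = (2/15) (w_N csa)^2.
oracleRates <- function(S2, tauE_ps, rex, S2f, tauM_ns, freqMHz = 600.13,
                        rNH = 1.02, csa = -160,
                        gH = 2.6752218744e8, gN = -2.71261804e7) {
    mu0 <- 4e-7 * pi; hbar <- 1.054571817e-34
    wh <- 2 * pi * freqMHz * 1e6
    wn <- abs(gN) / gH * wh
    tm <- tauM_ns * 1e-9; te <- tauE_ps * 1e-12
    tp <- if (te > 0) 1 / (1 / tm + 1 / te) else 0
    Jn <- function(w) S2 * tm / (1 + (w * tm)^2) +
        (S2f - S2) * tp / (1 + (w * tp)^2)
    dd <- (mu0 / (4 * pi)) * hbar * gH * abs(gN) / (rNH * 1e-10)^3
    d2 <- dd^2 / 10
    c2 <- (2 / 15) * (wn * csa * 1e-6)^2
    R1 <- d2 * (Jn(wh - wn) + 3 * Jn(wn) + 6 * Jn(wh + wn)) + c2 * Jn(wn)
    R2 <- (d2 / 2) * (4 * Jn(0) + Jn(wh - wn) + 3 * Jn(wn) + 6 * Jn(wh) +
                      6 * Jn(wh + wn)) +
        (c2 / 6) * (4 * Jn(0) + 3 * Jn(wn)) + rex
    NOE <- 1 + d2 * (gH / gN) * (6 * Jn(wh + wn) - Jn(wh - wn)) / R1
    c(R1 = R1, R2 = R2, NOE = NOE)
}

# --- independent torsion formula -----------------------------------------
oracleDihedral <- function(p1, p2, p3, p4) {
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    y <- sqrt(sum(b2^2)) * sum(b1 * cross(b2, b3))
    x <- sum(cross(b1, b2) * cross(b2, b3))
    ang <- atan2(y, x) * 180 / pi
    if (ang <= -180) ang + 360 else ang
}

# --- tiny fixtures --------------------------------------------------------
# Hand-built two-atom-per-residue ensembles and simple point clouds.
toyEnsemble <- function(coordList, names = NULL, resSeq = NULL) {
    k <- nrow(coordList[[1]])
    if (is.null(names)) names <- rep(c("N", "CA", "C"), length.out = k)
    if (is.null(resSeq)) resSeq <- rep(seq_len(ceiling(k / 3)), each = 3)[seq_len(k)]
    atoms <- data.frame(serial = seq_len(k), name = names,
                        element = substr(names, 1, 1), altLoc = "",
                        resName = "ALA", chain = "A", resSeq = resSeq)
    xyz <- array(0, dim = c(k, 3, length(coordList)))
    for (j in seq_along(coordList)) xyz[, , j] <- coordList[[j]]
    new("NMREnsemble", atoms = atoms, xyz = xyz,
        modelIds = seq_along(coordList))
}

randomRotation <- function() {
    q <- stats::rnorm(4)
    quatToRot(q / sqrt(sum(q^2)))
}
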