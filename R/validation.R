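## Structure validation: backbone torsions and Ramachandran region
## summaries, Cys4-Zn coordination geometry against restraint targets, and
## data-driven assignment of cysteines to zinc clusters.

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Signed torsion angle of four points
#'
#' IUPAC convention: looking from `p2` to `p3`, the angle is positive for a
#' clockwise rotation of `p3->p4` relative to `p1->p2`; result in
#' `(-180, 180]` degrees. Three collinear points leave the torsion
#' undefined and raise an error.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return angle in degrees
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
    if (sqrt(sum(n1^2)) < 1e-9 * sqrt(sum(b1^2) * sum(b2^2)) ||
        sqrt(sum(n2^2)) < 1e-9 * sqrt(sum(b2^2) * sum(b3^2)))
        stop("collinear points: torsion undefined")
    b2n <- b2 / sqrt(sum(b2^2))
    ang <- atan2(sum(.cross(n1, n2) * b2n), sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    ang
}

.angleDeg <- function(a, b, c) {
    u <- a - b; v <- c - b
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

## ---- Ramachandran -------------------------------------------------------

## 10 x 10 degree region grid in the style of the Morris et al. four-region
## classification used by PROCHECK: rectangular core and allowed regions
## around the alpha, beta and left-handed-alpha basins; the generous region
## is a 20-degree (2-cell) torus dilation of core+allowed; everything else
## is disallowed. Codes: 1 core, 2 additional, 3 generous, 4 disallowed.
.ramaGridBuild <- function() {
    g <- matrix(4L, 36, 36)     # [phi bin, psi bin]
    binSeq <- function(lo, hi) {        # half-open [lo, hi) in degrees
        i1 <- floor((lo + 180) / 10) + 1
        i2 <- ceiling((hi + 180) / 10)
        seq(max(1, i1), min(36, i2))
    }
    paint <- function(g, phis, psis, code) {
        idx <- as.matrix(expand.grid(binSeq(phis[1], phis[2]),
                                     binSeq(psis[1], psis[2])))
        keep <- g[idx] > code
        g[idx[keep, , drop = FALSE]] <- code
        g
    }
    ## additional allowed first, cores painted over them
    g <- paint(g, c(-180, -20), c(-120, 60), 2L)     # alpha basin + bridge
    g <- paint(g, c(-180, -20), c(60, 180), 2L)      # beta basin
    g <- paint(g, c(-180, -45), c(-180, -140), 2L)   # beta, psi wrap
    g <- paint(g, c(20, 100), c(-20, 90), 2L)        # left-handed alpha
    g <- paint(g, c(-160, -45), c(-70, 0), 1L)       # core alpha
    g <- paint(g, c(-170, -45), c(90, 180), 1L)      # core beta
    g <- paint(g, c(40, 80), c(15, 70), 1L)          # core L-alpha
    ## generous: 2-cell torus dilation of core+allowed
    fav <- g <= 2L
    gen <- matrix(FALSE, 36, 36)
    for (di in -2:2) for (dj in -2:2) {
        gen <- gen | fav[(seq_len(36) - 1 + di) %% 36 + 1,
                         (seq_len(36) - 1 + dj) %% 36 + 1]
    }
    g[gen & g == 4L] <- 3L
    g
}

.ramaEnv <- new.env(parent = emptyenv())

.ramaGrid <- function() {
    if (is.null(.ramaEnv$grid)) .ramaEnv$grid <- .ramaGridBuild()
    .ramaEnv$grid
}

.ramaRegions <- c("most_favoured", "additional", "generous", "disallowed")

.wrapAngle <- function(x) {
    x <- ((x + 180) %% 360) - 180
    ifelse(x == -180, 180, x)
}

#' Classify a phi/psi pair into a Ramachandran region
#'
#' Looks the torsion pair up in a packaged 10x10-degree four-region grid
#' (core / additional / generous / disallowed). Glycine (its achiral map is
#' different), proline (phi restricted by the ring) and chain-terminal
#' residues are conventionally not classified and return `"excluded"`.
#'
#' @param phi,psi backbone torsions in degrees (vectorised)
#' @param resName 3-letter residue code(s)
#' @param terminal logical: chain-terminal residue(s)
#' @return character vector of regions: `most_favoured`, `additional`,
#'   `generous`, `disallowed` or `excluded`
#' @examples
#' ramaClassify(-60, -45)   # canonical alpha-helix: most_favoured
#' @export
ramaClassify <- function(phi, psi, resName = "ALA", terminal = FALSE) {
    n <- max(length(phi), length(psi))
    phi <- rep_len(.wrapAngle(phi), n); psi <- rep_len(.wrapAngle(psi), n)
    resName <- rep_len(toupper(resName), n)
    terminal <- rep_len(terminal, n)
    g <- .ramaGrid()
    iF <- pmin(floor((phi + 180) / 10) + 1, 36)
    iS <- pmin(floor((psi + 180) / 10) + 1, 36)
    out <- .ramaRegions[g[cbind(iF, iS)]]
    out[resName %in% c("GLY", "PRO") | terminal | !is.finite(phi) |
            !is.finite(psi)] <- "excluded"
    out
}

## Per-model, per-residue backbone torsions. Residues lacking a sequential
## neighbour (chain termini or numbering gaps) get NA torsions.
.phiPsi <- function(e, chain = NULL) {
    a <- e@atoms
    if (is.null(chain)) chain <- a$chain[1]
    bb <- a$chain == chain & a$name %in% c("N", "CA", "C")
    res <- sort(unique(a$resSeq[bb]))
    idx <- function(r, nm) {
        i <- which(a$chain == chain & a$resSeq == r & a$name == nm)
        if (length(i) == 1L) i else NA_integer_
    }
    iN <- vapply(res, idx, integer(1), nm = "N")
    iCA <- vapply(res, idx, integer(1), nm = "CA")
    iC <- vapply(res, idx, integer(1), nm = "C")
    m <- nModels(e)
    out <- vector("list", m)
    for (j in seq_len(m)) {
        X <- e@xyz[, , j]
        phi <- psi <- rep(NA_real_, length(res))
        for (i in seq_along(res)) {
            prev <- match(res[i] - 1L, res)
            nxt <- match(res[i] + 1L, res)
            if (!is.na(prev) && !anyNA(c(iC[prev], iN[i], iCA[i], iC[i])))
                phi[i] <- dihedralAngle(X[iC[prev], ], X[iN[i], ],
                                        X[iCA[i], ], X[iC[i], ])
            if (!is.na(nxt) && !anyNA(c(iN[i], iCA[i], iC[i], iN[nxt])))
                psi[i] <- dihedralAngle(X[iN[i], ], X[iCA[i], ],
                                        X[iC[i], ], X[iN[nxt], ])
        }
        resName <- a$resName[iCA]
        out[[j]] <- data.frame(model = j, resSeq = res, resName = resName,
                               phi = phi, psi = psi,
                               terminal = is.na(phi) | is.na(psi))
    }
    do.call(rbind, out)
}

#' Backbone torsions of an ensemble
#'
#' @param e an [NMREnsemble-class]
#' @param chain chain identifier
#' @return data.frame with `model`, `resSeq`, `resName`, `phi`, `psi`,
#'   `terminal` (no sequential neighbour, torsion undefined)
#' @export
phiPsi <- function(e, chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    .phiPsi(e, chain)
}

#' Ramachandran summary over an ensemble selection
#'
#' Classifies the phi/psi of every selected residue in every conformer
#' (pooled, matching per-model classification aggregated over the
#' ensemble) and reports counts and percentages per region. Percentages
#' are over classifiable residues, i.e. excluding Gly/Pro/termini.
#'
#' @param e an [NMREnsemble-class] (>= 1 conformer)
#' @param sel residue selection ([atomSelection()] or its `residues`
#'   argument); the atom class is ignored.
#' @param chain chain identifier
#' @return object of class `RamaSummary`: list with `counts` (named,
#'   including `excluded`), `percent` (over classifiable residues, sums to
#'   100), `nClassifiable`, `points` (the classified torsion table).
#' @export
ramaSummary <- function(e, sel = NULL, chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    if (!is(sel, "AtomSelection")) sel <- atomSelection(sel)
    tp <- .phiPsi(e, chain)
    rr <- sel@residueRanges
    if (nrow(rr) > 0) {
        keep <- Reduce(`|`, lapply(seq_len(nrow(rr)), function(i)
            tp$resSeq >= rr[i, 1] & tp$resSeq <= rr[i, 2]))
        tp <- tp[keep, , drop = FALSE]
    }
    if (nrow(tp) == 0L) stop("selection contains no residues")
    tp$region <- ramaClassify(tp$phi, tp$psi, tp$resName, tp$terminal)
    counts <- table(factor(tp$region, levels = c(.ramaRegions, "excluded")))
    nc <- sum(counts[.ramaRegions])
    if (nc == 0L) stop("no classifiable residues in selection")
    structure(list(counts = c(counts),
                   percent = 100 * c(counts[.ramaRegions]) / nc,
                   nClassifiable = nc,
                   points = tp),
              class = "RamaSummary")
}

#' @export
print.RamaSummary <- function(x, ...) {
    cat("RamaSummary over", x$nClassifiable, "classifiable residue-conformers\n")
    for (r in .ramaRegions)
        cat(sprintf("  %-14s %6.1f %% (%d)\n", r, x$percent[r], x$counts[r]))
    cat("  excluded (Gly/Pro/termini):", x$counts["excluded"], "\n")
    invisible(x)
}

## ---- zinc-site geometry -------------------------------------------------

#' Target geometry of a Cys4-Zn coordination site
#'
#' Default targets are the tetrahedral thiolate-zinc restraint values used
#' for structural zinc sites: S-Zn 2.3 Angstrom, Ca-Cb-S 114.3558, Cb-S-Zn
#' 109.5, Hb-Cb-S 107.9185 and S-Zn-S 109.5 degrees. Tolerances are not
#' part of the targets; defaults of 0.1 Angstrom on bonds and 5 degrees on
#' angles are a documented package choice.
#'
#' @param sZnBond S-Zn bond length target, Angstrom
#' @param caCbSAngle,cbSZnAngle,hbCbSAngle,sZnSAngle angle targets, degrees
#' @param bondTol,angleTol pass/fail tolerances
#' @return object of class `ZincRestraintSet`
#' @export
zincRestraintSet <- function(sZnBond = 2.3, caCbSAngle = 114.3558,
                             cbSZnAngle = 109.5, hbCbSAngle = 107.9185,
                             sZnSAngle = 109.5, bondTol = 0.1,
                             angleTol = 5) {
    stopifnot(sZnBond > 0, caCbSAngle > 0, cbSZnAngle > 0, hbCbSAngle > 0,
              sZnSAngle > 0)
    structure(list(sZnBond = sZnBond, caCbSAngle = caCbSAngle,
                   cbSZnAngle = cbSZnAngle, hbCbSAngle = hbCbSAngle,
                   sZnSAngle = sZnSAngle, bondTol = bondTol,
                   angleTol = angleTol),
              class = "ZincRestraintSet")
}

.findAtom <- function(a, X, chain, resSeq, name) {
    i <- which(a$chain == chain & a$resSeq == resSeq & a$name == name)
    if (length(i) == 0L) return(NULL)
    X[i[1], ]
}

#' Measure Cys4-Zn coordination geometry in one conformer
#'
#' Reports the 4 S-Zn distances, 6 S-Zn-S angles, and per-cysteine
#' Ca-Cb-S, Cb-S-Zn and (when beta hydrogens are present) Hb-Cb-S angles.
#' The zinc is found as the `ZN` atom nearest the centroid of the four SG
#' atoms unless `znResSeq` pins it.
#'
#' @param e an [NMREnsemble-class]
#' @param cysResidues integer vector of 4 cysteine residue numbers
#' @param model conformer index (default 1)
#' @param znResSeq residue number of the zinc HETATM (optional)
#' @param chain chain identifier
#' @return object of class `ZincGeometry`: list of data.frames `bonds`
#'   (`resSeq`, `dist`), `sZnS` (`res1`, `res2`, `angle`), `caCbS`,
#'   `cbSZn`, `hbCbS` (possibly empty)
#' @export
zincGeometry <- function(e, cysResidues, model = 1, znResSeq = NULL,
                         chain = NULL) {
    stopifnot(is(e, "NMREnsemble"), length(cysResidues) == 4L)
    a <- e@atoms
    if (is.null(chain)) chain <- a$chain[1]
    X <- coords(e, model)
    sg <- lapply(cysResidues, function(r) .findAtom(a, X, chain, r, "SG"))
    missing <- cysResidues[vapply(sg, is.null, logical(1))]
    if (length(missing) > 0)
        stop("missing SG atom(s) for residue(s): ",
             paste(missing, collapse = ", "))
    znIdx <- which(a$name == "ZN" &
                   (is.null(znResSeq) | a$resSeq %in% znResSeq))
    if (length(znIdx) == 0L) stop("missing atom: ZN")
    cen <- colMeans(do.call(rbind, sg))
    zn <- X[znIdx[which.min(vapply(znIdx, function(i)
        sum((X[i, ] - cen)^2), numeric(1)))], ]
    bonds <- data.frame(resSeq = cysResidues,
                        dist = vapply(sg, function(s)
                            sqrt(sum((s - zn)^2)), numeric(1)))
    prs <- utils::combn(4, 2)
    sZnS <- data.frame(res1 = cysResidues[prs[1, ]],
                       res2 = cysResidues[prs[2, ]],
                       angle = apply(prs, 2, function(p)
                           .angleDeg(sg[[p[1]]], zn, sg[[p[2]]])))
    ang1 <- ang2 <- rep(NA_real_, 4)
    hb <- NULL
    for (i in seq_len(4)) {
        ca <- .findAtom(a, X, chain, cysResidues[i], "CA")
        cb <- .findAtom(a, X, chain, cysResidues[i], "CB")
        if (!is.null(ca) && !is.null(cb))
            ang1[i] <- .angleDeg(ca, cb, sg[[i]])
        if (!is.null(cb))
            ang2[i] <- .angleDeg(cb, sg[[i]], zn)
        for (h in c("HB1", "HB2", "HB3")) {
            hp <- .findAtom(a, X, chain, cysResidues[i], h)
            if (!is.null(hp) && !is.null(cb))
                hb <- rbind(hb, data.frame(resSeq = cysResidues[i], atom = h,
                                           angle = .angleDeg(hp, cb, sg[[i]])))
        }
    }
    structure(list(bonds = bonds, sZnS = sZnS,
                   caCbS = data.frame(resSeq = cysResidues, angle = ang1),
                   cbSZn = data.frame(resSeq = cysResidues, angle = ang2),
                   hbCbS = if (is.null(hb))
                       data.frame(resSeq = integer(0), atom = character(0),
                                  angle = numeric(0)) else hb),
              class = "ZincGeometry")
}

#' Check measured zinc-site geometry against restraint targets
#'
#' @param geom a [zincGeometry()] result
#' @param restraints a [zincRestraintSet()]
#' @return object of class `ZincCheck`: data.frame `items` with `item`,
#'   `label`, `measured`, `target`, `deviation`, `tolerance`, `pass`, plus
#'   `nViolations` and `nChecks` attributes-style fields
#' @export
checkZincRestraints <- function(geom, restraints = zincRestraintSet()) {
    stopifnot(inherits(geom, "ZincGeometry"),
              inherits(restraints, "ZincRestraintSet"))
    rows <- list(
        data.frame(item = "s_zn_bond",
                   label = paste0("S-Zn ", geom$bonds$resSeq),
                   measured = geom$bonds$dist,
                   target = restraints$sZnBond,
                   tolerance = restraints$bondTol),
        data.frame(item = "s_zn_s_angle",
                   label = paste0("S-Zn-S ", geom$sZnS$res1, "/", geom$sZnS$res2),
                   measured = geom$sZnS$angle,
                   target = restraints$sZnSAngle,
                   tolerance = restraints$angleTol),
        data.frame(item = "ca_cb_s_angle",
                   label = paste0("Ca-Cb-S ", geom$caCbS$resSeq),
                   measured = geom$caCbS$angle,
                   target = restraints$caCbSAngle,
                   tolerance = restraints$angleTol),
        data.frame(item = "cb_s_zn_angle",
                   label = paste0("Cb-S-Zn ", geom$cbSZn$resSeq),
                   measured = geom$cbSZn$angle,
                   target = restraints$cbSZnAngle,
                   tolerance = restraints$angleTol))
    if (nrow(geom$hbCbS) > 0)
        rows <- c(rows, list(
            data.frame(item = "hb_cb_s_angle",
                       label = paste0("Hb-Cb-S ", geom$hbCbS$resSeq, ".",
                                      geom$hbCbS$atom),
                       measured = geom$hbCbS$angle,
                       target = restraints$hbCbSAngle,
                       tolerance = restraints$angleTol)))
    items <- do.call(rbind, rows)
    items <- items[is.finite(items$measured), , drop = FALSE]
    items$deviation <- items$measured - items$target
    items$pass <- abs(items$deviation) <= items$tolerance
    structure(list(items = items,
                   nViolations = sum(!items$pass),
                   nChecks = nrow(items)),
              class = "ZincCheck")
}

#' @export
print.ZincCheck <- function(x, ...) {
    cat("ZincCheck:", x$nViolations, "violation(s) in", x$nChecks, "checks\n")
    bad <- x$items[!x$items$pass, , drop = FALSE]
    if (nrow(bad) > 0)
        for (i in seq_len(nrow(bad)))
            cat(sprintf("  %s: measured %.3f vs target %.3f (tol %.3f)\n",
                        bad$label[i], bad$measured[i], bad$target[i],
                        bad$tolerance[i]))
    invisible(x)
}

#' Assign cysteines to zinc clusters from ensemble geometry
#'
#' Average-linkage hierarchical clustering of the ensemble-mean SG-SG
#' distance matrix, cut into two clusters. This mirrors the observation
#' that, in structures calculated without zinc atoms or coordination
#' restraints, zinc-ligating cysteines cluster spatially into their two
#' sites. With 8 input cysteines, a split other than 4+4 is an error
#' reporting the offending partition.
#'
#' @param e an [NMREnsemble-class] (>= 2 conformers recommended)
#' @param cysResidues residue numbers of the cysteines; `NULL` selects all
#'   residues with an SG atom
#' @param chain chain identifier
#' @return object of class `ClusterAssignment`: list with `clusters`
#'   (list of two sorted residue vectors, ordered by first residue),
#'   `silhouette` (mean silhouette width of the 2-cut) and `meanDist`
#'   (the ensemble-mean SG-SG distance matrix)
#' @export
assignCysClusters <- function(e, cysResidues = NULL, chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    a <- e@atoms
    if (is.null(chain)) chain <- a$chain[1]
    if (is.null(cysResidues))
        cysResidues <- sort(unique(a$resSeq[a$chain == chain & a$name == "SG"]))
    cysResidues <- sort(as.integer(cysResidues))
    if (length(cysResidues) < 4L)
        stop("need at least 4 cysteines to split into two clusters")
    sc <- selectCoords(e, atomSelection(cysResidues, atoms = "SG"),
                       chain = chain)
    ord <- order(sc$atoms$resSeq)
    m <- nModels(e)
    k <- length(ord)
    D <- matrix(0, k, k)
    for (j in seq_len(m))
        D <- D + as.matrix(stats::dist(sc$xyz[ord, , j]))
    D <- D / m
    res <- sc$atoms$resSeq[ord]
    dimnames(D) <- list(res, res)
    cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                        k = 2)
    groups <- split(res, cl)
    groups <- groups[order(vapply(groups, min, numeric(1)))]
    groups <- lapply(groups, sort)
    names(groups) <- NULL
    sil <- mean(vapply(seq_len(k), function(i) {
        own <- cl == cl[i]; own[i] <- FALSE
        aI <- if (any(own)) mean(D[i, own]) else 0
        bI <- mean(D[i, cl != cl[i]])
        (bI - aI) / max(aI, bI)
    }, numeric(1)))
    if (length(res) == 8L && !all(lengths(groups) == c(4L, 4L)))
        stop("cysteines do not split 4+4: {",
             paste(groups[[1]], collapse = ","), "} / {",
             paste(groups[[2]], collapse = ","), "}")
    structure(list(clusters = groups, silhouette = sil, meanDist = D),
              class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
    cat("ClusterAssignment (mean silhouette", sprintf("%.3f", x$silhouette), ")\n")
    for (i in seq_along(x$clusters))
        cat("  cluster", i, ":", paste(x$clusters[[i]], collapse = ", "), "\n")
    invisible(x)
}
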