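## Ensemble and fragment RMSD statistics about the unbiased mean structure.

#' Ensemble RMSD about the unbiased mean structure
#'
#' Each conformer is Kabsch-superposed onto the unbiased mean over the
#' selection and its RMSD recorded. Because conventions differ on how
#' per-model RMSDs are pooled, both the arithmetic mean and the
#' root-mean-square over models are reported (mean <= rms always).
#' Per-residue RMSDs (over models and atoms of each residue, after the same
#' superpositions) are included for precision profiles along the chain.
#'
#' @param e an [NMREnsemble-class] with at least 2 conformers
#' @param sel an [AtomSelection-class] (or anything [atomSelection()] accepts)
#' @param chain chain identifier, defaulting to the first chain
#' @return object of class `RmsdReport`: list with `perModel` (Angstrom, one
#'   value per conformer), `mean`, `rms`, `perResidue` (data.frame with
#'   `resSeq`, `rmsd`, `nAtoms`), `selection`, and `meanStructure`.
#' @examples
#' ens <- perturbEnsemble(makeTemplate(12, "helix"), nModels = 5,
#'                        sigmaProfile = rep(0.3, 12), seed = 1)
#' ensembleRMSD(ens, atomSelection(atoms = "backbone_O"))
#' @export
ensembleRMSD <- function(e, sel, chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    if (!is(sel, "AtomSelection")) sel <- atomSelection(sel)
    if (nModels(e) < 2L) stop("ensemble RMSD requires at least 2 conformers")
    ms <- unbiasedMean(e, sel, chain = chain)
    sc <- selectCoords(e, sel, chain = chain)
    m <- dim(sc$xyz)[3]
    perModel <- numeric(m)
    sqdev <- matrix(0, dim(sc$xyz)[1], m)   # per-atom squared deviation
    for (j in seq_len(m)) {
        tr <- kabsch(sc$xyz[, , j], ms$coords)
        fitted <- .applyTransform(sc$xyz[, , j], tr)
        d2 <- rowSums((fitted - ms$coords)^2)
        sqdev[, j] <- d2
        perModel[j] <- sqrt(mean(d2))
    }
    res <- sc$atoms$resSeq
    perRes <- do.call(rbind, lapply(unique(res), function(r) {
        rows <- res == r
        data.frame(resSeq = r,
                   rmsd = sqrt(mean(sqdev[rows, , drop = FALSE])),
                   nAtoms = sum(rows))
    }))
    structure(list(perModel = perModel,
                   mean = mean(perModel),
                   rms = sqrt(mean(perModel^2)),
                   perResidue = perRes,
                   selection = sel,
                   meanStructure = ms),
              class = "RmsdReport")
}

#' @export
print.RmsdReport <- function(x, ...) {
    cat("RmsdReport over", length(x$perModel), "conformers\n")
    cat(sprintf("  mean-over-models RMSD: %.3f A\n", x$mean))
    cat(sprintf("  rms-over-models  RMSD: %.3f A\n", x$rms))
    cat(sprintf("  per-model range: %.3f - %.3f A\n",
                min(x$perModel), max(x$perModel)))
    invisible(x)
}

#' Representative conformer of an ensemble
#'
#' The conformer with the lowest Kabsch RMSD to the unbiased mean structure
#' over the given selection.
#'
#' @inheritParams ensembleRMSD
#' @return integer model index (1-based position)
#' @export
representativeModel <- function(e, sel, chain = NULL) {
    rep <- ensembleRMSD(e, sel, chain = chain)
    which.min(rep$perModel)
}

#' RMSD between two fragments of one conformer
#'
#' Kabsch-superposes the atoms of selection `selA` onto those of `selB`
#' within a single conformer, e.g. to compare the two CXXCXXC zinc-binding
#' repeats of a domain. The two selections must resolve to the same number
#' of atoms in matched order (same atom classes along equal-length residue
#' stretches).
#'
#' @param e an [NMREnsemble-class]
#' @param selA,selB selections resolving to equal atom counts
#' @param model integer model index, or `"representative"` to use the model
#'   closest to the unbiased mean over `selA` and `selB` combined.
#' @param chain chain identifier
#' @return list with `rmsd` (Angstrom, for the chosen model), `model`,
#'   and `perModel` (fragment RMSD evaluated in every conformer)
#' @export
fragmentRMSD <- function(e, selA, selB, model = "representative", chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    if (!is(selA, "AtomSelection")) selA <- atomSelection(selA)
    if (!is(selB, "AtomSelection")) selB <- atomSelection(selB)
    A <- selectCoords(e, selA, chain = chain)
    B <- selectCoords(e, selB, chain = chain)
    if (dim(A$xyz)[1] != dim(B$xyz)[1])
        stop("fragment selections resolve to different atom counts: ",
             dim(A$xyz)[1], " vs ", dim(B$xyz)[1])
    m <- nModels(e)
    perModel <- vapply(seq_len(m), function(j)
        kabsch(A$xyz[, , j], B$xyz[, , j])$rmsd, numeric(1))
    mi <- if (identical(model, "representative")) {
        if (m >= 2L) {
            both <- atomSelection(rbind(selA@residueRanges, selB@residueRanges),
                                  atoms = selA@atomClass,
                                  custom = selA@customAtoms)
            representativeModel(e, both, chain = chain)
        } else 1L
    } else as.integer(model)
    stopifnot(mi >= 1L, mi <= m)
    list(rmsd = perModel[mi], model = mi, perModel = perModel)
}
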