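#' @import methods
NULL

#' Multi-conformer NMR structure ensemble
#'
#' An `NMREnsemble` holds one atom topology shared by all conformers and a
#' coordinate array with one slice per conformer (one MODEL of a multi-model
#' PDB deposit). All conformers are guaranteed by the validity method to share
#' the identical `(chain, resSeq, name, altLoc)` atom set in the same order.
#'
#' @slot atoms `data.frame` with one row per atom and columns `serial`,
#'   `name`, `element`, `altLoc`, `resName`, `chain`, `resSeq`.
#' @slot xyz numeric array of dimension `nAtoms x 3 x nModels`, coordinates
#'   in Angstrom.
#' @slot modelIds integer vector of MODEL numbers, one per conformer.
#'
#' @seealso [readEnsemble()], [selectCoords()], [ensembleRMSD()]
#' @export
setClass("NMREnsemble",
         representation(atoms = "data.frame",
                        xyz = "array",
                        modelIds = "integer"))

setValidity("NMREnsemble", function(object) {
    a <- object@atoms
    need <- c("serial", "name", "element", "altLoc", "resName", "chain", "resSeq")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    d <- dim(object@xyz)
    if (length(d) != 3L || d[2] != 3L)
        return("xyz must be an nAtoms x 3 x nModels array")
    if (d[1] != nrow(a))
        return("nrow(atoms) must equal dim(xyz)[1]")
    if (d[3] < 1L)
        return("ensemble must contain at least one conformer")
    if (length(object@modelIds) != d[3])
        return("modelIds length must equal the number of conformers")
    if (!all(is.finite(object@xyz)))
        return("all coordinates must be finite")
    key <- paste(a$chain, a$resSeq, a$name, a$altLoc)
    if (anyDuplicated(key))
        return(paste("duplicate atom:", key[which(duplicated(key))[1]]))
    TRUE
})

#' Residue/atom selection on an ensemble
#'
#' Selections combine inclusive residue ranges (author numbering, as
#' deposited) with an atom class. Atom classes follow common ensemble-RMSD
#' conventions: `all_heavy` excludes hydrogen/deuterium, `backbone` is
#' N/CA/C, `backbone_O` adds the carbonyl O, `CA` and `SG` select single
#' atoms, `custom` uses an explicit atom-name list.
#'
#' @slot residueRanges two-column integer matrix of inclusive
#'   `(start, end)` residue ranges, or a 0-row matrix meaning all residues.
#' @slot atomClass one of `"all_heavy"`, `"backbone"`, `"backbone_O"`,
#'   `"CA"`, `"SG"`, `"custom"`.
#' @slot customAtoms character vector of atom names used when
#'   `atomClass == "custom"`.
#' @export
setClass("AtomSelection",
         representation(residueRanges = "matrix",
                        atomClass = "character",
                        customAtoms = "character"))

setValidity("AtomSelection", function(object) {
    ok <- c("all_heavy", "backbone", "backbone_O", "CA", "SG", "custom")
    if (length(object@atomClass) != 1L || !object@atomClass %in% ok)
        return(paste("atomClass must be one of:", paste(ok, collapse = ", ")))
    r <- object@residueRanges
    if (ncol(r) != 2L)
        return("residueRanges must have two columns (start, end)")
    if (nrow(r) > 0 && any(r[, 2] < r[, 1]))
        return("each residue range must satisfy start <= end")
    if (object@atomClass == "custom" && length(object@customAtoms) == 0L)
        return("custom atomClass requires customAtoms")
    TRUE
})

#' Number of conformers in an ensemble
#' @param x an [NMREnsemble-class]
#' @return integer
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname nModels
#' @export
setMethod("nModels", "NMREnsemble", function(x) dim(x@xyz)[3])

#' Number of atoms in the shared topology
#' @param x an [NMREnsemble-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "NMREnsemble", function(x) dim(x@xyz)[1])

#' Atom topology table
#' @param x an [NMREnsemble-class]
#' @return `data.frame` with one row per atom
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "NMREnsemble", function(x) x@atoms)

#' Coordinates of one conformer or the whole ensemble
#'
#' @param x an [NMREnsemble-class]
#' @param model integer model index (1-based position, not MODEL id); if
#'   missing, the full `nAtoms x 3 x nModels` array is returned.
#' @return numeric matrix `nAtoms x 3` (single model) or the full array
#' @export
setGeneric("coords", function(x, model) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "NMREnsemble", function(x, model) {
    if (missing(model)) return(x@xyz)
    stopifnot(length(model) == 1L, model >= 1L, model <= nModels(x))
    x@xyz[, , model, drop = FALSE][, , 1]
})

#' Model identifiers (MODEL record numbers)
#' @param x an [NMREnsemble-class]
#' @return integer vector
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' @rdname modelIds
#' @export
setMethod("modelIds", "NMREnsemble", function(x) x@modelIds)

#' Residue sequence map of an ensemble
#'
#' @param x an [NMREnsemble-class]
#' @return named character vector mapping residue number (author numbering)
#'   to 3-letter residue name, in chain order
#' @export
sequenceMap <- function(x) {
    stopifnot(is(x, "NMREnsemble"))
    a <- x@atoms[x@atoms$resName != "ZN", , drop = FALSE]
    keep <- !duplicated(paste(a$chain, a$resSeq))
    stats::setNames(a$resName[keep], a$resSeq[keep])
}

setMethod("show", "NMREnsemble", function(object) {
    a <- object@atoms
    res <- unique(paste(a$chain, a$resSeq))
    cat("NMREnsemble:", nModels(object), "conformer(s),",
        nAtoms(object), "atoms,", length(res), "residues\n")
    cat("  chains:", paste(unique(a$chain), collapse = ", "),
        " residue range:", min(a$resSeq), "-", max(a$resSeq), "\n")
    invisible(object)
})

setMethod("show", "AtomSelection", function(object) {
    r <- object@residueRanges
    rr <- if (nrow(r) == 0) "all" else
        paste(apply(r, 1, function(z) paste0(z[1], "-", z[2])), collapse = ",")
    cat("AtomSelection: residues", rr, "| atoms", object@atomClass, "\n")
    if (object@atomClass == "custom")
        cat("  atom names:", paste(object@customAtoms, collapse = ", "), "\n")
    invisible(object)
})
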