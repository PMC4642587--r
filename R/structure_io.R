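## Multi-model PDB input/output and coordinate selection.
## Parsing and record formatting are delegated to bio3d; this layer adds the
## ensemble container, strict cross-model topology checks and altloc policy.

.guessElement <- function(name) {
    nm <- toupper(gsub("[0-9' ]", "", name))
    el <- character(length(nm))
    el[grepl("^H", nm)] <- "H"
    el[grepl("^D$", nm)] <- "D"
    el[nm == "ZN"] <- "Zn"
    el[nm %in% c("SG", "SD", "S")] <- "S"
    rest <- el == ""
    el[rest] <- substr(nm[rest], 1, 1)
    el
}

## Light fixed-column scan of ATOM/HETATM identity fields, used only to
## verify that every MODEL block carries the identical topology and to
## report the first differing atom by name.
.modelBlocks <- function(lines) {
    isModel <- grepl("^MODEL", lines)
    if (!any(isModel)) return(list(`1` = lines))
    starts <- which(isModel)
    ids <- as.integer(sub("^MODEL\\s+", "", lines[starts]))
    ends <- c(starts[-1] - 1L, length(lines))
    blocks <- lapply(seq_along(starts),
                     function(i) lines[starts[i]:ends[i]])
    names(blocks) <- ids
    blocks
}

.atomKeys <- function(block) {
    rec <- block[grepl("^(ATOM  |HETATM)", block)]
    if (length(rec) == 0L) return(character(0))
    alt <- substr(rec, 17, 17)
    keep <- alt %in% c(" ", "A")
    rec <- rec[keep]
    paste0(substr(rec, 22, 22), "/",                      # chain
           trimws(substr(rec, 23, 26)), "/",              # resSeq
           trimws(substr(rec, 18, 20)), "/",              # resName
           trimws(substr(rec, 13, 16)))                   # atom name
}

#' Read a multi-model PDB ensemble
#'
#' Reads a (possibly multi-MODEL) PDB file into an [NMREnsemble-class].
#' One conformer is created per MODEL block; a file without MODEL records
#' yields a single-conformer ensemble. Alternate locations other than blank
#' or `'A'` are dropped (NMR ensembles essentially never carry altlocs, and
#' a fixed policy keeps selections deterministic). Hydrogens are retained;
#' the `all_heavy` atom class excludes them downstream. The atom topology is
#' verified to be identical across models and a mismatch is a hard error
#' naming the first differing atom.
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @return an [NMREnsemble-class]
#' @examples
#' tmpl <- makeTemplate(5, motif = "helix")
#' f <- tempfile(fileext = ".pdb")
#' writeEnsemble(tmpl, f)
#' readEnsemble(f)
#' @export
readEnsemble <- function(file) {
    lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
        readLines(file) else as.character(file)
    blocks <- .modelBlocks(lines)
    keys <- lapply(blocks, .atomKeys)
    if (all(lengths(keys) == 0L))
        stop("no ATOM/HETATM records found")
    ref <- keys[[1]]
    for (i in seq_along(keys)[-1]) {
        k <- keys[[i]]
        if (length(k) != length(ref) || any(k != ref)) {
            n <- max(length(k), length(ref))
            kp <- c(k, rep("", n - length(k)))
            rp <- c(ref, rep("", n - length(ref)))
            j <- which(kp != rp)[1]
            bad <- if (nzchar(kp[j])) kp[j] else rp[j]
            stop("topology mismatch between models 1 and ", names(keys)[i],
                 ": first differing atom ", bad)
        }
    }
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(lines, tf)
    pdb <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
    a <- pdb$atom
    nm <- nrow(pdb$xyz)
    nat <- nrow(a)
    xyz <- aperm(array(t(pdb$xyz), dim = c(3L, nat, nm)), c(2L, 1L, 3L))
    alt <- ifelse(is.na(a$alt), "", a$alt)
    keep <- alt %in% c("", "A")
    a <- a[keep, , drop = FALSE]
    xyz <- xyz[keep, , , drop = FALSE]
    el <- ifelse(is.na(a$elesy) | a$elesy == "", .guessElement(a$elety), a$elesy)
    atoms <- data.frame(serial = a$eleno,
                        name = a$elety,
                        element = el,
                        altLoc = alt[keep],
                        resName = a$resid,
                        chain = ifelse(is.na(a$chain), "A", a$chain),
                        resSeq = a$resno,
                        stringsAsFactors = FALSE)
    ids <- suppressWarnings(as.integer(names(blocks)))
    if (anyNA(ids)) ids <- seq_len(nm)
    new("NMREnsemble", atoms = atoms, xyz = xyz, modelIds = ids[seq_len(nm)])
}

#' Write an ensemble as a multi-model PDB
#'
#' Writes standard fixed-width MODEL/ENDMDL PDB records with coordinates to
#' three decimals. Residue numbers above 9999 do not fit the format and are
#' an error.
#'
#' @param e an [NMREnsemble-class]
#' @param file output path; if `NULL`, the PDB lines are returned as a
#'   character vector instead.
#' @return `file` invisibly, or the PDB text when `file` is `NULL`
#' @export
writeEnsemble <- function(e, file = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    if (nModels(e) < 1L || nAtoms(e) < 1L)
        stop("ensemble has no conformers or no atoms")
    if (any(e@atoms$resSeq > 9999L))
        stop("resSeq > 9999 cannot be represented in PDB format")
    tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
    m <- nModels(e)
    ## rows of flat: one model, columns interleaved (x1, y1, z1, x2, ...)
    flat <- t(vapply(seq_len(m),
                     function(j) as.vector(t(e@xyz[, , j])),
                     numeric(3L * nAtoms(e))))
    bio3d::write.pdb(file = tf,
                     xyz = flat,
                     type = ifelse(e@atoms$resName %in% c("ZN", "HOH"),
                                   "HETATM", "ATOM"),
                     resno = e@atoms$resSeq,
                     resid = e@atoms$resName,
                     eleno = e@atoms$serial,
                     elety = e@atoms$name,
                     chain = e@atoms$chain,
                     elesy = e@atoms$element)
    if (is.null(file)) {
        out <- readLines(tf)
        unlink(tf)
        return(out)
    }
    invisible(file)
}

#' Construct an atom/residue selection
#'
#' @param residues residue ranges in author numbering: a string such as
#'   `"175-196,208-217"`, a numeric vector of single residues, a list of
#'   `c(start, end)` pairs, or a two-column matrix. `NULL` selects all
#'   residues.
#' @param atoms atom class: `"all_heavy"` (default), `"backbone"` (N, CA, C),
#'   `"backbone_O"` (N, CA, C, O), `"CA"`, `"SG"` or `"custom"`.
#' @param custom character vector of atom names for `atoms = "custom"`.
#' @return an [AtomSelection-class]
#' @examples
#' atomSelection("175-196,208-217", atoms = "all_heavy")
#' atomSelection(c(176, 179, 182, 215), atoms = "SG")
#' @export
atomSelection <- function(residues = NULL, atoms = "all_heavy", custom = character(0)) {
    rr <- if (is.null(residues)) {
        matrix(integer(0), ncol = 2)
    } else if (is.character(residues)) {
        parts <- trimws(strsplit(paste(residues, collapse = ","), ",")[[1]])
        parts <- parts[nzchar(parts)]
        t(vapply(parts, function(p) {
            v <- as.integer(strsplit(p, "-")[[1]])
            if (length(v) == 1L) c(v, v) else v[1:2]
        }, integer(2)))
    } else if (is.matrix(residues)) {
        residues
    } else if (is.list(residues)) {
        t(vapply(residues, function(v) {
            v <- as.integer(v)
            if (length(v) == 1L) c(v, v) else v[1:2]
        }, integer(2)))
    } else {
        cbind(as.integer(residues), as.integer(residues))
    }
    rr <- matrix(as.integer(rr), ncol = 2)
    dimnames(rr) <- NULL
    new("AtomSelection", residueRanges = rr, atomClass = atoms,
        customAtoms = as.character(custom))
}

.atomClassMask <- function(atoms, sel) {
    switch(sel@atomClass,
           all_heavy = !(atoms$element %in% c("H", "D")),
           backbone = atoms$name %in% c("N", "CA", "C"),
           backbone_O = atoms$name %in% c("N", "CA", "C", "O"),
           CA = atoms$name == "CA",
           SG = atoms$name == "SG",
           custom = atoms$name %in% sel@customAtoms)
}

#' Resolve a selection into per-conformer coordinates
#'
#' Returns the selected coordinates of every conformer with an identical,
#' file-stable atom ordering, together with the matching rows of the atom
#' table. A residue range that matches no atom in the ensemble is an error.
#'
#' @param e an [NMREnsemble-class]
#' @param sel an [AtomSelection-class] (or arguments coercible via
#'   [atomSelection()])
#' @param chain chain identifier; defaults to the first chain in the file.
#' @return list with elements `xyz` (array `k x 3 x nModels`), `atoms`
#'   (the selected rows of the topology table) and `index` (row indices into
#'   [atomData()]).
#' @export
selectCoords <- function(e, sel, chain = NULL) {
    stopifnot(is(e, "NMREnsemble"))
    if (!is(sel, "AtomSelection")) sel <- atomSelection(sel)
    a <- e@atoms
    if (is.null(chain)) chain <- a$chain[1]
    inChain <- a$chain == chain
    rr <- sel@residueRanges
    if (nrow(rr) == 0L) {
        resMask <- inChain
    } else {
        perRange <- lapply(seq_len(nrow(rr)), function(i)
            inChain & a$resSeq >= rr[i, 1] & a$resSeq <= rr[i, 2])
        hit <- vapply(perRange, any, logical(1))
        if (any(!hit))
            stop("selection ranges match no atoms: ",
                 paste(apply(rr[!hit, , drop = FALSE], 1,
                             function(z) paste0(z[1], "-", z[2])),
                       collapse = ", "))
        resMask <- Reduce(`|`, perRange)
    }
    mask <- resMask & .atomClassMask(a, sel)
    if (!any(mask))
        stop("selection resolves to zero atoms (atom class ",
             sel@atomClass, ")")
    idx <- which(mask)
    list(xyz = e@xyz[idx, , , drop = FALSE],
         atoms = a[idx, , drop = FALSE],
         index = idx)
}

## Internal constructor from an atom table + coordinate array.
.newEnsemble <- function(atoms, xyz, modelIds = NULL) {
    if (length(dim(xyz)) == 2L) xyz <- array(xyz, dim = c(dim(xyz), 1L))
    if (is.null(modelIds)) modelIds <- seq_len(dim(xyz)[3])
    if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
    if (is.null(atoms$altLoc)) atoms$altLoc <- ""
    if (is.null(atoms$element)) atoms$element <- .guessElement(atoms$name)
    if (is.null(atoms$chain)) atoms$chain <- "A"
    new("NMREnsemble", atoms = atoms, xyz = xyz,
        modelIds = as.integer(modelIds))
}

#' Combine ensembles atom-wise (same conformer count)
#'
#' Concatenates the atom tables and coordinate arrays of two ensembles with
#' the same number of conformers, e.g. to merge a protein chain with zinc
#' sites. Atom serials are renumbered.
#'
#' @param e1,e2 [NMREnsemble-class] objects with equal `nModels`
#' @return an [NMREnsemble-class]
#' @export
bindEnsembles <- function(e1, e2) {
    stopifnot(is(e1, "NMREnsemble"), is(e2, "NMREnsemble"),
              nModels(e1) == nModels(e2))
    atoms <- rbind(e1@atoms, e2@atoms)
    atoms$serial <- seq_len(nrow(atoms))
    xyz <- array(0, dim = c(nrow(atoms), 3L, nModels(e1)))
    xyz[seq_len(nAtoms(e1)), , ] <- e1@xyz
    xyz[nAtoms(e1) + seq_len(nAtoms(e2)), , ] <- e2@xyz
    .newEnsemble(atoms, xyz, modelIds(e1))
}
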