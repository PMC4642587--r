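## Ground-truth-known synthetic inputs: ideal-geometry peptide templates,
## Gaussian-perturbed ensembles with a per-residue displacement profile,
## toy Cys4-Zn sites, and relaxation datasets generated from model-free
## parameters. All generators are pure functions of their arguments and a
## seed.

## Internal-coordinate (NeRF) placement: D is placed at bond length r from
## C, bond angle theta (B-C-D) and torsion chi (A-B-C-D).
.nerf <- function(A, B, C, r, thetaDeg, chiDeg) {
    th <- thetaDeg * pi / 180; ch <- chiDeg * pi / 180
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A; ab <- ab / sqrt(sum(ab^2))
    n <- .cross(ab, bc); n <- n / sqrt(sum(n^2))
    m <- .cross(n, bc)
    d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
    C + cbind(bc, m, n) %*% d
}

.BB <- list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
            bCACB = 1.53, bCBSG = 1.81, bCBHB = 1.09,
            aNCAC = 111.0, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.8,
            aNCACB = 110.5, aCACBSG = 114.3558, aSCBHB = 107.9185)

.threeLetter <- c(A = "ALA", C = "CYS", G = "GLY", P = "PRO", S = "SER",
                  L = "LEU", K = "LYS", R = "ARG", E = "GLU", D = "ASP",
                  F = "PHE", H = "HIS", M = "MET", Q = "GLN", V = "VAL",
                  T = "THR", N = "ASN", I = "ILE", W = "TRP", Y = "TYR")

.normSequence <- function(sequence, nRes) {
    if (is.null(sequence)) return(rep("ALA", nRes))
    if (length(sequence) == 1L && nchar(sequence) > 3L)
        sequence <- strsplit(sequence, "")[[1]]
    if (all(nchar(sequence) == 1L))
        sequence <- unname(.threeLetter[toupper(sequence)])
    stopifnot(length(sequence) == nRes, !anyNA(sequence))
    toupper(sequence)
}

## Draw one (phi, psi) pair uniformly from the favoured+additional regions.
.sampleAllowed <- function() {
    repeat {
        phi <- stats::runif(1, -180, 180); psi <- stats::runif(1, -180, 180)
        if (ramaClassify(phi, psi) %in% c("most_favoured", "additional"))
            return(c(phi, psi))
    }
}

#' Build an ideal-geometry peptide template
#'
#' Constructs a single-conformer backbone (N, CA, C, O, plus CB and, for
#' cysteine, SG) with standard bond lengths and angles. `"helix"` uses
#' phi = -57, psi = -47 throughout; `"coil"` draws torsions uniformly from
#' the favoured+additional Ramachandran regions (seeded); `"mixed"` mimics
#' a two-zinc-cluster domain layout: a flexible N-terminus, a first rigid
#' (helical) segment, a flexible loop, a second rigid segment and a
#' flexible C-terminus, with the segment boundaries recorded in the
#' `segments` attribute.
#'
#' @param nRes number of residues (>= 4)
#' @param motif `"helix"`, `"coil"` or `"mixed"`
#' @param sequence residue sequence (1- or 3-letter, length `nRes` or a
#'   single string); default poly-alanine
#' @param startRes author number of the first residue
#' @param seed RNG seed for coil torsions
#' @return a single-conformer [NMREnsemble-class]; for `"mixed"`, attribute
#'   `segments` holds the rigid/flexible residue ranges.
#' @examples
#' makeTemplate(12, motif = "helix")
#' @export
makeTemplate <- function(nRes, motif = c("helix", "coil", "mixed"),
                         sequence = NULL, startRes = 1L, seed = 1) {
    motif <- match.arg(motif)
    stopifnot(nRes >= 4L)
    sequence <- .normSequence(sequence, nRes)
    segments <- NULL
    kind <- switch(motif,
                   helix = rep("rigid", nRes),
                   coil = rep("flex", nRes),
                   mixed = {
                       nHead <- max(2L, round(nRes * 8 / 56))
                       nRig1 <- max(4L, round(nRes * 22 / 56))
                       nLoop <- max(2L, round(nRes * 11 / 56))
                       nRig2 <- max(4L, round(nRes * 10 / 56))
                       nTail <- nRes - nHead - nRig1 - nLoop - nRig2
                       stopifnot(nTail >= 1L)
                       lens <- c(nHead, nRig1, nLoop, nRig2, nTail)
                       ends <- cumsum(lens)
                       rng <- function(i) startRes + c(ends[i] - lens[i],
                                                       ends[i] - 1L)
                       segments <- list(rigid = list(rng(2), rng(4)),
                                        flexible = list(rng(1), rng(3), rng(5)))
                       rep(c("flex", "rigid", "flex", "rigid", "flex"), lens)
                   })
    torsions <- .withSeed(seed, t(vapply(kind, function(k)
        if (k == "rigid") c(-57, -47) else .sampleAllowed(), numeric(2))))
    phi <- torsions[, 1]; psi <- torsions[, 2]
    b <- .BB
    atoms <- list(); xyz <- list()
    ## seed atoms of residue 1
    N <- c(0, 0, 0)
    CA <- c(b$bNCA, 0, 0)
    C <- .nerf(c(0, 1, 0), N, CA, b$bCAC, b$aNCAC, phi[1])
    prevC <- NULL
    addAtom <- function(name, p, i) {
        atoms[[length(atoms) + 1L]] <<- data.frame(
            name = name, resName = sequence[i], chain = "A",
            resSeq = startRes + i - 1L, stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <<- as.numeric(p)
    }
    for (i in seq_len(nRes)) {
        addAtom("N", N, i); addAtom("CA", CA, i); addAtom("C", C, i)
        ## carbonyl O in the peptide plane, opposite the next N
        O <- .nerf(N, CA, C, b$bCO, b$aCACO, .wrapAngle(psi[i] + 180))
        addAtom("O", O, i)
        if (sequence[i] != "GLY") {
            CB <- .nerf(C, N, CA, b$bCACB, b$aNCACB, 122.5)
            addAtom("CB", CB, i)
            if (sequence[i] == "CYS") {
                SG <- .nerf(N, CA, CB, b$bCBSG, b$aCACBSG, -65)
                addAtom("SG", SG, i)
            }
        }
        if (i < nRes) {
            Nn <- .nerf(N, CA, C, b$bCN, b$aCACN, psi[i])
            CAn <- .nerf(CA, C, Nn, b$bNCA, b$aCNCA, 180)
            Cn <- .nerf(C, Nn, CAn, b$bCAC, b$aNCAC, phi[i + 1])
            N <- Nn; CA <- CAn; C <- Cn
        }
    }
    at <- do.call(rbind, atoms)
    e <- .newEnsemble(at, do.call(rbind, xyz))
    attr(e, "segments") <- segments
    e
}

.smoothNoise <- function(nRes, window) {
    G <- matrix(stats::rnorm(nRes * 3), nRes, 3)
    if (window <= 1L) return(G)
    half <- (window - 1L) %/% 2L
    S <- matrix(0, nRes, 3)
    for (i in seq_len(nRes)) {
        w <- max(1L, i - half):min(nRes, i + half)
        S[i, ] <- colSums(G[w, , drop = FALSE]) / sqrt(length(w))
    }
    S
}

#' Perturb a template into a synthetic ensemble
#'
#' Generates `nModels` conformers by adding Gaussian displacements to the
#' template. Displacements are drawn per residue and smoothed along the
#' chain with a moving average (default 3 residues, rescaled to keep the
#' marginal SD at the profile value), so neighbouring residues move
#' coherently, mimicking loop disorder rather than uncorrelated atomic
#' jitter. Side-chain atoms (beyond N/CA/C/O) can receive extra independent
#' displacement via `sideChainFactor` > 1, emulating their larger spread.
#'
#' @param template a single-conformer [NMREnsemble-class] (see
#'   [makeTemplate()])
#' @param nModels number of conformers to generate (>= 2)
#' @param sigmaProfile per-residue displacement SD, Angstrom: a single
#'   value, a vector along the chain, or a vector named by residue number
#' @param smoothWindow moving-average window in residues (default 3)
#' @param sideChainFactor total SD multiplier for side-chain atoms
#' @param seed RNG seed
#' @return an [NMREnsemble-class] with `nModels` conformers (the
#'   `segments` attribute of the template, if any, is carried over)
#' @export
perturbEnsemble <- function(template, nModels = 20, sigmaProfile = 0.5,
                            smoothWindow = 3, sideChainFactor = 1,
                            seed = 1) {
    stopifnot(is(template, "NMREnsemble"), nModels(template) == 1L,
              nModels >= 2L, all(sigmaProfile >= 0), sideChainFactor >= 1)
    a <- template@atoms
    res <- sort(unique(a$resSeq))
    nRes <- length(res)
    sig <- if (!is.null(names(sigmaProfile))) {
        s <- sigmaProfile[as.character(res)]
        stopifnot(!anyNA(s)); as.numeric(s)
    } else rep_len(as.numeric(sigmaProfile), nRes)
    resIdx <- match(a$resSeq, res)
    side <- !(a$name %in% c("N", "CA", "C", "O"))
    extra <- sig * sqrt(max(sideChainFactor^2 - 1, 0))
    X0 <- template@xyz[, , 1]
    xyz <- array(0, dim = c(nrow(a), 3L, nModels))
    .withSeed(seed, {
        for (j in seq_len(nModels)) {
            S <- .smoothNoise(nRes, smoothWindow) * sig
            disp <- S[resIdx, , drop = FALSE]
            if (any(side) && sideChainFactor > 1)
                disp[side, ] <- disp[side, ] +
                    matrix(stats::rnorm(sum(side) * 3), ncol = 3) *
                    extra[resIdx[side]]
            xyz[, , j] <- X0 + disp
        }
    })
    e <- .newEnsemble(a, xyz)
    attr(e, "segments") <- attr(template, "segments")
    e
}

#' Build a toy Cys4-Zn coordination site
#'
#' Places four SG atoms at ideal tetrahedral positions around a zinc and
#' grows a Cb/Ca (and optionally beta-hydrogen) scaffold outward using the
#' restraint-target angles, so at `distortion = 0` the site passes
#' [checkZincRestraints()] with zero violations. `distortion > 0` adds
#' Gaussian displacement of that SD to every atom.
#'
#' @param sZn S-Zn bond length, Angstrom
#' @param distortion per-atom Gaussian displacement SD, Angstrom
#' @param seed RNG seed (used when `distortion > 0`)
#' @param resSeq four cysteine residue numbers
#' @param znResSeq residue number given to the zinc HETATM
#' @param chain chain identifier
#' @param center 3-vector position of the zinc
#' @param withHB include two beta hydrogens per cysteine
#' @param includeZn include the zinc atom (set `FALSE` for an apo site)
#' @return a single-conformer [NMREnsemble-class] fragment
#' @export
makeZincSite <- function(sZn = 2.3, distortion = 0, seed = 1,
                         resSeq = c(1L, 2L, 3L, 4L), znResSeq = 901L,
                         chain = "A", center = c(0, 0, 0), withHB = TRUE,
                         includeZn = TRUE) {
    stopifnot(sZn > 0, length(resSeq) == 4L)
    b <- .BB
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    atoms <- list(); xyz <- list()
    addAtom <- function(name, p, rs, rn) {
        atoms[[length(atoms) + 1L]] <<- data.frame(
            name = name, resName = rn, chain = chain, resSeq = rs,
            stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <<- as.numeric(p)
    }
    zn <- center
    for (i in seq_len(4)) {
        SG <- zn + sZn * dirs[i, ]
        other <- zn + sZn * dirs[if (i == 4L) 1L else i + 1L, ]
        CB <- .nerf(other, zn, SG, b$bCBSG, 109.5, 60 * i)
        CA <- .nerf(zn, SG, CB, b$bCACB, b$aCACBSG, 180)
        addAtom("CA", CA, resSeq[i], "CYS")
        addAtom("CB", CB, resSeq[i], "CYS")
        addAtom("SG", SG, resSeq[i], "CYS")
        if (withHB) {
            addAtom("HB1", .nerf(zn, SG, CB, b$bCBHB, b$aSCBHB, 60),
                    resSeq[i], "CYS")
            addAtom("HB2", .nerf(zn, SG, CB, b$bCBHB, b$aSCBHB, -60),
                    resSeq[i], "CYS")
        }
    }
    if (includeZn) addAtom("ZN", zn, znResSeq, "ZN")
    at <- do.call(rbind, atoms)
    X <- do.call(rbind, xyz)
    if (distortion > 0)
        X <- X + .withSeed(seed,
            matrix(stats::rnorm(length(X), sd = distortion), ncol = 3))
    .newEnsemble(at, X)
}

#' Two well-separated apo Cys4 sites as an ensemble
#'
#' Convenience generator for cluster-assignment tests: two zinc-free Cys4
#' sites with the given residue numbering, separated by `separation`
#' Angstrom, perturbed over `nModels` conformers.
#'
#' @param res1,res2 residue numbers of the two cysteine quartets
#' @param separation centre-centre distance, Angstrom
#' @param nModels conformers
#' @param distortion per-atom displacement SD, Angstrom
#' @param seed RNG seed
#' @param includeZn include the two zinc atoms
#' @return an [NMREnsemble-class]
#' @export
makeCysClusterEnsemble <- function(res1 = c(176L, 179L, 182L, 215L),
                                   res2 = c(188L, 191L, 194L, 210L),
                                   separation = 15, nModels = 10,
                                   distortion = 0.3, seed = 1,
                                   includeZn = FALSE) {
    base <- bindEnsembles(
        makeZincSite(resSeq = res1, znResSeq = 901L, includeZn = includeZn),
        makeZincSite(resSeq = res2, znResSeq = 902L, includeZn = includeZn,
                     center = c(separation, 0, 0)))
    nat <- nAtoms(base)
    xyz <- array(0, dim = c(nat, 3L, nModels))
    .withSeed(seed, {
        for (j in seq_len(nModels))
            xyz[, , j] <- base@xyz[, , 1] +
                matrix(stats::rnorm(nat * 3, sd = distortion), ncol = 3)
    })
    .newEnsemble(base@atoms, xyz)
}

#' Simulate 15N relaxation records from model-free ground truth
#'
#' Computes R1/R2/NOE from the per-residue true motional parameters via
#' [predictRates()] and adds Gaussian noise: relative SD `noiseFraction`
#' on the rates, and `noiseFraction * sqrt(1 + NOE^2)` absolute SD on the
#' NOE (error propagation for a ratio of two intensities with fractional
#' noise). Reported errors are the true noise SDs. Optionally also emits
#' raw decay series at the standard T1/T2 delay lists plus a
#' saturated/reference intensity pair per residue.
#'
#' @param truth data.frame with columns `resSeq`, `model`, `S2`, `tauE`
#'   (ps), `rex` (s^-1), `S2f`; ground-truth motional parameters
#' @param tauM overall correlation time, ns
#' @param cfg a [fieldConfig()]
#' @param noiseFraction relative noise SD (> 0; use something tiny like
#'   1e-12 for effectively noiseless data)
#' @param seed RNG seed
#' @param decaySeries also generate per-residue T1/T2 decay series and NOE
#'   intensity pairs consistent with the noisy rates
#' @param t1Delays,t2Delays delay lists, seconds
#' @return data.frame of relaxation records (`resSeq`, `R1`, `R1err`,
#'   `R2`, `R2err`, `NOE`, `NOEerr`), with the truth attached as attribute
#'   `truth` and, if requested, attribute `decays` (named list per residue
#'   with elements `t1`, `t2`, `noe`).
#' @export
simulateRelaxation <- function(truth, tauM = 5.67, cfg = fieldConfig(),
                               noiseFraction = 0.02, seed = 1,
                               decaySeries = FALSE,
                               t1Delays = c(0.1, 1, 2, 4),
                               t2Delays = c(17, 34, 68, 102, 136, 237) / 1000) {
    stopifnot(is.data.frame(truth), noiseFraction > 0,
              all(c("resSeq", "model", "S2", "tauE", "rex", "S2f") %in%
                  names(truth)))
    k <- .rateConstants(cfg)
    pred <- t(vapply(seq_len(nrow(truth)), function(i)
        .ratesCore(k, truth$S2[i], truth$tauE[i], truth$rex[i],
                   truth$S2f[i], tauM), numeric(3)))
    n <- nrow(truth)
    sdR1 <- noiseFraction * pred[, 1]
    sdR2 <- noiseFraction * pred[, 2]
    sdNOE <- noiseFraction * sqrt(1 + pred[, 3]^2)
    out <- .withSeed(seed, {
        rec <- data.frame(resSeq = truth$resSeq,
                          R1 = stats::rnorm(n, pred[, 1], sdR1),
                          R1err = sdR1,
                          R2 = stats::rnorm(n, pred[, 2], sdR2),
                          R2err = sdR2,
                          NOE = stats::rnorm(n, pred[, 3], sdNOE),
                          NOEerr = sdNOE)
        if (decaySeries) {
            decays <- lapply(seq_len(n), function(i) {
                I0 <- 100
                i1 <- I0 * exp(-rec$R1[i] * t1Delays)
                i2 <- I0 * exp(-rec$R2[i] * t2Delays)
                list(t1 = data.frame(delay = t1Delays,
                         intensity = i1 * (1 + stats::rnorm(length(i1),
                                                            0, noiseFraction))),
                     t2 = data.frame(delay = t2Delays,
                         intensity = i2 * (1 + stats::rnorm(length(i2),
                                                            0, noiseFraction))),
                     noe = c(iSat = I0 * rec$NOE[i], iRef = I0))
            })
            names(decays) <- truth$resSeq
            attr(rec, "decays") <- decays
        }
        rec
    })
    attr(out, "truth") <- truth
    attr(out, "tauM") <- tauM
    out
}

#' Default model-free ground truth for a two-zinc-cluster domain
#'
#' Per-residue motional parameters for a 56-residue construct numbered
#' 167-222: flexible termini (167-174, 218-222) and loop (197-207) with
#' low order parameters, slow internal motion and a two-timescale
#' (extended) character, hence heteronuclear NOE below 0.6; rigid
#' zinc-binding segments (175-196, 208-217) with high order parameters and
#' fast internal motion, chemical exchange around the first cluster, and
#' slightly reduced order parameters at the second cysteine of each
#' cluster. The proline at 199 has no amide and is omitted.
#'
#' @param tauM overall correlation time, ns (recorded as an attribute by
#'   [simulateRelaxation()])
#' @return data.frame with `resSeq`, `model`, `S2`, `tauE`, `rex`, `S2f`
#'   and a `segment` label
#' @export
defaultRelaxationTruth <- function(tauM = 5.67) {
    res <- setdiff(167:222, 199L)
    seg <- ifelse(res <= 174 | res >= 218, "terminus",
           ifelse(res >= 197 & res <= 207, "loop", "core"))
    df <- do.call(rbind, lapply(seq_along(res), function(i) {
        r <- res[i]
        if (seg[i] == "terminus") {
            dist <- if (r <= 174) 174 - r else r - 218
            data.frame(resSeq = r, model = 5L,
                       S2 = max(0.15, 0.55 - 0.07 * dist),
                       tauE = 900 + 40 * (r %% 5), rex = 0,
                       S2f = 0.75)
        } else if (seg[i] == "loop") {
            data.frame(resSeq = r, model = 5L,
                       S2 = 0.42 + 0.01 * (r %% 4),
                       tauE = 1200 + 50 * (r %% 3), rex = 0, S2f = 0.72)
        } else if (r >= 176 && r <= 185) {
            data.frame(resSeq = r, model = 4L,
                       S2 = if (r == 179L) 0.684 else 0.80 + 0.005 * (r %% 4),
                       tauE = 35 + 5 * (r %% 3), rex = 2.5 + 0.3 * (r %% 4),
                       S2f = 1)
        } else if (r == 191L) {
            data.frame(resSeq = r, model = 2L, S2 = 0.679, tauE = 40,
                       rex = 0, S2f = 1)
        } else if (r == 212L) {
            data.frame(resSeq = r, model = 1L, S2 = 0.85, tauE = 0,
                       rex = 0, S2f = 1)
        } else {
            data.frame(resSeq = r, model = 2L,
                       S2 = 0.84 + 0.004 * (r %% 5), tauE = 25 + 4 * (r %% 4),
                       rex = 0, S2f = 1)
        }
    }))
    df$segment <- seg
    attr(df, "tauM") <- tauM
    df
}

#' Rigid-core / flexible-tail model-free ground truth
#'
#' A simpler truth profile for correlation-time recovery studies: a rigid
#' core of residues with high order parameters and fast, small-amplitude
#' internal motion (models 1/2, no exchange), followed by a flexible tail
#' with low order parameters and nanosecond two-timescale motion whose
#' true heteronuclear NOE falls below 0.6, so the tail is removed by the
#' NOE filter and the surviving core reports the tumbling time.
#'
#' @param nRes total number of residues (numbered from 1)
#' @param nTail number of flexible tail residues at the C-terminus
#' @param tauM overall correlation time, ns
#' @return data.frame as in [defaultRelaxationTruth()]
#' @export
coreTailTruth <- function(nRes = 40, nTail = 8, tauM = 5.67) {
    stopifnot(nRes >= nTail + 3)
    res <- seq_len(nRes)
    tail <- res > nRes - nTail
    df <- do.call(rbind, lapply(res, function(r) {
        if (r > nRes - nTail) {
            pos <- r - (nRes - nTail)
            data.frame(resSeq = r, model = 5L,
                       S2 = max(0.12, 0.45 - 0.045 * pos),
                       tauE = 1000 + 30 * (r %% 4), rex = 0, S2f = 0.75)
        } else if (r %% 7 == 0) {
            data.frame(resSeq = r, model = 1L, S2 = 0.85, tauE = 0,
                       rex = 0, S2f = 1)
        } else {
            data.frame(resSeq = r, model = 2L,
                       S2 = 0.83 + 0.005 * (r %% 5),
                       tauE = 20 + 4 * (r %% 5), rex = 0, S2f = 1)
        }
    }))
    df$segment <- ifelse(tail, "tail", "core")
    attr(df, "tauM") <- tauM
    df
}

#' Synthetic deposit-scale structure ensemble
#'
#' A 20-conformer synthetic stand-in for a two-zinc-cluster domain NMR
#' deposit: 56 residues numbered 167-222 with cysteines at 176, 179, 182,
#' 188, 191, 194, 210 and 215 and a proline at 199; rigid segments
#' 175-196 and 208-217 built as helix, flexible termini and loop built as
#' coil. The displacement profile (0.44 Angstrom backbone SD in the rigid
#' segments, ~2 Angstrom in the loop and termini, side chains 2.2x) is
#' chosen so the well-defined region shows a backbone ensemble spread of
#' about 0.75 Angstrom, the precision typical of a well-restrained NMR
#' ensemble of this size. This object is entirely synthetic: it emulates
#' the statistical structure of a real deposit but none of its actual
#' coordinates.
#'
#' @param seed RNG seed
#' @param nModels number of conformers
#' @return an [NMREnsemble-class] with a `segments` attribute
#' @export
syntheticDeposit <- function(seed = 1, nModels = 20) {
    seqs <- rep("ALA", 56)
    names(seqs) <- 167:222
    seqs[as.character(c(176, 179, 182, 188, 191, 194, 210, 215))] <- "CYS"
    seqs["199"] <- "PRO"
    seqs["204"] <- "GLY"
    tmpl <- makeTemplate(56, motif = "mixed", sequence = unname(seqs),
                         startRes = 167L, seed = seed)
    segs <- attr(tmpl, "segments")
    sig <- rep(2.5, 56)
    names(sig) <- 167:222
    for (rg in segs$rigid) sig[as.character(rg[1]:rg[2])] <- 0.44
    sig[as.character(197:207)] <- 2.0
    perturbEnsemble(tmpl, nModels = nModels, sigmaProfile = sig,
                    smoothWindow = 3, sideChainFactor = 2.2,
                    seed = seed + 1)
}
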