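## Rotational correlation time from the R2/R1 ratio.
##
## For a rigid residue (S2 = 1, tau_e = 0, Rex = 0) on an isotropic tumbler
## the R2/R1 ratio is a monotone function of the tumbling time, so a
## per-residue apparent tau_c can be read off by root finding. Aggregation
## to a molecular tau_m follows a two-step filter: residues with NOE < 0.6
## (fast internal motion) are removed first, then residues whose R2/R1
## ratio lies more than one standard deviation from the mean of the
## survivors (exchange or anisotropy) are removed, and tau_m is the
## arithmetic mean of the remaining per-residue tau_c values.

.rigidRatio <- function(taucNs, k) {
    r <- .ratesCore(k, 1, 0, 0, 1, taucNs)
    r[["R2"]] / r[["R1"]]
}

#' Apparent rotational correlation time from R2/R1
#'
#' Numerically inverts the rigid-residue R2/R1 ratio curve (Brent root
#' finding on a bracket, default 0.5-50 ns, covering peptides to large
#' domains). A ratio below the minimum achievable within the bracket (or
#' above its maximum) is an error naming the residue if given.
#'
#' @param R1,R2 longitudinal and transverse relaxation rates, s^-1
#' @param cfg a [fieldConfig()]
#' @param bracket search interval for tau_c, ns
#' @param resSeq optional residue number used in error messages
#' @return tau_c in ns
#' @examples
#' cfg <- fieldConfig(600.13)
#' r <- predictRates(motionalParams(1, S2 = 1, tauM = 5.67), cfg)
#' taucFromRatio(r["R1"], r["R2"], cfg)   # 5.67
#' @export
taucFromRatio <- function(R1, R2, cfg = fieldConfig(), bracket = c(0.5, 50),
                          resSeq = NULL) {
    stopifnot(R1 > 0, R2 > 0)
    ratio <- R2 / R1
    who <- if (is.null(resSeq)) "" else paste0(" (residue ", resSeq, ")")
    if (ratio < 1)
        stop("R2/R1 = ", signif(ratio, 4), " < 1 is infeasible for a rigid ",
             "isotropic tumbler", who)
    k <- .rateConstants(cfg)
    lo <- .rigidRatio(bracket[1], k)
    hi <- .rigidRatio(bracket[2], k)
    if (ratio < lo || ratio > hi)
        stop("R2/R1 = ", signif(ratio, 4), " has no solution in [",
             bracket[1], ", ", bracket[2], "] ns", who)
    stats::uniroot(function(tc) .rigidRatio(tc, k) - ratio,
                   interval = bracket, tol = 1e-10)$root
}

#' Filter relaxation records before tau_m estimation
#'
#' Single pass, order-independent: step 1 removes residues with NOE < 0.6;
#' step 2 computes the mean and standard deviation of R2/R1 over the
#' survivors of step 1 and removes residues with `|ratio - mean| > 1 SD`
#' (strict, so an all-identical set loses nothing). Records with missing
#' rates are excluded with reason `missing`.
#'
#' @param records data.frame with columns `resSeq`, `R1`, `R2`, `NOE`
#'   (errors optional); >= 3 rows.
#' @param noeCutoff NOE threshold (default 0.6)
#' @param sdMultiple ratio-outlier cut in standard deviations (default 1)
#' @param iterate if `TRUE`, repeat the SD trim until no residue is removed
#'   (sensitivity analysis; default `FALSE`, the single-pass reading).
#' @return list with `kept` (resSeq vector), `excluded` (data.frame
#'   `resSeq`, `reason` in `low_NOE`, `ratio_outlier`, `missing`), and
#'   `ratio` (named per-residue R2/R1 of the input).
#' @export
filterRelaxation <- function(records, noeCutoff = 0.6, sdMultiple = 1,
                             iterate = FALSE) {
    stopifnot(is.data.frame(records), nrow(records) >= 3L,
              all(c("resSeq", "R1", "R2", "NOE") %in% names(records)))
    ratio <- records$R2 / records$R1
    names(ratio) <- records$resSeq
    miss <- !is.finite(records$R1) | !is.finite(records$R2) |
        !is.finite(records$NOE)
    lowNoe <- !miss & records$NOE < noeCutoff
    surv <- !miss & !lowNoe
    if (sum(surv) < 2L)
        stop("fewer than 2 residues survive the NOE filter")
    out <- rep(FALSE, nrow(records))
    repeat {
        mu <- mean(ratio[surv & !out])
        sdv <- stats::sd(ratio[surv & !out])
        newOut <- surv & !out & abs(ratio - mu) > sdMultiple * sdv
        newOut[is.na(newOut)] <- FALSE
        if (!any(newOut) || !iterate) { out <- out | newOut; break }
        out <- out | newOut
    }
    kept <- records$resSeq[surv & !out]
    if (length(kept) < 1L)
        stop("no residues survive filtering")
    reas <- function(mask, why)
        data.frame(resSeq = records$resSeq[mask],
                   reason = rep_len(why, sum(mask)))
    excluded <- rbind(reas(miss, "missing"), reas(lowNoe, "low_NOE"),
                      reas(out, "ratio_outlier"))
    list(kept = kept, excluded = excluded, ratio = ratio)
}

#' Estimate the molecular rotational correlation time
#'
#' Applies [filterRelaxation()], inverts R2/R1 per kept residue with
#' [taucFromRatio()], and reports the arithmetic mean as tau_m. The spread
#' is reported both as the standard deviation over residues and as the
#' standard error of the mean, since "plus/minus" conventions differ.
#'
#' @inheritParams filterRelaxation
#' @param cfg a [fieldConfig()]
#' @param bracket tau_c search interval, ns
#' @return object of class `TaucResult`: list with `tauM` (ns), `sd`,
#'   `sem`, `perResidue` (data.frame `resSeq`, `ratio`, `tauc`, `status`),
#'   and `excluded`.
#' @export
estimateTauM <- function(records, cfg = fieldConfig(), noeCutoff = 0.6,
                         sdMultiple = 1, iterate = FALSE,
                         bracket = c(0.5, 50)) {
    f <- filterRelaxation(records, noeCutoff = noeCutoff,
                          sdMultiple = sdMultiple, iterate = iterate)
    keptRows <- records[records$resSeq %in% f$kept, , drop = FALSE]
    tauc <- vapply(seq_len(nrow(keptRows)), function(i)
        taucFromRatio(keptRows$R1[i], keptRows$R2[i], cfg, bracket,
                      resSeq = keptRows$resSeq[i]), numeric(1))
    status <- rep("kept", nrow(records))
    names(status) <- records$resSeq
    status[as.character(f$excluded$resSeq)] <- f$excluded$reason
    perRes <- data.frame(resSeq = records$resSeq,
                         ratio = as.numeric(f$ratio),
                         tauc = NA_real_,
                         status = as.character(status))
    perRes$tauc[match(keptRows$resSeq, perRes$resSeq)] <- tauc
    structure(list(tauM = mean(tauc),
                   sd = if (length(tauc) > 1) stats::sd(tauc) else 0,
                   sem = if (length(tauc) > 1)
                       stats::sd(tauc) / sqrt(length(tauc)) else 0,
                   nKept = length(tauc),
                   perResidue = perRes,
                   excluded = f$excluded),
              class = "TaucResult")
}

#' @export
print.TaucResult <- function(x, ...) {
    cat(sprintf("TaucResult: tau_m = %.3f ns (SD %.3f, SEM %.3f) from %d residues\n",
                x$tauM, x$sd, x$sem, x$nKept))
    if (nrow(x$excluded) > 0) {
        tab <- table(x$excluded$reason)
        cat("  excluded:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    invisible(x)
}
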