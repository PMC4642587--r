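## Lipari-Szabo model-free analysis of 15N backbone relaxation.
##
## The spectral density is the standard two-term (simple) or three-parameter
## extended form for an isotropic tumbler; relaxation rates follow the usual
## dipolar + CSA expressions for an amide 15N spin relaxed by its attached
## proton. Motional models 1-5 fix subsets of (S2, tau_e, Rex, Sf2):
##   1: S2                     2: S2, tau_e          3: S2, Rex
##   4: S2, tau_e, Rex         5: S2, tau_e, Sf2 (Rex = 0)

.MU0 <- 4e-7 * pi
.HBAR <- 1.054571817e-34

#' Spectrometer and spin-pair configuration
#'
#' Physical constants entering the 15N relaxation expressions. The N-H bond
#' length and 15N CSA are not universal constants and common model-free
#' practice varies slightly; both are overridable.
#'
#' @param protonFrequencyMHz 1H Larmor frequency in MHz (e.g. 600.13).
#' @param rNH N-H bond length, Angstrom (default 1.02).
#' @param csa 15N chemical-shift anisotropy, ppm (default -160).
#' @param gammaH,gammaN gyromagnetic ratios, rad s^-1 T^-1 (15N negative).
#' @return object of class `FieldConfig`
#' @export
fieldConfig <- function(protonFrequencyMHz = 600.13, rNH = 1.02, csa = -160,
                        gammaH = 2.6752218744e8, gammaN = -2.71261804e7) {
    stopifnot(protonFrequencyMHz > 0, rNH >= 0.9, rNH <= 1.1)
    structure(list(protonFrequencyMHz = protonFrequencyMHz, rNH = rNH,
                   csa = csa, gammaH = gammaH, gammaN = gammaN),
              class = "FieldConfig")
}

## Precomputed interaction constants: d2q = d^2/4 with
## d = (mu0/4pi) hbar gammaH gammaN <rNH^-3>, and c2 = (wN * csa)^2 / 3.
.rateConstants <- function(cfg) {
    wH <- 2 * pi * cfg$protonFrequencyMHz * 1e6
    wN <- abs(cfg$gammaN) / cfg$gammaH * wH
    d <- (.MU0 / (4 * pi)) * .HBAR * cfg$gammaH * abs(cfg$gammaN) /
        (cfg$rNH * 1e-10)^3
    list(wH = wH, wN = wN,
         d2q = d^2 / 4,
         c2 = (wN * cfg$csa * 1e-6)^2 / 3,
         gRatio = cfg$gammaH / cfg$gammaN)
}

#' Motional parameters of one residue
#'
#' @param model motional model id in 1..5; fixes the free-parameter subset
#'   (see the module header in the source or the vignette).
#' @param S2 generalised order parameter in `[0, 1]`.
#' @param tauE internal correlation time, picoseconds (>= 0).
#' @param rex chemical exchange contribution to R2, s^-1 (>= 0).
#' @param S2f fast-motion order parameter in `[0, 1]` (extended model);
#'   must satisfy `S2 <= S2f`.
#' @param tauM overall rotational correlation time, nanoseconds.
#' @return object of class `MotionalParams`
#' @export
motionalParams <- function(model, S2, tauE = 0, rex = 0, S2f = 1, tauM) {
    stopifnot(model %in% 1:5, S2 >= 0, S2 <= 1, tauE >= 0, rex >= 0,
              S2f >= 0, S2f <= 1, tauM > 0)
    if (model == 1L && (tauE != 0 || rex != 0 || S2f != 1))
        stop("model 1 fixes tauE = 0, rex = 0, S2f = 1")
    if (model == 2L && (rex != 0 || S2f != 1))
        stop("model 2 fixes rex = 0, S2f = 1")
    if (model == 3L && (tauE != 0 || S2f != 1))
        stop("model 3 fixes tauE = 0, S2f = 1")
    if (model == 4L && S2f != 1)
        stop("model 4 fixes S2f = 1")
    if (model == 5L && rex != 0)
        stop("model 5 fixes rex = 0")
    if (S2 > S2f + 1e-12)
        stop("S2 must not exceed S2f")
    structure(list(model = as.integer(model), S2 = S2, tauE = tauE,
                   rex = rex, S2f = S2f, tauM = tauM),
              class = "MotionalParams")
}

## Core spectral density, SI units (omega rad/s, taus in seconds):
## J(w) = 2/5 [ S2 tm/(1+(w tm)^2) + (Sf2 - S2) t'/(1+(w t')^2) ]
## with 1/t' = 1/tm + 1/te; the simple form is Sf2 = 1.
.J <- function(omega, S2, tauE_s, S2f, tauM_s) {
    tp <- if (tauE_s > 0) tauM_s * tauE_s / (tauM_s + tauE_s) else 0
    0.4 * (S2 * tauM_s / (1 + (omega * tauM_s)^2) +
           (S2f - S2) * tp / (1 + (omega * tp)^2))
}

#' Model-free spectral density
#'
#' @param p a [motionalParams()] object
#' @param omega angular frequency (rad/s), may be a vector
#' @return spectral density J(omega) in s/rad
#' @examples
#' p <- motionalParams(1, S2 = 1, tauM = 5.67)
#' spectralDensity(p, 0)       # 2/5 * tauM
#' @export
spectralDensity <- function(p, omega) {
    stopifnot(inherits(p, "MotionalParams"))
    .J(omega, p$S2, p$tauE * 1e-12, p$S2f, p$tauM * 1e-9)
}

.ratesCore <- function(k, S2, tauE_ps, rex, S2f, tauM_ns) {
    te <- tauE_ps * 1e-12; tm <- tauM_ns * 1e-9
    JhmN <- .J(k$wH - k$wN, S2, te, S2f, tm)
    JN   <- .J(k$wN, S2, te, S2f, tm)
    JhpN <- .J(k$wH + k$wN, S2, te, S2f, tm)
    Jh   <- .J(k$wH, S2, te, S2f, tm)
    J0   <- .J(0, S2, te, S2f, tm)
    R1 <- k$d2q * (JhmN + 3 * JN + 6 * JhpN) + k$c2 * JN
    R2 <- k$d2q / 2 * (4 * J0 + JhmN + 3 * JN + 6 * Jh + 6 * JhpN) +
        k$c2 / 6 * (4 * J0 + 3 * JN) + rex
    NOE <- 1 + k$d2q * k$gRatio * (6 * JhpN - JhmN) / R1
    c(R1 = R1, R2 = R2, NOE = NOE)
}

#' Predict 15N relaxation observables from motional parameters
#'
#' Standard dipolar + CSA expressions; the chemical-exchange term enters R2
#' only. The heteronuclear NOE uses the signed gyromagnetic ratio, so
#' flexible residues naturally acquire low or negative NOEs.
#'
#' @param p a [motionalParams()] object
#' @param cfg a [fieldConfig()]
#' @return named numeric vector `c(R1, R2, NOE)` (rates in s^-1)
#' @examples
#' cfg <- fieldConfig(600.13)
#' predictRates(motionalParams(1, S2 = 1, tauM = 5.67), cfg)
#' @export
predictRates <- function(p, cfg = fieldConfig()) {
    stopifnot(inherits(p, "MotionalParams"), inherits(cfg, "FieldConfig"))
    .ratesCore(.rateConstants(cfg), p$S2, p$tauE, p$rex, p$S2f, p$tauM)
}

#' Fit a mono-exponential intensity decay
#'
#' Weighted least-squares fit of `I(t) = I0 exp(-R t)` to a peak-intensity
#' decay series (T1/T2 experiments). Starting values come from a log-linear
#' regression; the parameter standard errors from the fit covariance.
#' Non-decaying data (fitted `R <= 0` or a failed fit) is flagged rather
#' than silently returned.
#'
#' @param delays relaxation delays, seconds (>= 3 distinct values)
#' @param intensities peak intensities, arbitrary units
#' @param sigma optional intensity noise (scalar or per-point); used as
#'   weights `1/sigma^2`.
#' @return list with `rate` (s^-1), `se`, `I0`, `flagged` (logical) and
#'   `fit` (the `nls` object or `NULL`)
#' @examples
#' fitDecay(c(0.1, 1, 2, 4), 100 * exp(-10 * c(0.1, 1, 2, 4)) )$rate
#' @export
fitDecay <- function(delays, intensities, sigma = NULL) {
    t <- as.numeric(delays); I <- as.numeric(intensities)
    stopifnot(length(t) == length(I), all(is.finite(t)), all(is.finite(I)))
    if (length(unique(t)) < 3L) stop("need at least 3 distinct delays")
    w <- if (is.null(sigma)) rep(1, length(t)) else 1 / rep(sigma, length.out = length(t))^2
    pos <- I > 0
    R0 <- if (sum(pos) >= 2) {
        sl <- stats::coef(stats::lm(log(I[pos]) ~ t[pos]))[2]
        max(-sl, 1e-6)
    } else 1
    I00 <- max(abs(I))
    ## convergence trouble is communicated through `flagged`, not warnings
    fit <- tryCatch(
        suppressWarnings(
            stats::nls(I ~ I0 * exp(-R * t),
                       start = list(I0 = I00, R = R0), weights = w,
                       control = stats::nls.control(maxiter = 200,
                                                    warnOnly = TRUE))),
        error = function(e) NULL)
    co <- if (!is.null(fit))
        tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (is.null(co)) {
        return(list(rate = NA_real_, se = NA_real_, I0 = NA_real_,
                    flagged = TRUE, fit = fit))
    }
    rate <- co["R", "Estimate"]
    list(rate = rate, se = co["R", "Std. Error"], I0 = co["I0", "Estimate"],
         flagged = !is.finite(rate) || rate <= 0, fit = fit)
}

#' Heteronuclear NOE from a saturation/reference intensity pair
#'
#' @param iSat peak intensity with proton saturation
#' @param iRef reference intensity (without saturation); must be non-zero
#' @return NOE = iSat / iRef (negative values pass through: mobile termini)
#' @export
noeRatio <- function(iSat, iRef) {
    if (any(iRef == 0)) stop("reference intensity is zero")
    iSat / iRef
}

## ---- chi-square fitting -------------------------------------------------

.mfModelInfo <- function(model, tauM, rexMax) {
    tauEMax <- tauM * 1e3                      # tau_e bounded by tau_m (ps)
    s2Starts <- c(0.2, 0.45, 0.7, 0.95)
    teStarts <- pmin(c(1, 20, 200, 1500), 0.8 * tauEMax)
    rxStarts <- pmin(c(0, 3, 10, 25), 0.9 * rexMax)
    switch(as.character(model),
        "1" = list(names = "S2", lower = 0, upper = 1,
                   starts = matrix(s2Starts, ncol = 1)),
        "2" = list(names = c("S2", "tauE"), lower = c(0, 0),
                   upper = c(1, tauEMax),
                   starts = as.matrix(expand.grid(s2Starts, teStarts))),
        "3" = list(names = c("S2", "rex"), lower = c(0, 0),
                   upper = c(1, rexMax),
                   starts = as.matrix(expand.grid(s2Starts, rxStarts))),
        "4" = list(names = c("S2", "tauE", "rex"), lower = c(0, 0, 0),
                   upper = c(1, tauEMax, rexMax),
                   starts = as.matrix(expand.grid(s2Starts, teStarts, rxStarts))),
        "5" = list(names = c("S2f", "sRatio", "tauE"), lower = c(0, 0, 0),
                   upper = c(1, 1, tauEMax),
                   starts = as.matrix(expand.grid(s2Starts, s2Starts, teStarts))))
}

.mfExpand <- function(model, par) {
    switch(as.character(model),
        "1" = list(S2 = par[1], tauE = 0, rex = 0, S2f = 1),
        "2" = list(S2 = par[1], tauE = par[2], rex = 0, S2f = 1),
        "3" = list(S2 = par[1], tauE = 0, rex = par[2], S2f = 1),
        "4" = list(S2 = par[1], tauE = par[2], rex = par[3], S2f = 1),
        "5" = list(S2 = par[1] * par[2], tauE = par[3], rex = 0,
                   S2f = par[1]))
}

.recVectors <- function(rec) {
    obs <- c(rec$R1, rec$R2, rec$NOE)
    err <- c(rec$R1err, rec$R2err, rec$NOEerr)
    stopifnot(length(obs) == 3L, all(is.finite(obs)),
              all(is.finite(err)), all(err > 0), obs[1] > 0, obs[2] > 0)
    list(obs = obs, err = err)
}

#' Fit one motional model to a relaxation record
#'
#' Minimises `chi2 = sum(((obs - pred)/err)^2)` over the model's free
#' parameters within physical bounds (order parameters in `[0, 1]`,
#' `tau_e` in `[0, tau_m]`, `Rex` in `[0, rexMax]`), with a deterministic
#' multi-start grid (4 points per free parameter) to avoid local minima.
#' The overall correlation time is held fixed (estimate it first with
#' [estimateTauM()]).
#'
#' @param rec one relaxation record: list/one-row data.frame with `R1`,
#'   `R2`, `NOE` and errors `R1err`, `R2err`, `NOEerr` (and optionally
#'   `resSeq`).
#' @param model motional model id, 1..5
#' @param tauM overall correlation time, ns (fixed)
#' @param cfg a [fieldConfig()]
#' @param rexMax upper bound on Rex, s^-1
#' @return object of class `ModelFreeResult`: list with `model`, `params`
#'   (a [motionalParams()] object), `chi2`, `dof` and `free` (named free
#'   parameter vector). `dof = 0` (models 4/5) is allowed and flagged by
#'   `exactlyDetermined = TRUE`.
#' @export
fitModelFree <- function(rec, model, tauM, cfg = fieldConfig(), rexMax = 50) {
    stopifnot(model %in% 1:5, tauM > 0)
    rv <- .recVectors(rec)
    k <- .rateConstants(cfg)
    info <- .mfModelInfo(model, tauM, rexMax)
    obj <- function(par) {
        p <- .mfExpand(model, par)
        pred <- .ratesCore(k, p$S2, p$tauE, p$rex, p$S2f, tauM)
        v <- sum(((rv$obs - pred) / rv$err)^2)
        if (!is.finite(v)) 1e12 else v   # S2 = Sf2 = 0 leaves R1 = 0, NOE undefined
    }
    starts <- t(apply(info$starts, 1, function(s)
        pmin(pmax(s, info$lower), info$upper)))
    if (ncol(starts) != length(info$lower)) starts <- t(starts)
    ## score the full deterministic grid, polish only the most promising starts
    startVals <- apply(starts, 1, obj)
    polish <- utils::head(order(startVals), 4L)
    best <- NULL
    for (i in polish) {
        fit <- stats::nlminb(starts[i, ], obj,
                             lower = info$lower, upper = info$upper)
        if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    par <- stats::setNames(best$par, info$names)
    p <- .mfExpand(model, best$par)
    dof <- 3L - length(par)
    structure(list(model = as.integer(model),
                   params = motionalParams(model, S2 = min(p$S2, p$S2f),
                                           tauE = p$tauE, rex = p$rex,
                                           S2f = p$S2f, tauM = tauM),
                   free = par,
                   chi2 = best$objective,
                   dof = dof,
                   exactlyDetermined = dof == 0L),
              class = "ModelFreeResult")
}

#' @export
print.ModelFreeResult <- function(x, ...) {
    if (is.null(x$params)) {
        cat("ModelFreeResult: no acceptable model\n")
    } else {
        p <- x$params
        cat(sprintf("ModelFreeResult: model %d | S2=%.3f tauE=%.1f ps Rex=%.2f /s Sf2=%.3f\n",
                    x$model, p$S2, p$tauE, p$rex, p$S2f))
        cat(sprintf("  chi2 = %.4g on %d dof\n", x$chi2, x$dof))
    }
    if (!is.null(x$trace)) {
        cat("  selection trace:\n")
        print(x$trace, row.names = FALSE)
    }
    invisible(x)
}

.gofCritical <- function(fit, rv, k, tauM, model, rexMax, alphaGof,
                         gof, mcDraws, seed, cfg) {
    if (fit$dof <= 0L) return(NA_real_)
    if (gof == "chisq") return(stats::qchisq(1 - alphaGof, fit$dof))
    ## Monte-Carlo null: simulate from the fitted parameters with the
    ## record's errors, refit, take the (1 - alpha) quantile of chi2.
    p <- fit$params
    pred <- .ratesCore(k, p$S2, p$tauE, p$rex, p$S2f, tauM)
    rng <- .withSeed(seed, {
        matrix(stats::rnorm(3L * mcDraws, mean = rep(pred, mcDraws),
                            sd = rep(rv$err, mcDraws)), nrow = 3L)
    })
    null <- vapply(seq_len(mcDraws), function(i) {
        recI <- list(R1 = rng[1, i], R2 = rng[2, i], NOE = rng[3, i],
                     R1err = rv$err[1], R2err = rv$err[2], NOEerr = rv$err[3])
        tryCatch(fitModelFree(recI, model, tauM, cfg, rexMax)$chi2,
                 error = function(e) NA_real_)
    }, numeric(1))
    stats::quantile(null, 1 - alphaGof, na.rm = TRUE, names = FALSE)
}

#' Select a motional model for one residue
#'
#' Mandel-style model selection at a single field: models are fitted in
#' order of increasing complexity; the simplest testable model (1, then
#' 2/3) is accepted when its chi2 passes a goodness-of-fit test at
#' `alphaGof` and, for models 2/3, when the F-test against model 1 shows a
#' significant improvement at `alphaF`. The exactly-determined models 4/5
#' (0 degrees of freedom) are accepted only when they fit essentially
#' perfectly (`chi2 < dof0Crit`). If nothing passes, `params` is `NULL`
#' ("not fitted to any model"). The goodness-of-fit critical value is
#' either the analytic chi-square quantile (default) or a seeded
#' Monte-Carlo null distribution (`gof = "mc"`).
#'
#' @inheritParams fitModelFree
#' @param alphaGof goodness-of-fit significance level (default 0.05)
#' @param alphaF F-test significance level for nested improvement (0.20)
#' @param gof `"chisq"` (analytic, default) or `"mc"` (Monte-Carlo null)
#' @param mcDraws draws for the Monte-Carlo null (default 500)
#' @param seed seed for the Monte-Carlo null
#' @param dof0Crit acceptance threshold on chi2 for 0-dof models
#' @return a `ModelFreeResult` with a `trace` data.frame recording every
#'   model's chi2, dof, critical value and decision; `params` is `NULL`
#'   when no model is acceptable.
#' @export
selectModelFree <- function(rec, tauM, cfg = fieldConfig(), alphaGof = 0.05,
                            alphaF = 0.20, gof = c("chisq", "mc"),
                            mcDraws = 500, seed = 1,
                            dof0Crit = stats::qchisq(0.95, 1), rexMax = 50) {
    gof <- match.arg(gof)
    rv <- .recVectors(rec)
    k <- .rateConstants(cfg)
    fits <- lapply(1:5, function(m)
        fitModelFree(rec, m, tauM, cfg, rexMax))
    crit <- vapply(fits, function(f)
        if (f$dof > 0L)
            .gofCritical(f, rv, k, tauM, f$model, rexMax, alphaGof, gof,
                         mcDraws, seed, cfg)
        else dof0Crit, numeric(1))
    gofPass <- vapply(seq_along(fits), function(i)
        fits[[i]]$chi2 < crit[i], logical(1))
    ## F-test of models 2/3 against model 1
    fPass <- c(NA, vapply(2:3, function(m) {
        f <- fits[[m]]
        if (f$chi2 >= fits[[1]]$chi2) return(FALSE)
        if (f$chi2 <= 0) return(TRUE)
        Fst <- ((fits[[1]]$chi2 - f$chi2) / 1) / (f$chi2 / f$dof)
        stats::pf(Fst, 1, f$dof, lower.tail = FALSE) < alphaF
    }, logical(1)), NA, NA)
    chosen <- if (gofPass[1]) {
        1L
    } else {
        cand23 <- c(2L, 3L)[gofPass[2:3] & fPass[2:3]]
        if (length(cand23) > 0) {
            cand23[order(vapply(cand23, function(m) fits[[m]]$chi2,
                                numeric(1)), cand23)][1]
        } else {
            cand45 <- c(4L, 5L)[gofPass[4:5]]
            if (length(cand45) > 0) {
                cand45[order(vapply(cand45, function(m) fits[[m]]$chi2,
                                    numeric(1)), cand45)][1]
            } else NA_integer_
        }
    }
    trace <- data.frame(model = 1:5,
                        chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
                        dof = vapply(fits, `[[`, integer(1), "dof"),
                        critical = crit,
                        gofPass = gofPass,
                        fPass = fPass,
                        selected = !is.na(chosen) & 1:5 == chosen)
    out <- if (is.na(chosen)) {
        structure(list(model = NA_integer_, params = NULL, free = NULL,
                       chi2 = NA_real_, dof = NA_integer_),
                  class = "ModelFreeResult")
    } else fits[[chosen]]
    out$trace <- trace
    out
}

#' Monte-Carlo parameter errors for a model-free fit
#'
#' Refits the selected model on `nDraws` noise-perturbed synthetic datasets
#' (observables drawn about the fitted back-prediction with the record's
#' errors) and reports the standard deviation of each refitted free
#' parameter. Deterministic for a fixed seed.
#'
#' @param result a fitted `ModelFreeResult` (with non-`NULL` params)
#' @inheritParams fitModelFree
#' @param nDraws number of Monte-Carlo draws (a warning below 50)
#' @param seed RNG seed
#' @return named numeric vector of standard errors (free parameters)
#' @export
mcErrors <- function(result, rec, tauM, cfg = fieldConfig(), nDraws = 200,
                     seed = 1, rexMax = 50) {
    stopifnot(inherits(result, "ModelFreeResult"))
    if (is.null(result$params)) stop("result has no fitted parameters")
    if (nDraws < 50) warning("fewer than 50 Monte-Carlo draws: errors unstable")
    rv <- .recVectors(rec)
    k <- .rateConstants(cfg)
    p <- result$params
    pred <- .ratesCore(k, p$S2, p$tauE, p$rex, p$S2f, tauM)
    draws <- .withSeed(seed, {
        matrix(stats::rnorm(3L * nDraws, mean = rep(pred, nDraws),
                            sd = rep(rv$err, nDraws)), nrow = 3L)
    })
    refits <- vapply(seq_len(nDraws), function(i) {
        recI <- list(R1 = draws[1, i], R2 = draws[2, i], NOE = draws[3, i],
                     R1err = rv$err[1], R2err = rv$err[2], NOEerr = rv$err[3])
        fitModelFree(recI, result$model, tauM, cfg, rexMax)$free
    }, numeric(length(result$free)))
    if (is.null(dim(refits))) refits <- matrix(refits, nrow = 1)
    stats::setNames(apply(refits, 1, stats::sd), names(result$free))
}

## Evaluate an expression under a local, restored RNG state.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
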