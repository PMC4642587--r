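cfg <- fieldConfig(600.13)

test_that("spectral density closed forms and limits", {
    ## rigid rotor: J(0) = 2/5 tau_m
    p <- motionalParams(1, S2 = 1, tauM = 5.67)
    expect_equal(spectralDensity(p, 0), 0.4 * 5.67e-9, tolerance = 1e-12)
    ## tau_e -> 0 reduces model 2 to model 1
    w <- 2 * pi * c(0, 60.8, 600.13) * 1e6
    p1 <- motionalParams(1, S2 = 0.8, tauM = 5.67)
    p2 <- motionalParams(2, S2 = 0.8, tauE = 1e-9, tauM = 5.67)
    expect_equal(spectralDensity(p2, w), spectralDensity(p1, w),
                 tolerance = 1e-9)
    ## model 5 with Sf2 = 1 equals model 2 term by term
    p5 <- motionalParams(5, S2 = 0.7, tauE = 80, S2f = 1, tauM = 5.67)
    p2b <- motionalParams(2, S2 = 0.7, tauE = 80, tauM = 5.67)
    expect_equal(spectralDensity(p5, w), spectralDensity(p2b, w),
                 tolerance = 1e-14)
})

test_that("J is non-negative and strictly decreasing in omega", {
    w <- 10^seq(6, 10, length.out = 40)
    for (p in list(motionalParams(2, S2 = 0.5, tauE = 300, tauM = 5.67),
                   motionalParams(5, S2 = 0.3, tauE = 1500, S2f = 0.7,
                                  tauM = 8),
                   motionalParams(1, S2 = 0.9, tauM = 3))) {
        J <- spectralDensity(p, w)
        expect_true(all(J >= 0))
        expect_true(all(diff(J) < 0))
    }
})

test_that("motional parameter invariants are enforced", {
    expect_error(motionalParams(1, S2 = 0.8, tauE = 50, tauM = 5),
                 "model 1")
    expect_error(motionalParams(5, S2 = 0.9, tauE = 50, S2f = 0.7, tauM = 5),
                 "S2f")
    expect_error(motionalParams(2, S2 = 1.2, tauM = 5))
})

test_that("predicted rates agree with an independent textbook formulation", {
    cases <- list(c(1, 0, 0, 1), c(0.85, 30, 0, 1), c(0.8, 50, 2, 1),
                  c(0.45, 1200, 0, 0.75))
    for (cs in cases) {
        model <- if (cs[4] < 1) 5 else if (cs[3] > 0) 4 else
            if (cs[2] > 0) 2 else 1
        p <- motionalParams(model, S2 = cs[1], tauE = cs[2], rex = cs[3],
                            S2f = cs[4], tauM = 5.67)
        got <- predictRates(p, cfg)
        ref <- oracleRates(cs[1], cs[2], cs[3], cs[4], 5.67)
        expect_equal(got, ref, tolerance = 1e-6)
    }
})

test_that("exchange enters R2 only", {
    p1 <- motionalParams(1, S2 = 0.85, tauM = 5.67)
    p3 <- motionalParams(3, S2 = 0.85, rex = 4, tauM = 5.67)
    r1 <- predictRates(p1, cfg); r3 <- predictRates(p3, cfg)
    expect_equal(r3["R1"], r1["R1"])
    expect_equal(r3["NOE"], r1["NOE"])
    expect_equal(unname(r3["R2"] - r1["R2"]), 4)
})

test_that("R2 >= R1 for nanosecond tumbling and the extreme narrowing NOE limit", {
    for (tm in c(1, 3, 5.67, 12)) {
        r <- predictRates(motionalParams(1, S2 = 1, tauM = tm), cfg)
        expect_gte(r[["R2"]], r[["R1"]])
    }
    ## tau_m -> 0: all J equal, so NOE -> 1 + (gH/gN) 5 d2q / (10 d2q + c2)
    r0 <- predictRates(motionalParams(1, S2 = 1, tauM = 1e-5), cfg)
    k <- nmrdyn:::.rateConstants(cfg)
    noeLimit <- 1 + k$gRatio * 5 * k$d2q / (10 * k$d2q + k$c2)
    expect_equal(unname(r0["NOE"]), noeLimit, tolerance = 1e-4)
})

test_that("decay fitting recovers exact and noisy rates", {
    t1 <- c(0.1, 1, 2, 4)
    fit <- fitDecay(t1, 100 * exp(-10 * t1))
    expect_equal(fit$rate, 10, tolerance = 1e-6)
    expect_false(fit$flagged)
    ## Monte-Carlo: 1% noise, 200 replicates; mean recovered rate within
    ## 2 standard errors of truth
    set.seed(41)
    rates <- replicate(200, {
        I <- 100 * exp(-10 * t1) * (1 + rnorm(4, sd = 0.01))
        fitDecay(t1, I)$rate
    })
    expect_lt(abs(mean(rates) - 10), 2 * sd(rates) / sqrt(200))
    ## constant intensities are flagged, not silently fitted
    expect_true(fitDecay(t1, rep(50, 4))$flagged)
})

test_that("NOE intensity ratio conventions", {
    expect_equal(noeRatio(80, 80), 1)
    expect_equal(noeRatio(0.78 * 120, 120), 0.78)
    expect_equal(noeRatio(-30, 100), -0.3)  # mobile termini go negative
    expect_error(noeRatio(10, 0), "zero")
})

test_that("noiseless model-1 data is recovered exactly", {
    r <- predictRates(motionalParams(1, S2 = 0.85, tauM = 5.67), cfg)
    rec <- list(R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
                R1err = 0.02 * r[["R1"]], R2err = 0.02 * r[["R2"]],
                NOEerr = 0.03)
    fit <- fitModelFree(rec, 1, 5.67, cfg)
    expect_equal(unname(fit$free["S2"]), 0.85, tolerance = 1e-6)
    expect_lt(fit$chi2, 1e-10)
})

test_that("optimizer chi2 matches a brute-force grid for model 2", {
    r <- oracleRates(0.72, 180, 0, 1, 5.67)
    set.seed(3)
    obs <- r * (1 + rnorm(3, sd = 0.02))
    err <- c(0.02 * r[1], 0.02 * r[2], 0.03)
    rec <- list(R1 = obs[1], R2 = obs[2], NOE = obs[3],
                R1err = err[1], R2err = err[2], NOEerr = err[3])
    fit <- fitModelFree(rec, 2, 5.67, cfg)
    ## dense independent grid (1e-3 in S2, 2 ps in tau_e)
    s2g <- seq(0.5, 0.95, by = 1e-3)
    teg <- seq(0, 600, by = 2)
    chiMin <- Inf
    for (te in teg) {
        pr <- vapply(s2g, function(s2) {
            p <- oracleRates(s2, te, 0, 1, 5.67)
            sum(((obs - p) / err)^2)
        }, numeric(1))
        chiMin <- min(chiMin, min(pr))
    }
    expect_lte(fit$chi2, chiMin + 1e-6)
    expect_equal(fit$chi2, chiMin, tolerance = 0.05)  # grid resolution limit
})

test_that("model-4 parameters are recovered from noisy data", {
    ## median over seeded replicates within Monte-Carlo SE
    truth <- c(S2 = 0.80, tauE = 50, rex = 2)
    r <- predictRates(motionalParams(4, S2 = 0.80, tauE = 50, rex = 2,
                                     tauM = 5.67), cfg)
    err <- c(0.02 * r[["R1"]], 0.02 * r[["R2"]], 0.02 * sqrt(1 + r[["NOE"]]^2))
    fits <- sapply(1:40, function(i) {
        set.seed(500 + i)
        obs <- rnorm(3, r, err)
        rec <- list(R1 = obs[1], R2 = obs[2], NOE = obs[3],
                    R1err = err[1], R2err = err[2], NOEerr = err[3])
        fitModelFree(rec, 4, 5.67, cfg)$free
    })
    rec0 <- list(R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
                 R1err = err[1], R2err = err[2], NOEerr = err[3])
    f0 <- fitModelFree(rec0, 4, 5.67, cfg)
    se <- mcErrors(f0, rec0, 5.67, cfg, nDraws = 100, seed = 9)
    for (nm in names(truth))
        expect_lt(abs(median(fits[nm, ]) - truth[[nm]]),
                  se[[nm]] + 1e-8)
})

test_that("model selection follows the parsimony cascade", {
    ## rigid residue -> model 1
    r <- predictRates(motionalParams(1, S2 = 0.87, tauM = 5.67), cfg)
    rec <- list(R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
                R1err = 0.02 * r[["R1"]], R2err = 0.02 * r[["R2"]],
                NOEerr = 0.03)
    s <- selectModelFree(rec, 5.67, cfg)
    expect_equal(s$model, 1L)
    expect_lt(s$chi2, 1e-8)
    expect_equal(nrow(s$trace), 5L)
})

test_that("large-exchange residues select the exchange family, never 1/2", {
    r <- predictRates(motionalParams(3, S2 = 0.85, rex = 6, tauM = 5.67), cfg)
    err <- c(0.02 * r[["R1"]], 0.02 * r[["R2"]], 0.02 * sqrt(1 + r[["NOE"]]^2))
    hits <- vapply(1:25, function(i) {
        set.seed(900 + i)
        obs <- rnorm(3, r, err)
        rec <- list(R1 = obs[1], R2 = obs[2], NOE = obs[3],
                    R1err = err[1], R2err = err[2], NOEerr = err[3])
        s <- selectModelFree(rec, 5.67, cfg)
        if (is.na(s$model)) NA_integer_ else s$model
    }, integer(1))
    expect_gte(mean(hits %in% c(3L, 4L), na.rm = TRUE), 0.95)
    expect_false(any(hits %in% c(1L, 2L)))
})

test_that("physically inconsistent rates are fitted to no model", {
    ## R2 far above anything reachable at tau_m with Rex <= rexMax, and a
    ## high NOE ruling out slow internal motion
    r <- predictRates(motionalParams(1, S2 = 0.85, tauM = 5.67), cfg)
    rec <- list(R1 = r[["R1"]], R2 = r[["R2"]] + 80, NOE = r[["NOE"]],
                R1err = 0.01 * r[["R1"]], R2err = 0.01 * r[["R2"]],
                NOEerr = 0.01)
    s <- selectModelFree(rec, 5.67, cfg)
    expect_true(is.na(s$model))
    expect_null(s$params)
})

test_that("noiseless data round-trips through selection with chi2 ~ 0", {
    for (gen in list(motionalParams(2, S2 = 0.75, tauE = 200, tauM = 5.67),
                     motionalParams(5, S2 = 0.45, tauE = 1200, S2f = 0.75,
                                    tauM = 5.67))) {
        r <- predictRates(gen, cfg)
        rec <- list(R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
                    R1err = 0.02 * r[["R1"]], R2err = 0.02 * r[["R2"]],
                    NOEerr = 0.03)
        s <- selectModelFree(rec, 5.67, cfg)
        expect_lte(s$model, gen$model)     # the generator or something simpler
        expect_lt(s$chi2, 1e-6)
    }
})

test_that("Monte-Carlo errors behave like errors", {
    r <- predictRates(motionalParams(1, S2 = 0.85, tauM = 5.67), cfg)
    mk <- function(f) list(R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
                           R1err = f * r[["R1"]], R2err = f * r[["R2"]],
                           NOEerr = f)
    rec <- mk(0.02)
    fit <- fitModelFree(rec, 1, 5.67, cfg)
    ## determinism
    se1 <- mcErrors(fit, rec, 5.67, cfg, nDraws = 80, seed = 5)
    se2 <- mcErrors(fit, rec, 5.67, cfg, nDraws = 80, seed = 5)
    expect_identical(se1, se2)
    ## noiseless data gives (numerically) zero errors
    recTiny <- mk(1e-9)
    fitT <- fitModelFree(recTiny, 1, 5.67, cfg)
    seT <- mcErrors(fitT, recTiny, 5.67, cfg, nDraws = 60, seed = 5)
    expect_lt(seT[["S2"]], 1e-6)
    ## doubling the noise roughly doubles the S2 error
    se4 <- mcErrors(fit, mk(0.04), 5.67, cfg, nDraws = 80, seed = 5)
    expect_gt(se4[["S2"]] / se1[["S2"]], 1.4)
    expect_lt(se4[["S2"]] / se1[["S2"]], 2.6)
    expect_warning(mcErrors(fit, rec, 5.67, cfg, nDraws = 20, seed = 1),
                   "50")
})

test_that("the Monte-Carlo goodness-of-fit null reproduces the analytic cut", {
    ## for a well-specified 1-parameter model the chi2 null has ~2 dof, so
    ## the seeded MC critical value should sit near qchisq(0.95, 2)
    r <- predictRates(motionalParams(1, S2 = 0.85, tauM = 5.67), cfg)
    rec <- list(R1 = r[["R1"]], R2 = r[["R2"]], NOE = r[["NOE"]],
                R1err = 0.02 * r[["R1"]], R2err = 0.02 * r[["R2"]],
                NOEerr = 0.02 * sqrt(1 + r[["NOE"]]^2))
    s <- selectModelFree(rec, 5.67, cfg, gof = "mc", mcDraws = 300, seed = 8)
    expect_equal(s$model, 1L)
    crit <- s$trace$critical[1]
    expect_gt(crit, qchisq(0.95, 2) * 0.6)
    expect_lt(crit, qchisq(0.95, 2) * 1.6)
})
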