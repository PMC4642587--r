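test_that("generators are pure functions of their seed", {
    t1 <- makeTemplate(10, "coil", seed = 5)
    t2 <- makeTemplate(10, "coil", seed = 5)
    expect_identical(coords(t1), coords(t2))
    e1 <- perturbEnsemble(t1, nModels = 4, sigmaProfile = 0.5, seed = 9)
    e2 <- perturbEnsemble(t1, nModels = 4, sigmaProfile = 0.5, seed = 9)
    expect_identical(coords(e1), coords(e2))
    e3 <- perturbEnsemble(t1, nModels = 4, sigmaProfile = 0.5, seed = 10)
    expect_gt(max(abs(coords(e3) - coords(e1))), 0.01)
    r1 <- simulateRelaxation(coreTailTruth(), seed = 3)
    r2 <- simulateRelaxation(coreTailTruth(), seed = 3)
    expect_identical(r1$R1, r2$R1)
    ## generators do not disturb the caller's RNG stream
    set.seed(123); a <- runif(1)
    set.seed(123); invisible(makeTemplate(6, "coil", seed = 1)); b <- runif(1)
    expect_identical(a, b)
})

test_that("helix templates have ideal geometry and torsions", {
    tmpl <- makeTemplate(10, "helix")
    pp <- phiPsi(tmpl)
    inner <- !pp$terminal
    expect_equal(pp$phi[inner], rep(-57, sum(inner)), tolerance = 1e-6)
    expect_equal(pp$psi[inner & !is.na(pp$psi)][1:8],
                 rep(-47, 8), tolerance = 1e-6)
    ## standard bond lengths along the backbone
    a <- atomData(tmpl)
    X <- coords(tmpl, 1)
    nIdx <- which(a$name == "N"); caIdx <- which(a$name == "CA")
    dNCA <- sqrt(rowSums((X[nIdx, ] - X[caIdx, ])^2))
    expect_equal(dNCA, rep(1.458, 10), tolerance = 1e-6)
})

test_that("mixed templates tag rigid and flexible segments", {
    tmpl <- makeTemplate(56, "mixed", startRes = 167L)
    segs <- attr(tmpl, "segments")
    expect_length(segs$rigid, 2L)
    expect_length(segs$flexible, 3L)
    covered <- sort(unlist(lapply(c(segs$rigid, segs$flexible),
                                  function(r) r[1]:r[2])))
    expect_equal(covered, 167:222)
})

test_that("coil torsions stay within the allowed Ramachandran regions", {
    tmpl <- makeTemplate(15, "coil", seed = 11)
    rs <- ramaSummary(tmpl)
    expect_equal(unname(rs$percent["most_favoured"] +
                        rs$percent["additional"]), 100)
})

test_that("zero displacement reproduces the template in every model", {
    tmpl <- makeTemplate(8, "helix")
    ens <- perturbEnsemble(tmpl, nModels = 5, sigmaProfile = 0)
    for (j in 1:5)
        expect_equal(coords(ens, j), coords(tmpl, 1), tolerance = 1e-12)
})

test_that("per-residue spread follows the sigma profile", {
    n <- 18
    sig <- seq(0.15, 1.8, length.out = n)
    ens <- perturbEnsemble(makeTemplate(n, "helix"), nModels = 20,
                           sigmaProfile = sig, seed = 21)
    rep <- ensembleRMSD(ens, atomSelection(atoms = "backbone"))
    expect_gt(cor(rep$perResidue$rmsd, sig, method = "spearman"), 0.9)
})

test_that("two seeds give different ensembles with matching statistics", {
    tmpl <- makeTemplate(14, "helix")
    eA <- perturbEnsemble(tmpl, nModels = 20, sigmaProfile = 0.5, seed = 1)
    eB <- perturbEnsemble(tmpl, nModels = 20, sigmaProfile = 0.5, seed = 2)
    rA <- ensembleRMSD(eA, atomSelection(atoms = "backbone"))
    rB <- ensembleRMSD(eB, atomSelection(atoms = "backbone"))
    expect_gt(max(abs(coords(eA) - coords(eB))), 0.1)
    expect_equal(rA$mean, rB$mean, tolerance = 0.25 * rA$mean)
})

test_that("distorted zinc sites violate restraints as designed", {
    ideal <- makeZincSite(distortion = 0)
    expect_equal(checkZincRestraints(zincGeometry(ideal, 1:4))$nViolations, 0L)
    warped <- makeZincSite(distortion = 0.3, seed = 7)
    expect_gte(checkZincRestraints(zincGeometry(warped, 1:4))$nViolations, 1L)
})

test_that("simulated relaxation reduces to the forward model without noise", {
    truth <- coreTailTruth(nRes = 10, nTail = 2)
    recs <- simulateRelaxation(truth, tauM = 5.67, noiseFraction = 1e-12,
                               seed = 1)
    cfg <- fieldConfig(600.13)
    for (i in seq_len(nrow(truth))) {
        p <- motionalParams(truth$model[i], S2 = truth$S2[i],
                            tauE = truth$tauE[i], rex = truth$rex[i],
                            S2f = truth$S2f[i], tauM = 5.67)
        expect_equal(unname(c(recs$R1[i], recs$R2[i], recs$NOE[i])),
                     unname(predictRates(p, cfg)), tolerance = 1e-6)
    }
})

test_that("decay series are consistent with the simulated rates", {
    truth <- coreTailTruth(nRes = 6, nTail = 1)
    recs <- simulateRelaxation(truth, noiseFraction = 0.01, seed = 2,
                               decaySeries = TRUE)
    dec <- attr(recs, "decays")
    expect_length(dec, nrow(truth))
    f <- fitDecay(dec[[1]]$t1$delay, dec[[1]]$t1$intensity)
    expect_equal(f$rate, recs$R1[1], tolerance = 0.1 * recs$R1[1])
    expect_equal(noeRatio(dec[[1]]$noe[["iSat"]], dec[[1]]$noe[["iRef"]]),
                 recs$NOE[1], tolerance = 1e-9)
})

test_that("generated records satisfy the relaxation-record invariants", {
    recs <- simulateRelaxation(defaultRelaxationTruth(), seed = 4)
    expect_true(all(recs$R1 > 0))
    expect_true(all(recs$R2 > 0))
    expect_true(all(recs$R1err > 0 & recs$R2err > 0 & recs$NOEerr > 0))
})

test_that("the deposit-scale stand-in has the designed architecture", {
    ens <- syntheticDeposit(seed = 2)
    expect_equal(nModels(ens), 20L)
    sq <- sequenceMap(ens)
    expect_equal(sort(as.integer(names(sq[sq == "CYS"]))),
                 c(176, 179, 182, 188, 191, 194, 210, 215))
    expect_equal(unname(sq["199"]), "PRO")
    ## rigid segments tighter than the loop
    repAll <- ensembleRMSD(ens, atomSelection("175-196,208-217",
                                              atoms = "backbone"))
    repLoop <- ensembleRMSD(ens, atomSelection("197-207", atoms = "backbone"))
    expect_lt(repAll$mean, repLoop$mean / 2)
})
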