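test_that("torsion angles follow the IUPAC sign convention", {
    ## planar anti (trans) butane-like chain
    p <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
    expect_equal(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]), 180)
    ## mirror image flips the sign
    q <- list(c(0, 1, 0.3), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0.4))
    a <- dihedralAngle(q[[1]], q[[2]], q[[3]], q[[4]])
    m <- lapply(q, function(v) v * c(1, 1, -1))
    expect_equal(dihedralAngle(m[[1]], m[[2]], m[[3]], m[[4]]), -a,
                 tolerance = 1e-12)
    expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(3, 1, 0)), "collinear")
})

test_that("torsions agree with an independent vector-algebra formula", {
    set.seed(14)
    for (i in 1:25) {
        pts <- lapply(1:4, function(j) rnorm(3, sd = 2))
        got <- dihedralAngle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
        ref <- oracleDihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
        expect_equal(got, ref, tolerance = 1e-9)
    }
})

test_that("Ramachandran classification of canonical conformations", {
    expect_equal(ramaClassify(-60, -45), "most_favoured")   # alpha helix
    expect_equal(ramaClassify(-120, 130), "most_favoured")  # beta sheet
    expect_equal(ramaClassify(60, 40), "most_favoured")     # left-handed alpha
    expect_equal(ramaClassify(60, 180), "disallowed")
    ## Gly/Pro/termini are excluded regardless of angles
    expect_equal(ramaClassify(-60, -45, "GLY"), "excluded")
    expect_equal(ramaClassify(-60, -45, "PRO"), "excluded")
    expect_equal(ramaClassify(-60, -45, terminal = TRUE), "excluded")
})

test_that("the region grid covers the full torus and is deterministic", {
    set.seed(15)
    phi <- runif(500, -180, 180); psi <- runif(500, -180, 180)
    r1 <- ramaClassify(phi, psi)
    r2 <- ramaClassify(phi, psi)
    expect_identical(r1, r2)
    expect_true(all(r1 %in% c("most_favoured", "additional", "generous",
                              "disallowed")))
    ## boundary angles (wrapping) classify without error
    expect_length(ramaClassify(c(-180, 180), c(180, -180)), 2)
})

test_that("an ideal helical ensemble is 100% most favoured", {
    ens <- perturbEnsemble(makeTemplate(12, "helix"), nModels = 3,
                           sigmaProfile = 1e-6)
    rs <- ramaSummary(ens)
    expect_equal(unname(rs$percent["most_favoured"]), 100)
    expect_equal(unname(sum(rs$percent)), 100, tolerance = 0.1)
})

test_that("summary percentages always sum to 100 over classifiable residues", {
    ens <- syntheticDeposit(seed = 3, nModels = 5)
    rs <- ramaSummary(ens, atomSelection("175-196,208-216"))
    expect_equal(unname(sum(rs$percent)), 100, tolerance = 0.1)
    ## Gly and Pro residues appear only under excluded
    expect_false(any(rs$points$region[rs$points$resName %in%
                                      c("GLY", "PRO")] != "excluded"))
    expect_error(ramaSummary(ens, atomSelection("300-310")), "no atoms|no residues")
})

test_that("ideal zinc sites measure exactly at the restraint targets", {
    zs <- makeZincSite(resSeq = c(176, 179, 182, 215))
    g <- zincGeometry(zs, c(176, 179, 182, 215))
    expect_equal(g$bonds$dist, rep(2.3, 4), tolerance = 1e-9)
    expect_equal(g$sZnS$angle, rep(acos(-1 / 3) * 180 / pi, 6),
                 tolerance = 1e-6)
    expect_equal(g$caCbS$angle, rep(114.3558, 4), tolerance = 1e-9)
    expect_equal(g$cbSZn$angle, rep(109.5, 4), tolerance = 1e-9)
    expect_equal(g$hbCbS$angle, rep(107.9185, 8), tolerance = 1e-9)
    chk <- checkZincRestraints(g)
    expect_equal(chk$nViolations, 0L)
})

test_that("a displaced sulphur flags exactly the right bond", {
    zs <- makeZincSite(resSeq = c(1, 2, 3, 4))
    i <- which(zs@atoms$resSeq == 2 & zs@atoms$name == "SG")
    dir <- zs@xyz[i, , 1]
    zs@xyz[i, , 1] <- dir * (1 + 0.2 / sqrt(sum(dir^2)))   # push 0.2 A outward
    g <- zincGeometry(zs, 1:4)
    chk <- checkZincRestraints(g)
    bad <- chk$items[!chk$items$pass & chk$items$item == "s_zn_bond", ]
    expect_equal(bad$label, "S-Zn 2")
    expect_equal(bad$deviation, 0.2, tolerance = 1e-6)
    ## bond arithmetic: 2.5 A at tolerance 0.1 is one violation of 0.2
    expect_equal(chk$items$measured[chk$items$label == "S-Zn 2"], 2.5,
                 tolerance = 1e-6)
})

test_that("violation totals equal the sum of per-item flags", {
    zs <- makeZincSite(distortion = 0.3, seed = 4, resSeq = 1:4)
    chk <- checkZincRestraints(zincGeometry(zs, 1:4))
    expect_equal(chk$nViolations, sum(!chk$items$pass))
    expect_gte(chk$nViolations, 1L)   # 0.3 A distortion must violate something
})

test_that("zinc geometry is invariant under rigid motion", {
    zs <- makeZincSite(distortion = 0.1, seed = 2, resSeq = 1:4)
    g1 <- zincGeometry(zs, 1:4)
    set.seed(3)
    R <- randomRotation()
    zs@xyz[, , 1] <- zs@xyz[, , 1] %*% t(R) + rep(c(3, -7, 2),
                                                  each = nAtoms(zs))
    g2 <- zincGeometry(zs, 1:4)
    expect_equal(g2$bonds$dist, g1$bonds$dist, tolerance = 1e-9)
    expect_equal(g2$sZnS$angle, g1$sZnS$angle, tolerance = 1e-9)
})

test_that("missing atoms are reported by name", {
    zs <- makeZincSite(resSeq = 1:4)
    keep <- !(zs@atoms$resSeq == 3 & zs@atoms$name == "SG")
    z2 <- new("NMREnsemble", atoms = zs@atoms[keep, ],
              xyz = zs@xyz[keep, , , drop = FALSE], modelIds = 1L)
    expect_error(zincGeometry(z2, 1:4), "missing SG.*3")
    z3 <- new("NMREnsemble",
              atoms = zs@atoms[zs@atoms$name != "ZN", ],
              xyz = zs@xyz[zs@atoms$name != "ZN", , , drop = FALSE],
              modelIds = 1L)
    expect_error(zincGeometry(z3, 1:4), "ZN")
})

test_that("cysteine clustering recovers the generating partition", {
    ce <- makeCysClusterEnsemble(seed = 6)
    ca <- assignCysClusters(ce)
    expect_equal(ca$clusters[[1]], c(176, 179, 182, 215))
    expect_equal(ca$clusters[[2]], c(188, 191, 194, 210))
    expect_gt(ca$silhouette, 0.5)
})

test_that("cluster assignment is invariant under input order", {
    ce <- makeCysClusterEnsemble(seed = 8)
    cys <- c(176, 179, 182, 188, 191, 194, 210, 215)
    a1 <- assignCysClusters(ce, cys)
    set.seed(2)
    a2 <- assignCysClusters(ce, sample(cys))
    expect_identical(a1$clusters, a2$clusters)
})

test_that("degenerate cluster inputs are guarded", {
    ce <- makeCysClusterEnsemble()
    expect_error(assignCysClusters(ce, c(176, 188)), "at least 4")
    ## an 8-cysteine set that cannot split 4+4 is an error showing the split
    bad <- makeCysClusterEnsemble(res1 = c(1, 2, 3, 4), res2 = c(5, 6, 7, 8),
                                  separation = 0.5, distortion = 0.01)
    ## with overlapping sites the average-linkage 2-cut is unlikely to be
    ## 4+4; accept either a clean error or (rarely) a lucky 4+4
    res <- tryCatch(assignCysClusters(bad), error = function(e) e)
    if (inherits(res, "error")) {
        expect_match(conditionMessage(res), "do not split 4\\+4")
    } else {
        expect_equal(lengths(res$clusters), c(4L, 4L))
    }
})
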