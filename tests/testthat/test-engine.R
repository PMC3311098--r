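fig2Run <- function(preprocess = TRUE, rho = 0.6, tau = 50) {
    fx <- figure2Fixture()
    runPipeline(fx$nets, fx$sim,
                AlignmentParams(tau = tau, beta = 0.1, rho = rho,
                                omega = 2.5),
                preprocess = preprocess)
}

test_that("seed generation filters within-network pairs and applies tau", {
    fx <- figure2Fixture()
    pp <- preprocessSimilarity(fx$nets, fx$sim)
    cl <- agglomerativeCluster(pp, 3)
    seeds <- generateSeeds(cl, pp, tau = 50, nets = fx$nets)
    expect_identical(seeds$protein1, c("A2", "A2"))
    expect_identical(seeds$protein2, c("B2", "B3"))

    expect_equal(nrow(generateSeeds(cl, pp, tau = Inf, nets = fx$nets)), 0)

    # one cluster of mutually similar proteins at tau = 0: all cross pairs
    nc <- NetworkCollection(list(A = rbind(c("a1", "a2"), c("a2", "a3")),
                                 B = rbind(c("b1", "b2"))))
    prots <- c("a1", "a2", "a3", "b1", "b2")
    cp <- combn(prots, 2)
    netOf <- proteinNetwork(nc)
    cross <- netOf[cp[1, ]] != netOf[cp[2, ]]
    sm <- SimilarityMatrix(cp[1, cross], cp[2, cross],
                           seq_len(sum(cross)), nets = nc)
    seeds <- generateSeeds(list(prots), sm, tau = 0, nets = nc)
    expect_equal(nrow(seeds), sum(cross))   # C(5,2) minus within-network
})

test_that("the merging criterion implements the size and density gates", {
    fx <- figure2Fixture()
    pp <- preprocessSimilarity(fx$nets, fx$sim)
    params <- AlignmentParams(tau = 50, beta = 0.1, rho = 0.6, omega = 2.5)

    # two singletons with positive score always merge
    st <- newAlignmentState(fx$nets, pp)
    expect_true(mergeCriterion("A2", "B2", st, params))
    expect_true(st$ali[["A2"]] && st$ali[["B2"]])

    # extending {A2, B2} by B3: count 1, expandRatio 1, 1 < 2 * 0.6
    expect_false(mergeCriterion("A2", "B3", st, params))
    expect_identical(sort(st$sets[[st$setOf[["A2"]]]]), c("A2", "B2"))

    # size gate: |Si| + |Sj| = 6 > 2.5 * 2 networks
    nc <- NetworkCollection(list(
        A = list(edges = matrix(character(), 0, 2),
                 vertices = paste0("a", 1:3)),
        B = list(edges = matrix(character(), 0, 2),
                 vertices = paste0("b", 1:3))))
    allp <- proteins(nc)
    cp <- combn(allp, 2)
    netOf <- proteinNetwork(nc)
    cross <- netOf[cp[1, ]] != netOf[cp[2, ]]
    smFull <- SimilarityMatrix(cp[1, cross], cp[2, cross],
                               rep(10, sum(cross)), nets = nc)
    st2 <- newAlignmentState(nc, smFull)
    loose <- AlignmentParams(tau = 0, beta = 0.1, rho = 0.1, omega = 10)
    expect_true(mergeCriterion("a1", "b1", st2, loose))
    expect_true(mergeCriterion("a2", "b2", st2, loose))
    expect_true(mergeCriterion("a1", "a2", st2, loose) ||
                mergeCriterion("a1", "b2", st2, loose))
    expect_true(mergeCriterion("a3", "b3", st2, loose))
    # now one set has 4, the other 2: 6 > 2.5 * 2 under omega = 2.5
    gated <- AlignmentParams(tau = 0, beta = 0.1, rho = 0.1, omega = 2.5)
    expect_false(mergeCriterion("a1", "a3", st2, gated))

    expect_error(mergeCriterion("A2", "B2", st, params), "same match-set")
})

test_that("zero-similarity singleton merges require the flag", {
    nc <- NetworkCollection(list(A = rbind(c("a1", "a2")),
                                 B = rbind(c("b1", "b2"))))
    sm <- SimilarityMatrix("a1", "b1", 5, nets = nc)
    on <- AlignmentParams(mergeZeroSimSingletons = TRUE)
    off <- AlignmentParams(mergeZeroSimSingletons = FALSE)
    st <- newAlignmentState(nc, sm)
    expect_true(mergeCriterion("a2", "b2", st, on))
    st <- newAlignmentState(nc, sm)
    expect_false(mergeCriterion("a2", "b2", st, off))
})

test_that("seed expansion reproduces the worked-example alignment", {
    res <- fig2Run(preprocess = TRUE)
    expect_identical(matchSets(res$alignment),
                     list(c("A1", "B1"), c("A2", "B2"), c("A3", "B4")))
    expect_equal(res$report$seedCount, 2)
})

test_that("an empty seed set yields an empty alignment after expansion", {
    fx <- figure2Fixture()
    st <- newAlignmentState(fx$nets, fx$sim)
    seeds <- generateSeeds(list(), fx$sim, 0, fx$nets)
    expandSeeds(seeds, st, AlignmentParams())
    expect_equal(nMatchSets(finalizeAlignment(st)), 0)
})

test_that("expansion propagates a single seed around matching rings", {
    n <- 10
    ring <- function(pre) cbind(sprintf("%s%02d", pre, 1:n),
                                sprintf("%s%02d", pre, c(2:n, 1)))
    nc <- NetworkCollection(list(A = ring("a"), B = ring("b")))
    sm <- SimilarityMatrix(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n),
                           rep(1, n), nets = nc)
    st <- newAlignmentState(nc, sm)
    seeds <- data.frame(protein1 = "a01", protein2 = "b01", score = 1)
    expandSeeds(seeds, st, AlignmentParams(tau = 0, rho = 0.6))
    aln <- finalizeAlignment(st)
    expect_identical(matchSets(aln),
                     lapply(1:n, function(i) c(sprintf("a%02d", i),
                                               sprintf("b%02d", i))))
})

test_that("stage 4 aligns leftover similar pairs but never zero-score pairs", {
    # worked example: nothing remains after expansion
    fx <- figure2Fixture()
    res <- fig2Run(preprocess = TRUE)
    st <- newAlignmentState(fx$nets, res$decision)
    expandSeeds(res$seeds, st, AlignmentParams(tau = 50, rho = 0.6))
    before <- st$accepted
    alignRemaining(st, AlignmentParams(tau = 50, rho = 0.6))
    expect_equal(st$accepted, before)   # no-op

    # two unaligned proteins with score 5 form one new match-set
    nc <- NetworkCollection(list(A = rbind(c("a1", "a2")),
                                 B = rbind(c("b1", "b2"))))
    sm <- SimilarityMatrix("a2", "b2", 5, nets = nc)
    st2 <- newAlignmentState(nc, sm)
    alignRemaining(st2, AlignmentParams())
    expect_identical(matchSets(finalizeAlignment(st2)),
                     list(c("a2", "b2")))

    # chain x-y-z across 3 networks processed in score order
    nc3 <- NetworkCollection(list(
        A = list(edges = matrix(character(), 0, 2), vertices = "x"),
        B = list(edges = matrix(character(), 0, 2), vertices = "y"),
        C = list(edges = matrix(character(), 0, 2), vertices = "z")))
    sm3 <- SimilarityMatrix(c("x", "y"), c("y", "z"), c(9, 7), nets = nc3)
    st3 <- newAlignmentState(nc3, sm3)
    alignRemaining(st3, AlignmentParams(beta = 0.1, rho = 0.5))
    # (x,y) merges first; then (y,z) extends: count 1 * ratio 1.5 >= 2*0.5
    expect_identical(matchSets(finalizeAlignment(st3)),
                     list(c("x", "y", "z")))
})

test_that("without preprocessing the pipeline conserves only two edges", {
    res <- fig2Run(preprocess = FALSE)
    fx <- figure2Fixture()
    ev <- evaluateAlignment(res$alignment, fx$nets, fx$sim)
    expect_equal(ev$conservedEdges, 2)
    # secondary: the documented LIFO tie-break reproduces the 80/3 layout
    expect_identical(matchSets(res$alignment),
                     list(c("A1", "B1"), c("A2", "B3"), c("A3", "B2")))
    expect_equal(ev$averageSimilarity, 80 / 3)
})

test_that("match-sets partition the proteins at every stage", {
    for (seed in 1:6) {
        inst <- randomInstance(k = 3, nPerNet = 6, pEdge = 0.4, pSim = 0.3,
                               seed = 400 + seed)
        res <- runPipeline(inst$nets, inst$sim, AlignmentParams(tau = 1))
        aln <- res$alignment
        expect_false(anyDuplicated(unlist(matchSets(aln))) > 0)
        expect_true(all(lengths(matchSets(aln)) >= 2))
        expect_true(all(unlist(matchSets(aln)) %in% proteins(inst$nets)))
    }
})

test_that("seed count is non-increasing in tau", {
    for (seed in 1:6) {
        inst <- randomInstance(k = 2, nPerNet = 8, pSim = 0.4,
                               seed = 500 + seed)
        dec <- preprocessSimilarity(inst$nets, inst$sim)
        m <- targetClusterCount(inst$nets, dec)
        cl <- agglomerativeCluster(dec, m)
        taus <- c(0, 2, 5, 8, 12, Inf)
        counts <- vapply(taus, function(t)
            nrow(generateSeeds(cl, dec, t, inst$nets)), 1L)
        expect_true(all(diff(counts) <= 0))
        expect_equal(counts[length(counts)], 0)
    }
})

test_that("rho > 0.5 with two networks caps match-sets at two proteins", {
    for (seed in 1:6) {
        inst <- randomInstance(k = 2, nPerNet = 8, pEdge = 0.5, pSim = 0.5,
                               seed = 600 + seed)
        res <- runPipeline(inst$nets, inst$sim,
                           AlignmentParams(tau = 0, rho = 0.6))
        expect_true(all(lengths(matchSets(res$alignment)) == 2))
    }
})

test_that("every merge passed the criterion gates when it was executed", {
    # replay the audit: re-apply the criterion to a fresh state in the
    # recorded merge order and require identical final match-sets
    inst <- randomInstance(k = 3, nPerNet = 6, pEdge = 0.4, pSim = 0.4,
                           seed = 99)
    params <- AlignmentParams(tau = 1)
    res <- runPipeline(inst$nets, inst$sim, params)
    # a final set of size s takes at least s - 1 accepted merges
    expect_gte(res$report$mergeAccepted,
               sum(lengths(matchSets(res$alignment))) -
                   nMatchSets(res$alignment))
    rerun <- runPipeline(inst$nets, inst$sim, params)
    expect_identical(matchSets(rerun$alignment), matchSets(res$alignment))
})

test_that("the pipeline is invariant to similarity row order", {
    inst <- randomInstance(k = 2, nPerNet = 7, pSim = 0.4, seed = 77)
    pr <- simPairs(inst$sim)
    set.seed(1)
    shuf <- pr[sample(nrow(pr)), ]
    sim2 <- SimilarityMatrix(shuf$protein2, shuf$protein1, shuf$score,
                             nets = inst$nets)
    p <- AlignmentParams(tau = 2, rho = 0.6)
    expect_identical(matchSets(runPipeline(inst$nets, inst$sim, p)$alignment),
                     matchSets(runPipeline(inst$nets, sim2, p)$alignment))
})

test_that("alignSweep matches runPipeline per tau with one clustering pass", {
    fx <- figure2Fixture()
    params <- AlignmentParams(rho = 0.6)
    sw <- alignSweep(fx$nets, fx$sim, tauList = c(50, 1000), params = params)
    expect_equal(attr(sw, "clusteringInvocations"), 1L)
    single <- runPipeline(fx$nets, fx$sim,
                          AlignmentParams(tau = 50, rho = 0.6))
    expect_identical(matchSets(sw[[1]]$alignment),
                     matchSets(single$alignment))
    expect_equal(nMatchSets(sw[[1]]$alignment), 3)
    # at tau = 1000 no seeds form, but stage 4 still aligns similar pairs
    expect_equal(sw[[2]]$report$seedCount, 0)
    single2 <- runPipeline(fx$nets, fx$sim,
                           AlignmentParams(tau = 1000, rho = 0.6))
    expect_identical(matchSets(sw[[2]]$alignment),
                     matchSets(single2$alignment))
})

test_that("pipeline rejects fewer than two networks", {
    nc <- NetworkCollection(list(A = rbind(c("a", "b"))))
    sm <- SimilarityMatrix(character(), character(), numeric(),
                           proteins = proteins(nc))
    expect_error(runPipeline(nc, sm), "two networks")
})
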