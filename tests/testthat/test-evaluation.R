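fig2Alignment <- function() {
    Alignment(list(c("A1", "B1"), c("A2", "B2"), c("A3", "B4")))
}

test_that("match-set similarity averages raw scores over all pairs", {
    fx <- figure2Fixture()
    expect_equal(matchSetSimilarity(c("A2", "B2"), fx$sim), 50)
    # 3-member set with one nonzero pair of 30: 30 / choose(3,2)
    nc <- NetworkCollection(list(
        A = list(edges = matrix(character(), 0, 2), vertices = c("a", "a2")),
        B = list(edges = matrix(character(), 0, 2), vertices = "b")))
    sm <- SimilarityMatrix("a", "b", 30, nets = nc)
    expect_equal(matchSetSimilarity(c("a", "a2", "b"), sm), 10)
    expect_error(matchSetSimilarity("a", sm), "at least 2")

    # random 5-member set equals brute-force pair enumeration
    inst <- randomInstance(k = 2, nPerNet = 6, pSim = 0.6, seed = 9)
    set.seed(9)
    S <- sample(proteins(inst$nets), 5)
    cp <- combn(S, 2)
    brute <- sum(simScore(inst$sim, cp[1, ], cp[2, ])) / choose(5, 2)
    expect_equal(matchSetSimilarity(S, inst$sim), brute)
})

test_that("average similarity is the size-weighted mean of set scores", {
    fx <- figure2Fixture()
    expect_equal(averageSimilarity(fig2Alignment(), fx$sim), 85 / 3)
    hung <- Alignment(list(c("A1", "B1"), c("A2", "B3"), c("A3", "B4")))
    expect_equal(averageSimilarity(hung, fx$sim), 95 / 3)
    expect_error(averageSimilarity(Alignment(), fx$sim), "no match-sets")
    # equal sizes: weighted mean equals unweighted mean
    simS <- vapply(matchSets(fig2Alignment()), matchSetSimilarity,
                   numeric(1), simRaw = fx$sim)
    expect_equal(averageSimilarity(fig2Alignment(), fx$sim), mean(simS))
})

test_that("conserved-edge counting matches the worked example", {
    fx <- figure2Fixture()
    ce <- conservedEdges(fig2Alignment(), fx$nets)
    expect_equal(ce$count, 4)
    expect_setequal(paste(ce$edges$from, ce$edges$to),
                    c("A1 A2", "A2 A3", "B1 B2", "B2 B4"))
    # a single all-protein match-set conserves every edge
    all_aln <- Alignment(list(proteins(fx$nets)))
    expect_equal(conservedEdges(all_aln, fx$nets)$count,
                 nrow(edgeTable(fx$nets)))
})

test_that("conserved and strictly conserved counts equal brute force", {
    for (seed in 1:25) {
        inst <- randomInstance(k = sample(2:3, 1), nPerNet = 5,
                               pEdge = 0.4, pSim = 0.4, seed = 700 + seed)
        aln <- randomAlignment(inst$nets, seed = seed)
        expect_equal(conservedEdges(aln, inst$nets)$count,
                     bruteConserved(aln, inst$nets))
        expect_equal(strictlyConservedEdges(aln, inst$nets, inst$sim),
                     bruteStrictlyConserved(aln, inst$nets, inst$sim))
    }
})

test_that("strict conservation needs positive-similarity witnesses", {
    fx <- figure2Fixture()
    expect_equal(strictlyConservedEdges(fig2Alignment(), fx$nets, fx$sim), 4)
    # condition-(2)-only conserved edge is excluded
    nc <- NetworkCollection(list(A = rbind(c("a1", "a2")),
                                 B = rbind(c("b1", "b2"))))
    sm <- SimilarityMatrix(c("a1", "a2"), c("b1", "b2"), c(1, 1), nets = nc)
    co <- Alignment(list(c("a1", "a2"), c("b1", "b2")))
    expect_equal(conservedEdges(co, nc)$count, 2)      # both colocated
    expect_equal(strictlyConservedEdges(co, nc, sm), 0)
    # witness with one zero similarity is excluded
    smHalf <- SimilarityMatrix("a1", "b1", 1, nets = nc)
    pairAln <- Alignment(list(c("a1", "b1"), c("a2", "b2")))
    expect_equal(conservedEdges(pairAln, nc)$count, 2)
    expect_equal(strictlyConservedEdges(pairAln, nc, smHalf), 0)
    expect_equal(strictlyConservedEdges(pairAln, nc, sm), 2)
})

test_that("coverage and conserved-edge rate follow their definitions", {
    fx <- figure2Fixture()
    cov <- coverageAndRate(fig2Alignment(), fx$nets)
    expect_equal(cov$coverage, 6)
    expect_equal(cov$coveredEdges, 4)   # B3 uncovered removes B2-B3
    expect_equal(cov$conservedEdgeRate, 1)
    all_aln <- Alignment(list(proteins(fx$nets)))
    expect_equal(coverageAndRate(all_aln, fx$nets)$conservedEdgeRate, 1)
})

test_that("hypergeometric p-values match direct combinatorial summation", {
    expect_equal(hypergeomPValue(10, 5, 4, 0), 1)
    expect_equal(hypergeomPValue(10, 5, 4, 4), 5 / 210)
    expect_equal(hypergeomPValue(6, 3, 3, 3), 1 / 20)
    expect_error(hypergeomPValue(10, 11, 4, 4), "inconsistent")
    expect_error(hypergeomPValue(10, 5, 4, 5), "inconsistent")

    for (N in seq(4, 24, by = 5)) {
        for (M in c(0, N %/% 3, N %/% 2, N)) {
            for (n in unique(c(1, N %/% 4, N %/% 2))) {
                if (n < 1) next
                for (m in 0:min(n, M)) {
                    expect_equal(hypergeomPValue(N, M, n, m),
                                 bruteHypergeom(N, M, n, m),
                                 tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("hypergeometric p-value is non-increasing in m", {
    for (N in c(10, 20)) for (M in c(4, 8)) for (n in c(3, 6)) {
        p <- vapply(0:min(n, M), function(m) hypergeomPValue(N, M, n, m),
                    numeric(1))
        expect_true(all(diff(p) <= 1e-14))
    }
})

test_that("enrichment flags terms concentrated in match-sets", {
    fx <- figure2Fixture()
    aln <- fig2Alignment()
    # no annotations: every p-value is 1, nothing enriched
    er <- enrichmentReport(aln, AnnotationMap(), fx$nets)
    expect_true(all(er$matchSetPValues == 1))
    expect_length(er$enrichedTerms, 0)
    # a term annotating all proteins is never enriched
    allAnn <- AnnotationMap(data.frame(protein = proteins(fx$nets),
                                       term = "GO:ALL"))
    er2 <- enrichmentReport(aln, allAnn, fx$nets)
    expect_true(all(er2$matchSetPValues == 1))
    expect_length(er2$enrichedTerms, 0)

    # one term annotating exactly one 5-member match-set of 1000 proteins
    nets <- NetworkCollection(list(
        A = list(edges = matrix(character(), 0, 2),
                 vertices = sprintf("a%03d", 1:500)),
        B = list(edges = matrix(character(), 0, 2),
                 vertices = sprintf("b%03d", 1:500))))
    S <- c(sprintf("a%03d", 1:3), sprintf("b%03d", 1:2))
    ann <- AnnotationMap(data.frame(protein = S, term = "GO:X"))
    aln2 <- Alignment(list(S, c("a004", "b004")))
    er3 <- enrichmentReport(aln2, ann, nets)
    expect_equal(er3$matchSetPValues[1], hypergeomPValue(1000, 5, 5, 5))
    expect_equal(er3$enrichedTerms, "GO:X")
    expect_equal(er3$matchSetPValues[2], 1)
})

test_that("the pairwise baseline maximizes total similarity", {
    fx <- figure2Fixture()
    hb <- hungarianBaseline(fx$nets, fx$sim)
    expect_identical(matchSets(hb),
                     list(c("A1", "B1"), c("A2", "B3"), c("A3", "B4")))
    expect_equal(averageSimilarity(hb, fx$sim), 95 / 3)
    expect_equal(conservedEdges(hb, fx$nets)$count, 0)

    # identity score matrix gives the identity matching
    nc <- NetworkCollection(list(
        A = list(edges = matrix(character(), 0, 2),
                 vertices = sprintf("a%d", 1:4)),
        B = list(edges = matrix(character(), 0, 2),
                 vertices = sprintf("b%d", 1:4))))
    sm <- SimilarityMatrix(sprintf("a%d", 1:4), sprintf("b%d", 1:4),
                           rep(1, 4), nets = nc)
    expect_identical(matchSets(hungarianBaseline(nc, sm)),
                     lapply(1:4, function(i) c(sprintf("a%d", i),
                                               sprintf("b%d", i))))

    expect_error(hungarianBaseline(NetworkCollection(
        list(A = rbind(c("a", "b")), B = rbind(c("c", "d")),
             C = rbind(c("e", "f")))), sm), "exactly 2")
})

test_that("baseline totals equal exhaustive assignment enumeration", {
    for (seed in 1:8) {
        set.seed(800 + seed)
        nr <- sample(4:6, 1); ncol_ <- sample(4:7, 1)
        scores <- matrix(round(runif(nr * ncol_), 3), nr, ncol_)
        scores[runif(nr * ncol_) < 0.4] <- 0
        left <- sprintf("a%d", seq_len(nr))
        right <- sprintf("b%d", seq_len(ncol_))
        nets <- NetworkCollection(list(
            A = list(edges = matrix(character(), 0, 2), vertices = left),
            B = list(edges = matrix(character(), 0, 2), vertices = right)))
        idx <- which(scores > 0, arr.ind = TRUE)
        if (!nrow(idx)) next
        sm <- SimilarityMatrix(left[idx[, 1]], right[idx[, 2]],
                               scores[idx], nets = nets)
        hb <- hungarianBaseline(nets, sm)
        total <- sum(vapply(matchSets(hb), function(s)
            simScore(sm, s[1], s[2]), numeric(1)))
        expect_equal(total, bruteAssignment(scores), tolerance = 1e-9)
    }
})

test_that("baseline total similarity dominates random one-to-one alignments", {
    totalSim <- function(aln, sim) sum(vapply(matchSets(aln), function(s)
        simScore(sim, s[1], s[2]), numeric(1)))
    inst <- randomInstance(k = 2, nPerNet = 6, pSim = 0.5, seed = 321)
    hb <- hungarianBaseline(inst$nets, inst$sim)
    best <- totalSim(hb, inst$sim)
    netOf <- proteinNetwork(inst$nets)
    left <- names(netOf)[netOf == "g1"]
    right <- names(netOf)[netOf == "g2"]
    set.seed(321)
    for (i in 1:30) {
        perm <- sample(right)
        sets <- Map(c, left, perm[seq_along(left)])
        sc <- simScore(inst$sim, left, perm[seq_along(left)])
        if (!any(sc > 0)) next
        rnd <- Alignment(unname(sets[sc > 0]))
        expect_lte(totalSim(rnd, inst$sim), best + 1e-9)
    }
})

test_that("evaluateAlignment bundles consistent metrics", {
    fx <- figure2Fixture()
    ev <- evaluateAlignment(fig2Alignment(), fx$nets, fx$sim)
    expect_equal(ev$conservedEdges, 4)
    expect_lte(ev$strictlyConservedEdges, ev$conservedEdges)
    expect_equal(ev$coverage, sum(lengths(matchSets(fig2Alignment()))))
    expect_true(ev$conservedEdgeRate >= 0 && ev$conservedEdgeRate <= 1)
    expect_equal(nrow(ev$matchSetTable), 3)
})
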