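test_that("hard filter applies each threshold and matches the rule oracle", {
    x <- BulkVariants(chrom = "Chr1", pos = c(10, 20, 30, 40),
                      ref = "A", alt = "T",
                      qd = c(25, 25, 1, 25), gq = 99,
                      dp = c(5, 30, 30, 30),
                      adRef = c(0, 20, 0, 0), adAlt = c(5, 10, 30, 30),
                      gt = c("1/1", "0/1", "1/1", "1/1"))
    kept <- hardFilter(x, FilterThresholds())
    # dp=5 < 6 dropped; balanced het (20/10) fails minAB 0.8; qd=1 < 2 dropped
    expect_identical(start(kept), 40L)
    # all-zero thresholds are the identity
    expect_length(hardFilter(x, FilterThresholds(0, 0, 0, 0)), length(x))
    # a skewed het call passes the allele-balance rule
    skew <- BulkVariants(chrom = "Chr1", pos = 1, ref = "A", alt = "T",
                         qd = 25, gq = 99, dp = 30, adRef = 26, adAlt = 4,
                         gt = "0/1")
    expect_length(hardFilter(skew), 1L)

    # randomized fixture versus an independently written rule-per-line oracle
    for (seed in c(101, 202)) {
        rb <- randomBulk(200, seed)
        for (th in list(FilterThresholds(), FilterThresholds(0.6, 10, 50, 5))) {
            got <- hardFilter(rb, th)
            want <- oracleHardFilter(rb, th@minAB, th@minDP, th@minGQ,
                                     th@minQD)
            expect_identical(variantKeys(got), variantKeys(want))
        }
    }
    # stricter thresholds always retain a subset
    rb <- randomBulk(200, 7)
    loose <- variantKeys(hardFilter(rb, FilterThresholds(0.5, 4, 0, 1)))
    strict <- variantKeys(hardFilter(rb, FilterThresholds(0.9, 10, 60, 5)))
    expect_true(all(strict %in% loose))
})

test_that("absent quality fields pass permissively and are logged", {
    x <- BulkVariants(chrom = "Chr1", pos = c(1, 2), ref = "A", alt = "T",
                      qd = NA, gq = NA, dp = c(NA, 30),
                      adRef = c(NA, 0), adAlt = c(NA, 30),
                      gt = c("0/1", "1/1"))
    expect_message(kept <- hardFilter(x), "absent")
    expect_length(kept, 2L)
    res <- suppressMessages(hardFilter(x, details = TRUE))
    expect_identical(res$reasons$reason, c("pass", "pass"))
})

test_that("consequence filter retains only the requested classes", {
    mk <- function(effects) BulkVariants(
        chrom = "Chr1", pos = seq_along(effects) * 10, ref = "A", alt = "T",
        qd = 25, gq = 99, dp = 30, adRef = 0, adAlt = 30, gt = "1/1",
        effects = effects)
    x <- mk(list("synonymous|g1|t1",
                 c("synonymous|g2|t2", "frameshift|g2|t2", "intron|g2|t2"),
                 "missense|g3|t3", character(0)))
    kept <- consequenceFilter(x)
    expect_identical(start(kept), c(20L, 30L))
    # gene/locus tally on a 10-variant, 4-gene fixture: 10 loci, 4 genes
    genes <- rep(c("gA", "gB", "gC", "gD"), c(4, 3, 2, 1))
    y <- mk(lapply(genes, function(g) paste("missense", g, "t", sep = "|")))
    expect_identical(countLociGenes(y), c(loci = 10L, genes = 4L))
})

test_that("bulk subtraction partitions exactly by allele key", {
    a <- randomBulk(20, 1, bulk = "A")
    expect_length(bulkSubtract(a, a)$aSpecific, 0L)
    b <- randomBulk(20, 2, bulk = "B")
    shared <- variantKeys(a) %in% variantKeys(b)
    # with these seeds the two random sets share some keys by position
    parts <- bulkSubtract(a, b)
    expect_identical(length(parts$aSpecific) + length(parts$common),
                     length(a))
    expect_identical(length(parts$bSpecific) + length(parts$common),
                     length(b))
    expect_identical(sum(shared), length(parts$common))
    # construct the 13/13/7 example: 20+20 records with 7 shared keys
    a2 <- BulkVariants(chrom = "Chr1", pos = 1:20, ref = "A", alt = "T",
                       qd = 25, gq = 99, dp = 10, adRef = 0, adAlt = 10,
                       gt = "1/1", bulk = "A")
    b2 <- BulkVariants(chrom = "Chr1", pos = 14:33, ref = "A", alt = "T",
                       qd = 25, gq = 99, dp = 10, adRef = 0, adAlt = 10,
                       gt = "1/1", bulk = "B")
    p2 <- bulkSubtract(a2, b2)
    expect_identical(vapply(p2, length, integer(1)),
                     c(aSpecific = 13L, bSpecific = 13L, common = 7L))
    # disjoint inputs: nothing in common
    b3 <- BulkVariants(chrom = "Chr2", pos = 1:20, ref = "A", alt = "T",
                       qd = 25, gq = 99, dp = 10, adRef = 0, adAlt = 10,
                       gt = "1/1", bulk = "B")
    expect_length(bulkSubtract(a2, b3)$common, 0L)
    # duplicate keys within one bulk are a usage error
    dup <- BulkVariants(chrom = "Chr1", pos = c(5, 5), ref = "A", alt = "T",
                        qd = 25, gq = 99, dp = 10, adRef = 0, adAlt = 10,
                        gt = "1/1", bulk = "A")
    expect_error(bulkSubtract(dup, b2), "duplicate")
})

test_that("candidate scoring ranks causal-like evidence first", {
    effects <- list("missense|g1|t1", "missense|g2|t2", "frameshift|g3|t3",
                    "missense|g4|t4")
    cand <- BulkVariants(chrom = "Chr1", pos = c(100, 200, 300, 400),
                         ref = "A", alt = "T", qd = 25, gq = 99, dp = 25,
                         adRef = 0, adAlt = 25, gt = "1/1",
                         effects = effects, bulk = "mutant")
    # evidence: g3 is causal-like (mut 25/25, wt 6/24 at expected 0.25);
    # g1 has no wildtype support, g2 is balanced in the wildtype bulk,
    # g4 is heterozygous-looking in the mutant bulk
    ev <- S4Vectors::DataFrame(
        key = variantKeys(cand),
        mutAdRef = c(0, 0, 0, 13), mutAdAlt = c(25, 25, 25, 12),
        wtAdRef = c(24, 12, 18, 24), wtAdAlt = c(0, 12, 6, 0))
    d <- defaultDesigns()
    sc <- scoreCandidates(cand, d$mutant, d$wildtype, ev)

    # oracle: recompute each candidate's score with binom.test and sort
    oracle <- vapply(seq_len(4), function(i)
        -2 * (log(binom.test(ev$mutAdAlt[i], ev$mutAdRef[i] + ev$mutAdAlt[i],
                             0.99)$p.value) +
              log(binom.test(ev$wtAdAlt[i], ev$wtAdRef[i] + ev$wtAdAlt[i],
                             0.25)$p.value)), numeric(1))
    expect_equal(sc$combined[match(variantKeys(cand), sc$key)], oracle,
                 tolerance = 1e-9)
    expect_identical(sc$key[sc$rank == 1], variantKeys(cand)[3])
    # mutant-bulk fraction below the floor is flagged incompatible and
    # ranks after every unflagged candidate
    flagged <- sc[sc$key == variantKeys(cand)[4], ]
    expect_true(flagged$incompatible)
    expect_identical(flagged$rank, 4L)
})

test_that("score ties break by effect severity, then genomic order", {
    cand <- BulkVariants(chrom = "Chr1", pos = c(100, 200),
                         ref = "A", alt = "T", qd = 25, gq = 99, dp = 20,
                         adRef = 0, adAlt = 20, gt = "1/1",
                         effects = list("missense|g1|t1",
                                        "frameshift|g2|t2"),
                         bulk = "mutant")
    ev <- S4Vectors::DataFrame(key = variantKeys(cand),
                               mutAdRef = c(0, 0), mutAdAlt = c(20, 20),
                               wtAdRef = c(15, 15), wtAdAlt = c(5, 5))
    d <- defaultDesigns()
    sc <- scoreCandidates(cand, d$mutant, d$wildtype, ev)
    expect_identical(sc$effectClass[1], "frameshift")
    expect_identical(sc$rank[sc$pos == 200], 1L)
})

test_that("candidates without evidence in either bulk stay unranked", {
    cand <- BulkVariants(chrom = "Chr1", pos = c(100, 200), ref = "A",
                         alt = "T", qd = 25, gq = 99, dp = 20, adRef = 0,
                         adAlt = 20, gt = "1/1",
                         effects = list("missense|g|t", "missense|g|t"),
                         bulk = "mutant")
    ev <- S4Vectors::DataFrame(key = variantKeys(cand)[1],
                               mutAdRef = 0, mutAdAlt = 20,
                               wtAdRef = 15, wtAdAlt = 5)
    d <- defaultDesigns()
    sc <- scoreCandidates(cand, d$mutant, d$wildtype, ev)
    expect_identical(sc$status[sc$pos == 200], "no_evidence")
    expect_true(is.na(sc$rank[sc$pos == 200]))
    expect_identical(sc$rank[sc$pos == 100], 1L)
})

test_that("per-site index and window means match a naive recomputation", {
    x <- BulkVariants(chrom = "Chr1", pos = c(10, 20, 30), ref = "A",
                      alt = "T", qd = 25, gq = 99, dp = 10,
                      adRef = c(8, 6, 4), adAlt = c(2, 4, 6), gt = "0/1")
    win <- snpIndex(x, windowSize = 100, step = 100)
    expect_equal(win$meanIndex, 0.4)      # mean of 0.2, 0.4, 0.6
    expect_identical(win$nSites, 3L)
    one <- BulkVariants(chrom = "Chr1", pos = 10, ref = "A", alt = "T",
                        qd = 25, gq = 99, dp = 10, adRef = 0, adAlt = 10,
                        gt = "1/1")
    expect_equal(snpIndex(one, 100, 100)$meanIndex, 1.0)

    set.seed(5)
    n <- 100
    big <- BulkVariants(chrom = "Chr1", pos = sort(sample(1e4, n)),
                        ref = "A", alt = "T", qd = 25, gq = 99,
                        dp = 30, adRef = rbinom(n, 15, 0.5) + 1,
                        adAlt = rbinom(n, 15, 0.5) + 1, gt = "0/1")
    win <- snpIndex(big, windowSize = 1000, step = 500)
    idx <- mcols(big)$adAlt / (mcols(big)$adRef + mcols(big)$adAlt)
    for (r in seq_len(nrow(win))) {    # brute-force windowing oracle
        inWin <- start(big) >= win$start[r] & start(big) <= win$end[r]
        expect_equal(win$meanIndex[r], mean(idx[inWin]))
    }
})

test_that("IGV batch script has the documented layout and arithmetic", {
    cand <- BulkVariants(chrom = c("chr11", "chr2", "chr11"),
                         pos = c(1000000, 500, 2000), ref = "A", alt = "T",
                         qd = 25, gq = 99, dp = 10, adRef = 0, adAlt = 10,
                         gt = "1/1")
    lines <- writeIgvBatch(cand, "soy1", "snaps", flankBp = 500)
    expect_identical(lines[1:3],
                     c("new", "genome soy1", "snapshotDirectory snaps"))
    expect_identical(lines[4], "goto chr11:1500-2500")
    expect_identical(lines[6], "goto chr11:999500-1000500")
    expect_identical(lines[8], "goto chr2:1-1000")   # clipped at 1
    expect_length(lines, 9L)
    empty <- writeIgvBatch(cand[0], "soy1", "snaps")
    expect_length(empty, 3L)                          # header only
})

test_that("filtering stages only ever shrink the variant set", {
    for (seed in 1:5) {
        x <- randomBulk(120, seed + 300)
        f1 <- consequenceFilter(x)
        f2 <- hardFilter(f1)
        expect_true(all(variantKeys(f1) %in% variantKeys(x)))
        expect_true(all(variantKeys(f2) %in% variantKeys(f1)))
    }
})
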