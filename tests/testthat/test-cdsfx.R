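# 60 bp toy CDS: ATG + 18 non-stop codons + TAA
toyCds <- function() paste0("ATG", strrep("GCTACTGGA", 6), "TAA")

test_that("plus-strand edits change exactly the mapped bases", {
    cds <- toyCds()
    seg <- GRanges("Chr1", IRanges(501, 560), strand = "+")
    snp <- applyVariantToCds(cds, 510, substr(cds, 10, 10), "T", seg)
    expect_identical(snp$status, "coding")
    expect_identical(nchar(as.character(snp$cds)), 60L)
    diffAt <- which(strsplit(as.character(snp$cds), "")[[1]] !=
                    strsplit(cds, "")[[1]])
    expect_identical(diffAt, 10L)

    # 4 bp deletion shortens the CDS by exactly 4
    del <- applyVariantToCds(cds, 509, substr(cds, 9, 13),
                             substr(cds, 9, 9), seg)
    expect_identical(nchar(as.character(del$cds)), 56L)

    # outside the CDS: reported non-coding, no edit
    out <- applyVariantToCds(cds, 499, "A", "T", seg)
    expect_identical(out$status, "non_coding")
    expect_null(out$cds)
})

test_that("minus-strand edits equal a hand-built reverse-complement edit", {
    # gene on the minus strand at 101-160; CDS = revcomp(genomic)
    genomic <- strsplit(paste0(strrep("ACGTTGCA", 7), "ACGT"), "")[[1]]
    expect_length(genomic, 60L)
    seg <- GRanges("Chr1", IRanges(101, 160), strand = "-")
    cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(genomic, collapse = ""))))

    # SNP at genomic position 130 (= CDS position 160-130+1 = 31)
    refBase <- genomic[30]
    ed <- applyVariantToCds(cds, 130, genomic[130 - 100], "A", seg)
    mutGenomic <- genomic
    mutGenomic[30] <- "A"
    byHand <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(mutGenomic, collapse = ""))))
    expect_identical(as.character(ed$cds), byHand)

    # a genomic deletion removes the strand-mapped CDS bases
    ed2 <- applyVariantToCds(cds, 120,
                             paste(genomic[20:24], collapse = ""),
                             genomic[20], seg)
    mutGenomic2 <- genomic[-(21:24)]
    byHand2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(mutGenomic2, collapse = ""))))
    expect_identical(as.character(ed2$cds), byHand2)
})

test_that("edits straddling an intron boundary are refused", {
    cds <- toyCds()
    segs <- GRanges("Chr1", IRanges(c(501, 601), c(530, 630)), strand = "+")
    expect_error(
        applyVariantToCds(cds, 528, "NNNNN", "N", segs), "boundary")
})

test_that("translation lengths and classes follow the genetic code", {
    # a full-length CDS of 1734 bp ending in a stop encodes 577 residues
    syn <- syntheticTruncationCds(seed = 3)
    expect_identical(nchar(as.character(syn$wtCds)), 1734L)
    same <- translateAndClassify(syn$wtCds, syn$wtCds)
    expect_identical(same$wtProteinLen, 577L)
    expect_identical(same$effectClass, "synonymous")
    expect_identical(same$truncation, 0L)

    # the engineered 4 bp deletion truncates 577 -> 380 (197 residues)
    ed <- applyVariantToCds(syn$wtCds, syn$pos, syn$ref, syn$alt,
                            syn$cdsSegments)
    fx <- translateAndClassify(syn$wtCds, ed$cds)
    expect_identical(fx$effectClass, "frameshift")
    expect_identical(fx$wtProteinLen, 577L)
    expect_identical(fx$mutProteinLen, 380L)
    expect_identical(fx$truncation, 197L)
    expect_identical(fx$stopCodonPosition, 381L)

    # toy CDS with a 4 bp deletion at codon 5: hand translation oracle
    cds <- toyCds()
    seg <- GRanges("Chr1", IRanges(1, 60), strand = "+")
    ed2 <- applyVariantToCds(cds, 13, substr(cds, 13, 17),
                             substr(cds, 13, 13), seg)
    mutProt <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(as.character(ed2$cds), 1, 54)))))
    handLen <- regexpr("*", mutProt, fixed = TRUE) - 1L
    if (handLen < 0) handLen <- nchar(mutProt)
    fx2 <- translateAndClassify(cds, ed2$cds)
    expect_identical(fx2$effectClass, "frameshift")
    expect_identical(fx2$mutProteinLen, as.integer(handLen))

    expect_error(translateAndClassify("ATGNNNTAA", "ATGNNNTAA"), "position 4")
})

test_that("frame law: indel lengths divisible by three never frameshift", {
    set.seed(11)
    cds <- toyCds()
    seg <- GRanges("Chr1", IRanges(1, 60), strand = "+")
    for (i in 1:25) {
        len <- sample(c(1:6), 1)
        p <- sample(4:(56 - len), 1)
        ed <- applyVariantToCds(cds, p, substr(cds, p, p + len),
                                substr(cds, p, p), seg)
        fx <- translateAndClassify(cds, ed$cds)
        if (len %% 3 == 0) expect_false(fx$effectClass == "frameshift")
        else expect_identical(fx$effectClass, "frameshift")
    }
})

test_that("deleting then re-inserting restores the wildtype exactly", {
    syn <- syntheticTruncationCds(seed = 5)
    ed <- applyVariantToCds(syn$wtCds, syn$pos, syn$ref, syn$alt,
                            syn$cdsSegments)
    mutSegs <- GRanges("CDS", IRanges(1, 1730), strand = "+")
    back <- applyVariantToCds(ed$cds, syn$pos, syn$alt, syn$ref, mutSegs)
    expect_identical(as.character(back$cds), as.character(syn$wtCds))
    fx <- translateAndClassify(syn$wtCds, back$cds)
    expect_identical(fx$truncation, 0L)
    expect_identical(fx$effectClass, "synonymous")
})

test_that("truncation report carries the sign convention", {
    expect_identical(as.integer(truncationReport(577, 380)), 197L)
    expect_identical(as.integer(truncationReport(577, 577)), 0L)
    ext <- truncationReport(100, 120)
    expect_identical(as.integer(ext), -20L)
    expect_true(attr(ext, "extension"))
})

test_that("coding effects resolve per gene across a model set", {
    sim <- simulateBulkExperiment(SimScenario(seed = 41, nBackground = 60))
    vs <- sim$mutant
    cdsSeqs <- Biostrings::DNAStringSet(setNames(
        rep(paste0("ATG", strrep("GCT", 298), "TAA"),
            length(cdsByGene(sim$genes))), names(cdsByGene(sim$genes))))
    fx <- suppressWarnings(
        predictCodingEffect(vs[1:10], sim$genes, cdsSeqs))
    expect_identical(nrow(fx), 10L)
    expect_true(all(fx$effectClass[is.na(fx$geneId)] == "non_coding"))
})
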