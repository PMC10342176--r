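suppressMessages({
    library(GenomicRanges)
    library(Biostrings)
})

# hand-written VCF exercising multi-allelic records, a VCF-style deletion,
# both annotation dialects and a record without AD
writeHandVcf <- function(path) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
        paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional",
               " annotations: 'Allele | Annotation | Impact | Gene_Name |",
               " Gene_ID | Feature_Type | Feature_ID | Rank'\">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "bulkA", sep = "\t"),
        paste("Chr11", 100, ".", "A", "T", 50, "PASS",
              "QD=25;ANN=T|missense_variant|MODERATE|g1|g1|transcript|g1.1|1",
              "GT:AD:DP:GQ", "1/1:0,30:30:99", sep = "\t"),
        paste("Chr11", 200, ".", "ACTTG", "A", 60, "PASS",
              "QD=30;ANN=A|frameshift variation|HIGH|g2|g2|transcript|g2.1|3",
              "GT:AD:DP:GQ", "0/1:15,0:16:99", sep = "\t"),
        paste("Chr11", 300, ".", "G", "C,T", 40, "PASS",
              paste0("QD=12;ANN=C|synonymous_variant|LOW|g3|g3|transcript|",
                     "g3.1|1,T|missense_variant|MODERATE|g3|g3|transcript|",
                     "g3.1|1"),
              "GT:AD:DP:GQ", "1/2:2,14,13:30:87", sep = "\t"),
        paste("Chr11", 400, ".", "C", "G", 30, "PASS", "QD=9",
              "GT:DP:GQ", "0/1:22:55", sep = "\t")), path)
    path
}

# three-gene GFF3: one minus-strand two-exon gene, one gene with two
# transcripts, one plain gene with CDS parented directly by the gene
writeHandGff <- function(path) {
    writeLines(c(
        "##gff-version 3",
        "Chr1\ttest\tgene\t100\t400\t.\t+\t.\tID=gA",
        "Chr1\ttest\tmRNA\t100\t400\t.\t+\t.\tID=gA.1;Parent=gA",
        "Chr1\ttest\tCDS\t100\t199\t.\t+\t0\tID=gA.1.c1;Parent=gA.1",
        "Chr1\ttest\tCDS\t300\t400\t.\t+\t0\tID=gA.1.c2;Parent=gA.1",
        "Chr1\ttest\tgene\t1000\t1600\t.\t-\t.\tID=gB",
        "Chr1\ttest\tmRNA\t1000\t1600\t.\t-\t.\tID=gB.1;Parent=gB",
        "Chr1\ttest\tCDS\t1000\t1199\t.\t-\t0\tID=gB.1.c1;Parent=gB.1",
        "Chr1\ttest\tCDS\t1400\t1600\t.\t-\t0\tID=gB.1.c2;Parent=gB.1",
        "Chr1\ttest\tgene\t2000\t2299\t.\t+\t.\tID=gC",
        "Chr1\ttest\tCDS\t2000\t2299\t.\t+\t0\tID=gC.c1;Parent=gC"), path)
    path
}

# GFF3 emulating a deleted interval annotated with stride-100 locus ids
writeStrideGff <- function(path, first = 23700, last = 27700,
                           stride = 100, chromStart = 1695723) {
    nums <- seq(first, last, by = stride)
    starts <- chromStart + (seq_along(nums) - 1L) * 7000L
    lines <- c("##gff-version 3",
               sprintf("Chr11\ttest\tgene\t%d\t%d\t.\t+\t.\tID=Glyma.11G%06d",
                       starts, starts + 3000L, nums))
    writeLines(lines, path)
    path
}

# random BulkVariants set for filter/subtraction property tests
randomBulk <- function(n, seed, bulk = "bulk", chrom = "Chr1",
                       classes = c("missense", "frameshift", "synonymous",
                                   "intergenic")) {
    set.seed(seed)
    pos <- sort(sample(1e6, n))
    gt <- sample(c("0/1", "1/1"), n, replace = TRUE)
    adRef <- rpois(n, 12)
    adAlt <- rpois(n, 12)
    adRef[gt == "1/1"] <- rpois(sum(gt == "1/1"), 0.2)
    BulkVariants(
        chrom = rep(chrom, n), pos = pos,
        ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
        alt = sample(c("AT", "TTT"), n, replace = TRUE),
        qd = round(runif(n, 0, 35), 2),
        gq = sample(c(NA, 10:99), n, replace = TRUE),
        dp = adRef + adAlt + rpois(n, 1),
        adRef = adRef, adAlt = adAlt, gt = gt,
        effects = lapply(seq_len(n), function(i)
            paste(sample(classes, sample(1:2, 1)), "gene1", "tx1",
                  sep = "|")),
        bulk = bulk)
}

# rule-per-line reimplementation of the hard filter, kept deliberately
# independent of the package's vectorized version
oracleHardFilter <- function(x, minAB, minDP, minGQ, minQD) {
    m <- mcols(x)
    keep <- logical(length(x))
    for (i in seq_along(x)) {
        ok <- TRUE
        if (!is.na(m$dp[i]) && m$dp[i] < minDP) ok <- FALSE
        if (!is.na(m$gq[i]) && m$gq[i] < minGQ) ok <- FALSE
        if (!is.na(m$qd[i]) && m$qd[i] < minQD) ok <- FALSE
        if (!is.na(m$zygosity[i]) && m$zygosity[i] == "het") {
            tot <- m$adRef[i] + m$adAlt[i]
            if (!is.na(tot) && tot > 0 &&
                max(m$adRef[i], m$adAlt[i]) / tot < minAB) ok <- FALSE
        }
        keep[i] <- ok
    }
    x[keep]
}

defaultDesigns <- function() list(mutant = BulkDesign("mutant", 4),
                                  wildtype = BulkDesign("wildtype", 6,
                                                        hetCount = 3))
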