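#' Simulate a selfed family segregating 3:1 and assemble the bulks
#'
#' Progeny of a selfed heterozygous parent carry genotypes mm / Mm / MM in
#' the Mendelian 1/4 : 1/2 : 1/4 proportions; the phenotype is mutant iff
#' mm. The mutant bulk pools homozygous-mutant plants and the wildtype
#' bulk pools phenotypically wildtype plants. A fixed \code{wtHetCount}
#' forces the wildtype bulk's carrier composition; \code{NA} draws it from
#' the family, conditional on the wildtype phenotype (2/3 Mm, 1/3 MM).
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param setSeed seed the RNG from the scenario (disable when called
#'   within a larger seeded simulation).
#' @return a \linkS4class{SimTruth} (read-level fields filled by
#'   \code{\link{simulateReads}}).
#' @export
simulateFamily <- function(scenario, setSeed = TRUE) {
    stopifnot(is(scenario, "SimScenario"))
    if (setSeed) set.seed(scenario@seed)
    nm <- scenario@bulkMutantN; nw <- scenario@bulkWtN
    gm <- rep("mm", nm)
    if (!is.na(scenario@wtHetCount)) {
        gw <- c(rep("Mm", scenario@wtHetCount),
                rep("MM", nw - scenario@wtHetCount))
    } else {
        gw <- character(0)
        draws <- 0L
        maxDraws <- 10000L * (nm + nw)
        while (length(gw) < nw) {
            g <- sample(c("mm", "Mm", "MM"), 1,
                        prob = c(0.25, 0.5, 0.25))
            draws <- draws + 1L
            if (draws > maxDraws)
                stop("could not assemble the wildtype bulk in ",
                     maxDraws, " draws")
            if (g != "mm") gw <- c(gw, g)
        }
    }
    new("SimTruth", genotypesMutant = gm, genotypesWt = gw,
        wtAltFraction = sum(gw == "Mm") / (2 * nw),
        causalKey = character(0), deletion = scenario@deletion,
        deletedGenes = character(0))
}

.simGeneTable <- function(scenario) {
    n <- scenario@nGenes
    spacing <- floor(scenario@genomeLength / (n + 1))
    start <- (seq_len(n)) * spacing
    data.frame(gene_id = sprintf("SimG.01G%06d", seq_len(n) * 100),
               start = start, end = start + 899L,
               strand = rep(c("+", "-"), length.out = n),
               stringsAsFactors = FALSE)
}

.simGeneModels <- function(geneTab, chrom = "Chr01") {
    genes <- GRanges(chrom, IRanges(geneTab$start, geneTab$end),
                     strand = geneTab$strand)
    genes$gene_id <- geneTab$gene_id
    names(genes) <- geneTab$gene_id
    seg <- GRanges(chrom, IRanges(geneTab$start, geneTab$end),
                   strand = geneTab$strand)
    cds <- S4Vectors::split(seg, factor(geneTab$gene_id,
                                        levels = geneTab$gene_id))
    GeneModels(genes = genes, cds = cds)
}

# a simple caller model: a site becomes a VCF record when >= 2 alternate
# reads support it at an alternate fraction above 0.2; calls at fraction
# >= 0.8 are emitted homozygous, the rest heterozygous
.emitCall <- function(k, n) {
    af <- ifelse(n > 0, k / n, 0)
    emitted <- k >= 2 & af > 0.2
    gt <- ifelse(af >= 0.8, "1/1", "0/1")
    list(emitted = emitted, gt = gt)
}

#' Simulate read-level evidence, tracks and fixture files for one scenario
#'
#' Places the causal variant (a frameshifting deletion by default) inside
#' its gene's CDS and \code{nBackground} induced variants across the
#' genome; a configurable consequence mix includes synonymous decoys, and
#' frameshift decoys are emitted as 1 bp deletions. Shared background
#' variants are homozygous in both bulks; bulk-specific ones are
#' heterozygous at alternate fraction 0.5 x carrier-fraction with the
#' carrier fraction drawn per variant. At every site each bulk draws depth
#' from Poisson(\code{meanDepth}) and alternate reads from a binomial at
#' the error-adjusted allele fraction. Variant records pass through the
#' caller model above into per-bulk call sets; a site-evidence table keeps
#' the raw depths of both bulks at every site (the automated stand-in for
#' read inspection in a genome viewer). A planted deletion zeroes the
#' mutant bulk's depth, coverage windows and gene expression inside its
#' interval.
#'
#' With \code{dir} set, all fixture files are written: FASTA genome, GFF3
#' gene models, one VCF per bulk, bedGraph coverage, expression TSV,
#' evidence TSV and truth JSON. Identical seed and scenario give
#' byte-identical files.
#'
#' @param truth a \linkS4class{SimTruth} from \code{\link{simulateFamily}}.
#' @param scenario the \linkS4class{SimScenario} used to build it.
#' @param dir optional output directory for fixture files.
#' @param setSeed seed the RNG from the scenario (disable inside
#'   \code{\link{simulateBulkExperiment}}, which seeds once).
#' @return a list: \code{truth} (completed), \code{mutant} and
#'   \code{wildtype} \linkS4class{BulkVariants}, \code{evidence} table,
#'   \code{coverage} track, \code{expression} vector, \code{genes}
#'   \linkS4class{GeneModels}, and \code{files} (paths, or \code{NULL}).
#' @export
simulateReads <- function(truth, scenario, dir = NULL, setSeed = FALSE) {
    stopifnot(is(truth, "SimTruth"), is(scenario, "SimScenario"))
    if (setSeed) set.seed(scenario@seed)
    chrom <- "Chr01"
    L <- scenario@genomeLength
    err <- scenario@errorRate
    geneTab <- .simGeneTable(scenario)
    genes <- .simGeneModels(geneTab, chrom)

    # causal variant: an indel in the middle of its gene's CDS
    ci <- scenario@causalGene
    causalPos <- geneTab$start[ci] + 450L
    indel <- scenario@indelLength

    # background variant positions on a spaced grid, keeping clear of the
    # causal footprint
    grid <- seq(10L, L - 10L, by = 10L)
    grid <- grid[abs(grid - causalPos) > 10L]
    bgPos <- sort(sample(grid, scenario@nBackground))

    bases <- c("A", "C", "G", "T")
    nb <- scenario@nBackground
    geneIdx <- findInterval(bgPos, geneTab$start)
    inGene <- geneIdx >= 1L & bgPos <= geneTab$end[pmax(geneIdx, 1L)]
    cls <- ifelse(inGene,
                  sample(c("synonymous", "missense", "frameshift"), nb,
                         replace = TRUE, prob = c(0.45, 0.40, 0.15)),
                  "intergenic")
    isFs <- cls == "frameshift"
    refBase <- sample(bases, nb, replace = TRUE)
    ref <- ifelse(isFs, paste0(refBase,
                               sample(bases, nb, replace = TRUE)), refBase)
    alt <- ifelse(isFs, refBase,
                  vapply(refBase, function(b)
                      sample(setdiff(bases, b), 1), character(1)))
    shared <- runif(nb) < scenario@sharedFraction
    toMutant <- runif(nb) < 0.5
    carrier <- runif(nb)
    fMut <- ifelse(shared, 1, ifelse(toMutant, 0.5 * carrier, 0))
    fWt <- ifelse(shared, 1, ifelse(toMutant, 0, 0.5 * carrier))

    causalRefExtra <- paste(sample(bases, indel, replace = TRUE),
                            collapse = "")
    causalAnchor <- sample(bases, 1)
    pos <- c(bgPos, causalPos)
    ref <- c(ref, paste0(causalAnchor, causalRefExtra))
    alt <- c(alt, causalAnchor)
    cls <- c(cls, scenario@causalClass)
    gene <- c(ifelse(inGene, geneTab$gene_id[pmax(geneIdx, 1L)], ""),
              geneTab$gene_id[ci])
    fMut <- c(fMut, 1)
    fWt <- c(fWt, truth@wtAltFraction)
    ord <- order(pos)
    pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]; cls <- cls[ord]
    gene <- gene[ord]; fMut <- fMut[ord]; fWt <- fWt[ord]
    nv <- length(pos)

    inDeletion <- if (length(truth@deletion) == 2L)
        pos > truth@deletion[1] & pos <= truth@deletion[2]
    else rep(FALSE, nv)

    depthMut <- rpois(nv, scenario@meanDepth)
    depthMut[inDeletion] <- 0L   # homozygous deletion: no mutant reads
    depthWt <- rpois(nv, scenario@meanDepth)
    altMut <- rbinom(nv, depthMut, fMut * (1 - err) + (1 - fMut) * err)
    altWt <- rbinom(nv, depthWt, fWt * (1 - err) + (1 - fWt) * err)
    qd <- round(runif(nv, 10, 35), 2)

    effects <- CharacterList(lapply(seq_len(nv), function(i)
        if (nzchar(gene[i]))
            paste(cls[i], gene[i], paste0(gene[i], ".1"), sep = "|")
        else paste(cls[i], "", "", sep = "|")))

    buildBulk <- function(k, n, label) {
        call <- .emitCall(k, n)
        sel <- call$emitted
        BulkVariants(chrom = rep(chrom, sum(sel)), pos = pos[sel],
                     ref = ref[sel], alt = alt[sel], qd = qd[sel],
                     gq = 99, dp = n[sel], adRef = n[sel] - k[sel],
                     adAlt = k[sel], gt = call$gt[sel],
                     effects = effects[sel], bulk = label)
    }
    mutant <- buildBulk(altMut, depthMut, "mutant")
    wildtype <- buildBulk(altWt, depthWt, "wildtype")

    keys <- paste(chrom, pos, ref, alt, sep = ":")
    evidence <- DataFrame(key = keys,
                          mutAdRef = depthMut - altMut, mutAdAlt = altMut,
                          wtAdRef = depthWt - altWt, wtAdAlt = altWt)

    winStarts <- seq(0L, L - 1L, by = 1000L)
    winEnds <- pmin(winStarts + 1000L, L)
    depth <- as.numeric(rpois(length(winStarts), scenario@meanDepth))
    if (length(truth@deletion) == 2L) {
        inside <- winStarts >= truth@deletion[1] &
            winEnds <= truth@deletion[2]
        depth[inside] <- 0
    }
    coverage <- GRanges(chrom, IRanges(winStarts + 1L, winEnds))
    coverage$score <- depth

    expression <- setNames(round(rlnorm(nrow(geneTab), log(20), 0.6), 2),
                           geneTab$gene_id)
    deletedGenes <- character(0)
    if (length(truth@deletion) == 2L) {
        deletedGenes <- genesInInterval(genes, chrom, truth@deletion[1],
                                        truth@deletion[2])
        expression[deletedGenes] <- 0
    }

    truth@causalKey <- keys[pos == causalPos]
    truth@deletedGenes <- deletedGenes

    files <- NULL
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        files <- file.path(dir, c(genome = "genome.fasta",
                                  gff = "genes.gff3",
                                  mutant = "mutant.vcf",
                                  wildtype = "wildtype.vcf",
                                  coverage = "coverage.bedGraph",
                                  expression = "expression.tsv",
                                  evidence = "evidence.tsv",
                                  truth = "truth.json"))
        names(files) <- c("genome", "gff", "mutant", "wildtype",
                          "coverage", "expression", "evidence", "truth")
        seedLine <- paste0("##simulation_seed=", scenario@seed)

        # genome drawn last so the evidence stream above is identical
        # whether or not files are written
        genome <- sample(bases, L, replace = TRUE)
        refSplit <- strsplit(ref, "")
        for (i in seq_len(nv))   # FASTA agrees with each REF footprint
            genome[pos[i]:(pos[i] + nchar(ref[i]) - 1L)] <- refSplit[[i]]
        gseq <- DNAStringSet(paste(genome, collapse = ""))
        names(gseq) <- chrom
        writeXStringSet(gseq, files["genome"])

        gffLines <- c("##gff-version 3", paste0("#", seedLine),
            unlist(lapply(seq_len(nrow(geneTab)), function(i) {
                g <- geneTab[i, ]
                c(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          chrom, g$start, g$end, g$strand, g$gene_id),
                  sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                          chrom, g$start, g$end, g$strand, g$gene_id,
                          g$gene_id),
                  sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
                          chrom, g$start, g$end, g$strand, g$gene_id,
                          g$gene_id))
            })))
        writeLines(gffLines, files["gff"])

        writeBulkVcf(mutant, files["mutant"], headerLines = seedLine)
        writeBulkVcf(wildtype, files["wildtype"], headerLines = seedLine)
        writeLines(sprintf("%s\t%d\t%d\t%g", chrom, winStarts, winEnds,
                           depth), files["coverage"])
        writeLines(c(sprintf("#%s", seedLine),
                     sprintf("%s\t%g", names(expression), expression)),
                   files["expression"])
        writeLines(c(paste0("# ", seedLine),
                     "key\tmutAdRef\tmutAdAlt\twtAdRef\twtAdAlt",
                     sprintf("%s\t%d\t%d\t%d\t%d", keys,
                             depthMut - altMut, altMut,
                             depthWt - altWt, altWt)), files["evidence"])
        write_json(list(seed = scenario@seed,
                        causalKey = truth@causalKey,
                        wtAltFraction = truth@wtAltFraction,
                        genotypesMutant = truth@genotypesMutant,
                        genotypesWt = truth@genotypesWt,
                        deletion = truth@deletion,
                        deletedGenes = truth@deletedGenes),
                   files["truth"], auto_unbox = TRUE, digits = NA)
    }

    list(truth = truth, mutant = mutant, wildtype = wildtype,
         evidence = evidence, coverage = coverage, expression = expression,
         genes = genes, files = files)
}

#' Run one full synthetic experiment
#'
#' Seeds the RNG once from the scenario, simulates the family and then the
#' read-level evidence; see \code{\link{simulateFamily}} and
#' \code{\link{simulateReads}}.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param dir optional output directory for fixture files.
#' @return the \code{\link{simulateReads}} result list.
#' @export
simulateBulkExperiment <- function(scenario = SimScenario(), dir = NULL) {
    set.seed(scenario@seed)
    truth <- simulateFamily(scenario, setSeed = FALSE)
    simulateReads(truth, scenario, dir = dir, setSeed = FALSE)
}

#' Read the simulator's site-evidence table back from disk
#'
#' @param path evidence TSV written by \code{\link{simulateReads}}.
#' @return a \code{DataFrame} usable by \code{\link{scoreCandidates}}.
#' @export
readEvidenceTable <- function(path) {
    if (!file.exists(path)) stop("evidence file not found: ", path)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    DataFrame(key = tab$key, mutAdRef = tab$mutAdRef,
              mutAdAlt = tab$mutAdAlt, wtAdRef = tab$wtAdRef,
              wtAdAlt = tab$wtAdAlt)
}

#' Synthetic CDS reproducing a frameshift truncation, for validation
#'
#' Constructs a synthetic 1734 bp coding sequence (577 residues plus a
#' terminal stop) together with a 4 bp deletion placed so the shifted
#' reading frame meets its first stop after residue 380 — the length
#' arithmetic of a frameshift-truncated protein, built from scratch since
#' the real allele's genomic coordinate is not public. All non-anchored
#' codons are drawn at random from the non-stop codons.
#'
#' @param seed RNG seed for the random codons.
#' @return a list: \code{wtCds} (\code{DNAString}), the deletion as
#'   \code{pos}/\code{ref}/\code{alt} in CDS coordinates (VCF anchor
#'   convention), and a single-exon plus-strand \code{cdsSegments} model
#'   starting at CDS coordinate 1.
#' @export
syntheticTruncationCds <- function(seed = 1) {
    set.seed(seed)
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    nonStop <- setdiff(codons, c("TAA", "TAG", "TGA"))
    cd <- c("ATG", sample(nonStop, 576, replace = TRUE), "TGA")
    s <- strsplit(paste(cd, collapse = ""), "")[[1]]
    # anchor the frame-shifted stop: deleting bases 1141-1144 makes TAA
    # (bases 1145-1147) the 381st codon of the mutant frame
    s[1144:1149] <- c("C", "T", "A", "A", "A", "A")
    wt <- paste(s, collapse = "")
    list(wtCds = DNAString(wt),
         pos = 1140L,
         ref = substr(wt, 1140, 1144),
         alt = substr(wt, 1140, 1140),
         cdsSegments = GRanges("CDS", IRanges(1, nchar(wt)), strand = "+"))
}
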