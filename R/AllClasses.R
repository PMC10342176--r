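#' Per-bulk variant calls
#'
#' A \code{BulkVariants} object holds the biallelic variant records of one
#' sequenced bulk, one row per (position, alternate allele). It extends
#' \link[GenomicRanges]{GRanges}; each range spans the reference allele.
#' Metadata columns: \code{ref}, \code{alt}, \code{vclass} (snp, insertion,
#' deletion), \code{qd}, \code{gq}, \code{dp}, \code{adRef}, \code{adAlt},
#' \code{gt} (genotype string as called), \code{zygosity} (hom/het) and
#' \code{effects}, a \link[IRanges]{CharacterList} of
#' \code{"class|gene|transcript"} consequence annotations.
#'
#' @slot bulk single string labelling the bulk (e.g. \code{"mutant"}).
#' @export
setClass("BulkVariants", contains = "GRanges",
         representation(bulk = "character"))

.BULKVAR_COLS <- c("ref", "alt", "vclass", "qd", "gq", "dp",
                   "adRef", "adAlt", "gt", "zygosity", "effects")

setValidity("BulkVariants", function(object) {
    msg <- character(0)
    miss <- setdiff(.BULKVAR_COLS, colnames(mcols(object)))
    if (length(miss))
        msg <- c(msg, paste("missing metadata columns:",
                            paste(miss, collapse = ", ")))
    if (length(object@bulk) != 1L || is.na(object@bulk))
        msg <- c(msg, "'bulk' must be a single non-NA string")
    if (!length(msg)) {
        m <- mcols(object)
        if (any(start(object) < 1L))
            msg <- c(msg, "positions must be >= 1")
        if (any(m$ref == m$alt, na.rm = TRUE))
            msg <- c(msg, "alt allele must differ from ref")
        bad <- !is.na(m$adRef) & !is.na(m$adAlt) & !is.na(m$dp) &
            (m$adRef + m$adAlt > m$dp)
        if (any(bad))
            msg <- c(msg, "adRef + adAlt must not exceed dp")
        if (!is(m$effects, "CharacterList"))
            msg <- c(msg, "'effects' must be a CharacterList")
    }
    if (length(msg)) msg else TRUE
})

.variantClass <- function(ref, alt) {
    ifelse(nchar(alt) > nchar(ref), "insertion",
           ifelse(nchar(alt) < nchar(ref), "deletion", "snp"))
}

.zygosityFromGT <- function(gt) {
    alleles <- strsplit(gt, "[/|]")
    vapply(alleles, function(a) {
        a <- a[a != "."]
        if (!length(a)) return(NA_character_)
        if (length(unique(a)) > 1L) "het" else "hom"
    }, character(1))
}

#' Construct a BulkVariants object
#'
#' @param chrom,pos,ref,alt parallel vectors defining each record.
#' @param qd,gq,dp,adRef,adAlt numeric quality and depth fields; \code{NA}
#'   marks an absent field.
#' @param gt genotype strings (\code{"0/1"} etc.); zygosity is derived.
#' @param effects a \code{CharacterList} (or plain list) of
#'   \code{"class|gene|transcript"} strings per record.
#' @param bulk label of the bulk the records belong to.
#' @return a \code{BulkVariants} object sorted by genomic position.
#' @export
BulkVariants <- function(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         qd = NA_real_, gq = NA_real_, dp = NA_real_,
                         adRef = NA_real_, adAlt = NA_real_,
                         gt = NA_character_, effects = NULL,
                         bulk = "bulk") {
    n <- length(pos)
    if (is.null(effects)) effects <- vector("list", n)
    if (!is(effects, "CharacterList")) effects <- CharacterList(effects)
    gr <- GRanges(chrom, IRanges(as.integer(pos),
                                 width = pmax(nchar(ref), 1L)))
    mcols(gr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        vclass = .variantClass(ref, alt),
        qd = rep_len(as.numeric(qd), n), gq = rep_len(as.numeric(gq), n),
        dp = rep_len(as.numeric(dp), n),
        adRef = rep_len(as.numeric(adRef), n),
        adAlt = rep_len(as.numeric(adAlt), n),
        gt = rep_len(as.character(gt), n),
        zygosity = .zygosityFromGT(rep_len(as.character(gt), n)),
        effects = effects)
    out <- new("BulkVariants", gr, bulk = bulk)
    sort(out)
}

#' Bulk composition under a stated inheritance model
#'
#' Describes one sequenced pool: its phenotypic role, the number of pooled
#' plants and, when known, how many of them are heterozygous carriers.
#' Only the monogenic-recessive model in a selfed heterozygous-parent family
#' is currently implemented.
#'
#' @slot role \code{"mutant"} or \code{"wildtype"}.
#' @slot nPlants number of pooled plants.
#' @slot hetCount heterozygous plants in the pool; \code{NA} when unknown.
#' @slot inheritance inheritance model identifier.
#' @slot family family structure identifier.
#' @export
setClass("BulkDesign",
         representation(role = "character", nPlants = "integer",
                        hetCount = "integer", inheritance = "character",
                        family = "character"))

setValidity("BulkDesign", function(object) {
    msg <- character(0)
    if (!object@role %in% c("mutant", "wildtype"))
        msg <- c(msg, "role must be 'mutant' or 'wildtype'")
    if (object@nPlants < 1L)
        msg <- c(msg, "nPlants must be positive")
    if (!is.na(object@hetCount)) {
        if (object@role == "mutant")
            msg <- c(msg, paste("hetCount must not be set on a mutant bulk:",
                     "recessive homozygotes only"))
        else if (object@hetCount < 0L || object@hetCount > object@nPlants)
            msg <- c(msg, "hetCount must lie in [0, nPlants]")
    }
    if (object@inheritance != "monogenic_recessive")
        msg <- c(msg, "only inheritance = 'monogenic_recessive' is supported")
    if (length(msg)) msg else TRUE
})

#' @rdname BulkDesign-class
#' @param role,nPlants,hetCount,inheritance,family see slots.
#' @export
BulkDesign <- function(role, nPlants, hetCount = NA,
                       inheritance = "monogenic_recessive",
                       family = "selfed_het_parent") {
    new("BulkDesign", role = role, nPlants = as.integer(nPlants),
        hetCount = as.integer(hetCount), inheritance = inheritance,
        family = family)
}

#' Hard-filter thresholds for per-bulk variant calls
#'
#' Thresholds applied to each call: minimum allele balance of heterozygous
#' calls (\code{minAB}, major-allele fraction), minimum depth (\code{minDP}),
#' minimum genotype quality (\code{minGQ}) and minimum quality-by-depth
#' (\code{minQD}). Defaults are 0.8 / 6 / 0 / 2.
#'
#' @slot minAB,minDP,minGQ,minQD numeric thresholds, all \code{>= 0},
#'   \code{minAB} in [0, 1].
#' @export
setClass("FilterThresholds",
         representation(minAB = "numeric", minDP = "numeric",
                        minGQ = "numeric", minQD = "numeric"))

setValidity("FilterThresholds", function(object) {
    msg <- character(0)
    if (object@minAB < 0 || object@minAB > 1)
        msg <- c(msg, "minAB must lie in [0, 1]")
    if (object@minDP < 0 || object@minGQ < 0 || object@minQD < 0)
        msg <- c(msg, "thresholds must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname FilterThresholds-class
#' @param minAB,minDP,minGQ,minQD see slots.
#' @export
FilterThresholds <- function(minAB = 0.8, minDP = 6, minGQ = 0, minQD = 2) {
    new("FilterThresholds", minAB = minAB, minDP = minDP,
        minGQ = minGQ, minQD = minQD)
}

#' Gene models read from a GFF3 annotation
#'
#' @slot genes a \code{GRanges} of gene loci with metadata column
#'   \code{gene_id}; names are gene ids.
#' @slot cds a \code{GRangesList}, one element per gene (named by gene id),
#'   holding that gene's CDS segments of the primary transcript ordered
#'   5'-to-3' in transcription orientation.
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", cds = "GRangesList"))

setValidity("GeneModels", function(object) {
    msg <- character(0)
    if (is.null(object@genes$gene_id))
        msg <- c(msg, "genes must carry a gene_id metadata column")
    extra <- setdiff(names(object@cds), names(object@genes))
    if (length(extra))
        msg <- c(msg, "cds entries must correspond to genes")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneModels-class
#' @param genes,cds see slots.
#' @export
GeneModels <- function(genes, cds = GRangesList()) {
    if (is.null(names(genes))) names(genes) <- genes$gene_id
    new("GeneModels", genes = genes, cds = cds)
}

#' Parameterization of a synthetic bulk-sequencing experiment
#'
#' Captures everything needed to regenerate one synthetic experiment: a
#' selfed family segregating 3:1 for a recessive causal variant, background
#' induced variants (shared between bulks or bulk-specific), Poisson read
#' depth with binomial alternate-read sampling at a fixed error rate, and
#' optionally a large genomic deletion zeroing coverage and expression.
#'
#' @slot seed RNG seed.
#' @slot genomeLength synthetic genome length in bp.
#' @slot nGenes number of evenly spaced gene models.
#' @slot nBackground number of background induced variants.
#' @slot sharedFraction fraction of background variants present in both bulks.
#' @slot causalGene index of the gene carrying the causal variant.
#' @slot causalClass consequence class of the causal variant.
#' @slot indelLength deleted length of the causal indel (bp).
#' @slot bulkMutantN,bulkWtN plants pooled per bulk.
#' @slot wtHetCount heterozygotes in the wildtype bulk; \code{NA} draws the
#'   composition from the 3:1 family.
#' @slot meanDepth mean per-bulk read depth at a site.
#' @slot errorRate per-read sequencing error rate.
#' @slot deletion numeric(2) 0-based half-open interval of a planted
#'   deletion, or numeric(0) for none.
#' @export
setClass("SimScenario",
         representation(seed = "integer", genomeLength = "integer",
                        nGenes = "integer", nBackground = "integer",
                        sharedFraction = "numeric", causalGene = "integer",
                        causalClass = "character", indelLength = "integer",
                        bulkMutantN = "integer", bulkWtN = "integer",
                        wtHetCount = "integer", meanDepth = "numeric",
                        errorRate = "numeric", deletion = "numeric"))

setValidity("SimScenario", function(object) {
    msg <- character(0)
    if (object@sharedFraction < 0 || object@sharedFraction > 1)
        msg <- c(msg, "sharedFraction must lie in [0, 1]")
    if (object@causalGene < 1L || object@causalGene > object@nGenes)
        msg <- c(msg, "causalGene must index an existing gene")
    if (any(c(object@genomeLength, object@nGenes, object@nBackground,
              object@bulkMutantN, object@bulkWtN) < 1L))
        msg <- c(msg, "all counts must be positive")
    if (!is.na(object@wtHetCount) &&
        (object@wtHetCount < 0L || object@wtHetCount > object@bulkWtN))
        msg <- c(msg, "wtHetCount must lie in [0, bulkWtN]")
    if (length(object@deletion) %in% c(0L, 2L) == FALSE)
        msg <- c(msg, "deletion must be numeric(0) or numeric(2)")
    if (length(object@deletion) == 2L &&
        object@deletion[2] <= object@deletion[1])
        msg <- c(msg, "deletion end must exceed start")
    if (length(msg)) msg else TRUE
})

#' @rdname SimScenario-class
#' @param seed,genomeLength,nGenes,nBackground,sharedFraction,causalGene,causalClass,indelLength,bulkMutantN,bulkWtN,wtHetCount,meanDepth,errorRate,deletion
#'   see slots. Defaults describe the standard validation scenario: a 2 Mb
#'   genome with 200 genes, 1000 background variants half of them shared,
#'   30x depth, 1 percent error, bulks of 4 mutant and 6 wildtype plants of
#'   which 3 are heterozygous, and a frameshifting 4 bp causal deletion.
#' @export
SimScenario <- function(seed = 1L, genomeLength = 2e6, nGenes = 200,
                        nBackground = 1000, sharedFraction = 0.5,
                        causalGene = 101, causalClass = "frameshift",
                        indelLength = 4, bulkMutantN = 4, bulkWtN = 6,
                        wtHetCount = 3, meanDepth = 30, errorRate = 0.01,
                        deletion = numeric(0)) {
    new("SimScenario", seed = as.integer(seed),
        genomeLength = as.integer(genomeLength), nGenes = as.integer(nGenes),
        nBackground = as.integer(nBackground),
        sharedFraction = sharedFraction, causalGene = as.integer(causalGene),
        causalClass = causalClass, indelLength = as.integer(indelLength),
        bulkMutantN = as.integer(bulkMutantN), bulkWtN = as.integer(bulkWtN),
        wtHetCount = as.integer(wtHetCount), meanDepth = meanDepth,
        errorRate = errorRate, deletion = as.numeric(deletion))
}

#' Ground truth of a simulated experiment
#'
#' @slot genotypesMutant,genotypesWt per-plant genotypes ("mm", "Mm", "MM")
#'   of each bulk.
#' @slot wtAltFraction true mutant-allele read fraction of the wildtype bulk.
#' @slot causalKey \code{"chrom:pos:ref:alt"} key of the planted causal
#'   variant (filled once reads are simulated).
#' @slot deletion planted deletion interval (0-based half-open) or
#'   numeric(0).
#' @slot deletedGenes gene ids inside the planted deletion.
#' @export
setClass("SimTruth",
         representation(genotypesMutant = "character",
                        genotypesWt = "character",
                        wtAltFraction = "numeric",
                        causalKey = "character",
                        deletion = "numeric",
                        deletedGenes = "character"))
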