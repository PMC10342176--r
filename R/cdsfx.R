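# genomic positions of a gene's CDS in transcription (5'->3') order
.cdsGenomicPositions <- function(cdsSegments) {
    unlist(lapply(seq_along(cdsSegments), function(i) {
        s <- start(cdsSegments)[i]; e <- end(cdsSegments)[i]
        if (as.character(strand(cdsSegments)[i]) == "-") e:s else s:e
    }))
}

#' Apply a variant to a gene's coding sequence
#'
#' Maps the variant's genomic footprint (the REF allele span) onto the CDS
#' coordinate system of the gene — respecting strand, so a minus-strand
#' gene is edited on the reverse complement — and substitutes the ALT
#' allele. Variants lying entirely outside the CDS are reported
#' \code{"non_coding"} without an edit; edits whose footprint straddles an
#' intron boundary (non-contiguous in CDS coordinates) are rejected.
#'
#' @param cds wildtype CDS as a \code{DNAString} (or string), 5'-to-3'.
#' @param pos,ref,alt the variant in genomic coordinates (VCF convention:
#'   indels share their first base).
#' @param cdsSegments the gene's CDS segments as returned in
#'   \code{\link{cdsByGene}} (a \code{GRanges}, transcription order).
#' @return a list with \code{status} (\code{"coding"} or
#'   \code{"non_coding"}) and \code{cds}, the edited \code{DNAString}
#'   (\code{NULL} when non-coding).
#' @export
applyVariantToCds <- function(cds, pos, ref, alt, cdsSegments) {
    cds <- DNAString(as.character(cds))
    map <- .cdsGenomicPositions(cdsSegments)
    if (length(map) != length(cds))
        stop("CDS length (", length(cds), ") does not match the gene ",
             "model's segments (", length(map), " bp)")
    footprint <- pos:(pos + nchar(ref) - 1L)
    idx <- match(footprint, map)
    if (all(is.na(idx)))
        return(list(status = "non_coding", cds = NULL))
    if (anyNA(idx) || (length(idx) > 1 && any(abs(diff(idx)) != 1L)))
        stop("variant footprint spans a CDS boundary; refusing to edit")
    minus <- idx[1] > idx[length(idx)] || (length(idx) == 1 &&
        as.character(strand(cdsSegments)[1]) == "-")
    lo <- min(idx); hi <- max(idx)
    refCds <- as.character(subseq(cds, lo, hi))
    expect <- if (minus)
        as.character(reverseComplement(DNAString(ref))) else ref
    if (refCds != expect)
        warning("CDS sequence disagrees with the variant's REF allele at ",
                pos, " (found ", refCds, ", expected ", expect, ")")
    altCds <- if (minus)
        as.character(reverseComplement(DNAString(alt))) else alt
    mut <- paste0(as.character(subseq(cds, 1, lo - 1)), altCds,
                  if (hi < length(cds))
                      as.character(subseq(cds, hi + 1, length(cds)))
                  else "")
    list(status = "coding", cds = DNAString(mut))
}

.proteinFromCds <- function(cds) {
    s <- as.character(cds)
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0)
        stop("non-ACGT base '", substr(s, bad, bad), "' at CDS position ",
             bad)
    n <- nchar(s) - nchar(s) %% 3
    if (n < 3) return(list(length = 0L, stopCodon = NA_integer_,
                           protein = ""))
    aa <- as.character(suppressWarnings(
        translate(DNAString(substr(s, 1, n)))))
    stopAt <- as.integer(regexpr("*", aa, fixed = TRUE))
    if (stopAt > 0)
        list(length = stopAt - 1L, stopCodon = stopAt,
             protein = substr(aa, 1, stopAt - 1))
    else
        list(length = nchar(aa), stopCodon = NA_integer_, protein = aa)
}

#' Translate wildtype and mutant CDS and classify the coding effect
#'
#' Protein length is the number of residues before the first in-frame stop
#' codon (the stop itself is not counted, so a 1734 bp CDS ending in a stop
#' encodes 577 residues). The effect class is \code{"frameshift"} when the
#' two CDS lengths differ by a non-multiple of 3; otherwise the translated
#' proteins decide: identical means \code{"synonymous"}, an earlier mutant
#' stop means \code{"stop_gain"}, a lost stop means \code{"stop_loss"},
#' any other substitution \code{"missense"}. A mutant CDS with no stop at
#' all is flagged \code{noStop}.
#'
#' @param wtCds,mutCds wildtype and mutant CDS (\code{DNAString} or
#'   string); the wildtype is expected to begin with a start codon and
#'   contain an in-frame stop.
#' @param geneId optional identifier carried through to the report.
#' @return a one-row \code{DataFrame}: geneId, effectClass, wtProteinLen,
#'   mutProteinLen, truncation, stopCodonPosition, noStop.
#' @export
translateAndClassify <- function(wtCds, mutCds, geneId = NA_character_) {
    wt <- .proteinFromCds(wtCds)
    mut <- .proteinFromCds(mutCds)
    if (substr(as.character(wtCds), 1, 3) != "ATG")
        warning("wildtype CDS does not begin with ATG")
    if (is.na(wt$stopCodon))
        warning("wildtype CDS has no in-frame stop codon")
    delta <- nchar(as.character(wtCds)) - nchar(as.character(mutCds))
    # premature = a stop before the last complete codon of that CDS
    premature <- !is.na(mut$stopCodon) &&
        mut$stopCodon < nchar(as.character(mutCds)) %/% 3
    cls <- if (delta %% 3 != 0) "frameshift"
        else if (wt$protein == mut$protein &&
                 identical(wt$stopCodon, mut$stopCodon)) "synonymous"
        else if (is.na(mut$stopCodon)) "stop_loss"
        else if (premature && mut$length < wt$length) "stop_gain"
        else "missense"
    DataFrame(geneId = geneId, effectClass = cls,
              wtProteinLen = wt$length, mutProteinLen = mut$length,
              truncation = wt$length - mut$length,
              stopCodonPosition = mut$stopCodon,
              noStop = is.na(mut$stopCodon))
}

#' Truncation of the mutant protein in residues
#'
#' Positive values are residues lost to truncation; a negative value marks
#' a C-terminal extension (as after a lost stop codon) and is flagged.
#'
#' @param wtLen,mutLen wildtype and mutant protein lengths in residues.
#' @return the signed truncation, with attribute \code{extension} set when
#'   negative.
#' @examples
#' truncationReport(577, 380)   # 197
#' @export
truncationReport <- function(wtLen, mutLen) {
    stopifnot(wtLen >= 0, mutLen >= 0)
    out <- wtLen - mutLen
    attr(out, "extension") <- out < 0
    out
}

#' Predict coding effects of variants over a set of gene models
#'
#' For each variant, locates the gene whose CDS footprint contains it,
#' applies the edit and classifies the consequence. Variants outside every
#' CDS are reported with effect class \code{"non_coding"} and no lengths.
#'
#' @param variants a \linkS4class{BulkVariants} object.
#' @param genes a \linkS4class{GeneModels} object.
#' @param cdsSeqs a named \code{DNAStringSet} of wildtype CDS per gene.
#' @return a \code{DataFrame}, one row per variant.
#' @export
predictCodingEffect <- function(variants, genes, cdsSeqs) {
    stopifnot(is(variants, "BulkVariants"), is(genes, "GeneModels"))
    cdsList <- cdsByGene(genes)
    rows <- lapply(seq_along(variants), function(i) {
        v <- variants[i]
        key <- variantKeys(v)
        hit <- NULL
        for (g in names(cdsList)) {
            segs <- cdsList[[g]]
            if (as.character(seqnames(v)) %in% as.character(seqnames(segs))
                && any(start(v) >= start(segs) & start(v) <= end(segs))) {
                hit <- g; break
            }
        }
        if (is.null(hit) || !hit %in% names(cdsSeqs))
            return(DataFrame(key = key, geneId = NA_character_,
                             effectClass = "non_coding",
                             wtProteinLen = NA_integer_,
                             mutProteinLen = NA_integer_,
                             truncation = NA_integer_,
                             stopCodonPosition = NA_integer_,
                             noStop = NA))
        ed <- applyVariantToCds(cdsSeqs[[hit]], start(v), mcols(v)$ref,
                                mcols(v)$alt, cdsList[[hit]])
        if (ed$status == "non_coding")
            return(DataFrame(key = key, geneId = hit,
                             effectClass = "non_coding",
                             wtProteinLen = NA_integer_,
                             mutProteinLen = NA_integer_,
                             truncation = NA_integer_,
                             stopCodonPosition = NA_integer_,
                             noStop = NA))
        res <- translateAndClassify(cdsSeqs[[hit]], ed$cds, geneId = hit)
        cbind(DataFrame(key = key), res)
    })
    do.call(rbind, rows)
}
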