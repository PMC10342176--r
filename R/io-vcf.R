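#' Canonicalize consequence-class strings
#'
#' Both annotation dialects are accepted case-insensitively
#' (\code{"missense_variant"} as annotators write it, \code{"missense
#' variation"} as humans write it); unknown classes pass through
#' lower-cased with separators normalized so downstream matching stays
#' exact.
#'
#' @param x character vector of consequence-class strings.
#' @return canonical class tokens (\code{"missense"}, \code{"frameshift"},
#'   \code{"stop_gain"}, ...).
#' @export
normalizeEffectClass <- function(x) {
    x <- tolower(trimws(x))
    x <- gsub("[ -]+", "_", x)
    x <- sub("_(variant|variation)$", "", x)
    map <- c(stop_gained = "stop_gain", stop_lost = "stop_loss",
             intergenic_region = "intergenic", intron = "intron",
             frameshift = "frameshift", missense = "missense",
             synonymous = "synonymous")
    out <- unname(map[x])
    ifelse(is.na(out), x, out)
}

.parseAnn <- function(annEntries, altAllele) {
    if (!length(annEntries)) return(character(0))
    fields <- strsplit(annEntries, "|", fixed = TRUE)
    alleles <- vapply(fields, `[`, character(1), 1L)
    keep <- alleles == altAllele
    # annotators encode indel alleles in more than one convention; when no
    # entry names this alt verbatim, keep all entries rather than drop them
    if (!any(keep)) keep <- rep(TRUE, length(fields))
    vapply(fields[keep], function(f) {
        cls <- normalizeEffectClass(if (length(f) >= 2) f[2] else "")
        gene <- if (length(f) >= 5 && nzchar(f[5])) f[5]
                else if (length(f) >= 4) f[4] else ""
        tx <- if (length(f) >= 7) f[7] else ""
        paste(cls, gene, tx, sep = "|")
    }, character(1))
}

.genoField <- function(vcf, field, sampleIdx, default = NA_real_) {
    g <- geno(vcf)
    if (!field %in% names(g)) return(rep(default, nrow(vcf)))
    as.numeric(g[[field]][, sampleIdx])
}

#' Read one bulk's variant calls from a VCF file
#'
#' Reads a VCF 4.x file, decomposes multi-allelic records into one row per
#' alternate allele, and normalizes each record into a
#' \linkS4class{BulkVariants} row. Allele depths are taken from the
#' per-sample \code{AD} field (reference count plus the count of the row's
#' alternate); records without \code{AD} are retained with the depth fields
#' set to \code{NA}. Consequence annotations are parsed from the pipe-
#' delimited \code{ANN} INFO field (effect class, gene, transcript), matched
#' to the row's alternate allele where the annotation names it.
#'
#' @param path VCF file.
#' @param bulk label to attach to the returned object.
#' @param sample sample name to read when the file holds several; a
#'   single-sample file needs no selector.
#' @return a \code{BulkVariants} object.
#' @export
readBulkVcf <- function(path, bulk = "bulk", sample = NULL) {
    if (!file.exists(path))
        stop("VCF file not found: ", path)
    vcf <- tryCatch(suppressWarnings(readVcf(path)),
                    error = function(e)
                        stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    vcf <- VariantAnnotation::expand(vcf)
    samples <- colnames(vcf)
    if (is.null(sample)) {
        if (length(samples) > 1L)
            stop("VCF has ", length(samples),
                 " samples; name one with 'sample='")
        sampleIdx <- 1L
    } else {
        sampleIdx <- match(sample, samples)
        if (is.na(sampleIdx))
            stop("sample '", sample, "' not present in ", path)
    }
    rr <- rowRanges(vcf)
    refs <- as.character(ref(vcf))
    alts <- as.character(alt(vcf))

    g <- geno(vcf)
    if ("AD" %in% names(g)) {
        ad <- g$AD
        adRef <- as.numeric(ad[, sampleIdx, 1L])
        adAlt <- as.numeric(ad[, sampleIdx, 2L])
    } else {
        adRef <- adAlt <- rep(NA_real_, nrow(vcf))
    }
    dp <- .genoField(vcf, "DP", sampleIdx)
    gq <- .genoField(vcf, "GQ", sampleIdx)
    qd <- if ("QD" %in% colnames(info(vcf))) as.numeric(info(vcf)$QD)
          else rep(NA_real_, nrow(vcf))
    gt <- if ("GT" %in% names(g)) as.character(g$GT[, sampleIdx])
          else rep(NA_character_, nrow(vcf))

    annAll <- if ("ANN" %in% colnames(info(vcf))) info(vcf)$ANN
              else CharacterList(vector("list", nrow(vcf)))
    effects <- CharacterList(lapply(seq_len(nrow(vcf)), function(i)
        .parseAnn(annAll[[i]], alts[i])))

    BulkVariants(chrom = as.character(seqnames(rr)), pos = start(rr),
                 ref = refs, alt = alts, qd = qd, gq = gq, dp = dp,
                 adRef = adRef, adAlt = adAlt, gt = gt,
                 effects = effects, bulk = bulk)
}

.effectToAnn <- function(eff, alt) {
    if (!length(eff)) return(".")
    parts <- strsplit(eff, "|", fixed = TRUE)
    paste(vapply(parts, function(p) {
        p <- c(p, rep("", max(0, 3 - length(p))))
        paste(alt, p[1], "MODIFIER", p[2], p[2], "transcript", p[3], "1",
              sep = "|")
    }, character(1)), collapse = ",")
}

#' Write BulkVariants back to a VCF file
#'
#' Emits a minimal VCF 4.2 file (single sample named after the bulk label)
#' carrying GT, AD, DP, GQ, the QD INFO field and re-serialized ANN
#' annotations. Reading the file back with \code{\link{readBulkVcf}} yields
#' the same records.
#'
#' @param x a \code{BulkVariants} object.
#' @param path output file.
#' @param headerLines extra \code{##}-prefixed header lines to embed.
#' @return \code{path}, invisibly.
#' @export
writeBulkVcf <- function(x, path, headerLines = character(0)) {
    m <- mcols(x)
    fmtNum <- function(v) ifelse(is.na(v), ".",
                                 sub("\\.?0+$", "", sprintf("%.4f", v)))
    fmtInt <- function(v) ifelse(is.na(v), ".", as.character(as.integer(v)))
    hdr <- c("##fileformat=VCFv4.2", headerLines,
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
        paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional",
               " annotations: 'Allele | Annotation | Impact | Gene_Name |",
               " Gene_ID | Feature_Type | Feature_ID | Rank'\">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
               "Description=\"Genotype quality\">"),
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", x@bulk, sep = "\t"))
    if (length(x)) {
        info <- paste0("QD=", fmtNum(m$qd), ";ANN=",
                       vapply(seq_along(x), function(i)
                           .effectToAnn(m$effects[[i]], m$alt[i]),
                           character(1)))
        info <- sub(";ANN=\\.$", "", info)
        sampleCol <- paste(ifelse(is.na(m$gt), "./.", m$gt),
                           ifelse(is.na(m$adRef) | is.na(m$adAlt), ".",
                                  paste0(fmtInt(m$adRef), ",",
                                         fmtInt(m$adAlt))),
                           fmtInt(m$dp), fmtInt(m$gq), sep = ":")
        recs <- paste(as.character(seqnames(x)), start(x), ".", m$ref,
                      m$alt, "100", "PASS", info, "GT:AD:DP:GQ", sampleCol,
                      sep = "\t")
    } else recs <- character(0)
    writeLines(c(hdr, recs), path)
    invisible(path)
}
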