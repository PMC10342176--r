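#' Read gene models from a GFF3 file
#'
#' Builds one \linkS4class{GeneModels} entry per \code{gene} feature.
#' CDS features are linked to their gene through \code{Parent} attributes,
#' following one mRNA level of indirection when present; the first
#' transcript (by id) is taken as the primary transcript of each gene.
#' CDS segments are returned 5'-to-3' in transcription orientation, i.e.
#' reversed relative to genomic order on the minus strand. CDS features
#' whose parent cannot be resolved are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return a \code{GeneModels} object.
#' @export
readGff3Genes <- function(path) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    gff <- import(path, format = "gff3")
    type <- as.character(gff$type)
    genes <- gff[type == "gene"]
    genes$gene_id <- as.character(genes$ID)
    names(genes) <- genes$gene_id
    mcols(genes) <- mcols(genes)[, "gene_id", drop = FALSE]
    genes <- sort(genes, ignore.strand = TRUE)

    mrna <- gff[type %in% c("mRNA", "transcript")]
    txParent <- setNames(vapply(mrna$Parent, function(p)
        if (length(p)) p[[1]] else NA_character_, character(1)),
        as.character(mrna$ID))

    cds <- gff[type == "CDS"]
    cdsParent <- vapply(cds$Parent, function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
    # a CDS parent is either an mRNA id or directly a gene id
    cdsGene <- ifelse(cdsParent %in% names(txParent),
                      txParent[cdsParent], cdsParent)
    bad <- is.na(cdsGene) | !cdsGene %in% genes$gene_id
    if (any(bad)) {
        warning(sum(bad), " CDS feature(s) without a resolvable parent ",
                "gene were skipped")
        cds <- cds[!bad]
        cdsParent <- cdsParent[!bad]
        cdsGene <- cdsGene[!bad]
    }
    # restrict to the primary (first) transcript where several share a gene
    primary <- vapply(base::split(cdsParent, cdsGene), function(tx)
        sort(unique(tx))[1], character(1))
    keep <- cdsParent == primary[cdsGene]
    cds <- cds[keep]
    cdsGene <- cdsGene[keep]

    mcols(cds) <- NULL
    cdsList <- S4Vectors::split(cds, factor(cdsGene,
                                                levels = genes$gene_id))
    cdsList <- cdsList[lengths(cdsList) > 0]
    cdsList <- GRangesList(lapply(cdsList, function(gr) {
        gr <- sort(gr)
        if (as.character(strand(gr)[1]) == "-") gr[seq(length(gr), 1)]
        else gr
    }))
    GeneModels(genes = genes, cds = cdsList)
}

#' Read a bedGraph coverage track
#'
#' Intervals are 0-based half-open in the file and returned as a 1-based
#' \code{GRanges} with the depth in the \code{score} column. Overlapping
#' intervals are rejected; unsorted input is rejected with a hint to sort.
#'
#' @param path bedGraph file.
#' @return a sorted \code{GRanges} with a \code{score} metadata column.
#' @export
readCoverage <- function(path) {
    if (!file.exists(path)) stop("bedGraph file not found: ", path)
    gr <- import(path, format = "bedGraph")
    if (!isDisjoint(gr))
        stop("bedGraph intervals overlap in ", path)
    srt <- sort(gr)
    if (!identical(start(srt), start(gr)) ||
        !identical(as.character(seqnames(srt)), as.character(seqnames(gr))))
        stop("bedGraph is not coordinate-sorted: ", path,
             " (sort it, e.g. with 'sort -k1,1 -k2,2n')")
    if (any(gr$score < 0)) stop("negative depth in ", path)
    gr
}

#' Read a two-column gene expression table
#'
#' Plain TSV with gene id and expression value; lines starting with
#' \code{#} are ignored. A header line is detected when the second field is
#' not numeric.
#'
#' @param path TSV file.
#' @return a named numeric vector (possibly empty).
#' @export
readExpression <- function(path) {
    if (!file.exists(path)) stop("expression file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines)) return(setNames(numeric(0), character(0)))
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) < 2L))
        stop("expression table must have two tab-separated columns: ", path)
    vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
    ids <- vapply(parts, `[`, character(1), 1L)
    if (is.na(vals[1]) && length(vals) >= 1L) {  # header line
        ids <- ids[-1]; vals <- vals[-1]
    }
    if (anyNA(vals)) stop("non-numeric expression value in ", path)
    setNames(vals, ids)
}
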