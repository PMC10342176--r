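.callGenes <- function(calls, genes) {
    if (is.null(genes)) {
        calls$nGenes <- rep(NA_integer_, length(calls))
        calls$genes <- CharacterList(vector("list", length(calls)))
        return(calls)
    }
    gr <- geneRanges(genes)
    hits <- findOverlaps(calls, gr)
    gl <- lapply(seq_along(calls), function(i) {
        g <- gr[subjectHits(hits)[queryHits(hits) == i]]
        g <- g[order(start(g))]
        unique(collapseSpliceSuffix(g$gene_id))
    })
    calls$genes <- CharacterList(gl)
    calls$nGenes <- lengths(calls$genes)
    calls
}

.meanDepthIn <- function(track, region) {
    ov <- findOverlaps(region, track)
    if (!length(ov)) return(NA_real_)
    pieces <- pintersect(rep(region, length(ov)), track[subjectHits(ov)])
    w <- width(pieces)
    sum(track$score[subjectHits(ov)] * w) / sum(w)
}

#' Detect large deletions as runs of (near-)zero coverage
#'
#' Scans a windowed coverage track for maximal runs of windows whose mean
#' depth is at most \code{zeroThreshold}, merges runs separated by at most
#' \code{maxGap} bases, and keeps runs spanning at least \code{minLength}.
#' Boundaries are reported at window resolution. The mean depth inside each
#' call and over \code{minLength} flanking bases each side is attached as
#' evidence, and overlapping gene models are listed when provided.
#'
#' @param track coverage \code{GRanges} with a \code{score} column (see
#'   \code{\link{readCoverage}}).
#' @param zeroThreshold maximum depth still counted as absence of signal.
#' @param minLength minimum span of a reported call, in bases.
#' @param maxGap maximum base gap bridged when merging sub-threshold runs.
#' @param genes optional \linkS4class{GeneModels} for gene listing.
#' @return a \code{GRanges} of calls with evidence metadata (empty when the
#'   track is empty or no run qualifies).
#' @export
detectDeletions <- function(track, zeroThreshold = 2, minLength = 5e4,
                            maxGap = 0, genes = NULL) {
    stopifnot(minLength > 0, maxGap >= 0)
    empty <- GRanges()
    if (!length(track)) return(.callGenes(empty, genes))
    sub <- track[track$score <= zeroThreshold]
    if (!length(sub)) return(.callGenes(empty, genes))
    calls <- reduce(sub, min.gapwidth = maxGap + 1)
    calls <- calls[width(calls) >= minLength]
    if (!length(calls)) return(.callGenes(empty, genes))
    calls$evidence <- "coverage"
    calls$meanInside <- vapply(seq_along(calls), function(i)
        .meanDepthIn(track, calls[i]), numeric(1))
    calls$meanFlank <- vapply(seq_along(calls), function(i) {
        ch <- as.character(seqnames(calls)[i])
        left <- GRanges(ch, IRanges(max(1, start(calls)[i] - minLength),
                                    max(1, start(calls)[i] - 1)))
        right <- GRanges(ch, IRanges(end(calls)[i] + 1,
                                     end(calls)[i] + minLength))
        mean(c(.meanDepthIn(track, left), .meanDepthIn(track, right)),
             na.rm = TRUE)
    }, numeric(1))
    .callGenes(calls, genes)
}

#' Detect deleted regions as runs of unexpressed genes
#'
#' Walks the genes of each chromosome in genomic order and reports maximal
#' runs of at least \code{minRun} consecutive genes whose expression is at
#' most \code{zeroThreshold}; each run becomes one call spanning the first
#' gene's start to the last gene's end. Genes present in the expression
#' table but absent from the annotation are ignored with a message; genes
#' missing from the table break a run (no evidence either way).
#'
#' @param expr named numeric vector of per-gene expression.
#' @param genes a \linkS4class{GeneModels} object.
#' @param zeroThreshold maximum expression still counted as silence.
#' @param minRun minimum number of consecutive silent genes.
#' @return a \code{GRanges} of calls listing the silent genes.
#' @export
deletedGenesFromExpression <- function(expr, genes, zeroThreshold = 0.1,
                                       minRun = 3) {
    stopifnot(is(genes, "GeneModels"), minRun >= 1)
    gr <- geneRanges(genes)
    unknown <- setdiff(names(expr), gr$gene_id)
    if (length(unknown))
        message(length(unknown), " expressed gene id(s) not in the ",
                "annotation were ignored")
    out <- GRanges()
    for (ch in unique(as.character(seqnames(gr)))) {
        g <- gr[as.character(seqnames(gr)) == ch]
        g <- g[order(start(g))]
        val <- expr[g$gene_id]
        silent <- !is.na(val) & val <= zeroThreshold
        r <- rle(silent)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (j in which(r$values & r$lengths >= minRun)) {
            run <- g[starts[j]:ends[j]]
            call <- GRanges(ch, IRanges(min(start(run)), max(end(run))))
            call$evidence <- "expression"
            call$meanInside <- mean(val[starts[j]:ends[j]])
            call$meanFlank <- NA_real_
            call$genes <- CharacterList(list(
                unique(collapseSpliceSuffix(run$gene_id))))
            call$nGenes <- lengths(call$genes)
            out <- c(out, call)
        }
    }
    out
}

#' Strip splice-variant suffixes from locus identifiers
#'
#' \code{"Glyma.11G023700.1"} and \code{"Glyma.11G023700.2"} both collapse
#' to the primary locus \code{"Glyma.11G023700"}; ids without a trailing
#' numeric suffix are returned unchanged.
#'
#' @param ids character vector of locus/transcript identifiers.
#' @return character vector of primary locus identifiers.
#' @export
collapseSpliceSuffix <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Genes intersecting a genomic interval
#'
#' @param genes a \linkS4class{GeneModels} object.
#' @param chrom chromosome name.
#' @param start0,end0 0-based half-open interval bounds.
#' @return gene ids (splice suffixes collapsed) of genes whose span
#'   intersects the interval, sorted by gene start.
#' @export
genesInInterval <- function(genes, chrom, start0, end0) {
    stopifnot(end0 > start0)
    gr <- geneRanges(genes)
    if (!chrom %in% as.character(seqnames(gr))) {
        warning("chromosome '", chrom, "' not present in the annotation")
        return(character(0))
    }
    q <- GRanges(chrom, IRanges(start0 + 1, end0))  # to 1-based inclusive
    hit <- subsetByOverlaps(gr, q)
    hit <- hit[order(start(hit))]
    unique(collapseSpliceSuffix(hit$gene_id))
}

#' Count loci in a stride-numbered identifier range
#'
#' Locus identifiers of the form \code{<prefix><digits>} numbered at a
#' fixed stride (e.g. \code{Glyma.11G023700} to \code{Glyma.11G027700} at
#' stride 100) span \code{(last - first)/stride + 1} loci.
#'
#' @param firstId,lastId boundary locus identifiers sharing a prefix.
#' @param stride numbering stride between adjacent loci.
#' @return the locus count.
#' @examples
#' countLocusIdRange("Glyma.11G023700", "Glyma.11G027700")  # 41
#' @export
countLocusIdRange <- function(firstId, lastId, stride = 100) {
    parse1 <- function(id) {
        m <- regmatches(id, regexec("^(.*?)([0-9]+)$", id))[[1]]
        if (length(m) != 3)
            stop("identifier has no numeric suffix: ", id)
        list(prefix = m[2], suffix = as.numeric(m[3]), width = nchar(m[3]))
    }
    a <- parse1(firstId); b <- parse1(lastId)
    if (a$prefix != b$prefix || a$width != b$width)
        stop("identifiers do not share a prefix/suffix layout: ",
             firstId, " vs ", lastId)
    d <- b$suffix - a$suffix
    if (d < 0) stop("lastId numbers below firstId")
    if (d %% stride != 0)
        stop("suffixes are not aligned to stride ", stride)
    as.integer(d / stride + 1)
}
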