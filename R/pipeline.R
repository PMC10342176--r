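.asBulk <- function(x, bulk, sample = NULL) {
    if (is(x, "BulkVariants")) return(x)
    readBulkVcf(x, bulk = bulk, sample = sample)
}

#' Run the bulk-variant prioritization pipeline end to end
#'
#' Chains the stages of the mapping-by-sequencing workflow: read both
#' bulks' calls, hard-filter each (\code{\link{hardFilter}}), restrict to
#' damaging consequence classes (\code{\link{consequenceFilter}}), remove
#' calls shared between bulks (\code{\link{bulkSubtract}}), and score the
#' mutant-bulk-specific candidates against the allele fractions the bulk
#' designs predict (\code{\link{scoreCandidates}}). Stage tallies are
#' recorded per bulk; a ranked candidate table, an IGV batch script and a
#' JSON-able run manifest are returned and, when \code{outDir} is set,
#' written to disk (\code{candidates.tsv}, \code{igv_batch.txt},
#' \code{manifest.json}). Output is deterministic for fixed inputs and
#' configuration.
#'
#' @param mutant,wildtype per-bulk calls: \linkS4class{BulkVariants}
#'   objects or VCF paths.
#' @param mutantDesign,wtDesign \linkS4class{BulkDesign} objects.
#' @param thresholds a \linkS4class{FilterThresholds}.
#' @param classes consequence classes retained by the consequence filter.
#' @param evidence optional site-evidence table (see
#'   \code{\link{evidenceFromBulks}}, \code{\link{readEvidenceTable}});
#'   when \code{NULL} it is assembled from the two raw call sets.
#' @param errorRate,minMutantFraction scoring parameters.
#' @param outDir optional report directory.
#' @param genomeId,flankBp IGV batch-script parameters.
#' @return a list: \code{candidates} (ranked \code{DataFrame}),
#'   \code{tallies}, \code{igvBatch} lines, \code{config}, and the
#'   intermediate variant sets (\code{mutantSpecific},
#'   \code{wildtypeSpecific}, \code{common}).
#' @export
runPipeline <- function(mutant, wildtype, mutantDesign, wtDesign,
                        thresholds = FilterThresholds(),
                        classes = c("missense", "frameshift"),
                        evidence = NULL, errorRate = 0.01,
                        minMutantFraction = 0.9, outDir = NULL,
                        genomeId = "custom", flankBp = 500) {
    mutRaw <- .asBulk(mutant, "mutant")
    wtRaw <- .asBulk(wildtype, "wildtype")
    if (is.null(evidence))
        evidence <- evidenceFromBulks(mutRaw, wtRaw)

    mutFilt <- hardFilter(mutRaw, thresholds)
    wtFilt <- hardFilter(wtRaw, thresholds)
    mutCons <- consequenceFilter(mutFilt, classes)
    wtCons <- consequenceFilter(wtFilt, classes)
    parts <- bulkSubtract(mutCons, wtCons)
    scored <- scoreCandidates(parts$aSpecific, mutantDesign, wtDesign,
                              evidence, errorRate = errorRate,
                              minMutantFraction = minMutantFraction)
    tallies <- list(
        mutant = c(raw = length(mutRaw), hard_filter = length(mutFilt),
                   consequence = length(mutCons),
                   bulk_specific = length(parts$aSpecific)),
        wildtype = c(raw = length(wtRaw), hard_filter = length(wtFilt),
                     consequence = length(wtCons),
                     bulk_specific = length(parts$bSpecific)),
        common = length(parts$common))
    config <- list(
        tool = "bulkscan", version = as.character(packageVersion("bulkscan")),
        minAB = thresholds@minAB, minDP = thresholds@minDP,
        minGQ = thresholds@minGQ, minQD = thresholds@minQD,
        classes = classes, errorRate = errorRate,
        minMutantFraction = minMutantFraction,
        mutantDesign = sprintf("mutant:n=%d", mutantDesign@nPlants),
        wtDesign = sprintf("wildtype:n=%d,het=%s", wtDesign@nPlants,
                           ifelse(is.na(wtDesign@hetCount), "unknown",
                                  wtDesign@hetCount)),
        expectedWtFraction = expectedAltFraction(wtDesign))
    batch <- writeIgvBatch(scored[!is.na(scored$rank), , drop = FALSE],
                           genomeId, if (is.null(outDir)) "snapshots"
                                     else file.path(outDir, "snapshots"),
                           flankBp)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        hdr <- sprintf("# %s %s | %s", config$tool, config$version,
                       paste(sprintf("%s=%s", names(config)[3:9], vapply(
                           config[3:9], function(v)
                               paste(v, collapse = ","),
                           character(1))), collapse = " "))
        tsv <- file.path(outDir, "candidates.tsv")
        writeLines(hdr, tsv)
        suppressWarnings(write.table(as.data.frame(scored), tsv, sep = "\t",
                    quote = FALSE, row.names = FALSE, append = TRUE))
        writeLines(batch, file.path(outDir, "igv_batch.txt"))
        write_json(list(config = config, tallies = tallies),
                   file.path(outDir, "manifest.json"),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(candidates = scored, tallies = tallies, igvBatch = batch,
         config = config, mutantSpecific = parts$aSpecific,
         wildtypeSpecific = parts$bSpecific, common = parts$common)
}
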