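#' Hard-filter variant calls on depth, quality and allele balance
#'
#' A call is retained iff \code{dp >= minDP}, \code{gq >= minGQ},
#' \code{qd >= minQD}, and — for heterozygous calls only — its major-allele
#' balance \code{max(adRef, adAlt) / (adRef + adAlt)} is at least
#' \code{minAB}. With the default \code{minAB = 0.8} a heterozygous call
#' therefore passes only on strongly skewed read support; balanced
#' heterozygous evidence is removed, which is what empties the wildtype
#' bulk of the causal call while its read-level support remains visible to
#' \code{\link{scoreCandidates}}. Absent QD/GQ/AD fields are treated as
#' passing their rule (permissive, matching a threshold of 0) and counted
#' in the attached drop log.
#'
#' @param x a \linkS4class{BulkVariants} object.
#' @param thresholds a \linkS4class{FilterThresholds} object.
#' @param details also return per-record pass/fail reasons.
#' @return the retained subset; with \code{details = TRUE}, a list of
#'   \code{retained} and a \code{reasons} \code{DataFrame}.
#' @export
hardFilter <- function(x, thresholds = FilterThresholds(),
                       details = FALSE) {
    stopifnot(is(x, "BulkVariants"), is(thresholds, "FilterThresholds"))
    m <- mcols(x)
    passDP <- is.na(m$dp) | m$dp >= thresholds@minDP
    passGQ <- is.na(m$gq) | m$gq >= thresholds@minGQ
    passQD <- is.na(m$qd) | m$qd >= thresholds@minQD
    tot <- m$adRef + m$adAlt
    majorAB <- ifelse(is.na(tot) | tot == 0, NA_real_,
                      pmax(m$adRef, m$adAlt) / tot)
    isHet <- !is.na(m$zygosity) & m$zygosity == "het"
    passAB <- !isHet | is.na(majorAB) | majorAB >= thresholds@minAB
    keep <- passDP & passGQ & passQD & passAB
    nAbsent <- sum(is.na(m$dp) | is.na(m$gq) | is.na(m$qd) |
                   (isHet & is.na(majorAB)))
    if (nAbsent)
        message(nAbsent, " record(s) had absent quality fields treated ",
                "as passing")
    if (details) {
        reason <- rep("pass", length(x))
        reason[!passAB] <- "allele_balance"
        reason[!passQD] <- "qd"
        reason[!passGQ] <- "gq"
        reason[!passDP] <- "dp"
        return(list(retained = x[keep],
                    reasons = DataFrame(key = variantKeys(x),
                                        retained = keep, reason = reason)))
    }
    x[keep]
}

#' Restrict variants to damaging consequence classes
#'
#' Retains a variant iff any of its consequence annotations belongs to one
#' of the requested classes (default: missense and frameshift, the classes
#' a loss-of-function screen of an induced mutant focuses on). Class
#' strings are canonicalized, so both \code{"missense_variant"} and
#' \code{"missense variation"} match \code{"missense"}.
#'
#' @param x a \linkS4class{BulkVariants} object.
#' @param classes consequence classes to retain.
#' @return the retained subset.
#' @export
consequenceFilter <- function(x, classes = c("missense", "frameshift")) {
    stopifnot(is(x, "BulkVariants"))
    classes <- normalizeEffectClass(classes)
    keep <- vapply(as.list(mcols(x)$effects), function(eff) {
        if (!length(eff)) return(FALSE)
        any(vapply(strsplit(eff, "|", fixed = TRUE), `[`,
                   character(1), 1L) %in% classes)
    }, logical(1))
    x[keep]
}

#' Count distinct loci and genes in a variant set
#'
#' @param x a \linkS4class{BulkVariants} object.
#' @param classes restrict the gene tally to effects of these classes;
#'   \code{NULL} counts genes of every annotated effect.
#' @return named integer vector \code{c(loci = ..., genes = ...)}.
#' @export
countLociGenes <- function(x, classes = NULL) {
    effs <- unlist(as.list(mcols(x)$effects), use.names = FALSE)
    genes <- character(0)
    if (length(effs)) {
        parts <- strsplit(effs, "|", fixed = TRUE)
        cls <- vapply(parts, `[`, character(1), 1L)
        g <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
                    character(1))
        if (!is.null(classes)) g <- g[cls %in% normalizeEffectClass(classes)]
        genes <- unique(g[nzchar(g)])
    }
    c(loci = length(x), genes = length(genes))
}

#' Partition two bulks' calls into bulk-specific and shared sets
#'
#' Identity is the full allele key (chrom, pos, ref, alt). Presence means a
#' call in that bulk's (typically filtered) set — not read-level support;
#' read-level re-examination is the job of \code{\link{scoreCandidates}}.
#' The partition is exact: \code{aSpecific} plus \code{common} reconstitute
#' bulk A.
#'
#' @param a,b \linkS4class{BulkVariants} objects from the same reference.
#' @return list of \code{aSpecific}, \code{bSpecific}, \code{common}
#'   (records taken from bulk A).
#' @export
bulkSubtract <- function(a, b) {
    stopifnot(is(a, "BulkVariants"), is(b, "BulkVariants"))
    ka <- variantKeys(a); kb <- variantKeys(b)
    if (anyDuplicated(ka))
        stop("duplicate variant keys within bulk '", a@bulk, "'")
    if (anyDuplicated(kb))
        stop("duplicate variant keys within bulk '", b@bulk, "'")
    list(aSpecific = a[!ka %in% kb],
         bSpecific = b[!kb %in% ka],
         common = a[ka %in% kb])
}

#' Assemble per-candidate read evidence from two bulks' raw calls
#'
#' Builds the site-evidence table \code{\link{scoreCandidates}} consumes,
#' from the unfiltered per-bulk call sets. Sites absent from a bulk's VCF
#' have no depth evidence there and will surface as \code{"no_evidence"}
#' candidates; supply a dedicated site-evidence table (as the simulator
#' emits) when read-level counts at uncalled sites are available.
#'
#' @param mutant,wildtype \linkS4class{BulkVariants} objects.
#' @return a \code{DataFrame} keyed by variant with per-bulk allele depths.
#' @export
evidenceFromBulks <- function(mutant, wildtype) {
    km <- variantKeys(mutant); kw <- variantKeys(wildtype)
    keys <- union(km, kw)
    im <- match(keys, km); iw <- match(keys, kw)
    DataFrame(key = keys,
              mutAdRef = mcols(mutant)$adRef[im],
              mutAdAlt = mcols(mutant)$adAlt[im],
              wtAdRef = mcols(wildtype)$adRef[iw],
              wtAdAlt = mcols(wildtype)$adAlt[iw])
}

.EFFECT_SEVERITY <- c("frameshift", "stop_gain", "missense")

.bestEffect <- function(eff, order = .EFFECT_SEVERITY) {
    if (!length(eff)) return(list(class = NA_character_,
                                  rank = length(order) + 1L))
    cls <- vapply(strsplit(eff, "|", fixed = TRUE), `[`, character(1), 1L)
    r <- match(cls, order)
    r[is.na(r)] <- length(order) + 1L
    i <- which.min(r)
    list(class = cls[i], rank = r[i])
}

#' Score and rank candidate causal variants by segregation consistency
#'
#' For each candidate (normally the mutant-bulk-specific variants after
#' filtering) the allele depths of both bulks are tested against the
#' fractions Mendelian segregation predicts: the mutant bulk against
#' fraction 1 and the wildtype bulk against
#' \code{\link{expectedAltFraction}} of its design, each with the exact
#' two-sided binomial test of \code{\link{binomialConsistency}}. The two
#' p-values are Fisher-combined, \eqn{-2(\ln p_m + \ln p_w)}; smaller
#' means more consistent with a causal recessive variant. Candidates whose
#' mutant-bulk alternate fraction falls below \code{minMutantFraction} are
#' flagged incompatible (a truly causal recessive site must be nearly
#' homozygous in the mutant bulk) and rank after all unflagged candidates.
#' Ties are broken by effect severity (frameshift, then stop-gain, then
#' missense), then genomic order. Candidates lacking depth evidence in
#' either bulk are reported unranked with status \code{"no_evidence"}.
#'
#' @param candidates a \linkS4class{BulkVariants} object.
#' @param mutantDesign,wtDesign \linkS4class{BulkDesign} objects.
#' @param evidence a site-evidence \code{DataFrame} as produced by
#'   \code{\link{evidenceFromBulks}} (columns key, mutAdRef, mutAdAlt,
#'   wtAdRef, wtAdAlt).
#' @param errorRate sequencing error rate for expectation clamping.
#' @param minMutantFraction incompatibility floor on the mutant-bulk
#'   alternate fraction.
#' @return a \code{DataFrame}, one row per candidate, ordered by rank.
#' @export
scoreCandidates <- function(candidates, mutantDesign, wtDesign, evidence,
                            errorRate = 0.01, minMutantFraction = 0.9) {
    stopifnot(is(candidates, "BulkVariants"),
              is(mutantDesign, "BulkDesign"), is(wtDesign, "BulkDesign"))
    if (mutantDesign@role != "mutant" || wtDesign@role != "wildtype")
        stop("designs must be given as (mutant, wildtype)")
    fWt <- expectedAltFraction(wtDesign)
    keys <- variantKeys(candidates)
    ev <- evidence[match(keys, evidence$key), , drop = FALSE]
    n <- length(candidates)
    pMut <- pWt <- mutFrac <- wtFrac <- rep(NA_real_, n)
    status <- rep("ok", n)
    for (i in seq_len(n)) {
        mAlt <- ev$mutAdAlt[i]; mDep <- ev$mutAdRef[i] + mAlt
        wAlt <- ev$wtAdAlt[i]; wDep <- ev$wtAdRef[i] + wAlt
        if (is.na(mDep) || is.na(wDep)) { status[i] <- "no_evidence"; next }
        bm <- binomialConsistency(mAlt, mDep, 1, errorRate)
        bw <- binomialConsistency(wAlt, wDep, fWt, errorRate)
        if (bm$status == "no_evidence" || bw$status == "no_evidence") {
            status[i] <- "no_evidence"; next
        }
        pMut[i] <- bm$p; pWt[i] <- bw$p
        mutFrac[i] <- if (mDep > 0) mAlt / mDep else NA_real_
        wtFrac[i] <- if (wDep > 0) wAlt / wDep else NA_real_
    }
    combined <- -2 * (log(pMut) + log(pWt))
    incompatible <- !is.na(mutFrac) & mutFrac < minMutantFraction
    be <- lapply(as.list(mcols(candidates)$effects), .bestEffect)
    effectClass <- vapply(be, `[[`, character(1), "class")
    effectRank <- vapply(be, `[[`, integer(1), "rank")

    out <- DataFrame(
        key = keys, chrom = as.character(seqnames(candidates)),
        pos = start(candidates), ref = mcols(candidates)$ref,
        alt = mcols(candidates)$alt,
        mutAdAlt = ev$mutAdAlt, mutDepth = ev$mutAdRef + ev$mutAdAlt,
        mutFraction = mutFrac,
        wtAdAlt = ev$wtAdAlt, wtDepth = ev$wtAdRef + ev$wtAdAlt,
        wtFraction = wtFrac, expectedWtFraction = rep(fWt, n),
        pMutantBulk = pMut, pWtBulk = pWt, combined = combined,
        effectClass = effectClass, effectRank = effectRank,
        incompatible = incompatible, status = status)
    scorable <- status == "ok"
    ord <- order(!scorable,              # no-evidence rows last
                 incompatible,           # flagged after unflagged
                 combined, effectRank,
                 out$chrom, out$pos, method = "radix")
    out <- out[ord, , drop = FALSE]
    rank <- rep(NA_integer_, n)
    rank[out$status == "ok"] <- seq_len(sum(out$status == "ok"))
    out$rank <- rank
    out
}

#' Per-site alternate-read fraction with sliding-window means
#'
#' The per-site index is \code{adAlt / (adRef + adAlt)}; windows of
#' \code{windowSize} bases advanced by \code{step} average the sites they
#' contain (arithmetic mean), and empty windows are omitted. Sites with
#' zero usable depth are skipped. Near a causal recessive locus the mutant
#' bulk's index approaches 1.
#'
#' @param x a \linkS4class{BulkVariants} object.
#' @param windowSize,step window width and stride in bases.
#' @return a \code{DataFrame} of windows: chrom, start, end, nSites,
#'   meanIndex.
#' @export
snpIndex <- function(x, windowSize = 1e6, step = windowSize / 2) {
    stopifnot(is(x, "BulkVariants"), windowSize > 0, step > 0)
    idx <- altFraction(x)
    ok <- !is.na(idx)
    if (sum(!ok))
        message(sum(!ok), " zero-depth site(s) skipped")
    pos <- start(x)[ok]; chrom <- as.character(seqnames(x))[ok]
    idx <- idx[ok]
    res <- lapply(unique(chrom), function(ch) {
        p <- pos[chrom == ch]; v <- idx[chrom == ch]
        starts <- seq(1, max(p), by = step)
        rows <- lapply(starts, function(s) {
            inWin <- p >= s & p < s + windowSize
            if (!any(inWin)) return(NULL)
            DataFrame(chrom = ch, start = s, end = s + windowSize - 1,
                      nSites = sum(inWin), meanIndex = mean(v[inWin]))
        })
        do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        return(DataFrame(chrom = character(0), start = numeric(0),
                         end = numeric(0), nSites = integer(0),
                         meanIndex = numeric(0)))
    do.call(rbind, res)
}

#' Emit an IGV batch script imaging each candidate locus
#'
#' Writes the plain-text command list IGV's batch runner consumes: a
#' \code{new}/\code{genome}/\code{snapshotDirectory} preamble, then one
#' \code{goto}/\code{snapshot} pair per candidate with \code{flankBp}
#' padding either side, in genomic order.
#'
#' @param candidates a \linkS4class{BulkVariants} object or a scored
#'   \code{DataFrame} with chrom/pos columns.
#' @param genomeId IGV genome identifier.
#' @param snapshotDir directory IGV should write snapshots into.
#' @param flankBp padding around each candidate position.
#' @param path optional file to write the script to.
#' @return the script lines, invisibly when \code{path} is given.
#' @export
writeIgvBatch <- function(candidates, genomeId, snapshotDir,
                          flankBp = 500, path = NULL) {
    if (is(candidates, "BulkVariants")) {
        chrom <- as.character(seqnames(candidates)); pos <- start(candidates)
    } else {
        chrom <- as.character(candidates$chrom); pos <- candidates$pos
    }
    ord <- order(chrom, pos, method = "radix")
    chrom <- chrom[ord]; pos <- pos[ord]
    lines <- c("new", paste("genome", genomeId),
               paste("snapshotDirectory", snapshotDir))
    if (length(pos)) {
        left <- pmax(1, pos - flankBp); right <- pos + flankBp
        lines <- c(lines, as.vector(rbind(
            sprintf("goto %s:%d-%d", chrom, left, right),
            sprintf("snapshot %s_%d.png", chrom, pos))))
    }
    if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
    lines
}
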