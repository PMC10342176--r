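#' Expected mutant-allele read fraction of a bulk
#'
#' Under a monogenic recessive model in a selfed family, the mutant bulk
#' pools only homozygous mutants, so every read carries the mutant allele
#' (fraction 1). A wildtype-phenotype bulk pools homozygous wildtype plants
#' and heterozygous carriers: with a known count \eqn{h} of heterozygotes
#' among \eqn{n} pooled plants, each carrier contributes a half dose, giving
#' \eqn{h/(2n)}. When the composition is unknown, phenotypically wildtype
#' progeny of a selfed heterozygote are carriers with probability 2/3, so
#' the expectation is \eqn{(2/3)(1/2) = 1/3}. Equal per-plant contribution
#' to the pool is assumed.
#'
#' @param design a \linkS4class{BulkDesign}.
#' @return expected alternate-allele read fraction in [0, 1].
#' @examples
#' expectedAltFraction(BulkDesign("mutant", 4))            # 1
#' expectedAltFraction(BulkDesign("wildtype", 6, hetCount = 3))  # 0.25
#' expectedAltFraction(BulkDesign("wildtype", 6))          # 1/3
#' @export
expectedAltFraction <- function(design) {
    stopifnot(is(design, "BulkDesign"))
    if (design@role == "mutant") return(1)
    if (!is.na(design@hetCount))
        design@hetCount / (2 * design@nPlants)
    else 1 / 3
}

#' Chi-square goodness of fit to a Mendelian segregation ratio
#'
#' Pearson chi-square test (1 df) of observed phenotype counts against an
#' expected ratio, 3:1 wildtype:mutant by default. The uncorrected
#' statistic is the default; Yates' continuity correction is available via
#' \code{correct = TRUE}.
#'
#' @param nMutant,nWildtype observed plant counts per phenotype class.
#' @param ratio expected \code{c(wildtype, mutant)} ratio parts.
#' @param correct apply Yates' continuity correction.
#' @return a list with \code{chi2}, \code{df} (always 1) and \code{p}.
#' @examples
#' chisqSegregation(57, 171)   # exact 3:1 fit: chi2 = 0, p = 1
#' @export
chisqSegregation <- function(nMutant, nWildtype, ratio = c(3, 1),
                             correct = FALSE) {
    stopifnot(length(ratio) == 2, all(ratio > 0),
              nMutant >= 0, nWildtype >= 0)
    total <- nMutant + nWildtype
    if (total <= 0) stop("at least one plant must be counted")
    expected <- total * c(ratio[2], ratio[1]) / sum(ratio)
    if (any(expected == 0)) stop("zero expected count")
    observed <- c(nMutant, nWildtype)
    dev <- abs(observed - expected)
    if (correct) dev <- pmax(dev - 0.5, 0)
    chi2 <- sum(dev^2 / expected)
    list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Exact binomial consistency of observed allele depths with an expectation
#'
#' Two-sided exact binomial p-value for observing \code{adAlt} alternate
#' reads out of \code{depth} when the true alternate fraction is
#' \code{fExpected}. The two-sided p is the minimum-likelihood summation:
#' the total probability of all outcomes no more likely than the one
#' observed. The expectation is clamped to
#' \code{[errorRate, 1 - errorRate]} first, so an expectation of 0 or 1 can
#' never yield certainty against a single errored read.
#'
#' Large p means the depths look like what segregation predicts; small p
#' flags a candidate inconsistent with the expected dose.
#'
#' @param adAlt observed alternate-supporting reads.
#' @param depth reads used (defaults to ref + alt support upstream).
#' @param fExpected expected alternate fraction before clamping.
#' @param errorRate per-read sequencing error rate used for clamping.
#' @return a list with \code{p} in (0, 1] and \code{status}, \code{"ok"} or
#'   \code{"no_evidence"} when \code{depth} is zero (p defined as 1).
#' @examples
#' binomialConsistency(6, 24, 0.25)   # consistent with a quarter dose
#' binomialConsistency(0, 24, 0.25)   # inconsistent: p is small
#' @export
binomialConsistency <- function(adAlt, depth, fExpected, errorRate = 0.01) {
    stopifnot(adAlt >= 0, depth >= 0, adAlt <= depth,
              fExpected >= 0, fExpected <= 1,
              errorRate >= 0, errorRate < 0.5)
    if (depth == 0)
        return(list(p = 1, status = "no_evidence"))
    f <- min(max(fExpected, errorRate), 1 - errorRate)
    list(p = .binomTwoSided(adAlt, depth, f), status = "ok")
}

# minimum-likelihood two-sided binomial p; relative tolerance guards
# against ties broken by floating-point noise
.binomTwoSided <- function(k, n, f) {
    d <- dbinom(0:n, n, f)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

#' Total sequenced bases of a bulk
#'
#' Bookkeeping arithmetic for run reports: with fixed-length reads the
#' sequenced yield is simply reads x read length.
#'
#' @param nReads total read count of the bulk.
#' @param readLength read length in bp (150 for the usual paired-end runs).
#' @return total bases.
#' @export
sequencedBases <- function(nReads, readLength = 150) {
    stopifnot(nReads >= 0, readLength > 0)
    nReads * readLength
}
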