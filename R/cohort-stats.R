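#' @include piston.R
NULL

#' Exact Wilcoxon signed-rank test for small paired samples
#'
#' Paired test on the signed ranks of the differences \code{x - y}.  Zero
#' differences are dropped before ranking (Wilcoxon's original procedure) and
#' tied absolute differences receive average ranks.  The two-sided p-value is
#' exact: the null distribution of the positive-rank sum \eqn{W^+} over all
#' \eqn{2^{n}} equally likely sign assignments is computed by a
#' generating-function convolution over the realized ranks, and
#' \eqn{p = \min(1,\; 2\min(P(W \le w),\, P(W \ge w)))}.
#'
#' Only the exact test is provided, for \eqn{n \le 15} effective pairs; there
#' is deliberately no normal approximation.
#'
#' @param x numeric values (e.g. VSA at a timepoint, cm^2).
#' @param y paired values (e.g. ASA), same length.
#' @return An object of class \code{"wilcoxonExact"}: a list with
#'   \code{wPlus} (positive-rank sum), \code{nEff} (pairs after zero removal)
#'   and \code{pTwoSided}.
#' @examples
#' res <- wilcoxonSignedRankExact(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
#' res$pTwoSided   # 0.0625 = 2/32
#' @export
wilcoxonSignedRankExact <- function(x, y) {
    if (length(x) != length(y) || length(x) < 1L)
        stop("x and y must be paired vectors of equal length >= 1")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("x and y must be finite")
    d <- x - y
    d <- d[d != 0]
    nEff <- length(d)
    if (nEff == 0L)
        stop("degenerate sample: all paired differences are zero")
    if (nEff > 15L)
        stop("unsupported size: exact enumeration is limited to n <= 15")
    r <- rank(abs(d))
    wPlus <- sum(r[d > 0])
    ## doubled ranks are integers even with average ranks from ties
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1L)   # index i <=> doubled rank-sum i - 1
    dist[1L] <- 1
    for (ri in r2) {
        shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
        dist <- (dist + shifted) / 2
    }
    w2 <- as.integer(round(2 * wPlus))
    pLe <- sum(dist[seq_len(w2 + 1L)])
    pGe <- sum(dist[seq.int(w2 + 1L, length(dist))])
    structure(list(wPlus = wPlus, nEff = nEff,
                   pTwoSided = min(1, 2 * min(pLe, pGe))),
              class = "wilcoxonExact")
}

#' @export
print.wilcoxonExact <- function(x, ...) {
    cat("Exact Wilcoxon signed-rank test\n")
    cat(sprintf("  n (non-zero pairs) = %d\n", x$nEff))
    cat(sprintf("  W+ = %g\n", x$wPlus))
    cat(sprintf("  two-sided exact p = %.5g\n", x$pTwoSided))
    invisible(x)
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 2.
#' @return List with \code{mean}, \code{sem} (sample SD / sqrt(n)) and
#'   \code{n}.
#' @examples
#' meanSem(c(1, 2, 3))   # mean 2, sem 0.577
#' @export
meanSem <- function(values) {
    if (length(values) < 2L)
        stop("at least two values are required for a SEM")
    if (any(!is.finite(values))) stop("values must be finite")
    list(mean = mean(values), sem = sd(values) / sqrt(length(values)),
         n = length(values))
}

#' Three-timepoint area comparison of a cohort
#'
#' For each of the three cardinal timepoints (end diastole, end systole, mid
#' diastasis) and each ventricular area definition (endocardial, epicardial),
#' summarizes the paired difference VSA - ASA across subjects as mean and SEM
#' and tests it with the exact Wilcoxon signed-rank test.  With fewer than
#' two subjects the SEM is \code{NA}; Wilcoxon columns are \code{NA} when the
#' test is degenerate or the cohort exceeds the exact-test size limit.
#'
#' @param cohort an [AVAreaCohort-class].
#' @return A \code{data.frame} with one row per timepoint x measure:
#'   \code{timepoint}, \code{measure}, \code{n}, \code{meanVsa},
#'   \code{meanAsa}, \code{meanDiff}, \code{semDiff}, \code{wPlus},
#'   \code{pTwoSided}.
#' @examples
#' cohort <- generateCohort(defaultCohortParams(seed = 3))
#' threeTimepointTable(cohort)
#' @export
threeTimepointTable <- function(cohort) {
    stopifnot(is(cohort, "AVAreaCohort"))
    if (ncol(cohort) < 1L) stop("cohort is empty")
    phases <- cyclePhases(cohort)
    tps <- c(end_diastole = 0, end_systole = phases@tEs,
             mid_diastasis = phases@tDd)
    rows <- list()
    for (tp in names(tps)) {
        asa <- .assayAt(cohort, "asa", tps[[tp]])
        for (ms in c("endo", "epi")) {
            vsa <- .assayAt(cohort,
                            if (ms == "endo") "vsa_endo" else "vsa_epi",
                            tps[[tp]])
            d <- vsa - asa
            sem <- if (length(d) >= 2L) meanSem(d)$sem else NA_real_
            wt <- tryCatch(wilcoxonSignedRankExact(vsa, asa),
                           error = function(e) NULL)
            rows[[length(rows) + 1L]] <- data.frame(
                timepoint = tp, measure = ms, n = length(d),
                meanVsa = mean(vsa), meanAsa = mean(asa),
                meanDiff = mean(d), semDiff = sem,
                wPlus = if (is.null(wt)) NA_real_ else wt$wPlus,
                pTwoSided = if (is.null(wt)) NA_real_ else wt$pTwoSided)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
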