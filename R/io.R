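#' @include cohort-stats.R
NULL

.CURVE_COLS <- c("subject_id", "time_frac", "asa_cm2", "vsa_endo_cm2",
                 "vsa_epi_cm2")

#' Read and write cohort area curves as CSV
#'
#' One row per subject-frame with columns \code{subject_id}, \code{time_frac},
#' \code{asa_cm2}, \code{vsa_endo_cm2}, \code{vsa_epi_cm2}; header required,
#' decimal point, comma separator.  Areas are written with six decimals, so a
#' write/read round trip reproduces a cohort to that precision.  Malformed
#' rows are rejected with their file line number.
#'
#' Cycle phases are not part of the CSV schema, so \code{readCurvesCsv} takes
#' them as an argument (defaulting to the generator's standard timing).
#'
#' @param cohort an [AVAreaCohort-class].
#' @param path file path.
#' @param phases a [CyclePhases-class] attached to the cohort on read.
#' @return \code{readCurvesCsv} returns an [AVAreaCohort-class];
#'   \code{writeCurvesCsv} returns \code{path} invisibly.
#' @export
writeCurvesCsv <- function(cohort, path) {
    stopifnot(is(cohort, "AVAreaCohort"))
    times <- rowData(cohort)$time_frac
    ids <- colData(cohort)$subject_id
    df <- data.frame(
        subject_id = rep(ids, each = length(times)),
        time_frac = round(rep(times, times = length(ids)), 6),
        asa_cm2 = round(as.vector(assay(cohort, "asa")), 6),
        vsa_endo_cm2 = round(as.vector(assay(cohort, "vsa_endo")), 6),
        vsa_epi_cm2 = round(as.vector(assay(cohort, "vsa_epi")), 6))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCurvesCsv
#' @export
readCurvesCsv <- function(path, phases = defaultCyclePhases()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.CURVE_COLS, colnames(df))
    if (length(missing))
        stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
    if (nrow(df) == 0L) {
        warning("curve file contains a header only; returning an empty cohort")
        se <- SummarizedExperiment(
            assays = list(asa = matrix(numeric(0), 0, 0),
                          vsa_endo = matrix(numeric(0), 0, 0),
                          vsa_epi = matrix(numeric(0), 0, 0)),
            rowData = DataFrame(time_frac = numeric(0)),
            colData = DataFrame(subject_id = character(0)),
            metadata = list(phases = phases))
        return(new("AVAreaCohort", se))
    }
    line <- seq_len(nrow(df)) + 1L   # file line numbers incl. header
    num <- c("time_frac", "asa_cm2", "vsa_endo_cm2", "vsa_epi_cm2")
    for (cn in num)
        if (!is.numeric(df[[cn]]) || any(!is.finite(df[[cn]])))
            stop("schema error: non-numeric values in column ", cn)
    bad <- df$asa_cm2 <= 0 | df$vsa_endo_cm2 <= 0 | df$vsa_epi_cm2 <= 0
    if (any(bad))
        stop("schema error: non-positive area at line ", line[which(bad)[1L]])
    bad <- df$vsa_epi_cm2 - df$vsa_endo_cm2 < -1e-6
    if (any(bad))
        stop("schema error: vsa_epi_cm2 < vsa_endo_cm2 at line ",
             line[which(bad)[1L]])
    ids <- unique(df$subject_id)
    grids <- split(seq_len(nrow(df)), factor(df$subject_id, levels = ids))
    times <- df$time_frac[grids[[1L]]]
    for (id in ids) {
        idx <- grids[[id]]
        tt <- df$time_frac[idx]
        if (any(diff(tt) <= 0))
            stop("schema error: non-monotone time_frac for subject ", id,
                 " at line ", line[idx[which(diff(tt) <= 0)[1L] + 1L]])
        if (tt[1L] != 0 || tt[length(tt)] != 1)
            stop("schema error: subject ", id,
                 " must span time_frac 0 to 1")
        if (!isTRUE(all.equal(tt, times, tolerance = 1e-9)))
            stop("schema error: subject ", id,
                 " is not on the shared time grid")
    }
    mk <- function(col) vapply(ids, function(id) df[[col]][grids[[id]]],
                               numeric(length(times)))
    se <- SummarizedExperiment(
        assays = list(asa = mk("asa_cm2"), vsa_endo = mk("vsa_endo_cm2"),
                      vsa_epi = mk("vsa_epi_cm2")),
        rowData = DataFrame(time_frac = times),
        colData = DataFrame(subject_id = ids, row.names = ids),
        metadata = list(phases = phases))
    new("AVAreaCohort", se)
}

#' Write per-subject diastolic force curves as CSV
#'
#' Columns: \code{subject_id}, \code{time_frac}, \code{force_endo_N},
#' \code{force_epi_N}.
#'
#' @param forces a [ForceCurve-class] or list of them.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeForcesCsv <- function(forces, path) {
    if (is(forces, "ForceCurve")) forces <- list(forces)
    df <- do.call(rbind, lapply(forces, function(fc)
        data.frame(subject_id = fc@subjectId,
                   time_frac = round(fc@times, 6),
                   force_endo_N = round(fc@forceEndo, 6),
                   force_epi_N = round(fc@forceEpi, 6))))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
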