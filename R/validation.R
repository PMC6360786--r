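#' Accuracy statistics for lidar-vs-field validation pairs
#'
#' The published accuracy statistics, implemented exactly as printed:
#' `R^2 = 1 - (n-1) sum((x_i - xhat_i)^2) / ((n-2) sum((x_i - xbar)^2))`
#' where `x_i` are field measurements, `xhat_i` the lidar estimates, and --
#' notably -- `xbar` is the mean of the *estimates*. The classical
#' coefficient of determination (residuals against the mean of the
#' observations, no degree-of-freedom factor) is available behind
#' `classical = TRUE` as a sanity-check mode. The printed form is never
#' greater than 1 and equals 1 only at perfect agreement.
#'
#' @param x field-measured values.
#' @param xhat lidar-derived estimates, paired with `x`.
#' @param classical use the classical R^2 definition instead (default FALSE).
#' @return the R^2 value.
#' @export
r_squared <- function(x, xhat, classical = FALSE) {
  stopifnot(length(x) == length(xhat), all(is.finite(x)), all(is.finite(xhat)))
  n <- length(x)
  if (n < 3L) stop("need at least 3 validation pairs, got ", n)
  if (classical) {
    denom <- sum((x - mean(x))^2)
    if (denom == 0) stop("zero variance in observations")
    return(1 - sum((x - xhat)^2) / denom)
  }
  xbar <- mean(xhat)
  denom <- sum((x - xbar)^2)
  if (denom == 0) stop("zero denominator: observations equal the estimate mean")
  1 - (n - 1) * sum((x - xhat)^2) / ((n - 2) * denom)
}

#' @rdname r_squared
#' @details `rmse` uses the printed `n - 2` denominator:
#'   `RMSE = sqrt(sum((x_i - xhat_i)^2) / (n - 2))`. It scales linearly with
#'   the data: scaling all pairs by `c` scales RMSE by `|c|`.
#' @export
rmse <- function(x, xhat) {
  stopifnot(length(x) == length(xhat), all(is.finite(x)), all(is.finite(xhat)))
  n <- length(x)
  if (n < 3L) stop("need at least 3 validation pairs, got ", n)
  sqrt(sum((x - xhat)^2) / (n - 2))
}

#' Stage-level summary statistics of a phenotype
#'
#' Min, max, arithmetic mean and sample standard deviation (n - 1) of one
#' phenotype over all individuals at one growth stage.
#'
#' @param phenos phenotype table with columns `stage` and the phenotype, or a
#'   plain numeric vector (then `stage`/`phenotype` are tags only).
#' @param stage growth stage to summarize.
#' @param phenotype phenotype column name.
#' @return a one-row data.frame: stage, phenotype, min, max, avg, std.
#' @export
stage_summary <- function(phenos, stage, phenotype) {
  v <- if (is.numeric(phenos)) phenos else {
    sel <- phenos$stage == stage & !is.na(phenos[[phenotype]])
    phenos[[phenotype]][sel]
  }
  if (length(v) < 2L)
    stop("need at least 2 records for stage ", stage, " / ", phenotype)
  data.frame(stage = stage, phenotype = phenotype,
             min = min(v), max = max(v), avg = mean(v), std = stats::sd(v),
             stringsAsFactors = FALSE)
}

#' Summaries for every stage and phenotype present
#'
#' @param phenos phenotype table (see [extract_phenotypes()]).
#' @param phenotypes phenotype columns to summarize.
#' @param stages stage order.
#' @return a data.frame of stacked [stage_summary()] rows.
#' @export
stage_summaries <- function(phenos, phenotypes = c("height", "pai", "pla"),
                            stages = maize_stages) {
  out <- list()
  for (ph in phenotypes) for (s in stages) {
    if (any(phenos$stage == s & !is.na(phenos[[ph]])))
      out[[length(out) + 1L]] <- stage_summary(phenos, s, ph)
  }
  do.call(rbind, out)
}

# round half away from zero, the convention of the reported percentages
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derived ratios from the stage summary table
#'
#' The summary-level statistics reported for a full drought trial:
#' peak-to-maturity decreases (D60 to D95) of the mean height, PAI and PLA;
#' the mean std/avg ratio for plant height across the six stages; and, per
#' phenotype, the ratio of the mean late-stage (D60, D70, D95) standard
#' deviation to the D20 standard deviation. Percentages are reported rounded
#' half away from zero to the nearest integer.
#'
#' @param summaries a stage-summary table (see [stage_summaries()]) covering
#'   all six stages for height, pai and pla.
#' @return a list with `decrease_pct` (named vector, %, rounded),
#'   `decrease_raw` (unrounded fractions), `height_std_over_avg_pct`
#'   (rounded %), `height_std_over_avg_raw`, `late_std_ratio` (named vector,
#'   mean std of D60/D70/D95 over D20 std, unrounded).
#' @export
derived_ratios <- function(summaries) {
  need <- c("stage", "phenotype", "min", "max", "avg", "std")
  stopifnot(all(need %in% names(summaries)))
  get <- function(ph, st, col) {
    v <- summaries[[col]][summaries$phenotype == ph & summaries$stage == st]
    if (length(v) != 1L) stop("missing summary for ", ph, " at ", st)
    v
  }
  phs <- c("height", "pai", "pla")
  dec <- vapply(phs, function(ph) {
    a60 <- get(ph, "D60", "avg"); a95 <- get(ph, "D95", "avg")
    (a60 - a95) / a60
  }, 0)
  sa <- vapply(maize_stages, function(st)
    get("height", st, "std") / get("height", st, "avg"), 0)
  late <- vapply(phs, function(ph) {
    mean(vapply(c("D60", "D70", "D95"), function(st) get(ph, st, "std"), 0)) /
      get(ph, "D20", "std")
  }, 0)
  list(decrease_pct = round_half_away(100 * dec),
       decrease_raw = dec,
       height_std_over_avg_pct = round_half_away(100 * mean(sa)),
       height_std_over_avg_raw = mean(sa),
       late_std_ratio = late)
}

#' Published stage-summary reference table
#'
#' The stage-level Min/Max/Avg/Std statistics of lidar-derived plant height,
#' PAI and PLA for all individuals of a 17-variety maize drought trial at six
#' growth stages (D20-D95), bundled as the package's reference input for
#' [derived_ratios()] worked examples.
#'
#' @return a data.frame with columns stage, phenotype, min, max, avg, std.
#' @export
reference_stage_summary <- function() {
  path <- system.file("extdata", "stage_summary_reference.csv",
                      package = "maizetls", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
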