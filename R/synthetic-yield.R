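#' Generate per-variety grain yields for control and drought treatments
#'
#' Simulates a drought trial's yield table: each variety gets a baseline
#' control yield; its drought yield is the control scaled by
#' `1 - mean_reduction[group]` with multiplicative noise of coefficient of
#' variation `cv` on each replicate, truncated at zero. With `cv = 0` every
#' variety's realized yield reduction rate equals its group's configured
#' reduction exactly; with noise, group means stay within a few standard
#' errors of the configuration.
#'
#' @param n_varieties number of varieties.
#' @param group_assignment character vector of length `n_varieties` mapping
#'   each variety to a tolerance group (e.g. `"L1"`, `"L2"`, `"L3"`); every
#'   named group must contain at least one variety.
#' @param mean_reduction named numeric vector of per-group mean yield
#'   reductions in `[0, 1)` (the trial emulated here averaged 0.85 / 0.48 /
#'   0.27 for its low / medium / high tolerance groups).
#' @param cv coefficient of variation of the replicate noise (>= 0).
#' @param replicates replicates per variety x treatment (default 3).
#' @param base_yield mean control yield per plant in grams (default 200).
#' @param seed integer RNG seed.
#' @return a data.frame (YieldTable) with columns `variety_id`, `treatment`
#'   (`"control"` or `"drought"`), `replicate`, `yield_g`, plus the
#'   generating `group` for reference.
#' @export
generate_yields <- function(n_varieties, group_assignment, mean_reduction,
                            cv = 0.05, replicates = 3L, base_yield = 200,
                            seed = 1L) {
  stopifnot(n_varieties >= 1, length(group_assignment) == n_varieties,
            cv >= 0, replicates >= 1L, base_yield > 0)
  group_assignment <- as.character(group_assignment)
  groups <- unique(group_assignment)
  if (!all(groups %in% names(mean_reduction)))
    stop("mean_reduction lacks groups: ",
         paste(setdiff(groups, names(mean_reduction)), collapse = ", "))
  empty <- setdiff(names(mean_reduction), groups)
  if (length(empty))
    stop("group(s) with zero varieties: ", paste(empty, collapse = ", "))
  if (any(mean_reduction < 0 | mean_reduction >= 1))
    stop("reductions must be in [0, 1)")
  with_seed(seed, {
    rows <- vector("list", n_varieties)
    for (v in seq_len(n_varieties)) {
      g <- group_assignment[v]
      r <- mean_reduction[[g]]
      base_v <- base_yield * exp(stats::rnorm(1, 0, 0.15))
      ctl <- pmax(base_v * (1 + stats::rnorm(replicates, 0, cv)), 0)
      drt <- pmax(base_v * (1 - r) * (1 + stats::rnorm(replicates, 0, cv)), 0)
      rows[[v]] <- data.frame(
        variety_id = sprintf("V%02d", v),
        treatment = rep(c("control", "drought"), each = replicates),
        replicate = rep(seq_len(replicates), 2L),
        yield_g = c(ctl, drt),
        group = g,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Aggregate a yield table to per-variety mean yields
#'
#' @param yields a YieldTable from [generate_yields()] or read from CSV with
#'   columns `variety_id`, `treatment`, `yield_g`.
#' @return a data.frame with one row per variety: `variety_id`, `Y_a` (mean
#'   drought yield), `Y_m` (mean control yield), and `group` if present.
#' @export
variety_yields <- function(yields) {
  stopifnot(all(c("variety_id", "treatment", "yield_g") %in% names(yields)))
  bad <- setdiff(unique(yields$treatment), c("control", "drought"))
  if (length(bad)) stop("unknown treatments: ", paste(bad, collapse = ", "))
  ids <- unique(yields$variety_id)
  ya <- ym <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sel <- yields$variety_id == ids[i]
    ya[i] <- mean(yields$yield_g[sel & yields$treatment == "drought"])
    ym[i] <- mean(yields$yield_g[sel & yields$treatment == "control"])
  }
  if (anyNA(ya) || anyNA(ym))
    stop("every drought variety needs a control counterpart")
  out <- data.frame(variety_id = ids, Y_a = ya, Y_m = ym,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(yields))
    out$group <- yields$group[match(ids, yields$variety_id)]
  out
}
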