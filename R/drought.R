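#' Drought tolerance indices
#'
#' Yield-based indices of a variety's drought response. `Y_a` is the
#' variety's yield under drought stress, `Y_m` its control yield, and `Y_A`,
#' `Y_M` the population means of the stressed and control yields:
#' * yield reduction rate `YRR = (Y_m - Y_a) / Y_m`
#' * drought susceptibility index `DSI = (1 - Y_a/Y_m) / (1 - Y_A/Y_M)`
#' * drought resistance index `DRI = Y_a^2 / Y_m x Y_M / Y_A^2`
#'
#' All three are invariant to rescaling every yield by a common factor.
#'
#' @param Y_a,Y_m variety yield under stress and control (grams; `Y_m > 0`).
#' @param Y_A,Y_M population mean yields under stress and control.
#' @return the index value.
#' @export
yrr <- function(Y_a, Y_m) {
  if (any(Y_m <= 0)) stop("Y_m must be positive")
  (Y_m - Y_a) / Y_m
}

#' @rdname yrr
#' @export
dsi <- function(Y_a, Y_m, Y_A, Y_M) {
  if (any(Y_m <= 0) || any(Y_M <= 0)) stop("Y_m and Y_M must be positive")
  if (any(abs(1 - Y_A / Y_M) < 1e-12))
    stop("Y_A equals Y_M: no population-level stress, DSI undefined")
  (1 - Y_a / Y_m) / (1 - Y_A / Y_M)
}

#' @rdname yrr
#' @export
dri <- function(Y_a, Y_m, Y_A, Y_M) {
  if (any(Y_m <= 0)) stop("Y_m must be positive")
  if (any(Y_A <= 0)) stop("Y_A must be positive")
  Y_a^2 / Y_m * Y_M / Y_A^2
}

#' Per-variety drought index table
#'
#' Computes YRR, DSI and DRI for every variety from per-variety mean yields,
#' using the population means `Y_A` and `Y_M` over the included varieties.
#'
#' @param vy per-variety yields from [variety_yields()] (columns
#'   `variety_id`, `Y_a`, `Y_m`).
#' @return the input with `yrr`, `dsi`, `dri` columns appended.
#' @export
drought_indices <- function(vy) {
  stopifnot(all(c("variety_id", "Y_a", "Y_m") %in% names(vy)))
  Y_A <- mean(vy$Y_a); Y_M <- mean(vy$Y_m)
  vy$yrr <- yrr(vy$Y_a, vy$Y_m)
  vy$dsi <- dsi(vy$Y_a, vy$Y_m, Y_A, Y_M)
  vy$dri <- dri(vy$Y_a, vy$Y_m, Y_A, Y_M)
  vy
}

#' Classify varieties into drought tolerance groups
#'
#' Distance-based clustering of the (YRR, DSI, DRI) triples: indices are
#' z-scored per column, clustered by Ward-linkage agglomerative clustering on
#' Euclidean distances, and the tree is cut at `k` groups. Groups are labeled
#' `L1..Lk` by descending mean YRR, so `L1` is the highest yield loss (lowest
#' tolerance) and `Lk` the highest tolerance. The procedure is deterministic
#' and invariant to the input's row order.
#'
#' @param records a data.frame with columns `variety_id`, `yrr`, `dsi`,
#'   `dri` (see [drought_indices()]). Rows with non-finite indices are
#'   excluded with a warning (mirroring the exclusion of varieties with
#'   incomplete drought-stress samples).
#' @param k number of groups (default 3).
#' @return the (possibly reduced) records with a `group` column; attribute
#'   `"degenerate"` is `TRUE` when all varieties have identical indices.
#' @export
classify_tolerance <- function(records, k = 3L) {
  stopifnot(all(c("variety_id", "yrr", "dsi", "dri") %in% names(records)))
  X <- as.matrix(records[, c("yrr", "dsi", "dri")])
  ok <- apply(is.finite(X), 1, all)
  if (!all(ok)) {
    warning("excluding varieties with non-finite indices: ",
            paste(records$variety_id[!ok], collapse = ", "))
    records <- records[ok, , drop = FALSE]
    X <- X[ok, , drop = FALSE]
  }
  if (nrow(X) < k) stop("fewer varieties (", nrow(X), ") than groups (", k, ")")
  # order-invariant tie-breaking: sort by variety id before clustering
  o <- order(records$variety_id)
  records <- records[o, , drop = FALSE]
  X <- X[o, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  degenerate <- all(sds < 1e-12)
  Z <- sweep(X, 2, colMeans(X))
  nz <- sds > 1e-12
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sds[nz], "/")
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  mean_yrr <- tapply(records$yrr, cl, mean)
  lab <- paste0("L", seq_len(k))
  names(lab) <- names(sort(mean_yrr, decreasing = TRUE))
  records$group <- unname(lab[as.character(cl)])
  rownames(records) <- NULL
  if (degenerate)
    warning("all varieties have identical indices; grouping is degenerate")
  attr(records, "degenerate") <- degenerate
  records
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b two label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Growth-stage order used throughout
#'
#' The six key growth stages, labeled by days of drought stress, from
#' six-leaf (D20) to physiological maturity (D95).
#'
#' @format character vector of length 6.
#' @export
maize_stages <- c("D20", "D35", "D45", "D60", "D70", "D95")

#' Per-group phenotype dynamics across growth stages
#'
#' For each growth stage: mean and sample standard deviation of a phenotype
#' over all individuals of the group's varieties, plus the change rate versus
#' the previous stage, `(mean_t - mean_{t-1}) / mean_{t-1}`. The change rate
#' of the first stage -- and of any stage following a missing one -- is `NA`,
#' never 0.
#'
#' @param phenos phenotype table (see [extract_phenotypes()]) with columns
#'   `variety`, `stage` and the phenotype.
#' @param groups data.frame mapping `variety` to `group` (or a named vector).
#' @param group group label to summarize (e.g. `"L1"`).
#' @param phenotype column name: `"height"`, `"pai"` or `"pla"`.
#' @param stages stage order (default [maize_stages]).
#' @return a data.frame: group, phenotype, stage, n, mean, std, change_rate.
#' @export
group_dynamics <- function(phenos, groups, group, phenotype,
                           stages = maize_stages) {
  if (is.data.frame(groups)) {
    gmap <- stats::setNames(groups$group, groups$variety)
  } else gmap <- groups
  sel <- !is.na(phenos[[phenotype]]) &
    gmap[as.character(phenos$variety)] == group
  sel[is.na(sel)] <- FALSE
  dat <- phenos[sel, , drop = FALSE]
  out <- data.frame(group = group, phenotype = phenotype, stage = stages,
                    n = NA_integer_, mean = NA_real_, std = NA_real_,
                    change_rate = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    v <- dat[[phenotype]][dat$stage == stages[i]]
    out$n[i] <- length(v)
    if (length(v) >= 1L) out$mean[i] <- mean(v)
    if (length(v) >= 2L) out$std[i] <- stats::sd(v)
  }
  for (i in seq_along(stages)[-1]) {
    if (!is.na(out$mean[i]) && !is.na(out$mean[i - 1]) && out$mean[i - 1] != 0)
      out$change_rate[i] <- (out$mean[i] - out$mean[i - 1]) / out$mean[i - 1]
  }
  out
}

#' Significance test between two growth stages
#'
#' Welch two-sample t-test of a phenotype between two stages within one
#' tolerance group, pooling individual plants. The null hypothesis is no
#' difference between stages; flags are reported at the 0.05 and 0.01
#' levels. Two identical zero-variance samples give p = 1 by convention
#' (and p = 0 when their means differ).
#'
#' @inheritParams group_dynamics
#' @param stage_a,stage_b the two stages to compare.
#' @return a list: `p_value`, `sig_05`, `sig_01`, `n_a`, `n_b`.
#' @export
stage_significance <- function(phenos, groups, group, phenotype,
                               stage_a, stage_b) {
  if (is.data.frame(groups)) {
    gmap <- stats::setNames(groups$group, groups$variety)
  } else gmap <- groups
  sel <- !is.na(phenos[[phenotype]]) &
    gmap[as.character(phenos$variety)] == group
  sel[is.na(sel)] <- FALSE
  dat <- phenos[sel, , drop = FALSE]
  a <- dat[[phenotype]][dat$stage == stage_a]
  b <- dat[[phenotype]][dat$stage == stage_b]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per stage (got ", length(a), " and ",
         length(b), ")")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  list(p_value = p, sig_05 = p < 0.05, sig_01 = p < 0.01,
       n_a = length(a), n_b = length(b))
}

#' Mean per-layer PAD profile of a tolerance group at one stage
#'
#' @inheritParams group_dynamics
#' @param stage the growth stage.
#' @return a list: `mean` and `std`, each a vector over the 5 layers, and
#'   `n` plants; all-`NA` profile if the group is empty at that stage.
#' @export
pad_profile <- function(phenos, groups, group, stage) {
  if (is.data.frame(groups)) {
    gmap <- stats::setNames(groups$group, groups$variety)
  } else gmap <- groups
  padcols <- grep("^pad_l[0-9]+$", names(phenos), value = TRUE)
  sel <- gmap[as.character(phenos$variety)] == group &
    phenos$stage == stage & !is.na(phenos[[padcols[1]]])
  sel[is.na(sel)] <- FALSE
  dat <- phenos[sel, padcols, drop = FALSE]
  if (nrow(dat) == 0L)
    return(list(mean = rep(NA_real_, length(padcols)),
                std = rep(NA_real_, length(padcols)), n = 0L))
  list(mean = colMeans(dat),
       std = apply(dat, 2, stats::sd),
       n = nrow(dat))
}
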