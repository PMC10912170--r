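#' Group and per-animal medians of a hierarchical sample
#'
#' Cells are nested in animals; alongside the per-group (pooled-cell)
#' median the per-animal medians are returned, since the animal is the
#' independent replicate.
#'
#' @param sample data.frame with columns `animal_id`, `value` and the
#'   grouping columns named in `keys`.
#' @param keys character vector of grouping column names.
#' @param value name of the value column.
#' @return list with `group` (median per key combination, midpoint rule
#'   for even counts) and `per_animal` (median per key x animal).
#' @export
group_median <- function(sample, keys = "group", value = "value") {
  stopifnot(nrow(sample) > 0, all(keys %in% names(sample)))
  g <- aggregate(sample[[value]], by = sample[keys], FUN = median)
  names(g)[ncol(g)] <- "median"
  pa <- aggregate(sample[[value]], by = sample[c(keys, "animal_id")],
                  FUN = median)
  names(pa)[ncol(pa)] <- "median"
  list(group = g, per_animal = pa)
}

#' Animal-clustered bootstrap comparison of two groups
#'
#' Cells from the same animal are not independent, so naive cell-level
#' tests are pseudoreplicated. This comparison resamples animals with
#' replacement within each group and then cells with replacement within
#' each drawn animal, and studentizes every replicate by its own
#' cluster-level standard error (a cluster bootstrap-t), which keeps the
#' test close to nominal size even with as few as five animals per group.
#' The standard error is computed from the per-animal statistics,
#' `sqrt(s_A^2/n_A + s_B^2/n_B)`; the confidence interval is the
#' bootstrap-t interval and the two-sided p-value is the fraction of
#' studentized replicates at least as extreme as the observed studentized
#' difference.
#'
#' @param sample data.frame with columns `animal_id`, `group`, `value`.
#' @param groupA,groupB levels of `group` to compare (estimate = A - B).
#' @param n_boot bootstrap replicates (>= 1000 recommended; > 0 required).
#' @param stat `"mean"` or `"median"`; the group statistic is the mean (or
#'   median) of per-animal statistics, making the animal the unit.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `estimate`, `ci` (length 2), `p`, `n_animals`,
#'   `n_cells`, `n_boot`, `stat`, `seed`.
#' @export
cluster_bootstrap_diff <- function(sample, groupA, groupB, n_boot = 2000,
                                   stat = c("mean", "median"), seed = 1,
                                   conf = 0.95) {
  stat <- match.arg(stat)
  if (n_boot < 1) stopf("n_boot must be >= 1")
  sfun <- if (stat == "mean") mean else median
  take <- function(g) {
    d <- sample[sample$group == g, c("animal_id", "value")]
    if (!nrow(d)) stopf("group '%s' has no rows", g)
    split(d$value, d$animal_id)
  }
  a <- take(groupA); b <- take(groupB)
  if (length(a) < 2) stopf("group '%s' has only %d animal(s); need >= 2 for the cluster bootstrap", groupA, length(a))
  if (length(b) < 2) stopf("group '%s' has only %d animal(s); need >= 2 for the cluster bootstrap", groupB, length(b))
  nA <- length(a); nB <- length(b)
  animal_stats <- function(cells) vapply(cells, sfun, numeric(1))
  gstat <- function(as_) mean(as_)
  se_of <- function(sa, sb) sqrt(var(sa) / length(sa) + var(sb) / length(sb))
  sa0 <- animal_stats(a); sb0 <- animal_stats(b)
  obs <- gstat(sa0) - gstat(sb0)
  se0 <- se_of(sa0, sb0)
  if (se0 <= 0) stopf("degenerate sample: zero between-animal variance")
  boot_group <- function(cells) {
    pick <- sample.int(length(cells), length(cells), replace = TRUE)
    vapply(cells[pick], function(v) {
      sfun(v[sample.int(length(v), length(v), replace = TRUE)])
    }, numeric(1))
  }
  with_rng(seed, {
    tstar <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      sa <- boot_group(a); sb <- boot_group(b)
      se <- se_of(sa, sb)
      if (se <= 0) se <- se0
      tstar[i] <- (gstat(sa) - gstat(sb) - obs) / se
    }
    # finite-cluster correction: resampling n of n animals understates the
    # between-animal variance by (n-1)/n per group
    tstar <- tstar * sqrt((nA / (nA - 1) + nB / (nB - 1)) / 2)
    tobs <- obs / se0
    alpha <- 1 - conf
    q <- quantile(tstar, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    ci <- c(obs - q[2] * se0, obs - q[1] * se0)
    p <- (1 + sum(abs(tstar) >= abs(tobs))) / (n_boot + 1)
    list(estimate = obs, ci = ci, p = p,
         n_animals = c(nA, nB),
         n_cells = c(length(unlist(a)), length(unlist(b))),
         n_boot = n_boot, stat = stat, seed = seed)
  })
}

#' Per-animal association percentages and their group summary
#'
#' The animal is the statistical unit: the percentage of extensively
#' associated microglia is computed per animal (and region, if given) and
#' summarised as mean +/- SEM over animals. With a single animal the SEM
#' is reported as missing.
#'
#' @param flags data.frame with logical `extensive`, `animal_id`, and
#'   optionally `region`.
#' @return list with `per_animal` (percent per animal x region) and
#'   `group` (mean, sem, n_animals per region).
#' @export
proportion_summary <- function(flags) {
  stopifnot(nrow(flags) > 0, all(c("extensive", "animal_id") %in% names(flags)))
  keys <- intersect(c("region", "animal_id"), names(flags))
  pa <- aggregate(flags$extensive, by = flags[keys],
                  FUN = function(z) 100 * mean(z))
  names(pa)[ncol(pa)] <- "pct"
  gkeys <- intersect("region", names(flags))
  if (length(gkeys)) {
    sp <- split(pa$pct, pa[gkeys])
  } else {
    sp <- list(all = pa$pct)
  }
  g <- do.call(rbind, lapply(names(sp), function(nm) {
    v <- sp[[nm]]
    data.frame(region = nm, mean_pct = mean(v),
               sem_pct = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n_animals = length(v))
  }))
  list(per_animal = pa, group = g)
}
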