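#' Statistics configuration
#'
#' Defaults follow the analysis protocol: 5000 Monte-Carlo permutations,
#' cluster-forming alpha and significance alpha both 0.05, 100 bootstrap
#' equalization repeats, 7 SUVr quantiles, Bonferroni correction for the
#' pairwise quantile comparisons.
#'
#' @param n_permutations Monte-Carlo permutation count.
#' @param cluster_alpha two-tailed alpha defining the voxel-wise
#'   cluster-forming t threshold.
#' @param alpha significance level for cluster p-values.
#' @param n_bootstrap bootstrap equalization repeats.
#' @param n_quantiles SUVr quantile count.
#' @param bonferroni apply Bonferroni correction to pairwise comparisons.
#' @param seed master seed; permutation and bootstrap streams are derived
#'   from it deterministically.
#' @return list of class `stat_config`.
#' @export
stat_config <- function(n_permutations = 5000, cluster_alpha = 0.05,
                        alpha = 0.05, n_bootstrap = 100, n_quantiles = 7,
                        bonferroni = TRUE, seed = 1) {
  stopifnot(n_permutations >= 1, n_bootstrap >= 1, n_quantiles >= 1,
            cluster_alpha > 0, cluster_alpha < 1, alpha > 0, alpha < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_alpha = cluster_alpha, alpha = alpha,
                 n_bootstrap = as.integer(n_bootstrap),
                 n_quantiles = as.integer(n_quantiles),
                 bonferroni = bonferroni, seed = as.integer(seed)),
            class = "stat_config")
}

#' Voxel-wise independent-samples t map
#'
#' Two-sample pooled-variance t statistic per voxel, computed as group A
#' minus group B (the amyloid-negative group is passed first, so a power
#' increase in A+ shows up as negative t). Voxels with zero pooled variance
#' get t = 0 with a warning.
#'
#' @param a,b subjects x voxels matrices for the two groups (>= 2 rows
#'   each).
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled-variance one. The unbalanced-group analyses rely on bootstrap
#'   equalization rather than Welch correction, so the default is pooled.
#' @return numeric t vector, one value per voxel.
#' @export
tmap_independent <- function(a, b, welch = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 subjects per group")
  if (ncol(a) != ncol(b)) stop("voxel count mismatch")
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(a^2) - na * ma^2
  vb <- colSums(b^2) - nb * mb^2
  denom <- if (welch) {
    sqrt(va / (na - 1L) / na + vb / (nb - 1L) / nb)
  } else {
    sp2 <- (va + vb) / (na + nb - 2L)
    sqrt(sp2 * (1 / na + 1 / nb))
  }
  t <- (ma - mb) / denom
  if (any(denom == 0)) {
    warning("zero pooled variance at ", sum(denom == 0), " voxel(s); t = 0")
    t[denom == 0] <- 0
  }
  t
}

# Connected components of the suprathreshold voxel set, split by t sign.
# Returns a list of clusters: list(voxels, sign, sum_t).
find_clusters <- function(t, threshold, adjacency) {
  out <- list()
  for (sgn in c(1, -1)) {
    member <- if (sgn > 0) t >= threshold else t <= -threshold
    idx <- which(member)
    if (!length(idx)) next
    seen <- logical(length(t))
    for (s in idx) {
      if (seen[s]) next
      comp <- integer(0)
      stack <- s
      seen[s] <- TRUE
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, v)
        nb <- adjacency[[v]]
        nb <- nb[member[nb] & !seen[nb]]
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
      out[[length(out) + 1L]] <- list(voxels = sort(comp),
                                      sign = if (sgn > 0) "+" else "-",
                                      sum_t = sum(t[comp]))
    }
  }
  out
}

# Vectorized pooled-variance t maps for many label permutations at once.
# X: subjects x voxels; Z: subjects x n_perm 0/1 indicators of group A
# membership (column sums all equal na). Returns voxels x n_perm.
tmaps_permuted <- function(X, Z, na, nb) {
  S1 <- crossprod(X, Z)                 # voxel sums in group A
  SS1 <- crossprod(X^2, Z)
  Tot <- colSums(X); Tot2 <- colSums(X^2)
  m1 <- S1 / na
  m2 <- (Tot - S1) / nb
  ss1 <- SS1 - S1^2 / na
  ss2 <- (Tot2 - SS1) - (Tot - S1)^2 / nb
  sp2 <- (ss1 + ss2) / (na + nb - 2L)
  denom <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (m1 - m2) / denom
  t[denom == 0] <- 0
  t
}

#' Cluster-based Monte-Carlo permutation test
#'
#' Voxel-wise two-sample t map between the groups, thresholded at the
#' two-tailed critical t for `cluster_alpha` with `n_A + n_B - 2` degrees
#' of freedom; suprathreshold voxels are grouped into sign-consistent
#' adjacency-connected clusters scored by the sum of their t values. The
#' null distribution is built by randomly permuting group labels: each
#' permutation contributes the maximum over its clusters of |sum t|
#' (max-statistic, both signs pooled, giving two-tailed family-wise error
#' control). Cluster p-values use the +1-corrected Monte-Carlo estimate
#' `(1 + #{null >= |observed|}) / (n_permutations + 1)`.
#'
#' @param maps subjects x voxels matrix (e.g. z-scored relative power of
#'   one band).
#' @param labels factor with two levels, first level = group A (A-).
#' @param adjacency list of neighbour-index vectors covering all voxels.
#' @param config a [stat_config()].
#' @return object of class `cluster_result`: `clusters` (data.frame with
#'   `sign`, `size`, `maxsum_t`, `p_mc`, `significant` and a `voxels` list
#'   column), `t_map`, `threshold_t`, `null_max`, `config`.
#' @export
cluster_permutation_test <- function(maps, labels, adjacency,
                                     config = stat_config()) {
  maps <- as.matrix(maps)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (length(labels) != nrow(maps)) stop("one label per subject required")
  if (ncol(maps) < 1L) stop("no voxels")
  if (length(adjacency) != ncol(maps))
    stop("adjacency must cover all voxels")
  ga <- labels == levels(labels)[1L]
  na <- sum(ga); nb <- sum(!ga)
  if (na < 2L || nb < 2L) stop("need >= 2 subjects per group")
  df <- na + nb - 2L
  thr <- stats::qt(1 - config$cluster_alpha / 2, df)
  t_obs <- tmap_independent(maps[ga, , drop = FALSE],
                            maps[!ga, , drop = FALSE])
  obs <- find_clusters(t_obs, thr, adjacency)

  set.seed(config$seed)
  P <- config$n_permutations
  n <- nrow(maps)
  Z <- matrix(0, n, P)
  for (p in seq_len(P)) Z[sample.int(n, na), p] <- 1
  tm <- tmaps_permuted(maps, Z, na, nb)
  null_max <- null_max_cluster_sums(tm, thr, adjacency)
  clusters <- if (length(obs)) {
    stat <- vapply(obs, `[[`, numeric(1), "sum_t")
    p_mc <- vapply(stat, function(s)
      (1 + sum(null_max >= abs(s))) / (P + 1), numeric(1))
    data.frame(
      sign = vapply(obs, `[[`, character(1), "sign"),
      size = vapply(obs, function(cl) length(cl$voxels), integer(1)),
      maxsum_t = stat, p_mc = p_mc,
      significant = p_mc < config$alpha,
      stringsAsFactors = FALSE)
  } else {
    data.frame(sign = character(0), size = integer(0),
               maxsum_t = numeric(0), p_mc = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  }
  clusters$voxels <- lapply(obs, `[[`, "voxels")
  structure(list(clusters = clusters, t_map = t_obs, threshold_t = thr,
                 null_max = null_max, config = config,
                 groups = c(levels(labels)[1L], levels(labels)[2L]),
                 n = c(na, nb)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test (%s n=%d vs %s n=%d, %d permutations)\n",
    x$groups[1], x$n[1], x$groups[2], x$n[2], x$config$n_permutations))
  cat(sprintf("  cluster-forming |t| >= %.3f\n", x$threshold_t))
  if (nrow(x$clusters) == 0L) {
    cat("  no suprathreshold clusters\n")
  } else {
    df <- x$clusters[order(x$clusters$p_mc), c("sign", "size", "maxsum_t",
                                               "p_mc", "significant")]
    print(utils::head(df, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Bootstrap-equalized reliability of a cluster effect
#'
#' Handles unequal group sizes by repeatedly drawing, without replacement,
#' a random subsample of the larger group matching the smaller group's
#' size, re-running the cluster permutation test on the equalized data, and
#' recording whether a significant cluster of the specified sign overlaps
#' the target region. The replication proportion over the repeats estimates
#' the reliability of the original effect.
#'
#' @param maps subjects x voxels matrix.
#' @param labels two-level factor (first level = larger or smaller group;
#'   sizes are detected).
#' @param adjacency neighbour list.
#' @param config a [stat_config()]; `n_bootstrap` repeats are run, each
#'   with an independent derived seed.
#' @param effect_spec list with `sign` (`"+"` or `"-"`), `roi_voxels`
#'   (non-empty integer vector), and optionally `overlap_frac` (minimum
#'   fraction of the ROI a cluster must cover; default any overlap).
#' @return object of class `reliability_result`: `replication_count`,
#'   `proportion`, `n_bootstrap`, per-repeat `replicated` flags.
#' @export
bootstrap_equalized_reliability <- function(maps, labels, adjacency,
                                            config = stat_config(),
                                            effect_spec) {
  maps <- as.matrix(maps)
  labels <- as.factor(labels)
  if (is.null(effect_spec$roi_voxels) || !length(effect_spec$roi_voxels))
    stop("effect_spec$roi_voxels must be a non-empty voxel set")
  if (!effect_spec$sign %in% c("+", "-"))
    stop("effect_spec$sign must be '+' or '-'")
  overlap_frac <- effect_spec$overlap_frac %||% 0
  roi <- effect_spec$roi_voxels
  need <- max(1L, ceiling(overlap_frac * length(roi)))
  sizes <- table(labels)
  small <- names(sizes)[which.min(sizes)]
  large <- setdiff(levels(labels), small)
  n_small <- min(sizes)
  idx_small <- which(labels == small)
  idx_large <- which(labels == large)
  replicated <- logical(config$n_bootstrap)
  for (r in seq_len(config$n_bootstrap)) {
    set.seed(derive_seed(config$seed, r))
    sub_large <- if (length(idx_large) > n_small)
      sample(idx_large, n_small) else idx_large
    take <- c(idx_small, sub_large)
    sub_cfg <- config
    sub_cfg$seed <- derive_seed(config$seed, 100000L + r)
    res <- cluster_permutation_test(maps[take, , drop = FALSE],
                                    droplevels(labels[take]),
                                    adjacency, sub_cfg)
    cl <- res$clusters
    hit <- FALSE
    if (nrow(cl)) {
      for (i in seq_len(nrow(cl))) {
        if (cl$significant[i] && cl$sign[i] == effect_spec$sign &&
            length(intersect(cl$voxels[[i]], roi)) >= need) {
          hit <- TRUE; break
        }
      }
    }
    replicated[r] <- hit
  }
  structure(list(replication_count = sum(replicated),
                 proportion = mean(replicated),
                 n_bootstrap = config$n_bootstrap,
                 replicated = replicated,
                 effect_spec = effect_spec),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap-equalized reliability: %d / %d repeats replicated (%.0f%%)\n",
    x$replication_count, x$n_bootstrap, 100 * x$proportion))
  invisible(x)
}

#' Classify amyloid status from SUVr
#'
#' Subjects with SUVr strictly above the threshold are amyloid positive
#' (`A+`); at or below it, amyloid negative (`A-`).
#'
#' @param suvr positive SUVr value(s).
#' @param threshold positivity cutoff (default 0.79).
#' @return factor with levels `A-`, `A+`.
#' @export
classify_amyloid <- function(suvr, threshold = 0.79) {
  if (any(!is.finite(suvr)) || any(suvr <= 0))
    stop("SUVr must be positive")
  factor(ifelse(suvr > threshold, "A+", "A-"), levels = c("A-", "A+"))
}

#' Equal-count quantile (vincentile) binning
#'
#' Rank-based partition of a continuous variable into `k` bins of
#' equal-as-possible size (sizes differ by at most one), ordered by value;
#' ties keep their original input order.
#'
#' @param values numeric vector (length >= k).
#' @param k number of quantile bins.
#' @return integer bin assignment (1..k) aligned with `values`.
#' @export
vincentize_quantiles <- function(values, k) {
  n <- length(values)
  k <- as.integer(k)
  if (n < k) stop("need at least k = ", k, " values (got ", n, ")")
  cuts <- round(seq(0, n, length.out = k + 1L))
  sizes <- diff(cuts)
  ord <- order(values)                  # stable for ties
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(k), sizes)
  bins
}

#' One-way between-subjects ANOVA with Bonferroni pairwise tests
#'
#' F-test of the bin factor (df = k-1, n-k) with eta-squared, plus all
#' pairwise pooled-variance t tests whose p-values are multiplied by
#' `k (k - 1) / 2` (capped at 1) when Bonferroni correction is on.
#'
#' @param values numeric outcome per subject.
#' @param bins integer or factor bin assignment (>= 2 subjects per bin).
#' @param bonferroni apply the multiplicity correction (default `TRUE`).
#' @return list: `F`, `df`, `p`, `eta_squared`, `bin_means`,
#'   `pairwise` (data.frame i, j, t, p_raw, p_adj).
#' @export
oneway_anova_bonferroni <- function(values, bins, bonferroni = TRUE) {
  bins <- as.factor(bins)
  k <- nlevels(bins)
  cnt <- table(bins)
  if (any(cnt < 2L))
    stop("each bin needs >= 2 subjects (bin ",
         names(cnt)[which.min(cnt)], " has ", min(cnt), ")")
  fit <- stats::lm(values ~ bins)
  an <- stats::anova(fit)
  ssb <- an$`Sum Sq`[1L]; ssw <- an$`Sum Sq`[2L]
  m <- k * (k - 1) / 2
  pairs <- utils::combn(levels(bins), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1L, c_]; j <- pairs[2L, c_]
    tt <- stats::t.test(values[bins == i], values[bins == j],
                        var.equal = TRUE)
    data.frame(bin_i = i, bin_j = j, t = unname(tt$statistic),
               p_raw = tt$p.value,
               p_adj = if (bonferroni) min(1, tt$p.value * m) else
                 tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(F = unname(an$`F value`[1L]),
       df = c(an$Df[1L], an$Df[2L]),
       p = unname(an$`Pr(>F)`[1L]),
       eta_squared = ssb / (ssb + ssw),
       bin_means = tapply(values, bins, mean),
       pairwise = pw)
}

#' Regress band power on a cognitive score
#'
#' Ordinary least squares of power on the memory score, with the F test of
#' the slope; optionally refit within each group.
#'
#' @param power numeric outcome (e.g. cluster-mean z power).
#' @param score numeric predictor (e.g. FCSRT total recall); must vary.
#' @param group optional factor; per-level fits are returned as well.
#' @return list: `slope`, `intercept`, `r_squared`, `p`, `n`, and
#'   `by_group` (named list of the same) when `group` is given.
#' @export
regress_power_on_score <- function(power, score, group = NULL) {
  if (length(power) < 3L) stop("need at least 3 subjects")
  if (stats::sd(score) == 0) stop("score is constant; slope undefined")
  fit <- stats::lm(power ~ score)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = sm$r.squared,
              p = unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                   sm$fstatistic[3L], lower.tail = FALSE)),
              se_slope = sm$coefficients[2L, 2L],
              n = length(power))
  if (!is.null(group)) {
    group <- as.factor(group)
    out$by_group <- lapply(stats::setNames(levels(group), levels(group)),
                           function(g)
                             regress_power_on_score(power[group == g],
                                                    score[group == g]))
  }
  out
}

#' Monotone dose-response check on quantile-bin means
#'
#' Assesses whether bin means follow a non-decreasing dose-response, in
#' the form appropriate for a thresholded effect observed with sampling
#' noise: no adjacent bin-mean decrease may exceed `se_factor` standard
#' errors of that difference (bins sharing one expected value are allowed
#' to fluctuate), and the last-minus-first contrast must be positive by
#' more than its standard error times `se_factor_overall`.
#'
#' @param values numeric outcome per subject.
#' @param bins integer/factor bin assignment (ordered dose levels).
#' @param se_factor tolerance, in SEs, for adjacent decreases (default 3).
#' @param se_factor_overall required SEs for the overall increase
#'   (default 2).
#' @return list: `monotone` (no significant adjacent decrease),
#'   `increasing` (significant overall rise), `bin_means`, `bin_se`.
#' @export
quantile_trend_check <- function(values, bins, se_factor = 3,
                                 se_factor_overall = 2) {
  bins <- as.factor(bins)
  m <- tapply(values, bins, mean)
  se <- tapply(values, bins, function(v) stats::sd(v) / sqrt(length(v)))
  d <- diff(m)
  d_se <- sqrt(se[-length(se)]^2 + se[-1]^2)
  overall <- m[length(m)] - m[1]
  overall_se <- sqrt(se[1]^2 + se[length(se)]^2)
  list(monotone = all(d > -se_factor * d_se),
       increasing = overall > se_factor_overall * overall_se,
       bin_means = m, bin_se = se)
}

#' Amyloid-by-APOE analysis of covariance
#'
#' General linear model of cluster-mean power on amyloid status, APOE
#' epsilon-4 status, their interaction, and the sex and age covariates,
#' with Type-II F tests per term.
#'
#' @param power numeric outcome per subject.
#' @param meta data.frame with columns `amyloid` (2 levels), `apoe_e4`
#'   (2 levels), `sex`, `age`; every amyloid x APOE cell needs >= 2
#'   subjects.
#' @return list: `table` (Type-II ANOVA data.frame), `model` (the `lm`
#'   fit).
#' @export
ancova_amyloid_apoe <- function(power, meta) {
  need <- c("amyloid", "apoe_e4", "sex", "age")
  if (!all(need %in% names(meta)))
    stop("meta must contain ", paste(need, collapse = ", "))
  d <- data.frame(power = power,
                  amyloid = as.factor(meta$amyloid),
                  apoe = as.factor(meta$apoe_e4),
                  sex = as.factor(meta$sex),
                  age = as.numeric(meta$age))
  cells <- table(d$amyloid, d$apoe)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1L, ]
    stop("amyloid x APOE cell ", rownames(cells)[bad[1L]], " x ",
         colnames(cells)[bad[2L]], " has fewer than 2 subjects")
  }
  fit <- stats::lm(power ~ amyloid * apoe + sex + age, data = d)
  tab <- as.data.frame(car::Anova(fit, type = "II"))
  list(table = tab, model = fit)
}
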