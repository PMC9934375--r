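# Resampling machinery: rarefaction (cumulative prey curves) with an
# asymptote slope test, and bootstrap comparison of GII between strata.
# RNG discipline: every routine takes one root seed and derives an
# independent child seed per permutation/replicate, so results are
# reproducible and order-independent.

child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

perms_all <- function(n) {
  # all permutations of 1..n as a matrix (n! rows); guarded small n
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    out[r + seq_len(nrow(sub)), ] <- cbind(i, sub + (sub >= i))
    r <- r + nrow(sub)
  }
  out
}

curve_from_order <- function(first_idx, k) {
  # first_idx: first position at which each taxon appears (Inf if absent)
  cnt <- tabulate(first_idx[is.finite(first_idx)], nbins = k)
  cumsum(cnt)
}

#' Rarefaction (cumulative prey) curve
#'
#' Randomizes the order in which stomachs are accumulated and records the
#' number of distinct prey taxa seen after 1, 2, ..., k stomachs; reports the
#' mean and standard deviation over permutations together with the
#' mean +/- 2 sd band. Taxa enter at the lowest identified level, unidentified
#' categories included. With `n_permutations = "all"` every ordering of the
#' stomachs is enumerated (k <= 8), giving the exact expectation and sd.
#'
#' @param x a `diet_dataset` (stomachs with food only are used).
#' @param n_permutations number of random orderings (default 100) or `"all"`.
#' @param seed root seed; one independent child seed is derived per
#'   permutation.
#' @return object of class `rarefaction_result`: data.frame-like list with
#'   `n_stomachs`, `mean_taxa`, `sd_taxa`, `lo`, `hi`, plus `n_permutations`
#'   and `seed`.
#' @export
rarefaction_curve <- function(x, n_permutations = 100L, seed = 1L) {
  stopifnot(inherits(x, "diet_dataset"))
  pres <- diet_matrix(x, "presence", "with_food")
  k <- nrow(pres)
  if (k == 0) stop("no stomachs with food")
  pres <- pres[, colSums(pres) > 0, drop = FALSE]

  first_of <- function(ord) {
    # position of first occurrence of each taxon under ordering `ord`
    apply(pres[ord, , drop = FALSE], 2L, function(col) match(1, col))
  }

  if (identical(n_permutations, "all")) {
    if (k > 8) stop("exhaustive enumeration supported only for k <= 8")
    P <- perms_all(k)
    curves <- t(apply(P, 1L, function(ord) curve_from_order(first_of(ord), k)))
    n_perm <- nrow(P)
    seed_used <- NA_integer_
  } else {
    n_perm <- as.integer(n_permutations)
    stopifnot(n_perm >= 1L)
    seeds <- child_seeds(seed, n_perm)
    curves <- matrix(0, n_perm, k)
    for (p in seq_len(n_perm)) {
      set.seed(seeds[p])
      ord <- sample.int(k)
      curves[p, ] <- curve_from_order(first_of(ord), k)
    }
    seed_used <- as.integer(seed)
  }
  m <- colMeans(curves)
  s <- apply(curves, 2L, stats::sd)
  if (n_perm == 1L) s <- rep(0, k)
  structure(list(n_stomachs = seq_len(k), mean_taxa = m, sd_taxa = s,
                 lo = m - 2 * s, hi = m + 2 * s,
                 n_permutations = n_perm, seed = seed_used),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  k <- length(x$n_stomachs)
  cat("rarefaction over", k, "stomachs,", x$n_permutations,
      "permutations; terminal richness", x$mean_taxa[k], "\n")
  invisible(x)
}

#' Asymptote slope test for a rarefaction curve
#'
#' Fits an ordinary least-squares line to the rightmost `n_points` of the mean
#' accumulation curve and tests the slope against zero (two-sided t test with
#' `n_points - 2` df). A slope not significantly different from zero is taken
#' as evidence the curve has reached an asymptote. Degenerate fits (zero
#' residual variance) give p = 1 when the slope is zero and p = 0, with a
#' warning, when it is not.
#'
#' @param result a `rarefaction_result`.
#' @param n_points number of terminal points to fit (default 4).
#' @param alpha significance level for the asymptote call (default 0.05).
#' @return list with `slope`, `p_value`, `n_points`, `asymptote_reached`.
#' @export
asymptote_slope_test <- function(result, n_points = 4L, alpha = 0.05) {
  stopifnot(inherits(result, "rarefaction_result"))
  k <- length(result$n_stomachs)
  if (k < n_points) stop("curve has fewer than ", n_points, " points")
  idx <- (k - n_points + 1L):k
  xs <- result$n_stomachs[idx]
  ys <- result$mean_taxa[idx]
  fit <- stats::lm(ys ~ xs)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  scale <- max(sum(ys^2), 1)
  if (rss < 1e-12 * scale) {
    if (abs(slope) < 1e-12) {
      p <- 1
    } else {
      warning("degenerate fit: points lie exactly on a line of nonzero slope")
      p <- 0
    }
  } else {
    se <- summary(fit)$coefficients[2, 2]
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df = n_points - 2L)
  }
  list(slope = slope, p_value = p, n_points = as.integer(n_points),
       asymptote_reached = p >= alpha)
}

#' Bootstrap comparison of GII between two strata
#'
#' For each of `n_replicates` bootstrap replicates, stomachs with food are
#' resampled with replacement within each group (keeping the observed group
#' sizes), the relative measures of prey quantity are recomputed from the
#' replicate, and per-taxon GII values are compared between groups. A taxon
#' absent from a replicate scores GII 0; ties count in neither direction. A
#' taxon is significantly more important in a group when its GII is higher
#' there in more than 95% of replicates. Groups with fewer than `min_stomachs`
#' stomachs with food are refused (minimum-sample rule).
#'
#' @param x a `diet_dataset` with exclusions applied.
#' @param stratum_axis one of `"size_class"`, `"area"`, `"season_year"`,
#'   `"half_year"`.
#' @param level_a,level_b the two stratum levels to compare.
#' @param taxa taxon_ids to compare; default the six top-ranked by overall
#'   GII.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed root seed; independent child seed per replicate.
#' @param min_stomachs minimum with-food stomachs per group (default 10).
#' @return data.frame with one row per taxon: `prop_a_gt_b`, `significant`,
#'   `direction` (`"a"`, `"b"` or `"none"`), replicate count and seed.
#' @export
bootstrap_gii_compare <- function(x, stratum_axis, level_a, level_b,
                                  taxa = NULL, n_replicates = 1000L,
                                  seed = 1L, min_stomachs = 10L) {
  stopifnot(inherits(x, "diet_dataset"))
  lab <- assign_strata(x)
  v <- as.character(lab[[stratum_axis]])
  wf <- x$stomachs$status == "with_food"
  ids_a <- lab$stomach_id[wf & !is.na(v) & v == as.character(level_a)]
  ids_b <- lab$stomach_id[wf & !is.na(v) & v == as.character(level_b)]
  if (length(ids_a) < min_stomachs)
    stop("group '", level_a, "' has ", length(ids_a),
         " stomachs with food (< ", min_stomachs, ")")
  if (length(ids_b) < min_stomachs)
    stop("group '", level_b, "' has ", length(ids_b),
         " stomachs with food (< ", min_stomachs, ")")

  if (is.null(taxa)) {
    it <- index_table(x, min_stomachs = min_stomachs)
    taxa <- utils::head(it$taxon_id, 6L)
  }

  cnt <- diet_matrix(x, "count", "with_food")
  wgt <- diet_matrix(x, "weight", "with_food")
  prs <- diet_matrix(x, "presence", "with_food")
  tcol <- match(taxa, colnames(cnt))
  if (anyNA(tcol)) stop("unknown taxon_id(s): ",
                        paste(taxa[is.na(tcol)], collapse = ", "))

  gii_of <- function(rows) {
    C <- cnt[rows, , drop = FALSE]; W <- wgt[rows, , drop = FALSE]
    P <- prs[rows, , drop = FALSE]
    N <- colSums(C); Wt <- colSums(W); F_ <- colSums(P)
    pF <- 100 * F_ / length(rows)
    pN <- if (sum(N) > 0) 100 * N / sum(N) else N * 0
    pW <- if (sum(Wt) > 0) 100 * Wt / sum(Wt) else Wt * 0
    ((pF + pN + pW) / sqrt(3))[tcol]
  }

  ra <- match(ids_a, rownames(cnt)); rb <- match(ids_b, rownames(cnt))
  n_replicates <- as.integer(n_replicates)
  seeds <- child_seeds(seed, n_replicates)
  wins_a <- numeric(length(taxa)); wins_b <- numeric(length(taxa))
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    ga <- gii_of(ra[sample.int(length(ra), replace = TRUE)])
    gb <- gii_of(rb[sample.int(length(rb), replace = TRUE)])
    wins_a <- wins_a + (ga > gb)
    wins_b <- wins_b + (gb > ga)
  }
  prop <- wins_a / n_replicates
  sig <- prop > 0.95 | prop < 0.05
  dir <- ifelse(prop > 0.95, "a", ifelse(prop < 0.05, "b", "none"))
  data.frame(taxon_id = taxa, group_a = as.character(level_a),
             group_b = as.character(level_b),
             n_replicates = n_replicates, prop_a_gt_b = prop,
             significant = sig, direction = dir, seed = as.integer(seed),
             row.names = NULL, stringsAsFactors = FALSE)
}
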