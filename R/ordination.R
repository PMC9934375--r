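# Constrained ordination: chord transformation, dummy coding and redundancy
# analysis (RDA) with marginal permutation tests. The RDA is a direct
# least-squares implementation so the per-variable pseudo-F and the
# permutation scheme (permute the tested predictor's rows) are exactly as
# documented; vegan serves as an independent cross-check in the test suite.

#' Chord transformation
#'
#' Scales each row of a count matrix to unit Euclidean norm, so Euclidean
#' distances between transformed rows equal chord distances between the
#' original composition profiles. Down-weights rare taxa. Idempotent and
#' invariant to positive row scaling.
#'
#' @param m numeric matrix (stomachs x taxa), no all-zero rows.
#' @return matrix of the same shape with unit-norm rows.
#' @export
chord_transform <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    who <- if (!is.null(rownames(m))) rownames(m)[zero] else which(zero)
    stop("all-zero row(s): ", paste(who, collapse = ", "))
  }
  m / norms
}

#' Dummy-code a categorical variable
#'
#' Replaces a variable with X categories by X-1 binary columns, omitting the
#' declared reference level (whose value is implied when all the others are
#' known).
#'
#' @param x factor or character vector with at least 2 observed categories.
#' @param reference the level to omit; default the first sorted level.
#' @param prefix column-name prefix.
#' @return numeric 0/1 matrix with `length(levels) - 1` columns.
#' @export
dummy_code <- function(x, reference = NULL, prefix = "x") {
  x <- as.character(x)
  levs <- sort(unique(x[!is.na(x)]))
  if (length(levs) < 2) stop("need at least 2 observed categories")
  if (is.null(reference)) reference <- levs[1]
  if (!reference %in% levs) stop("reference level '", reference,
                                 "' not observed")
  keep <- setdiff(levs, reference)
  out <- vapply(keep, function(l) as.numeric(x == l), numeric(length(x)))
  colnames(out) <- paste0(prefix, "_", keep)
  out
}

#' Build an RDA design from a diet dataset
#'
#' Response: the stomach x taxon count matrix over stomachs with food and
#' complete predictors, with rare taxa (found in fewer than `min_stomachs`
#' stomachs) removed, chord-transformed. Predictors: eye-to-fork length and
#' SST as continuous columns; area and half-year as single dummies; fishing
#' seasons grouped into year classes, dummy-coded against `year_reference`.
#'
#' @param x a `diet_dataset` with exclusions applied.
#' @param min_stomachs rare-taxon inclusion threshold (default 4).
#' @param year_groups named list mapping group label to the seasons it
#'   contains; default the study grouping 2007 / 2008-2010 / 2011-2014.
#' @param year_reference year-group dummy omitted (default "2011-2014").
#' @return list with `response` (chord-transformed matrix), `predictors`
#'   (numeric matrix), `terms` (mapping variable -> columns), `stomach_ids`.
#' @export
rda_design <- function(x, min_stomachs = 4L,
                       year_groups = list("2007" = 2007,
                                          "2008-2010" = 2008:2010,
                                          "2011-2014" = 2011:2014),
                       year_reference = "2011-2014") {
  stopifnot(inherits(x, "diet_dataset"))
  lab <- assign_strata(x)
  st <- x$stomachs
  keep <- st$status == "with_food" & !is.na(st$efl_cm) & !is.na(st$sst_c) &
    !is.na(lab$area) & !is.na(lab$half_year)
  ids <- st$stomach_id[keep]
  cnt <- diet_matrix(x, "count", "all")[ids, , drop = FALSE]
  common <- colSums(cnt > 0)
  cnt <- cnt[, common >= min_stomachs, drop = FALSE]
  nz <- rowSums(cnt) > 0
  ids <- ids[nz]; cnt <- cnt[nz, , drop = FALSE]

  lab <- lab[match(ids, lab$stomach_id), ]
  st <- st[match(ids, st$stomach_id), ]
  ygrp <- rep(NA_character_, length(ids))
  for (g in names(year_groups)) ygrp[lab$season_year %in% year_groups[[g]]] <- g
  if (anyNA(ygrp)) stop("season year(s) outside the declared year groups: ",
                        paste(unique(lab$season_year[is.na(ygrp)]),
                              collapse = ", "))

  X <- cbind(EFL = st$efl_cm, SST = st$sst_c,
             dummy_code(lab$area, reference = "beyond_SCB", prefix = "area"),
             dummy_code(lab$half_year, reference = "second",
                        prefix = "half_year"))
  terms <- list(EFL = 1L, SST = 2L, area = 3L, half_year = 4L)
  if (length(unique(ygrp)) > 1) {
    yd <- dummy_code(ygrp, reference = year_reference, prefix = "year")
    for (j in seq_len(ncol(yd))) {
      X <- cbind(X, yd[, j, drop = FALSE])
      terms[[colnames(yd)[j]]] <- ncol(X)
    }
  }
  rownames(X) <- ids
  list(response = chord_transform(cnt), predictors = X, terms = terms,
       stomach_ids = ids)
}

rda_core <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(ncol(X)) || ncol(X) == 0) {
    # intercept-only model: nothing is explained beyond the centroid
    return(list(Yc = Yc, Xc = NULL, fitted = Yc * 0,
                ss_total = sum(Yc^2), ss_fit = 0))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    drop <- colnames(Xc)[qrx$pivot[(qrx$rank + 1L):ncol(Xc)]]
    stop("rank-deficient predictors; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fitted <- qr.fitted(qrx, Yc)
  list(Yc = Yc, Xc = Xc, fitted = fitted,
       ss_total = sum(Yc^2), ss_fit = sum(fitted^2))
}

#' Fit a redundancy analysis
#'
#' Regresses the (already transformed) multivariate response on the centered
#' predictors and ordinates the fitted values. Reports the constrained
#' fraction of total variance, the per-axis fractions of the constrained
#' variance (eigendecomposition of the fitted-value matrix), and for each
#' variable a marginal pseudo-F: the drop in explained sum of squares when
#' the variable's columns are removed, per df, over the full-model residual
#' mean square.
#'
#' @param response numeric matrix (rows = stomachs); pass a chord-transformed
#'   matrix for chord-distance RDA.
#' @param predictors numeric matrix or data.frame; factor/character columns
#'   are dummy-coded automatically.
#' @param terms optional named list mapping variable names to predictor
#'   column indices (as from [rda_design()]); default one term per column.
#' @return object of class `rda_result`: `total_constrained_fraction`,
#'   `axis_fractions`, `pseudo_f` (named), dfs, and the fitted pieces needed
#'   by [rda_permutation_test()].
#' @export
fit_rda <- function(response, predictors, terms = NULL) {
  Y <- as.matrix(response)
  X <- build_predictor_matrix(predictors)
  if (nrow(Y) != nrow(X)) stop("response and predictors disagree on rows")
  if (nrow(Y) <= ncol(X) + 1) stop("need more rows than predictors + 1")
  if (is.null(terms)) {
    terms <- as.list(seq_len(ncol(X)))
    names(terms) <- colnames(X)
  }
  core <- rda_core(Y, X)
  n <- nrow(Y); p <- ncol(X)
  resid_df <- n - 1L - p
  ms_resid <- (core$ss_total - core$ss_fit) / resid_df

  sv <- svd(core$fitted, nu = 0, nv = 0)$d
  ev <- sv^2
  ev <- ev[ev > max(ev, 0) * 1e-12]
  axis_fractions <- if (length(ev)) ev / sum(ev) else numeric(0)

  pseudo_f <- vapply(names(terms), function(v) {
    cols <- terms[[v]]
    red <- rda_core(Y, X[, -cols, drop = FALSE])
    ss_v <- core$ss_fit - red$ss_fit
    (ss_v / length(cols)) / ms_resid
  }, 0)

  structure(list(total_constrained_fraction = core$ss_fit / core$ss_total,
                 axis_fractions = axis_fractions,
                 pseudo_f = pseudo_f,
                 df = vapply(terms, length, 0L),
                 residual_df = resid_df,
                 response = Y, predictors = X, terms = terms),
            class = "rda_result")
}

build_predictor_matrix <- function(predictors) {
  if (is.matrix(predictors)) {
    storage.mode(predictors) <- "double"
    return(predictors)
  }
  df <- as.data.frame(predictors, stringsAsFactors = FALSE)
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- matrix(v, dimnames = list(NULL, nm))
    } else {
      cols[[nm]] <- dummy_code(v, prefix = nm)
    }
  }
  do.call(cbind, cols)
}

#' @export
print.rda_result <- function(x, ...) {
  cat("RDA:", nrow(x$response), "sites,", ncol(x$response), "response vars,",
      ncol(x$predictors), "predictor cols\n")
  cat("constrained fraction:",
      format(x$total_constrained_fraction, digits = 4), "\n")
  if (length(x$axis_fractions))
    cat("axis fractions:", paste(format(x$axis_fractions[
      seq_len(min(4, length(x$axis_fractions)))], digits = 4),
      collapse = " "), "\n")
  print(round(x$pseudo_f, 3))
  invisible(x)
}

#' Permutation test for one RDA variable
#'
#' Permutes the rows of the tested variable's predictor columns (all other
#' predictors fixed), recomputes the marginal pseudo-F, and reports
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`. The smallest
#' attainable p is therefore `1 / (1 + n_permutations)` (0.005 at the default
#' 199 permutations).
#'
#' @param fit an `rda_result` from [fit_rda()].
#' @param variable a name from `fit$terms`.
#' @param n_permutations at least 19 (default 199).
#' @param seed root seed; independent child seed per permutation.
#' @return list with `variable`, `f_observed`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
rda_permutation_test <- function(fit, variable, n_permutations = 199L,
                                 seed = 1L) {
  stopifnot(inherits(fit, "rda_result"))
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 19L) stop("need at least 19 permutations")
  if (!variable %in% names(fit$terms)) stop("unknown variable: ", variable)
  cols <- fit$terms[[variable]]
  Y <- fit$response; X <- fit$predictors
  n <- nrow(X); p <- ncol(X)

  f_of <- function(Xv) {
    core <- rda_core(Y, Xv)
    red <- rda_core(Y, Xv[, -cols, drop = FALSE])
    ms_resid <- (core$ss_total - core$ss_fit) / (n - 1L - p)
    ((core$ss_fit - red$ss_fit) / length(cols)) / ms_resid
  }
  f_obs <- f_of(X)
  seeds <- child_seeds(seed, n_permutations)
  count <- 0L
  for (i in seq_len(n_permutations)) {
    set.seed(seeds[i])
    Xp <- X
    Xp[, cols] <- X[sample.int(n), cols, drop = FALSE]
    if (f_of(Xp) >= f_obs) count <- count + 1L
  }
  list(variable = variable, f_observed = f_obs,
       p_value = (1 + count) / (1 + n_permutations),
       n_permutations = n_permutations, seed = as.integer(seed))
}
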