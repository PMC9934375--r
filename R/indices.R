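# Relative measures of prey quantity (%F, %N, %W) and the combined importance
# indices: GII/%GII, IRI/%IRI, and the prey-specific %PSIRI. These are the
# analytical core of the package.

#' Relative measures of prey quantity
#'
#' Per-taxon frequency of occurrence, total count and total weight with their
#' percentage forms over a set of stomachs. Denominators follow the standard
#' convention: `%F = 100 F / k` where `k` counts only stomachs with food
#' (empty and slurry-only stomachs never enter the percentages), while `%N`
#' and `%W` are pooled taxon totals over the grand totals. Weights are
#' as-found totals (digested material contributes what remains, with no
#' back-calculation to ingested mass).
#'
#' @param x a `diet_dataset` with exclusions already applied.
#' @return data.frame with `taxon_id`, `F`, `pF`, `N`, `pN`, `W_g`, `pW` for
#'   every taxon that occurs.
#' @export
rmpq_table <- function(x) {
  stopifnot(inherits(x, "diet_dataset"))
  wf_ids <- x$stomachs$stomach_id[x$stomachs$status == "with_food"]
  k <- length(wf_ids)
  if (k == 0) stop("no stomachs with food; percentages are undefined")
  p <- x$prey[x$prey$stomach_id %in% wf_ids &
                (x$prey$count > 0 | x$prey$weight_g > 0), , drop = FALSE]
  taxa <- x$taxa$taxon_id[x$taxa$taxon_id %in% p$taxon_id]
  F_ <- vapply(taxa, function(t)
    length(unique(p$stomach_id[p$taxon_id == t])), 0L)
  N <- vapply(taxa, function(t) sum(p$count[p$taxon_id == t]), 0)
  W <- vapply(taxa, function(t) sum(p$weight_g[p$taxon_id == t]), 0)
  data.frame(taxon_id = taxa, F = as.integer(F_), pF = 100 * F_ / k,
             N = as.integer(N), pN = 100 * N / sum(N),
             W_g = W, pW = if (sum(W) > 0) 100 * W / sum(W) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

check_pct <- function(...) {
  for (v in list(...)) {
    if (any(is.na(v)) || any(v < 0) || any(v > 100))
      stop("percentage inputs must lie in [0, 100]")
  }
}

#' Geometric index of importance
#'
#' Combines the three relative measures of prey quantity into a single rank
#' score: with `n = 3` measures, `GII = (%W + %N + %F) / sqrt(n)` and its
#' percentage-scale form `%GII = (%W + %N + %F) / n`, so `GII = sqrt(3) %GII`
#' and `%GII` ranges over \[0, 100\].
#'
#' @param pW,pN,pF percentages in \[0, 100\] (vectorized).
#' @return list with components `gii` and `pct_gii`.
#' @export
gii <- function(pW, pN, pF) {
  check_pct(pW, pN, pF)
  s <- pW + pN + pF
  list(gii = s / sqrt(3), pct_gii = s / 3)
}

#' Index of relative importance
#'
#' `IRI = (%N + %W) * %F`, ranging over \[0, 20000\].
#'
#' @param pN,pW,pF percentages in \[0, 100\] (vectorized).
#' @return numeric vector.
#' @export
iri <- function(pN, pW, pF) {
  check_pct(pN, pW, pF)
  (pN + pW) * pF
}

#' Percentage IRI
#'
#' Normalizes IRI values across taxa: `%IRI_j = 100 IRI_j / sum(IRI)`.
#'
#' @param iri_values non-negative IRI values, at least one positive.
#' @return numeric vector summing to 100.
#' @export
pct_iri <- function(iri_values) {
  if (any(is.na(iri_values)) || any(iri_values < 0))
    stop("IRI values must be non-negative")
  tot <- sum(iri_values)
  if (tot == 0) stop("all IRI values are zero; %IRI is undefined")
  100 * iri_values / tot
}

#' Prey-specific IRI components
#'
#' Within each stomach the count and weight of a taxon are expressed as
#' percentages of that stomach's totals; the prey-specific abundances `%PN`
#' and `%PW` average these within-stomach percentages over the stomachs that
#' contain the taxon (`divisor = "occupied"`, the prey-specific convention).
#' The stomach-averaged compositions follow as `pN = %F %PN / 100` and
#' `pW = %F %PW / 100`, and `%PSIRI = %F (%PN + %PW) / 200 = (pN + pW) / 2`,
#' which sums to 100 across taxa. `divisor = "all"` divides the sums by the
#' number of stomachs with food instead (the literal formula variant, kept
#' for audit).
#'
#' @param x a `diet_dataset` with exclusions applied.
#' @param divisor `"occupied"` (default) or `"all"`.
#' @return data.frame with `taxon_id`, `pF`, `pPN`, `pPW`, `pN`, `pW`
#'   (stomach-averaged compositions) and `pct_psiri`.
#' @export
psiri <- function(x, divisor = c("occupied", "all")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(x, "diet_dataset"))
  wf_ids <- x$stomachs$stomach_id[x$stomachs$status == "with_food"]
  k <- length(wf_ids)
  if (k == 0) stop("no stomachs with food; percentages are undefined")
  p <- x$prey[x$prey$stomach_id %in% wf_ids &
                (x$prey$count > 0 | x$prey$weight_g > 0), , drop = FALSE]
  tot_n <- tapply(p$count, p$stomach_id, sum)
  tot_w <- tapply(p$weight_g, p$stomach_id, sum)
  n_pct <- ifelse(tot_n[p$stomach_id] > 0,
                  100 * p$count / tot_n[p$stomach_id], 0)
  w_pct <- ifelse(tot_w[p$stomach_id] > 0,
                  100 * p$weight_g / tot_w[p$stomach_id], 0)
  taxa <- x$taxa$taxon_id[x$taxa$taxon_id %in% p$taxon_id]
  rows <- lapply(taxa, function(t) {
    sel <- p$taxon_id == t
    F_ <- length(unique(p$stomach_id[sel]))
    div <- if (divisor == "occupied") F_ else k
    pPN <- sum(n_pct[sel]) / div
    pPW <- sum(w_pct[sel]) / div
    pF <- 100 * F_ / k
    data.frame(taxon_id = t, pF = pF, pPN = pPN, pPW = pPW,
               pN = pF * pPN / 100, pW = pF * pPW / 100,
               pct_psiri = pF * (pPN + pPW) / 200,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prey-specific IRI from composition percentages
#'
#' The identity form `%PSIRI = (%N + %W) / 2`, for computing the index
#' directly from published composition-by-number and composition-by-weight
#' columns.
#'
#' @param pN,pW percentages in \[0, 100\].
#' @return numeric vector.
#' @export
psiri_from_rmpq <- function(pN, pW) {
  check_pct(pN, pW)
  (pN + pW) / 2
}

#' Combined importance index table
#'
#' The full per-taxon table: relative measures of prey quantity, GII/%GII,
#' IRI/%IRI, prey-specific components and %PSIRI, with ranks, sorted by GII
#' decreasing (ties broken by %IRI then taxon_id). Following the
#' minimum-sample rule, no table is produced when fewer than `min_stomachs`
#' stomachs contain food, since small samples produce biased index values.
#'
#' @param x a `diet_dataset` with exclusions applied.
#' @param min_stomachs minimum stomachs with food (default 10).
#' @return data.frame, one row per occurring taxon.
#' @export
index_table <- function(x, min_stomachs = 10L) {
  stopifnot(inherits(x, "diet_dataset"))
  k <- sum(x$stomachs$status == "with_food")
  if (k < min_stomachs)
    stop("only ", k, " stomachs with food (< ", min_stomachs,
         "); no index value is estimated for samples this small")
  r <- rmpq_table(x)
  g <- gii(r$pW, r$pN, r$pF)
  iri_v <- iri(r$pN, r$pW, r$pF)
  ps <- psiri(x)
  ps <- ps[match(r$taxon_id, ps$taxon_id), ]
  out <- data.frame(taxon_id = r$taxon_id,
                    name = x$taxa$name[match(r$taxon_id, x$taxa$taxon_id)],
                    W_g = r$W_g, pW = r$pW, N = r$N, pN = r$pN,
                    F = r$F, pF = r$pF,
                    gii = g$gii, pct_gii = g$pct_gii,
                    iri = iri_v, pct_iri = pct_iri(iri_v),
                    pPN = ps$pPN, pPW = ps$pPW, pct_psiri = ps$pct_psiri,
                    stringsAsFactors = FALSE)
  out$rank_gii <- rank(-out$gii, ties.method = "min")
  out$rank_iri <- rank(-out$iri, ties.method = "min")
  ord <- order(-out$gii, -out$pct_iri, out$taxon_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
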