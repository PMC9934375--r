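# Shared fixture builders and independent oracles.

# Build a diet_dataset from a compact spec: `contents` is a list, one element
# per stomach, each a data.frame with taxon_id, count, weight_g (and optional
# further prey columns). NULL elements are empty stomachs.
make_dataset <- function(contents, efl = NULL, lon = NULL, date = NULL,
                         sst = NULL, taxa_ids = NULL) {
  n <- length(contents)
  ids <- sprintf("st%02d", seq_len(n))
  full_cols <- c("stomach_id", "taxon_id", "count", "weight_g",
                 paste0("ds", 1:6), "upper_beaks", "lower_beaks",
                 "otoliths_left", "otoliths_right", "intact_individuals",
                 "lengths_mm", "net_feeding_flag", "secondary_prey_flag")
  prey_rows <- list()
  for (i in seq_len(n)) {
    ct <- contents[[i]]
    if (is.null(ct) || nrow(ct) == 0) next
    ct$stomach_id <- ids[i]
    # items default to an advanced digestion state unless states were given
    if (!any(paste0("ds", 1:6) %in% names(ct))) ct$ds4 <- ct$count
    for (nm in setdiff(full_cols, names(ct))) {
      ct[[nm]] <- if (nm == "lengths_mm") I(replicate(nrow(ct), numeric(0),
                                                      simplify = FALSE))
      else if (grepl("flag", nm)) FALSE else 0L
    }
    prey_rows[[length(prey_rows) + 1L]] <- ct[full_cols]
  }
  prey <- if (length(prey_rows)) do.call(rbind, prey_rows) else
    data.frame(stomach_id = character(0), taxon_id = character(0),
               count = integer(0), weight_g = numeric(0))
  if (is.null(taxa_ids)) taxa_ids <- sort(unique(prey$taxon_id))
  if (!length(taxa_ids)) taxa_ids <- "tx1"
  taxa <- data.frame(taxon_id = taxa_ids, name = taxa_ids, rank = "species",
                     group_label = NA_character_, stringsAsFactors = FALSE)
  status <- vapply(seq_len(n), function(i) {
    ct <- contents[[i]]
    if (!is.null(ct) && nrow(ct) > 0 && any(ct$count > 0 | ct$weight_g > 0))
      "with_food" else "empty"
  }, "")
  stomachs <- data.frame(
    stomach_id = ids,
    efl_cm = if (is.null(efl)) rep(150, n) else efl,
    date = if (is.null(date)) rep(as.Date("2010-10-01"), n) else
      as.Date(date),
    longitude_deg = if (is.null(lon)) rep(-119, n) else lon,
    latitude_deg = rep(32, n),
    sst_c = if (is.null(sst)) rep(18, n) else sst,
    status = status, stringsAsFactors = FALSE)
  diet_dataset(stomachs, prey, taxa)
}

occ <- function(taxon_id, count, weight_g, ...) {
  data.frame(taxon_id = taxon_id, count = count, weight_g = weight_g, ...,
             stringsAsFactors = FALSE)
}

# small random dataset for property suites: k stomachs, up to n_taxa taxa,
# every stomach non-empty
random_dataset <- function(seed, k = 12, n_taxa = 5) {
  set.seed(seed)
  taxa_ids <- sprintf("tx%d", seq_len(n_taxa))
  contents <- lapply(seq_len(k), function(i) {
    m <- sample.int(n_taxa, 1)
    pick <- sample(taxa_ids, m)
    occ(pick, count = rpois(m, 2) + 1L,
        weight_g = round(rlnorm(m, 2, 1), 3))
  })
  make_dataset(contents, taxa_ids = taxa_ids)
}

# deliberately naive double-loop oracle for the RMPQ/index arithmetic
naive_indices <- function(x) {
  wf <- x$stomachs$stomach_id[x$stomachs$status == "with_food"]
  k <- length(wf)
  taxa <- sort(unique(x$prey$taxon_id))
  out <- NULL
  tot_n <- 0; tot_w <- 0
  for (t in taxa) {
    for (s in wf) {
      r <- x$prey[x$prey$stomach_id == s & x$prey$taxon_id == t, ]
      tot_n <- tot_n + sum(r$count); tot_w <- tot_w + sum(r$weight_g)
    }
  }
  for (t in taxa) {
    F_ <- 0; N <- 0; W <- 0; ppn <- 0; ppw <- 0
    for (s in wf) {
      r <- x$prey[x$prey$stomach_id == s & x$prey$taxon_id == t, ]
      if (nrow(r) == 0 || (sum(r$count) == 0 && sum(r$weight_g) == 0)) next
      F_ <- F_ + 1; N <- N + sum(r$count); W <- W + sum(r$weight_g)
      all_s <- x$prey[x$prey$stomach_id == s, ]
      ppn <- ppn + 100 * sum(r$count) / sum(all_s$count)
      ppw <- ppw + 100 * sum(r$weight_g) / sum(all_s$weight_g)
    }
    pF <- 100 * F_ / k; pN <- 100 * N / tot_n; pW <- 100 * W / tot_w
    out <- rbind(out, data.frame(
      taxon_id = t, F = F_, pF = pF, pN = pN, pW = pW,
      gii = (pF + pN + pW) / sqrt(3), pct_gii = (pF + pN + pW) / 3,
      iri = (pN + pW) * pF,
      pPN = ppn / F_, pPW = ppw / F_,
      pct_psiri = pF * (ppn / F_ + ppw / F_) / 200,
      stringsAsFactors = FALSE))
  }
  out
}

# closed-form rarefaction expectation: P(taxon t seen in first d of k) =
# 1 - C(k - F_t, d) / C(k, d)
rarefaction_expectation <- function(pres) {
  k <- nrow(pres)
  Fs <- colSums(pres > 0)
  Fs <- Fs[Fs > 0]
  vapply(seq_len(k), function(d)
    sum(1 - choose(k - Fs, d) / choose(k, d)), 0)
}
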