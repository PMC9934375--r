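# Published aggregate tables for broadbill swordfish diet in the California
# Current, shipped as plain-text fixtures. Used to validate the index
# arithmetic against independently computed values.

parse_censored <- function(x) {
  # printed below-detection entries "<0.1"/"<0.01" are parsed at the interval
  # midpoint; the caller gets a logical censoring flag alongside
  cens <- grepl("^<", x)
  val <- suppressWarnings(as.numeric(sub("^<", "", x)))
  val[cens] <- val[cens] / 2
  list(value = val, censored = cens)
}

#' Published swordfish diet-composition reference table
#'
#' The per-taxon relative measures of prey quantity (W, %W, N, %N, F, %F) and
#' combined indices (GII, %GII, IRI, %IRI, %PSIRI) for 292 swordfish stomachs
#' with food, as printed. Entries printed as "<0.1" g or "<0.01" % are
#' returned at the interval midpoint with `*_censored` flags.
#'
#' @return data.frame, one row per prey taxon in decreasing GII order.
#' @export
swordfish_rmpq <- function() {
  path <- system.file("extdata", "swordfish_rmpq.csv", package = "dietcomp",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  out <- data.frame(taxon = raw$taxon, stringsAsFactors = FALSE)
  for (nm in c("W_g", "pW", "pIRI")) {
    p <- parse_censored(raw[[nm]])
    out[[nm]] <- p$value
    out[[paste0(nm, "_censored")]] <- p$censored
  }
  for (nm in c("N", "pN", "F", "pF", "GII", "pGII", "IRI", "pPSIRI"))
    out[[nm]] <- as.numeric(raw[[nm]])
  out
}

#' Published sample-size table by stratum
#'
#' Stomach counts (all / with food / percent with food) by predator size
#' class, area and fishing season for the 299-stomach study sample.
#'
#' @return data.frame with `axis`, `level`, `n_all`, `n_with_food`,
#'   `pct_with_food`.
#' @export
swordfish_sample_counts <- function() {
  path <- system.file("extdata", "swordfish_sample_counts.csv",
                      package = "dietcomp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(level = "character"))
}

#' Published prey-size summary table
#'
#' Size range, mean and median (whole mm, truncated) for 328 measured prey
#' items in fresh or intermediate digestion state; means and medians are
#' reported only for taxa with at least two specimens.
#'
#' @return data.frame with `taxon`, `n`, `size_min`, `size_max`, `mean_mm`,
#'   `median_mm`.
#' @export
swordfish_prey_sizes <- function() {
  path <- system.file("extdata", "swordfish_prey_sizes.csv",
                      package = "dietcomp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
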