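# Laboratory-protocol processing: minimum numbers from paired hard parts,
# exclusion of net-feeding and secondary prey, prey-size summaries and the
# digestion-state profile.

#' Minimum number of prey individuals from hard parts
#'
#' Otoliths and squid beaks are counted in pairs; the higher count of each
#' pair type is the minimum number of individuals it represents, and intact
#' individuals are added on top:
#' `max(upper_beaks, lower_beaks) + max(otoliths_left, otoliths_right) +
#' intact_individuals`. Vectorized; monotone non-decreasing in every argument.
#'
#' @param upper_beaks,lower_beaks cephalopod beak counts.
#' @param otoliths_left,otoliths_right teleost sagittal otolith counts.
#' @param intact_individuals whole (countable) individuals.
#' @return integer vector of minimum numbers.
#' @export
minimum_number <- function(upper_beaks = 0L, lower_beaks = 0L,
                           otoliths_left = 0L, otoliths_right = 0L,
                           intact_individuals = 0L) {
  args <- list(upper_beaks, lower_beaks, otoliths_left, otoliths_right,
               intact_individuals)
  for (a in args) {
    if (any(is.na(a)) || any(a < 0) || any(a != floor(a)))
      stop("hard-part and intact counts must be non-negative integers")
  }
  as.integer(pmax(upper_beaks, lower_beaks) +
               pmax(otoliths_left, otoliths_right) + intact_individuals)
}

#' Apply the net-feeding and secondary-prey exclusions
#'
#' Removes flagged occurrences (prey taken from the net at capture, in fresh
#' digestion states; prey of prey) and recomputes stomach statuses: a stomach
#' whose only contents were excluded is reclassified `empty`. Optionally, an
#' occurrence whose mean item weight reaches `mass_threshold_g` while it
#' contains fresh/intermediate items (states 1-2) is treated as net feeding --
#' off by default since the field protocol flags these upstream.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param x a `diet_dataset`.
#' @param mass_threshold_g optional numeric; `NULL` disables the mass rule.
#' @return list with `dataset` (filtered, statuses recomputed) and `report`
#'   (counts of removals by reason and statuses changed).
#' @export
apply_exclusions <- function(x, mass_threshold_g = NULL) {
  stopifnot(inherits(x, "diet_dataset"))
  p <- x$prey
  net <- p$net_feeding_flag %in% TRUE
  sec <- p$secondary_prey_flag %in% TRUE
  mass <- rep(FALSE, nrow(p))
  if (!is.null(mass_threshold_g) && nrow(p)) {
    mean_item <- p$weight_g / pmax(p$count, 1L)
    mass <- mean_item >= mass_threshold_g & (p$ds1 + p$ds2) > 0
  }
  drop <- net | sec | mass
  kept <- p[!drop, , drop = FALSE]
  rownames(kept) <- NULL

  st <- x$stomachs
  food_ids <- unique(kept$stomach_id[kept$count > 0 | kept$weight_g > 0])
  new_status <- st$status
  lost <- st$status == "with_food" & !st$stomach_id %in% food_ids
  new_status[lost] <- "empty"
  changed <- sum(new_status != st$status)
  st$status <- new_status

  out <- structure(list(stomachs = st, prey = kept, taxa = x$taxa,
                        provenance = x$provenance), class = "diet_dataset")
  validate_diet_dataset(out)
  report <- data.frame(reason = c("net_feeding", "secondary_prey",
                                  "mass_threshold"),
                       n_removed = c(sum(net), sum(sec & !net),
                                     sum(mass & !net & !sec)),
                       stringsAsFactors = FALSE)
  attr(report, "statuses_changed") <- changed
  list(dataset = out, report = report)
}

#' Prey-size summary table
#'
#' Per-taxon count, range, mean and median of length measurements taken on
#' fresh/intermediate items. Printed means and medians are truncated toward
#' zero to whole mm (so 217.5 reports as 217), with full precision retained in
#' `raw_mean_mm`/`raw_median_mm`; mean and median are only reported for taxa
#' with at least `min_n` measured specimens -- a single measurement appears as
#' its range only.
#'
#' @param x a `diet_dataset`.
#' @param min_n minimum specimens for mean/median (default 2).
#' @param include_state3 admit occurrences whose only measurable items are in
#'   digestion state 3 (reconstructable skeletons); default `FALSE` restricts
#'   to occurrences holding state 1-2 items.
#' @return data.frame sorted by `n_measured` decreasing.
#' @export
prey_size_table <- function(x, min_n = 2L, include_state3 = FALSE) {
  stopifnot(inherits(x, "diet_dataset"))
  p <- x$prey
  measurable <- (p$ds1 + p$ds2 + if (include_state3) p$ds3 else 0L) > 0
  has_len <- vapply(p$lengths_mm, length, 0L) > 0
  p <- p[measurable & has_len, , drop = FALSE]
  taxa <- unique(p$taxon_id)
  rows <- lapply(taxa, function(tid) {
    lens <- unlist(p$lengths_mm[p$taxon_id == tid], use.names = FALSE)
    n <- length(lens)
    full_mean <- mean(lens)
    full_med <- stats::median(lens)
    data.frame(taxon_id = tid, n_measured = n,
               min_mm = min(lens), max_mm = max(lens),
               mean_mm = if (n >= min_n) trunc(full_mean) else NA_real_,
               median_mm = if (n >= min_n) trunc(full_med) else NA_real_,
               raw_mean_mm = if (n >= min_n) full_mean else NA_real_,
               raw_median_mm = if (n >= min_n) full_med else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(taxon_id = character(0),
                                      n_measured = integer(0)))
  out[order(-out$n_measured, out$taxon_id), , drop = FALSE]
}

#' Digestion-state profile
#'
#' Proportion of food items in each of the six digestion states (1 fresh ...
#' 6 fully digested slurry), over all recorded item-state tallies.
#'
#' @param x a `diet_dataset`.
#' @return named numeric vector of length 6 summing to 1.
#' @export
digestion_profile <- function(x) {
  stopifnot(inherits(x, "diet_dataset"))
  tot <- vapply(paste0("ds", 1:6), function(nm) sum(x$prey[[nm]]), 0)
  if (sum(tot) == 0) stop("no items with recorded digestion states")
  prop <- tot / sum(tot)
  names(prop) <- paste0("state", 1:6)
  prop
}
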