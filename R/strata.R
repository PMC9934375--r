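# Stratification of stomachs into the study's analysis groups: predator size
# class, inshore/offshore area, fishing-season year and half-season.

#' Assign stratification labels to stomachs
#'
#' Labels each stomach on four axes:
#' \describe{
#'   \item{size_class}{`small` if eye-to-fork length < 165 cm, `large` if
#'     >= 165 cm, `NA` when EFL is missing.}
#'   \item{area}{`within_SCB` when longitude is strictly east of 120 deg 30' W
#'     (i.e. `longitude_deg > -120.5`), else `beyond_SCB`; the exact boundary
#'     falls in `beyond_SCB`.}
#'   \item{season_year}{the fishing season runs Aug 15 through Jan 31 and is
#'     labelled by its start year: months Aug-Dec keep the calendar year,
#'     Jan (and any straggler through Jul) map to the previous year.}
#'   \item{half_year}{`first` for Aug 15 - Nov 7, `second` for Nov 8 - Jan 31;
#'     `NA` (with a warning) for dates outside the season window.}
#' }
#'
#' @param x a `diet_dataset` or a stomachs data.frame.
#' @return data.frame with `stomach_id`, `size_class`, `area`, `season_year`,
#'   `half_year`.
#' @export
assign_strata <- function(x) {
  st <- if (inherits(x, "diet_dataset")) x$stomachs else x
  stopifnot(all(c("stomach_id", "date") %in% names(st)))
  date <- as.Date(st$date)
  if (anyNA(date)) stop("missing date for stomach(s): ",
                        paste(st$stomach_id[is.na(date)], collapse = ", "))
  mon <- as.integer(format(date, "%m"))
  day <- as.integer(format(date, "%d"))
  yr <- as.integer(format(date, "%Y"))
  md <- mon * 100L + day

  size_class <- ifelse(is.na(st$efl_cm), NA_character_,
                       ifelse(st$efl_cm < 165, "small", "large"))
  area <- ifelse(is.na(st$longitude_deg), NA_character_,
                 ifelse(st$longitude_deg > -120.5, "within_SCB",
                        "beyond_SCB"))
  season_year <- ifelse(mon >= 8L, yr, yr - 1L)

  in_window <- md >= 815L | md <= 131L
  if (any(!in_window))
    warning(sum(!in_window), " stomach(s) dated outside the Aug 15 - Jan 31 ",
            "season window; half_year set to NA")
  half_year <- rep(NA_character_, length(md))
  half_year[md >= 815L & md <= 1107L] <- "first"
  half_year[md >= 1108L | md <= 131L] <- "second"

  data.frame(stomach_id = st$stomach_id, size_class = size_class,
             area = area, season_year = as.integer(season_year),
             half_year = half_year, stringsAsFactors = FALSE)
}

#' Tabulate sample sizes by stratum
#'
#' For each stratification axis, counts all stomachs, stomachs with food, and
#' the percentage with food (1 decimal, the reporting convention of
#' sample-composition tables). Stomachs with a missing label on an axis are
#' omitted from that axis.
#'
#' @param x a `diet_dataset` (strata are assigned internally).
#' @param axes which axes to tabulate.
#' @return data.frame with `axis`, `level`, `n_all`, `n_with_food`,
#'   `pct_with_food`.
#' @export
stratum_counts <- function(x, axes = c("size_class", "area", "season_year",
                                       "half_year")) {
  stopifnot(inherits(x, "diet_dataset"))
  lab <- assign_strata(x)
  wf <- x$stomachs$status[match(lab$stomach_id, x$stomachs$stomach_id)] ==
    "with_food"
  out <- list()
  for (ax in axes) {
    v <- lab[[ax]]
    keep <- !is.na(v)
    levs <- sort(unique(v[keep]))
    for (lv in levs) {
      sel <- keep & v == lv
      n_all <- sum(sel)
      n_wf <- sum(wf[sel])
      out[[length(out) + 1L]] <- data.frame(
        axis = ax, level = as.character(lv), n_all = n_all,
        n_with_food = n_wf,
        pct_with_food = if (n_all > 0) round(100 * n_wf / n_all, 1) else NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
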