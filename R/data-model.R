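# Tabular data model: a diet dataset is three linked tables (stomachs, prey
# occurrences, taxa). Kept as plain data.frames inside a lightweight S3 class
# so every downstream operation is ordinary data-frame arithmetic.

STATUS_LEVELS <- c("with_food", "empty", "slurry_only")
RANK_LEVELS <- c("species", "genus", "family", "order", "higher")

STOMACH_COLS <- c("stomach_id", "efl_cm", "date", "longitude_deg",
                  "latitude_deg", "sst_c", "status")
PREY_COLS <- c("stomach_id", "taxon_id", "count", "weight_g",
               paste0("ds", 1:6), "upper_beaks", "lower_beaks",
               "otoliths_left", "otoliths_right", "intact_individuals",
               "lengths_mm", "net_feeding_flag", "secondary_prey_flag")
TAXA_COLS <- c("taxon_id", "name", "rank", "group_label")

#' Construct a diet dataset
#'
#' Bundles the three tables of the stomach-content data model and validates
#' them. `stomachs` holds one row per predator stomach with covariates and a
#' status (`with_food`, `empty`, `slurry_only`); `prey` one row per taxon
#' occurrence within a stomach (count, weight in g, per-state digestion tallies
#' `ds1`..`ds6`, hard-part counts, a numeric-list column `lengths_mm`, and the
#' two exclusion flags); `taxa` the taxon dictionary.
#'
#' @param stomachs data.frame with columns `stomach_id`, `efl_cm`, `date`
#'   (Date), `longitude_deg` (decimal degrees, west negative), `latitude_deg`,
#'   `sst_c`, `status`.
#' @param prey data.frame of prey occurrences; `lengths_mm` may be a
#'   semicolon-separated character column or a list of numeric vectors.
#' @param taxa data.frame with `taxon_id`, `name`, `rank` (one of species,
#'   genus, family, order, higher), `group_label`.
#' @param provenance free-text metadata (source file, simulation seed, ...).
#' @return An object of class `diet_dataset`.
#' @export
diet_dataset <- function(stomachs, prey, taxa, provenance = "") {
  stomachs <- as.data.frame(stomachs, stringsAsFactors = FALSE)
  prey <- as.data.frame(prey, stringsAsFactors = FALSE)
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)

  # tolerate missing optional prey columns (filled with inert defaults)
  defaults <- list(ds1 = 0L, ds2 = 0L, ds3 = 0L, ds4 = 0L, ds5 = 0L, ds6 = 0L,
                   upper_beaks = 0L, lower_beaks = 0L, otoliths_left = 0L,
                   otoliths_right = 0L, intact_individuals = 0L,
                   net_feeding_flag = FALSE, secondary_prey_flag = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(prey)) prey[[nm]] <- rep(defaults[[nm]], nrow(prey))
  }
  if (!"lengths_mm" %in% names(prey)) {
    prey$lengths_mm <- rep(list(numeric(0)), nrow(prey))
  }
  if (is.character(prey$lengths_mm)) {
    prey$lengths_mm <- parse_lengths(prey$lengths_mm)
  }
  if (!"group_label" %in% names(taxa)) taxa$group_label <- NA_character_
  stomachs$date <- as.Date(stomachs$date)

  x <- structure(list(stomachs = stomachs, prey = prey, taxa = taxa,
                      provenance = provenance),
                 class = "diet_dataset")
  validate_diet_dataset(x)
  x
}

#' Validate a diet dataset
#'
#' Checks schema (mandatory columns), value constraints (non-negative counts
#' and weights, counts at least the number of intact individuals, ranks and
#' statuses from their closed sets), referential integrity (every occurrence's
#' `taxon_id` and `stomach_id` resolve), and the status invariant: a stomach is
#' `with_food` iff it has at least one occurrence with positive count or
#' weight, and empty/slurry-only stomachs carry no occurrences.
#'
#' @param x a `diet_dataset`.
#' @return `x`, invisibly; errors describe every offending row.
#' @export
validate_diet_dataset <- function(x) {
  stopifnot(inherits(x, "diet_dataset"))
  miss <- setdiff(STOMACH_COLS, names(x$stomachs))
  if (length(miss)) stop("stomachs table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(PREY_COLS, names(x$prey))
  if (length(miss)) stop("prey table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(TAXA_COLS, names(x$taxa))
  if (length(miss)) stop("taxa table missing column(s): ",
                         paste(miss, collapse = ", "))

  if (anyDuplicated(x$taxa$taxon_id))
    stop("duplicated taxon_id in taxa table: ",
         paste(unique(x$taxa$taxon_id[duplicated(x$taxa$taxon_id)]),
               collapse = ", "))
  if (anyDuplicated(x$stomachs$stomach_id))
    stop("duplicated stomach_id in stomachs table")
  bad <- !x$taxa$rank %in% RANK_LEVELS
  if (any(bad)) stop("invalid taxon rank(s): ",
                     paste(unique(x$taxa$rank[bad]), collapse = ", "))
  bad <- !x$stomachs$status %in% STATUS_LEVELS
  if (any(bad)) stop("invalid stomach status(es): ",
                     paste(unique(x$stomachs$status[bad]), collapse = ", "))

  p <- x$prey
  bad <- which(is.na(p$count) | p$count < 0)
  if (length(bad)) stop("negative or missing count in prey row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(is.na(p$weight_g) | p$weight_g < 0)
  if (length(bad)) stop("negative or missing weight_g in prey row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(p$count < p$intact_individuals)
  if (length(bad)) stop("count < intact_individuals in prey row(s): ",
                        paste(bad, collapse = ", "))
  unknown <- setdiff(p$taxon_id, x$taxa$taxon_id)
  if (length(unknown)) stop("prey rows reference unknown taxon_id(s): ",
                            paste(unknown, collapse = ", "))
  unknown <- setdiff(p$stomach_id, x$stomachs$stomach_id)
  if (length(unknown)) stop("prey rows reference unknown stomach_id(s): ",
                            paste(unknown, collapse = ", "))

  has_food <- p$count > 0 | p$weight_g > 0
  food_stomachs <- unique(p$stomach_id[has_food])
  wf <- x$stomachs$status == "with_food"
  bad <- x$stomachs$stomach_id[wf & !x$stomachs$stomach_id %in% food_stomachs]
  if (length(bad)) stop("with_food stomach(s) without any prey occurrence: ",
                        paste(bad, collapse = ", "))
  bad <- intersect(x$stomachs$stomach_id[!wf], food_stomachs)
  if (length(bad)) stop("empty/slurry stomach(s) with prey occurrences: ",
                        paste(bad, collapse = ", "))
  invisible(x)
}

#' @export
print.diet_dataset <- function(x, ...) {
  wf <- sum(x$stomachs$status == "with_food")
  cat("diet_dataset:", nrow(x$stomachs), "stomachs (", wf, "with food ),",
      nrow(x$taxa), "taxa,", nrow(x$prey), "prey occurrences\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

parse_lengths <- function(s) {
  lapply(s, function(z) {
    if (is.na(z) || !nzchar(z)) numeric(0)
    else as.numeric(strsplit(z, ";", fixed = TRUE)[[1]])
  })
}

parse_ds <- function(s) {
  # "s1:0;s2:1;...;s6:0" -> integer vector of length 6
  out <- matrix(0L, nrow = length(s), ncol = 6,
                dimnames = list(NULL, paste0("ds", 1:6)))
  for (i in seq_along(s)) {
    if (is.na(s[i]) || !nzchar(s[i])) next
    parts <- strsplit(s[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    idx <- as.integer(sub("^s", "", vapply(kv, `[`, "", 1L)))
    out[i, idx] <- as.integer(vapply(kv, `[`, "", 2L))
  }
  out
}

format_ds <- function(prey) {
  m <- as.matrix(prey[paste0("ds", 1:6)])
  apply(m, 1L, function(r) paste0("s", 1:6, ":", as.integer(r), collapse = ";"))
}

format_lengths <- function(lst) {
  vapply(lst, function(z) paste(format(z, trim = TRUE, digits = 15),
                                collapse = ";"), "")
}

read_table_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
}

#' Read a diet dataset from delimited tables
#'
#' Reads `stomachs.csv`, `prey.csv` and `taxa.csv` (comma- or tab-delimited,
#' auto-detected) from a directory, reconstructs the typed columns
#' (`digestion_state_counts` strings such as `"s1:0;...;s6:2"` become the
#' `ds1`..`ds6` tallies; `lengths_mm` semicolon lists become numeric vectors),
#' and validates the result.
#'
#' @param dir directory containing the three files, or `NULL` when the three
#'   file paths are given explicitly.
#' @param stomachs,prey,taxa file names (within `dir`) or full paths.
#' @param quiet suppress the per-file row-count message.
#' @return A validated [diet_dataset()].
#' @export
read_diet_dataset <- function(dir = NULL, stomachs = "stomachs.csv",
                              prey = "prey.csv", taxa = "taxa.csv",
                              quiet = FALSE) {
  paths <- c(stomachs, prey, taxa)
  if (!is.null(dir)) paths <- file.path(dir, paths)
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)

  st <- read_table_auto(paths[1])
  pr <- read_table_auto(paths[2])
  tx <- read_table_auto(paths[3])

  need <- c("stomach_id", "efl_cm", "date", "longitude_deg", "latitude_deg",
            "sst_c", "status")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("stomachs file missing column(s): ",
                         paste(miss, collapse = ", "))
  for (nm in c("efl_cm", "longitude_deg", "latitude_deg", "sst_c"))
    st[[nm]] <- as.numeric(st[[nm]])
  st$date <- as.Date(st$date)

  need <- c("stomach_id", "taxon_id", "count", "weight_g")
  miss <- setdiff(need, names(pr))
  if (length(miss)) stop("prey file missing column(s): ",
                         paste(miss, collapse = ", "))
  pr2 <- data.frame(stomach_id = pr$stomach_id, taxon_id = pr$taxon_id,
                    count = as.integer(pr$count),
                    weight_g = as.numeric(pr$weight_g),
                    stringsAsFactors = FALSE)
  ds <- if ("digestion_state_counts" %in% names(pr))
    parse_ds(pr$digestion_state_counts) else
    matrix(0L, nrow(pr), 6, dimnames = list(NULL, paste0("ds", 1:6)))
  pr2 <- cbind(pr2, as.data.frame(ds))
  for (nm in c("upper_beaks", "lower_beaks", "otoliths_left",
               "otoliths_right", "intact_individuals")) {
    pr2[[nm]] <- if (nm %in% names(pr)) as.integer(pr[[nm]]) else 0L
  }
  pr2$lengths_mm <- if ("lengths_mm" %in% names(pr))
    parse_lengths(pr$lengths_mm) else rep(list(numeric(0)), nrow(pr))
  for (nm in c("net_feeding_flag", "secondary_prey_flag")) {
    pr2[[nm]] <- if (nm %in% names(pr)) as.logical(pr[[nm]]) else FALSE
  }

  miss <- setdiff(c("taxon_id", "name", "rank"), names(tx))
  if (length(miss)) stop("taxa file missing column(s): ",
                         paste(miss, collapse = ", "))
  if ("group_label" %in% names(tx))
    tx$group_label[!nzchar(tx$group_label)] <- NA_character_

  x <- diet_dataset(st, pr2, tx,
                    provenance = paste("read from", paths[1]))
  if (!quiet)
    message("read ", nrow(st), " stomachs, ", nrow(pr2), " prey rows, ",
            nrow(tx), " taxa")
  x
}

#' Write a diet dataset to delimited tables
#'
#' Inverse of [read_diet_dataset()]: writes `stomachs.csv`, `prey.csv`,
#' `taxa.csv` with the documented serialized columns. A read of the written
#' files reproduces the dataset field-for-field.
#'
#' @param x a `diet_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_diet_dataset <- function(x, dir) {
  stopifnot(inherits(x, "diet_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- x$stomachs
  st$date <- format(st$date, "%Y-%m-%d")
  utils::write.csv(st, file.path(dir, "stomachs.csv"), row.names = FALSE,
                   na = "")
  pr <- x$prey
  out <- data.frame(stomach_id = pr$stomach_id, taxon_id = pr$taxon_id,
                    count = pr$count, weight_g = pr$weight_g,
                    digestion_state_counts = format_ds(pr),
                    upper_beaks = pr$upper_beaks, lower_beaks = pr$lower_beaks,
                    otoliths_left = pr$otoliths_left,
                    otoliths_right = pr$otoliths_right,
                    intact_individuals = pr$intact_individuals,
                    lengths_mm = format_lengths(pr$lengths_mm),
                    net_feeding_flag = pr$net_feeding_flag,
                    secondary_prey_flag = pr$secondary_prey_flag,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(dir, "prey.csv"), row.names = FALSE, na = "")
  utils::write.csv(x$taxa, file.path(dir, "taxa.csv"), row.names = FALSE,
                   na = "")
  invisible(dir)
}

#' Stomach-by-taxon matrix
#'
#' Pivots the occurrence table into a stomachs x taxa matrix of counts,
#' weights, or presence (0/1). Rows are the selected stomachs (default: those
#' with food), columns every taxon in the dictionary.
#'
#' @param x a `diet_dataset`.
#' @param value `"count"`, `"weight"` or `"presence"`.
#' @param stomachs `"with_food"` (default) or `"all"`.
#' @return numeric matrix with stomach_id rownames and taxon_id colnames.
#' @export
diet_matrix <- function(x, value = c("count", "weight", "presence"),
                        stomachs = c("with_food", "all")) {
  value <- match.arg(value)
  stomachs <- match.arg(stomachs)
  ids <- if (stomachs == "with_food")
    x$stomachs$stomach_id[x$stomachs$status == "with_food"] else
    x$stomachs$stomach_id
  m <- matrix(0, length(ids), nrow(x$taxa),
              dimnames = list(ids, x$taxa$taxon_id))
  p <- x$prey[x$prey$stomach_id %in% ids, , drop = FALSE]
  if (nrow(p)) {
    v <- switch(value, count = p$count, weight = p$weight_g,
                presence = as.numeric(p$count > 0 | p$weight_g > 0))
    idx <- cbind(match(p$stomach_id, ids), match(p$taxon_id, colnames(m)))
    # accumulate in case a stomach-taxon pair spans several rows
    for (i in seq_len(nrow(p))) m[idx[i, 1], idx[i, 2]] <-
        m[idx[i, 1], idx[i, 2]] + v[i]
    if (value == "presence") m <- (m > 0) + 0
  }
  m
}
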