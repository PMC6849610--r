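## Survey assembly: cell:year surveys with list-length categories, the 1980
## period split, cell/species filters, and the indexed model dataset.

#' Assign records to a period (before / after 1980)
#'
#' Records dated to a year are split at the period boundary (default 1980,
#' the median year of observation in the motivating compilation); the
#' boundary year itself goes to period 2 ("post-1980" read as >= 1980).
#' Undated records with a coarse era flag use the flag.  Records with
#' neither are unusable and return `NA`.
#'
#' @param year integer years (NA allowed).
#' @param period_flag optional character: "pre1980", "post1980" or
#'   "unknown"/NA.
#' @param boundary period boundary year.
#' @return integer vector of periods (1, 2, or NA for unusable records).
#' @export
assign_period <- function(year, period_flag = NULL, boundary = 1980) {
  year <- suppressWarnings(as.integer(year))
  t <- ifelse(is.na(year), NA_integer_, ifelse(year < boundary, 1L, 2L))
  if (!is.null(period_flag)) {
    flag <- as.character(period_flag)
    use <- is.na(t) & !is.na(flag)
    t[use & flag == "pre1980"] <- 1L
    t[use & flag == "post1980"] <- 2L
  }
  t
}

.list_category <- function(n) {
  ifelse(n == 1L, "single", ifelse(n <= 3L, "short", "long"))
}

#' Group records into cell:year surveys
#'
#' A survey is the set of unique species records from one cell:year
#' combination.  Every species on the list -- native or not -- counts
#' toward the list length (survey effort); the list-length category is
#' single (1 species), short (2-3) or long (>3).  Records that carry only
#' an era flag (no year) cannot join a cell:year survey and are pooled into
#' one pseudo-survey per cell and period (`pooled = TRUE`, `year = NA`).
#' Records with neither year nor flag are dropped; the count is attached as
#' attribute `n_dropped_undated`.
#'
#' @param records data frame with columns `species_id`, `cell_id`, `year`
#'   (NA allowed) and optionally `period_flag`.
#' @param boundary period boundary year passed to [assign_period()].
#' @return data frame of surveys: `survey_id`, `cell_id`, `year`, `period`,
#'   `pooled`, `list_length`, `category`, `short_k`, `long_k`, `species`
#'   (pipe-delimited sorted species list).
#' @export
build_surveys <- function(records, boundary = 1980) {
  stopifnot(all(c("species_id", "cell_id") %in% names(records)))
  if (!"year" %in% names(records)) records$year <- NA_integer_
  flag <- if ("period_flag" %in% names(records)) records$period_flag else NULL
  period <- assign_period(records$year, flag, boundary)
  dropped <- sum(is.na(period))
  records <- records[!is.na(period), , drop = FALSE]
  period <- period[!is.na(period)]

  dated <- !is.na(records$year)
  key <- ifelse(dated,
                paste0(records$cell_id, ":", records$year),
                paste0(records$cell_id, ":era", period))
  sp_by_key <- split(as.character(records$species_id), key)
  sp_by_key <- lapply(sp_by_key, function(s) sort(unique(s)))
  first <- !duplicated(key)
  meta <- data.frame(key = key[first], cell_id = records$cell_id[first],
                     year = ifelse(dated[first], records$year[first],
                                   NA_integer_),
                     period = period[first], pooled = !dated[first],
                     stringsAsFactors = FALSE)
  meta <- meta[order(meta$cell_id, meta$period, meta$year, na.last = FALSE), ]
  n <- vapply(sp_by_key[meta$key], length, 1L)
  out <- data.frame(survey_id = seq_len(nrow(meta)),
                    cell_id = meta$cell_id, year = meta$year,
                    period = meta$period, pooled = meta$pooled,
                    list_length = as.integer(n),
                    category = .list_category(n),
                    stringsAsFactors = FALSE)
  out$short_k <- as.integer(out$category == "short")
  out$long_k <- as.integer(out$category == "long")
  out$species <- vapply(sp_by_key[meta$key], paste, "", collapse = "|")
  rownames(out) <- NULL
  attr(out, "n_dropped_undated") <- dropped
  out
}

#' Retain cells surveyed in both periods
#'
#' Cells observed in only one era carry no information about extinction or
#' colonization between the eras and are excluded.
#'
#' @param surveys survey table from [build_surveys()].
#' @return list: `retained` (cell ids), `dropped_period1_only`,
#'   `dropped_period2_only` (counts are the filter log).
#' @export
filter_cells_both_periods <- function(surveys) {
  p1 <- unique(surveys$cell_id[surveys$period == 1L])
  p2 <- unique(surveys$cell_id[surveys$period == 2L])
  retained <- sort(intersect(p1, p2))
  if (length(retained) == 0L)
    stop("no cells have surveys in both periods; nothing to model")
  list(retained = retained,
       dropped_period1_only = sort(setdiff(p1, p2)),
       dropped_period2_only = sort(setdiff(p2, p1)))
}

# long (survey x species) detections restricted to retained cells
.survey_species_long <- function(surveys) {
  sp <- strsplit(surveys$species, "|", fixed = TRUE)
  data.frame(survey_id = rep(surveys$survey_id, lengths(sp)),
             cell_id = rep(surveys$cell_id, lengths(sp)),
             period = rep(surveys$period, lengths(sp)),
             species_id = unlist(sp, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Retain species observable in both periods
#'
#' A species stays in the model if at least one retained, in-range cell
#' holds a record of it in each period; otherwise its data cannot inform a
#' persistence rate.
#'
#' @param ranges named list of per-species range cell vectors.
#' @param retained_cells cell ids surviving [filter_cells_both_periods()].
#' @param surveys survey table.
#' @return list: `retained` (species ids), `dropped` (species ids).
#' @export
filter_species <- function(ranges, retained_cells, surveys) {
  long <- .survey_species_long(surveys)
  long <- long[long$cell_id %in% retained_cells, , drop = FALSE]
  keep <- vapply(names(ranges), function(sid) {
    rows <- long$species_id == sid & long$cell_id %in% ranges[[sid]]
    any(long$period[rows] == 1L) && any(long$period[rows] == 2L)
  }, TRUE)
  if (!any(keep)) stop("no species detected in both periods; nothing to model")
  list(retained = names(ranges)[keep], dropped = names(ranges)[!keep])
}

#' Assemble the indexed model dataset
#'
#' Applies the cell and species filters (unless pre-computed sets are
#' given), restricts to in-range species:cell pairs, and reduces every
#' pair's detection history to sufficient statistics: counts of detections
#' and surveys per period and list-length category.  The reduction is exact
#' because detection probability is constant within a
#' species:period:category stratum.  Out-of-range and non-modeled
#' detections still count toward list length (effort) but never produce a
#' binary observation.
#'
#' @param surveys survey table from [build_surveys()].
#' @param ranges named list of per-species range cell vectors.
#' @param cell_attr data frame with `cell_id`, `realm`, and `C` or
#'   `converted_fraction`.
#' @param grid a [grid_spec()] (used to compute D' for the pairs).
#' @param retained_cells,retained_species optional pre-computed filter
#'   results.
#' @return an object of class `occu_data`: species/cell indices, pair table
#'   with covariates, detection-count matrices, the retained surveys, and a
#'   `counts` log (pairs, surveys, binary observations, drops).
#' @export
build_model_dataset <- function(surveys, ranges, cell_attr,
                                grid = grid_spec(),
                                retained_cells = NULL,
                                retained_species = NULL) {
  cell_filter <- NULL
  if (is.null(retained_cells)) {
    cell_filter <- filter_cells_both_periods(surveys)
    retained_cells <- cell_filter$retained
  }
  sp_filter <- NULL
  if (is.null(retained_species)) {
    sp_filter <- filter_species(ranges, retained_cells, surveys)
    retained_species <- sp_filter$retained
  }
  surveys <- surveys[surveys$cell_id %in% retained_cells, , drop = FALSE]
  species <- sort(retained_species)
  S <- length(species)

  cov <- range_covariates(ranges[species], cell_attr, grid)
  cov <- cov[cov$cell_id %in% retained_cells, , drop = FALSE]
  if (nrow(cov) == 0L) stop("no in-range pairs on retained cells")
  if (anyNA(cov$Dprime) || anyNA(cov$R) || anyNA(cov$C))
    stop("in-range pair with missing D', realm or conversion covariate")
  cov <- cov[order(match(cov$species_id, species), cov$cell_id), ]
  cov$sp <- match(cov$species_id, species)
  rownames(cov) <- NULL

  cells <- sort(unique(surveys$cell_id))
  cat_lev <- c("single", "short", "long")

  # surveys per cell x period x category
  tot <- array(0, dim = c(length(cells), 2L, 3L))
  ci <- match(surveys$cell_id, cells)
  ki <- match(surveys$category, cat_lev)
  for (r in seq_len(nrow(surveys)))
    tot[ci[r], surveys$period[r], ki[r]] <- tot[ci[r], surveys$period[r], ki[r]] + 1

  # detections per pair x period x category
  long <- .survey_species_long(surveys)
  long$category <- surveys$category[match(long$survey_id, surveys$survey_id)]
  pair_key <- paste0(cov$species_id, "\r", cov$cell_id)
  long$pair <- match(paste0(long$species_id, "\r", long$cell_id), pair_key)
  long_in <- long[!is.na(long$pair), , drop = FALSE]
  det <- array(0, dim = c(nrow(cov), 2L, 3L))
  kk <- match(long_in$category, cat_lev)
  for (r in seq_len(nrow(long_in)))
    det[long_in$pair[r], long_in$period[r], kk[r]] <-
      det[long_in$pair[r], long_in$period[r], kk[r]] + 1

  pc <- match(cov$cell_id, cells)
  ds <- structure(list(
    species = species, cells = cells, pairs = cov,
    det1 = matrix(det[, 1L, ], nrow(cov), 3L,
                  dimnames = list(NULL, cat_lev)),
    det2 = matrix(det[, 2L, ], nrow(cov), 3L,
                  dimnames = list(NULL, cat_lev)),
    tot1 = matrix(tot[pc, 1L, ], nrow(cov), 3L,
                  dimnames = list(NULL, cat_lev)),
    tot2 = matrix(tot[pc, 2L, ], nrow(cov), 3L,
                  dimnames = list(NULL, cat_lev)),
    surveys = surveys), class = "occu_data")

  n_surv_by_cell <- apply(tot, 1L, sum)
  ds$counts <- list(
    n_species = S, n_cells = length(cells), n_pairs = nrow(cov),
    n_surveys = nrow(surveys),
    n_binary_obs = sum(n_surv_by_cell[pc]),
    n_cells_dropped_period1_only =
      if (is.null(cell_filter)) NA_integer_
      else length(cell_filter$dropped_period1_only),
    n_cells_dropped_period2_only =
      if (is.null(cell_filter)) NA_integer_
      else length(cell_filter$dropped_period2_only),
    species_dropped =
      if (is.null(sp_filter)) character(0) else sp_filter$dropped)
  ds
}

#' @export
print.occu_data <- function(x, ...) {
  cat(sprintf(paste0("occupancy model dataset: %d species, %d cells, ",
                     "%d in-range pairs\n%d surveys, %d binary observations\n"),
              x$counts$n_species, x$counts$n_cells, x$counts$n_pairs,
              x$counts$n_surveys, x$counts$n_binary_obs))
  invisible(x)
}
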