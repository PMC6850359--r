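#' The farmland bird species set
#'
#' The fixed set of 15 farmland bird species modelled jointly: the union of
#' the Swedish Farmland Bird Index species and the species of environmental
#' objective 13 ("A varied agricultural landscape") that breed regularly in
#' the study region.
#'
#' @return Character vector of 15 English species names.
#' @export
farmland_species <- function() {
  c("Barn Swallow", "Curlew", "Greater Whitethroat", "Lapwing", "Linnet",
    "Meadow Pipit", "Red-backed Shrike", "Rook", "Skylark", "Starling",
    "Tree Sparrow", "Wheatear", "Whinchat", "Yellow Wagtail", "Yellowhammer")
}

#' Filter observations by distance from the survey point
#'
#' Retains bird observations made within `max_distance` metres of the survey
#' point (inclusive). Records with missing distance cannot be assessed and
#' are rejected with a warning.
#'
#' @param observations data.frame with at least a `distance_m` column.
#' @param max_distance inclusion radius in metres (default 150).
#' @return The retained rows of `observations`.
#' @export
filter_by_distance <- function(observations, max_distance = 150) {
  if (nrow(observations) == 0) return(observations)
  if (!"distance_m" %in% names(observations))
    stop("observations lack a distance_m column")
  nas <- is.na(observations$distance_m)
  if (any(nas))
    warning(sum(nas), " observation(s) with missing distance rejected")
  observations[!nas & observations$distance_m <= max_distance, , drop = FALSE]
}

#' Adult fraction of a post-fledging flock
#'
#' If each pair (2 adults) fledges `young_per_pair` young, the fraction of
#' adults in a mixed post-fledging flock is `2 / (2 + young_per_pair)`. With
#' the regional nest-box estimate of 4.01 fledged young per pair this gives
#' 0.333, i.e. about one third of a Starling flock after synchronized
#' fledging consists of adults -- the basis of the Starling correction.
#'
#' @param young_per_pair nonnegative number of fledged young per pair.
#' @return Adult fraction in `(0, 1]`.
#' @seealso [starling_correction()]
#' @export
adult_fraction_from_brood <- function(young_per_pair) {
  if (any(young_per_pair < 0)) stop("young_per_pair must be nonnegative")
  2 / (2 + young_per_pair)
}

#' Starling flock correction
#'
#' Starlings fledge synchronously in late May / early June, after which
#' flocks contain adults and young mixed roughly 1:2. To keep counts on the
#' adult scale, Starling counts dated strictly after the cutoff date
#' (4 June of the observation year) are divided by `divisor` (default 3,
#' the reciprocal of the adult fraction). All other records are unchanged.
#' Corrected counts may be fractional; discretization is deferred to the
#' model-fitting step (see [fit_model()]).
#'
#' @param observations data.frame with columns `species`, `count` and `date`
#'   (coercible with [as.Date()]).
#' @param species_name species label to correct (default `"Starling"`).
#' @param cutoff_md month-day of the cutoff, `"MM-DD"`; counts on the cutoff
#'   day itself are *not* corrected.
#' @param divisor division factor for post-cutoff counts.
#' @return `observations` with corrected counts and a logical attribute
#'   `starling_corrected` used to guarantee single application.
#' @export
starling_correction <- function(observations, species_name = "Starling",
                                cutoff_md = "06-04", divisor = 3) {
  if (isTRUE(attr(observations, "starling_corrected")))
    stop("starling_correction has already been applied to this table")
  if (nrow(observations)) {
    d <- as.Date(observations$date)
    if (anyNA(d)) stop("observations contain unparseable dates")
    cutoff <- as.Date(paste0(format(d, "%Y"), "-", cutoff_md))
    hit <- observations$species == species_name & d > cutoff
    observations$count[hit] <- observations$count[hit] / divisor
  }
  attr(observations, "starling_corrected") <- TRUE
  observations
}

#' Aggregate point observations to the landscape-level count table
#'
#' Sums (corrected) observations over survey points within each site and
#' visit, for each species of the modelled species universe, zero-filling
#' species that were surveyed but not observed. Observations of species
#' outside the universe are dropped with a message tallying them.
#'
#' @param observations data.frame with columns `site_id`, `visit`,
#'   `point_id`, `observer_id`, `species`, `count` (post-filter,
#'   post-correction). Duplicated (site, visit, point, species) rows are
#'   summed.
#' @param visits optional data.frame `site_id`, `visit`, `observer_id`,
#'   `n_points` giving the number of points actually surveyed per visit; if
#'   `NULL`, `n_points` is the number of distinct `point_id` values seen and
#'   the observer is taken from the records (must be unique per visit).
#' @param species character vector defining the species universe (default
#'   [farmland_species()]).
#' @return data.frame of class `"count_table"` in long format: `site_id`,
#'   `visit`, `observer_id`, `n_points`, `species`, `count`.
#' @export
aggregate_counts <- function(observations, visits = NULL,
                             species = farmland_species()) {
  obs <- observations
  keep <- obs$species %in% species
  if (any(!keep)) {
    message("dropping ", sum(!keep), " observation(s) of ",
            length(unique(obs$species[!keep])),
            " species outside the modelled set")
    obs <- obs[keep, , drop = FALSE]
  }
  if (is.null(visits)) {
    if (nrow(observations) == 0) stop("cannot derive visits from empty input")
    visits <- unique(observations[c("site_id", "visit", "observer_id")])
    if (anyDuplicated(visits[c("site_id", "visit")]))
      stop("multiple observers recorded for one (site, visit)")
    np <- stats::aggregate(point_id ~ site_id + visit, observations,
                           function(p) length(unique(p)))
    names(np)[3] <- "n_points"
    visits <- merge(visits, np, by = c("site_id", "visit"))
  }
  grid <- merge(visits, data.frame(species = species), by = NULL)
  if (nrow(obs)) {
    sums <- stats::aggregate(count ~ site_id + visit + species, obs, sum)
    grid <- merge(grid, sums, by = c("site_id", "visit", "species"),
                  all.x = TRUE)
    grid$count[is.na(grid$count)] <- 0
  } else {
    grid$count <- 0
  }
  grid <- grid[order(grid$site_id, grid$visit, grid$species),
               c("site_id", "visit", "observer_id", "n_points",
                 "species", "count")]
  rownames(grid) <- NULL
  class(grid) <- c("count_table", "data.frame")
  grid
}

#' Maximum count over the two visits
#'
#' Elementwise maximum of the counts over a site's visits, per species. A
#' descriptive summary only (e.g. "total maximum individuals observed");
#' never a model input -- the model uses both visits with offsets.
#'
#' @param counts a [aggregate_counts()] count table.
#' @return data.frame `site_id`, `species`, `max_count`.
#' @export
max_over_visits <- function(counts) {
  nv <- stats::aggregate(visit ~ site_id, counts,
                         function(v) length(unique(v)))
  if (any(nv$visit < 2))
    warning(sum(nv$visit < 2), " site(s) with a single visit; using that ",
            "visit's counts")
  out <- stats::aggregate(count ~ site_id + species, counts, max)
  names(out)[3] <- "max_count"
  out[order(out$site_id, out$species), ]
}

#' Count-table CSV I/O
#'
#' @param x count table ([aggregate_counts()]).
#' @param path file path.
#' @name count_io
#' @export
write_count_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname count_io
#' @export
read_count_table <- function(path) {
  out <- utils::read.csv(path)
  req <- c("site_id", "visit", "observer_id", "n_points", "species", "count")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "))
  class(out) <- c("count_table", "data.frame")
  out
}
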