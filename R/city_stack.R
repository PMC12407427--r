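#' Aligned raster stack for one city
#'
#' Bundles everything the exposure analysis needs for a single city on one
#' common grid: a land mask, twelve monthly daytime and nighttime population
#' frames, and a multi-year cube of daily mean 2-m air temperature. All rasters
#' are plain matrices with `rows x cols` cells of size `cell_km` km in a
#' planar, metric coordinate frame; row `i`, column `j` has its cell centre at
#' `x = (j - 0.5) * cell_km`, `y = (i - 0.5) * cell_km`. Water cells are
#' excluded from every statistic computed on the stack.
#'
#' @param city_id Character label.
#' @param land_mask Logical matrix, `TRUE` on land.
#' @param pop_day,pop_night Lists of 12 numeric matrices (January = 1),
#'   population counts per cell (persons), non-negative.
#' @param temp Numeric array `ndays x rows x cols`, daily mean temperature in
#'   degrees Celsius.
#' @param dates `Date` vector of length `ndays` matching the first dimension of
#'   `temp`.
#' @param cell_km Cell size in km (default 1, the analysis resolution).
#' @param center Optional `c(x, y)` in km. Defaults to the geometric centre of
#'   the bounding box of the land cells, which is where radial distances are
#'   measured from.
#' @param meta Optional list of provenance metadata (e.g. the generating
#'   config and seed); stored verbatim.
#'
#' @return An object of class `city_stack`.
#' @export
city_stack <- function(city_id, land_mask, pop_day, pop_night, temp, dates,
                       cell_km = 1, center = NULL, meta = list()) {
  stopifnot(is.character(city_id), length(city_id) == 1L)
  if (!is.matrix(land_mask) || !is.logical(land_mask))
    stop("`land_mask` must be a logical matrix", call. = FALSE)
  dm <- dim(land_mask)
  check_frames <- function(frames, what) {
    if (!is.list(frames) || length(frames) != 12L)
      stop(sprintf("`%s` must be a list of 12 monthly frames", what),
           call. = FALSE)
    for (m in seq_len(12L)) {
      f <- frames[[m]]
      if (!is.matrix(f) || !identical(dim(f), dm))
        stop(sprintf("`%s` frame %d does not match the mask grid", what, m),
             call. = FALSE)
      if (any(f[land_mask] < 0, na.rm = TRUE))
        stop(sprintf("`%s` frame %d has negative population", what, m),
             call. = FALSE)
    }
  }
  check_frames(pop_day, "pop_day")
  check_frames(pop_night, "pop_night")
  if (length(dim(temp)) != 3L || !identical(dim(temp)[2:3], dm))
    stop("`temp` must be a ndays x rows x cols array on the mask grid",
         call. = FALSE)
  dates <- as.Date(dates)
  if (length(dates) != dim(temp)[1L])
    stop("`dates` length must match the temperature cube", call. = FALSE)
  if (!any(land_mask)) stop("stack has no land cells", call. = FALSE)
  if (is.null(center)) center <- land_bbox_center(land_mask, cell_km)
  structure(
    list(city_id = city_id, land_mask = land_mask,
         pop_day = pop_day, pop_night = pop_night,
         temp = temp, dates = dates, cell_km = cell_km,
         center = as.numeric(center), meta = meta),
    class = "city_stack")
}

#' @export
print.city_stack <- function(x, ...) {
  dm <- dim(x$land_mask)
  cat(sprintf(
    "<city_stack '%s'>  %d x %d cells at %g km, %d land, %d days (%s..%s)\n",
    x$city_id, dm[1L], dm[2L], x$cell_km, sum(x$land_mask),
    length(x$dates), min(x$dates), max(x$dates)))
  invisible(x)
}

# geometric centre of the land-cell bounding box, km
land_bbox_center <- function(land_mask, cell_km) {
  idx <- which(land_mask, arr.ind = TRUE)
  rows <- range(idx[, 1L]); cols <- range(idx[, 2L])
  c(x = mean(cols - 0.5) * cell_km, y = mean(rows - 0.5) * cell_km)
}

# matrices of cell-centre coordinates (km)
cell_coordinates <- function(stack) {
  dm <- dim(stack$land_mask)
  list(x = matrix(rep((seq_len(dm[2L]) - 0.5) * stack$cell_km, each = dm[1L]),
                  dm[1L], dm[2L]),
       y = matrix(rep((seq_len(dm[1L]) - 0.5) * stack$cell_km, dm[2L]),
                  dm[1L], dm[2L]))
}

#' Distance of every cell centre from the city centre
#'
#' @param stack A [city_stack()].
#' @return Numeric matrix of distances in km.
#' @export
cell_distances <- function(stack) {
  xy <- cell_coordinates(stack)
  sqrt((xy$x - stack$center[1L])^2 + (xy$y - stack$center[2L])^2)
}

#' Land-masked copy of a raster field
#'
#' Sets water cells to `NA` so they drop out of any subsequent statistic.
#' Idempotent: masking a masked field changes nothing.
#'
#' @param field Numeric matrix on the stack grid.
#' @param land_mask Logical matrix.
#' @return The field with `NA` off land.
#' @export
mask_field <- function(field, land_mask) {
  stopifnot(identical(dim(field), dim(land_mask)))
  field[!land_mask] <- NA_real_
  field
}

# land-cell sum of a population frame
land_total <- function(field, land_mask) sum(field[land_mask], na.rm = TRUE)

#' Monthly city-total population series
#'
#' City totals (land cells only) of the 12 monthly frames, the `P_t` series
#' the seasonal cosine model is fitted to.
#'
#' @param stack A [city_stack()].
#' @param when `"night"` or `"day"`.
#' @return Numeric vector of 12 totals, January first.
#' @export
monthly_population_totals <- function(stack, when = c("night", "day")) {
  when <- match.arg(when)
  frames <- if (when == "night") stack$pop_night else stack$pop_day
  vapply(frames, land_total, numeric(1L), land_mask = stack$land_mask)
}

#' Monthly mean temperature series
#'
#' For each calendar month, the mean over all days of that month (all years
#' pooled) of the daily land-only domain-mean temperature.
#'
#' @param stack A [city_stack()].
#' @return Numeric vector of 12 monthly means, degrees Celsius.
#' @export
monthly_mean_temperature <- function(stack) {
  daily <- daily_domain_means(stack)
  mon <- as.integer(format(stack$dates, "%m"))
  vapply(1:12, function(m) mean(daily[mon == m]), numeric(1L))
}

# land-only domain mean of each daily temperature slice
daily_domain_means <- function(stack) {
  land <- stack$land_mask
  nd <- dim(stack$temp)[1L]
  flat <- matrix(stack$temp, nrow = nd)      # days x cells, column-major cells
  rowMeans(flat[, as.vector(land), drop = FALSE])
}
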