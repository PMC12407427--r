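#' Block-mean regridding of a fine raster
#'
#' Aggregates a fine-resolution raster (e.g. 100 m temperature) to a coarser
#' grid (e.g. 1 km) by taking the arithmetic mean of the valid fine cells under
#' each coarse cell. Grids are assumed axis-aligned with exactly nesting cells,
#' so no area weighting is needed. A coarse cell whose covered fine cells are
#' all missing is itself missing. If the fine dimensions are not divisible by
#' `factor`, the raster is padded with missing values at the high ends.
#'
#' The block mean conserves the domain mean exactly when no cells are missing.
#'
#' @param field_fine Numeric matrix; `NA` marks missing (e.g. water) cells.
#' @param factor Integer aggregation factor >= 1 (10 for 100 m -> 1 km).
#' @return Numeric matrix of block means, `ceiling(dim/factor)` in size.
#' @export
regrid_block_mean <- function(field_fine, factor) {
  if (!is.matrix(field_fine) || length(field_fine) == 0L)
    stop("invalid input: `field_fine` must be a non-empty matrix",
         call. = FALSE)
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != as.integer(factor))
    stop("invalid argument: `factor` must be a positive integer",
         call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(field_fine)
  nr <- nrow(field_fine); nc <- ncol(field_fine)
  nrp <- as.integer(ceiling(nr / factor) * factor)
  ncp <- as.integer(ceiling(nc / factor) * factor)
  padded <- matrix(NA_real_, nrp, ncp)
  padded[seq_len(nr), seq_len(nc)] <- field_fine
  valid <- !is.na(padded)
  vals <- ifelse(valid, padded, 0)
  rg <- rep(seq_len(nrp %/% factor), each = factor)
  cg <- rep(seq_len(ncp %/% factor), each = factor)
  sum2 <- function(m) t(rowsum(t(rowsum(m, rg)), cg))
  sums <- sum2(vals)
  counts <- sum2(valid + 0)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  dimnames(out) <- NULL
  out
}

#' Majority-rule regridding of a land mask
#'
#' A coarse cell is water when at least half of the fine mask cells it covers
#' are water; otherwise it is land. Symmetric between land and water apart from
#' the tie, which goes to water.
#'
#' @param mask_fine Logical matrix, `TRUE` = land.
#' @param factor Integer aggregation factor >= 1.
#' @return Logical matrix at the coarse resolution.
#' @export
regrid_mask <- function(mask_fine, factor) {
  if (!is.matrix(mask_fine) || !is.logical(mask_fine))
    stop("invalid input: `mask_fine` must be a logical matrix", call. = FALSE)
  frac_land <- regrid_block_mean(mask_fine + 0, factor)
  out <- !is.na(frac_land) & frac_land > 0.5
  out
}

#' Monthly-mean temperature scenario
#'
#' Per-cell average of daily temperature over every day of the given calendar
#' month, all years pooled ("July" means all July days on record). This is the
#' default exposure scenario.
#'
#' @param stack A [city_stack()].
#' @param month Calendar month 1-12.
#' @return A `temperature_scenario`: list with `mode`, `month`, `fraction`,
#'   `n_days`, and `field` (per-cell degrees C, `NA` off land).
#' @export
monthly_mean_scenario <- function(stack, month) {
  idx <- month_day_index(stack, month)
  field <- composite_field(stack, idx)
  structure(list(mode = "monthly_mean", month = as.integer(month),
                 side = NA_character_, fraction = 1, n_days = length(idx),
                 field = field),
            class = "temperature_scenario")
}

#' Extreme-day composite temperature scenario
#'
#' Ranks the days of a calendar month (all years pooled) by their land-only
#' domain-mean temperature, selects the `ceiling(fraction * n)` most extreme
#' days on the requested side, and averages temperature per cell over the
#' selected days. With `fraction = 0.03` this is the "hottest/coldest 3% of
#' days" composite; with `fraction = 1` it reduces to the monthly mean.
#' Ranking is by city-scale daily mean, not per cell, so a hot day is a hot
#' day for the whole city.
#'
#' @param stack A [city_stack()].
#' @param month Calendar month 1-12.
#' @param side `"hot"` or `"cold"`.
#' @param fraction Proportion of days to composite, in (0, 1]; default 0.03.
#' @return A `temperature_scenario` (see [monthly_mean_scenario()]).
#' @export
extreme_day_composite <- function(stack, month, side = c("hot", "cold"),
                                  fraction = 0.03) {
  side <- match.arg(side)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("invalid argument: `fraction` must be in (0, 1]", call. = FALSE)
  idx <- month_day_index(stack, month)
  means <- daily_domain_means(stack)[idx]
  n_sel <- as.integer(ceiling(fraction * length(idx)))
  ord <- order(means, decreasing = (side == "hot"))
  sel <- idx[ord[seq_len(n_sel)]]
  structure(list(mode = "extreme", month = as.integer(month), side = side,
                 fraction = fraction, n_days = n_sel,
                 field = composite_field(stack, sel)),
            class = "temperature_scenario")
}

#' Land-only domain mean of a temperature scenario
#'
#' The unweighted mean over land cells of the scenario's per-cell temperature
#' field; the city mean `T-bar` that radial profiles and risk comparisons are
#' anchored to.
#'
#' @param stack A [city_stack()].
#' @param scenario A `temperature_scenario`.
#' @return Degrees Celsius, scalar.
#' @export
domain_mean_temperature <- function(stack, scenario) {
  stopifnot(inherits(scenario, "temperature_scenario"))
  vals <- scenario$field[stack$land_mask]
  if (!length(vals) || all(is.na(vals)))
    stop("invalid input: no land cells to average", call. = FALSE)
  mean(vals, na.rm = TRUE)
}

# indices of the days belonging to a calendar month, pooled over years
month_day_index <- function(stack, month) {
  if (!is.numeric(month) || length(month) != 1L || !(month %in% 1:12))
    stop("invalid argument: `month` must be 1..12", call. = FALSE)
  idx <- which(as.integer(format(stack$dates, "%m")) == as.integer(month))
  if (!length(idx))
    stop(sprintf("invalid input: month %d absent from the record", month),
         call. = FALSE)
  idx
}

# per-cell mean over selected days, masked to land
composite_field <- function(stack, day_idx) {
  nd <- dim(stack$temp)[1L]
  flat <- matrix(stack$temp, nrow = nd)
  field <- matrix(colMeans(flat[day_idx, , drop = FALSE]),
                  nrow = dim(stack$temp)[2L])
  mask_field(field, stack$land_mask)
}

# ---- plain-text raster I/O (Esri ASCII grid) --------------------------------

#' Write a raster to an Esri ASCII grid (.asc)
#'
#' Plain-text single-band raster with the standard six-line header. Row 1 of
#' the matrix is taken as the southernmost row, so the file is written from the
#' last matrix row down to the first.
#'
#' @param field Numeric or logical matrix (`NA` written as the nodata value).
#' @param path Output file path.
#' @param cell_km Cell size (written in the same unit as the corner offsets).
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_asc <- function(field, path, cell_km = 1, xll = 0, yll = 0,
                      nodata = -9999) {
  stopifnot(is.matrix(field))
  m <- field + 0  # logical -> numeric
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cell_km),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1L,
                function(r) paste(format(r, digits = 17, trim = TRUE,
                                         scientific = FALSE),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an Esri ASCII grid (.asc)
#'
#' @param path File path.
#' @return List with `field` (numeric matrix, row 1 = south), `cell_km`,
#'   `xll`, `yll`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2L]); names(vals) <- tolower(kv[, 1L])
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(field = m[rev(seq_len(nr)), , drop = FALSE],
       cell_km = vals[["cellsize"]],
       xll = vals[["xllcorner"]], yll = vals[["yllcorner"]])
}

#' Write a city stack to a directory of plain-text rasters
#'
#' Layout: `mask.asc`, `pop/<city>_<MM>_<day|night>.asc` (24 frames),
#' `temperature.csv` (one row per day: date then cell values in column-major
#' order), and `stack.json` (city id, cell size, centre, dates, metadata).
#' Everything [read_city_stack()] needs to reconstruct the object.
#'
#' @param stack A [city_stack()].
#' @param dir Output directory (created if needed).
#' @export
write_city_stack <- function(stack, dir) {
  dir.create(file.path(dir, "pop"), recursive = TRUE, showWarnings = FALSE)
  write_asc(stack$land_mask, file.path(dir, "mask.asc"),
            cell_km = stack$cell_km)
  for (m in 1:12) {
    for (when in c("day", "night")) {
      frames <- if (when == "day") stack$pop_day else stack$pop_night
      write_asc(frames[[m]],
                file.path(dir, "pop",
                          sprintf("%s_%02d_%s.asc", stack$city_id, m, when)),
                cell_km = stack$cell_km)
    }
  }
  nd <- dim(stack$temp)[1L]
  flat <- matrix(stack$temp, nrow = nd)
  tmp <- data.frame(date = as.character(stack$dates))
  tmp <- cbind(tmp, as.data.frame(flat))
  utils::write.csv(tmp, file.path(dir, "temperature.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(city_id = stack$city_id, cell_km = stack$cell_km,
         center = stack$center, nrows = nrow(stack$land_mask),
         ncols = ncol(stack$land_mask), meta = stack$meta),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a city stack written by [write_city_stack()]
#'
#' All rasters are checked for a shared shape and cell size; any mismatch is a
#' hard error naming the offending files. Temperature values that look like
#' Kelvin (> 150) are converted to Celsius.
#'
#' @param dir Directory path.
#' @return A [city_stack()].
#' @export
read_city_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  mask_r <- read_asc(file.path(dir, "mask.asc"))
  land_mask <- !is.na(mask_r$field) & mask_r$field == 1
  dm <- dim(land_mask)
  bad <- character()
  frames <- list(day = vector("list", 12L), night = vector("list", 12L))
  for (m in 1:12) {
    for (when in c("day", "night")) {
      p <- file.path(dir, "pop",
                     sprintf("%s_%02d_%s.asc", meta$city_id, m, when))
      r <- read_asc(p)
      if (!identical(dim(r$field), dm) || r$cell_km != mask_r$cell_km)
        bad <- c(bad, p)
      frames[[when]][[m]] <- r$field
    }
  }
  if (length(bad))
    stop("rasters not aligned with mask.asc: ",
         paste(basename(bad), collapse = ", "), call. = FALSE)
  tmp <- utils::read.csv(file.path(dir, "temperature.csv"),
                         check.names = FALSE)
  dates <- as.Date(tmp$date)
  flat <- as.matrix(tmp[, -1L, drop = FALSE])
  if (ncol(flat) != prod(dm))
    stop("temperature.csv cell count does not match mask.asc", call. = FALSE)
  if (stats::median(flat, na.rm = TRUE) > 150) flat <- flat - 273.15
  temp <- array(flat, dim = c(nrow(flat), dm))
  city_stack(meta$city_id, land_mask, frames$day, frames$night, temp, dates,
             cell_km = mask_r$cell_km, center = unlist(meta$center),
             meta = if (is.null(meta$meta)) list() else meta$meta)
}
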