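# Applying the fitted models to birth records and aggregating to areas:
# per-birth unintended probabilities, inverse-probability pregnancy
# multipliers, point-in-polygon area assignment, and the per-area outcome
# table (births and pregnancies, counts, percentages, incidence per 1,000
# women).

#' Predict unintended-pregnancy probabilities for a birth-record file
#'
#' Applies the intendedness model to every birth record. Records with
#' missing coordinates cannot be mapped to an area and are excluded up
#' front, with the exclusion count reported (the real-data analogue: a
#' handful of birth certificates fail geocoding and are dropped). The
#' model's frozen imputation state fills any covariate missingness.
#'
#' @param model_f Fitted intendedness \code{uisae_model} (its
#'   \code{imputer} field should hold the state frozen on the fitting
#'   table).
#' @param birth_table Birth-record data.frame with \code{lon}/\code{lat}
#'   columns and the model's feature columns.
#' @return A list: \code{estimates} (the retained records with a
#'   \code{y_hat} column appended) and \code{n_excluded} (records dropped
#'   for unusable coordinates).
#' @export
predict_births <- function(model_f, birth_table) {
  stopifnot(inherits(model_f, "uisae_model"))
  usable <- !is.na(birth_table$lon) & !is.na(birth_table$lat)
  est <- birth_table[usable, , drop = FALSE]
  est$y_hat <- predict(model_f, est)
  list(estimates = est, n_excluded = sum(!usable))
}

#' Inverse-probability multipliers from births to pregnancies
#'
#' Each live birth represents, in expectation, \eqn{\hat U = \hat y /
#' \hat g(Z, 1)} unintended pregnancies and \eqn{\hat P = \hat y / \hat
#' g(Z, 1) + (1 - \hat y) / \hat g(Z, 0)} total pregnancies, where
#' \eqn{\hat g(Z, y)} is the fitted probability that a pregnancy with
#' covariates Z and intendedness y ends in a live birth. With an overall
#' live-birth share of 0.71 this gives the familiar 1 birth : 1.4
#' pregnancies multiplier. Both denominators are floored at \code{g_floor}
#' before dividing so near-zero fitted probabilities cannot explode the
#' weights.
#'
#' @param y_hat Per-birth unintended probabilities in [0, 1].
#' @param g1 Fitted live-birth probabilities given unintended (in (0, 1]).
#' @param g0 Fitted live-birth probabilities given intended (in (0, 1]).
#' @param g_floor Positive lower bound applied to \code{g1}, \code{g0}.
#' @return A data.frame with columns \code{u_hat}, \code{p_hat};
#'   \code{u_hat <= p_hat} and \code{p_hat >= 1} always hold.
#' @examples
#' pregnancy_multipliers(1, 0.71, 0.71)   # 1 birth ~ 1.41 pregnancies
#' @export
pregnancy_multipliers <- function(y_hat, g1, g0, g_floor = 0.05) {
  if (length(g_floor) != 1 || g_floor <= 0)
    stop("`g_floor` must be a single positive number", call. = FALSE)
  stopifnot(all(y_hat >= 0), all(y_hat <= 1),
            all(g1 > 0), all(g1 <= 1), all(g0 > 0), all(g0 <= 1))
  g1f <- pmax(g1, g_floor)
  g0f <- pmax(g0, g_floor)
  u <- y_hat / g1f
  p <- u + (1 - y_hat) / g0f
  data.frame(u_hat = u, p_hat = p)
}

# Even-odd ray-casting containment for one ring, vectorised over points.
# Points exactly on an edge count as inside (the tie-break across adjacent
# polygons is resolved by assign_area's id ordering).
point_in_ring <- function(ring, x, y) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_seg <- cross == 0 &
      x >= pmin(x1, x2) & x <= pmax(x1, x2) &
      y >= pmin(y1, y2) & y <= pmax(y1, y2)
    on_edge <- on_edge | on_seg
  }
  inside | on_edge
}

#' Assign points to areas by coordinates
#'
#' Point-in-polygon lookup over a non-overlapping tiling. Boundary points,
#' which touch two adjacent polygons, resolve deterministically to the
#' polygon whose id sorts first. Points inside no polygon return \code{NA}
#' (unassigned) and are counted by the caller.
#'
#' @param lat Numeric y-coordinates (planar miles in the synthetic frame).
#' @param lon Numeric x-coordinates.
#' @param polygons A \code{uisae_polygons} tiling.
#' @return Character vector of area ids, \code{NA} where unassigned.
#' @export
assign_area <- function(lat, lon, polygons) {
  stopifnot(inherits(polygons, "uisae_polygons"))
  if (length(polygons$ids) == 0)
    stop("empty polygon set", call. = FALSE)
  out <- rep(NA_character_, length(lat))
  todo <- rep(TRUE, length(lat))
  for (id in sort(polygons$ids)) {
    if (!any(todo)) break
    hit <- todo
    hit[todo] <- point_in_ring(polygons$rings[[id]], lon[todo], lat[todo])
    out[hit] <- id
    todo <- todo & !hit
  }
  out
}

age_bin_label <- function(age, age_bins) {
  a <- pmin(pmax(floor(age), age_bins$age_lo[1]),
            age_bins$age_hi[nrow(age_bins)])
  k <- findInterval(a, age_bins$age_lo)
  paste0(age_bins$age_lo[k], "-", age_bins$age_hi[k])
}

cell_outcomes <- function(sub, N, years_span) {
  B <- nrow(sub)
  sy <- sum(sub$y_hat); su <- sum(sub$u_hat); sp <- sum(sub$p_hat)
  data.frame(
    births_per_year = B / years_span,
    unintended_births_per_year = sy / years_span,
    pct_births_unintended = if (B > 0) 100 * sy / B else NA_real_,
    incidence_births_per_1000 =
      if (!is.na(N) && N > 0) 1000 * (sy / years_span) / N else NA_real_,
    pregnancies_per_year = sp / years_span,
    unintended_pregnancies_per_year = su / years_span,
    pct_pregnancies_unintended = if (sp > 0) 100 * su / sp else NA_real_,
    incidence_pregnancies_per_1000 =
      if (!is.na(N) && N > 0) 1000 * (su / years_span) / N else NA_real_,
    women_count = N
  )
}

#' Aggregate per-birth estimates into area-level outcomes
#'
#' Produces, for every area (and every age bin, and an \code{"all"} age
#' row, plus a statewide \code{"ALL"} area), the seven outcomes of the
#' method: births per year, unintended births per year, percent of births
#' unintended (100 sum(y)/B), incidence of unintended births per 1,000
#' women, pregnancies per year, unintended pregnancies per year, percent of
#' pregnancies unintended (100 sum(U)/sum(P)), and incidence of unintended
#' pregnancies per 1,000 women. All "per year" outcomes divide the 3-year
#' (or \code{years_span}-year) sums by \code{years_span}.
#'
#' @param birth_estimates Data.frame with columns \code{area_id},
#'   \code{age}, \code{y_hat}, and optionally \code{u_hat}, \code{p_hat}
#'   (absent: the no-loss limit u = y, p = 1 is used, i.e. pregnancies
#'   collapse to births).
#' @param population_table Data.frame \code{area_id}, \code{age_lo},
#'   \code{age_hi}, \code{women}; the denominator N as-is.
#' @param years_span Years of data the sums cover (> 0); default 3.
#' @param age_bins Age bins; must match the population table's bins.
#' @return A data.frame of class \code{uisae_area_estimates}, one row per
#'   area x age-group plus \code{"all"} rows and statewide \code{"ALL"}
#'   rows; attribute \code{n_undefined_incidence} counts cells with births
#'   but no population denominator.
#' @export
aggregate_areas <- function(birth_estimates, population_table,
                            years_span = 3, age_bins = default_age_bins()) {
  stopifnot(years_span > 0)
  validate_age_bins(age_bins)
  be <- birth_estimates
  if (any(is.na(be$area_id)))
    stop("every birth estimate must carry an area id", call. = FALSE)
  if (is.null(be$u_hat)) be$u_hat <- be$y_hat
  if (is.null(be$p_hat)) be$p_hat <- 1
  be$age_group <- age_bin_label(be$age, age_bins)

  pop <- population_table
  pop$age_group <- paste0(pop$age_lo, "-", pop$age_hi)
  pop_cell <- function(area, grp) {
    if (area == "ALL" && grp == "all") return(sum(pop$women))
    if (area == "ALL") return(sum(pop$women[pop$age_group == grp]))
    if (grp == "all") return(sum(pop$women[pop$area_id == area]))
    w <- pop$women[pop$area_id == area & pop$age_group == grp]
    if (length(w) == 0) NA_integer_ else sum(w)
  }

  areas <- sort(unique(c(be$area_id, pop$area_id)))
  groups <- c(paste0(age_bins$age_lo, "-", age_bins$age_hi), "all")
  rows <- list(); undef <- 0L
  for (area in c(areas, "ALL")) {
    in_area <- if (area == "ALL") rep(TRUE, nrow(be)) else be$area_id == area
    for (grp in groups) {
      sub <- if (grp == "all") be[in_area, , drop = FALSE]
             else be[in_area & be$age_group == grp, , drop = FALSE]
      N <- pop_cell(area, grp)
      oc <- cell_outcomes(sub, N, years_span)
      if (nrow(sub) > 0 && (is.na(N) || N == 0)) undef <- undef + 1L
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(area_id = area, age_group = grp), oc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("uisae_area_estimates", "data.frame"),
            years_span = years_span,
            n_undefined_incidence = undef)
}

#' @method print uisae_area_estimates
#' @export
print.uisae_area_estimates <- function(x, ...) {
  n_area <- length(setdiff(unique(x$area_id), "ALL"))
  cat(sprintf("Area estimates: %d areas x %d age groups (+ statewide), %d rows\n",
              n_area, length(unique(x$age_group)) - 1, nrow(x)))
  sw <- x[x$area_id == "ALL" & x$age_group == "all", ]
  cat(sprintf("  statewide: %.0f births/yr, %.1f%% unintended; %.0f pregnancies/yr, %.1f%% unintended\n",
              sw$births_per_year, sw$pct_births_unintended,
              sw$pregnancies_per_year, sw$pct_pregnancies_unintended))
  invisible(x)
}

#' Statewide one-row summary with reporting-grain rounding
#'
#' Collapses the aggregate table to its statewide all-ages row, rounded at
#' the grain results are conventionally reported: annual counts to the
#' nearest 100, percentages to 0.1, incidence to the nearest integer per
#' 1,000 women. The unrounded row is attached as attribute
#' \code{"unrounded"}. Invariant to the row order of the input.
#'
#' @param area_estimates A [aggregate_areas()] result.
#' @param n_excluded Count of birth records excluded for unusable
#'   coordinates, carried through for the accounting log.
#' @return A one-row data.frame of class \code{uisae_statewide}.
#' @export
statewide_report <- function(area_estimates, n_excluded = 0L) {
  sw <- area_estimates[area_estimates$area_id == "ALL" &
                         area_estimates$age_group == "all", , drop = FALSE]
  stopifnot(nrow(sw) == 1)
  out <- data.frame(
    births_per_year = round(sw$births_per_year / 100) * 100,
    unintended_births_per_year =
      round(sw$unintended_births_per_year / 100) * 100,
    pct_births_unintended = round(sw$pct_births_unintended, 1),
    incidence_births_per_1000 = round(sw$incidence_births_per_1000),
    pregnancies_per_year = round(sw$pregnancies_per_year / 100) * 100,
    unintended_pregnancies_per_year =
      round(sw$unintended_pregnancies_per_year / 100) * 100,
    pct_pregnancies_unintended = round(sw$pct_pregnancies_unintended, 1),
    incidence_pregnancies_per_1000 = round(sw$incidence_pregnancies_per_1000),
    women_count = sw$women_count,
    n_excluded_coordinates = as.integer(n_excluded),
    n_undefined_incidence = attr(area_estimates, "n_undefined_incidence")
  )
  rownames(out) <- NULL
  structure(out, class = c("uisae_statewide", "data.frame"),
            unrounded = sw)
}

#' @method print uisae_statewide
#' @export
print.uisae_statewide <- function(x, ...) {
  cat("Statewide summary (rounded to reporting grain)\n")
  cat(sprintf("  unintended births/yr:      %7.0f of %7.0f (%.1f%%), %d per 1,000 women\n",
              x$unintended_births_per_year, x$births_per_year,
              x$pct_births_unintended, x$incidence_births_per_1000))
  cat(sprintf("  unintended pregnancies/yr: %7.0f of %7.0f (%.1f%%), %d per 1,000 women\n",
              x$unintended_pregnancies_per_year, x$pregnancies_per_year,
              x$pct_pregnancies_unintended, x$incidence_pregnancies_per_1000))
  cat(sprintf("  excluded records (coordinates): %d; undefined-incidence cells: %d\n",
              x$n_excluded_coordinates, x$n_undefined_incidence))
  invisible(x)
}

#' Attach area estimates to polygons as a choropleth-ready GeoJSON
#'
#' Writes a FeatureCollection whose polygon properties carry the
#' all-ages outcomes for each area, ready for choropleth rendering.
#'
#' @param polygons A \code{uisae_polygons} tiling.
#' @param area_estimates A [aggregate_areas()] result.
#' @param path Output GeoJSON path.
#' @return \code{path}, invisibly.
#' @export
write_estimates_geojson <- function(polygons, area_estimates, path) {
  est <- area_estimates[area_estimates$age_group == "all" &
                          area_estimates$area_id != "ALL", , drop = FALSE]
  feats <- lapply(polygons$ids, function(id) {
    ring <- polygons$rings[[id]]
    row <- est[est$area_id == id, , drop = FALSE]
    props <- list(id = id, area_sqmi = unname(polygons$area_sqmi[[id]]))
    if (nrow(row) == 1)
      props <- c(props, as.list(row[setdiff(names(row),
                                            c("area_id", "age_group"))]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2])))))
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "planar miles, not geodetic",
             bbox = polygons$bbox, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
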