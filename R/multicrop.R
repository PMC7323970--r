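# Multi-crop aggregation: per-pixel crop counts by suitability level,
# rank-sum scores (4-16 for four crops, 2-8 for a pair), and area /
# percentage accounting with change tables.

as_rank_matrix <- function(x) {
  if (inherits(x, "suitability_map")) return(x$rank)
  if (is.matrix(x)) return(x)
  stop("expected a suitability_map or a rank matrix")
}

check_same_maps <- function(ms) {
  d <- dim(ms[[1]])
  for (m in ms) {
    if (!identical(dim(m), d)) stop("maps do not share a grid")
    if (!identical(is.na(m), is.na(ms[[1]]))) stop("maps do not share a mask")
  }
  vals <- unlist(lapply(ms, function(m) m[!is.na(m)]))
  if (length(vals) > 0 && !all(vals %in% 1:4))
    stop("rank values must be in 1..4")
  invisible(TRUE)
}

#' Per-pixel crop counts at each suitability level
#'
#' Stacks single-crop maps and, for each class level, counts how many
#' crops sit at exactly that level per pixel; the four counts sum to the
#' number of crops at every masked pixel.
#'
#' @param maps list of suitability maps (or rank matrices) on one grid.
#' @return array `[lat, lon, 4]` with the levels as third dimension names.
#' @export
count_by_class <- function(maps) {
  ms <- lapply(maps, as_rank_matrix)
  check_same_maps(ms)
  d <- dim(ms[[1]])
  out <- array(NA_integer_, c(d, 4),
               dimnames = list(NULL, NULL, suitability_levels()))
  for (k in 1:4) {
    cnt <- Reduce(`+`, lapply(ms, function(m) (m == k) * 1L))
    out[, , k] <- cnt
  }
  out
}

#' Combined multi-crop rank-sum score
#'
#' Per-pixel sum of class ranks (limited=1 ... optimal=4) across crops;
#' for four crops the score runs from 4 (very low multi-crop potential) to
#' 16 (very high).
#'
#' @param maps list of suitability maps (or rank matrices) on one grid.
#' @return integer matrix of rank sums, `NA` off-mask.
#' @export
combined_score <- function(maps) {
  ms <- lapply(maps, as_rank_matrix)
  check_same_maps(ms)
  Reduce(`+`, ms)
}

pair_abbrev <- c("Ld", "Mg", "Md", "Op")

#' Category labels for a crop pair
#'
#' All unordered rank-pair categories, ordered by rank sum: `Ld-Ld` (both
#' limited) up to `Op-Op` (both optimal).
#'
#' @return character vector of the 10 category labels.
#' @export
pair_category_levels <- function() {
  combos <- expand.grid(a = 1:4, b = 1:4)
  combos <- combos[combos$a <= combos$b, ]
  combos <- combos[order(combos$a + combos$b, combos$a), ]
  paste(pair_abbrev[combos$a], pair_abbrev[combos$b], sep = "-")
}

#' Pairwise two-crop rank-sum score
#'
#' Per-pixel rank sum for two crops (2 = both limited, 8 = both optimal)
#' plus the unordered category label (`Ld-Ld` ... `Op-Op`).
#'
#' @param map_a,map_b suitability maps (or rank matrices) on one grid.
#' @return list with `score` (integer matrix) and `category` (factor
#'   matrix with levels [pair_category_levels()]).
#' @export
pair_score <- function(map_a, map_b) {
  a <- as_rank_matrix(map_a); b <- as_rank_matrix(map_b)
  check_same_maps(list(a, b))
  score <- a + b
  lo <- pmin(a, b); hi <- pmax(a, b)
  lab <- matrix(factor(paste(pair_abbrev[lo], pair_abbrev[hi], sep = "-"),
                       levels = pair_category_levels()),
                nrow(a), ncol(a))
  lab[is.na(a)] <- NA
  list(score = score, category = lab)
}

#' Per-pixel cell areas
#'
#' Equal-area by default (a nominal cell size in km^2); the
#' latitude-cosine mode scales the nominal size by `cos(lat)` for
#' geographic grids.
#'
#' @param lat,lon grid coordinate vectors.
#' @param mode `"equal"` or `"cosine"`.
#' @param cell_km2 nominal cell area (default the area of a 0.05-degree
#'   cell at the equator, ~30.98 km^2).
#' @return numeric matrix `[lat, lon]` of areas, km^2.
#' @export
cell_areas <- function(lat, lon, mode = c("equal", "cosine"),
                       cell_km2 = (111.32 * 0.05)^2) {
  mode <- match.arg(mode)
  m <- matrix(cell_km2, length(lat), length(lon))
  if (mode == "cosine") m <- m * cos(lat * pi / 180)
  m
}

#' Area and percentage per category
#'
#' Sums cell areas per map category over masked pixels and expresses each
#' as a percent of the total masked area.
#'
#' @param map rank matrix, factor/character category matrix, or
#'   suitability map.
#' @param cell_area scalar or `[lat, lon]` matrix of areas (km^2).
#' @param categories category set fixing row order; defaults to
#'   [suitability_levels()] for rank maps and observed levels otherwise.
#' @return data.frame with `category`, `area_km2`, `percent`.
#' @export
area_table <- function(map, cell_area = 1, categories = NULL) {
  if (inherits(map, "suitability_map")) map <- map$rank
  if (is.numeric(map)) {
    if (is.null(categories)) categories <- suitability_levels()
    vals <- suitability_levels()[map]
  } else {
    vals <- as.character(map)
    if (is.null(categories))
      categories <- if (is.factor(map)) levels(map) else sort(unique(vals[!is.na(vals)]))
  }
  ok <- !is.na(vals)
  if (!any(ok)) stop("zero masked area")
  if (length(cell_area) == 1) cell_area <- rep(cell_area, length(vals))
  area <- vapply(categories, function(cat) {
    sum(cell_area[ok & vals == cat])
  }, numeric(1))
  total <- sum(cell_area[ok])
  data.frame(category = categories, area_km2 = as.numeric(area),
             percent = 100 * as.numeric(area) / total, row.names = NULL)
}

#' Change in area between a current and future map
#'
#' Per category: percentage-point and km^2 change (future minus current).
#' When `future` is a list of per-GCM tables, changes are averaged across
#' them (multi-model mean change).
#'
#' @param current area table from [area_table()].
#' @param future a matching area table, or a list of them (one per GCM).
#' @return data.frame with `category`, current/future area and percent,
#'   `change_pp` (percentage points) and `change_km2`.
#' @export
change_table <- function(current, future) {
  futures <- if (is.data.frame(future)) list(future) else future
  for (f in futures) {
    if (!identical(as.character(f$category), as.character(current$category)))
      stop("category sets do not match")
  }
  fut_pct <- rowMeans(sapply(futures, `[[`, "percent"))
  fut_area <- rowMeans(sapply(futures, `[[`, "area_km2"))
  data.frame(
    category = current$category,
    current_area_km2 = current$area_km2, current_percent = current$percent,
    future_area_km2 = fut_area, future_percent = fut_pct,
    change_pp = fut_pct - current$percent,
    change_km2 = fut_area - current$area_km2,
    row.names = NULL
  )
}
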