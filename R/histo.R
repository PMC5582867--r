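#' Coronal-section geometry for sectorized quantification
#'
#' The analyzed cortical strip of a P5-7 coronal section is modeled as a flat
#' rectangle divided mediolaterally into six sectors `a`-`f` of 0.55 mm width
#' starting 0.73 mm from the midline, and in depth into three laminar bands:
#' layers I-IV, layer V and layer VI, as fractions of the cortical thickness
#' (0 at the pia, 1 at the white matter). The default band fractions
#' (0.45/0.30/0.25) reflect typical P6 cytoarchitecture.
#'
#' @param sector_start_mm mediolateral offset of sector `a` from the midline.
#' @param sector_width_mm sector width, mm.
#' @param n_sectors number of sectors (labeled `a`, `b`, ...).
#' @param cortical_thickness_mm pia-to-white-matter distance, mm.
#' @param layer_breaks_frac interior fractional depth breaks separating the
#'   laminar bands (must be increasing, within (0, 1)).
#' @param layer_names one name per band.
#' @return a `bq_geometry` list with a `layers` tibble (`layer`, `lo_frac`,
#'   `hi_frac`) and a `sectors` tibble (`sector`, `lo_mm`, `hi_mm`).
#' @examples
#' section_geometry()
#' @export
section_geometry <- function(sector_start_mm = 0.73,
                             sector_width_mm = 0.55,
                             n_sectors = 6,
                             cortical_thickness_mm = 1.0,
                             layer_breaks_frac = c(0.45, 0.75),
                             layer_names = c("I-IV", "V", "VI")) {
  check_number(sector_start_mm, "sector_start_mm", lower = 0)
  check_number(sector_width_mm, "sector_width_mm", lower = 0, strict_lower = TRUE)
  check_number(cortical_thickness_mm, "cortical_thickness_mm",
               lower = 0, strict_lower = TRUE)
  stopifnot(n_sectors >= 1, n_sectors <= 26)
  breaks <- c(0, layer_breaks_frac, 1)
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks < 0 | breaks > 1)) {
    rlang::abort("`layer_breaks_frac` must be strictly increasing within (0, 1).")
  }
  if (length(layer_names) != length(breaks) - 1L) {
    rlang::abort("`layer_names` must name every band between the breaks.")
  }
  sectors <- tibble::tibble(
    sector = letters[seq_len(n_sectors)],
    lo_mm = sector_start_mm + (seq_len(n_sectors) - 1) * sector_width_mm,
    hi_mm = sector_start_mm + seq_len(n_sectors) * sector_width_mm
  )
  layers <- tibble::tibble(
    layer = layer_names,
    lo_frac = breaks[-length(breaks)],
    hi_frac = breaks[-1]
  )
  out <- list(
    sector_start_mm = sector_start_mm,
    sector_width_mm = sector_width_mm,
    n_sectors = as.integer(n_sectors),
    cortical_thickness_mm = cortical_thickness_mm,
    sectors = sectors,
    layers = layers
  )
  class(out) <- "bq_geometry"
  out
}

#' @export
print.bq_geometry <- function(x, ...) {
  cat(sprintf(
    "<bq_geometry> %d sectors of %.2f mm from %.2f mm; thickness %.2f mm\n",
    x$n_sectors, x$sector_width_mm, x$sector_start_mm, x$cortical_thickness_mm
  ))
  print(x$layers)
  invisible(x)
}

# area (mm^2) of one (sector, layer) bin
bin_areas <- function(geometry) {
  dplyr::mutate(
    tidyr::crossing(sector = geometry$sectors$sector, geometry$layers),
    area_mm2 = geometry$sector_width_mm *
      (.data$hi_frac - .data$lo_frac) * geometry$cortical_thickness_mm
  )
}

#' Simulate a spatial Poisson map of marker-positive cells
#'
#' Draws a homogeneous Poisson point process within each (sector, layer-band)
#' rectangle of the geometry at the given intensity. Points carry coordinates
#' only; bin labels are re-derived downstream by [assign_bins()].
#'
#' @param geometry a `bq_geometry` from [section_geometry()].
#' @param intensity a tibble with columns `sector`, `layer`,
#'   `intensity_per_mm2` covering exactly the geometry's bins (e.g. from
#'   [get_intensity_preset()]).
#' @param seed integer seed.
#' @param marker marker label stored with each point.
#' @return a `bq_cellmap` tibble with columns `x_mm` (mediolateral distance
#'   from the midline), `depth_frac` (0 pia, 1 white matter) and `marker`.
#' @examples
#' geom <- section_geometry()
#' cells <- generate_cell_map(geom, get_intensity_preset(), seed = 1)
#' nrow(cells)
#' @export
generate_cell_map <- function(geometry, intensity, seed, marker = "aCasp3") {
  stopifnot(inherits(geometry, "bq_geometry"))
  req <- c("sector", "layer", "intensity_per_mm2")
  if (!all(req %in% names(intensity))) {
    rlang::abort("`intensity` needs columns sector, layer, intensity_per_mm2.")
  }
  if (any(intensity$intensity_per_mm2 < 0)) {
    rlang::abort("Intensities must be >= 0.")
  }
  bins <- bin_areas(geometry)
  grid <- dplyr::left_join(bins, intensity, by = c("sector", "layer"))
  if (anyNA(grid$intensity_per_mm2)) {
    rlang::abort("`intensity` must provide a value for every (sector, layer) bin of the geometry.")
  }
  sec <- geometry$sectors
  with_stream(seed, "generate_cell_map", {
    pts <- purrr::pmap_dfr(grid, function(sector, layer, lo_frac, hi_frac,
                                          area_mm2, intensity_per_mm2) {
      n <- stats::rpois(1, intensity_per_mm2 * area_mm2)
      if (n == 0) {
        return(tibble::tibble(x_mm = numeric(0), depth_frac = numeric(0)))
      }
      lo_mm <- sec$lo_mm[sec$sector == sector]
      tibble::tibble(
        x_mm = stats::runif(n, lo_mm, lo_mm + geometry$sector_width_mm),
        depth_frac = stats::runif(n, lo_frac, hi_frac)
      )
    })
    pts$marker <- rep(marker, nrow(pts))
    class(pts) <- c("bq_cellmap", class(pts))
    pts
  })
}

#' Sector and layer binning of cell coordinates
#'
#' Labels each point with its sector (half-open mediolateral bins
#' `[lo, hi)`) and laminar band (half-open depth bins; the deepest band is
#' closed at `depth_frac = 1`). Points left of sector `a` or right of the
#' last sector are labeled out-of-grid (`NA`).
#'
#' @param cells a tibble with columns `x_mm` and `depth_frac`.
#' @param geometry a `bq_geometry`.
#' @return the input tibble with added `sector` and `layer` columns.
#' @examples
#' geom <- section_geometry()
#' assign_bins(tibble::tibble(x_mm = 0.9, depth_frac = 0.2), geom)
#' @export
assign_bins <- function(cells, geometry) {
  stopifnot(inherits(geometry, "bq_geometry"))
  if (!all(c("x_mm", "depth_frac") %in% names(cells))) {
    rlang::abort("`cells` needs columns x_mm and depth_frac.")
  }
  bad <- which(!is.finite(cells$x_mm) | !is.finite(cells$depth_frac) |
                 cells$depth_frac < 0 | cells$depth_frac > 1)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Malformed coordinates (non-finite or depth_frac outside [0, 1]) at row(s) %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  idx <- floor((cells$x_mm - geometry$sector_start_mm) / geometry$sector_width_mm)
  sector <- rep(NA_character_, length(idx))
  in_grid <- idx >= 0 & idx < geometry$n_sectors
  sector[in_grid] <- letters[idx[in_grid] + 1]
  breaks <- c(geometry$layers$lo_frac, 1)
  li <- findInterval(cells$depth_frac, breaks, rightmost.closed = TRUE)
  layer <- geometry$layers$layer[li]
  dplyr::mutate(cells, sector = sector, layer = layer)
}

#' Per-bin cell density table
#'
#' Counts labeled points per (sector, layer-band) bin and divides by the
#' anatomical bin area (sector width times band height). Bins with no points
#' appear with count 0; out-of-grid points are excluded and reported in the
#' `n_out_of_grid` attribute.
#'
#' @param labeled output of [assign_bins()].
#' @param geometry the same `bq_geometry` used for binning.
#' @return a `bq_density` tibble with columns `sector`, `layer`, `count`,
#'   `area_mm2`, `density_per_mm2`.
#' @export
density_table <- function(labeled, geometry) {
  stopifnot(inherits(geometry, "bq_geometry"))
  if (!all(c("sector", "layer") %in% names(labeled))) {
    rlang::abort("`labeled` must carry sector/layer labels from assign_bins().")
  }
  bins <- bin_areas(geometry)
  if (any(bins$area_mm2 <= 0)) rlang::abort("Geometry contains a zero-area bin.")
  counts <- labeled |>
    dplyr::filter(!is.na(.data$sector), !is.na(.data$layer)) |>
    dplyr::mutate(sector = as.character(.data$sector),
                  layer = as.character(.data$layer)) |>
    dplyr::count(.data$sector, .data$layer, name = "count")
  out <- bins |>
    dplyr::left_join(counts, by = c("sector", "layer")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      density_per_mm2 = .data$count / .data$area_mm2
    ) |>
    dplyr::select("sector", "layer", "count", "area_mm2", "density_per_mm2") |>
    dplyr::arrange(.data$sector, match(.data$layer, geometry$layers$layer))
  attr(out, "n_out_of_grid") <- sum(is.na(labeled$sector) | is.na(labeled$layer))
  class(out) <- c("bq_density", class(out))
  out
}

#' Pool sector densities into named areas
#'
#' Pools counts and areas (not densities) across the sectors of each named
#' area — by default M1 = sectors a/b and S1 = sectors c-f — and returns the
#' pooled density per area and layer band.
#'
#' @param table a `bq_density` from [density_table()].
#' @param mapping named list mapping area names to sector labels.
#' @return a tibble with columns `area`, `layer`, `count`, `area_mm2`,
#'   `density_per_mm2`.
#' @examples
#' geom <- section_geometry()
#' cells <- generate_cell_map(geom, get_intensity_preset(), seed = 1)
#' cells |> assign_bins(geom) |> density_table(geom) |> area_aggregate()
#' @export
area_aggregate <- function(table,
                           mapping = list(M1 = c("a", "b"),
                                          S1 = c("c", "d", "e", "f"))) {
  unknown <- setdiff(unlist(mapping), unique(table$sector))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown sector(s) in mapping: %s.",
                         paste(unknown, collapse = ", ")))
  }
  purrr::imap_dfr(mapping, function(sectors, area) {
    table |>
      dplyr::filter(.data$sector %in% sectors) |>
      dplyr::group_by(.data$layer) |>
      dplyr::summarise(count = sum(.data$count),
                       area_mm2 = sum(.data$area_mm2), .groups = "drop") |>
      dplyr::mutate(area = area,
                    density_per_mm2 = .data$count / .data$area_mm2) |>
      dplyr::select("area", "layer", "count", "area_mm2", "density_per_mm2")
  })
}
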