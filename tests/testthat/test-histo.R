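test_that("bin assignment follows the published geometry with half-open bins", {
  geom <- section_geometry()
  lab <- assign_bins(tibble::tibble(
    x_mm = c(0.90, 0.50, 0.73 + 0.55, 4.5),
    depth_frac = c(0.20, 0.5, 0.1, 0.5)
  ), geom)
  expect_equal(lab$sector, c("a", NA, "b", NA))
  expect_equal(lab$layer[1], "I-IV")
  expect_error(assign_bins(tibble::tibble(x_mm = c(1, NA), depth_frac = c(0.2, 0.3)),
                           geom), "row")
  expect_error(assign_bins(tibble::tibble(x_mm = 1, depth_frac = 1.2), geom),
               "row")
})

test_that("density tables divide counts by anatomical bin area", {
  geom <- section_geometry()
  empty <- density_table(assign_bins(tibble::tibble(x_mm = numeric(0),
                                                    depth_frac = numeric(0)),
                                     geom), geom)
  expect_true(all(empty$density_per_mm2 == 0))
  expect_equal(nrow(empty), 18)  # 6 sectors x 3 bands
  # 10 points in sector a, layers I-IV: area 0.55 * 0.45 = 0.2475 mm^2
  pts <- tibble::tibble(x_mm = runif(10, 0.75, 1.25),
                        depth_frac = runif(10, 0.05, 0.40))
  tab <- density_table(assign_bins(pts, geom), geom)
  d <- tab$density_per_mm2[tab$sector == "a" & tab$layer == "I-IV"]
  expect_equal(round(d, 2), 40.40)
})

test_that("counts are conserved including out-of-grid points", {
  geom <- section_geometry()
  withr::with_seed(31, {
    pts <- tibble::tibble(x_mm = runif(500, 0, 5), depth_frac = runif(500))
    tab <- density_table(assign_bins(pts, geom), geom)
    expect_equal(sum(tab$count) + attr(tab, "n_out_of_grid"), 500)
  })
})

test_that("shifting x by one sector width shifts interior labels one sector", {
  geom <- section_geometry()
  withr::with_seed(32, {
    pts <- tibble::tibble(x_mm = runif(200, 0.73, 0.73 + 5 * 0.55),
                          depth_frac = runif(200))
    l1 <- assign_bins(pts, geom)
    l2 <- assign_bins(dplyr::mutate(pts, x_mm = x_mm + 0.55), geom)
    expect_true(all(match(l2$sector, letters) == match(l1$sector, letters) + 1))
    expect_identical(l1$layer, l2$layer)
  })
})

test_that("area aggregation pools counts, not densities", {
  geom <- section_geometry(sector_start_mm = 0, sector_width_mm = 1,
                           n_sectors = 2, layer_breaks_frac = c(0.5),
                           layer_names = c("up", "down"))
  # equal-area sectors with densities 20 and 40 -> pooled 30
  pts <- tibble::tibble(
    x_mm = c(runif(10, 0, 1), runif(20, 1, 2)),
    depth_frac = runif(30, 0, 0.49)
  )
  tab <- density_table(assign_bins(pts, geom), geom)
  agg <- area_aggregate(tab, mapping = list(both = c("a", "b"), solo = "a"))
  expect_equal(agg$density_per_mm2[agg$area == "both" & agg$layer == "up"], 30)
  expect_equal(agg$density_per_mm2[agg$area == "solo" & agg$layer == "up"],
               tab$density_per_mm2[tab$sector == "a" & tab$layer == "up"])
  expect_error(area_aggregate(tab, mapping = list(x = "z")), "Unknown sector")
})

test_that("cell maps are Poisson with the configured intensity (Monte-Carlo oracle)", {
  geom <- section_geometry(sector_start_mm = 0, sector_width_mm = 1,
                           n_sectors = 1, cortical_thickness_mm = 1,
                           layer_breaks_frac = numeric(0), layer_names = "all")
  intensity <- tibble::tibble(sector = "a", layer = "all",
                              intensity_per_mm2 = 50)
  counts <- vapply(1:200, function(s) {
    nrow(generate_cell_map(geom, intensity, seed = s))
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se)
  # index of dispersion for a Poisson process
  expect_gt(stats::var(counts) / mean(counts), 0.8)
  expect_lt(stats::var(counts) / mean(counts), 1.2)
})

test_that("cell-map generation validates inputs and is deterministic", {
  geom <- section_geometry()
  intensity <- get_intensity_preset("P5_7_in_vivo")
  expect_identical(generate_cell_map(geom, intensity, seed = 5),
                   generate_cell_map(geom, intensity, seed = 5))
  zero <- dplyr::mutate(intensity, intensity_per_mm2 = 0)
  expect_equal(nrow(generate_cell_map(geom, zero, seed = 1)), 0)
  neg <- dplyr::mutate(intensity, intensity_per_mm2 = -1)
  expect_error(generate_cell_map(geom, neg, seed = 1), ">= 0")
  expect_error(generate_cell_map(geom, intensity[-1, ], seed = 1), "every")
  expect_error(get_intensity_preset("nope"), "Unknown")
})

test_that("sectorized quantification recovers the preset intensities", {
  geom <- section_geometry()
  intensity <- get_intensity_preset("P5_7_in_vivo")
  agg <- purrr::map_dfr(1:20, function(s) {
    cells <- generate_cell_map(geom, intensity, seed = s)
    area_aggregate(density_table(assign_bins(cells, geom), geom))
  })
  means <- agg |>
    dplyr::group_by(area, layer) |>
    dplyr::summarise(d = mean(density_per_mm2), .groups = "drop")
  m1 <- means$d[means$area == "M1" & means$layer == "I-IV"]
  s1 <- means$d[means$area == "S1" & means$layer == "I-IV"]
  expect_lt(abs(m1 - 57.76) / 57.76, 0.10)
  expect_lt(abs(s1 - 14.86) / 14.86, 0.10)
  expect_gt(m1 / s1, 3.3)
  expect_lt(m1 / s1, 4.6)
})
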