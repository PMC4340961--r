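#' Parameters of the synthetic raster archipelago
#'
#' The generator emulates a post-glacial land-uplift coastline: a mainland
#' strip along the western edge with a noisy coast, and islands whose
#' expected radius decays with distance from the mainland, so that islands
#' are larger near the mainland and dwindle to skerries towards the open
#' sea.
#'
#' @param nx,ny grid extent in 1 km squares, east-west and north-south.
#' @param cell_size raster cell size in m; must divide 1000.
#' @param n_islands number of island seeds to place.
#' @param island_radius_base expected island radius (m) at the mainland
#'   coast.
#' @param island_decay radius decay rate per metre of distance from the
#'   mainland coast (`radius = base * exp(-decay * d)`).
#' @param mainland_width mean mainland strip width in m.
#' @param roughness SD (m) of the random-walk perturbation of the
#'   mainland coastline.
#' @param seed integer seed.
#' @return a `landscape_params` list.
#' @export
landscape_params <- function(nx = 10, ny = 20, cell_size = 50,
                             n_islands = 120, island_radius_base = 300,
                             island_decay = 3e-4, mainland_width = 600,
                             roughness = 150, seed = 1) {
  stopifnot(nx >= 2, ny >= 1, cell_size > 0, 1000 %% cell_size == 0,
            n_islands >= 1, island_radius_base > 0, island_decay >= 0,
            mainland_width > 0, roughness >= 0)
  structure(list(nx = nx, ny = ny, cell_size = cell_size,
                 n_islands = n_islands,
                 island_radius_base = island_radius_base,
                 island_decay = island_decay,
                 mainland_width = mainland_width, roughness = roughness,
                 seed = seed),
            class = "landscape_params")
}

# mask codes
.WATER <- 0L
.ISLAND <- 1L
.MAINLAND <- 2L

#' Generate a raster archipelago landscape
#'
#' @param p a [landscape_params()] object.
#' @return a `raster_landscape`: list with `mask` (ny_cells x nx_cells
#'   integer matrix, rows = south to north, cols = west to east; 0 water,
#'   1 island, 2 mainland), `cell_size`, `origin` (lower-left corner,
#'   m), `squares_shape` `(ny, nx)` and the generating parameters.
#' @export
generate_landscape <- function(p) {
  stopifnot(inherits(p, "landscape_params"))
  k <- 1000 %/% p$cell_size
  ncx <- p$nx * k
  ncy <- p$ny * k
  cs <- p$cell_size
  with_seed(p$seed, {
    mask <- matrix(.WATER, ncy, ncx)

    # mainland strip on the western edge, noisy eastward extent per row
    walk <- cumsum(stats::rnorm(ncy))
    walk <- walk - mean(walk)
    if (stats::sd(walk) > 0) walk <- walk / stats::sd(walk) * p$roughness
    wcells <- pmax(1L, pmin(ncx %/% 3L,
                            as.integer(round((p$mainland_width + walk) / cs))))
    for (iy in seq_len(ncy)) mask[iy, seq_len(wcells[iy])] <- .MAINLAND
    coast_x <- wcells * cs  # eastward extent of mainland, per row (m)

    max_coast <- max(coast_x)
    if ((ncx * cs - max_coast) < 3 * cs)
      stop_named("skerrydiv_extent_too_small",
                 "extent too small to host mainland plus islands")

    # cell centres
    cxs <- (seq_len(ncx) - 0.5) * cs
    cys <- (seq_len(ncy) - 0.5) * cs

    for (i in seq_len(p$n_islands)) {
      cx <- stats::runif(1, max_coast + cs, ncx * cs - cs)
      cy <- stats::runif(1, 0, ncy * cs)
      d_main <- max(0, cx - coast_x[pmin(ncy, pmax(1L, ceiling(cy / cs)))])
      r <- p$island_radius_base * exp(-p$island_decay * d_main) *
        exp(stats::rnorm(1, 0, 0.3))
      r <- max(r, cs / 2)  # at least one cell: a bare skerry
      ix <- which(abs(cxs - cx) <= r + cs)
      iy <- which(abs(cys - cy) <= r + cs)
      if (!length(ix) || !length(iy)) next
      sub <- outer((cys[iy] - cy)^2, (cxs[ix] - cx)^2, `+`) <= r^2
      blk <- mask[iy, ix, drop = FALSE]
      blk[sub & blk == .WATER] <- .ISLAND
      mask[iy, ix] <- blk
    }
    # guarantee at least one island cell
    if (!any(mask == .ISLAND)) {
      iy <- ncy %/% 2 + 1L
      ix <- min(ncx, wcells[iy] + 2L)
      if (mask[iy, ix] != .WATER)
        stop_named("skerrydiv_extent_too_small",
                   "extent too small to host mainland plus islands")
      mask[iy, ix] <- .ISLAND
    }
    structure(list(mask = mask, cell_size = cs, origin = c(x = 0, y = 0),
                   squares_shape = c(ny = p$ny, nx = p$nx), params = p),
              class = "raster_landscape")
  })
}

#' @export
print.raster_landscape <- function(x, ...) {
  tab <- table(factor(x$mask, levels = c(.WATER, .ISLAND, .MAINLAND),
                      labels = c("water", "island", "mainland")))
  cat(sprintf("raster_landscape: %d x %d squares, cell %g m\n",
              x$squares_shape[["ny"]], x$squares_shape[["nx"]], x$cell_size))
  print(tab)
  invisible(x)
}

# shift a logical matrix by (dy, dx), padding with FALSE
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[oky, okx] <- m[ys[oky], xs[okx], drop = FALSE]
  out
}

# minimum Euclidean distance from points to the centres of TRUE cells,
# using only region-boundary cells (points inside the region get 0)
min_dist_to_region <- function(px, py, region, cell_size) {
  nb <- shift_mat(region, 1, 0) & shift_mat(region, -1, 0) &
    shift_mat(region, 0, 1) & shift_mat(region, 0, -1)
  boundary <- region & !nb
  idx <- which(boundary, arr.ind = TRUE)
  bx <- (idx[, 2] - 0.5) * cell_size
  by <- (idx[, 1] - 0.5) * cell_size
  d <- vapply(seq_along(px), function(i) {
    sqrt(min((bx - px[i])^2 + (by - py[i])^2))
  }, numeric(1))
  # points whose containing cell lies in the region are inside: distance 0
  cxi <- pmin(ncol(region), pmax(1L, ceiling(px / cell_size)))
  cyi <- pmin(nrow(region), pmax(1L, ceiling(py / cell_size)))
  inside <- region[cbind(cyi, cxi)]
  d[inside] <- 0
  d
}

#' Derive the four per-square environmental metrics
#'
#' For every 1 km square of the landscape: `land_area` is the land-cell
#' count times the cell area; `shoreline` is the number of land/water
#' 4-neighbour cell edges, attributed to the land cell's square, times
#' the cell size; `dist_sea` is the Euclidean distance from the square
#' midpoint to the open-sea boundary line, a 150 m seaward offset of
#' the outermost (easternmost, per raster row) land envelope — squares
#' beyond the boundary get 0; `width` is `dist_sea` plus the distance
#' from the midpoint to the nearest mainland cell. Beyond the western
#' raster edge the mainland is assumed to continue (no phantom
#' shoreline); beyond the other edges lies water.
#'
#' @param r a `raster_landscape`.
#' @param buffer open-sea buffer width in m (default 150).
#' @return data.frame of square records (columns `square_id`, `x`, `y`,
#'   `land_area`, `shoreline`, `dist_sea`, `width`), row-major from the
#'   south-west corner.
#' @export
derive_environment <- function(r, buffer = 150) {
  stopifnot(inherits(r, "raster_landscape"))
  cs <- r$cell_size
  k <- 1000 %/% cs
  ny <- r$squares_shape[["ny"]]; nx <- r$squares_shape[["nx"]]
  mask <- r$mask
  land <- mask != .WATER
  ncy <- nrow(mask); ncx <- ncol(mask)

  # square index of every cell (row-major from SW: id = (sy-1)*nx + sx)
  sx <- rep(ceiling(seq_len(ncx) / k), each = ncy)
  sy <- rep.int(ceiling(seq_len(ncy) / k), ncx)
  sq_of_cell <- (sy - 1L) * nx + sx
  n_sq <- nx * ny

  land_cells <- tabulate(sq_of_cell[land], nbins = n_sq)
  land_area <- land_cells * cs^2

  # shoreline: land/water 4-neighbour edges, attributed to the land cell.
  # Outside the raster: land continues to the west (mainland) and the
  # coast continues north-south (mirrored edge rows); open water lies east.
  pad_w <- cbind(land[, 1], land[, -ncx, drop = FALSE])       # west neighbour
  pad_e <- cbind(land[, -1, drop = FALSE], FALSE)             # east neighbour
  pad_s <- rbind(land[1, , drop = FALSE], land[-ncy, , drop = FALSE])
  pad_n <- rbind(land[-1, , drop = FALSE], land[ncy, , drop = FALSE])
  exposed <- land * ((land & !pad_w) + (land & !pad_e) +
                       (land & !pad_s) + (land & !pad_n))
  shoreline <- tapply_sum(as.numeric(exposed), sq_of_cell, n_sq) * cs

  # open-sea boundary: 150 m seaward offset of the per-row outermost land
  # envelope (the line beyond which lies open water)
  east_land <- apply(land, 1, function(row) max(which(row)))  # mainland => >= 1
  boundary_x <- (east_land - 0.5) * cs + buffer
  # wrap the boundary around the outermost islands: limit its north-south
  # slope to 45 degrees so it cannot dip into gaps between islands
  for (i in seq(2, ncy)) boundary_x[i] <- max(boundary_x[i], boundary_x[i - 1] - cs)
  for (i in seq(ncy - 1, 1)) boundary_x[i] <- max(boundary_x[i], boundary_x[i + 1] - cs)
  row_y <- (seq_len(ncy) - 0.5) * cs
  if (all(boundary_x >= ncx * cs))
    stop_named("skerrydiv_no_open_sea", "landscape has no open-sea water")

  mx <- (rep(seq_len(nx), times = ny) - 0.5) * 1000 + r$origin[["x"]]
  my <- (rep(seq_len(ny), each = nx) - 0.5) * 1000 + r$origin[["y"]]
  dist_sea <- vapply(seq_along(mx), function(i) {
    iy <- pmin(ncy, pmax(1L, ceiling(my[i] / cs)))
    if (mx[i] >= boundary_x[iy]) return(0)  # midpoint on/beyond the boundary
    sqrt(min((boundary_x - mx[i])^2 + (row_y - my[i])^2))
  }, numeric(1))
  dist_main <- min_dist_to_region(mx, my, mask == .MAINLAND, cs)
  width <- dist_main + dist_sea

  data.frame(square_id = sprintf("sq_%04d", seq_len(n_sq)),
             x = mx, y = my,
             land_area = land_area[order_rowmajor(nx, ny)],
             shoreline = shoreline[order_rowmajor(nx, ny)],
             dist_sea = dist_sea, width = width,
             stringsAsFactors = FALSE)
}

# square ids were assigned row-major from SW both for cells and midpoints;
# identity map kept explicit for clarity
order_rowmajor <- function(nx, ny) seq_len(nx * ny)

tapply_sum <- function(x, group, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
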