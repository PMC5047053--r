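#' Default seven-tissue layer stack
#'
#' The symmetric nine-entry stack crossed by the ultrasound beam, from the
#' top surface downward: skin 0.55, fat 0.58, muscle 1.73, cortical 0.04,
#' marrow 0.10, cortical 0.04, muscle 1.73, fat 0.58, skin 0.55 mm
#' (total 5.90 mm). Thicknesses are radiographic averages for the rat
#' hind limb.
#'
#' @return A `layer_stack`: data frame with columns `tissue`, `thickness_mm`.
#' @export
default_layer_stack <- function() {
  layer_stack(
    tissue = c("skin", "fat", "muscle", "cortical bone", "bone marrow",
               "cortical bone", "muscle", "fat", "skin"),
    thickness_mm = c(0.55, 0.58, 1.73, 0.04, 0.10, 0.04, 1.73, 0.58, 0.55))
}

#' Construct a layer stack
#' @param tissue character vector of tissue names (top surface first).
#' @param thickness_mm positive layer thicknesses, mm.
#' @return data frame of class `layer_stack`.
#' @export
layer_stack <- function(tissue, thickness_mm) {
  if (length(tissue) != length(thickness_mm)) stop("length mismatch")
  if (any(thickness_mm <= 0)) stop("thicknesses must be positive")
  structure(data.frame(tissue = tissue, thickness_mm = thickness_mm,
                       stringsAsFactors = FALSE),
            class = c("layer_stack", "data.frame"))
}

stack_total <- function(stack) sum(stack$thickness_mm)

#' Receiver positions along the propagation axis
#'
#' Places the fifteen receivers R1--R15 on the vertical axis through the
#' gap center. R1 sits on the top surface. Even receivers (R2, R4, ...,
#' R14) sit at the mid-depth of each of the seven layers the axis crosses
#' (skin, fat, muscle, gap, muscle, fat, skin; the gap spans the
#' cortical--marrow--cortical band). Odd receivers from R3 on sit one grid
#' cell on the shallow side of each internal interface, and R15 one cell
#' above the bottom surface. The lower muscle--fat interface receiver is
#' R11 (the only assignment consistent with fifteen receivers).
#'
#' @param stack a `layer_stack` (default [default_layer_stack()]).
#' @param dx grid step in mm used for the "one cell above" offsets.
#' @return data frame: `label`, `depth_mm`, `role`
#'   (`surface`/`mid-layer`/`interface`), `layer` (tissue at the axis).
#' @export
place_receivers <- function(stack = default_layer_stack(), dx = 0.01) {
  cum <- cumsum(stack$thickness_mm)
  total <- cum[length(cum)]
  # axis layers: merge the cortical/marrow/cortical band into one "gap" span
  icort <- which(stack$tissue == "cortical bone")
  if (length(icort) == 2) {
    top <- c(0, cum)[icort[1]]
    bot <- cum[icort[2]]
    ax_bounds <- c(0, cum[seq_len(icort[1] - 1)], bot,
                   cum[seq(icort[2] + 1, length(cum))])
    ax_tissue <- c(stack$tissue[seq_len(icort[1] - 1)], "gap",
                   stack$tissue[seq(icort[2] + 1, nrow(stack))])
  } else {
    ax_bounds <- c(0, cum)
    ax_tissue <- stack$tissue
  }
  nlay <- length(ax_tissue)
  mids <- (ax_bounds[-1] + ax_bounds[-(nlay + 1)]) / 2
  internal <- ax_bounds[2:nlay]           # internal interfaces
  depth <- numeric(2 * nlay + 1)
  role <- character(2 * nlay + 1)
  layer <- character(2 * nlay + 1)
  depth[1] <- 0; role[1] <- "surface"; layer[1] <- ax_tissue[1]
  for (k in seq_len(nlay)) {
    depth[2 * k] <- mids[k]; role[2 * k] <- "mid-layer"; layer[2 * k] <- ax_tissue[k]
    d_int <- if (k < nlay) internal[k] else total
    depth[2 * k + 1] <- d_int - dx
    role[2 * k + 1] <- "interface"
    layer[2 * k + 1] <- ax_tissue[k]
  }
  data.frame(label = paste0("R", seq_along(depth)), depth_mm = depth,
             role = role, layer = layer, stringsAsFactors = FALSE)
}

#' Rasterize the layered fracture model onto a regular grid
#'
#' Builds the 2D material-index map: horizontal layers from the stack,
#' with the cortical plates interrupted over a centered lateral span of
#' `gap_width` mm (the fracture gap), filled with `gap_fill`. A cell at
#' row i, column j covers the half-open square
#' `[i dx, (i+1) dx) x [j dx, (j+1) dx)`; a cell is inside the gap iff its
#' center's lateral offset from the mid-line satisfies
#' `|x - width/2| < gap_width/2`. Layer boundaries that do not fall on a
#' grid line snap to the nearest row (with a warning).
#'
#' @param stack a `layer_stack`.
#' @param dx grid step, mm (default 0.01).
#' @param width lateral extent, mm (default 16: a centered 10-mm source
#'   plus >= 3-mm margins).
#' @param gap_width fracture gap width, mm; 0 gives the intact-bone
#'   control model.
#' @param gap_fill tissue occupying the interrupted cortical cells
#'   (default `"bone marrow"`, the medullary channel exposed by the gap).
#' @param materials a `tissue_table` supplying the material list.
#' @param source_mm source aperture length on the top surface, mm.
#' @param plate_tissue the tissue whose plates the gap interrupts
#'   (default `"cortical bone"`).
#' @return A `model_grid`: list with `mat` (integer matrix, rows = depth),
#'   `materials`, `dx`, `width`, `height`, `gap_width`, `gap_fill`,
#'   `source_cols`, `receivers` (with grid rows/cols attached), `stack`.
#' @export
rasterize_model <- function(stack = default_layer_stack(), dx = 0.01,
                            width = 16, gap_width = 4,
                            gap_fill = "bone marrow",
                            materials = tissue_table("reconciled"),
                            source_mm = 10,
                            plate_tissue = "cortical bone") {
  if (gap_width < 0) stop("gap_width must be >= 0")
  if (width < source_mm) stop("width must hold the source aperture")
  nr <- as.integer(ceiling(round(stack_total(stack) / dx, 9)))
  nc <- as.integer(round(width / dx))
  midx <- match(stack$tissue, materials$name)
  if (anyNA(midx)) stop("unknown tissue in stack: ",
                        paste(stack$tissue[is.na(midx)], collapse = ", "))
  bounds <- cumsum(stack$thickness_mm) / dx
  snapped <- floor(bounds + 0.5)   # half-up, so thin layers never collapse
  if (any(abs(bounds - snapped) > 1e-9))
    warning("layer boundary not on a grid line; snapped to nearest row")
  snapped <- as.integer(pmin(snapped, nr))
  mat <- matrix(0L, nr, nc)
  r0 <- 0L
  for (k in seq_len(nrow(stack))) {
    if (snapped[k] > r0) mat[(r0 + 1L):snapped[k], ] <- midx[k]
    r0 <- snapped[k]
  }
  # fracture gap: replace cortical cells within the central lateral span
  if (gap_width > 0) {
    gidx <- match(gap_fill, materials$name)
    if (is.na(gidx)) stop("unknown gap_fill tissue: ", gap_fill)
    xc <- (seq_len(nc) - 0.5) * dx
    in_gap <- abs(xc - width / 2) < gap_width / 2
    cort <- match(plate_tissue, materials$name)
    if (!is.na(cort) && any(in_gap)) {
      cort_rows <- which(apply(mat == cort, 1, any))
      for (i in cort_rows) mat[i, in_gap & mat[i, ] == cort] <- gidx
    }
  }
  xc <- (seq_len(nc) - 0.5) * dx
  source_cols <- which(abs(xc - width / 2) <= source_mm / 2)
  rec <- place_receivers(stack, dx)
  rec$row <- pmin(pmax(1L, as.integer(floor(rec$depth_mm / dx)) + 1L), nr)
  rec$col <- which.min(abs(xc - width / 2))
  structure(list(mat = mat, materials = materials, dx = dx, width = width,
                 height = stack_total(stack), gap_width = gap_width,
                 gap_fill = gap_fill, source_cols = source_cols,
                 receivers = rec, stack = stack),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat(sprintf("<model_grid> %d x %d cells (dx=%g mm, %.2f x %.2f mm), gap %g mm (%s), %d receivers\n",
              nrow(x$mat), ncol(x$mat), x$dx, x$height, x$width,
              x$gap_width, x$gap_fill, nrow(x$receivers)))
  invisible(x)
}

#' Export a material map as a delimited integer matrix
#' @param grid a `model_grid`.
#' @param path output path (TSV, one row per depth row).
#' @export
write_material_map <- function(grid, path) {
  utils::write.table(grid$mat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot the material map (geometry diagram analogue)
#' @param x a `model_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.model_grid <- function(x, ...) {
  nr <- nrow(x$mat)
  graphics::image(x = (seq_len(ncol(x$mat)) - 0.5) * x$dx,
                  y = (seq_len(nr) - 0.5) * x$dx,
                  z = t(x$mat[nr:1, ]), xlab = "lateral, mm",
                  ylab = "depth (flipped), mm", useRaster = TRUE, ...)
  invisible(x)
}
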