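#' Voxel grid geometry
#'
#' A minimal description of the sampling grid every volume in the pipeline
#' lives on: array shape, voxel size in mm, and a world-space origin. All
#' masks and maps in an analysis share one grid (inter-space registration is
#' assumed to have happened upstream); two grids are compatible iff their
#' shapes and voxel sizes match.
#'
#' @param shape integer triple, number of voxels per axis (all >= 1).
#' @param voxel_size_mm positive real triple, voxel edge lengths in mm.
#' @param origin_mm real triple, world coordinate of the first voxel corner.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size_mm = c(1, 1, 1),
                       origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be an integer triple with all entries >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be a positive real triple")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s @ %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Test whether two grids are compatible
#'
#' @param a,b `voxel_grid` objects.
#' @return logical: `TRUE` iff shapes and voxel sizes match.
#' @export
grids_compatible <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}

voxel_volume_mm3 <- function(grid) prod(grid$voxel_size_mm)

#' Scalar volume: one real value per voxel
#'
#' @param values numeric array with dimensions equal to `grid$shape`.
#' @param grid a `voxel_grid`.
#' @return object of class `scalar_volume` with fields `values`, `grid`.
#' @export
scalar_volume <- function(values, grid) {
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("value array dimensions must equal grid shape")
  structure(list(values = values, grid = grid), class = "scalar_volume")
}

#' Label volume: one non-negative integer label per voxel (0 = background)
#'
#' @param labels integer array with dimensions equal to `grid$shape`.
#' @param grid a `voxel_grid`.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, grid) {
  labels <- as.array(labels)
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array dimensions must equal grid shape")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers (0 = background)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, grid = grid), class = "label_volume")
}

#' 4-D time-series volume (BOLD data)
#'
#' @param values numeric 4-D array `(x, y, z, t)`; spatial dims must equal
#'   `grid$shape` and the 4th dimension must be >= 2.
#' @param grid a `voxel_grid`.
#' @param tr_seconds repetition time in seconds (> 0).
#' @return object of class `timeseries_volume` with field `n_timepoints`.
#' @export
timeseries_volume <- function(values, grid, tr_seconds) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), grid$shape))
    stop("values must be a 4-D array whose spatial dimensions equal grid shape")
  if (d[4] < 2L) stop("n_timepoints must be >= 2")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be > 0")
  structure(list(values = values, grid = grid,
                 n_timepoints = as.integer(d[4]),
                 tr_seconds = as.numeric(tr_seconds)),
            class = "timeseries_volume")
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into the matching container. The returned
#' grid reflects the header voxel sizes and array shape.
#'
#' @param path path to a NIfTI-1 file.
#' @param expect_4d logical: `TRUE` to read a 4-D time series, `FALSE`
#'   (default) for a 3-D volume. A mismatch is an error.
#' @param as_labels logical: return a `label_volume` (integer-valued 3-D
#'   image) instead of a `scalar_volume`.
#' @param tr_seconds optional TR override for 4-D reads; by default the
#'   header's 4th pixdim entry is used.
#' @return `scalar_volume`, `label_volume`, or `timeseries_volume`.
#' @export
read_volume <- function(path, expect_4d = FALSE, as_labels = FALSE,
                        tr_seconds = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a valid NIfTI-1 file: ", path))
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))   # drop niftiImage attributes
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) { # degenerate trailing dim
    arr <- arr[, , , 1, drop = TRUE]
    nd <- 3L
  }
  if (expect_4d && nd != 4L) stop("expected 4-D volume, file is 3-D")
  if (!expect_4d && nd == 4L) stop("expected 3-D volume, file is 4-D")
  grid <- voxel_grid(dim(arr)[1:3], voxel_size_mm = abs(pd[1:3]))
  if (expect_4d) {
    tr <- tr_seconds %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1)
    return(timeseries_volume(arr, grid, tr_seconds = tr))
  }
  if (as_labels) label_volume(round(arr), grid) else scalar_volume(arr, grid)
}

#' Write a volume to NIfTI-1
#'
#' @param vol a `scalar_volume`, `label_volume`, or `timeseries_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "timeseries_volume")) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- c(vol$grid$voxel_size_mm, vol$tr_seconds)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (inherits(vol, "label_volume")) {
    img <- RNifti::asNifti(vol$labels)
    RNifti::pixdim(img) <- vol$grid$voxel_size_mm
    RNifti::writeNifti(img, path, datatype = "int32")
  } else if (inherits(vol, "scalar_volume")) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$grid$voxel_size_mm
    RNifti::writeNifti(img, path, datatype = "double")
  } else stop("unsupported volume type")
  invisible(path)
}

#' Block-sum down-sampling of a count volume
#'
#' Aggregates `factor^3` blocks of voxels by summation, conserving the total
#' count; trailing partial blocks sum the voxels present. The output voxel
#' size is the input voxel size times `factor`. Used to reduce streamline
#' arrival maps to a coarse (e.g. 3 mm) target grid.
#'
#' @param v a `scalar_volume` of counts.
#' @param factor positive integer down-sampling factor per axis.
#' @return a `scalar_volume` on the coarse grid.
#' @export
downsample_counts <- function(v, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(v)
  d <- v$grid$shape
  od <- as.integer(ceiling(d / factor))
  bx <- (seq_len(d[1]) - 1L) %/% factor
  by <- (seq_len(d[2]) - 1L) %/% factor
  bz <- (seq_len(d[3]) - 1L) %/% factor
  lin <- 1L + outer(outer(bx, by * od[1], `+`), bz * (od[1] * od[2]), `+`)
  out <- numeric(prod(od))
  agg <- rowsum(as.vector(v$values), group = as.vector(lin))
  out[as.integer(rownames(agg))] <- agg[, 1]
  scalar_volume(array(out, od),
                voxel_grid(od, voxel_size_mm = v$grid$voxel_size_mm * factor,
                           origin_mm = v$grid$origin_mm))
}

# Neighborhood offsets for 6/18/26-connectivity, as an n x 3 integer matrix.
conn_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' In-bounds neighbors of a voxel
#'
#' @param voxel 1-based integer index triple.
#' @param grid a `voxel_grid`.
#' @param connectivity one of 6 (faces), 18 (faces+edges), 26 (full cube).
#' @return integer matrix of neighbor index triples (one row each).
#' @export
neighbors <- function(voxel, grid, connectivity = 6) {
  voxel <- as.integer(voxel)
  if (any(voxel < 1L) || any(voxel > grid$shape))
    stop("voxel index out of grid bounds")
  offs <- conn_offsets(as.integer(connectivity))
  nb <- sweep(offs, 2L, voxel, `+`)
  ok <- nb[, 1] >= 1L & nb[, 1] <= grid$shape[1] &
        nb[, 2] >= 1L & nb[, 2] <= grid$shape[2] &
        nb[, 3] >= 1L & nb[, 3] <= grid$shape[3]
  nb[ok, , drop = FALSE]
}

#' Connected components of a foreground label
#'
#' Labels maximal connected components of `labels == foreground_label` under
#' the chosen neighborhood, breadth-first. Component ids are assigned in
#' order of first (column-major) encounter, so the partition does not depend
#' on traversal details.
#'
#' @param m a `label_volume`.
#' @param foreground_label the label value treated as foreground (may be
#'   absent, yielding zero components).
#' @param connectivity one of 6, 18, 26.
#' @return a list with `labels` (a `label_volume` of component ids, 0
#'   outside), `sizes_voxels` (integer vector per component), and
#'   `sizes_mm3`.
#' @export
connected_components <- function(m, foreground_label = 1L, connectivity = 26) {
  offs <- conn_offsets(as.integer(connectivity))
  d <- m$grid$shape
  fg <- which(m$labels == foreground_label)
  comp <- integer(prod(d))
  nxy <- d[1] * d[2]
  if (length(fg)) {
    state <- integer(prod(d)); state[fg] <- -1L
    ncomp <- 0L
    for (s in fg) {
      if (state[s] != -1L) next
      ncomp <- ncomp + 1L
      state[s] <- ncomp
      frontier <- s
      while (length(frontier)) {
        i0 <- frontier - 1L
        fz <- i0 %/% nxy; r <- i0 %% nxy
        fy <- r %/% d[1]; fx <- r %% d[1]
        cx <- rep(fx, each = nrow(offs)) + offs[, 1]
        cy <- rep(fy, each = nrow(offs)) + offs[, 2]
        cz <- rep(fz, each = nrow(offs)) + offs[, 3]
        ok <- cx >= 0L & cx < d[1] & cy >= 0L & cy < d[2] & cz >= 0L & cz < d[3]
        cand <- unique(1L + cx[ok] + cy[ok] * d[1] + cz[ok] * nxy)
        cand <- cand[state[cand] == -1L]
        state[cand] <- ncomp
        frontier <- cand
      }
    }
    comp <- pmax(state, 0L)
  }
  sizes <- if (any(comp > 0L)) tabulate(comp) else integer(0)
  list(labels = label_volume(array(comp, d), m$grid),
       sizes_voxels = sizes,
       sizes_mm3 = sizes * voxel_volume_mm3(m$grid))
}

# linear index <-> triple helpers (1-based, column-major)
lin_index <- function(ix, iy, iz, d) ix + (iy - 1L) * d[1] + (iz - 1L) * d[1] * d[2]

lin_to_triple <- function(lin, d) {
  i0 <- lin - 1L
  nxy <- d[1] * d[2]
  cbind(i0 %% d[1] + 1L, (i0 %% nxy) %/% d[1] + 1L, i0 %/% nxy + 1L)
}
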