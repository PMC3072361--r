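# Hexagonal lattice geometry. Axial coordinates (col, row), both 0-based,
# 0 <= col < width, 0 <= row < height. Cartesian embedding with unit
# center-to-center spacing: x = col + row/2, y = row * sqrt(3)/2. The six
# neighbor offsets are listed in cyclic order so consecutive offsets are
# themselves adjacent. Boundaries are non-periodic: out-of-field space is
# treated as matrix.

HEX_DC <- c(1L, 0L, -1L, -1L, 0L, 1L)
HEX_DR <- c(0L, 1L, 1L, 0L, -1L, -1L)

#' Cartesian embedding of hexagonal lattice sites
#'
#' @param col,row 0-based axial coordinates (vectorized).
#' @return data.frame with columns `x`, `y` (unit center-to-center distance).
#' @export
hex_xy <- function(col, row) {
  data.frame(x = col + row / 2, y = row * sqrt(3) / 2)
}

#' In-field hexagonal neighbors of a site
#'
#' Neighbors are returned in a fixed cyclic order; sites on the field
#' boundary have fewer than six.
#'
#' @param col,row 0-based site coordinates.
#' @param width,height lattice dimensions.
#' @return data.frame with columns `col`, `row`.
#' @export
hex_neighbors <- function(col, row, width = 100, height = 100) {
  if (length(col) != 1 || length(row) != 1)
    stop("hex_neighbors() takes a single site")
  if (col < 0 || col >= width || row < 0 || row >= height)
    stop("site (", col, ",", row, ") is outside the ", width, "x", height,
         " field")
  nc <- col + HEX_DC
  nr <- row + HEX_DR
  keep <- nc >= 0 & nc < width & nr >= 0 & nr < height
  data.frame(col = nc[keep], row = nr[keep])
}

#' Hexagonal (axial) lattice distance between sites
#' @param c1,r1,c2,r2 axial coordinates (vectorized).
#' @return integer distances.
#' @export
hex_distance <- function(c1, r1, c2, r2) {
  dc <- c1 - c2
  dr <- r1 - r2
  (abs(dc) + abs(dr) + abs(dc + dr)) / 2
}

empty_objects <- function() {
  data.frame(id = integer(), kind = integer(), state = integer(),
             dying = logical(), alive = logical(), A = integer(),
             TA = numeric(), P = integer(), TP = numeric(),
             cycle_counter = numeric(), polar_counter = numeric(),
             polar_started = logical(), shift_counter = numeric(),
             shift_started = logical(), mb_x = numeric(), mb_y = numeric(),
             has_midbody = logical(), death_start = integer())
}

#' Create an empty (all-matrix) simulation state
#'
#' @param width,height lattice dimensions.
#' @return a simulation state: list with `width`, `height`, `owner` (a
#'   width x height integer matrix of object ids, 0 = extracellular matrix),
#'   `objects` (one row per object), `cycle`, `first_division_done`.
#' @export
empty_state <- function(width = 100, height = 100) {
  list(width = as.integer(width), height = as.integer(height),
       owner = matrix(0L, nrow = width, ncol = height),
       objects = empty_objects(), cycle = 0L, first_division_done = FALSE)
}

state_codes <- c(unpolarized = 0L, polarized = 1L, stabilized = 2L)
kind_codes <- c(cell = 0L, lumen = 1L)

#' Add a cell or lumen occupying the given sites
#'
#' Used to build initial conditions and test fixtures. Area and perimeter
#' are counted from the lattice after placement.
#'
#' @param state a simulation state.
#' @param sites data.frame with columns `col`, `row` (0-based); must be
#'   currently matrix.
#' @param kind `"cell"` or `"lumen"`.
#' @param cell_state `"unpolarized"`, `"polarized"` or `"stabilized"`.
#' @param TA,TP target area/perimeter; default current area and a relaxed
#'   perimeter target of 0 (callers normally set these).
#' @param dying logical.
#' @param cycle_counter,polar_counter,shift_counter counters (cycles).
#' @param polar_started,shift_started whether the counters are running.
#' @param midbody optional c(x, y) in embedded coordinates.
#' @return the state with one more object; the new id is
#'   `attr(, "last_id")`.
#' @export
add_object <- function(state, sites, kind = "cell",
                       cell_state = "unpolarized", TA = NULL, TP = 0,
                       dying = FALSE, cycle_counter = 0,
                       polar_counter = 0, polar_started = FALSE,
                       shift_counter = 0, shift_started = FALSE,
                       midbody = NULL) {
  stopifnot(nrow(sites) >= 1, all(c("col", "row") %in% names(sites)))
  id <- nrow(state$objects) + 1L
  ix <- cbind(sites$col + 1L, sites$row + 1L)
  if (any(sites$col < 0 | sites$col >= state$width |
          sites$row < 0 | sites$row >= state$height))
    stop("sites outside the field")
  if (any(state$owner[ix] != 0L))
    stop("sites already occupied")
  state$owner[ix] <- id
  A <- nrow(sites)
  if (is.null(TA)) TA <- A
  row <- data.frame(
    id = id, kind = kind_codes[[kind]],
    state = state_codes[[cell_state]], dying = dying, alive = TRUE,
    A = A, TA = TA, P = 0L, TP = TP,
    cycle_counter = cycle_counter, polar_counter = polar_counter,
    polar_started = polar_started, shift_counter = shift_counter,
    shift_started = shift_started,
    mb_x = if (is.null(midbody)) 0 else midbody[1],
    mb_y = if (is.null(midbody)) 0 else midbody[2],
    has_midbody = !is.null(midbody), death_start = 0L)
  state$objects <- rbind(state$objects, row)
  state$objects$P[id] <- boundary_edge_counts(state, id)$total_edges
  state
}

owner_at <- function(state, col, row) {
  out <- integer(length(col))
  inf <- col >= 0 & col < state$width & row >= 0 & row < state$height
  out[inf] <- state$owner[cbind(col[inf] + 1L, row[inf] + 1L)]
  out
}

#' Sites of an object
#' @param state a simulation state.
#' @param id object id.
#' @return data.frame with columns `col`, `row` (0-based).
#' @export
object_sites <- function(state, id) {
  w <- which(state$owner == id, arr.ind = TRUE)
  if (nrow(w) == 0) stop("object ", id, " owns no sites")
  data.frame(col = w[, 1] - 1L, row = w[, 2] - 1L)
}

#' Boundary edge counts of an object, classified by the outside occupant
#'
#' An edge is an adjacent site pair with one site inside the object and one
#' outside; out-of-field space counts as matrix. The half-counts `M` and `L`
#' (matrix and lumen contact) are the quantities used by the wedge-area and
#' stabilization rules.
#'
#' @param state a simulation state.
#' @param object_id object id present in the lattice.
#' @return list with `matrix_edges`, `lumen_edges`, `cell_edges`,
#'   `total_edges`, and the half-counts `M`, `L`.
#' @export
boundary_edge_counts <- function(state, object_id) {
  if (!object_id %in% state$objects$id || !state$objects$alive[object_id])
    stop("unknown or dead object id ", object_id)
  s <- object_sites(state, object_id)
  lum_ids <- state$objects$id[state$objects$kind == 1L]
  mat <- 0L; lum <- 0L; cel <- 0L
  for (k in 1:6) {
    w <- owner_at(state, s$col + HEX_DC[k], s$row + HEX_DR[k])
    w <- w[w != object_id]
    mat <- mat + sum(w == 0L)
    lum <- lum + sum(w %in% lum_ids)
    cel <- cel + sum(w != 0L & !(w %in% lum_ids))
  }
  list(matrix_edges = mat, lumen_edges = lum, cell_edges = cel,
       total_edges = mat + lum + cel, M = mat / 2, L = lum / 2)
}

#' Centroid of an object in embedded Cartesian coordinates
#' @param state a simulation state.
#' @param object_id object id with at least one site.
#' @return numeric c(x, y).
#' @export
centroid <- function(state, object_id) {
  s <- object_sites(state, object_id)
  xy <- hex_xy(s$col, s$row)
  c(x = mean(xy$x), y = mean(xy$y))
}

#' Export / import a lattice snapshot as plain text
#'
#' The text format is: a header line `width height cycle`, then `height`
#' lines of `width` integers (row 0 first, i.e. top-to-bottom), then one
#' line per object: `id kind state dying`. Only fields needed to recompute
#' morphometrics are kept.
#'
#' @param state a simulation state.
#' @param file path.
#' @export
snapshot_write <- function(state, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(state$width, state$height, state$cycle), con)
  for (r in seq_len(state$height)) {
    writeLines(paste(state$owner[, r], collapse = " "), con)
  }
  o <- state$objects
  writeLines(paste(o$id, o$kind, o$state, as.integer(o$dying),
                   as.integer(o$alive)), con)
  invisible(file)
}

#' @rdname snapshot_write
#' @return `snapshot_read()` returns a simulation state with areas and
#'   perimeters recounted from the grid (targets and counters are not part
#'   of the snapshot and are zeroed).
#' @export
snapshot_read <- function(file) {
  lines <- readLines(file)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  width <- hdr[1]; height <- hdr[2]; cyc <- hdr[3]
  owner <- matrix(0L, width, height)
  for (r in seq_len(height)) {
    owner[, r] <- as.integer(strsplit(lines[1 + r], " ")[[1]])
  }
  state <- empty_state(width, height)
  state$owner <- owner
  state$cycle <- cyc
  obj_lines <- lines[-seq_len(1 + height)]
  obj_lines <- obj_lines[nzchar(obj_lines)]
  if (length(obj_lines)) {
    m <- do.call(rbind, lapply(strsplit(obj_lines, " "), as.integer))
    o <- empty_objects()
    for (i in seq_len(nrow(m))) {
      id <- m[i, 1]
      A <- sum(owner == id)
      o <- rbind(o, data.frame(
        id = id, kind = m[i, 2], state = m[i, 3], dying = m[i, 4] == 1L,
        alive = m[i, 5] == 1L, A = A, TA = A, P = 0L, TP = 0,
        cycle_counter = 0, polar_counter = 0, polar_started = FALSE,
        shift_counter = 0, shift_started = FALSE, mb_x = 0, mb_y = 0,
        has_midbody = FALSE, death_start = 0L))
    }
    state$objects <- o
    for (id in o$id[o$alive & o$A > 0]) {
      state$objects$P[id] <- boundary_edge_counts(state, id)$total_edges
    }
  }
  state
}

#' Render a lattice snapshot to PNG
#'
#' State coloring: unpolarized cells green, polarized gray, stabilized
#' orange, dying dark red, lumen blue, matrix black; cell-cell and
#' cell-matrix border sites are overdrawn red and cell-lumen border sites
#' yellow. Requires the `png` package.
#'
#' @param state a simulation state.
#' @param file output path.
#' @param pixels_per_site square pixel block per lattice site.
#' @export
snapshot_png <- function(state, file, pixels_per_site = 4) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("snapshot_png() requires the 'png' package")
  W <- state$width; H <- state$height
  o <- state$objects
  cols <- matrix("#000000", W, H)
  for (i in seq_len(nrow(o))) {
    if (!o$alive[i]) next
    col <- if (o$kind[i] == 1L) "#3060D0"
           else if (o$dying[i]) "#702020"
           else c("#30A030", "#909090", "#E08020")[o$state[i] + 1]
    cols[state$owner == o$id[i]] <- col
  }
  lum_ids <- o$id[o$kind == 1L]
  for (r in 0:(H - 1)) {
    for (cc in 0:(W - 1)) {
      a <- state$owner[cc + 1, r + 1]
      if (a == 0L || a %in% lum_ids) next
      w <- owner_at(state, cc + HEX_DC, r + HEX_DR)
      if (any(w %in% lum_ids)) cols[cc + 1, r + 1] <- "#E0E030"
      else if (any(w != a)) cols[cc + 1, r + 1] <- "#C03030"
    }
  }
  px <- pixels_per_site
  img <- array(0, dim = c(H * px, W * px, 3))
  rgbm <- grDevices::col2rgb(cols) / 255
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      i <- (cc - 1) * H + r
      img[(r - 1) * px + seq_len(px), (cc - 1) * px + seq_len(px), 1] <- rgbm[1, i]
      img[(r - 1) * px + seq_len(px), (cc - 1) * px + seq_len(px), 2] <- rgbm[2, i]
      img[(r - 1) * px + seq_len(px), (cc - 1) * px + seq_len(px), 3] <- rgbm[3, i]
    }
  }
  png::writePNG(img, file)
  invisible(file)
}
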