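# Fixture builders. All lattices are constructed in code; coordinates are
# 0-based axial (col, row).

# a compact hexagonal disc of n sites centered at (c0, r0)
hex_disc_sites <- function(n, c0, r0, rad = 8) {
  cols <- rep((c0 - rad):(c0 + rad), times = 2 * rad + 1)
  rows <- rep((r0 - rad):(r0 + rad), each = 2 * rad + 1)
  d <- hex_distance(cols, rows, c0, r0)
  ord <- order(d, cols, rows)
  data.frame(col = cols[ord][seq_len(n)], row = rows[ord][seq_len(n)])
}

# two adjacent multi-site cells in open matrix
two_cell_state <- function(width = 20, height = 20, n1 = 7, n2 = 7) {
  st <- empty_state(width, height)
  s1 <- hex_disc_sites(n1, 7, 10)
  st <- add_object(st, s1, kind = "cell", TA = n1 + 3,
                   TP = target_perimeter(n1))
  s2 <- hex_disc_sites(n2 + 10, 11, 10)
  taken <- paste(s1$col, s1$row)
  s2 <- s2[!paste(s2$col, s2$row) %in% taken, ][seq_len(n2), ]
  st <- add_object(st, s2, kind = "cell", TA = n2,
                   TP = target_perimeter(n2))
  st$cycle <- 10L               # past the forced first-division cycle
  st$first_division_done <- TRUE
  st
}

# a monolayer ring cyst: central lumen (radius lumen_r) surrounded by
# n_cells wedge cells spanning radii (lumen_r+1)..outer_r
ring_state <- function(width = 40, lumen_r = 2, outer_r = 7, n_cells = 6,
                       cell_state = "polarized", lumen_TA = NULL,
                       midbody_center = TRUE) {
  st <- empty_state(width, width)
  ctr <- width %/% 2
  cols <- rep(0:(width - 1), width)
  rows <- rep(0:(width - 1), each = width)
  d <- hex_distance(cols, rows, ctr, ctr)
  xy <- hex_xy(cols, rows)
  cxy <- hex_xy(ctr, ctr)
  ang <- atan2(xy$y - cxy$y, xy$x - cxy$x)
  lum <- d <= lumen_r
  st <- add_object(st, data.frame(col = cols[lum], row = rows[lum]),
                   kind = "lumen", TA = if (is.null(lumen_TA)) sum(lum) else lumen_TA)
  sector <- floor((ang + pi) / (2 * pi) * n_cells)
  sector[sector == n_cells] <- n_cells - 1
  for (k in 0:(n_cells - 1)) {
    sel <- d > lumen_r & d <= outer_r & sector == k
    st <- add_object(st, data.frame(col = cols[sel], row = rows[sel]),
                     kind = "cell", cell_state = cell_state, TA = sum(sel),
                     TP = target_perimeter(sum(sel)),
                     midbody = if (midbody_center) unlist(cxy) else NULL)
  }
  st$cycle <- 10L               # past the forced first-division cycle
  st$first_division_done <- TRUE
  st
}

# rebuild a state's object table from an owner matrix (kinds: 0 cell,
# 1 lumen per object id in sort order)
state_from_owner <- function(owner, kinds, states = NULL, dying = NULL) {
  st <- empty_state(nrow(owner), ncol(owner))
  ids <- sort(setdiff(unique(as.vector(owner)), 0L))
  stopifnot(length(kinds) == length(ids))
  for (i in seq_along(ids)) {
    w <- which(owner == ids[i], arr.ind = TRUE)
    st <- add_object(st, data.frame(col = w[, 1] - 1L, row = w[, 2] - 1L),
                     kind = c("cell", "lumen")[kinds[i] + 1],
                     cell_state = if (is.null(states)) "polarized"
                                  else states[i],
                     TA = nrow(w), TP = target_perimeter(max(1, nrow(w))),
                     dying = if (is.null(dying)) FALSE else dying[i])
  }
  st
}

# a random toy lattice: partition a small grid among matrix, cells and
# lumens by nearest-seed assignment (objects may be ragged but are valid
# partitions)
random_toy_state <- function(width = 6, height = 6, n_obj = 3,
                             p_lumen = 0.3) {
  owner <- matrix(0L, width, height)
  sc <- sample.int(width, n_obj, replace = TRUE) - 1L
  sr <- sample.int(height, n_obj, replace = TRUE) - 1L
  for (c in 0:(width - 1)) {
    for (r in 0:(height - 1)) {
      d <- hex_distance(c, r, sc, sr)
      if (min(d) <= 1) owner[c + 1, r + 1] <- which.min(d)
    }
  }
  ids <- sort(setdiff(unique(as.vector(owner)), 0L))
  if (!length(ids)) {
    owner[3, 3] <- 1L
    ids <- 1L
  }
  # compact ids
  own2 <- owner
  for (i in seq_along(ids)) own2[owner == ids[i]] <- i
  kinds <- as.integer(stats::runif(length(ids)) < p_lumen)
  state_from_owner(own2, kinds)
}
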