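# Independent oracles used to validate the engine. These deliberately avoid
# the engine's code paths: energies are recomputed from scratch off the
# lattice, tight junctions are enumerated globally, and SM1 is counted by
# brute force.

oracle_adh_type <- function(objects, id) {
  if (id == 0) return(1L)                       # matrix
  i <- match(id, objects$id)
  if (objects$kind[i] == 1L) return(6L)         # lumen
  if (objects$dying[i]) return(5L)              # dying
  objects$state[i] + 2L                         # unpol/pol/stab -> 2/3/4
}

# total Hamiltonian: area + perimeter constraints (recounted from the grid)
# plus per-edge adhesion, each boundary edge (including edges to
# out-of-field space, treated as matrix) counted once
oracle_total_energy <- function(state, params) {
  o <- state$objects
  W <- state$width; H <- state$height
  E <- 0
  for (i in seq_len(nrow(o))) {
    if (!o$alive[i]) next
    id <- o$id[i]
    w <- which(state$owner == id, arr.ind = TRUE)
    A <- nrow(w)
    lam <- if (o$kind[i] == 1L) params$lambda_lumen else params$lambda_area
    E <- E + lam * (o$TA[i] - A)^2
    if (o$kind[i] == 0L) {
      P <- 0L
      for (k in 1:6) {
        nb <- owner_vec(state, w[, 1] - 1L + HEX_DC_T[k],
                        w[, 2] - 1L + HEX_DR_T[k])
        P <- P + sum(nb != id)
      }
      E <- E + params$lambda_perim * (o$TP[i] - P)^2
    }
  }
  J <- params$adhesion
  types <- vapply(c(0L, o$id), function(id) oracle_adh_type(o, id), 1L)
  # half-edge sum over all sites and all 6 directions counts interior edges
  # twice and field-boundary edges once; sum J over ordered pairs and halve
  # interior, so instead enumerate each edge once by direction subset
  for (c in 0:(W - 1)) {
    for (r in 0:(H - 1)) {
      a <- state$owner[c + 1, r + 1]
      for (k in 1:6) {
        nc <- c + HEX_DC_T[k]; nr <- r + HEX_DR_T[k]
        infield <- nc >= 0 && nc < W && nr >= 0 && nr < H
        b <- if (infield) state$owner[nc + 1, nr + 1] else 0L
        if (infield && k > 3) next   # interior edges once (3 of 6 dirs)
        if (!infield && a == 0L) next
        if (a == b) next
        E <- E + J[types[a + 1], types[b + 1]]
      }
    }
  }
  E
}

HEX_DC_T <- c(1L, 0L, -1L, -1L, 0L, 1L)
HEX_DR_T <- c(0L, 1L, 1L, 0L, -1L, -1L)

owner_vec <- function(state, col, row) {
  out <- integer(length(col))
  inf <- col >= 0 & col < state$width & row >= 0 & row < state$height
  out[inf] <- state$owner[cbind(col[inf] + 1L, row[inf] + 1L)]
  out
}

# oracle delta-G: copy the state, apply the flip, recompute the full
# Hamiltonian (no constraint penalties; the test accounts for those)
oracle_delta_g <- function(state, params, col, row, candidate) {
  before <- oracle_total_energy(state, params)
  st2 <- state
  old <- st2$owner[col + 1, row + 1]
  st2$owner[col + 1, row + 1] <- candidate
  i <- match(old, st2$objects$id)
  if (!is.na(i)) {
    n_left <- sum(st2$owner == old)
    if (n_left == 0) st2$objects$alive[i] <- FALSE
  }
  oracle_total_energy(st2, params) - before
}

# global tight-junction triangle count: every triangle of three mutually
# adjacent in-field sites with exactly one lumen corner and two corners in
# distinct cells
oracle_tj_count <- function(state) {
  o <- state$objects
  lum_ids <- o$id[o$kind == 1L]
  cell_ids <- o$id[o$kind == 0L]
  W <- state$width; H <- state$height
  cnt <- 0L
  for (c in 0:(W - 1)) {
    for (r in 0:(H - 1)) {
      for (k in 1:6) {
        k2 <- k %% 6 + 1
        c1 <- c + HEX_DC_T[k]; r1 <- r + HEX_DR_T[k]
        c2 <- c + HEX_DC_T[k2]; r2 <- r + HEX_DR_T[k2]
        if (c1 < 0 || c1 >= W || r1 < 0 || r1 >= H) next
        if (c2 < 0 || c2 >= W || r2 < 0 || r2 >= H) next
        s0 <- c + r * W; s1 <- c1 + r1 * W; s2 <- c2 + r2 * W
        if (s0 > s1 || s0 > s2) next   # count each triangle once
        ws <- c(state$owner[c + 1, r + 1], state$owner[c1 + 1, r1 + 1],
                state$owner[c2 + 1, r2 + 1])
        if (any(ws == 0L)) next
        nl <- sum(ws %in% lum_ids)
        cl <- ws[ws %in% cell_ids]
        if (nl == 1L && length(cl) == 2L && cl[1] != cl[2]) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# brute-force SM1: count simulated values inside the closed +/-25% window
oracle_sm1_fraction <- function(values, ref_mean) {
  hits <- 0L
  for (v in values) {
    if (v >= 0.75 * ref_mean && v <= 1.25 * ref_mean) hits <- hits + 1L
  }
  hits / length(values)
}
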