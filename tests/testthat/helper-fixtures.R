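# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small default-style phantom (anisotropic, ~40 nuclei) + features + model
small_phantom <- function() fixture("small_phantom", function() {
  generate_phantom(phantom_spec(extent = c(20L, 64L, 64L), seed = 11L))
})

small_features <- function() fixture("small_features", function() {
  suppressWarnings(compute_features(small_phantom()$volume))
})

small_model <- function() fixture("small_model", function() {
  ann <- annotations_from_truth(small_phantom()$truth, n_nuclei = 15, seed = 4L)
  train_classifier(small_features(), ann, n_trees = 50, seed = 9L)
})

# binary mask with axis-aligned ellipsoids/spheres rendered in physical units
sphere_mask <- function(dim, spacing, centers, radii) {
  m <- array(FALSE, dim)
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]; r <- radii[k]
    rng <- lapply(1:3, function(a) {
      i0 <- max(0L, ceiling((ctr[a] - r) / spacing[a]))
      i1 <- min(dim[a] - 1L, floor((ctr[a] + r) / spacing[a]))
      if (i0 > i1) integer(0) else i0:i1
    })
    if (!all(lengths(rng) > 0L)) next
    qz <- ((rng[[1]] * spacing[1] - ctr[1]) / r)^2
    qy <- ((rng[[2]] * spacing[2] - ctr[2]) / r)^2
    qx <- ((rng[[3]] * spacing[3] - ctr[3]) / r)^2
    q <- outer(outer(qz, qy, `+`), qx, `+`)
    m[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] <-
      m[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] | (q <= 1)
  }
  m
}

# independent flood-fill component-count oracle (pure R, queue-based)
flood_fill_components <- function(mask, connectivity) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  lab <- array(0L, d)
  k <- 0L
  for (s in which(mask & lab == 0L)) {
    if (lab[s] != 0L) next
    k <- k + 1L
    queue <- s
    lab[s] <- k
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i0 <- cur - 1L
      z <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; x <- i0 %/% (d[1] * d[2])
      nb <- cbind(z + off[, 1], y + off[, 2], x + off[, 3])
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
            nb[, 3] >= 0 & nb[, 3] < d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + 1L + d[1] * nb[, 2] + d[1] * d[2] * nb[, 3]
      new <- lin[mask[lin] & lab[lin] == 0L]
      lab[new] <- k
      queue <- c(queue, new)
    }
  }
  k
}

# brute-force maximum one-to-one matching within tolerance (tiny scenes)
optimal_match_count <- function(pc, tc, tol) {
  np <- nrow(pc); nt <- nrow(tc)
  if (np == 0 || nt == 0) return(0L)
  d <- sqrt(outer(rowSums(pc^2), rowSums(tc^2), `+`) - 2 * pc %*% t(tc))
  ok <- d <= tol
  best <- 0L
  rec <- function(p, used_t, count) {
    if (count + (np - p + 1) <= best) return()
    if (p > np) { best <<- max(best, count); return() }
    rec(p + 1L, used_t, count) # leave p unmatched
    for (t in which(ok[p, ] & !used_t)) {
      used_t[t] <- TRUE
      rec(p + 1L, used_t, count + 1L)
      used_t[t] <- FALSE
    }
  }
  rec(1L, logical(nt), 0L)
  best
}
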