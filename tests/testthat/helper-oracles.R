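# Independent oracles used across the suite. These deliberately use naive
# formulations (explicit image enumeration, per-candidate BFS, Monte-Carlo
# surface integration) so they share no code path with the implementation.

# minimum-image distance by enumerating all 27 periodic images
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((a - (b + c(i, j, k) * box))^2))
    if (d < best) best <- d
  }
  best
}

# O(N^2) contact counts with brute-force periodic distances
oracle_contact_counts <- function(traj, frame, ion_role, site_role, thr) {
  ii <- which(traj$atoms$role == ion_role)
  is <- which(traj$atoms$role == site_role)
  box <- traj$box[frame, ]
  per_ion <- integer(length(ii)); per_site <- integer(length(is))
  for (a in seq_along(ii)) for (b in seq_along(is)) {
    d <- brute_min_image(traj$coords[ii[a], , frame],
                         traj$coords[is[b], , frame], box)
    if (d < thr) {
      per_ion[a] <- per_ion[a] + 1L
      per_site[b] <- per_site[b] + 1L
    }
  }
  list(per_ion = per_ion, per_site = per_site)
}

# Prominence-based maxima counting by per-candidate breadth-first search:
# a plateau-free formulation independent of the implementation's
# sorted-flood marking.
oracle_find_maxima <- function(m, tol) {
  H <- nrow(m); W <- ncol(m)
  dyx <- cbind(dy = rep(-1:1, 3), dx = rep(-1:1, each = 3))
  dyx <- dyx[!(dyx[, 1] == 0 & dyx[, 2] == 0), ]
  nb <- function(y, x) {
    ys <- y + dyx[, 1]; xs <- x + dyx[, 2]
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    cbind(ys[ok], xs[ok])
  }
  # candidate plateaus: equal-value connected sets, no higher neighbour,
  # at least one lower neighbour; identified by their smallest index
  seen <- matrix(FALSE, H, W)
  cands <- list()
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (seen[y, x]) next
    v <- m[y, x]
    comp <- matrix(c(y, x), 1); seen[y, x] <- TRUE; q <- comp
    hi <- FALSE; lo <- FALSE
    while (nrow(q)) {
      cur <- q[1, ]; q <- q[-1, , drop = FALSE]
      nbs <- nb(cur[1], cur[2])
      for (r in seq_len(nrow(nbs))) {
        n <- nbs[r, ]
        if (m[n[1], n[2]] > v) hi <- TRUE
        else if (m[n[1], n[2]] < v) lo <- TRUE
        else if (!seen[n[1], n[2]]) {
          seen[n[1], n[2]] <- TRUE
          comp <- rbind(comp, n); q <- rbind(q, n)
        }
      }
    }
    if (!hi && lo) cands[[length(cands) + 1]] <- list(cells = comp, value = v)
  }
  if (!length(cands)) return(0L)
  vals <- vapply(cands, `[[`, numeric(1), "value")
  accepted <- 0L
  accepted_cells <- list()
  for (k in order(-vals)) {
    cand <- cands[[k]]
    v <- cand$value
    start <- cand$cells[1, ]
    # BFS over strictly-above-(v - tol) region
    reach <- matrix(FALSE, H, W)
    reach[start[1], start[2]] <- TRUE
    q <- matrix(start, 1)
    higher <- FALSE
    while (nrow(q) && !higher) {
      cur <- q[1, ]; q <- q[-1, , drop = FALSE]
      nbs <- nb(cur[1], cur[2])
      for (r in seq_len(nrow(nbs))) {
        n <- nbs[r, ]
        if (reach[n[1], n[2]]) next
        if (m[n[1], n[2]] > v) { higher <- TRUE; break }
        if (m[n[1], n[2]] > v - tol) {
          reach[n[1], n[2]] <- TRUE
          q <- rbind(q, n)
        }
      }
    }
    if (higher) next
    # reject if an already accepted equal-valued maximum lies in the region
    clash <- FALSE
    for (ac in accepted_cells) {
      if (abs(ac$value - v) < .Machine$double.eps * 4 &&
          reach[ac$cells[1, 1], ac$cells[1, 2]]) { clash <- TRUE; break }
    }
    if (!clash) {
      accepted <- accepted + 1L
      accepted_cells[[length(accepted_cells) + 1]] <- cand
    }
  }
  accepted
}

# Monte-Carlo accessible-surface oracle for a two-sphere configuration:
# random directions on sphere 1's extended surface, rejected when inside
# sphere 2's extended surface (and vice versa).
oracle_two_sphere_sasa <- function(x1, r1, x2, r2, probe, n = 200000L,
                                   seed = 42L) {
  set.seed(seed)
  area_one <- function(xa, ra, xb, rb) {
    u <- matrix(rnorm(n * 3), n, 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * (ra + probe), 2, xa, `+`)
    acc <- rowSums(sweep(pts, 2, xb, `-`)^2) > (rb + probe)^2
    mean(acc) * 4 * pi * (ra + probe)^2
  }
  area_one(x1, r1, x2, r2) + area_one(x2, r2, x1, r1)
}

# small helper: trajectory from a bare coordinate matrix of generic atoms
atoms_traj <- function(xyz, elements = rep("C", nrow(xyz)), box = NULL) {
  trajectory(data.frame(atom_id = seq_len(nrow(xyz)),
                        atom_name = elements, residue_name = "UNK",
                        residue_number = seq_len(nrow(xyz)), chain_id = "A",
                        element = elements, role = "other",
                        stringsAsFactors = FALSE),
             xyz, box = box)
}

# sheet image with explicit Gaussian spots at given centres (0-based)
spot_image <- function(W, H, centers, sigma_px, amplitude = 100,
                       background = 0, pixel_size_nm = 40) {
  m <- matrix(background, H, W)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    for (y in seq_len(H)) for (x in seq_len(W)) {
      m[y, x] <- m[y, x] + amplitude *
        exp(-((x - 1 - cx)^2 + (y - 1 - cy)^2) / (2 * sigma_px^2))
    }
  }
  sheet_image(m, pixel_size_nm)
}
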