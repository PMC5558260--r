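# 10-20 site placement and montage construction on voxel phantoms.
# Convention: x left(-)/right(+), y anterior(-)/posterior(+), z up(+),
# all relative to the head (ellipsoid) centre.

shift_array <- function(a, d, fill = 0L) {
  # shift array contents by offset d (length 3); vacated cells get `fill`
  out <- array(fill, dim(a))
  dims <- dim(a)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dims[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- (1 - d[ax]):dims[ax]
      dst[[ax]] <- seq_len(dims[ax] + d[ax])
    }
    if (dims[ax] + d[ax] <= 0 || dims[ax] - d[ax] <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Scalp (or neck) surface voxels
#'
#' Voxels of the given tissue with at least one 6-neighbour that is air or
#' outside the grid.
#' @param phantom a `head_phantom`.
#' @param tissue tissue name(s), default `"scalp"`.
#' @return logical array marking surface voxels.
#' @keywords internal
surface_mask <- function(phantom, tissue = "scalp") {
  lab <- phantom$label
  own <- array(lab %in% TISSUE_CODES[tissue], dim(lab))
  airish <- lab == TISSUE_CODES[["air"]]
  exposed <- array(FALSE, dim(lab))
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    exposed <- exposed | shift_array(airish, d, fill = TRUE)
  own & exposed
}

voxel_centers_mm <- function(idx_mat, h) (idx_mat - 0.5) * h

ellipsoid_normal <- function(p_mm, center, radii) {
  n <- (p_mm - center) / radii^2
  n / sqrt(sum(n^2))
}

#' Place 10-20 stimulation sites on a phantom scalp
#'
#' Sites are found by angular parametrization of the scalp: a unit direction
#' from the head centre is cast outward and the outermost scalp voxel along
#' it is taken. C3/C4 sit at 40% of the vertex-to-ear arc (36 degrees
#' lateral); F3/F4 add a 20% anterior arc (18 degrees toward the face). The
#' non-cephalic return site is the centre of the neck-stub base on the
#' domain floor.
#'
#' @param phantom a `head_phantom`.
#' @return named list of `electrode_site` objects (`C3`, `C4`, `F3`, `F4`,
#'   `neck`), each with `label`, `voxel` (grid index), `pos_mm`, `normal`.
#' @export
place_1020_sites <- function(phantom) {
  h <- phantom$voxel_size_mm
  ctr <- phantom$center
  lab <- phantom$label
  dims <- dim(lab)
  th_lat <- 0.4 * pi / 2        # 36 deg toward the ear
  th_ap <- 0.2 * pi / 2         # 18 deg toward the face (anterior = -y)
  dirs <- list(
    C3 = c(-sin(th_lat), 0, cos(th_lat)),
    C4 = c(sin(th_lat), 0, cos(th_lat)),
    F3 = c(-sin(th_lat), -sin(th_ap),
           sqrt(max(1 - sin(th_lat)^2 - sin(th_ap)^2, 0))),
    F4 = c(sin(th_lat), -sin(th_ap),
           sqrt(max(1 - sin(th_lat)^2 - sin(th_ap)^2, 0))))
  surf <- surface_mask(phantom)
  # snap a ray-cast scalp voxel onto the air-adjacent surface shell
  snap_to_surface <- function(vx) {
    if (surf[vx[1], vx[2], vx[3]]) return(vx)
    for (rad in 1:3) {
      lo <- pmax(vx - rad, 1L); hi <- pmin(vx + rad, dims)
      box <- which(surf[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
                   arr.ind = TRUE)
      if (nrow(box) > 0L) {
        box <- sweep(box, 2, lo - 1L, "+")
        d2 <- rowSums(sweep(box, 2, vx)^2)
        return(unname(box[which.min(d2), ]))
      }
    }
    stop("no scalp-surface voxel near site candidate")
  }
  sites <- lapply(names(dirs), function(nm) {
    u <- dirs[[nm]] / sqrt(sum(dirs[[nm]]^2))
    rmax <- max(phantom$morphology$radii_scalp) + 4 * h
    last_scalp <- NULL
    for (t in seq(0, rmax, by = h / 4)) {
      p <- ctr + t * u
      ijk <- pmin(pmax(ceiling(p / h), 1L), dims)
      code <- lab[ijk[1], ijk[2], ijk[3]]
      if (code == TISSUE_CODES[["scalp"]]) last_scalp <- ijk
      if (code == TISSUE_CODES[["air"]] && !is.null(last_scalp)) break
    }
    if (is.null(last_scalp))
      stop("surface extraction failed for site ", nm)
    last_scalp <- snap_to_surface(last_scalp)
    p_mm <- voxel_centers_mm(last_scalp, h)
    structure(list(label = nm, voxel = last_scalp, pos_mm = p_mm,
                   normal = ellipsoid_normal(p_mm, ctr,
                                             phantom$morphology$radii_scalp)),
              class = "electrode_site")
  })
  names(sites) <- names(dirs)
  # neck return: centre of the stub base at the domain floor
  base <- which(lab[, , 1] == TISSUE_CODES[["neck"]], arr.ind = TRUE)
  if (nrow(base) == 0L) stop("phantom has no neck-stub base on the floor")
  cidx <- base[which.min((base[, 1] - ctr[1] / h)^2 +
                           (base[, 2] - ctr[2] / h)^2), ]
  nv <- c(unname(cidx[1]), unname(cidx[2]), 1L)
  sites$neck <- structure(list(label = "neck", voxel = nv,
                               pos_mm = voxel_centers_mm(nv, h),
                               normal = c(0, 0, -1)),
                          class = "electrode_site")
  sites
}

#' Geodesic distances along a surface-voxel shell
#'
#' Dijkstra over the 26-connected graph of surface voxels (edge weights =
#' Euclidean centre distances, mm), restricted to a bounding box around the
#' source for economy.
#' @keywords internal
surface_geodesic <- function(phantom, surf, source_voxel, max_mm) {
  h <- phantom$voxel_size_mm
  dims <- dim(surf)
  rad <- ceiling(max_mm * 1.8 / h)
  lo <- pmax(source_voxel - rad, 1L)
  hi <- pmin(source_voxel + rad, dims)
  idx <- which(surf, arr.ind = TRUE)
  keep <- idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
    idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
    idx[, 3] >= lo[3] & idx[, 3] <= hi[3]
  idx <- idx[keep, , drop = FALSE]
  n <- nrow(idx)
  key <- function(m) (m[, 1] - 1) + dims[1] * ((m[, 2] - 1) +
                                                 dims[2] * (m[, 3] - 1))
  keys <- key(idx)
  # vertex ids by key via match on sorted keys
  ord <- order(keys)
  skeys <- keys[ord]
  vid_of <- function(k) {
    pos <- findInterval(k, skeys)
    ok <- pos >= 1L & skeys[pmax(pos, 1L)] == k
    out <- rep(NA_integer_, length(k))
    out[ok] <- ord[pos[ok]]
    out
  }
  ee <- list(); wts <- list(); m <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx < 0 || (dx == 0 && dy < 0) || (dx == 0 && dy == 0 && dz < 0))
      next  # undirected: half the offsets
    nb <- cbind(idx[, 1] + dx, idx[, 2] + dy, idx[, 3] + dz)
    vb <- vid_of(key(nb))
    ok <- !is.na(vb)
    if (!any(ok)) next
    m <- m + 1L
    ee[[m]] <- cbind(which(ok), vb[ok])
    wts[[m]] <- rep(sqrt(sum(c(dx, dy, dz)^2)) * h, sum(ok))
  }
  edges <- do.call(rbind, ee)
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  src <- vid_of(key(matrix(source_voxel, nrow = 1)))
  if (is.na(src)) stop("source voxel is not on the surface")
  d <- as.numeric(igraph::distances(g, v = src,
                                    weights = unlist(wts)))
  list(voxels = idx, dist_mm = d)
}

#' Electrode footprint on the scalp surface
#'
#' Surface voxels within geodesic `radius_mm` of the site centre, together
#' with the corner nodes of their exposed (air-facing) faces. The electrode
#' current is split uniformly over those nodes when the load vector is
#' assembled.
#'
#' @param site an `electrode_site`.
#' @param radius_mm footprint radius (>= voxel size); default 5 (10 mm
#'   diameter disc electrode).
#' @param phantom a `head_phantom`.
#' @return list with `voxels` (index matrix), `nodes` (node-grid linear
#'   ids), `site`, `radius_mm`.
#' @export
electrode_footprint <- function(site, radius_mm = 5, phantom) {
  h <- phantom$voxel_size_mm
  if (radius_mm < h) stop("footprint radius must be >= voxel size")
  if (site$label == "neck") {
    lab <- phantom$label
    base <- which(lab[, , 1] == TISSUE_CODES[["neck"]], arr.ind = TRUE)
    vox <- cbind(base, 1L)
  } else {
    surf <- surface_mask(phantom)
    geo <- surface_geodesic(phantom, surf, site$voxel, radius_mm)
    vox <- geo$voxels[geo$dist_mm <= radius_mm, , drop = FALSE]
  }
  if (nrow(vox) == 0L) stop("empty electrode footprint at ", site$label)
  nodes <- exposed_face_nodes(vox, phantom)
  if (length(nodes) == 0L) stop("footprint has no exposed faces at ",
                                site$label)
  list(voxels = vox, nodes = nodes, site = site, radius_mm = radius_mm)
}

# node-grid linear id for corner (i,j,k) in 1..(n+1) per axis
node_id <- function(i, j, k, dims)
  i + (dims[1] + 1) * ((j - 1) + (dims[2] + 1) * (k - 1))

exposed_face_nodes <- function(vox, phantom) {
  lab <- phantom$label
  dims <- dim(lab)
  is_air <- function(i, j, k) {
    out <- rep(TRUE, length(i))
    ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] &
      k >= 1 & k <= dims[3]
    out[ok] <- lab[cbind(i[ok], j[ok], k[ok])] == TISSUE_CODES[["air"]]
    out
  }
  i <- vox[, 1]; j <- vox[, 2]; k <- vox[, 3]
  nodes <- integer(0)
  add_face <- function(sel, base, ax1, ax2) {
    if (!any(sel)) return(invisible(NULL))
    b <- base[sel, , drop = FALSE]
    for (o1 in 0:1) for (o2 in 0:1) {
      p <- b
      p[, ax1] <- p[, ax1] + o1
      p[, ax2] <- p[, ax2] + o2
      nodes <<- c(nodes, node_id(p[, 1], p[, 2], p[, 3], dims))
    }
    invisible(NULL)
  }
  # voxel (i,j,k) spans nodes i..i+1, j..j+1, k..k+1
  add_face(is_air(i + 1, j, k), cbind(i + 1, j, k), 2L, 3L)
  add_face(is_air(i - 1, j, k), cbind(i, j, k), 2L, 3L)
  add_face(is_air(i, j + 1, k), cbind(i, j + 1, k), 1L, 3L)
  add_face(is_air(i, j - 1, k), cbind(i, j, k), 1L, 3L)
  add_face(is_air(i, j, k + 1), cbind(i, j, k + 1), 1L, 2L)
  add_face(is_air(i, j, k - 1), cbind(i, j, k), 1L, 2L)
  sort(unique(nodes))
}

#' Stimulation specification
#'
#' @param configuration `"non_cephalic"`, `"bi_cranial"` or `"ring"`.
#' @param site `"C3"` or `"F3"` (anode position).
#' @param intensity_mA positive stimulation current in mA.
#' @return a list of class `stimulation_spec`.
#' @export
stimulation_spec <- function(configuration = c("ring", "bi_cranial",
                                               "non_cephalic"),
                             site = c("C3", "F3"), intensity_mA = 1.0) {
  configuration <- match.arg(configuration)
  site <- match.arg(site)
  if (!(intensity_mA > 0)) stop("intensity_mA must be > 0")
  structure(list(configuration = configuration, site = site,
                 intensity_mA = intensity_mA), class = "stimulation_spec")
}

ring_cathode_sites <- function(anode, phantom, ring_mm = 30,
                               tol_mm = 2) {
  surf <- surface_mask(phantom)
  geo <- surface_geodesic(phantom, surf, anode$voxel, ring_mm + tol_mm)
  h <- phantom$voxel_size_mm
  cand <- which(is.finite(geo$dist_mm) &
                  abs(geo$dist_mm - ring_mm) <= tol_mm)
  if (length(cand) == 0L)
    stop("phantom too small: no scalp surface at ", ring_mm,
         " mm geodesic distance from ", anode$label)
  n <- anode$normal
  e1 <- c(-n[2], n[1], 0)
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  pc <- voxel_centers_mm(geo$voxels[cand, , drop = FALSE], h)
  rel <- sweep(pc, 2, anode$pos_mm)
  az <- atan2(rel %*% e2, rel %*% e1)
  picks <- integer(4)
  for (q in 0:3) {
    target <- -pi + q * pi / 2 + pi / 4
    dang <- abs(atan2(sin(az - target), cos(az - target)))
    score <- dang + abs(geo$dist_mm[cand] - ring_mm) / ring_mm
    picks[q + 1L] <- cand[which.min(score)]
  }
  if (anyDuplicated(picks))
    stop("phantom too small: ring cathodes collapse onto each other")
  lapply(seq_along(picks), function(q) {
    vx <- geo$voxels[picks[q], ]
    p_mm <- voxel_centers_mm(vx, h)
    structure(list(label = paste0(anode$label, "_ring", q), voxel = vx,
                   pos_mm = p_mm,
                   normal = ellipsoid_normal(p_mm, phantom$center,
                                             phantom$morphology$radii_scalp),
                   geodesic_mm = geo$dist_mm[picks[q]]),
              class = "electrode_site")
  })
}

#' Build a stimulation montage
#'
#' Realizes one of the three configurations at the requested site and
#' intensity: `non_cephalic` pairs the scalp anode (+I) with the neck-base
#' return (-I); `bi_cranial` pairs it with the contralateral homologue
#' (C4 or F4, -I); `ring` surrounds it with four cathodes at one quarter
#' the anode current each, placed 30 mm away geodesically at 90-degree
#' spacing. Net current is exactly zero by construction.
#'
#' @param spec a [stimulation_spec()].
#' @param sites site map from [place_1020_sites()].
#' @param phantom a `head_phantom`.
#' @param radius_mm electrode disc radius (default 5 mm).
#' @param ring_mm anode-to-cathode geodesic distance for the ring (30 mm).
#' @return object of class `montage`: list with `electrodes` (each carrying
#'   `site`, `current_mA`, `footprint`) and `spec`.
#' @export
build_montage <- function(spec, sites, phantom, radius_mm = 5,
                          ring_mm = 30) {
  stopifnot(inherits(spec, "stimulation_spec"))
  I <- spec$intensity_mA
  anode_site <- sites[[spec$site]]
  if (is.null(anode_site)) stop("anode site ", spec$site, " not in site map")
  mk <- function(site, current) {
    list(site = site, current_mA = current,
         footprint = electrode_footprint(site, radius_mm, phantom))
  }
  electrodes <- switch(spec$configuration,
    non_cephalic = list(mk(anode_site, I), mk(sites$neck, -I)),
    bi_cranial = {
      homologue <- c(C3 = "C4", F3 = "F4")[[spec$site]]
      list(mk(anode_site, I), mk(sites[[homologue]], -I))
    },
    ring = {
      cath <- ring_cathode_sites(anode_site, phantom, ring_mm)
      c(list(mk(anode_site, I)), lapply(cath, mk, current = -I / 4))
    })
  tot <- sum(vapply(electrodes, `[[`, numeric(1), "current_mA"))
  stopifnot(abs(tot) == 0)
  structure(list(electrodes = electrodes, spec = spec), class = "montage")
}

#' Serialize a montage to a data frame
#' @param montage a `montage`.
#' @return data frame with label, position (mm), current and radius.
#' @export
montage_table <- function(montage) {
  do.call(rbind, lapply(montage$electrodes, function(e)
    data.frame(label = e$site$label, x_mm = e$site$pos_mm[1],
               y_mm = e$site$pos_mm[2], z_mm = e$site$pos_mm[3],
               current_mA = e$current_mA,
               radius_mm = e$footprint$radius_mm)))
}
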