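# Spherical cortical target under the stimulating electrode and the dose
# statistic (mean |J| over member voxels).

#' Locate the spherical brain target beneath an electrode site
#'
#' Marches inward from the scalp site along the inward electrode normal to
#' the brain surface, then one sphere radius deeper, so the 10 mm sphere
#' sits tangent to the brain surface directly under the electrode. If the
#' sphere pokes out of the brain compartment (tight phantoms), the centre
#' is stepped deeper along the same line, up to 8 mm, before failing.
#' Membership is voxel-centre-within-radius.
#'
#' @param site an `electrode_site` (anode).
#' @param phantom a `head_phantom`.
#' @param diameter_mm sphere diameter, default 10.
#' @return object of class `target_sphere`: `center_mm`, `member_voxels`
#'   (linear indices), `n_voxels`, `diameter_mm`.
#' @export
locate_target <- function(site, phantom, diameter_mm = 10) {
  h <- phantom$voxel_size_mm
  lab <- phantom$label
  dims <- dim(lab)
  radius <- diameter_mm / 2
  u <- -site$normal
  entry <- NULL
  for (t in seq(0, 4 * max(phantom$morphology$radii_scalp), by = h / 4)) {
    p <- site$pos_mm + t * u
    ijk <- round(p / h + 0.5)
    if (any(ijk < 1) || any(ijk > dims)) break
    if (lab[ijk[1], ijk[2], ijk[3]] == TISSUE_CODES[["brain"]]) {
      entry <- p
      break
    }
  }
  if (is.null(entry))
    stop("no brain tissue found beneath site ", site$label)
  for (extra in seq(0, 8, by = h / 2)) {
    center <- entry + (radius + extra) * u
    mem <- sphere_members(center, radius, dims, h)
    if (length(mem) > 0L &&
        all(lab[mem] == TISSUE_CODES[["brain"]])) {
      return(structure(list(center_mm = center, member_voxels = mem,
                            n_voxels = length(mem),
                            diameter_mm = diameter_mm,
                            site_label = site$label),
                       class = "target_sphere"))
    }
  }
  stop("a ", diameter_mm, " mm sphere does not fit in brain beneath ",
       site$label)
}

# linear indices of voxels whose centres lie within radius of center (mm)
sphere_members <- function(center_mm, radius_mm, dims, h) {
  lo <- pmax(floor((center_mm - radius_mm) / h), 0L)
  hi <- pmin(ceiling((center_mm + radius_mm) / h), dims)
  if (any(lo >= hi)) return(integer(0))
  gi <- (lo[1] + 1):hi[1]; gj <- (lo[2] + 1):hi[2]; gk <- (lo[3] + 1):hi[3]
  gr <- expand.grid(i = gi, j = gj, k = gk)
  cx <- (gr$i - 0.5) * h; cy <- (gr$j - 0.5) * h; cz <- (gr$k - 0.5) * h
  d2 <- (cx - center_mm[1])^2 + (cy - center_mm[2])^2 +
    (cz - center_mm[3])^2
  sel <- d2 <= radius_mm^2
  gr <- gr[sel, , drop = FALSE]
  as.integer(gr$i + dims[1] * ((gr$j - 1) + dims[2] * (gr$k - 1)))
}

#' Dose summary over a target sphere
#'
#' The dose statistic is the arithmetic mean of per-voxel current-density
#' magnitude (uA/cm^2) over the sphere's member voxels, with spread
#' statistics and condition tags carried along.
#'
#' @param J a `current_density_field`.
#' @param sphere a [locate_target()] result.
#' @param tags named list of condition tags (subject, sex, configuration,
#'   site, intensity) copied onto the row.
#' @return one-row data frame: tags + `mean_J`, `sd_J`, `min_J`, `max_J`,
#'   `n_voxels`.
#' @export
dose_summary <- function(J, sphere, tags = list()) {
  mem <- sphere$member_voxels
  if (length(mem) == 0L) stop("target sphere has no member voxels")
  vals <- J$Jmag[mem]
  out <- data.frame(mean_J = mean(vals),
                    sd_J = if (length(vals) > 1L) stats::sd(vals) else 0,
                    min_J = min(vals), max_J = max(vals),
                    n_voxels = length(vals))
  if (length(tags) > 0L) out <- cbind(as.data.frame(tags), out)
  out
}
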