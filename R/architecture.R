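# quarter-ellipsoid sector volume (m^3) between depths a and b, for a
# sector with horizontal max radius r and vertical max depth z; the sector
# is the up- or downslope half of the below-ground half of an ellipsoid of
# revolution, so its horizontal cross-section at depth t is a half-disc of
# radius r*sqrt(1 - (t/z)^2)
ellipsoid_slab <- function(r, z, a, b) {
  if (z <= 0 || r <= 0) return(0)
  a <- min(max(a, 0), z); b <- min(max(b, 0), z)
  if (b <= a) return(0)
  (pi * r^2 / 2) * ((b - a) - (b^3 - a^3) / (3 * z^2))
}

# quarter-cylinder sector volume (m^3) between depths a and b: cylinder
# axis along the stem (length l), elliptical quarter cross-section with
# horizontal semi-axis r and vertical semi-axis z
cylinder_slab <- function(r, z, l, a, b) {
  if (z <= 0 || r <= 0 || l <= 0) return(0)
  a <- min(max(a, 0), z); b <- min(max(b, 0), z)
  if (b <= a) return(0)
  s <- function(t) (z / 2) * (asin(t / z) + (t / z) * sqrt(pmax(0, 1 - (t / z)^2)))
  l * r * (s(b) - s(a))
}

#' Individual soil volume (ISV) of a root system
#'
#' The ISV is the envelope volume a plant's roots occupy. For radial root
#' systems each slope sector (up, down) contributes a quarter of an
#' ellipsoid of revolution — horizontal semi-axes equal to the sector's
#' maximal radius, vertical semi-axis equal to the maximal rooting depth —
#' i.e. \eqn{\frac{1}{3}\pi r^2 z} per sector. For linear root systems
#' (roots arranged along a horizontal stem) each sector contributes a
#' quarter cylinder of length `stem_length` with elliptical cross-section
#' (semi-axes r and z), i.e. \eqn{\frac{\pi}{4} r z L} per sector. The total
#' is partitioned into depth layers by horizontal slab slicing of the solid,
#' and standardised by the collar diameter so differently sized individuals
#' can be compared.
#'
#' @param system A `root_system` (see [generate_root_system]) or any list
#'   with fields `max_radius_up`, `max_radius_down`, `max_depth` (m),
#'   `collar_diameter` (cm), `layout`, and `stem_length` (m) when
#'   `layout == "linear"`.
#' @param layer_height Depth-layer thickness (m), default 0.10.
#' @return An `isv_result` list: `total` (m^3), `per_sector_per_layer`
#'   (data frame `sector`, `depth_layer`, `volume`), `isv_over_dc`
#'   (m^3 cm^-1).
#' @examples
#' sys <- list(max_radius_up = 1, max_radius_down = 1, max_depth = 1,
#'             collar_diameter = 1, layout = "radial")
#' individual_soil_volume(sys)$total   # 2 * pi / 3
#' @export
individual_soil_volume <- function(system, layer_height = 0.10) {
  stopifnot(layer_height > 0)
  r_up <- system$max_radius_up
  r_down <- system$max_radius_down
  z <- system$max_depth
  if (any(c(r_up, r_down, z) < 0)) stop("extents must be non-negative")
  if (is.null(system$collar_diameter) || system$collar_diameter <= 0) {
    stop("collar diameter must be positive")
  }
  linear <- identical(system$layout, "linear")
  if (linear && (is.null(system$stem_length) || !is.finite(system$stem_length))) {
    stop("linear layout requires a measured 'stem_length'; it is never inferred")
  }

  sector_slab <- function(r, a, b) {
    if (linear) cylinder_slab(r, z, system$stem_length, a, b)
    else ellipsoid_slab(r, z, a, b)
  }
  n_layers <- if (z > 0) ceiling(z / layer_height - 1e-12) else 0L
  parts <- expand.grid(sector = c("up", "down"),
                       depth_layer = seq_len(max(n_layers, 1L)) - 1L,
                       stringsAsFactors = FALSE)
  parts$volume <- mapply(function(sec, layer) {
    r <- if (sec == "up") r_up else r_down
    sector_slab(r, layer * layer_height, (layer + 1) * layer_height)
  }, parts$sector, parts$depth_layer)
  if (n_layers == 0L) parts$volume <- 0

  total_up <- sector_slab(r_up, 0, z)
  total_down <- sector_slab(r_down, 0, z)
  total <- total_up + total_down
  structure(list(total = total, per_sector_per_layer = parts,
                 isv_over_dc = total / system$collar_diameter,
                 layer_height = layer_height),
            class = "isv_result")
}

# cylinder-approximated volume where not measured; errors if neither the
# volume nor (diameter, length) is available
segment_volumes <- function(segments) {
  vol <- segments$volume
  missing_vol <- is.na(vol)
  if (any(missing_vol)) {
    dl_ok <- !is.na(segments$diameter) & !is.na(segments$length)
    if (any(missing_vol & !dl_ok)) {
      stop("segment with neither a measured volume nor diameter+length")
    }
    vol[missing_vol] <- pi * (segments$diameter[missing_vol] / 2)^2 *
      segments$length[missing_vol]
  }
  vol
}

#' Root area ratio (RAR) by depth layer, slope sector and diameter class
#'
#' RAR is the cumulated root cross-sectional area per unit of soil area
#' crossing a plane; assuming all roots within a layer cross its surface
#' perpendicularly this equals the cumulated root volume per soil volume,
#' \eqn{RAR = \sum V_r / (A h)}. Roots are split at 2 mm into fine
#' (`d < 2`) and coarse (`d >= 2`) classes (the boundary diameter goes to
#' the coarse class), plus an `all` class; fine + coarse = all by
#' construction.
#'
#' @param segments Data frame of root segments: `depth_layer`, `sector`,
#'   `diameter` (mm), `length` (mm), `volume` (mm^3; may be `NA`, then the
#'   cylinder approximation is used).
#' @param reference_area Soil reference area A (mm^2) per layer surface.
#' @param layer_height Layer height h (mm).
#' @param fine_boundary Diameter class boundary (mm), default 2.
#' @return A `rar_result` data frame with columns `depth_layer`, `sector`,
#'   `class` (`fine`/`coarse`/`all`) and `rar` (dimensionless); reference
#'   area and layer height kept as attributes.
#' @examples
#' seg <- data.frame(depth_layer = 0, sector = "up", diameter = 2,
#'                   length = 100, volume = NA)
#' root_area_ratio(seg, reference_area = 1e4, layer_height = 100)
#' @export
root_area_ratio <- function(segments, reference_area, layer_height = 100,
                            fine_boundary = 2) {
  stopifnot(reference_area > 0, layer_height > 0)
  if (!nrow(segments)) {
    out <- data.frame(depth_layer = integer(), sector = character(),
                      class = character(), rar = numeric())
    return(structure(out, class = c("rar_result", "data.frame"),
                     reference_area = reference_area,
                     layer_height = layer_height))
  }
  vol <- segment_volumes(segments)
  cls <- ifelse(segments$diameter < fine_boundary, "fine", "coarse")
  soil_volume <- reference_area * layer_height

  agg <- function(keep, label) {
    if (!any(keep)) return(NULL)
    s <- stats::aggregate(vol[keep],
                          by = list(depth_layer = segments$depth_layer[keep],
                                    sector = segments$sector[keep]),
                          FUN = sum)
    data.frame(depth_layer = s$depth_layer, sector = s$sector,
               class = label, rar = s$x / soil_volume,
               stringsAsFactors = FALSE)
  }
  cells <- unique(segments[c("depth_layer", "sector")])
  full <- function(part, label) {
    base <- cells
    base$class <- label
    base$rar <- 0
    if (!is.null(part)) {
      key <- paste(base$depth_layer, base$sector)
      pkey <- paste(part$depth_layer, part$sector)
      base$rar[match(pkey, key)] <- part$rar
    }
    base
  }
  out <- rbind(full(agg(cls == "fine", "fine"), "fine"),
               full(agg(cls == "coarse", "coarse"), "coarse"),
               full(agg(rep(TRUE, length(cls)), "all"), "all"))
  rownames(out) <- NULL
  structure(out, class = c("rar_result", "data.frame"),
            reference_area = reference_area, layer_height = layer_height)
}

#' Per-layer RAR of a root system using the ISV footprint as soil area
#'
#' Convenience wrapper computing, for each (sector, depth layer), the RAR of
#' the system's segments against that layer's own ISV footprint: the
#' horizontal cross-section of the sector's envelope solid at the top of the
#' layer (a half-disc for radial layouts, a stem-length x half-width
#' rectangle for linear layouts). A fixed `reference_area` (mm^2) can be
#' supplied instead to override the footprint convention.
#'
#' @param system A `root_system`.
#' @param layer_height Layer thickness (m).
#' @param fine_boundary Diameter class boundary (mm).
#' @param reference_area Optional fixed soil area (mm^2) overriding the
#'   per-layer footprint.
#' @return Data frame `depth_layer`, `sector`, `class`, `rar`.
#' @export
system_rar <- function(system, layer_height = 0.10, fine_boundary = 2,
                       reference_area = NULL) {
  seg <- system$segments
  if (!nrow(seg)) {
    return(data.frame(depth_layer = integer(), sector = character(),
                      class = character(), rar = numeric()))
  }
  h_mm <- layer_height * 1000
  z <- system$max_depth
  footprint <- function(sector, layer) {
    if (!is.null(reference_area)) return(reference_area)
    a <- min(layer * layer_height, z)
    r <- if (sector == "up") system$max_radius_up else system$max_radius_down
    half_width <- r * sqrt(max(0, 1 - (a / z)^2))
    area_m2 <- if (identical(system$layout, "linear")) {
      system$stem_length * half_width
    } else {
      (pi / 2) * half_width^2
    }
    area_m2 * 1e6
  }
  parts <- lapply(split(seg, list(seg$depth_layer, seg$sector), drop = TRUE),
                  function(s) {
                    area <- footprint(s$sector[1], s$depth_layer[1])
                    if (area <= 0) return(NULL)
                    root_area_ratio(s, reference_area = area,
                                    layer_height = h_mm,
                                    fine_boundary = fine_boundary)
                  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Architectural trait table for a set of root systems
#'
#' Computes ISV, ISV/Dc and per-layer/sector/class RAR for each plant and
#' stacks them into the `arch_traits` table keyed by (species, plant_id,
#' depth_layer, sector, class).
#'
#' @param systems List of `root_system` objects.
#' @param layer_height Layer thickness (m).
#' @param fine_boundary Diameter class boundary (mm).
#' @return Data frame with per-plant `isv_total`, `isv_over_dc` and the RAR
#'   breakdown.
#' @export
arch_traits <- function(systems, layer_height = 0.10, fine_boundary = 2) {
  rows <- lapply(systems, function(sys) {
    isv <- individual_soil_volume(sys, layer_height)
    rar <- system_rar(sys, layer_height, fine_boundary)
    if (!nrow(rar)) return(NULL)
    cbind(data.frame(species = sys$species, plant_id = sys$plant_id,
                     site = sys$site, isv_total = isv$total,
                     isv_over_dc = isv$isv_over_dc,
                     stringsAsFactors = FALSE),
          rar)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
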