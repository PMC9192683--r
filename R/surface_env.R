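#' Surface-area enlargement factor for algal mats
#'
#' Scales a subsample's image-derived two-sided thallus area to the main
#' sample by wet weight, SA_MS = WW_MS * SA_SS / WW_SS, and relates it to the
#' planar frame area: EF = (SA_MS + frame) / frame.
#'
#' @param ww_subsample wet weight of the imaged subsample (g).
#' @param sa_subsample two-sided surface area of the subsample (m^2).
#' @param ww_main wet weight of the main sample (g).
#' @param frame_area planar frame area in m^2 (0.09 for the mat frames).
#' @return Enlargement factor (>= 1).
#' @export
ef_phyllophora <- function(ww_subsample, sa_subsample, ww_main,
                           frame_area = 0.09) {
  if (ww_subsample <= 0) stop("subsample wet weight must be > 0")
  if (sa_subsample < 0 || ww_main < 0) stop("areas and weights must be >= 0")
  sa_main <- ww_main * sa_subsample / ww_subsample
  (sa_main + frame_area) / frame_area
}

#' Surface-area enlargement factor for seagrass
#'
#' Models the rhizome as a cylinder (lateral surface 2*pi*r*h, no end caps)
#' and each leaf as a two-sided rectangle (2 * length * width), scales to a
#' square metre by shoot density, and relates to the frame:
#' EF = (SA_per_shoot * shoots_per_m2 * frame + frame) / frame, i.e.
#' SA_per_shoot * shoots_per_m2 + 1.
#'
#' @param rhizome_radius,rhizome_length cylinder radius and length (m).
#' @param leaf_length,leaf_width leaf dimensions (m).
#' @param leaves_per_rhizome number of leaves per shoot.
#' @param rhizomes_per_m2 shoot density (counted in 0.16 m^2 frames).
#' @param include which structures contribute surface area: `"holobiont"`
#'   (both), `"leaves"` or `"rhizomes"`.
#' @return Enlargement factor (>= 1).
#' @export
ef_posidonia <- function(rhizome_radius, rhizome_length, leaf_length,
                         leaf_width, leaves_per_rhizome, rhizomes_per_m2,
                         include = c("holobiont", "leaves", "rhizomes")) {
  include <- match.arg(include)
  if (any(c(rhizome_radius, rhizome_length, leaf_length, leaf_width) < 0) ||
      leaves_per_rhizome < 0 || rhizomes_per_m2 < 0)
    stop("geometry must be non-negative")
  sa_rhizome <- 2 * pi * rhizome_radius * rhizome_length
  sa_leaves <- 2 * leaf_length * leaf_width * leaves_per_rhizome
  sa_shoot <- switch(include,
    holobiont = sa_rhizome + sa_leaves,
    leaves = sa_leaves,
    rhizomes = sa_rhizome)
  sa_shoot * rhizomes_per_m2 + 1
}

#' Heron's formula for a triangle area
#'
#' @param a,b,c side lengths.
#' @return Triangle area.
#' @export
heron_area <- function(a, b, c) {
  if (a + b <= c || a + c <= b || b + c <= a)
    stop("triangle inequality violated for sides (", a, ", ", b, ", ", c, ")")
  s <- (a + b + c) / 2
  sqrt(s * (s - a) * (s - b) * (s - c))
}

#' Convert ball-chain link counts to lengths
#'
#' @param n_links number of links (rounded to the nearest whole link).
#' @param pitch centre-to-centre ball pitch in metres (2.4 mm chain).
#' @return Length in metres.
#' @export
chain_length <- function(n_links, pitch = 0.0024) round(n_links) * pitch

#' Surface-area enlargement factor for hard-bottom substrate
#'
#' A square frame is laid on the substrate and ball chains are draped along
#' its four edges and two diagonals, tracing the true relief. For each
#' diagonal the quadrilateral is split into two triangles (the measured edge
#' chains plus that diagonal chain) whose Heron areas are summed; the two
#' diagonal-based totals are averaged and divided by the planar frame area.
#'
#' @param edges measured chain lengths (m) along the four edges, in order
#'   AB, BC, CD, DA.
#' @param diagonals measured chain lengths (m) of the diagonals AC, BD.
#' @param frame_area planar frame area in m^2 (0.04 for the 20 x 20 cm
#'   frame).
#' @return Enlargement factor (>= 1 whenever the chains trace real relief).
#' @export
ef_hardbottom <- function(edges, diagonals, frame_area = 0.04) {
  if (length(edges) != 4 || length(diagonals) != 2)
    stop("need 4 edge lengths and 2 diagonal lengths")
  ab <- edges[1]; bc <- edges[2]; cd <- edges[3]; da <- edges[4]
  ac <- diagonals[1]; bd <- diagonals[2]
  area_ac <- heron_area(ab, bc, ac) + heron_area(cd, da, ac)
  area_bd <- heron_area(ab, da, bd) + heron_area(bc, cd, bd)
  mean(c(area_ac, area_bd)) / frame_area
}

#' Gypsum clod-card dissolution rate
#'
#' Weight loss per day as a relative index of water movement.
#'
#' @param w_pre,w_post constant dry weights before and after deployment (g).
#' @param days deployment duration in days (> 0).
#' @return Dissolution rate in g per day.
#' @export
clod_card_rate <- function(w_pre, w_post, days) {
  if (any(days <= 0)) stop("deployment duration must be > 0")
  if (any(w_post > w_pre))
    stop("weight gain during deployment (contamination?)")
  (w_pre - w_post) / days
}

#' Daily summary of a logger time series
#'
#' Calendar-day aggregation of a timestamped series to daily mean, min, max
#' and number of readings. Days with no readings between the first and last
#' observation are reported via `message()` and omitted.
#'
#' @param timestamps `POSIXct` (or coercible) timestamps, non-decreasing.
#' @param values numeric measurements.
#' @return Data frame with columns `date`, `mean`, `min`, `max`, `n`.
#' @export
daily_summary <- function(timestamps, values) {
  timestamps <- as.POSIXct(timestamps)
  if (length(timestamps) != length(values)) stop("length mismatch")
  if (is.unsorted(timestamps)) stop("timestamps must be non-decreasing")
  day <- as.Date(timestamps)
  agg <- do.call(rbind, lapply(split(values, day), function(v)
    data.frame(mean = mean(v), min = min(v), max = max(v), n = length(v))))
  out <- data.frame(date = as.Date(rownames(agg)), agg, row.names = NULL)
  full <- seq(min(day), max(day), by = "day")
  gaps <- setdiff(as.character(full), as.character(out$date))
  if (length(gaps))
    message("daily_summary: no readings on ", paste(gaps, collapse = ", "))
  out[order(out$date), , drop = FALSE]
}
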