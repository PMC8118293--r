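# Habitat degradation and quality: a from-scratch implementation of the
# InVEST-style habitat-quality model. Threat intensity drifts from
# treated crop pixels into neighboring habitat with an exponential
# distance decay truncated at 60 m (95% of spray deposited within the
# maximum distance), accumulates into a per-pixel degradation score
# normalized to [0, 1], and degrades habitat through a half-saturation
# transform.

#' Distance-decay factor of the drift kernel
#'
#' Exponential mode: `exp(-(coef / d_max) * d)` for `d <= d_max`, 0
#' beyond, with `coef = -ln(0.05)` so the 1-D cumulative deposition
#' within `d_max` is exactly 95%. Linear mode (`1 - d/d_max`) is provided
#' for completeness.
#'
#' @param d Distance(s) in meters (>= 0).
#' @param d_max Maximum drift distance in meters (default 60).
#' @param mode `"exponential"` (default) or `"linear"`.
#' @param coef Decay coefficient for the exponential mode (default
#'   `-ln(0.05)`, about 2.996).
#' @return Decay factor(s) in `[0, 1]`.
#' @export
#' @examples
#' decay_factor(c(0, 30, 60, 90))
decay_factor <- function(d, d_max = D_MAX_M, mode = c("exponential", "linear"),
                         coef = DECAY_COEF) {
  mode <- match.arg(mode)
  stopifnot(all(d >= 0), d_max > 0)
  f <- switch(mode,
    exponential = exp(-(coef / d_max) * d),
    linear = 1 - d / d_max
  )
  ifelse(d <= d_max, pmax(f, 0), 0)
}

#' Habitat map from a land-cover grid
#'
#' Natural covers (grassland, herbaceous wetland, forest) get habitat
#' score 1; all cropland and everything else (including nodata) gets 0.
#' The same 0/1 scheme serves as the per-landcover threat sensitivity.
#'
#' @param landcover Reclassified land-cover `bee_grid`.
#' @return A `bee_grid` with values in `{0, 1}`.
#' @export
habitat_map <- function(landcover) {
  h <- matrix(0, nrow(landcover), ncol(landcover))
  h[unclass(landcover) %in% natural_codes()] <- 1
  grid_like(landcover, h)
}

# integer cell offsets within d_max of the origin and their decay
# factors; includes the origin cell. For 30-m cells and d_max = 60 this
# is the 13-cell kernel (distances 0, 30, 42.43, 60).
kernel_offsets <- function(cell, d_max = D_MAX_M, mode = "exponential",
                           coef = DECAY_COEF) {
  k <- floor(d_max / cell)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  dist <- sqrt(off$dr^2 + off$dc^2) * cell
  keep <- dist <= d_max + 1e-9
  data.frame(
    dr = off$dr[keep], dc = off$dc[keep],
    w = decay_factor(dist[keep], d_max, mode, coef)
  )
}

# zero-padded shift of a matrix by (dr, dc)
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr)
  cs <- seq_len(nc)
  dest_r <- rs[rs - dr >= 1 & rs - dr <= nr]
  dest_c <- cs[cs - dc >= 1 & cs - dc <= nc]
  if (length(dest_r) && length(dest_c)) {
    out[dest_r, dest_c] <- m[dest_r - dr, dest_c - dc]
  }
  out
}

#' Per-pixel habitat degradation
#'
#' Accumulates decayed threat intensity into a degradation score:
#' for pixel `x`,
#' `D_x = S_x * sum_r (w_r / sum_r w_r) * sum_y r_y * decay(d_xy) / K`
#' over threat pixels `y` within the maximum distance, where `K` is the
#' truncated kernel's total mass. The normalization makes `D = 1` when
#' every cell within range (including the pixel itself) carries full
#' threat from every layer, so `D` lies in `[0, 1]` for intensities in
#' `[0, 1]`. Sensitivity `S_x` is the 0/1 habitat score: degradation is
#' only scored on habitat pixels.
#'
#' @param threats List of `threat_layer` objects (possibly empty).
#' @param habitat Habitat `bee_grid` from [habitat_map()].
#' @return A `bee_grid` of degradation scores in `[0, 1]`.
#' @export
degradation <- function(threats, habitat) {
  D <- matrix(0, nrow(habitat), ncol(habitat))
  if (length(threats) > 0) {
    wsum <- sum(vapply(threats, function(t) t$weight, 0))
    if (wsum > 0) {
      for (th in threats) {
        stopifnot_aligned(habitat, th$intensity)
        if (th$weight == 0) next
        ker <- kernel_offsets(cell_size(habitat), th$max_distance,
          mode = th$decay
        )
        acc <- matrix(0, nrow(habitat), ncol(habitat))
        r <- unclass(th$intensity)
        for (i in seq_len(nrow(ker))) {
          acc <- acc + ker$w[i] * shift_matrix(r, ker$dr[i], ker$dc[i])
        }
        D <- D + (th$weight / wsum) * acc / sum(ker$w)
      }
    }
  }
  grid_like(habitat, D * unclass(habitat))
}

#' Habitat quality from degradation
#'
#' Half-saturation transform:
#' `Q_x = H_x * (1 - D_x^z / (D_x^z + k^z))`, so quality equals the
#' habitat score where degradation is zero and is halved at `D = k`. The
#' exponent `z` is fixed at 2.5; the half-saturation constant `k` is
#' configurable.
#'
#' @param D Degradation `bee_grid` from [degradation()].
#' @param habitat Habitat `bee_grid` from [habitat_map()].
#' @param k Half-saturation constant (> 0, default 0.5).
#' @param z Transform exponent (default 2.5).
#' @return A `bee_grid` of quality scores in `[0, 1]`.
#' @export
quality <- function(D, habitat, k = QUALITY_K, z = QUALITY_Z) {
  stopifnot(k > 0, z > 0)
  stopifnot_aligned(D, habitat)
  d <- unclass(D)
  q <- unclass(habitat) * (1 - d^z / (d^z + k^z))
  grid_like(habitat, q)
}

#' Run the full habitat-quality model for one year
#'
#' Convenience wrapper: habitat map, degradation, quality.
#'
#' @param landcover Reclassified land-cover `bee_grid`.
#' @param threats List of `threat_layer` objects.
#' @inheritParams quality
#' @return A list with `habitat`, `D`, `Q` grids.
#' @export
habitat_quality <- function(landcover, threats, k = QUALITY_K, z = QUALITY_Z) {
  H <- habitat_map(landcover)
  D <- degradation(threats, H)
  list(habitat = H, D = D, Q = quality(D, H, k = k, z = z))
}
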