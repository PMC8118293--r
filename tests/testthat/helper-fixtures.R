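# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain double loops / closed forms, independent of the
# package's optimized code paths.

# uniform single-class grid
const_grid <- function(code, nr = 50, nc = 50, cell = 30) {
  bee_grid(matrix(as.integer(code), nr, nc), cell_size = cell)
}

# a grid whose left half is grassland and right half is corn
split_grid <- function(nr = 50, nc = 50, cell = 30) {
  m <- matrix(class_codes()[["grassland"]], nr, nc)
  m[, (nc %/% 2 + 1):nc] <- class_codes()[["corn"]]
  bee_grid(matrix(as.integer(m), nr, nc), cell_size = cell)
}

# brute-force degradation oracle: for every pixel, loop over every other
# pixel within d_max of it, for every threat layer, and accumulate
# decayed intensity; same normalization definition as the model states
# (truncated-kernel mass), computed independently here.
brute_degradation <- function(threats, habitat, d_max = 60, coef = -log(0.05)) {
  nr <- nrow(habitat)
  nc <- ncol(habitat)
  cell <- cell_size(habitat)
  k <- floor(d_max / cell)
  # kernel mass over all lattice offsets within d_max (incl. origin)
  kmass <- 0
  for (dr in -k:k) {
    for (dc in -k:k) {
      d <- sqrt(dr^2 + dc^2) * cell
      if (d <= d_max + 1e-9) kmass <- kmass + exp(-coef * d / d_max)
    }
  }
  wsum <- sum(vapply(threats, function(t) t$weight, 0))
  D <- matrix(0, nr, nc)
  if (length(threats) == 0 || wsum == 0) {
    return(grid_like_oracle(habitat, D * unclass(habitat)))
  }
  for (th in threats) {
    r <- unclass(th$intensity)
    acc <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        s <- 0
        for (di in -k:k) {
          for (dj in -k:k) {
            ii <- i + di
            jj <- j + dj
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
            d <- sqrt(di^2 + dj^2) * cell
            if (d > d_max + 1e-9) next
            s <- s + r[ii, jj] * exp(-coef * d / d_max)
          }
        }
        acc[i, j] <- s
      }
    }
    D <- D + (th$weight / wsum) * acc / kmass
  }
  grid_like_oracle(habitat, D * unclass(habitat))
}

# independent re-implementation of grid_like for the oracle
grid_like_oracle <- function(template, values) {
  bee_grid(values, cell_size = cell_size(template), origin = origin(template))
}

# closed-form OLS slope/intercept oracle
ols_oracle <- function(x, y) {
  xm <- mean(x)
  ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(slope = slope, intercept = ym - slope * xm)
}

# a minimal hand-built pesticide table set: two counties in one district
hand_tables <- function(kg = c(100, 200), ratio = 0.5, area = 1000,
                        compound = "Chlorpyrifos", crop = "soybeans",
                        year = 2006) {
  list(
    use = tibble::tibble(
      county = seq_along(kg), year = year, compound = compound, kg = kg
    ),
    ratios = tibble::tibble(
      compound = compound, crop = crop, year = year, ratio = ratio
    ),
    areas = tibble::tibble(
      district = 1L, crop = crop, year = year, hectares = area
    ),
    lookup = tibble::tibble(county = seq_along(kg), district = 1L)
  )
}

# single constant-intensity threat layer covering chosen cells
make_threat <- function(template, cells, intensity = 1, weight = 1,
                        compound = "Chlorpyrifos", crop = "corn") {
  m <- matrix(0, nrow(template), ncol(template))
  m[cells] <- intensity
  structure(
    list(
      intensity = bee_grid(m,
        cell_size = cell_size(template),
        origin = origin(template)
      ),
      compound = compound, crop = crop, weight = weight,
      max_distance = 60, decay = "exponential"
    ),
    class = "threat_layer"
  )
}
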