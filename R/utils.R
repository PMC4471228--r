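# Internal geometry and RNG helpers.

# Run expr with a private RNG stream; the caller's RNG state is untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed)) stop("seed must be a finite integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Even-odd (ray casting) point-in-polygon, vectorized over points.
# Points exactly on a horizontal edge are treated per the half-open rule;
# band ROIs avoid the ambiguity by using half-integer polygon edges.
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (vx[j] - vx[i]) * (py - yi) / (yj - yi) + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Signed polygon area (shoelace); sign encodes orientation.
.polygonArea <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

# Distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorized
# over points.
.pointSegDist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

.clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Column lookup tolerant to the documented schema synonyms.
.greyColumn <- function(data) {
  for (nm in c("grey_obs", "grey", "mean_grey", "grey_value")) {
    if (nm %in% names(data)) return(nm)
  }
  stop("no grey-value column found (expected one of grey_obs, grey, ",
       "mean_grey, grey_value)")
}

.distanceColumn <- function(data) {
  for (nm in c("distance_m", "distance", "x")) {
    if (nm %in% names(data)) return(nm)
  }
  stop("no distance column found (expected distance_m, distance or x)")
}
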