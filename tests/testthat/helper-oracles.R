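# Independent oracles and small fixture builders shared across tests.

# breadth-first flood fill over the 26-neighborhood; returns components as a
# list of sorted linear index vectors, independent of the graph-based
# implementation under test
bfs_components_oracle <- function(arr) {
  d <- dim(arr)
  nz <- which(arr != 0)
  if (length(nz) == 0L) return(list())
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lookup <- new.env(parent = emptyenv(), size = length(nz))
  for (v in nz) assign(as.character(v), FALSE, envir = lookup)  # FALSE = unvisited
  comps <- list()
  for (start in nz) {
    if (get(as.character(start), envir = lookup)) next
    queue <- start
    assign(as.character(start), TRUE, envir = lookup)
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      p <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1L) || any(q > d)) next
        w <- q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]
        key <- as.character(w)
        if (exists(key, envir = lookup, inherits = FALSE) &&
            !get(key, envir = lookup)) {
          assign(key, TRUE, envir = lookup)
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# brute-force Minkowski sum of a 2D mask with a centered square of
# half-width r: union of translated squares around every on-pixel
minkowski_dilate_oracle <- function(m, r) {
  out <- matrix(0, nrow(m), ncol(m))
  for (idx in which(m != 0)) {
    i <- (idx - 1L) %% nrow(m) + 1L
    j <- (idx - 1L) %/% nrow(m) + 1L
    out[max(1, i - r):min(nrow(m), i + r),
        max(1, j - r):min(ncol(m), j + r)] <- 1
  }
  out
}

# canonical partition representation for comparing component outputs
partition_signature <- function(comps) {
  sets <- unname(lapply(comps, sort))
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

rand_sparse_vol <- function(d, density, spacing = c(1, 1, 1)) {
  arr <- array(as.numeric(runif(prod(d)) < density), dim = d)
  vol3d(arr, spacing, kind = "mask")
}

mask_vol <- function(arr, spacing = c(1, 1, 1)) vol3d(arr, spacing, "mask")
prob_vol <- function(arr, spacing = c(1, 1, 1)) vol3d(arr, spacing, "probability")

# tiny phantom conditions used by fast unit tests (coarser grid than the
# generator default so each case builds in milliseconds)
small_phantom <- function(lesions, noise = 0, seed = 1) {
  make_case(phantom_spec(shape = c(96, 96, 10), spacing = c(0.6, 0.6, 3),
                         semiaxes_mm = c(22, 18, 12), lesions = lesions,
                         noise = noise, seed = seed))
}
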