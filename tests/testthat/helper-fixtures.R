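# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately use naive algorithms distinct
# from the package's implementation paths.

# Disc mask in an h x w matrix (1-based centre, pixel units).
disc_mask <- function(h, w, cr, cc, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt((rows - cr)^2 + (cols - cc)^2) <= r
}

# Brute-force 2-D convolution with replicate border padding.
dense_conv2 <- function(image, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      ii <- min(max(i + a, 1L), h)
      jj <- min(max(j + b, 1L), w)
      acc <- acc + image[ii, jj] * kernel[kr + 1L + a, kc + 1L + b]
    }
    out[i, j] <- acc
  }
  out
}

# Exhaustive split-point threshold oracle: try every boundary between
# adjacent distinct values, computing within-class SSE naively.
split_oracle <- function(v) {
  ux <- sort(unique(v))
  best <- Inf; best_thr <- NA
  for (s in seq_len(length(ux) - 1L)) {
    thr <- (ux[s] + ux[s + 1L]) / 2
    lo <- v[v <= thr]; hi <- v[v > thr]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best) { best <- sse; best_thr <- thr }
  }
  best_thr
}

# Per-region mean/area oracle computed one label at a time.
region_stats_oracle <- function(labels, image) {
  ids <- sort(unique(labels[labels > 0]))
  do.call(rbind, lapply(ids, function(id) {
    px <- labels == id
    data.frame(label = id, area = sum(px), mean = mean(image[px]))
  }))
}

# Small noise-free field used by several deterministic tests.
clean_field <- function(n = 20, seed = 5, shape = c(256L, 256L),
                        touching = 0, noise_sd = 0,
                        background_amplitude = 0, ...) {
  simulate_field(simulation_config(
    image_shape = shape, n_cells = n, touching_fraction = touching,
    noise_sd = noise_sd, background_amplitude = background_amplitude,
    seed = seed, ...))
}

# Synthetic PDB writer: a chain of glycine residues, one or more atoms
# per residue at given coordinates. coords: data.frame(resno, elety, x, y, z).
write_synthetic_pdb <- function(coords, path, het_rows = NULL) {
  fmt <- function(i, type, resno, elety, x, y, z)
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            type, i, elety, "GLY", "A", resno, x, y, z)
  lines <- character(0)
  for (i in seq_len(nrow(coords)))
    lines <- c(lines, fmt(i, "ATOM", coords$resno[i], coords$elety[i],
                          coords$x[i], coords$y[i], coords$z[i]))
  if (!is.null(het_rows))
    for (j in seq_len(nrow(het_rows)))
      lines <- c(lines, fmt(nrow(coords) + j, "HETATM", het_rows$resno[j],
                            het_rows$elety[j], het_rows$x[j], het_rows$y[j],
                            het_rows$z[j]))
  writeLines(c(lines, "END"), path)
  path
}

# Atom table constructor for in-memory distance tests.
atoms <- function(x, y, z, resno = seq_along(x)) {
  data.frame(resno = resno, resid = "GLY", elety = "CA", chain = "A",
             x = x, y = y, z = z)
}
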