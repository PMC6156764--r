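#' Simulation configuration for synthetic three-channel fields
#'
#' Builds and validates the parameter set of the synthetic microscopy
#' generator. The generator emulates a slide-scanner field of roundish
#' nuclei: a DAPI channel containing every nucleus, a Flag channel whose
#' per-cell intensity follows a bimodal (non-transfected / transfected)
#' distribution, and an EdU channel whose per-cell intensity is drawn from
#' a positive or negative mode according to the cell's proliferation state.
#' All intensities live on a float scale in \[0, 1\] and are quantized to
#' 16 bit only on TIFF export.
#'
#' @param image_shape integer(2), image height and width in pixels.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param n_cells number of nuclei to place (>= 1).
#' @param radius_mean,radius_sd mean and SD of nucleus radii in pixels.
#' @param touching_fraction fraction of cells deliberately placed so close
#'   to a neighbour that the two nuclei fuse into one connected blob
#'   (centre distance 0.65-0.80 of the summed radii); these are the cases
#'   the watershed stage must split.
#' @param transfected_fraction probability that a cell is transfected.
#' @param edu_fraction_transfected,edu_fraction_control probability of EdU
#'   positivity for transfected and non-transfected cells respectively.
#' @param dapi_mean,dapi_sd per-cell DAPI intensity distribution.
#' @param flag_mean_neg,flag_mean_pos,flag_sd the two modes and common SD
#'   of the per-cell Flag marker intensity (`flag_mean_pos` must exceed
#'   `flag_mean_neg`).
#' @param edu_mean_pos,edu_mean_neg,edu_sd per-cell EdU intensity modes.
#' @param background_amplitude amplitude of the smooth low-frequency
#'   background added to every channel.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param seed integer seed; identical configurations (including the seed)
#'   produce bit-identical fields.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_cells = 50, seed = 7)
#' field <- simulate_field(cfg)
simulation_config <- function(image_shape = c(512L, 512L),
                              pixel_size = 0.65,
                              n_cells = 300L,
                              radius_mean = 8,
                              radius_sd = 1.2,
                              touching_fraction = 0.10,
                              transfected_fraction = 0.40,
                              edu_fraction_transfected = 0.20,
                              edu_fraction_control = 0.50,
                              dapi_mean = 0.55,
                              dapi_sd = 0.08,
                              flag_mean_neg = 0.06,
                              flag_mean_pos = 0.50,
                              flag_sd = 0.06,
                              edu_mean_pos = 0.55,
                              edu_mean_neg = 0.04,
                              edu_sd = 0.06,
                              background_amplitude = 0.05,
                              noise_sd = 0.02,
                              seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    n_cells = as.integer(n_cells),
    radius_mean = radius_mean, radius_sd = radius_sd,
    touching_fraction = touching_fraction,
    transfected_fraction = transfected_fraction,
    edu_fraction_transfected = edu_fraction_transfected,
    edu_fraction_control = edu_fraction_control,
    dapi_mean = dapi_mean, dapi_sd = dapi_sd,
    flag_mean_neg = flag_mean_neg, flag_mean_pos = flag_mean_pos,
    flag_sd = flag_sd,
    edu_mean_pos = edu_mean_pos, edu_mean_neg = edu_mean_neg,
    edu_sd = edu_sd,
    background_amplitude = background_amplitude,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 32L))
    stop("image_shape must be two integers >= 32")
  fracs <- c(cfg$touching_fraction, cfg$transfected_fraction,
             cfg$edu_fraction_transfected, cfg$edu_fraction_control)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must lie in [0, 1]")
  if (cfg$n_cells < 1L) stop("n_cells must be >= 1")
  if (cfg$radius_mean <= 0) stop("radius_mean must be positive")
  if (cfg$flag_mean_pos <= cfg$flag_mean_neg)
    stop("flag_mean_pos must exceed flag_mean_neg")
  if (cfg$pixel_size <= 0) stop("pixel_size must be positive")
  if (cfg$noise_sd < 0 || cfg$background_amplitude < 0)
    stop("noise_sd and background_amplitude must be non-negative")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic field configuration\n")
  cat(sprintf("  field: %d x %d px (%.3g um/px), %d cells, %.0f%% fused pairs\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_cells,
              100 * x$touching_fraction))
  cat(sprintf("  transfected fraction %.2f; EdU+ fraction %.2f (transf.) / %.2f (control)\n",
              x$transfected_fraction, x$edu_fraction_transfected,
              x$edu_fraction_control))
  cat(sprintf("  background %.3g, noise sd %.3g, seed %d\n",
              x$background_amplitude, x$noise_sd, x$seed))
  invisible(x)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Guarantees bit-identical output per seed.
with_field_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Nucleus edge profile: flat top inside the ellipse, Gaussian taper outside,
# truncated 3 px past the boundary so nearby cells do not bleed into each
# other's ground-truth masks.
.edge_sigma <- 1.2
.edge_reach <- 3

#' Simulate a three-channel microscopy field with ground truth
#'
#' Places elliptical nuclei with Gaussian-profile edges (some deliberately
#' fused), draws per-cell transfection and proliferation states and channel
#' intensity levels, renders the DAPI/Flag/EdU channels, and adds a smooth
#' low-frequency background plus Gaussian pixel noise. Pixel coordinates
#' are 0-based `(row, col)`.
#'
#' @param config a [simulation_config()].
#' @return An object of class `sim_field`: a list with
#'   \describe{
#'     \item{channels}{named list of numeric matrices `dapi`, `flag`, `edu`
#'       in \[0, 1\].}
#'     \item{truth}{data frame of per-cell ground truth: `id`, `center_row`,
#'       `center_col` (0-based), `radius`, `transfected`, `proliferating`,
#'       and the drawn per-cell intensity levels `dapi_level`, `flag_level`,
#'       `edu_level`.}
#'     \item{label_map}{integer matrix, the true label map (0 = background,
#'       labels match `truth$id`).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_field <- function(config) {
  validate_simulation_config(config)
  with_field_seed(config$seed, simulate_field_impl(config))
}

simulate_field_impl <- function(cfg) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  n <- cfg$n_cells

  radii <- pmax(2, stats::rnorm(n, cfg$radius_mean, cfg$radius_sd))
  ecc <- stats::runif(n, 0, 0.15)          # mild ellipticity
  theta <- stats::runif(n, 0, pi)
  n_touch <- round(cfg$touching_fraction * n)
  touching <- rep(FALSE, n)
  if (n_touch > 0 && n > 1) touching[sample(2:n, min(n_touch, n - 1))] <- TRUE

  centers <- matrix(NA_real_, n, 2)
  max_attempts <- 20000L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      if (touching[i]) {
        j <- sample(which(!is.na(centers[, 1])), 1L)
        d <- stats::runif(1, 0.65, 0.80) * (radii[i] + radii[j])
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- centers[j, ] + d * c(cos(ang), sin(ang))
        partner <- j
      } else {
        cand <- c(stats::runif(1, radii[i] + 2, H - radii[i] - 2),
                  stats::runif(1, radii[i] + 2, W - radii[i] - 2))
        partner <- 0L
      }
      if (cand[1] < radii[i] + 2 || cand[1] > H - radii[i] - 2 ||
          cand[2] < radii[i] + 2 || cand[2] > W - radii[i] - 2) next
      ok <- TRUE
      prev <- which(!is.na(centers[, 1]))
      if (length(prev)) {
        dd <- sqrt((centers[prev, 1] - cand[1])^2 +
                   (centers[prev, 2] - cand[2])^2)
        lim <- radii[prev] + radii[i] + .edge_reach + 1
        lim[prev == partner] <- 0          # the chosen partner may touch
        ok <- all(dd >= lim)
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(
        "could not place cell %d of %d after %d attempts: n_cells too large for a %dx%d field at radius_mean %.1f",
        i, n, max_attempts, H, W, cfg$radius_mean))
  }

  transfected <- stats::runif(n) < cfg$transfected_fraction
  p_edu <- ifelse(transfected, cfg$edu_fraction_transfected,
                  cfg$edu_fraction_control)
  proliferating <- stats::runif(n) < p_edu

  dapi_level <- pmax(0.05, stats::rnorm(n, cfg$dapi_mean, cfg$dapi_sd))
  flag_level <- pmax(0, stats::rnorm(
    n, ifelse(transfected, cfg$flag_mean_pos, cfg$flag_mean_neg), cfg$flag_sd))
  edu_level <- pmax(0, stats::rnorm(
    n, ifelse(proliferating, cfg$edu_mean_pos, cfg$edu_mean_neg), cfg$edu_sd))

  dapi <- matrix(0, H, W); flag <- matrix(0, H, W); edu <- matrix(0, H, W)
  labels <- matrix(0L, H, W)
  claim <- matrix(Inf, H, W)               # elliptical radius of current owner

  for (i in seq_len(n)) {
    r <- radii[i]
    a <- r * (1 + ecc[i]); b <- r / (1 + ecc[i])
    reach <- ceiling(a + .edge_reach)
    r0 <- max(1, floor(centers[i, 1] - reach)); r1 <- min(H, ceiling(centers[i, 1] + reach))
    c0 <- max(1, floor(centers[i, 2] - reach)); c1 <- min(W, ceiling(centers[i, 2] + reach))
    rows <- r0:r1; cols <- c0:c1
    dy <- rows - centers[i, 1]
    dx <- cols - centers[i, 2]
    # rotate into the ellipse frame
    ct <- cos(theta[i]); st <- sin(theta[i])
    u <- outer(dy, dx, function(y, x) (y * ct + x * st) / a)
    v <- outer(dy, dx, function(y, x) (-y * st + x * ct) / b)
    rho <- sqrt(u^2 + v^2)                 # 1 at the nucleus boundary
    excess <- pmax(0, (rho - 1) * r)       # px beyond the boundary
    prof <- exp(-excess^2 / (2 * .edge_sigma^2))
    prof[excess > .edge_reach] <- 0
    inside <- rho <= 1

    sub <- function(m) m[rows, cols, drop = FALSE]
    dapi[rows, cols] <- pmax(sub(dapi), dapi_level[i] * prof)
    flag[rows, cols] <- pmax(sub(flag), flag_level[i] * prof)
    edu[rows, cols]  <- pmax(sub(edu),  edu_level[i] * prof)

    lab_sub <- labels[rows, cols, drop = FALSE]
    claim_sub <- claim[rows, cols, drop = FALSE]
    take <- inside & rho < claim_sub       # contested px go to the closer cell
    lab_sub[take] <- i
    claim_sub[take] <- rho[take]
    labels[rows, cols] <- lab_sub
    claim[rows, cols] <- claim_sub
  }

  if (cfg$background_amplitude > 0) {
    for (ch in c("dapi", "flag", "edu")) {
      f1 <- stats::runif(1, 0.5, 1.5); f2 <- stats::runif(1, 0.5, 1.5)
      p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
      bg <- cfg$background_amplitude *
        outer(0.5 * (1 + sin(2 * pi * f1 * seq_len(H) / H + p1)),
              0.5 * (1 + cos(2 * pi * f2 * seq_len(W) / W + p2)))
      m <- get(ch); m <- m + bg; assign(ch, m)
    }
  }
  if (cfg$noise_sd > 0) {
    dapi <- dapi + stats::rnorm(H * W, 0, cfg$noise_sd)
    flag <- flag + stats::rnorm(H * W, 0, cfg$noise_sd)
    edu  <- edu  + stats::rnorm(H * W, 0, cfg$noise_sd)
  }
  clamp <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }

  truth <- data.frame(
    id = seq_len(n),
    center_row = centers[, 1] - 1,         # 0-based, matches region tables
    center_col = centers[, 2] - 1,
    radius = radii,
    touching = touching,
    transfected = transfected,
    proliferating = proliferating,
    dapi_level = dapi_level,
    flag_level = flag_level,
    edu_level = edu_level
  )

  structure(list(
    channels = list(dapi = clamp(dapi), flag = clamp(flag), edu = clamp(edu)),
    truth = truth,
    label_map = labels,
    config = cfg
  ), class = "sim_field")
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("Synthetic field: %d x %d px, %d cells (%d transfected, %d EdU+)\n",
              nrow(x$channels$dapi), ncol(x$channels$dapi), nrow(x$truth),
              sum(x$truth$transfected), sum(x$truth$proliferating)))
  invisible(x)
}

#' Write a simulated field to disk
#'
#' Exports the three channels as 16-bit grayscale TIFFs
#' (`<prefix>_dapi.tif`, `_flag.tif`, `_edu.tif`), the true label map as a
#' 16-bit TIFF (`<prefix>_labels.tif`), the per-cell ground truth as CSV and
#' the generating configuration as a plain `key: value` file, so a complete
#' field is reproducible from the manifest alone.
#'
#' @param field a `sim_field` from [simulate_field()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default `"field"`.
#' @return Invisibly, the named vector of written paths.
#' @export
simulate_to_dir <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "sim_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
    flag = file.path(dir, paste0(prefix, "_flag.tif")),
    edu = file.path(dir, paste0(prefix, "_edu.tif")),
    labels = file.path(dir, paste0(prefix, "_labels.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")),
    config = file.path(dir, paste0(prefix, "_config.txt"))
  )
  for (ch in c("dapi", "flag", "edu"))
    write_channel_tiff(field$channels[[ch]], paths[[ch]])
  write_label_tiff(field$label_map, paths[["labels"]])
  utils::write.csv(field$truth, paths[["truth"]], row.names = FALSE)
  write_plain_config(unclass(field$config), paths[["config"]])
  invisible(paths)
}
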