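#' Simulate circular cell-cycle phases
#'
#' Draws i.i.d. phases from the uniform distribution on `[0, 2*pi)` or from
#' a von Mises mixture (Best-Fisher rejection sampling).
#'
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param distribution `"uniform"` (default) or `"vonmises_mixture"`.
#' @param mu,kappa,weights Mixture parameters (means in radians,
#'   concentrations, mixing weights) for the von Mises option.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
simulate_phases <- function(n, seed = 1,
                            distribution = c("uniform", "vonmises_mixture"),
                            mu = c(pi / 2, 3 * pi / 2), kappa = c(2, 2),
                            weights = NULL) {
  if (n < 1) stop("n must be positive")
  distribution <- match.arg(distribution)
  with_seed(seed, {
    if (distribution == "uniform") return(runif(n, 0, 2 * pi))
    if (is.null(weights)) weights <- rep(1 / length(mu), length(mu))
    comp <- sample.int(length(mu), n, replace = TRUE, prob = weights)
    vapply(comp, function(j) rvonmises1(mu[j], kappa[j]), numeric(1))
  })
}

# One von Mises draw (Best & Fisher 1979 wrapped-Cauchy envelope).
rvonmises1 <- function(mu, kappa) {
  if (kappa < 1e-8) return(runif(1, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u1 <- runif(1); u2 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- runif(1)
      return((mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi))
    }
  }
}

#' Build a ground-truth specification for a paired synthetic experiment
#'
#' Defines the cells (true phase, individual, plate, library size) and the
#' genes (amplitude, phase offset, baseline, noise level, cyclic flag) of a
#' synthetic paired FUCCI + scRNA-seq dataset. Defaults emulate the scale
#' of a C1 experiment: six individuals in a balanced design, library sizes
#' around 56,724 +/- 12,762 molecules, cyclic genes of amplitude 1 with
#' Gaussian noise of SD 0.3 on the normalized scale.
#'
#' @param n_cells,n_genes Dataset dimensions (defaults 300 cells, 220
#'   genes).
#' @param n_cyclic Number of cyclic genes (default 20; the rest have
#'   amplitude 0).
#' @param n_individuals,n_plates Batch structure (defaults 6 and 4; cells
#'   are assigned round-robin).
#' @param amplitude,noise_sd Cyclic amplitude and residual SD on the
#'   normalized scale (defaults 1 and 0.3).
#' @param library_size_mean,library_size_sd Per-cell molecule totals
#'   (defaults 56724 and 12762, floored at 1000).
#' @param seed Integer seed.
#' @return A list of class `"synthetic_truth"` with `cells` and `genes`
#'   data frames and the seed.
#' @export
simulate_truth <- function(n_cells = 300, n_genes = 220, n_cyclic = 20,
                           n_individuals = 6, n_plates = 4, amplitude = 1,
                           noise_sd = 0.3, library_size_mean = 56724,
                           library_size_sd = 12762, seed = 1) {
  if (n_cyclic > n_genes) stop("n_cyclic cannot exceed n_genes")
  thetas <- simulate_phases(n_cells, seed = seed)
  with_seed(seed + 1L, {
    cells <- data.frame(
      cell_id = sprintf("cell_%04d", seq_len(n_cells)),
      theta_true = thetas,
      individual_id = sprintf("NA%05d",
                              18500 + (seq_len(n_cells) - 1L) %% n_individuals),
      plate_id = sprintf("plate_%02d",
                         1L + (seq_len(n_cells) - 1L) %/%
                           ceiling(n_cells / n_plates)),
      library_size = pmax(1000, round(rnorm(n_cells, library_size_mean,
                                            library_size_sd))))
    genes <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      amplitude = c(rep(amplitude, n_cyclic),
                    rep(0, n_genes - n_cyclic)),
      phase_offset = runif(n_genes, 0, 2 * pi),
      baseline = rnorm(n_genes, 0, 1),
      noise_sd = rep(noise_sd, n_genes),
      is_cyclic = c(rep(TRUE, n_cyclic), rep(FALSE, n_genes - n_cyclic)))
    structure(list(cells = cells, genes = genes, seed = seed),
              class = "synthetic_truth")
  })
}

#' Simulate cyclic expression on the normalized and count scales
#'
#' Normalized scale:
#' `y[g, c] = amplitude[g] * cos(theta[c] + offset[g]) + eps`,
#' `eps ~ N(0, noise_sd[g]^2)`. Count scale: molecule counts are Poisson
#' with per-cell means `library_size[c] * p[g, c]`, where `p[, c]` is the
#' softmax over genes of `baseline[g] + amplitude[g] * cos(theta[c] +
#' offset[g]) + eps`, so cyclic structure, library-size variation and
#' dropout at small totals all appear in the counts. The same Gaussian
#' noise term drives both scales.
#'
#' @param truth A [simulate_truth()] object.
#' @param seed Seed (defaults to `truth$seed + 2`).
#' @param dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) gives Poisson counts.
#' @return List with `normalized` (genes x cells) and `counts`
#'   (genes x cells, integer), both with identifiers.
#' @export
simulate_cyclic_expression <- function(truth, seed = NULL,
                                       dispersion = NULL) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  if (is.null(seed)) seed <- truth$seed + 2L
  g <- truth$genes; cl <- truth$cells
  G <- nrow(g); n <- nrow(cl)
  with_seed(seed, {
    signal <- outer(seq_len(G), seq_len(n), function(i, j) {
      g$amplitude[i] * cos(cl$theta_true[j] + g$phase_offset[i])
    })
    eps <- matrix(rnorm(G * n, 0, g$noise_sd), G, n)
    normalized <- signal + eps
    logmean <- g$baseline + signal + eps
    p <- apply(logmean, 2, function(x) { e <- exp(x - max(x)); e / sum(e) })
    mu <- sweep(p, 2, cl$library_size, "*")
    counts <- if (is.null(dispersion)) {
      matrix(rpois(G * n, mu), G, n)
    } else {
      matrix(stats::rnbinom(G * n, size = dispersion, mu = mu), G, n)
    }
    dimnames(normalized) <- dimnames(counts) <-
      list(g$gene_id, cl$cell_id)
    list(normalized = normalized, counts = counts)
  })
}

#' Simulate raw FUCCI reporter scores with batch structure
#'
#' The two reporters oscillate in quadrature:
#' `egfp = sin(theta) + plate + individual + eps` and
#' `mcherry = cos(theta) + plate + individual + eps`. A constant DAPI score
#' with the same additive structure is included for completeness.
#'
#' @param thetas True phases.
#' @param plates,individuals Per-cell batch labels.
#' @param noise_sd Gaussian noise SD (default 0.05).
#' @param plate_offsets,individual_offsets Named offset vectors (default all
#'   zero).
#' @param seed Integer seed.
#' @return Data frame with `cell_id`, the three scores, `plate_id`,
#'   `individual_id`; attribute `"corrected"` is unset (raw scores).
#' @export
simulate_fucci_scores <- function(thetas, plates, individuals,
                                  noise_sd = 0.05, plate_offsets = NULL,
                                  individual_offsets = NULL, seed = 1) {
  n <- length(thetas)
  plates <- as.character(plates); individuals <- as.character(individuals)
  if (length(plates) != n || length(individuals) != n)
    stop("plates and individuals must be aligned with thetas")
  off <- function(x, levels_of) {
    if (is.null(x)) return(stats::setNames(rep(0, length(levels_of)), levels_of))
    if (is.null(names(x))) names(x) <- levels_of
    x[levels_of]
  }
  po <- off(plate_offsets, unique(plates))
  io <- off(individual_offsets, unique(individuals))
  with_seed(seed, {
    base <- po[plates] + io[individuals]
    data.frame(
      cell_id = names(thetas) %||% sprintf("cell_%04d", seq_len(n)),
      egfp_score = sin(thetas) + base + rnorm(n, 0, noise_sd),
      mcherry_score = cos(thetas) + base + rnorm(n, 0, noise_sd),
      dapi_score = 3 + base + rnorm(n, 0, noise_sd),
      plate_id = plates, individual_id = individuals,
      row.names = NULL)
  })
}

#' Binomially thin a count matrix
#'
#' Emulates lower sequencing depth: every count is replaced by a
#' `Binomial(count, 1/factor)` draw, so the expected total shrinks by the
#' thinning factor while zeros stay zero.
#'
#' @param counts Genes-by-cells integer matrix.
#' @param factor Thinning factor, at least 1 (1 returns the input).
#' @param seed Integer seed.
#' @return Thinned matrix of the same shape.
#' @export
thin_counts <- function(counts, factor, seed = 1) {
  counts <- validate_counts(counts)
  if (factor < 1) stop("thinning factor must be >= 1")
  if (factor == 1) return(counts)
  with_seed(seed, {
    thinned <- matrix(rbinom(length(counts), as.integer(counts), 1 / factor),
                      nrow(counts), ncol(counts), dimnames = dimnames(counts))
    thinned
  })
}

#' Simulate per-well fluorescence channel images
#'
#' Constant-intensity discs on a constant background with additive Gaussian
#' pixel noise, clipped at zero — the idealized geometry the imaging module
#' assumes.
#'
#' @param nuclei Matrix with columns `row`, `col`, `radius` (one row per
#'   nucleus).
#' @param intensities Named list/vector of disc intensities per channel,
#'   e.g. `c(dapi = 0.8, egfp = 0.3, mcherry = 0.5)`.
#' @param background Background level (default 0.1).
#' @param noise_sd Pixel noise SD (default 0; noiseless).
#' @param size Image side in pixels (default 300).
#' @param seed Integer seed.
#' @return Named list of channel matrices.
#' @export
simulate_channel_images <- function(nuclei, intensities,
                                    background = 0.1, noise_sd = 0,
                                    size = 300, seed = 1) {
  nuclei <- as.matrix(nuclei)
  if (!all(c("row", "col", "radius") %in% colnames(nuclei)))
    stop("nuclei must have columns row, col, radius")
  if (any(nuclei[, "row"] - nuclei[, "radius"] < 1 |
          nuclei[, "row"] + nuclei[, "radius"] > size |
          nuclei[, "col"] - nuclei[, "radius"] < 1 |
          nuclei[, "col"] + nuclei[, "radius"] > size))
    stop("discs must lie inside the image bounds")
  if (nrow(nuclei) > 1) {
    dd <- as.matrix(stats::dist(nuclei[, c("row", "col")]))
    rr <- outer(nuclei[, "radius"], nuclei[, "radius"], "+")
    diag(dd) <- Inf
    if (any(dd < rr)) warning("overlapping discs")
  }
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  disc_mask <- matrix(FALSE, size, size)
  per_disc <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    per_disc[[i]] <- (rows - nuclei[i, "row"])^2 +
      (cols - nuclei[i, "col"])^2 <= nuclei[i, "radius"]^2
    disc_mask <- disc_mask | per_disc[[i]]
  }
  with_seed(seed, {
    out <- lapply(stats::setNames(names(intensities), names(intensities)),
                  function(ch) {
      img <- matrix(background, size, size)
      for (i in seq_len(nrow(nuclei)))
        img[per_disc[[i]]] <- background + intensities[[ch]]
      if (noise_sd > 0)
        img <- img + matrix(rnorm(size * size, 0, noise_sd), size, size)
      pmax(img, 0)
    })
    out
  })
}
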