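#' Specification of a synthetic texture-phantom dataset
#'
#' Phantoms are 64^3, 1 mm isotropic patches: a spherical "nodule" of random
#' radius on a uniform lung background, carrying a correlated random texture
#' whose correlation length differs between the two classes. Intensity means
#' are identical between classes, so any class separation is texture-only
#' (mean shifts are invisible to LBP anyway, by its monotone-offset
#' invariance).
#'
#' Defaults emulate a low-dose chest-CT nodule patch: lung-parenchyma
#' background (-800 HU), a soft-tissue nodule 200 HU above background,
#' 20 HU observation noise, nodule radii 10-20 mm, and texture correlation
#' lengths of 1 voxel (benign) vs 4 voxels (cancer).
#'
#' @param n_per_class patches per class (>= 2).
#' @param lambda_benign,lambda_cancer Gaussian correlation length (voxels)
#'   of the texture field for each class; must be > 0.
#' @param noise_sd observation noise standard deviation (HU).
#' @param radius_range nodule radius range (mm), inside the 64^3 patch.
#' @param background background level (HU).
#' @param contrast foreground contrast (HU): both the nodule's offset above
#'   background and the texture amplitude, so `contrast = 0` with
#'   `noise_sd = 0` yields a constant patch.
#' @param seed dataset-level seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_per_class = 20, lambda_benign = 1,
                         lambda_cancer = 4, noise_sd = 20,
                         radius_range = c(10, 20), background = -800,
                         contrast = 200, seed = 1) {
  stopifnot(n_per_class >= 2, lambda_benign > 0, lambda_cancer > 0,
            noise_sd >= 0, length(radius_range) == 2,
            radius_range[1] > 0, radius_range[2] >= radius_range[1],
            radius_range[2] < 32)
  structure(list(n_per_class = as.integer(n_per_class),
                 lambda_benign = lambda_benign, lambda_cancer = lambda_cancer,
                 noise_sd = noise_sd, radius_range = radius_range,
                 background = background, contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing of a 64^3 array: a row-normalized 1D kernel
# matrix is applied along each axis in turn (row normalization keeps the
# field unbiased at the faces).
#' @noRd
.smooth3d <- function(arr, lambda) {
  n <- dim(arr)[1]
  K <- outer(seq_len(n), seq_len(n), function(i, j) dnorm((i - j) / lambda))
  K <- K / rowSums(K)
  a <- K %*% matrix(arr, n, n * n)                               # x axis
  a <- array(a, dim(arr))
  a <- aperm(array(K %*% matrix(aperm(a, c(2, 1, 3)), n, n * n),
                   dim(arr)), c(2, 1, 3))                        # y axis
  aperm(array(K %*% matrix(aperm(a, c(3, 1, 2)), n, n * n),
              dim(arr)), c(2, 3, 1))                             # z axis
}

#' Generate one labelled texture phantom
#'
#' Gaussian-filtered white noise (filter width = the class's correlation
#' length) is standardized, scaled by the contrast, masked to a centered
#' sphere of random radius, offset by the contrast on the background level,
#' and finally perturbed by observation noise. Deterministic given the spec,
#' class and RNG state; draws come from the current RNG stream.
#'
#' @param spec a [phantom_spec()].
#' @param class_label 0 (benign) or 1 (cancer).
#' @param id provenance identifier.
#' @return A [volume_patch()].
#' @export
generate_phantom <- function(spec, class_label, id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), class_label %in% c(0, 1))
  lambda <- if (class_label == 1) spec$lambda_cancer else spec$lambda_benign
  field <- .smooth3d(array(rnorm(64^3), c(64, 64, 64)), lambda)
  field <- field / sd(field)
  radius <- runif(1, spec$radius_range[1], spec$radius_range[2])
  ax <- (0:63) + 0.5 - 32                       # voxel centers, mm from patch center
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- d2 <= radius^2
  arr <- spec$background + mask * (spec$contrast + spec$contrast * field)
  if (spec$noise_sd > 0) arr <- arr + array(rnorm(64^3, sd = spec$noise_sd),
                                            c(64, 64, 64))
  volume_patch(arr, provenance = list(id = id, center = c(32, 32, 32),
                                      label = as.integer(class_label)))
}

#' Generate a labelled phantom dataset
#'
#' `n_per_class` phantoms per class, deterministically shuffled under the
#' spec seed. If `dir` is given, each phantom is written as a NIfTI volume
#' together with a `manifest.csv` (`id,path,cx,cy,cz,label`), so the full
#' disk-based pipeline ([load_dataset()]) can run on synthetic data exactly
#' as it would on clinical data.
#'
#' @param spec a [phantom_spec()].
#' @param dir optional output directory.
#' @return A `cadx_dataset`; when `dir` is given, with attribute
#'   `manifest` (path to the manifest CSV).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  ds <- with_seed(spec$seed, {
    patches <- list(); labels <- integer(0)
    for (cl in c(0L, 1L)) {
      for (i in seq_len(spec$n_per_class)) {
        id <- sprintf("phantom_%s_%02d", c("benign", "cancer")[cl + 1L], i)
        patches[[length(patches) + 1L]] <- generate_phantom(spec, cl, id = id)
        labels <- c(labels, cl)
      }
    }
    perm <- sample.int(length(patches))
    cadx_dataset(patches[perm], labels[perm],
                 ids = vapply(patches[perm], function(p) p$provenance$id,
                              character(1)))
  })
  if (!is.null(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
    rows <- lapply(seq_along(ds$patches), function(i) {
      fn <- paste0(ds$ids[i], ".nii.gz")
      write_volume(ds$patches[[i]], file.path(dir, fn))
      data.frame(id = ds$ids[i], path = fn, cx = 32, cy = 32, cz = 32,
                 label = ds$labels[i])
    })
    manifest <- file.path(dir, "manifest.csv")
    write.csv(do.call(rbind, rows), manifest, row.names = FALSE, quote = FALSE)
    attr(ds, "manifest") <- manifest
  }
  ds
}
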