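#' LBP texture operator configuration
#'
#' @param R sampling radius in pixels (> 0).
#' @param P number of circular samples; at least 4 and divisible by 4 so
#'   that 90-degree rotations map sample positions onto sample positions.
#' @return An object of class `lbp_config`.
#' @export
lbp_config <- function(R, P) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) stop("R must be > 0")
  P <- as.integer(P)
  if (length(P) != 1L || P < 4L || P %% 4L != 0L)
    stop("P must be >= 4 and divisible by 4")
  structure(list(R = as.numeric(R), P = P, margin = as.integer(ceiling(R))),
            class = "lbp_config")
}

# Circle offsets shared by the naive R sampler and the C++ code-map path.
# Neighbor i sits at angle 2*pi*i/P counter-clockwise from the positive
# first-axis direction. Offsets within 1e-9 of a lattice point are snapped
# so axis-aligned samples (e.g. R = 1, P = 4) carry no interpolation error.
#' @noRd
lbp_offsets <- function(config) {
  theta <- 2 * pi * (seq_len(config$P) - 1) / config$P
  dr <- config$R * cos(theta)
  dc <- config$R * sin(theta)
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  list(dr = snap(dr), dc = snap(dc))
}

# Bilinear interpolation of the difference from the center intensity.
# Interpolating corner differences keeps d exactly 0 on constant
# neighborhoods (the four weights need not sum to 1 in floating point) and
# mirrors the compiled code-map route term for term, so the two routes agree
# bit for bit.
#' @noRd
.bilinear_diff1 <- function(S, rr, cc, center) {
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  i0 <- r0 + 1L; j0 <- c0 + 1L
  i1 <- if (fr > 0) i0 + 1L else i0
  j1 <- if (fc > 0) j0 + 1L else j0
  (1 - fr) * (1 - fc) * (S[i0, j0] - center) +
    fr * (1 - fc) * (S[i1, j0] - center) +
    (1 - fr) * fc * (S[i0, j1] - center) +
    fr * fc * (S[i1, j1] - center)
}

# P neighbor-minus-center differences of one pixel; shared by
# sample_neighbors and lbp_code.
#' @noRd
.neighbor_diffs <- function(slice, x, config) {
  m <- config$margin
  r <- x[1]; c <- x[2]
  if (r < m + 1 || r > nrow(slice) - m || c < m + 1 || c > ncol(slice) - m)
    stop("pixel (", r, ", ", c, ") is closer than ceiling(R) = ", m,
         " to a border")
  off <- lbp_offsets(config)
  center <- slice[r, c]
  vapply(seq_len(config$P), function(i)
    .bilinear_diff1(slice, (r - 1) + off$dr[i], (c - 1) + off$dc[i], center),
    numeric(1))
}

#' Sample the circular neighborhood of a pixel
#'
#' Returns the `P` neighbor intensities on the circle of radius `R` around
#' pixel `x`, obtained by bilinear interpolation. Neighbor `i` (starting at
#' 0) lies at angle `2*pi*i/P` counter-clockwise from the positive
#' first-axis direction.
#'
#' @param slice 2D numeric matrix.
#' @param x length-2 pixel coordinate (row, col), 1-based, at least
#'   `ceiling(R)` away from every border.
#' @param config an [lbp_config()].
#' @return Numeric vector of length `P`.
#' @export
sample_neighbors <- function(slice, x, config) {
  stopifnot(inherits(config, "lbp_config"), is.matrix(slice))
  slice[x[1], x[2]] + .neighbor_diffs(slice, x, config)
}

#' Naive local binary pattern code of one pixel
#'
#' `code = sum_i 2^i * s(d_i)` with `d_i` the difference between neighbor
#' `i` and the center, and `s(v) = 1` iff `v >= 0`. Stored as a double, which
#' is exact for `P <= 52`.
#'
#' @inheritParams sample_neighbors
#' @return The unmapped LBP code (numeric scalar in `[0, 2^P - 1]`).
#' @export
lbp_code <- function(slice, x, config) {
  stopifnot(inherits(config, "lbp_config"), is.matrix(slice))
  bits <- as.numeric(.neighbor_diffs(slice, x, config) >= 0)
  sum(bits * 2^(seq_along(bits) - 1))
}

#' Rotation-invariant uniform (riu2) mapping of an LBP code
#'
#' Let `U` be the number of circular 0/1 transitions of the `P`-bit pattern.
#' Uniform patterns (`U <= 2`) map to their count of 1-bits (0..P); all
#' others map to the catch-all bin `P + 1`.
#'
#' @param code unmapped LBP code in `[0, 2^P - 1]`.
#' @param P number of bits.
#' @return Integer in `{0, ..., P + 1}`.
#' @export
riu2_map <- function(code, P) {
  stopifnot(code >= 0, code < 2^P)
  bits <- floor(code / 2^(0:(P - 1))) %% 2
  U <- sum(bits != bits[c(2:P, 1)])
  if (U <= 2) as.integer(sum(bits)) else as.integer(P + 1)
}

#' riu2 LBP code map of a 2D slice
#'
#' Computes the mapped code at every pixel of the valid region (a border
#' margin of `ceiling(R)` pixels is excluded rather than padded, so no
#' fabricated texture enters the histogram).
#'
#' @param slice 2D numeric matrix with each side at least `2*ceiling(R)+1`.
#' @param config an [lbp_config()].
#' @return Integer matrix of dim `(nrow-2m) x (ncol-2m)`, values in
#'   `{0, ..., P+1}`.
#' @export
lbp_slice <- function(slice, config) {
  stopifnot(inherits(config, "lbp_config"), is.matrix(slice))
  m <- config$margin
  if (nrow(slice) < 2 * m + 1 || ncol(slice) < 2 * m + 1)
    stop("slice too small: need at least ", 2 * m + 1, " pixels per side")
  off <- lbp_offsets(config)
  lbp_codemap_cpp(slice, off$dr, off$dc, m)
}

#' LBP-TOP feature vector of a 64^3 patch
#'
#' 2D riu2 LBP is computed on every XY, XZ and YZ slice of the patch; the
#' mapped codes of all slices of an orientation are pooled into one
#' `(P+2)`-bin histogram, each histogram is L1-normalized, and the three are
#' concatenated in order (XY, XZ, YZ), giving a vector of length `3*(P+2)`.
#'
#' @param patch a [volume_patch()] (or bare 64^3 array).
#' @param config an [lbp_config()].
#' @return Named numeric vector of length `3*(P+2)`; each orientation block
#'   sums to 1.
#' @export
lbp_top <- function(patch, config) {
  arr <- if (inherits(patch, "volume_patch")) patch$intensities else patch
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  off <- lbp_offsets(config)
  blocks <- lapply(0:2, function(axis) {
    h <- lbp_top_hist_cpp(arr, axis, off$dr, off$dc, config$margin)
    h / sum(h)
  })
  v <- c(blocks[[1]], blocks[[2]], blocks[[3]])
  names(v) <- as.vector(vapply(c("xy", "xz", "yz"), function(o)
    paste0(o, 0:(config$P + 1)), character(config$P + 2)))
  v
}

#' Compute the LBP-TOP feature matrix of a dataset
#'
#' @param dataset a `cadx_dataset`.
#' @param config an [lbp_config()].
#' @param cache optional environment; features are memoized under the key
#'   `"R=<R>,P=<P>"` so repeated searches over the four (R, P) combinations
#'   featurize each patch at most once per combination.
#' @return Numeric matrix, one row per patch, `3*(P+2)` columns.
#' @export
featurize_dataset <- function(dataset, config, cache = NULL) {
  key <- sprintf("R=%g,P=%d", config$R, config$P)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  X <- t(vapply(dataset$patches, function(p) lbp_top(p, config),
                numeric(3 * (config$P + 2))))
  rownames(X) <- dataset$ids
  if (!is.null(cache)) cache[[key]] <- X
  X
}

#' Write a feature matrix as TSV with a JSON sidecar
#'
#' Columns are `id`, `label`, `f0` .. `f{3(P+2)-1}`; the sidecar
#' `<path>.json` records `R` and `P`.
#'
#' @param features numeric matrix (rows = patches).
#' @param labels 0/1 vector.
#' @param ids identifiers.
#' @param config the [lbp_config()] that produced the features.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, labels, ids, config, path) {
  df <- data.frame(id = ids, label = as.integer(labels),
                   features, check.names = FALSE)
  names(df) <- c("id", "label", paste0("f", seq_len(ncol(features)) - 1))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(R = config$R, P = config$P), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature TSV written by [write_features()]
#'
#' @param path TSV path.
#' @return List with `features` (matrix), `labels`, `ids`, `config`.
#' @export
read_features <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(df[, grep("^f", names(df)), drop = FALSE])
  rownames(X) <- df$id
  list(features = X, labels = as.integer(df$label), ids = df$id,
       config = lbp_config(meta$R, meta$P))
}
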