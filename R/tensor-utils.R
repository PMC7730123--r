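# Gait-signature tensors are 32 x 11 x 3 arrays: 32 time-normalized frames
# per gait cycle, 10 bone channels plus one auxiliary channel, and 3 angles
# per channel.  Channel 11 carries (person height, distance between ankles, 0)
# in every frame.  In tabular form a cycle is one row of 32*11*3 = 1056
# values laid out frame-major, channel-middle, angle-minor.

GAIT_DIMS <- c(frames = 32L, channels = 11L, angles = 3L)

META_COLS <- c("cycle_id", "subject_id", "covariate", "cycle_index")

#' Column names of a flattened gait-signature tensor
#'
#' One gait cycle occupies one table row whose 1056 value columns are the
#' flattened 32 x 11 x 3 tensor in frame-major, channel-middle, angle-minor
#' order: `t01_b01_a1, t01_b01_a2, t01_b01_a3, t01_b02_a1, ...` where `t` is
#' the frame, `b` the bone/auxiliary channel, and `a` the angle slot.
#'
#' @return Character vector of length 1056.
#' @export
gait_feature_names <- function() {
  as.vector(vapply(seq_len(GAIT_DIMS[["frames"]]), function(f) {
    vapply(seq_len(GAIT_DIMS[["channels"]]), function(b) {
      sprintf("t%02d_b%02d_a%d", f, b, seq_len(GAIT_DIMS[["angles"]]))
    }, character(GAIT_DIMS[["angles"]]))
  }, character(GAIT_DIMS[["channels"]] * GAIT_DIMS[["angles"]])))
}

#' Flatten or restore a single gait-signature tensor
#'
#' `flatten_gait_tensor()` turns a 32 x 11 x 3 array into the 1056-long
#' vector used as a table row (frame-major, channel-middle, angle-minor);
#' `unflatten_gait_tensor()` inverts it.
#'
#' @param x A 32 x 11 x 3 numeric array.
#' @param v A numeric vector of length 1056 in row layout.
#' @return A named numeric vector, or a 32 x 11 x 3 array.
#' @export
flatten_gait_tensor <- function(x) {
  stopifnot(is.array(x), identical(dim(x), unname(GAIT_DIMS)))
  stats::setNames(as.vector(aperm(x, c(3L, 2L, 1L))), gait_feature_names())
}

#' @rdname flatten_gait_tensor
#' @export
unflatten_gait_tensor <- function(v) {
  stopifnot(length(v) == prod(GAIT_DIMS))
  aperm(array(as.numeric(v), dim = rev(unname(GAIT_DIMS))), c(3L, 2L, 1L))
}

# Feature columns of a gait/feature tibble: every numeric column that is not
# bookkeeping metadata or the label.
feature_cols <- function(data, label_col = "subject_id") {
  is_num <- vapply(data, is.numeric, logical(1))
  setdiff(names(data)[is_num], c(META_COLS, label_col))
}

# N x d numeric matrix + labels from a tibble.
feature_matrix <- function(data, label_col = "subject_id") {
  if (!label_col %in% names(data)) {
    stop("column `", label_col, "` not found in the data", call. = FALSE)
  }
  cols <- feature_cols(data, label_col)
  if (length(cols) == 0L) stop("no numeric feature columns found", call. = FALSE)
  x <- as.matrix(data[cols])
  storage.mode(x) <- "double"
  list(x = x, y = data[[label_col]], cols = cols)
}

# Stack the value columns of a gait tibble into a (32, 11, 3, N) array.
gait_to_array <- function(data) {
  cols <- gait_feature_names()
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop("data is missing ", length(missing),
         " gait tensor columns (e.g. ", missing[1], ")", call. = FALSE)
  }
  x <- t(as.matrix(data[cols]))  # 1056 x N, angle fastest within each row
  aperm(array(x, dim = c(rev(unname(GAIT_DIMS)), ncol(x))), c(3L, 2L, 1L, 4L))
}

# Inverse of gait_to_array(): (32, 11, 3, N) -> N x 1056 matrix.
array_to_rows <- function(arr) {
  n <- dim(arr)[4]
  m <- t(matrix(aperm(arr, c(3L, 2L, 1L, 4L)), ncol = n))
  colnames(m) <- gait_feature_names()
  m
}

# Mode-m unfolding of a k-way array: rows indexed by mode m, remaining modes
# in increasing order with the first of them varying fastest.
unfold_tensor <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

fold_tensor <- function(mat, mode, dims) {
  perm <- c(mode, setdiff(seq_along(dims), mode))
  aperm(array(mat, dim = dims[perm]), order(perm))
}

# Multiply array `x` along `mode` by matrix `m` (rows of `m` index the new
# mode dimension).
mode_multiply <- function(x, m, mode) {
  d <- dim(x)
  out_dims <- d
  out_dims[mode] <- nrow(m)
  fold_tensor(m %*% unfold_tensor(x, mode), mode, out_dims)
}
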