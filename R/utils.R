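# Internal helpers: RNG scoping, seed derivation, input coercion.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with a stream index through two rounds of a
#' multiplicative-congruential scramble, so that each view (or pipeline
#' stage) gets an independent, order-insensitive seed below 2^31.
#'
#' @param seed Master integer seed.
#' @param stream Non-negative integer stream index.
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream), length(stream) == 1)
  m <- 2^31
  # multipliers < 2^17 keep every intermediate product exactly representable
  x <- (abs(seed) + 747491 * (stream + 1)) %% m
  x <- (x * 69069 + 12345) %% m
  x <- (x * 30269 + stream + 1) %% m
  as.integer(x)
}

# Deterministic stream index from a string (polynomial hash, < 2^20).
string_stream <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 1048576
  as.integer(h)
}

# Coerce a data frame (first column = instance id when non-numeric, or any
# character/factor column named instance_id) or numeric matrix to a numeric
# matrix plus instance ids.
as_view_matrix <- function(data, arg = "data") {
  if (is.matrix(data)) {
    x <- data
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  } else if (is.data.frame(data)) {
    df <- data
    id_col <- which(names(df) == "instance_id")
    if (length(id_col) == 0 && ncol(df) >= 2 && !is.numeric(df[[1]])) id_col <- 1L
    if (length(id_col) > 0) {
      ids <- as.character(df[[id_col[1]]])
      df <- df[-id_col[1]]
    } else {
      ids <- rownames(data)
      if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
    }
    if (!all(vapply(df, is.numeric, logical(1)))) {
      stop(arg, " must contain only numeric feature columns (plus an instance id column)",
           call. = FALSE)
    }
    x <- as.matrix(df)
    rownames(x) <- ids
  } else {
    stop(arg, " must be a data frame or numeric matrix", call. = FALSE)
  }
  if (anyNA(x)) stop(arg, " contains missing values; impute or filter before clustering",
                     call. = FALSE)
  if (anyDuplicated(ids)) stop(arg, " has duplicated instance ids", call. = FALSE)
  if (nrow(x) < 3) stop(arg, " must have at least 3 instances", call. = FALSE)
  if (ncol(x) < 1) stop(arg, " must have at least 1 feature", call. = FALSE)
  list(x = x, ids = ids)
}

# Relabel an integer vector to contiguous 1..K by order of first appearance.
relabel_contiguous <- function(labels) {
  match(labels, unique(labels))
}

check_labels <- function(labels, n = NULL, arg = "labels") {
  if (is.factor(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || anyNA(labels)) {
    stop(arg, " must be an integer label vector without NAs", call. = FALSE)
  }
  if (!is.null(n) && length(labels) != n) {
    stop(arg, " has length ", length(labels), ", expected ", n, call. = FALSE)
  }
  as.integer(labels)
}
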