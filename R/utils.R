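# Shared internal helpers: seeding, validation, stratified splitting.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit seed derived from a base seed and a stage/tag name, so every
# stage of a pipeline gets its own reproducible stream. Arithmetic stays
# below 2^53, exact in doubles.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% 2147483629
  as.integer(((as.numeric(seed) %% 2147483629) * 48271 + h + 1) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

#' Stratified train/test split
#'
#' Splits samples into a training and a test set while preserving the class
#' proportions of `labels` (the 8:2 split used before multi-class training
#' mirrors this at synthetic scale).
#'
#' @param labels Vector of class labels, one per sample.
#' @param train_fraction Fraction assigned to the training set (default 0.8).
#' @param seed Integer seed controlling the split.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must be in (0, 1)")
  }
  labels <- as.character(labels)
  train <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- max(1L, round(length(idx) * train_fraction))
      train <- c(train, sort(sample(idx, n_tr)))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, balancing class membership across
#' folds. Every fold contains at least one sample of every class when
#' `k <= min(class size)`.
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the assignment.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  k <- assert_count(k, "k", min = 2L)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stopf("class '%s' has %d samples, fewer than k = %d folds", cl,
              length(idx), k)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to score how well detected communities recover known classes.
#'
#' @param a,b Vectors of cluster/class labels of equal length.
#' @return Numeric scalar; 1 for identical partitions, ~0 for random ones.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
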