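#' Inter-species distance matrix for one UCO gene
#'
#' Aligns every unordered pair of species' representative proteins for one
#' UCO and records the identity distance `1 - pident/100`. The matrix is
#' symmetric by construction (each pair is aligned once) with a zero
#' diagonal, and all entries lie in [0, 1].
#'
#' @param seqs per-species protein sequences for one UCO: an `AAStringSet`
#'   (or named character vector) named by species id.
#' @param uco_id identifier attached to the matrix.
#' @return A `uco_dist` object: list with `uco_id`, `species`, and `values`
#'   (symmetric numeric matrix with species ids as dimnames), or `NULL` with
#'   a warning when fewer than two species carry the UCO.
#' @export
pairwise_distance_matrix <- function(seqs, uco_id = "uco") {
  seqs <- as_aa_set(seqs)
  n <- length(seqs)
  if (n < 2L) {
    warning(sprintf("UCO %s present in fewer than 2 species: skipped", uco_id))
    return(NULL)
  }
  sp <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      hit <- smith_waterman(stats::setNames(as.character(seqs[[i]]), sp[i]),
                            stats::setNames(as.character(seqs[[j]]), sp[j]))
      d[i, j] <- d[j, i] <- 1 - hit$pident / 100
    }
  }
  structure(list(uco_id = uco_id, species = sp, values = d),
            class = "uco_dist")
}

# coerce matrix-like input to uco_dist
as_uco_dist <- function(x, uco_id = "uco") {
  if (inherits(x, "uco_dist")) return(x)
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (is.null(rownames(x))) {
    rownames(x) <- colnames(x) <- paste0("sp", seq_len(nrow(x)))
  }
  structure(list(uco_id = uco_id, species = rownames(x), values = x),
            class = "uco_dist")
}

# upper-triangle (off-diagonal) entries of the two matrices restricted to
# their shared species, in a fixed species order
shared_triangles <- function(x, y) {
  x <- as_uco_dist(x, "x"); y <- as_uco_dist(y, "y")
  shared <- sort(intersect(x$species, y$species))
  if (length(shared) < 3L) {
    stop(sprintf("only %d species shared between matrices; need at least 3",
                 length(shared)))
  }
  xv <- x$values[shared, shared, drop = FALSE]
  yv <- y$values[shared, shared, drop = FALSE]
  ut <- upper.tri(xv)
  list(x = xv[ut], y = yv[ut], xmat = xv, ymat = yv, shared = shared)
}

# standardized cross-product correlation of two equal-length vectors,
# divisor m - 1 (so r(x, x) = 1 exactly)
std_crossprod_r <- function(xv, yv) {
  m <- length(xv)
  sx <- stats::sd(xv)
  sy <- stats::sd(yv)
  if (sx == 0 || sy == 0) {
    stop("zero variance in a distance matrix: correlation undefined")
  }
  sum(((xv - mean(xv)) / sx) * ((yv - mean(yv)) / sy)) / (m - 1)
}

#' Mantel correlation of two distance matrices
#'
#' Standardized cross-product correlation of the matrices' upper-triangle
#' off-diagonal entries: with m such entries,
#' `r = 1/(m-1) * sum((x - mean(x))/s_x * (y - mean(y))/s_y)`,
#' where standard deviations use divisor `m - 1`. Matrices are first
#' restricted to their shared species (UCO matrices cover different species
#' sets, so only species carrying both genes are compared); `r` is 1 exactly
#' when the restricted matrices agree up to a positive affine transform and
#' -1 under reflection.
#'
#' @param x,y `uco_dist` objects or symmetric matrices with species-id
#'   dimnames. At least 3 shared species are required.
#' @return The correlation, a number in [-1, 1].
#' @export
mantel_r <- function(x, y) {
  tri <- shared_triangles(x, y)
  std_crossprod_r(tri$x, tri$y)
}

#' Permutation significance of the Mantel correlation
#'
#' The null distribution is obtained by simultaneously permuting the rows
#' and columns of `y` (a species relabelling) and recomputing `r`. The
#' one-tailed p-value counts permutations with `r` at least as large as
#' observed, including the observed statistic itself:
#' `p = (1 + #permuted >= observed) / (permutations + 1)`, so the smallest
#' attainable p is `1/(permutations + 1)`.
#'
#' @param x,y as in [mantel_r()].
#' @param permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream (required for
#'   reproducibility).
#' @return A `mantel_result`: list with `r`, `p`, `n_shared`,
#'   `permutations`, `seed`.
#' @export
mantel_permutation_p <- function(x, y, permutations = 999L, seed) {
  if (missing(seed)) stop("seed is required")
  tri <- shared_triangles(x, y)
  r_obs <- std_crossprod_r(tri$x, tri$y)
  n <- length(tri$shared)
  ut <- upper.tri(tri$ymat)
  xs <- (tri$x - mean(tri$x)) / stats::sd(tri$x)
  m <- length(tri$x)
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      p <- sample.int(n)
      yv <- tri$ymat[p, p][ut]
      sy <- stats::sd(yv)
      r_b <- if (sy == 0) 0 else sum(xs * ((yv - mean(yv)) / sy)) / (m - 1)
      if (r_b >= r_obs) count <- count + 1L
    }
  })
  structure(list(r = r_obs,
                 p = (1 + count) / (permutations + 1),
                 n_shared = n,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations, %d shared species)\n",
              x$r, x$p, x$permutations, x$n_shared))
  invisible(x)
}

#' Mantel correlations for all pairs of UCO distance matrices
#'
#' Computes `r` for every unordered pair of matrices, restricting each pair
#' to its shared species. Pairs sharing fewer than `min_shared` species, or
#' with zero variance in a restricted matrix, are reported with `r = NA`
#' rather than dropped, so the output always has `choose(m, 2)` rows.
#'
#' The computation is vectorised over pairs: all upper triangles are stacked
#' (indexed by species pair, `NA` where a matrix lacks a species) and the
#' pairwise standardized cross-products of Mantel's statistic are assembled
#' from masked cross-product sums, which keeps hundreds of matrices
#' (tens of thousands of pairs) well under a second.
#'
#' @param matrices a list of `uco_dist` objects (or named symmetric
#'   matrices).
#' @param min_shared minimum shared species for a defined correlation
#'   (default 3).
#' @return A data.frame with one row per unordered pair: `uco_i`, `uco_j`,
#'   `r`, `n_shared`.
#' @export
all_pairs_correlation <- function(matrices, min_shared = 3L) {
  K <- length(matrices)
  if (K < 2L) stop("need at least 2 matrices")
  matrices <- lapply(seq_along(matrices), function(i) {
    as_uco_dist(matrices[[i]],
                if (!is.null(names(matrices))) names(matrices)[i]
                else paste0("uco", i))
  })
  ids <- vapply(matrices, `[[`, "", "uco_id")
  all_sp <- sort(unique(unlist(lapply(matrices, `[[`, "species"))))
  ns <- length(all_sp)
  pair_i <- rep(seq_len(ns - 1L), times = (ns - 1L):1L)
  pair_j <- unlist(lapply(2:ns, function(j) seq.int(j, ns)))
  # pair index table for the union species set
  P <- length(pair_i)

  X <- matrix(NA_real_, nrow = P, ncol = K)
  present <- matrix(FALSE, nrow = ns, ncol = K)
  for (k in seq_len(K)) {
    sp <- matrices[[k]]$species
    idx <- match(sp, all_sp)
    present[idx, k] <- TRUE
    v <- matrices[[k]]$values[sp, sp, drop = FALSE]
    # reorder to the union ordering so triangle indices line up
    o <- order(idx)
    v <- v[o, o, drop = FALSE]
    idx <- idx[o]
    row_pos <- match(paste(idx[row(v)], idx[col(v)]),
                     paste(pair_i, pair_j))
    ut <- upper.tri(v)
    X[row_pos[ut], k] <- v[ut]
  }

  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0
  Mn <- matrix(as.numeric(M), nrow = P)
  n_entries <- crossprod(Mn)                     # common triangle entries
  s_x <- crossprod(X0, Mn)                       # sum of x over common entries
  s_xx <- crossprod(X0^2, Mn)
  s_xy <- crossprod(X0)
  n_shared_sp <- crossprod(matrix(as.numeric(present), nrow = ns))

  # Pearson form of the standardized cross-product over common entries
  num <- n_entries * s_xy - s_x * t(s_x)
  den_x <- n_entries * s_xx - s_x^2
  den <- sqrt(pmax(den_x, 0) * pmax(t(den_x), 0))
  R <- ifelse(den > 0, num / den, NA_real_)
  R[n_shared_sp < min_shared] <- NA_real_

  iu <- rep(seq_len(K - 1L), times = (K - 1L):1L)
  ju <- unlist(lapply(2:K, function(j) seq.int(j, K)))
  data.frame(uco_i = ids[iu], uco_j = ids[ju],
             r = R[cbind(iu, ju)],
             n_shared = as.integer(n_shared_sp[cbind(iu, ju)]),
             stringsAsFactors = FALSE)
}

#' Read / write a square distance matrix as TSV
#'
#' The format is a square table with species ids as both header row and
#' first column.
#'
#' @param x a `uco_dist` (for writing).
#' @param path file path.
#' @param uco_id id to attach when reading.
#' @return `read_dist_tsv` returns a `uco_dist`; `write_dist_tsv` returns
#'   `path` invisibly.
#' @export
write_dist_tsv <- function(x, path) {
  x <- as_uco_dist(x)
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path, uco_id = sub("\\.[^.]*$", "", basename(path))) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  as_uco_dist(m, uco_id)
}
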