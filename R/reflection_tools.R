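# Reflection bookkeeping: asymmetric-unit mapping under a Laue group,
# unique-set generation to a resolution limit, and merging statistics
# (completeness, multiplicity, R_merge, CC1/2, mean I/sigma).

#' Unit cell
#'
#' Orthogonal cells only (all angles 90 degrees), which covers the
#' tetragonal case the merging code targets. When `laue_group = "4/mmm"` is
#' used downstream the tetragonal constraint a = b is enforced.
#'
#' @param a,b,c Cell edges in Angstrom (b defaults to a, c to a).
#' @param alpha,beta,gamma Cell angles in degrees (must be 90).
#' @return A `unit_cell` object.
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell edges must be positive", call. = FALSE)
  if (any(c(alpha, beta, gamma) != 90))
    stop("only orthogonal cells (all angles 90) are supported", call. = FALSE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

.supported_laue <- c("-1", "4/mmm")

# Returns a list of 3x3 integer matrices, the Laue-group action on (h,k,l)
# (Friedel inversion included).
.laue_ops <- function(laue_group) {
  if (!laue_group %in% .supported_laue)
    stop("unsupported Laue group '", laue_group, "' (supported: ",
         paste(.supported_laue, collapse = ", "), ")", call. = FALSE)
  if (laue_group == "-1")
    return(list(diag(3), -diag(3)))
  ops <- list()
  swap <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  for (sw in list(diag(3), swap))
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1))
      ops[[length(ops) + 1L]] <- diag(c(s1, s2, s3)) %*% sw
  ops
}

#' Map Miller indices to a canonical asymmetric-unit representative
#'
#' Applies every operation of the Laue group (Friedel inversion included)
#' and picks the lexicographically greatest equivalent index, compared on
#' h, then k, then l. The map is idempotent and constant on each symmetry
#' orbit, so merging by canonical index merges symmetry mates.
#'
#' @param h,k,l Integer Miller indices (vectorised, equal length).
#' @param laue_group `"4/mmm"` (tetragonal) or `"-1"` (Friedel only).
#' @return Integer matrix with columns `h`, `k`, `l`.
#' @export
map_to_asu <- function(h, k, l, laue_group = "4/mmm") {
  ops <- .laue_ops(laue_group)
  hkl <- cbind(h = as.integer(h), k = as.integer(k), l = as.integer(l))
  big <- max(1L, max(abs(hkl)))
  base <- 2 * big + 1
  best_key <- rep(-Inf, nrow(hkl))
  best <- hkl
  for (op in ops) {
    cand <- hkl %*% t(op)
    key <- (cand[, 1] + big) * base^2 + (cand[, 2] + big) * base + (cand[, 3] + big)
    better <- key > best_key
    best[better, ] <- cand[better, , drop = FALSE]
    best_key[better] <- key[better]
  }
  colnames(best) <- c("h", "k", "l")
  best
}

#' d-spacing of reflections in an orthogonal cell
#'
#' `1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2`; for a tetragonal cell this is the
#' familiar `(h^2 + k^2)/a^2 + l^2/c^2`.
#'
#' @param h,k,l Miller indices (vectorised).
#' @param cell A [unit_cell()].
#' @return d in Angstrom (`Inf` for (0,0,0)).
#' @export
d_spacing <- function(h, k, l, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  inv_d2 <- (h / cell$a)^2 + (k / cell$b)^2 + (l / cell$c)^2
  1 / sqrt(inv_d2)
}

#' Generate the unique reflection set to a resolution limit
#'
#' Enumerates all reflections with `d >= d_min`, maps each to its canonical
#' asymmetric-unit representative and returns the unique set, excluding
#' (0,0,0). This is the denominator of completeness.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @param laue_group See [map_to_asu()].
#' @return Integer matrix of unique canonical `h`, `k`, `l` rows.
#' @export
generate_unique_set <- function(cell, d_min, laue_group = "4/mmm") {
  stopifnot(inherits(cell, "unit_cell"))
  if (d_min <= 0) stop("d_min must be positive", call. = FALSE)
  if (laue_group == "4/mmm" && cell$a != cell$b)
    stop("Laue group 4/mmm requires a tetragonal cell (a = b)", call. = FALSE)
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  if (hmax < 1 && kmax < 1 && lmax < 1)
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("h", "k", "l"))))
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  keep <- d_spacing(grid$h, grid$k, grid$l, cell) >= d_min &
    !(grid$h == 0 & grid$k == 0 & grid$l == 0)
  grid <- grid[keep, , drop = FALSE]
  asu <- map_to_asu(grid$h, grid$k, grid$l, laue_group)
  big <- max(1L, max(abs(asu)))
  base <- 2 * big + 1
  key <- (asu[, 1] + big) * base^2 + (asu[, 2] + big) * base + (asu[, 3] + big)
  res <- asu[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read / write a reflection table
#'
#' Whitespace-delimited text with a header line
#' `h k l frame intensity sigma [tilt]`. Sigma must be positive.
#'
#' @param path File path.
#' @return A data frame with the named columns.
#' @export
read_reflection_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  required <- c("h", "k", "l", "frame", "intensity", "sigma")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("reflection table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(tab$sigma <= 0))
    stop("reflection table contains non-positive sigma values", call. = FALSE)
  tab
}

#' @rdname read_reflection_table
#' @param table Data frame with at least `h k l frame intensity sigma`.
#' @export
write_reflection_table <- function(table, path) {
  utils::write.table(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merging statistics for a reflection table
#'
#' Groups observations by canonical asymmetric-unit index (reflections
#' beyond `d_min` are dropped first) and computes:
#' \itemize{
#'   \item multiplicity = observations / unique reflections observed;
#'   \item completeness against [generate_unique_set()];
#'   \item `R_merge = sum |I_i - <I>| / sum I_i` over multiply-observed
#'     reflections (singletons have zero numerator and are excluded from
#'     both sums);
#'   \item CC1/2, the Pearson correlation between mean intensities of two
#'     random half-data sets (groups of size 1 excluded; split is seeded);
#'   \item mean I/sigma over observations.
#' }
#' Negative intensities are retained: clipping them would bias the merge.
#'
#' @param table Reflection data frame (`h k l frame intensity sigma`).
#' @param cell A [unit_cell()].
#' @param laue_group See [map_to_asu()].
#' @param d_min Resolution limit in Angstrom.
#' @param seed Integer seed for the CC1/2 half-set split.
#' @return A `merge_stats` object.
#' @export
merge_stats <- function(table, cell, laue_group = "4/mmm", d_min, seed = 1L) {
  if (is.null(table) || nrow(table) == 0)
    stop("empty reflection table", call. = FALSE)
  d <- d_spacing(table$h, table$k, table$l, cell)
  table <- table[d >= d_min, , drop = FALSE]
  if (nrow(table) == 0)
    stop("no observations at or below the resolution limit", call. = FALSE)
  asu <- map_to_asu(table$h, table$k, table$l, laue_group)
  key <- paste(asu[, 1], asu[, 2], asu[, 3])
  groups <- split(table$intensity, key)
  n_obs <- nrow(table)
  n_unique <- length(groups)
  sizes <- lengths(groups)
  multi <- groups[sizes >= 2L]
  # R_merge over multiply-observed reflections
  if (length(multi)) {
    num <- sum(vapply(multi, function(I) sum(abs(I - mean(I))), numeric(1)))
    den <- sum(vapply(multi, sum, numeric(1)))
    r_merge <- if (den != 0) num / den else NA_real_
  } else r_merge <- NA_real_
  cc_half <- .cc_half(multi, seed)
  unique_set <- generate_unique_set(cell, d_min, laue_group)
  completeness <- if (nrow(unique_set)) n_unique / nrow(unique_set) else NA_real_
  structure(list(n_observations = n_obs,
                 n_unique = n_unique,
                 multiplicity = n_obs / n_unique,
                 completeness = completeness,
                 r_merge = r_merge,
                 cc_half = cc_half,
                 mean_i_over_sigma = mean(table$intensity / table$sigma)),
            class = "merge_stats")
}

# Pearson correlation between half-set means over multiply-observed groups.
.cc_half <- function(multi, seed) {
  if (length(multi) < 3L) return(NA_real_)
  half_means <- with_preserved_rng(seed, {
    vapply(multi, function(I) {
      idx <- sample.int(length(I))
      nh <- length(I) %/% 2L
      c(mean(I[idx[seq_len(nh)]]), mean(I[idx[(nh + 1L):length(I)]]))
    }, numeric(2))
  })
  if (stats::sd(half_means[1, ]) == 0 || stats::sd(half_means[2, ]) == 0)
    return(NA_real_)
  stats::cor(half_means[1, ], half_means[2, ])
}

# Run code with a seeded RNG, restoring the caller's RNG state afterwards.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @export
print.merge_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Merge statistics: %d observations, %d unique\n",
    "  multiplicity %.2f, completeness %.1f%%, R_merge %.3f, ",
    "CC1/2 %.3f, <I/sigma> %.2f\n"),
    x$n_observations, x$n_unique, x$multiplicity, 100 * x$completeness,
    x$r_merge, x$cc_half, x$mean_i_over_sigma))
  invisible(x)
}
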