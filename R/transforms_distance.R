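# Hellinger transform, Bray-Curtis / Euclidean distances, Gini-Simpson
# diversity, and principal coordinates analysis.

#' Hellinger transform
#'
#' Square root of row-relative abundance. Makes Euclidean geometry
#' appropriate for community data prior to RDA: each output row's squared
#' entries sum to 1.
#'
#' @param m an [abundance_matrix()]; counts are converted to relative
#'   internally.
#' @return hellinger-mode `abundance_matrix` of square-root scores.
#' @export
hellinger <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("all-zero sample row(s): ", paste(rownames(m)[rs <= 0], collapse = ", "))
  out <- sqrt(unclass_mat(m) / rs)
  abundance_matrix(out, mode = "hellinger")
}

#' Distance matrix container
#' @param d symmetric nonnegative matrix with zero diagonal and dimnames.
#' @param metric metric name (for reports).
#' @return a `distance_matrix` (matrix with `metric` attribute).
#' @export
distance_matrix <- function(d, metric = "unknown") {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  structure(d, metric = metric, class = c("distance_matrix", "matrix", "array"))
}

#' Bray-Curtis dissimilarity
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i), computed on relative
#' abundances; lies in [0, 1].
#'
#' @param m an `abundance_matrix` (counts converted to relative).
#' @return a [distance_matrix()].
#' @export
bray_curtis <- function(m) {
  m <- to_relative(m)
  x <- unclass_mat(m)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    rest <- x[(i + 1):n, , drop = FALSE]
    num <- rowSums(abs(sweep(rest, 2, xi)))
    den <- rowSums(sweep(rest, 2, xi, `+`))
    if (any(den == 0)) stop("Bray-Curtis undefined for a pair of all-zero samples")
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- num / den
  }
  distance_matrix(d, metric = "bray_curtis")
}

#' Euclidean distance between rows
#' @param x numeric matrix (rows are items).
#' @return a [distance_matrix()].
#' @export
euclidean_distance <- function(x) {
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  diag(d) <- 0
  distance_matrix(d, metric = "euclidean")
}

#' Gini-Simpson diversity
#'
#' For nonnegative weights p with q = p / sum(p), returns 1 - sum(q^2)
#' (probability two random draws differ); range [0, 1 - 1/k]. The
#' inverse-Simpson convention 1 / sum(q^2) is available via `convention`.
#' An all-zero vector returns 0 by definition (an empty guild carries no
#' diversity weight).
#'
#' @param p nonnegative numeric vector.
#' @param convention `"gini"` (default) or `"inverse"`.
#' @return scalar diversity.
#' @export
simpson_diversity <- function(p, convention = c("gini", "inverse")) {
  convention <- match.arg(convention)
  if (any(p < 0)) stop("weights must be nonnegative")
  s <- sum(p)
  if (s == 0) return(0)
  q <- p / s
  ss <- sum(q^2)
  if (convention == "gini") 1 - ss else 1 / ss
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by sqrt(eigenvalue) for positive
#' eigenvalues; negative eigenvalues are reported but excluded from
#' coordinates (no Cailliez/Lingoes correction by default). Axis signs are
#' fixed by forcing the largest-magnitude loading positive.
#'
#' @param d a [distance_matrix()] with n >= 3.
#' @return list of class `ordination`: `coordinates` (n x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  G <- gower_center(unclass(d))
  eig <- eigen(G, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(vals) * 1e-10 & vals > 0)
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  prop <- vals[pos] / sum(vals[pos])
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 proportion_explained = prop),
            class = "ordination")
}

# Gower-centered inner-product matrix from a distance matrix:
# G = (I - J/n) (-D^2/2) (I - J/n)
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a); cm <- colMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, cm) + gm
}

#' Write a square distance matrix to TSV
#' @param d a `distance_matrix`.
#' @param path output path.
#' @export
write_distance <- function(d, path) {
  df <- data.frame(id = rownames(d), unclass(d), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
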