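# Landmark-based geometric morphometrics: generalized Procrustes
# superimposition, removal of the dorsoventral arching nuisance by Burnaby's
# orthogonal projection, and PCA-based shape scores.

#' Generalized Procrustes superimposition
#'
#' Translates every configuration to centroid origin, scales it to unit
#' centroid size, and iteratively rotates each configuration to the current
#' consensus (optimal rotation from the SVD of the cross-covariance matrix,
#' reflections disallowed since all photographs show the same body side),
#' re-estimating the consensus until its change falls below `tol`.
#' The procedure is deterministic and its output is invariant to arbitrary
#' rotation, translation and scaling of any input configuration.
#'
#' @param configs a `k x 2 x n` array or list of `k x 2` matrices, n >= 2.
#' @param tol convergence tolerance on the Frobenius change of the consensus.
#' @param max_iter maximum number of consensus updates.
#' @return An object of class `gpa`: list with `aligned` (an `n x 2k` matrix,
#'   columns `x1, y1, x2, y2, ...`), `csize` (centroid sizes), `consensus`
#'   (`k x 2`), `iterations`, `delta` (final consensus change) and `ids`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-10, max_iter = 100L) {
  arr <- landmark_array(configs)
  k <- dim(arr)[1L]; n <- dim(arr)[3L]
  if (n < 2L) stop("need at least 2 configurations")
  ids <- dimnames(arr)[[3L]]
  if (is.null(ids)) ids <- sprintf("specimen_%d", seq_len(n))

  csize <- numeric(n)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    x <- arr[, , i]
    x <- sweep(x, 2L, colMeans(x))
    s <- sqrt(sum(x^2))
    if (s < .Machine$double.eps * k)
      stop("degenerate configuration (all landmarks coincident): ", ids[i])
    csize[i] <- s
    shapes[[i]] <- x / s
  }

  rotate_to <- function(x, target) {
    sv <- svd(crossprod(x, target))
    r <- sv$u %*% t(sv$v)
    if (det(r) < 0) {  # no reflections
      u <- sv$u; u[, 2L] <- -u[, 2L]
      r <- u %*% t(sv$v)
    }
    x %*% r
  }

  consensus <- shapes[[1L]]
  delta <- Inf; it <- 0L
  while (delta > tol && it < max_iter) {
    it <- it + 1L
    shapes <- lapply(shapes, rotate_to, target = consensus)
    new_cons <- Reduce(`+`, shapes) / n
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
  }

  # canonical orientation: rotate the whole superimposed set so the
  # consensus lies along its principal axes (long axis first, largest
  # loading positive, det +1 so no reflection sneaks in); this makes the
  # output independent of the input configurations' arbitrary orientations
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  rot <- e$vectors
  if (det(rot) < 0) rot[, 2L] <- -rot[, 2L]
  u <- consensus %*% rot
  # disambiguate the remaining 180-degree rotation with the first nonzero
  # skewness of the landmark projections (frame-invariant)
  skews <- c(sum(u[, 1L]^3), sum(u[, 2L]^3), u[1L, 1L])
  pick <- skews[which(abs(skews) > 1e-12)[1L]]
  if (!is.na(pick) && pick < 0) rot <- -rot
  consensus <- consensus %*% rot
  shapes <- lapply(shapes, `%*%`, rot)

  aligned <- t(vapply(shapes, function(m) as.vector(t(m)), numeric(2L * k)))
  colnames(aligned) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2L))
  rownames(aligned) <- ids
  structure(list(aligned = aligned, csize = csize, consensus = consensus,
                 iterations = it, delta = delta, ids = ids, k = k),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("Procrustes superimposition: %d specimens, %d landmarks, %d iterations (delta %.2g)\n",
              nrow(x$aligned), x$k, x$iterations, x$delta))
  invisible(x)
}

# Per-specimen arching score: the signed quadratic coefficient of a parabola
# fitted to the y-coordinates of the midline landmarks (jaw tip 1, eye 14,
# operculum 16, lateral line end 8, and the dorsal/ventral peduncle midpoint
# of 7 and 9).  The abscissae are taken from the consensus shape so that
# x-displacements (e.g. head elongation) cannot leak into the bend score.
arching_scores <- function(gpa, midline = c(1L, 14L, 16L, 8L),
                           peduncle_pair = c(7L, 9L)) {
  n <- nrow(gpa$aligned)
  cons <- gpa$consensus
  x_ref <- c(cons[midline, 1L], mean(cons[peduncle_pair, 1L]))
  basis_q <- cbind(1, x_ref, x_ref^2)
  hat <- solve(crossprod(basis_q), t(basis_q))[3L, ]  # quadratic-coef extractor
  vapply(seq_len(n), function(i) {
    m <- matrix(gpa$aligned[i, ], ncol = 2L, byrow = TRUE)
    y <- c(m[midline, 2L], mean(m[peduncle_pair, 2L]))
    sum(hat * y)
  }, numeric(1))
}

#' Estimate the arching nuisance direction in shape space
#'
#' Fish photographed with a bent (arched) body posture contaminate shape
#' variation.  The nuisance direction is constructed geometrically from the
#' consensus shape: a pure dorsoventral bend displaces every landmark in y
#' by a quadratic function of its position along the body axis, so the
#' default basis is the y-displacement pattern `(x_consensus - mean(x))^2`,
#' orthogonalized against the similarity modes (translation, rotation,
#' scaling) that the superimposition has already removed, and normalized.
#' Per-specimen arching scores (the signed quadratic-bend coefficient of
#' the midline landmarks) are attached as a diagnostic: their variance, and
#' the explained-variance change reported by [arching_diagnostic()], show
#' how much bending the data actually carry.  A user-supplied basis
#' overrides the estimate and is returned normalized.
#'
#' @param gpa a [generalized_procrustes()] result (16-landmark analysis).
#' @param user_basis optional `2k x m` matrix of nuisance directions.
#' @return A `2k x m` matrix with unit-length columns, with the per-specimen
#'   arching scores attached as attribute `scores` (estimated basis only).
#' @export
estimate_arching_basis <- function(gpa, user_basis = NULL) {
  stopifnot(inherits(gpa, "gpa"))
  if (!is.null(user_basis)) {
    b <- as.matrix(user_basis)
    return(apply(b, 2L, function(v) v / sqrt(sum(v^2))))
  }
  sc <- arching_scores(gpa)
  if (sd(sc) < 1e-12)
    stop("arching scores have zero variance; supply user_basis instead")
  cons <- gpa$consensus
  k <- nrow(cons)
  interleave <- function(x, y) as.vector(rbind(x, y))  # x1,y1,x2,y2,...
  unit <- function(v) v / sqrt(sum(v^2))
  q <- (cons[, 1L] - mean(cons[, 1L]))^2
  w <- interleave(rep(0, k), q - mean(q))
  similarity <- list(
    interleave(rep(1, k), rep(0, k)),            # x translation
    interleave(rep(0, k), rep(1, k)),            # y translation
    interleave(-cons[, 2L], cons[, 1L]),         # rotation
    interleave(cons[, 1L], cons[, 2L])           # scaling
  )
  for (m in similarity) {
    m <- unit(m)
    w <- w - sum(w * m) * m
  }
  basis <- matrix(unit(w), ncol = 1L)
  attr(basis, "scores") <- sc
  basis
}

#' Burnaby's orthogonal projection
#'
#' Projects the aligned coordinate matrix onto the orthogonal complement of
#' the nuisance basis: `X (I - F (F'F)^-1 F')`.  The projection is idempotent
#' and the projected data are orthogonal to every nuisance column.
#'
#' @param x `n x 2k` aligned coordinate matrix.
#' @param basis `2k x m` nuisance basis with linearly independent columns.
#' @return The projected `n x 2k` matrix.
#' @export
burnaby_project <- function(x, basis) {
  x <- as.matrix(x)
  f <- as.matrix(basis)
  if (nrow(f) != ncol(x))
    stop("basis rows must match coordinate columns")
  if (qr(f)$rank < ncol(f)) stop("nuisance basis is rank deficient")
  proj <- diag(nrow(f)) - f %*% solve(crossprod(f), t(f))
  out <- x %*% proj
  dimnames(out) <- dimnames(x)
  out
}

#' Arching-removal diagnostic
#'
#' Compares the PC1 explained-variance fraction before and after Burnaby
#' projection of the estimated arching direction.  A small change (the
#' original analysis reports under 5 percentage points) indicates the
#' photographed fish were only mildly bent.
#'
#' @param gpa a [generalized_procrustes()] result.
#' @param basis optional basis (default: estimated from `gpa`).
#' @return A list: `explained_before`, `explained_after`, `change_pp`
#'   (percentage points, positive = variance removed).
#' @export
arching_diagnostic <- function(gpa, basis = NULL) {
  if (is.null(basis)) basis <- estimate_arching_basis(gpa)
  before <- shape_pca(gpa$aligned)$explained[1L]
  after <- shape_pca(burnaby_project(gpa$aligned, basis))$explained[1L]
  list(explained_before = before, explained_after = after,
       change_pp = 100 * (before - after))
}

#' Subset configurations to the six head landmarks
#'
#' Retains landmarks 1, 2, 12, 13, 15 and 16 (jaw tip, jaw corner, dorsal
#' head insertion, dorsal and ventral head edges, operculum) for the
#' separate head-shape analysis; downstream superimposition and PCA are run
#' on the subset.  Six-landmark input is returned unchanged.
#'
#' @param configs a `16 x 2 x n` array or list of `16 x 2` matrices.
#' @return The same container type with 6 landmarks per specimen.
#' @export
head_subset <- function(configs) {
  idx <- c(1L, 2L, 12L, 13L, 15L, 16L)
  if (is.array(configs) && length(dim(configs)) == 3L) {
    if (dim(configs)[1L] == 6L) return(configs)
    stopifnot(dim(configs)[1L] == 16L)
    return(configs[idx, , , drop = FALSE])
  }
  k <- nrow(configs[[1L]])
  if (k == 6L) return(configs)
  stopifnot(k == 16L)
  lapply(configs, function(m) m[idx, , drop = FALSE])
}

#' Principal component analysis of shape coordinates
#'
#' Column-centers the (projected) Procrustes coordinates and
#' eigendecomposes their covariance.  Scores are the centered data times the
#' eigenvectors; the sign of each eigenvector is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms.
#'
#' @param x `n x 2k` coordinate matrix, n >= 3.
#' @return An object of class `shape_pca`: `scores` (`n x r`), `loadings`
#'   (`2k x r`), `explained` (variance fractions), `center`.
#' @export
shape_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 specimens for PCA")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  e <- eigen(stats::cov(xc), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  scores <- xc %*% load
  total <- sum(ev)
  explained <- if (total > 0) ev / total else rep(0, length(ev))
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(ncol(load)))
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, loadings = load, explained = explained,
                 center = ctr), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d specimens; PC1 explains %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained[1L]))
  invisible(x)
}

#' Size-correct shape scores
#'
#' Ordinary least-squares regression of a shape score on total length; the
#' residuals (exactly mean-zero and uncorrelated with length) are the
#' size-corrected score used as the `SB`/`SH` trait.
#'
#' @param scores numeric score vector.
#' @param tl paired total lengths, n >= 3.
#' @return Residual scores.
#' @export
size_correct <- function(scores, tl) {
  stopifnot(length(scores) == length(tl), length(tl) >= 3L)
  if (sd(tl) == 0) stop("total length is constant; cannot size-correct")
  unname(resid(lm(scores ~ tl)))
}
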