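#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `b`
#' superposed onto `a`, with correspondence fixed by row order. Reflections
#' are excluded (determinant of the rotation is +1), so a chiral structure
#' does not superpose onto its mirror image.
#'
#' @param a Reference coordinates, m x 3 matrix.
#' @param b Mobile coordinates, m x 3 matrix.
#' @return List with `rotation` (3 x 3), `translation` (length-3), `rmsd`,
#'   and `b_aligned` (`b %*% rotation` + translation).
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stop("coordinate sets differ in length: ", nrow(a), " vs ", nrow(b))
  }
  if (nrow(a) < 3L) stop("need at least 3 points to superpose")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca)
  b0 <- sweep(b, 2L, cb)
  h <- crossprod(b0, a0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # b_aligned = (b - cb) %*% t(rot') ... with rot mapping b-frame into a-frame
  b_al <- b0 %*% t(rot)
  b_al <- sweep(b_al, 2L, ca, `+`)
  trans <- ca - as.numeric(rot %*% cb)
  rmsd <- sqrt(mean(rowSums((a - b_al)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd, b_aligned = b_al)
}

tm_d0 <- function(L) {
  d0 <- if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else 0.5
  max(d0, 0.5)
}

tm_from_dist2 <- function(d2, d0sq) mean(1 / (1 + d2 / d0sq))

#' TM-score between two equal-length bead chains
#'
#' Length-normalized structural similarity in (0, 1]:
#' `TM = max over superpositions of mean(1 / (1 + (d_i / d0(L))^2))` with
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 for short chains.
#' Correspondence is fixed by bead order. The maximization runs iterative
#' Kabsch refitting on the currently well-fitting subset (distance below
#' `2 * d0`), seeded from four starts (all beads and three fragments) to
#' escape local optima. Symmetric in its arguments for equal-length input.
#'
#' @param a,b Conformations (`lattice_conformation` or m x 3 matrices).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(a, b) {
  xa <- coords_of(a)
  xb <- coords_of(b)
  if (nrow(xa) != nrow(xb)) stop("structures differ in length")
  L <- nrow(xa)
  if (L < 3L) stop("TM-score needs at least 3 beads")
  d0sq <- tm_d0(L)^2

  # seed subsets: the full chain plus sliding contiguous fragments at two
  # lengths, as in standard TM-score maximization
  starts <- list(seq_len(L))
  frag_lens <- if (L <= 20L) seq.int(3L, L - 1L)
               else unique(pmax(3L, c(L %/% 2L, L %/% 4L)))
  for (fl in frag_lens) {
    stride <- if (L <= 20L) 1L else max(1L, fl %/% 2L)
    for (s0 in unique(c(seq.int(1L, L - fl + 1L, by = stride), L - fl + 1L))) {
      starts[[length(starts) + 1L]] <- seq.int(s0, s0 + fl - 1L)
    }
  }
  score_fit <- function(sub) {
    fit <- kabsch_superpose(xa[sub, , drop = FALSE], xb[sub, , drop = FALSE])
    b_all <- sweep(xb %*% t(fit$rotation), 2L, fit$translation, `+`)
    rowSums((xa - b_all)^2)
  }
  best <- 0
  for (sub in starts) {
    sub <- unique(sub)
    if (length(sub) < 3L) next
    d2_conv <- NULL
    for (iter in 1:20) {
      d2 <- score_fit(sub)
      best <- max(best, tm_from_dist2(d2, d0sq))
      d2_conv <- d2
      new_sub <- which(d2 < 4 * d0sq)
      if (length(new_sub) < 3L) new_sub <- order(d2)[1:3]
      if (identical(new_sub, sub)) break
      sub <- new_sub
    }
    # extension round: refit on the k best-superposed beads for every k
    ord <- order(d2_conv)
    for (k in 3:L) {
      best <- max(best, tm_from_dist2(score_fit(sort(ord[1:k])), d0sq))
    }
  }
  best
}

#' Select the consensus model from a replicate ensemble
#'
#' Computes all pairwise TM-scores, averages each model's similarity to the
#' others, and returns the model with the highest average (ties broken by
#' lowest index) — the replicate most representative of the ensemble.
#'
#' @param models List of equal-length conformations.
#' @return List with `index` (selected model), `ensemble` (list with
#'   `scores` symmetric TM-score matrix with unit diagonal and
#'   `avg_similarity` per-model mean over the other models).
#' @export
select_best <- function(models) {
  m <- length(models)
  if (m < 1L) stop("no models supplied")
  if (m == 1L) {
    warning("single model supplied; selection is trivial")
    return(list(index = 1L,
                ensemble = list(scores = matrix(1, 1, 1),
                                avg_similarity = NA_real_)))
  }
  lens <- vapply(models, function(x) nrow(coords_of(x)), integer(1))
  if (length(unique(lens)) != 1L) stop("models differ in bead count")
  scores <- diag(m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      s <- tm_score(models[[i]], models[[j]])
      scores[i, j] <- s
      scores[j, i] <- s
    }
  }
  avg <- (rowSums(scores) - 1) / (m - 1)
  idx <- which.max(avg)  # which.max takes the first maximum: lowest index
  list(index = idx, ensemble = list(scores = scores, avg_similarity = avg))
}
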