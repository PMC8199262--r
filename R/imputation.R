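#' Imputation parameters for the 2D Gaussian contact spreading
#'
#' @param mu2 Gaussian shape parameter (bead-index squared units); larger
#'   values spread the influence of a contact over more neighbouring pairs.
#' @param d0 Influence radius in bead indices: pairs further than `d0` from a
#'   contact along either matrix axis receive no contribution from it.
#' @return An `impute_params` object.
#' @export
impute_params <- function(mu2 = 4, d0 = 3L) {
  stopifnot(mu2 > 0, d0 >= 0)
  structure(list(mu2 = mu2, d0 = as.integer(d0)), class = "impute_params")
}

#' Impute a sparse binary contact matrix with a 2D Gaussian kernel
#'
#' Each observed contact at matrix position (xp, yp) contributes
#' `exp(-((xp - i)^2 + (yp - j)^2) / mu2)` to every pair (i, j) within
#' Chebyshev distance `d0` of it; contributions from all contacts are summed
#' and the result clipped to 1, giving contact confidences
#' `0 <= theta[i,j] <= 1` with `theta = 1` exactly at observed contacts.
#' Pairs untouched by any contact stay at 0 and later contribute no loss, so
#' they are left unconstrained rather than pushed apart.
#'
#' @param contacts A `contact_matrix`.
#' @param params An [impute_params()] object.
#' @param connect_chain If `TRUE` (default) set `theta = 1` for every
#'   sequentially adjacent pair (i, i+1) after imputation, giving the
#'   backbone a deep well so the chain stays connected during annealing.
#' @param combine `"sum"` (clip the summed contributions at 1) or `"max"`
#'   (take the largest single contribution, never exceeding 1).
#' @return A `theta_matrix` object: list with `values` (symmetric l x l
#'   matrix in \[0,1\]) and `params`.
#' @export
gaussian_impute <- function(contacts, params = impute_params(),
                            connect_chain = TRUE,
                            combine = c("sum", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(contacts, "contact_matrix"))
  cm <- contacts$values
  l <- nrow(cm)
  d0 <- params$d0
  mu2 <- params$mu2
  theta <- matrix(0, l, l)
  # iterate over all non-zero entries (both triangles): the contact set is
  # symmetric, so the summed field is symmetric by construction
  idx <- which(cm == 1L, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    offs <- seq.int(-d0, d0)
    kern <- exp(-outer(offs^2, offs^2, `+`) / mu2)
    for (k in seq_len(nrow(idx))) {
      xp <- idx[k, 1L]
      yp <- idx[k, 2L]
      ii <- pmax(1L, xp - d0):pmin(l, xp + d0)
      jj <- pmax(1L, yp - d0):pmin(l, yp + d0)
      patch <- kern[ii - xp + d0 + 1L, jj - yp + d0 + 1L, drop = FALSE]
      if (combine == "sum") {
        theta[ii, jj] <- theta[ii, jj] + patch
      } else {
        theta[ii, jj] <- pmax(theta[ii, jj], patch)
      }
    }
    theta <- pmin(theta, 1)
  }
  diag(theta) <- 0
  if (connect_chain && l > 1L) {
    adj <- cbind(seq_len(l - 1L), seq.int(2L, l))
    theta[adj] <- 1
    theta[adj[, 2:1, drop = FALSE]] <- 1
  }
  structure(list(values = theta, params = params,
                 connect_chain = connect_chain),
            class = "theta_matrix")
}

#' @export
print.theta_matrix <- function(x, ...) {
  v <- x$values
  cat("theta_matrix:", nrow(v), "beads,",
      sum(v[upper.tri(v)] > 0), "non-zero pairs, mu2 =", x$params$mu2,
      ", d0 =", x$params$d0, "\n")
  invisible(x)
}

theta_values <- function(theta) {
  if (inherits(theta, "theta_matrix")) theta$values else as.matrix(theta)
}
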