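#' Additive (numerator) relationship matrix
#'
#' Henderson's tabular recursion in topological order. Entry (i, j) is twice
#' the coefficient of coancestry; diagonals are 1 + F_i. Unknown parents are
#' treated as unique unrelated founders.
#'
#' @param ped a validated `ped` (see [validate_pedigree()]).
#' @return dense symmetric matrix with pedigree ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped) {
  stopifnot_ped(ped)
  n <- nrow(ped)
  A <- diag(1, n)
  si <- ped$si; di <- ped$di
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- if (!is.na(s) && !is.na(d)) 1 + 0.5 * A[s, d] else 1
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Pedigree inbreeding coefficients
#'
#' F_i is half the numerator relationship of the parents; 0 when either parent
#' is unknown.
#'
#' @inheritParams additive_relationship_matrix
#' @return named numeric vector of F in pedigree order.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot_ped(ped)
  A <- additive_relationship_matrix(ped)
  stats::setNames(diag(A) - 1, ped$id)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with the inbreeding correction, using Mendelian-sampling
#' variances d_i computed from parental inbreeding coefficients. Used by the
#' animal-model sampler; `additive_relationship_matrix` is its dense oracle.
#'
#' @inheritParams additive_relationship_matrix
#' @param f optional precomputed inbreeding coefficients (pedigree order).
#' @return sparse symmetric `Matrix` A^-1.
#' @export
ainverse <- function(ped, f = NULL) {
  stopifnot_ped(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding_coefficients(ped)
  si <- ped$si; di <- ped$di
  fs <- ifelse(is.na(si), 0, f[si])
  fd <- ifelse(is.na(di), 0, f[di])
  nk <- (!is.na(si)) + (!is.na(di))
  d <- ifelse(nk == 2L, 0.5 - 0.25 * (fs + fd),
              ifelse(nk == 1L, 0.75 - 0.25 * (fs + fd), 1))
  # bulk triplets; sparseMatrix() sums duplicates
  w <- 1 / d
  ii <- seq_len(n); jj <- seq_len(n); xx <- w
  for (p in list(si, di)) {
    k <- which(!is.na(p))
    ii <- c(ii, k, p[k], p[k])
    jj <- c(jj, p[k], k, p[k])
    xx <- c(xx, -0.5 * w[k], -0.5 * w[k], 0.25 * w[k])
  }
  k <- which(!is.na(si) & !is.na(di))
  ii <- c(ii, si[k], di[k])
  jj <- c(jj, di[k], si[k])
  xx <- c(xx, 0.25 * w[k], 0.25 * w[k])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Genetic-group (immigrant ancestry) proportions
#'
#' Each founder carries a group label (1 = immigrant, 0 = resident); q is
#' propagated down the pedigree as the parental mean. An unknown parent
#' contributes the configured founder default.
#'
#' @inheritParams additive_relationship_matrix
#' @param immigrant_founders character vector of founder ids with q = 1, or a
#'   named numeric vector of founder q values in `[0, 1]`.
#' @param default q contribution of unknown parents and unassigned founders
#'   (`NA` makes unassigned founders a fatal error).
#' @return named numeric vector q in `[0, 1]`, pedigree order.
#' @export
genetic_group_proportions <- function(ped, immigrant_founders = character(),
                                      default = 0) {
  stopifnot_ped(ped)
  n <- nrow(ped)
  q <- rep(NA_real_, n)
  founder <- is.na(ped$si) & is.na(ped$di)
  if (is.character(immigrant_founders)) {
    unknown <- setdiff(immigrant_founders, ped$id[founder])
    if (length(unknown))
      stop("not founders of this pedigree: ", paste(unknown, collapse = ", "))
    q[founder] <- if (is.na(default)) NA_real_ else default
    q[match(immigrant_founders, ped$id)] <- 1
  } else {
    if (is.null(names(immigrant_founders)))
      stop("numeric founder assignment must be named by id")
    if (any(immigrant_founders < 0 | immigrant_founders > 1))
      stop("founder q values must lie in [0, 1]")
    q[founder] <- if (is.na(default)) NA_real_ else default
    q[match(names(immigrant_founders), ped$id)] <- immigrant_founders
  }
  if (anyNA(q[founder]))
    stop("unassigned founders and no default group configured: ",
         paste(utils::head(ped$id[founder & is.na(q)], 5), collapse = ", "))
  udef <- if (is.na(default)) 0 else default
  si <- ped$si; di <- ped$di
  for (i in which(!founder)) {
    qs <- if (is.na(si[i])) udef else q[si[i]]
    qd <- if (is.na(di[i])) udef else q[di[i]]
    q[i] <- (qs + qd) / 2
  }
  stats::setNames(q, ped$id)
}

#' Gene-drop breeding values down a pedigree
#'
#' Simulates additive genetic values conditional on the pedigree: founders are
#' drawn from N(0, G); every non-founder is the parental midpoint plus a
#' Mendelian-sampling deviate with (co)variance G/2 * (1 - (F_sire + F_dam)/2).
#' An unknown parent's contribution is drawn as a unique unrelated founder
#' (with F = 0). Used both by the drift-null machinery and by the synthetic
#' population generator, so the two cross-validate each other.
#'
#' @inheritParams additive_relationship_matrix
#' @param G additive genetic variance (scalar) or k x k covariance matrix for a
#'   joint drop of k traits.
#' @param n number of independent replicate drops.
#' @param f optional precomputed inbreeding coefficients.
#' @return for scalar `G`, an `nrow(ped) x n` matrix; otherwise an
#'   `nrow(ped) x k x n` array. Rows follow pedigree order.
#' @export
gene_drop <- function(ped, G, n = 1, f = NULL) {
  stopifnot_ped(ped)
  G <- as.matrix(G)
  k <- nrow(G)
  if (!isSymmetric(unname(G)) || any(eigen(G, symmetric = TRUE,
                                           only.values = TRUE)$values < -1e-8))
    stop("G must be a symmetric positive semi-definite matrix")
  if (k == 1 && G[1, 1] < 0) stop("negative additive variance")
  if (is.null(f)) f <- inbreeding_coefficients(ped)
  np <- nrow(ped)
  vals <- array(0, c(k, n, np))
  if (any(G != 0)) {
    L <- t(chol(G + diag(1e-12 * max(diag(G)), k)))
    si <- ped$si; di <- ped$di
    fs <- ifelse(is.na(si), 0, f[si])
    fd <- ifelse(is.na(di), 0, f[di])
    mend_sd <- sqrt(pmax(0, 0.5 * (1 - (fs + fd) / 2)))
    draw <- function() L %*% matrix(stats::rnorm(k * n), k, n)
    for (i in seq_len(np)) {
      s <- si[i]; d <- di[i]
      if (is.na(s) && is.na(d)) {
        vals[, , i] <- draw()
      } else {
        hs <- if (is.na(s)) 0.5 * draw() else 0.5 * vals[, , s, drop = FALSE][, , 1]
        hd <- if (is.na(d)) 0.5 * draw() else 0.5 * vals[, , d, drop = FALSE][, , 1]
        vals[, , i] <- hs + hd + mend_sd[i] * draw()
      }
    }
  }
  if (k == 1)
    return(matrix(vals[1, , ], np, n, byrow = TRUE,
                  dimnames = list(ped$id, NULL)))
  aperm(vals, c(3, 1, 2)) -> out
  dimnames(out) <- list(ped$id, rownames(G), NULL)
  out
}
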