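MOMENT_ORDERS <- cbind(
  a = c(0L, 0L, 1L, 1L, 2L, 0L, 2L, 1L, 0L, 3L),
  b = c(0L, 1L, 0L, 1L, 0L, 2L, 1L, 2L, 3L, 0L)
)

moment_names <- function() {
  sprintf("m%d%d", MOMENT_ORDERS[, "a"], MOMENT_ORDERS[, "b"])
}

moment_set <- function(coefficients, family) {
  stopifnot(length(coefficients) == 10L, all(is.finite(coefficients)))
  structure(stats::setNames(as.numeric(coefficients), moment_names()),
            class = "moment_set", family = family)
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> family = %s\n", attr(x, "family")))
  print(unclass(x))
  invisible(x)
}

as_grid_matrix <- function(grid) {
  if (inherits(grid, "square_grid")) grid$entries else as.matrix(grid)
}

#' Reshape an encoded sequence into a square grid
#'
#' The length-n numeric sequence is laid out row-major in a k x k matrix with
#' k = ceiling(sqrt(n)); the trailing k^2 - n cells are zero. The grid is a
#' two-dimensional image of the sequence whose moments summarise both
#' composition and position.
#'
#' @param enc `encoded_sequence` (or bare numeric vector).
#' @return Object of class `square_grid`: list with `entries` (k x k matrix),
#'   `k`, and `fill_count` = n.
#' @examples
#' reshape_to_grid(encode_sequence("ACGT"))$entries
#' @export
reshape_to_grid <- function(enc) {
  values <- if (inherits(enc, "encoded_sequence")) enc$values else as.numeric(enc)
  n <- length(values)
  if (n < 4L) stop("sequence must have at least 4 bases (grid at least 2x2)", call. = FALSE)
  k <- as.integer(ceiling(sqrt(n)))
  padded <- c(values, rep(0, k * k - n))
  structure(list(entries = matrix(padded, nrow = k, ncol = k, byrow = TRUE),
                 k = k, fill_count = n),
            class = "square_grid")
}

#' Raw moments of a matrix up to order 3
#'
#' Computes the ten coefficients U_ab = sum_e sum_f e^a f^b delta_ef for
#' (a,b) in {(0,0),(0,1),(1,0),(1,1),(2,0),(0,2),(2,1),(1,2),(0,3),(3,0)},
#' with 1-based row index e and column index f.
#'
#' @param grid A numeric matrix or `square_grid`.
#' @return A `moment_set` with family `"raw"`.
#' @examples
#' raw_moments(matrix(1:4, 2, byrow = TRUE))[c("m00", "m10", "m01")]
#' @export
raw_moments <- function(grid) {
  m <- as_grid_matrix(grid)
  e <- seq_len(nrow(m))
  f <- seq_len(ncol(m))
  co <- apply(MOMENT_ORDERS, 1L, function(ab) {
    as.numeric(e^ab[["a"]] %*% m %*% f^ab[["b"]])
  })
  moment_set(co, "raw")
}

#' Central moments and centroid of a matrix up to order 3
#'
#' V_ab = sum_e sum_f (e - xbar)^a (f - ybar)^b delta_ef with the centroid
#' xbar = U10/U00, ybar = U01/U00. When the matrix has zero total mass the
#' centroid falls back to the geometric centre (k+1)/2 and all higher central
#' moments are zero; V00 equals U00 always.
#'
#' @param grid A numeric matrix or `square_grid`.
#' @return List with `centroid` (named vector `x`, `y`) and `moments`
#'   (a `moment_set` with family `"central"`).
#' @export
central_moments <- function(grid) {
  m <- as_grid_matrix(grid)
  u00 <- sum(m)
  e <- seq_len(nrow(m))
  f <- seq_len(ncol(m))
  if (u00 != 0) {
    xbar <- sum(e * rowSums(m)) / u00
    ybar <- sum(f * colSums(m)) / u00
    co <- apply(MOMENT_ORDERS, 1L, function(ab) {
      as.numeric((e - xbar)^ab[["a"]] %*% m %*% (f - ybar)^ab[["b"]])
    })
  } else {
    xbar <- (nrow(m) + 1) / 2
    ybar <- (ncol(m) + 1) / 2
    co <- c(u00, rep(0, 9L))
  }
  list(centroid = c(x = xbar, y = ybar), moments = moment_set(co, "central"))
}

hahn_basis_cache <- new.env(parent = emptyenv())

#' Discrete Hahn polynomial basis
#'
#' Builds the N x N table of weighted, orthonormal discrete Hahn polynomial
#' values h_p(x) for orders p = 0..N-1 on the grid x = 0..N-1, with Hahn
#' parameters `a`, `b` (defaults 0, the discrete Chebyshev case). Values are
#' produced by the three-term recurrence, multiplied by the square root of the
#' Hahn weight, and re-orthonormalised by one modified Gram-Schmidt pass so
#' that rows satisfy sum_x h_p(x) h_q(x) = delta_pq to machine precision.
#' Orthonormality makes the full N^2-coefficient moment transform exactly
#' invertible, so no sequence information is lost by the transform itself.
#'
#' @param N Grid side (>= 2).
#' @param a,b Non-negative Hahn parameters.
#' @return Object of class `hahn_basis`: list with `N`, `a`, `b`, and `table`
#'   (N x N matrix, row p+1 = order-p polynomial values).
#' @export
build_hahn_basis <- function(N, a = 0, b = 0) {
  if (N < 2L) stop("Hahn basis requires N >= 2", call. = FALSE)
  if (a < 0 || b < 0) stop("Hahn parameters a, b must be >= 0", call. = FALSE)
  key <- sprintf("N%d_a%g_b%g", N, a, b)
  hit <- hahn_basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  x <- 0:(N - 1)
  # Hahn weight rho(x) = C(x+a, x) * C(N-1-x+b, N-1-x), computed in log space.
  log_rho <- lchoose(x + a, x) + lchoose(N - 1 - x + b, N - 1 - x)
  sqrt_rho <- exp((log_rho - max(log_rho)) / 2)
  tab <- matrix(0, N, N)
  q_prev <- rep(1, N)                 # Q_0(x) = 1
  q_curr <- NULL
  for (p in 0:(N - 1)) {
    if (p == 0) {
      q <- q_prev
    } else if (p == 1) {
      A0 <- (a + b + 1) * (a + 1) * (N - 1) / ((a + b + 1) * (a + b + 2))
      q <- ((A0 - x) * q_prev) / A0    # C_0 = 0
      q_curr <- q
    } else {
      nn <- p - 1
      An <- (nn + a + b + 1) * (nn + a + 1) * (N - 1 - nn) /
        ((2 * nn + a + b + 1) * (2 * nn + a + b + 2))
      Cn <- nn * (nn + a + b + N) * (nn + b) /
        ((2 * nn + a + b) * (2 * nn + a + b + 1))
      q <- ((An + Cn - x) * q_curr - Cn * q_prev) / An
      q_prev <- q_curr
      q_curr <- q
    }
    v <- q * sqrt_rho
    if (p > 0) {                       # modified Gram-Schmidt against lower orders
      for (j in seq_len(p)) v <- v - sum(v * tab[j, ]) * tab[j, ]
    }
    nv <- sqrt(sum(v * v))
    if (!is.finite(nv) || nv == 0) {
      stop(sprintf("Hahn basis degenerate at order %d (N=%d, a=%g, b=%g)", p, N, a, b),
           call. = FALSE)
    }
    tab[p + 1, ] <- v / nv
  }
  out <- structure(list(N = as.integer(N), a = a, b = b, table = tab),
                   class = "hahn_basis")
  hahn_basis_cache[[key]] <- out
  out
}

#' Hahn moments of a matrix up to order 3
#'
#' H_pq = sum_i sum_j delta_ij h_p(i-1) h_q(j-1) over the orthonormal basis
#' table; returns the same ten (p,q) index subset as [raw_moments].
#'
#' @param grid A numeric matrix or `square_grid` with side equal to `basis$N`.
#' @param basis A [build_hahn_basis] result; built on the fly if omitted.
#' @return A `moment_set` with family `"hahn"`.
#' @export
hahn_moments <- function(grid, basis = NULL) {
  m <- as_grid_matrix(grid)
  if (nrow(m) != ncol(m)) stop("Hahn moments require a square matrix", call. = FALSE)
  if (is.null(basis)) basis <- build_hahn_basis(nrow(m))
  if (basis$N != nrow(m)) {
    stop(sprintf("basis side %d does not match grid side %d", basis$N, nrow(m)),
         call. = FALSE)
  }
  full <- basis$table %*% m %*% t(basis$table)   # full N x N transform
  # orders p or q >= N do not exist for an N-point basis (grids of side 2 or
  # 3); their coefficients are 0 so the moment set keeps its fixed shape
  co <- apply(MOMENT_ORDERS, 1L, function(ab) {
    if (ab[["a"]] >= basis$N || ab[["b"]] >= basis$N) 0
    else full[ab[["a"]] + 1L, ab[["b"]] + 1L]
  })
  moment_set(co, "hahn")
}

#' Full Hahn transform and its inverse
#'
#' `hahn_transform` computes all N^2 Hahn moments; `hahn_reconstruct` inverts
#' the transform through the transposed orthonormal basis, reproducing the
#' original matrix (the transform is reversible).
#'
#' @param m Square numeric matrix.
#' @param H Full moment matrix from `hahn_transform`.
#' @param basis A [build_hahn_basis] of matching side.
#' @return A matrix of the same dimensions.
#' @export
hahn_transform <- function(m, basis = NULL) {
  m <- as_grid_matrix(m)
  if (is.null(basis)) basis <- build_hahn_basis(nrow(m))
  basis$table %*% m %*% t(basis$table)
}

#' @rdname hahn_transform
#' @export
hahn_reconstruct <- function(H, basis) {
  t(basis$table) %*% H %*% basis$table
}
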