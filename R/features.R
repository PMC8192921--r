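#' Names of the 102 feature slots
#'
#' Layout: raw, central, and Hahn moments (10 coefficients each) of the
#' sequence grid, of PRIM, and of RPRIM, followed by the frequency vector,
#' AAPIV, and RAAPIV (4 slots each): 9 x 10 + 3 x 4 = 102.
#'
#' @return Character vector of length 102.
#' @export
feature_slot_names <- function() {
  mom <- moment_names()
  c(
    paste0("grid_raw_", mom), paste0("grid_central_", mom), paste0("grid_hahn_", mom),
    paste0("prim_raw_", mom), paste0("prim_central_", mom), paste0("prim_hahn_", mom),
    paste0("rprim_raw_", mom), paste0("rprim_central_", mom), paste0("rprim_hahn_", mom),
    paste0("fv_", DNA_BASES), paste0("aapiv_", DNA_BASES), paste0("raapiv_", DNA_BASES)
  )
}

#' Featurization configuration
#'
#' @param mapping Base-to-integer encoding table (see [default_mapping]).
#' @param prim_convention `"signed"` or `"absolute"` (see [prim]).
#' @param hahn_a,hahn_b Hahn basis parameters (default 0).
#' @return List of class `feature_config`.
#' @export
feature_config <- function(mapping = default_mapping(),
                           prim_convention = c("signed", "absolute"),
                           hahn_a = 0, hahn_b = 0) {
  structure(list(mapping = check_mapping(mapping),
                 prim_convention = match.arg(prim_convention),
                 hahn_a = hahn_a, hahn_b = hahn_b),
            class = "feature_config")
}

moment_block <- function(m, basis) {
  c(as.numeric(raw_moments(m)),
    as.numeric(central_moments(m)$moments),
    as.numeric(hahn_moments(m, basis)))
}

#' Compute the 102-slot feature vector of one sequence
#'
#' Assembles, in a fixed documented order, the raw/central/Hahn moments of the
#' square-grid sequence image (grid side k = ceiling(sqrt(n)), Hahn basis of
#' side k), of the 4x4 PRIM, and of the 4x4 RPRIM (Hahn basis of side 4),
#' followed by the frequency vector, AAPIV, and RAAPIV. The result has length
#' 102 for every sequence length >= 4.
#'
#' @param seq [nt_sequence] or character scalar.
#' @param config A [feature_config].
#' @return Named numeric vector of length 102.
#' @examples
#' length(featurize("ACGTACGTACGTACGT"))
#' @export
featurize <- function(seq, config = feature_config()) {
  seq <- as_nt_sequence(seq)
  grid <- reshape_to_grid(encode_sequence(seq, config$mapping))
  basis_k <- build_hahn_basis(grid$k, config$hahn_a, config$hahn_b)
  basis_4 <- build_hahn_basis(4L, config$hahn_a, config$hahn_b)
  pm <- prim(seq, convention = config$prim_convention)
  rm_ <- rprim(seq, convention = config$prim_convention)
  zeta <- c(
    moment_block(grid$entries, basis_k),
    moment_block(matrix(as.numeric(pm), 4, 4), basis_4),
    moment_block(matrix(as.numeric(rm_), 4, 4), basis_4),
    frequency_vector(seq), aapiv(seq), raapiv(seq)
  )
  stats::setNames(zeta, feature_slot_names())
}

#' Build the design matrix of a labeled dataset
#'
#' One [featurize] row per sample, dataset order preserved, labels carried
#' through unchanged.
#'
#' @param data A [labeled_dataset].
#' @param config A [feature_config].
#' @return Object of class `feature_matrix`: list with `x` (n x 102 numeric
#'   matrix, column names = slot names, row names = sample ids), `labels`,
#'   `ids`, and `feature_names`.
#' @export
build_feature_matrix <- function(data, config = feature_config()) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- length(data$sequences)
  if (n == 0L) stop("dataset is empty", call. = FALSE)
  x <- matrix(NA_real_, n, 102L)
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- data$sequences[[i]]
    row <- tryCatch(featurize(s, config),
                    error = function(e) stop(sprintf("featurize failed for sample '%s': %s",
                                                    s$id, conditionMessage(e)),
                                             call. = FALSE))
    x[i, ] <- row
    ids[[i]] <- s$id
  }
  colnames(x) <- feature_slot_names()
  rownames(x) <- make.unique(ids)
  structure(list(x = x, labels = data$labels, ids = ids,
                 feature_names = feature_slot_names()),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%d driver, %d passenger)\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Delimited text with an `id` column, one column per named feature slot, and
#' a trailing `label` column; round-trips numerically.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV file path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = fm$ids, fm$x, label = fm$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "label")
  if (!all(need %in% names(df))) {
    stop("feature CSV must contain 'id' and 'label' columns", call. = FALSE)
  }
  feats <- setdiff(names(df), need)
  x <- as.matrix(df[, feats, drop = FALSE])
  rownames(x) <- make.unique(df$id)
  structure(list(x = x, labels = as.integer(df$label), ids = df$id,
                 feature_names = feats),
            class = "feature_matrix")
}

subset_feature_matrix <- function(fm, idx) {
  structure(list(x = fm$x[idx, , drop = FALSE], labels = fm$labels[idx],
                 ids = fm$ids[idx], feature_names = fm$feature_names),
            class = "feature_matrix")
}
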