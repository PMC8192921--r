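#' Classifier configuration
#'
#' Uniform contract over the three backends. Hyperparameters default to
#' conventional values (the method's contribution is the featurization, not
#' classifier tuning): rf = 100 trees, mtry = floor(sqrt(p)), nodes grown to
#' purity; svm = RBF kernel least-squares SVM with cost 1 and gamma = 1/p on
#' standardized features; nn = one hidden layer of 32 tanh units trained by
#' full-batch Adam for up to 500 iterations on standardized features.
#'
#' @param backend One of `"rf"`, `"svm"`, `"nn"`.
#' @param seed Integer; fully determines any stochastic element of training.
#' @param standardize Standardize features from training rows? Default: FALSE
#'   for rf, TRUE for svm and nn.
#' @param ... Backend hyperparameters: `ntree`, `mtry`, `min_node` (rf);
#'   `cost`, `gamma` (svm); `hidden`, `maxit`, `learn_rate`, `l2` (nn).
#' @return List of class `model_config`.
#' @export
model_config <- function(backend = c("rf", "svm", "nn"), seed = 1L,
                         standardize = NULL, ...) {
  backend <- match.arg(backend)
  params <- list(...)
  defaults <- switch(backend,
    rf  = list(ntree = 100L, mtry = NULL, min_node = 1L),
    svm = list(cost = 1, gamma = NULL),
    nn  = list(hidden = 32L, maxit = 500L, learn_rate = 0.01, l2 = 1e-4)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown hyperparameter(s) for backend '%s': %s",
                 backend, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(params)] <- params
  if (is.null(standardize)) standardize <- backend %in% c("svm", "nn")
  structure(list(backend = backend, seed = as.integer(seed),
                 standardize = standardize, params = defaults),
            class = "model_config")
}

standardizer_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mean = mu, sd = sdev)
}

standardizer_apply <- function(x, sc) {
  sweep(sweep(x, 2L, sc$mean, "-"), 2L, sc$sd, "/")
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

fit_svm <- function(x, y, cost, gamma) {
  # least-squares SVM with bias: [0 1'; 1 K + I/C][b; alpha] = [0; y(+/-1)]
  n <- nrow(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  K <- rbf_kernel(x, x, gamma)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / cost))
  rhs <- c(0, 2 * y - 1)
  coef <- solve(M, rhs)
  list(alpha = coef[-1L], b = coef[[1L]], sv = x, gamma = gamma)
}

svm_decision <- function(fit, x) {
  as.numeric(rbf_kernel(x, fit$sv, fit$gamma) %*% fit$alpha + fit$b)
}

fit_nn <- function(x, y, hidden, maxit, learn_rate, l2) {
  n <- nrow(x); p <- ncol(x); h <- hidden
  W1 <- matrix(stats::rnorm(p * h, sd = sqrt(1 / p)), p, h)
  b1 <- rep(0, h)
  W2 <- matrix(stats::rnorm(h, sd = sqrt(1 / h)), h, 1)
  b2 <- 0
  mom <- lapply(list(W1, b1, W2, b2), function(z) z * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (it in seq_len(maxit)) {
    A1 <- tanh(sweep(x %*% W1, 2L, b1, "+"))
    z2 <- as.numeric(A1 %*% W2) + b2
    prob <- stats::plogis(z2)
    dz2 <- (prob - y) / n
    gW2 <- crossprod(A1, dz2) + l2 * W2
    gb2 <- sum(dz2)
    dA1 <- outer(dz2, as.numeric(W2)) * (1 - A1^2)
    gW1 <- crossprod(x, dA1) + l2 * W1
    gb1 <- colSums(dA1)
    grads <- list(gW1, gb1, gW2, gb2)
    for (j in 1:4) {
      mom[[j]] <- beta1 * mom[[j]] + (1 - beta1) * grads[[j]]
      vel[[j]] <- beta2 * vel[[j]] + (1 - beta2) * grads[[j]]^2
      step <- learn_rate * (mom[[j]] / (1 - beta1^it)) /
        (sqrt(vel[[j]] / (1 - beta2^it)) + eps)
      if (j == 1) W1 <- W1 - step
      else if (j == 2) b1 <- b1 - step
      else if (j == 3) W2 <- W2 - step
      else b2 <- b2 - step
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

nn_scores <- function(fit, x) {
  A1 <- tanh(sweep(x %*% fit$W1, 2L, fit$b1, "+"))
  stats::plogis(as.numeric(A1 %*% fit$W2) + fit$b2)
}

#' Train a classifier on a feature matrix
#'
#' Deterministic given `(matrix, config)` including the config seed. Any
#' standardization parameters are learned from the training rows only and
#' stored in the model.
#'
#' @param fm A `feature_matrix` (see [build_feature_matrix]).
#' @param config A [model_config].
#' @return Object of class `dg_model`.
#' @export
train_model <- function(fm, config = model_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "model_config"))
  y <- fm$labels
  if (length(unique(y)) < 2L) {
    stop("training requires both classes to be present", call. = FALSE)
  }
  x <- fm$x
  if (anyNA(x) || any(!is.finite(x))) stop("feature matrix contains non-finite values", call. = FALSE)
  scaling <- NULL
  if (config$standardize) {
    scaling <- standardizer_fit(x)
    x <- standardizer_apply(x, scaling)
  }
  p <- config$params
  fit <- with_seed(config$seed, switch(config$backend,
    rf = rf_train_cpp(x, as.integer(y),
                      ntree = as.integer(p$ntree),
                      mtry = as.integer(p$mtry %||% max(1L, floor(sqrt(ncol(x))))),
                      min_node = as.integer(p$min_node)),
    svm = fit_svm(x, y, cost = p$cost, gamma = p$gamma),
    nn = fit_nn(x, y, hidden = p$hidden, maxit = p$maxit,
                learn_rate = p$learn_rate, l2 = p$l2)
  ))
  structure(list(backend = config$backend, fit = fit,
                 feature_names = fm$feature_names, config = config,
                 scaling = scaling),
            class = "dg_model")
}

#' @export
print.dg_model <- function(x, ...) {
  cat(sprintf("<dg_model> backend = %s, %d features, seed = %d\n",
              x$backend, length(x$feature_names), x$config$seed))
  invisible(x)
}

#' Predict driver/passenger labels and scores
#'
#' Scores are class-1 (driver) membership scores in \[0, 1\], monotone in
#' classifier confidence and usable for ROC analysis: the fraction of trees
#' voting driver (rf), a logistic map of the decision value (svm), or the
#' output activation (nn). Labels are `score >= threshold`. Prediction
#' refuses matrices whose feature names do not match training (order checked).
#'
#' @param object A `dg_model`.
#' @param fm A `feature_matrix` or bare numeric matrix with matching columns.
#' @param threshold Decision threshold on the score (default 0.5).
#' @param ... Unused.
#' @return List with `labels` (integer 0/1) and `scores` (numeric in \[0,1\]).
#' @export
predict.dg_model <- function(object, fm, threshold = 0.5, ...) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  nm <- if (inherits(fm, "feature_matrix")) fm$feature_names else colnames(fm)
  if (is.null(nm) || !identical(nm, object$feature_names)) {
    stop("feature names of the prediction matrix do not match training (order matters)",
         call. = FALSE)
  }
  if (!is.null(object$scaling)) x <- standardizer_apply(x, object$scaling)
  scores <- switch(object$backend,
    rf = rf_predict_cpp(object$fit, x),
    svm = stats::plogis(svm_decision(object$fit, x)),
    nn = nn_scores(object$fit, x)
  )
  scores <- pmin(pmax(as.numeric(scores), 0), 1)
  list(labels = as.integer(scores >= threshold), scores = scores)
}

#' Save / load a trained model
#'
#' The model is serialized next to a JSON sidecar recording backend,
#' hyperparameters, seed, feature names, and package version; loading
#' verifies the sidecar against the deserialized model.
#'
#' @param model A `dg_model`.
#' @param path Model file path; the sidecar is written to `<path>.json`.
#' @return `save_model` returns `path` invisibly; `load_model` a `dg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dg_model"))
  saveRDS(model, path)
  sidecar <- list(backend = model$backend,
                  hyperparameters = model$config$params,
                  seed = model$config$seed,
                  standardize = model$config$standardize,
                  feature_names = model$feature_names,
                  version = as.character(utils::packageVersion("drivergene")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("model sidecar not found: %s", sidecar_path), call. = FALSE)
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(sidecar$backend, model$backend) ||
      !identical(as.character(sidecar$feature_names),
                 as.character(model$feature_names))) {
    stop("model sidecar does not match serialized model", call. = FALSE)
  }
  model
}
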