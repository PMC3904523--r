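#' Model specification
#'
#' The default family is Gaussian-process regression/classification with a
#' stationary radial-basis kernel (via kernlab). The kernel inverse width
#' is fitted automatically from the data by a seeded median-distance
#' heuristic unless given; the observation-noise variance defaults to a
#' fixed fraction of the target variance.
#'
#' @param family `"gp"` (Gaussian process, default) or `"linear"` (an
#'   ordinary least-squares fit, useful as a diagnostic baseline).
#' @param sigma RBF kernel inverse width; `NULL` fits it from the data.
#' @param noiseVar observation-noise variance for GP regression; `NULL`
#'   uses `noiseFrac * var(y)`.
#' @param noiseFrac fraction of target variance used as noise variance
#'   when `noiseVar` is `NULL` (default 0.1).
#' @param corThreshold absolute-correlation threshold for noise reduction
#'   (default 0.999).
#' @param dropCorrelated drop one of each near-duplicate feature pair
#'   during noise reduction (default TRUE).
#' @return list of class `modelSpec`.
#' @export
modelSpec <- function(family = "gp", sigma = NULL, noiseVar = NULL,
                      noiseFrac = 0.1, corThreshold = 0.999,
                      dropCorrelated = TRUE) {
  stopifnot(family %in% c("gp", "linear"))
  structure(list(family = family, sigma = sigma, noiseVar = noiseVar,
                 noiseFrac = noiseFrac, corThreshold = corThreshold,
                 dropCorrelated = dropCorrelated), class = "modelSpec")
}

#' Noise reduction of a signature matrix
#'
#' Drops zero-variance columns and (optionally) one column of each pair
#' with absolute Pearson correlation above the threshold, keeping the
#' earlier column. The kept-feature mask is returned so that test data
#' can be reduced identically by name.
#'
#' @param x numeric matrix with named columns.
#' @param corThreshold absolute-correlation threshold (default 0.999).
#' @param dropCorrelated logical.
#' @return list with `x` (reduced matrix) and `mask` (logical over the
#'   input columns).
#' @export
noiseReduction <- function(x, corThreshold = 0.999, dropCorrelated = TRUE) {
  if (nrow(x) < 2L) stop("noise reduction needs at least 2 rows")
  v <- apply(x, 2L, var)
  mask <- v > 0
  if (dropCorrelated && sum(mask) > 1L) {
    xs <- x[, mask, drop = FALSE]
    cm <- abs(cor(xs))
    cm[!upper.tri(cm)] <- 0
    drop <- rep(FALSE, ncol(xs))
    for (j in seq_len(ncol(xs)))
      if (!drop[j]) drop <- drop | (cm[j, ] > corThreshold & !drop[j])
    keepIdx <- which(mask)
    mask[keepIdx[drop]] <- FALSE
  }
  if (!any(mask)) stop("noise reduction removed every feature")
  list(x = x[, mask, drop = FALSE], mask = mask)
}

# deterministic RBF inverse-width heuristic: median squared distance
# between (up to 300 seeded-sampled) standardized rows
fitSigma <- function(xs, seed) {
  n <- nrow(xs)
  idx <- if (n > 300L) withr_seed(seed, sample.int(n, 300L)) else seq_len(n)
  d2 <- as.vector(stats::dist(xs[idx, , drop = FALSE]))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) med <- 1
  1 / med
}

# run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

prepareFeatures <- function(x, spec) {
  nr <- noiseReduction(x, spec$corThreshold, spec$dropCorrelated)
  ctr <- colMeans(nr$x)
  scl <- apply(nr$x, 2L, sd)
  scl[scl == 0] <- 1
  xs <- scale(nr$x, center = ctr, scale = scl)
  list(xs = xs, mask = nr$mask, center = ctr, scale = scl)
}

#' Train a regression model on signatures
#'
#' Fits the default Gaussian-process regressor (stationary RBF kernel,
#' seeded automatic scale fitting) to predict free-energy changes in
#' kcal/mol. Noise reduction and feature standardization are fitted on the
#' training matrix and stored in the model so new data is transformed
#' identically, aligned by feature name. Deterministic for a fixed seed;
#' row order does not affect predictions.
#'
#' @param x numeric feature matrix, named columns (rows = mutations).
#' @param y numeric targets (kcal/mol), finite.
#' @param spec a [modelSpec()].
#' @param seed integer seed.
#' @return a [SignatureModel-class].
#' @export
trainRegressor <- function(x, y, spec = modelSpec(), seed = 1L) {
  if (any(!is.finite(y))) stop("targets must be finite")
  if (nrow(x) != length(y)) stop("rows of x must match length of y")
  prep <- prepareFeatures(x, spec)
  fit <- fitCore(prep$xs, y, spec, seed, task = "regression")
  new("SignatureModel", fit = fit$fit, family = spec$family,
      task = "regression", featureNames = colnames(x), mask = prep$mask,
      center = prep$center, scale = prep$scale, levels = character(0),
      seed = as.integer(seed))
}

#' Train a direction-of-change classifier on signatures
#'
#' As [trainRegressor()] but for the classification task (stabilizing vs
#' destabilizing); the default family is the Gaussian-process classifier.
#'
#' @param x numeric feature matrix, named columns.
#' @param labels character/factor class labels (two classes).
#' @param spec a [modelSpec()].
#' @param seed integer seed.
#' @return a [SignatureModel-class].
#' @export
trainClassifier <- function(x, labels, spec = modelSpec(), seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("need exactly two classes")
  if (nrow(x) != length(labels)) stop("rows of x must match labels")
  prep <- prepareFeatures(x, spec)
  fit <- fitCore(prep$xs, labels, spec, seed, task = "classification")
  new("SignatureModel", fit = fit$fit, family = spec$family,
      task = "classification", featureNames = colnames(x),
      mask = prep$mask, center = prep$center, scale = prep$scale,
      levels = levels(labels), seed = as.integer(seed))
}

fitCore <- function(xs, y, spec, seed, task) {
  if (spec$family == "linear") {
    df <- data.frame(y = if (task == "classification")
      as.integer(y == levels(y)[2L]) else y, xs)
    return(list(fit = stats::lm(y ~ ., data = df)))
  }
  sigma <- spec$sigma %||% fitSigma(xs, seed)
  if (task == "regression") {
    nv <- spec$noiseVar %||% max(spec$noiseFrac * var(y), 1e-8)
    # exact conjugate GP posterior mean: with a Gaussian likelihood the
    # predictive mean is K*(K + s2 I)^-1 (y - m) + m, computed directly
    # so the noise variance is not floor-limited
    kern <- kernlab::rbfdot(sigma = sigma)
    K <- kernlab::kernelMatrix(kern, xs)
    n <- nrow(xs)
    ym <- mean(y)
    alpha <- solve(K + nv * diag(n), y - ym)
    fit <- structure(list(xtrain = xs, alpha = as.numeric(alpha),
                          ym = ym, sigma = sigma, noiseVar = nv),
                     class = "gpExactFit")
  } else {
    fit <- withr_seed(seed, kernlab::gausspr(
      x = xs, y = y, type = "classification", kernel = "rbfdot",
      kpar = list(sigma = sigma), scaled = FALSE))
  }
  list(fit = fit)
}

predictGpExact <- function(fit, xs) {
  kern <- kernlab::rbfdot(sigma = fit$sigma)
  Ks <- kernlab::kernelMatrix(kern, xs, fit$xtrain)
  as.numeric(Ks %*% fit$alpha + fit$ym)
}

#' Predict from a trained signature model
#'
#' New data is aligned to the training layout by feature name (column
#' order is irrelevant; a missing feature is an explicit error), reduced
#' with the stored mask and standardization, and passed to the fitted
#' model.
#'
#' @param object a [SignatureModel-class].
#' @param newdata numeric matrix with named columns.
#' @param type `"response"` (numeric prediction or class label) or
#'   `"score"` (classification only: probability of the second class
#'   level).
#' @return numeric vector, factor, or score vector.
#' @export
setMethod("predict", "SignatureModel",
  function(object, newdata, type = "response") {
  if (is.null(colnames(newdata)))
    stop("newdata must carry feature names")
  missing <- setdiff(object@featureNames, colnames(newdata))
  if (length(missing))
    stop("newdata lacks required features: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...")
  x <- newdata[, object@featureNames, drop = FALSE]
  xs <- scale(x[, object@mask, drop = FALSE], center = object@center,
              scale = object@scale)
  if (object@family == "linear") {
    p <- stats::predict(object@fit, newdata = data.frame(xs))
    if (object@task == "classification") {
      if (type == "score") return(as.numeric(p))
      return(factor(object@levels[1L + (p > 0.5)],
                    levels = object@levels))
    }
    return(as.numeric(p))
  }
  if (object@task == "regression")
    return(if (inherits(object@fit, "gpExactFit"))
      predictGpExact(object@fit, xs)
    else as.numeric(predict(object@fit, xs)))
  if (type == "score") {
    pr <- predict(object@fit, xs, type = "probabilities")
    return(as.numeric(pr[, object@levels[2L]]))
  }
  factor(as.character(predict(object@fit, xs)),
         levels = object@levels)
})
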