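# Temporal Type Disambiguation (TTD): DATE vs DURATION.
#
# A linear support vector machine over phrase feature vectors decides
# whether a relative temporal phrase is a point in time (DATE, the positive
# class, +1) or a span (DURATION, the negative class, -1). No SVM library
# is assumed: the model is an L2-regularised squared-hinge linear SVM
# minimised with L-BFGS from a zero start, which is deterministic and
# reproducible without a seed. The squared hinge is used for smoothness;
# with a linear kernel and moderate C its decision boundary is equivalent
# in practice to the standard hinge for this binary task.

TTD_LEVELS <- c("DATE", "DURATION")

#' Encode DATE/DURATION labels as +1/-1
#'
#' DATE is the positive class (+1) and DURATION the negative class (-1).
#'
#' @param labels character vector of `"DATE"`/`"DURATION"`.
#' @return Numeric vector of +1/-1.
#' @export
ttd_encode <- function(labels) {
  if (!all(labels %in% TTD_LEVELS))
    stop("labels must be DATE or DURATION")
  ifelse(labels == "DATE", 1, -1)
}

#' Decode +1/-1 back to DATE/DURATION
#'
#' @param y numeric vector; non-negative values decode to DATE.
#' @return Character vector.
#' @export
ttd_decode <- function(y) {
  ifelse(y >= 0, "DATE", "DURATION")
}

feature_matrix <- function(features) {
  if (is.matrix(features)) {
    return(list(x = features, variant = NA_character_,
                dim = ncol(features)))
  }
  if (inherits(features, "phrase_feature")) features <- list(features)
  variants <- unique(vapply(features, function(f) f$variant, ""))
  dims <- unique(vapply(features, function(f) f$dim, 0L))
  if (length(variants) != 1L || length(dims) != 1L)
    stop("features mix variants or dimensions: ",
         paste(variants, collapse = "/"), ", dims ",
         paste(dims, collapse = "/"))
  list(x = do.call(rbind, lapply(features, function(f) f$vector)),
       variant = variants, dim = dims)
}

#' Fit the TTD linear SVM
#'
#' Trains a linear SVM classifying phrase features as DATE (+1) or DURATION
#' (-1). Training minimises `0.5 ||w||^2 + C * sum(max(0, 1 - y f(x))^2)`
#' by L-BFGS from a zero start, so the fit is deterministic for a given
#' input.
#'
#' @param features a list of `phrase_feature`s (uniform variant and
#'   dimension) or a numeric matrix with one row per phrase.
#' @param labels character vector of `"DATE"`/`"DURATION"`, one per phrase;
#'   both classes must be present.
#' @param C soft-margin cost (default 1, linear kernel).
#' @param provider_id,seed training metadata recorded for reproducibility
#'   of the feature pipeline (the fit itself is deterministic).
#' @param maxit L-BFGS iteration cap.
#' @return An object of class `ttd_svm` with weights `w`, intercept `b`,
#'   the feature `variant`/`dim` contract and training metadata.
#' @export
ttd_svm <- function(features, labels, C = 1, provider_id = NA_character_,
                    seed = NA_integer_, maxit = 200L) {
  fm <- feature_matrix(features)
  x <- fm$x
  if (nrow(x) != length(labels))
    stop("number of features and labels differ")
  if (length(unique(labels)) < 2L)
    stop("training data must contain both DATE and DURATION examples")
  y <- ttd_encode(labels)
  d <- ncol(x)
  obj <- function(theta) {
    w <- theta[-1L]; b <- theta[1L]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(theta) {
    w <- theta[-1L]; b <- theta[1L]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    coefm <- -2 * C * y * m
    c(sum(coefm), w + drop(crossprod(x, coefm)))
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  structure(list(w = fit$par[-1L], b = fit$par[1L],
                 variant = fm$variant, dim = d, C = C,
                 levels = TTD_LEVELS,
                 n_train = nrow(x),
                 metadata = list(provider_id = provider_id, seed = seed),
                 converged = fit$convergence == 0L),
            class = "ttd_svm")
}

#' @export
print.ttd_svm <- function(x, ...) {
  cat(sprintf(
    "<ttd_svm> linear SVM, %d-dim %s features, C = %g, %d training phrases\n",
    x$dim, ifelse(is.na(x$variant), "matrix", x$variant), x$C, x$n_train))
  if (!is.na(x$metadata$provider_id))
    cat("  provider:", x$metadata$provider_id, "\n")
  invisible(x)
}

#' @export
coef.ttd_svm <- function(object, ...) {
  c(intercept = object$b, stats::setNames(object$w,
                                          paste0("f", seq_along(object$w))))
}

check_feature_dims <- function(model, fm) {
  if (fm$dim != model$dim)
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 fm$dim, model$dim))
  if (!is.na(fm$variant) && !is.na(model$variant) &&
      fm$variant != model$variant)
    stop(sprintf("feature variant %s does not match model variant %s",
                 fm$variant, model$variant))
}

#' Predict DATE/DURATION for phrase features
#'
#' @param object a fitted [ttd_svm()].
#' @param features a `phrase_feature`, list thereof, or numeric matrix;
#'   variant and dimension must match the model.
#' @param decision return the raw decision values instead of labels.
#' @param ... unused.
#' @return Character vector of `"DATE"`/`"DURATION"` (or decision values).
#' @export
predict.ttd_svm <- function(object, features, decision = FALSE, ...) {
  fm <- feature_matrix(features)
  check_feature_dims(object, fm)
  f <- drop(fm$x %*% object$w) + object$b
  if (decision) f else ttd_decode(f)
}

#' Classify one phrase feature
#'
#' Single-phrase front end used by the converter: the +1 side of the
#' decision function is DATE, the -1 side DURATION.
#'
#' @param model a fitted [ttd_svm()].
#' @param feature one `phrase_feature`.
#' @return `"DATE"` or `"DURATION"`.
#' @export
predict_type <- function(model, feature) {
  stopifnot(inherits(model, "ttd_svm"))
  unname(predict(model, feature)[1])
}

#' Serialize a TTD model to JSON
#'
#' Plain-text, versioned serialization carrying the weights and the
#' provider/seed metadata needed to rebuild the feature pipeline.
#'
#' @param model a `ttd_svm`.
#' @param path output file.
#' @export
write_ttd_model <- function(model, path) {
  payload <- list(format = "ternr-ttd", version = 1L,
                  w = model$w, b = model$b, variant = model$variant,
                  dim = model$dim, C = model$C, n_train = model$n_train,
                  metadata = model$metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TTD model written by [write_ttd_model()]
#'
#' @param path JSON file.
#' @return A `ttd_svm`.
#' @export
read_ttd_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ternr-ttd"))
    stop("not a ternr TTD model file")
  structure(list(w = as.numeric(p$w), b = as.numeric(p$b),
                 variant = p$variant, dim = as.integer(p$dim),
                 C = p$C, levels = TTD_LEVELS, n_train = p$n_train,
                 metadata = p$metadata, converged = NA),
            class = "ttd_svm")
}
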