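# Pluggable classifier backends behind a train/predict contract. Tree
# ensembles are delegated to randomForest and xgboost; the registry accepts
# user backends (e.g. for boosting variants without an R implementation
# here).

.backend_registry <- new.env(parent = emptyenv())

#' Register a model backend
#'
#' A backend is a list with functions `train(x, y, params, seed)` returning a
#' fitted handle and `predict(handle, x)` returning a factor of class labels,
#' plus a `defaults` parameter list.
#'
#' @param id backend identifier.
#' @param backend the backend list.
#' @return `id`, invisibly.
#' @export
register_model_backend <- function(id, backend) {
  stopifnot(is.list(backend), is.function(backend$train),
            is.function(backend$predict))
  assign(id, backend, envir = .backend_registry)
  invisible(id)
}

get_backend <- function(id) {
  if (!exists(id, envir = .backend_registry)) {
    hint <- if (id == "ordered_boosting")
      "; no ordered-boosting (CatBoost-style) R backend is available -- register one via register_model_backend()"
    else ""
    thal_error("thal_model_error",
               sprintf("no backend registered for algorithm '%s'%s", id, hint))
  }
  get(id, envir = .backend_registry)
}

#' List registered model backends
#' @return character vector of backend ids.
#' @export
list_model_backends <- function() sort(ls(envir = .backend_registry))

#' Model specification
#'
#' @param algorithm backend id (`"random_forest"`,
#'   `"extreme_gradient_boosting"`, or a user-registered id).
#' @param params named list of hyperparameters overriding backend defaults.
#' @param grid optional named list of candidate value vectors for
#'   [grid_search()].
#' @param seed seed used when fitting.
#' @return a `model_spec`.
#' @export
model_spec <- function(algorithm, params = list(), grid = list(), seed = 1L) {
  get_backend(algorithm)  # fail fast on unknown ids
  structure(list(algorithm = algorithm, params = params, grid = grid,
                 seed = as.integer(seed)),
            class = "model_spec")
}

train_model <- function(spec, x, y) {
  be <- get_backend(spec$algorithm)
  params <- utils::modifyList(be$defaults, spec$params)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  handle <- be$train(x, factor(y), params, spec$seed)
  structure(list(algorithm = spec$algorithm, handle = handle,
                 params = params, features = colnames(x),
                 classes = levels(factor(y))),
            class = "thal_model")
}

#' Predict class labels from a fitted model
#' @param object a `thal_model` from the harness.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.thal_model <- function(object, newdata, ...) {
  be <- get_backend(object$algorithm)
  be$predict(object$handle, newdata[, object$features, drop = FALSE])
}

# -- randomForest backend ----------------------------------------------------

rf_backend <- list(
  defaults = list(ntree = 300L, mtry = NULL),
  train = function(x, y, params, seed) {
    args <- list(x = as.data.frame(x), y = y, ntree = params$ntree)
    if (!is.null(params$mtry)) args$mtry <- params$mtry
    list(fit = do.call(randomForest::randomForest, args), classes = levels(y))
  },
  predict = function(handle, x) {
    stats::predict(handle$fit, as.data.frame(x))
  }
)

# -- xgboost backend ---------------------------------------------------------

xgb_backend <- list(
  defaults = list(nrounds = 60L, eta = 0.3, max_depth = 4L,
                  subsample = 1, colsample_bytree = 1),
  train = function(x, y, params, seed) {
    k <- nlevels(y)
    lab <- as.integer(y) - 1L
    pars <- list(eta = params$eta, max_depth = params$max_depth,
                 subsample = params$subsample,
                 colsample_bytree = params$colsample_bytree,
                 nthread = 1L, seed = seed)
    if (k == 2) {
      pars$objective <- "binary:logistic"
    } else {
      pars$objective <- "multi:softprob"
      pars$num_class <- k
    }
    fit <- xgboost::xgb.train(params = pars,
                              data = xgboost::xgb.DMatrix(as.matrix(x),
                                                          label = lab),
                              nrounds = params$nrounds, verbose = 0)
    list(fit = fit, classes = levels(y), k = k)
  },
  predict = function(handle, x) {
    p <- stats::predict(handle$fit, xgboost::xgb.DMatrix(as.matrix(x)))
    if (handle$k == 2) {
      idx <- as.integer(p > 0.5) + 1L
    } else {
      if (is.null(dim(p))) p <- matrix(p, ncol = handle$k, byrow = TRUE)
      idx <- max.col(p, ties.method = "first")
    }
    factor(handle$classes[idx], levels = handle$classes)
  }
)
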