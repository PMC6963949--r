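#' Neural-network configuration
#'
#' Settings for the single-hidden-layer classifier that seeds rule
#' extraction.  The network has sigmoidal hidden and output units and is
#' fitted by minimizing cross-entropy plus an L2 weight penalty
#' (\code{weight_penalty}), the penalty that later makes irrelevant
#' inputs recognisable by their small aggregate weights.
#'
#' @param hidden_units hidden-layer size (>= 1); small networks keep the
#'   downstream rules concise.
#' @param epochs maximum optimizer iterations.
#' @param weight_penalty L2 penalty coefficient (decay).
#' @param learning_rate accepted for interface compatibility with
#'   stochastic backpropagation trainers; the quasi-Newton optimizer
#'   used here does not consume it.
#' @param init_seed seed for weight initialization.
#' @param pruning_accuracy_tolerance maximum training-accuracy drop
#'   (fraction) tolerated while pruning input attributes.
#' @param pruning_epochs optimizer iterations for the short retrains
#'   during attribute pruning.
#' @return a \code{net_config} list.
#' @export
net_config <- function(hidden_units = 4, epochs = 200,
                       weight_penalty = 5e-4, learning_rate = NULL,
                       init_seed = 1,
                       pruning_accuracy_tolerance = 0.01,
                       pruning_epochs = 100) {
  stopifnot(hidden_units >= 1, epochs >= 0, weight_penalty >= 0,
            pruning_accuracy_tolerance >= 0, pruning_epochs >= 1)
  structure(list(hidden_units = hidden_units, epochs = epochs,
                 weight_penalty = weight_penalty,
                 learning_rate = learning_rate, init_seed = init_seed,
                 pruning_accuracy_tolerance = pruning_accuracy_tolerance,
                 pruning_epochs = pruning_epochs),
            class = "net_config")
}

# Per-attribute design-matrix encoding: continuous columns standardized
# with training mean/sd, categorical attributes expanded to one column
# per level (full indicator coding keeps the attribute <-> column map
# trivial for weight aggregation).
encode_design <- function(data, attrs, schema, centers = NULL) {
  cols <- list()
  groups <- character(0)
  if (is.null(centers)) {
    centers <- list()
    fit_centers <- TRUE
  } else fit_centers <- FALSE
  for (a in attrs) {
    kind <- schema[[a]]$kind
    if (kind == "continuous") {
      x <- as.numeric(data[[a]])
      if (fit_centers) {
        s <- stats::sd(x)
        centers[[a]] <- c(mean = mean(x), sd = if (is.finite(s) && s > 0) s else 1)
      }
      cc <- centers[[a]]
      cols[[a]] <- (x - cc[["mean"]]) / cc[["sd"]]
      groups <- c(groups, a)
    } else {
      lv <- schema[[a]]$levels
      for (l in lv) {
        nm <- paste0(a, "=", l)
        cols[[nm]] <- as.numeric(as.character(data[[a]]) == l)
        groups <- c(groups, a)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, groups = groups, centers = centers)
}

#' Train the hidden-layer network
#'
#' Fits a single-hidden-layer sigmoidal classifier on the given
#' attributes (all schema predictors by default).  Continuous inputs are
#' standardized and categorical inputs one-hot encoded internally;
#' weight initialization is seeded, so the fit is reproducible.  With
#' \code{epochs = 0} the network is returned at its random
#' initialization.
#'
#' @param cohort labelled cohort.
#' @param config a [net_config()].
#' @param attrs attribute subset to use (default: all predictors).
#' @return an object of class \code{rerx_net}: the \code{nnet} fit,
#'   active attributes, encoding parameters and training accuracy.
#' @export
train_network <- function(cohort, config = net_config(),
                          attrs = NULL) {
  cohort <- as.data.frame(cohort)
  schema <- attr(cohort, "schema") %||% infer_schema(cohort)
  attrs <- attrs %||% intersect(names(schema), names(cohort))
  y <- factor(cohort$class)
  if (nlevels(droplevels(y)) < 2)
    stop("train_network: cohort must contain both classes")
  enc <- encode_design(cohort, attrs, schema)
  target <- as.numeric(y == levels(y)[2])
  fit <- with_seed(config$init_seed, {
    nnet::nnet(enc$X, target, size = config$hidden_units,
               decay = config$weight_penalty, entropy = TRUE,
               maxit = max(config$epochs, 0), trace = FALSE,
               MaxNWts = 10000, rang = 0.5)
  })
  if (any(!is.finite(fit$wts)))
    stop("train_network: optimization produced non-finite weights ",
         "(value = ", fit$value, "); lower the learning settings or penalty")
  net <- structure(list(fit = fit, active_attributes = attrs,
                        schema = schema, centers = enc$centers,
                        groups = enc$groups, levels = levels(y),
                        config = config),
                   class = "rerx_net")
  net$accuracy <- mean(predict(net, cohort) == as.character(y))
  net
}

#' @export
predict.rerx_net <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  enc <- encode_design(newdata, object$active_attributes, object$schema,
                       centers = object$centers)
  p <- as.numeric(stats::predict(object$fit, enc$X))
  if (type == "prob") return(p)
  ifelse(p > 0.5, object$levels[2], object$levels[1])
}

# aggregate |input weight| per attribute (summed over the attribute's
# design columns and all hidden units)
attribute_weight_magnitude <- function(net) {
  fit <- net$fit
  p <- fit$n[1]; h <- fit$n[2]
  W <- matrix(fit$wts[seq_len((p + 1) * h)], nrow = p + 1)  # rows: bias, inputs
  w_in <- abs(W[-1, , drop = FALSE])
  agg <- tapply(rowSums(w_in), net$groups, sum)
  agg[unique(net$groups)]
}

#' Prune irrelevant input attributes from a trained network
#'
#' Iteratively removes active attributes in order of smallest aggregate
#' input-weight magnitude: each round, the candidates with the smallest
#' magnitudes are tried in turn (up to three, so a mildly informative
#' attribute cannot shield a noise attribute behind it), the network is
#' retrained briefly without the candidate, and the first removal that
#' keeps training accuracy within \code{tolerance} of the original
#' (unpruned) accuracy is accepted.  Stops when no candidate passes or
#' a single attribute remains.
#'
#' @param net a trained \code{rerx_net}.
#' @param cohort the training cohort.
#' @param tolerance maximum accuracy drop; defaults to the network
#'   config's \code{pruning_accuracy_tolerance}.
#' @return the pruned \code{rerx_net} (possibly the input unchanged).
#' @export
prune_attributes <- function(net, cohort,
                             tolerance = net$config$pruning_accuracy_tolerance) {
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0)
    stop("prune_attributes: tolerance must be a non-negative number")
  ref_acc <- net$accuracy
  cfg <- net$config
  cfg$epochs <- cfg$pruning_epochs
  current <- net
  repeat {
    if (length(current$active_attributes) <= 1) break
    mag <- sort(attribute_weight_magnitude(current))
    accepted <- FALSE
    for (drop_attr in names(mag)[seq_len(min(3, length(mag)))]) {
      trial_attrs <- setdiff(current$active_attributes, drop_attr)
      trial <- train_network(cohort, cfg, attrs = trial_attrs)
      if (trial$accuracy >= ref_acc - tolerance) {
        current <- trial
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  current
}

#' @export
print.rerx_net <- function(x, ...) {
  cat(sprintf("Hidden-layer network: %d hidden units, %d/%d active attributes, training accuracy %.3f\n",
              x$config$hidden_units, length(x$active_attributes),
              length(x$schema), x$accuracy))
  cat("active:", paste(x$active_attributes, collapse = ", "), "\n")
  invisible(x)
}
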